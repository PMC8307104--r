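# Minimal single-record GenBank flat-file reader for annotated mitogenomes.
# Supports the feature keys used by mitogenome submissions (CDS, tRNA, rRNA,
# misc_feature, D-loop), simple and complement() locations, and the ORIGIN
# sequence block. Plain "gene" features are skipped as duplicates of the
# typed features.

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Every typed feature (CDS, tRNA, rRNA, misc_feature/D-loop) becomes one
#' feature-table row: CDS rows are categorised `PCG`, misc_feature/D-loop
#' rows `control`. Strand is mapped to `J` (forward) / `N` (`complement()`).
#' Initiation and termination codons of PCGs are derived from the sequence
#' slice (the termination codon is the trailing `length %% 3` bases when the
#' stop is incomplete, e.g. "T" or "TA"). When no feature names the control
#' region, the unannotated span between the end of the small rRNA and the
#' genome end is inferred as `AT_rich`.
#'
#' @param path Path to a GenBank flat file with a single record.
#' @return A `mito_record` (genome plus feature table).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stop("parse error: not a GenBank flat file: ", path, call. = FALSE)

  locus <- lines[grep("^LOCUS", lines)[1L]]
  circular <- grepl("circular", locus, ignore.case = TRUE)
  org <- sub("^ *ORGANISM *", "", lines[grep("^ {2,}ORGANISM", lines)[1L]])
  if (!length(org) || is.na(org)) org <- "unknown"
  acc <- sub("^ACCESSION *", "", lines[grep("^ACCESSION", lines)][1L])
  if (!length(acc) || is.na(acc)) acc <- sub(" .*", "", sub("^LOCUS *", "", locus))

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("parse error: missing sequence (no ORIGIN block)",
                         call. = FALSE)
  seq_lines <- lines[(ori[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L)
    stop("parse error: missing sequence", call. = FALSE)
  genome <- mito_genome(sequence, id = acc, species = org,
                        circular = circular)

  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start)) stop("parse error: no FEATURES block",
                                call. = FALSE)
  fl <- lines[(feat_start[1L] + 1L):(ori[1L] - 1L)]
  # feature key lines have the key at column 6
  key_idx <- grep("^ {3,5}\\S", fl)
  keep_keys <- c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop")
  rows <- list()
  for (j in seq_along(key_idx)) {
    i0 <- key_idx[j]
    i1 <- if (j < length(key_idx)) key_idx[j + 1L] - 1L else length(fl)
    key <- sub("^ +", "", sub("^( {3,5}\\S+).*", "\\1", fl[i0]))
    if (!key %in% keep_keys) next
    block <- fl[i0:i1]
    loc <- sub("^ {3,5}\\S+ +", "", block[1L])
    strand <- if (grepl("complement", loc)) "N" else "J"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
    if (length(nums) < 2L)
      stop("parse error: unsupported location: ", loc, call. = FALSE)
    start <- min(nums); end <- max(nums)
    if (end > genome$length)
      stop("coordinate error: feature beyond sequence length", call. = FALSE)
    qual <- function(name) {
      hit <- grep(paste0("^/", name, "="), sub("^ +", "", block))
      if (!length(hit)) return(NA_character_)
      gsub("\"", "", sub(paste0("^/", name, "="), "",
                         sub("^ +", "", block[hit[1L]])))
    }
    nm <- qual("gene")
    if (is.na(nm)) nm <- qual("product")
    if (is.na(nm)) nm <- paste0(key, "_", start)
    anticodon <- NA_character_
    if (key == "tRNA") {
      ac <- qual("anticodon")
      if (!is.na(ac)) {
        m <- regmatches(ac, regexpr("seq:[A-Za-z]{3}", ac))
        if (length(m)) anticodon <- toupper(sub("seq:", "", m))
      }
    }
    category <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       "control")
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, category = category, strand = strand,
      start = start, end = end, anticodon = anticodon,
      initiation_codon = NA_character_,
      termination_codon = NA_character_, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("parse error: no usable features", call. = FALSE)
  df <- do.call(rbind, rows)
  df <- df[order(df$start), , drop = FALSE]

  # derive PCG start/stop codons from the sequence
  for (i in which(df$category == "PCG")) {
    s <- extract_feature_sequence(genome, df[i, ])
    df$initiation_codon[i] <- substr(s, 1L, 3L)
    len <- nchar(s)
    r <- len %% 3L
    df$termination_codon[i] <-
      if (r == 0L) substr(s, len - 2L, len) else substr(s, len - r + 1L, len)
  }

  # infer the control region when not annotated
  if (!any(df$category == "control")) {
    sr <- grep("^(srRNA|rrnS|12S|s-rRNA)", df$name, ignore.case = TRUE)
    anchor <- if (length(sr)) max(df$end[sr]) else max(df$end)
    if (anchor < genome$length)
      df <- rbind(df, data.frame(
        name = "AT_rich", category = "control", strand = "J",
        start = anchor + 1L, end = genome$length, anticodon = NA_character_,
        initiation_codon = NA_character_, termination_codon = NA_character_,
        stringsAsFactors = FALSE))
  }
  mito_record(genome, mito_features(df, genome_length = genome$length))
}

#' Write a mito_record as a GenBank-like flat file
#'
#' Emits the minimal subset of the flat-file format that [read_genbank()]
#' consumes (LOCUS, FEATURES with typed keys, ORIGIN). Intended for tests
#' and for exporting simulated genomes.
#'
#' @param record A `mito_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  g <- record$genome; ft <- record$features
  con <- file(path, "w"); on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con)
  wr("LOCUS       %s %d bp    DNA     circular INV", g$id, g$length)
  wr("ACCESSION   %s", g$id)
  wr("  ORGANISM  %s", g$species)
  wr("FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(ft))) {
    key <- switch(ft$category[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control = "misc_feature")
    loc <- sprintf("%d..%d", ft$start[i], ft$end[i])
    if (ft$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
    wr("     %-16s%s", key, loc)
    wr("                     /gene=\"%s\"", ft$name[i])
    if (!is.na(ft$anticodon[i]))
      wr("                     /anticodon=\"(pos:0..0,aa:Xxx,seq:%s)\"",
         tolower(ft$anticodon[i]))
  }
  wr("ORIGIN")
  s <- g$sequence
  for (p in seq(1L, nchar(s), by = 60L))
    wr("%9d %s", p, tolower(substr(s, p, min(p + 59L, nchar(s)))))
  wr("//")
  invisible(path)
}
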