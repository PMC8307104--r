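# Data model for annotated circular mitogenomes.
#
# A mito_genome holds the major-strand (J) sequence; a mito_features table
# holds the ordered gene annotations with 1-based inclusive coordinates, as
# in published mitogenome annotation tables. Strand "J" is the orientation
# of the deposited sequence, "N" the minor strand; N-strand features are
# extracted in reading direction (reverse complement).

FEATURE_CATEGORIES <- c("PCG", "tRNA", "rRNA", "control")

#' Construct a mitochondrial genome object
#'
#' @param sequence Character scalar, major-strand nucleotide sequence
#'   (A/C/G/T/N).
#' @param id Identifier (e.g. an accession).
#' @param species Species label.
#' @param circular Logical; complete insect mitogenomes are circular.
#' @return An object of class `mito_genome` with fields `id`, `species`,
#'   `sequence`, `length` and `circular`.
#' @export
mito_genome <- function(sequence, id = "genome", species = id,
                        circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty genome sequence", call. = FALSE)
  check_alphabet(sequence, "genome sequence")
  structure(
    list(id = id, species = species, sequence = sequence,
         length = nchar(sequence), circular = isTRUE(circular)),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s (%s): %s bp, %s\n", x$id, x$species,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a feature table
#'
#' @param df Data frame with columns `name`, `category` (PCG/tRNA/rRNA/
#'   control), `strand` (J/N), `start`, `end` (1-based inclusive) and
#'   optionally `anticodon`, `initiation_codon`, `termination_codon`.
#' @param genome_length Genome length in bp; defaults to `max(df$end)`.
#' @return A data frame of class `mito_features`, ordered as given (genomic
#'   order), with a `genome_length` attribute.
#' @export
mito_features <- function(df, genome_length = max(df$end)) {
  req <- c("name", "category", "strand", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty feature table", call. = FALSE)
  for (col in c("anticodon", "initiation_codon", "termination_codon"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    stop("non-numeric coordinates", call. = FALSE)
  if (any(df$start < 1L))
    stop("coordinate error: start < 1", call. = FALSE)
  if (any(df$end < df$start))
    stop("coordinate error: end < start", call. = FALSE)
  if (any(df$end > genome_length))
    stop("coordinate error: feature beyond genome length", call. = FALSE)
  if (!all(df$category %in% FEATURE_CATEGORIES))
    stop("unknown feature category", call. = FALSE)
  if (!all(df$strand %in% c("J", "N")))
    stop("strand must be J or N", call. = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicate feature names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  rownames(df) <- NULL
  structure(df, genome_length = as.integer(genome_length),
            class = c("mito_features", "data.frame"))
}

#' @export
print.mito_features <- function(x, ...) {
  cat(sprintf("<mito_features> %d features, genome %s bp\n", nrow(x),
              format(attr(x, "genome_length"), big.mark = ",")))
  print.data.frame(head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("...", nrow(x) - 8L, "more rows\n")
  invisible(x)
}

#' Genome length recorded in a feature table
#' @param table A `mito_features` object.
#' @return Integer genome length in bp.
#' @export
genome_length <- function(table) attr(table, "genome_length")

#' Read an annotation feature table (TSV)
#'
#' The dialect is one header row and the columns `name`, `category`,
#' `strand`, `start`, `end`, `anticodon`, `initiation_codon`,
#' `termination_codon` (the last three may be empty), tab-separated, fully
#' expanded (no "same as previous" shorthand). The genome length is taken as
#' the maximum feature end.
#'
#' @param path Path to the TSV file.
#' @param sequence Optional major-strand sequence; when given, a
#'   `mito_genome` is returned alongside the table.
#' @param id Identifier used when `sequence` is given.
#' @return A `mito_features` table, or, when `sequence` is supplied, a list
#'   with elements `genome` and `features` (class `mito_record`).
#' @export
read_feature_table <- function(path, sequence = NULL, id = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(df) == 0L) stop("empty-table error: ", path, call. = FALSE)
  ft <- mito_features(df)
  if (is.null(sequence)) return(ft)
  g <- mito_genome(sequence, id = id)
  if (g$length < genome_length(ft))
    stop("coordinate error: features beyond supplied sequence",
         call. = FALSE)
  mito_record(g, ft)
}

#' Bundle a genome and its feature table
#' @param genome A `mito_genome`.
#' @param features A `mito_features` table.
#' @return List of class `mito_record` with elements `genome`, `features`.
#' @export
mito_record <- function(genome, features) {
  stopifnot(inherits(genome, "mito_genome"),
            inherits(features, "mito_features"))
  if (genome_length(features) > genome$length)
    stop("coordinate error: feature beyond sequence length", call. = FALSE)
  structure(list(genome = genome, features = features),
            class = "mito_record")
}

#' @export
print.mito_record <- function(x, ...) {
  print(x$genome)
  print(x$features)
  invisible(x)
}

#' Extract a feature's sense-strand sequence
#'
#' Returns the reading-direction sequence of a feature: the plain slice for
#' J-strand features, the reverse complement of the slice for N-strand
#' features. Circular wrap-around features (`start > end` is not allowed in
#' the table; wrapping is expressed as `end > length` never occurring) are
#' handled by `start`..`length` + `1`..`end` when `wrap = TRUE` slices are
#' requested via coordinates beyond the stored range; study annotations do
#' not use them.
#'
#' @param genome A `mito_genome`.
#' @param feature One row of a `mito_features` table (data frame or list
#'   with `start`, `end`, `strand`), or a feature name when `table` given.
#' @param table Optional `mito_features` used to look `feature` up by name.
#' @return Character scalar of length `end - start + 1`.
#' @export
extract_feature_sequence <- function(genome, feature, table = NULL) {
  if (is.character(feature)) {
    stopifnot(!is.null(table))
    i <- match(feature, table$name)
    if (is.na(i)) stop("unknown feature: ", feature, call. = FALSE)
    feature <- table[i, ]
  }
  start <- as.integer(feature$start)
  end <- as.integer(feature$end)
  if (end > genome$length || start < 1L)
    stop("coordinate error: feature outside genome", call. = FALSE)
  s <- substr(genome$sequence, start, end)
  check_alphabet(s, "feature sequence")
  if (identical(feature$strand, "N")) rev_comp(s) else s
}

#' Intergenic spacers between consecutive features
#'
#' One record per consecutive feature pair in genomic order; the value
#' attached to a gene is the gap to the next gene (negative values are
#' overlaps). The last feature wraps circularly to the first.
#'
#' @param table A `mito_features` table in genomic order.
#' @return Data frame with columns `upstream_gene`, `downstream_gene`,
#'   `spacer_length`.
#' @export
compute_spacers <- function(table) {
  stopifnot(inherits(table, "mito_features"))
  if (is.unsorted(table$start))
    stop("ordering error: features not in genomic order", call. = FALSE)
  n <- nrow(table)
  glen <- genome_length(table)
  nxt_start <- c(table$start[-1L], glen + table$start[1L])
  data.frame(
    upstream_gene = table$name,
    downstream_gene = c(table$name[-1L], table$name[1L]),
    spacer_length = as.integer(nxt_start - table$end - 1L),
    stringsAsFactors = FALSE
  )
}

#' Gene counts by category and strand
#'
#' @param table A `mito_features` table.
#' @return Integer matrix (categories x strands J/N), zero-filled.
#' @export
summarize_gene_counts <- function(table) {
  stopifnot(inherits(table, "mito_features"))
  m <- matrix(0L, nrow = length(FEATURE_CATEGORIES), ncol = 2L,
              dimnames = list(FEATURE_CATEGORIES, c("J", "N")))
  if (nrow(table)) {
    tb <- table(factor(table$category, FEATURE_CATEGORIES),
                factor(table$strand, c("J", "N")))
    m[rownames(tb), colnames(tb)] <- tb
  }
  m
}

#' Table-3-style annotation summary
#'
#' Sizes, spacers and codon annotations for one genome, matching the layout
#' of published mitogenome annotation tables.
#'
#' @param table A `mito_features` table.
#' @return Data frame with one row per feature.
#' @export
annotation_summary <- function(table) {
  sp <- compute_spacers(table)
  data.frame(
    name = table$name, category = table$category, strand = table$strand,
    start = table$start, end = table$end,
    size = table$end - table$start + 1L,
    intergenic = sp$spacer_length,
    anticodon = table$anticodon,
    initiation_codon = table$initiation_codon,
    termination_codon = table$termination_codon,
    stringsAsFactors = FALSE
  )
}
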