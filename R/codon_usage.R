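# Codon extraction (with incomplete stops), pooled codon counting, RSCU and
# start/stop codon surveys under the invertebrate mitochondrial code
# (translation table 5).

#' Split a coding sequence into codons and an incomplete-stop remainder
#'
#' @param cds Character scalar, reading-direction coding sequence of length
#'   at least 6. A length not divisible by 3 leaves a 1- or 2-base remainder
#'   interpreted as an incomplete stop codon ("T" or "TA", completed by
#'   polyadenylation in vivo).
#' @return List with `codons` (character vector of triplets) and `remainder`
#'   (character scalar, possibly "").
#' @export
extract_codons <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  len <- nchar(cds)
  if (len < 6L) stop("too-short error: CDS under 6 bp", call. = FALSE)
  n <- len %/% 3L
  starts <- seq(1L, by = 3L, length.out = n)
  list(codons = substring(cds, starts, starts + 2L),
       remainder = if (len %% 3L) substr(cds, 3L * n + 1L, len) else "")
}

#' Pool codon counts over protein-coding genes
#'
#' Counts sense codons over one or more reading-direction CDS sequences;
#' complete stop codons are tallied separately and incomplete stop
#' remainders are dropped. Codons containing non-A/C/G/T characters are
#' skipped.
#'
#' @param cds_list Character vector or list of reading-direction CDS
#'   sequences (may be empty).
#' @return Object of class `codon_counts`: list with `counts` (named integer
#'   vector over the 64 codons, stops zero), `stop_counts` (named integer
#'   over TAA/TAG), `n_codons`, `n_skipped`.
#' @export
count_codons <- function(cds_list) {
  codons <- all_codons()
  counts <- setNames(integer(64L), codons)
  stops <- stop_codons()
  stop_counts <- setNames(integer(length(stops)), stops)
  skipped <- 0L
  for (cds in cds_list) {
    cod <- extract_codons(cds)$codons
    ok <- !grepl("[^ACGT]", cod)
    skipped <- skipped + sum(!ok)
    cod <- cod[ok]
    tab <- table(cod)
    is_stop <- names(tab) %in% stops
    stop_counts[names(tab)[is_stop]] <-
      stop_counts[names(tab)[is_stop]] + as.integer(tab[is_stop])
    counts[names(tab)[!is_stop]] <-
      counts[names(tab)[!is_stop]] + as.integer(tab[!is_stop])
  }
  structure(list(counts = counts, stop_counts = stop_counts,
                 n_codons = sum(counts), n_skipped = skipped),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon_counts> %d sense codons, %d complete stops, %d skipped\n",
              x$n_codons, sum(x$stop_counts), x$n_skipped))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) * k / sum(counts over c's synonymous family)`, where
#' `k` is the family size under translation table 5 (e.g. 6 for Leu and Ser,
#' 4 for Gly, 2 for Phe). Families with zero total usage score 0 for every
#' member; stop codons are excluded.
#'
#' @param counts A `codon_counts` object.
#' @return Data frame of class `rscu_table` with columns `amino_acid`,
#'   `codon`, `count`, `family_size`, `rscu`, ordered by amino acid.
#' @export
rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  gc <- code5()
  sense <- names(gc)[gc != "*"]
  aa <- gc[sense]
  fam_size <- table(aa)
  fam_total <- tapply(counts$counts[sense], aa, sum)
  k <- as.integer(fam_size[aa])
  tot <- as.numeric(fam_total[aa])
  val <- ifelse(tot == 0, 0, counts$counts[sense] * k / tot)
  out <- data.frame(amino_acid = unname(aa), codon = sense,
                    count = unname(counts$counts[sense]),
                    family_size = k, rscu = unname(val),
                    stringsAsFactors = FALSE)
  out <- out[order(out$amino_acid, out$codon), ]
  rownames(out) <- NULL
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' Survey initiation and termination codons of the 13 PCGs
#'
#' Termination codons are reported verbatim, including incomplete stops
#' ("T", "TA"); nonstandard initiation codons are flagged, not corrected.
#'
#' @param table A `mito_features` table with PCG codon annotations.
#' @return List of class `start_stop_survey`: `genes` (data frame gene /
#'   initiation / termination / standard_initiation), `modal_initiation`,
#'   `modal_termination` (most frequent complete or incomplete codon).
#' @export
survey_start_stop <- function(table) {
  stopifnot(inherits(table, "mito_features"))
  pcg <- table[table$category == "PCG", ]
  if (!nrow(pcg)) stop("incomplete-annotation error: no PCGs", call. = FALSE)
  if (anyNA(pcg$initiation_codon) || anyNA(pcg$termination_codon))
    stop("incomplete-annotation error: missing start/stop annotation",
         call. = FALSE)
  modal <- function(x) names(sort(table(x), decreasing = TRUE))[1L]
  genes <- data.frame(
    gene = pcg$name,
    initiation = pcg$initiation_codon,
    termination = pcg$termination_codon,
    standard_initiation = grepl("^AT[ACGT]$", pcg$initiation_codon),
    stringsAsFactors = FALSE)
  structure(list(genes = genes,
                 modal_initiation = modal(genes$initiation),
                 modal_termination = modal(genes$termination)),
            class = "start_stop_survey")
}

#' @export
print.start_stop_survey <- function(x, ...) {
  cat(sprintf("<start_stop_survey> %d PCGs; modal initiation %s, modal termination %s\n",
              nrow(x$genes), x$modal_initiation, x$modal_termination))
  if (any(!x$genes$standard_initiation))
    cat("nonstandard initiation:",
        paste(sprintf("%s (%s)",
                      x$genes$gene[!x$genes$standard_initiation],
                      x$genes$initiation[!x$genes$standard_initiation]),
              collapse = ", "), "\n")
  invisible(x)
}

#' Extract all PCG coding sequences of a genome record
#'
#' Convenience wrapper returning reading-direction CDS sequences for every
#' PCG in the feature table, named by gene.
#'
#' @param record A `mito_record`.
#' @return Named character vector.
#' @export
pcg_sequences <- function(record) {
  ft <- record$features
  idx <- which(ft$category == "PCG")
  setNames(
    vapply(idx, function(i)
      extract_feature_sequence(record$genome, ft[i, ]), ""),
    ft$name[idx])
}
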