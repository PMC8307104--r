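# Nucleotide composition and strand-skew statistics, per region and per
# codon position. Percentages are computed over counted A/C/G/T (ambiguity
# characters excluded from numerator and denominator); skews from raw counts
# at full precision. Report output rounds percentages to 1 decimal and skews
# to 2 decimals.

#' Compositional skew
#'
#' `skew(x, y) = (x - y) / (x + y)`, the strand-asymmetry statistic used for
#' AT-skew (`x` = A, `y` = T) and GC-skew (`x` = G, `y` = C). Returns 0 when
#' `x + y` is 0 (degenerate convention).
#'
#' @param x,y Non-negative counts (or percentages; the ratio is scale-free).
#' @return Numeric in `[-1, 1]`.
#' @export
skew <- function(x, y) {
  if (any(c(x, y) < 0)) stop("domain error: negative counts", call. = FALSE)
  tot <- x + y
  ifelse(tot == 0, 0, (x - y) / tot)
}

new_composition_stats <- function(counts, size) {
  acgt <- sum(counts)
  if (acgt == 0) stop("degenerate-input error: no A/C/G/T bases",
                      call. = FALSE)
  pct <- 100 * counts / acgt
  structure(
    list(t_pct = pct[["T"]], c_pct = pct[["C"]], a_pct = pct[["A"]],
         g_pct = pct[["G"]], size = size,
         at_pct = pct[["A"]] + pct[["T"]],
         at_skew = skew(counts[["A"]], counts[["T"]]),
         gc_skew = skew(counts[["G"]], counts[["C"]])),
    class = "composition_stats"
  )
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "T%% %.1f  C%% %.1f  A%% %.1f  G%% %.1f  size %d  A+T%% %.1f  AT-skew %.2f  GC-skew %.2f\n",
    x$t_pct, x$c_pct, x$a_pct, x$g_pct, x$size, x$at_pct, x$at_skew,
    x$gc_skew))
  invisible(x)
}

#' @method as.data.frame composition_stats
#' @export
as.data.frame.composition_stats <- function(x, ...) {
  data.frame(t_pct = x$t_pct, c_pct = x$c_pct, a_pct = x$a_pct,
             g_pct = x$g_pct, size = x$size, at_pct = x$at_pct,
             at_skew = x$at_skew, gc_skew = x$gc_skew)
}

#' Base composition of a nucleotide sequence
#'
#' @param seq Character scalar over A/C/G/T/N (N excluded from percentage
#'   denominators but counted in `size`).
#' @return A `composition_stats` object: percentages of T/C/A/G, region size
#'   in bp, A+T%, AT-skew and GC-skew (full precision).
#' @export
base_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty-input error", call. = FALSE)
  seq <- toupper(seq)
  check_alphabet(seq)
  ch <- seq_chars(seq)
  counts <- vapply(BASES, function(b) sum(ch == b), 0L)
  new_composition_stats(counts, nchar(seq))
}

region_members <- function(table, region) {
  switch(region,
    all_genes = table$name,
    rRNA_genes = table$name[table$category == "rRNA"],
    tRNA_genes = table$name[table$category == "tRNA"],
    AT_rich = table$name[table$category == "control"],
    PCGs = table$name[table$category == "PCG"],
    stop("unknown region: ", region, call. = FALSE))
}

#' Composition statistics per genome region
#'
#' Reproduces the layout of per-region composition tables: `all_genes` (the
#' whole circular genome on the J strand, control region included),
#' `rRNA_genes`, `tRNA_genes`, `AT_rich` and `PCGs`. Gene regions
#' concatenate member sense-strand sequences in genomic order, so N-strand
#' genes contribute their reverse complement.
#'
#' @param genome A `mito_genome`.
#' @param table The matching `mito_features` table.
#' @param regions Character vector of region names to compute.
#' @return Data frame, one row per region, with the `composition_stats`
#'   fields.
#' @export
region_composition <- function(genome, table,
                               regions = c("all_genes", "rRNA_genes",
                                           "tRNA_genes", "AT_rich",
                                           "PCGs")) {
  stopifnot(inherits(genome, "mito_genome"),
            inherits(table, "mito_features"))
  out <- lapply(regions, function(r) {
    if (r == "all_genes") {
      cs <- base_composition(genome$sequence)
    } else {
      members <- region_members(table, r)
      if (!length(members))
        stop("incomplete-annotation error: no features for region ", r,
             call. = FALSE)
      seqs <- vapply(members, function(nm)
        extract_feature_sequence(genome, nm, table), "")
      cs <- base_composition(paste(seqs, collapse = ""))
    }
    as.data.frame(cs)
  })
  cbind(region = regions, do.call(rbind, out))
}

# pooled PCG sense sequences for a strand class, with per-base codon
# positions (1/2/3); incomplete stop bases keep their frame positions
pooled_pcg_positions <- function(genome, table, strand_class) {
  idx <- which(table$category == "PCG")
  if (strand_class != "all")
    idx <- idx[table$strand[idx] == strand_class]
  if (!length(idx))
    stop("incomplete-annotation error: no PCGs in strand class ",
         strand_class, call. = FALSE)
  bases <- character(0); pos <- integer(0)
  for (i in idx) {
    s <- extract_feature_sequence(genome, table[i, ])
    ch <- seq_chars(s)
    bases <- c(bases, ch)
    pos <- c(pos, ((seq_along(ch) - 1L) %% 3L) + 1L)
  }
  list(bases = bases, pos = pos)
}

#' Composition by codon position over pooled protein-coding genes
#'
#' Pools the sense-strand sequences of all PCGs in a strand class and
#' tallies composition at each codon position (frame anchored at the
#' initiation codon). Incomplete stop codons contribute their bases at
#' positions 1 (and 2), so position sizes may differ by a few bases.
#'
#' @param genome A `mito_genome`.
#' @param table The matching `mito_features` table.
#' @param strand_class `"all"`, `"J"` or `"N"`.
#' @return Data frame with rows `1st`, `2nd`, `3rd`, `total`.
#' @export
codon_position_composition <- function(genome, table,
                                       strand_class = c("all", "J", "N")) {
  strand_class <- match.arg(strand_class)
  pooled <- pooled_pcg_positions(genome, table, strand_class)
  rows <- lapply(1:3, function(p) {
    b <- pooled$bases[pooled$pos == p]
    counts <- vapply(BASES, function(x) sum(b == x), 0L)
    as.data.frame(new_composition_stats(counts, length(b)))
  })
  counts <- vapply(BASES, function(x) sum(pooled$bases == x), 0L)
  rows[[4L]] <- as.data.frame(new_composition_stats(counts,
                                                    length(pooled$bases)))
  cbind(position = c("1st", "2nd", "3rd", "total"), do.call(rbind, rows))
}

#' Round a composition data frame to report precision
#'
#' Percentages to 1 decimal, skews to 2 decimals (the package-wide report
#' rounding rule).
#'
#' @param df Data frame from [region_composition()] or
#'   [codon_position_composition()].
#' @return The data frame with rounded numeric columns.
#' @export
round_composition <- function(df) {
  for (col in c("t_pct", "c_pct", "a_pct", "g_pct", "at_pct"))
    df[[col]] <- round(df[[col]], 1L)
  for (col in c("at_skew", "gc_skew"))
    df[[col]] <- round(df[[col]], 2L)
  df
}
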