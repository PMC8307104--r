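# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction under translation
# table 5. Synonymous/nonsynonymous site fractions per codon weight each
# position 1/3 per possible mutation, with mutations to stop codons excluded
# and the position weight renormalized over the non-stop mutants. Pairwise
# differences average synonymous/nonsynonymous counts over all mutational
# pathways that avoid stop codons, with equal pathway weighting.

codon_index <- function(codon) match(codon, all_codons())

mutate_codon <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' Each position contributes the fraction of its non-stop single-base
#' mutants that are synonymous to the synonymous site count S, the rest to
#' N; S + N = 3 for every sense codon.
#'
#' @param codon Sense codon (3-letter, A/C/G/T) under translation table 5.
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon) || nchar(codon) != 3L)
    stop("skip signal: codon with ambiguity or wrong length", call. = FALSE)
  gc <- code5()
  aa <- gc[[codon]]
  if (aa == "*") stop("domain error: stop codon", call. = FALSE)
  S <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    mut <- vapply(setdiff(BASES, ref), function(b)
      gc[[mutate_codon(codon, pos, b)]], "")
    mut <- mut[mut != "*"]              # stop-bound mutations excluded
    if (length(mut)) S <- S + sum(mut == aa) / length(mut)
  }
  c(S = S, N = 3 - S)
}

# site-count lookup over all 64 codons (NA rows for stops)
sites_table <- function() {
  if (!is.null(.mc_cache$sites)) return(.mc_cache$sites)
  codons <- all_codons()
  m <- matrix(NA_real_, 64L, 2L, dimnames = list(codons, c("S", "N")))
  for (cd in sense_codons()) m[cd, ] <- count_sites(cd)
  .mc_cache$sites <- m
  m
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Enumerates all orders in which the differing positions can be substituted,
#' discards pathways passing through a stop codon, classifies each step as
#' synonymous or nonsynonymous, and averages the two counts over the
#' surviving pathways. When every pathway passes through a stop (possible
#' only for some 3-fold-different pairs), the average is taken over all
#' pathways and the result is flagged.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(sd = ..., nd = ...)`, with attribute
#'   `stop_pathways_used = TRUE` in the degenerate case;
#'   `sd + nd` equals the number of differing positions.
#' @export
count_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  gc <- code5()
  if (grepl("[^ACGT]", codon_a) || grepl("[^ACGT]", codon_b))
    stop("skip signal: ambiguity character", call. = FALSE)
  if (gc[[codon_a]] == "*" || gc[[codon_b]] == "*")
    stop("domain error: stop codon", call. = FALSE)
  diff_pos <- which(seq_chars(codon_a) != seq_chars(codon_b))
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(k, list(1L), list(1:2, 2:1),
                  list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                       c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  walk <- function(order) {
    cur <- codon_a; sd <- 0; nd <- 0
    for (j in order) {
      p <- diff_pos[j]
      nxt <- mutate_codon(cur, p, substr(codon_b, p, p))
      if (gc[[nxt]] == "*") return(NULL)
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, is.null, TRUE)
  flagged <- FALSE
  if (!any(ok)) {
    # all routes pass through stops: average over them anyway, flagged
    flagged <- TRUE
    walk_any <- function(order) {
      cur <- codon_a; sd <- 0; nd <- 0
      for (j in order) {
        p <- diff_pos[j]
        nxt <- mutate_codon(cur, p, substr(codon_b, p, p))
        same <- !is.na(gc[[cur]]) && gc[[cur]] == gc[[nxt]] &&
          gc[[cur]] != "*"
        if (same) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(perms, walk_any)
    ok <- rep(TRUE, length(res))
  }
  m <- colMeans(do.call(rbind, res[ok]))
  out <- c(sd = m[1L], nd = m[2L])
  names(out) <- c("sd", "nd")
  if (flagged) attr(out, "stop_pathways_used") <- TRUE
  out
}

# 64 x 64 lookup matrices of pathway-averaged sd/nd (built once)
diff_tables <- function() {
  if (!is.null(.mc_cache$diffs)) return(.mc_cache$diffs)
  codons <- all_codons()
  sense <- sense_codons()
  Sd <- Nd <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
  for (a in sense) for (b in sense) {
    d <- count_differences(a, b)
    Sd[a, b] <- d[["sd"]]; Nd[a, b] <- d[["nd"]]
  }
  .mc_cache$diffs <- list(Sd = Sd, Nd = Nd)
  .mc_cache$diffs
}

jc_correct <- function(p) {
  if (p >= 0.75) stop("saturation error: proportion >= 3/4", call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise NG86 Ka/Ks between two aligned coding sequences
#'
#' Codons containing gaps (`-`) or ambiguity characters in either sequence
#' are deleted pairwise; incomplete-stop remainders are trimmed; terminal
#' (and any other) stop codons are skipped pairwise. Site totals are
#' averaged over the two sequences, proportions Jukes-Cantor corrected.
#' Symmetric in its arguments.
#'
#' @param a,b Equal-length reading-direction coding sequences.
#' @return Object of class `kaks`: list with `S`, `N` (mean site counts),
#'   `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio` (NA with
#'   `undefined = TRUE` when Ks = 0), `n_codons`.
#' @export
pairwise_kaks <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop("alignment error: unequal sequence lengths", call. = FALSE)
  trim <- nchar(a) - nchar(a) %% 3L
  ca <- extract_codons(substr(a, 1L, trim))$codons
  cb <- extract_codons(substr(b, 1L, trim))$codons
  stops <- stop_codons()
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    !(ca %in% stops) & !(cb %in% stops)
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codons", call. = FALSE)
  st <- sites_table()
  Sa <- sum(st[ca, "S"]); Na <- sum(st[ca, "N"])
  Sb <- sum(st[cb, "S"]); Nb <- sum(st[cb, "N"])
  S <- (Sa + Sb) / 2; N <- (Na + Nb) / 2
  dt <- diff_tables()
  idx <- cbind(codon_index(ca), codon_index(cb))
  Sd <- sum(dt$Sd[idx]); Nd <- sum(dt$Nd[idx])
  pS <- Sd / S; pN <- Nd / N
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  undefined <- Ks == 0
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka,
                 ratio = if (undefined) NA_real_ else Ka / Ks,
                 undefined = undefined, n_codons = length(ca)),
            class = "kaks")
}

#' @export
print.kaks <- function(x, ...) {
  cat(sprintf("<kaks> %d codons: Ka %.5f  Ks %.5f  Ka/Ks %s\n",
              x$n_codons, x$Ka, x$Ks,
              if (x$undefined) "undefined (Ks = 0)" else
                sprintf("%.5f", x$ratio)))
  invisible(x)
}

#' Mean Ka/Ks of one gene across a taxon set
#'
#' Computes pairwise NG86 Ka/Ks over all C(n, 2) taxon pairs and aggregates.
#' The default aggregation is the unweighted mean of the defined pairwise
#' ratios; `method = "ratio_of_means"` instead returns mean(Ka)/mean(Ks).
#'
#' @param seqs Named character vector/list of equal-length (pre-aligned or
#'   alignment-free comparable) reading-direction CDS sequences, one per
#'   taxon.
#' @param gene Gene label carried into the summary.
#' @param method Aggregation rule.
#' @return List of class `gene_kaks`: `gene`, `mean_ka`, `mean_ks`,
#'   `mean_ratio`, `n_pairs` (pairs with defined ratio), `n_taxa`.
#' @export
gene_mean_kaks <- function(seqs, gene = "gene",
                           method = c("mean_ratio", "ratio_of_means")) {
  method <- match.arg(method)
  if (length(seqs) < 2L)
    stop("insufficient-data error: need >= 2 taxa", call. = FALSE)
  prs <- combn(length(seqs), 2L)
  res <- lapply(seq_len(ncol(prs)), function(j)
    pairwise_kaks(seqs[[prs[1L, j]]], seqs[[prs[2L, j]]]))
  ka <- vapply(res, `[[`, 0, "Ka")
  ks <- vapply(res, `[[`, 0, "Ks")
  ratio <- vapply(res, `[[`, 0, "ratio")
  defined <- !is.na(ratio)
  mean_ratio <- switch(method,
    mean_ratio = if (any(defined)) mean(ratio[defined]) else NA_real_,
    ratio_of_means = if (mean(ks) > 0) mean(ka) / mean(ks) else NA_real_)
  structure(list(gene = gene, mean_ka = mean(ka), mean_ks = mean(ks),
                 mean_ratio = mean_ratio, n_pairs = sum(defined),
                 n_taxa = length(seqs), method = method),
            class = "gene_kaks")
}

#' @export
print.gene_kaks <- function(x, ...) {
  cat(sprintf("<gene_kaks> %s (%d taxa, %d pairs): mean Ka %.5f  mean Ks %.5f  mean Ka/Ks %.5f\n",
              x$gene, x$n_taxa, x$n_pairs, x$mean_ka, x$mean_ks,
              x$mean_ratio))
  invisible(x)
}

#' Per-gene Ka/Ks summary across a set of annotated genomes
#'
#' Extracts each PCG from every record, checks length compatibility and
#' aggregates pairwise NG86 estimates per gene, ranked by mean ratio.
#'
#' @param records Named list of `mito_record` objects sharing gene names and
#'   per-gene lengths (pre-aligned or simulator output).
#' @param method Aggregation rule, see [gene_mean_kaks()].
#' @return Data frame: `gene`, `mean_ka`, `mean_ks`, `mean_ratio`,
#'   `n_pairs`, sorted by decreasing `mean_ratio`.
#' @export
clade_kaks <- function(records, method = "mean_ratio") {
  stopifnot(length(records) >= 2L)
  per_taxon <- lapply(records, pcg_sequences)
  genes <- names(per_taxon[[1L]])
  rows <- lapply(genes, function(g) {
    seqs <- lapply(per_taxon, function(x) {
      if (is.na(x[g])) stop("missing-data error: gene ", g, call. = FALSE)
      x[[g]]
    })
    lens <- vapply(seqs, nchar, 0L)
    if (length(unique(lens)) != 1L)
      stop("alignment-required error: unequal lengths for gene ", g,
           call. = FALSE)
    s <- gene_mean_kaks(seqs, gene = g, method = method)
    data.frame(gene = g, mean_ka = s$mean_ka, mean_ks = s$mean_ks,
               mean_ratio = s$mean_ratio, n_pairs = s$n_pairs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_ratio), , drop = FALSE]
}
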