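# PCG+rRNA supermatrix assembly, export for external tree software, and an
# internal p-distance / neighbor-joining tree used as a pipeline smoke test.
# Maximum-likelihood and Bayesian inference are run by the user outside this
# package on the exported files.

#' Assemble a concatenated PCG+rRNA supermatrix
#'
#' Concatenates the 13 protein-coding and 2 rRNA genes (15 partitions) of
#' every taxon in a fixed canonical order (the genomic order of the feature
#' tables). Per-gene blocks must be equal length across taxa (pre-aligned
#' input, or simulator output which is alignment-free comparable).
#'
#' @param records Named list of `mito_record` objects, one per taxon.
#' @param categories Feature categories to include.
#' @return Object of class `supermatrix`: `taxa`, `seqs` (named equal-length
#'   character vector), `partitions` (data frame `gene`, `start`, `end` in
#'   1-based inclusive concatenated coordinates).
#' @export
build_supermatrix <- function(records, categories = c("PCG", "rRNA")) {
  stopifnot(length(records) >= 1L)
  taxa <- names(records)
  if (is.null(taxa)) stop("records must be named by taxon", call. = FALSE)
  ref <- records[[1L]]$features
  genes <- ref$name[ref$category %in% categories]
  blocks <- lapply(records, function(rec) {
    ft <- rec$features
    vapply(genes, function(g) {
      i <- match(g, ft$name)
      if (is.na(i)) stop("missing-data error: taxon lacks gene ", g,
                         call. = FALSE)
      extract_feature_sequence(rec$genome, ft[i, ])
    }, "")
  })
  lens <- vapply(genes, function(g)
    nchar(blocks[[1L]][[g]]), 0L)
  for (tx in taxa)
    for (g in genes)
      if (nchar(blocks[[tx]][[g]]) != lens[[g]])
        stop("alignment-required error: unequal block lengths for gene ", g,
             call. = FALSE)
  ends <- cumsum(lens)
  partitions <- data.frame(gene = genes,
                           start = as.integer(ends - lens + 1L),
                           end = as.integer(ends),
                           stringsAsFactors = FALSE, row.names = NULL)
  seqs <- vapply(blocks, function(bl) paste(bl, collapse = ""), "")
  out <- list(taxa = taxa, seqs = setNames(seqs, taxa),
              partitions = partitions)
  class(out) <- "supermatrix"
  out
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d sites, %d partitions\n",
              length(x$taxa), nchar(x$seqs[[1L]]), nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix to phylogenetics input formats
#'
#' Writers for FASTA, relaxed PHYLIP, NEXUS (with a sets block of charsets)
#' and RAxML-style partition text. Byte-stable: identical input gives
#' identical files.
#'
#' @param sm A `supermatrix`.
#' @param prefix Output path prefix; files `<prefix>.fasta`, `.phy`, `.nex`,
#'   `.partitions.txt` and `.partitions.tsv` are written.
#' @param formats Subset of `c("fasta", "phylip", "nexus", "partitions")`.
#' @return Character vector of files written, invisibly.
#' @export
write_supermatrix <- function(sm, prefix,
                              formats = c("fasta", "phylip", "nexus",
                                          "partitions")) {
  written <- character(0)
  nsite <- nchar(sm$seqs[[1L]])
  if ("fasta" %in% formats) {
    f <- paste0(prefix, ".fasta")
    writeLines(as.vector(rbind(paste0(">", sm$taxa), sm$seqs)), f)
    written <- c(written, f)
  }
  if ("phylip" %in% formats) {
    f <- paste0(prefix, ".phy")
    writeLines(c(sprintf(" %d %d", length(sm$taxa), nsite),
                 sprintf("%s  %s", sm$taxa, sm$seqs)), f)
    written <- c(written, f)
  }
  if ("nexus" %in% formats) {
    f <- paste0(prefix, ".nex")
    lines <- c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa),
                       nsite),
               "  FORMAT DATATYPE=DNA MISSING=N GAP=-;", "  MATRIX",
               sprintf("    %s  %s", sm$taxa, sm$seqs),
               "  ;", "END;", "BEGIN SETS;",
               sprintf("  CHARSET %s = %d-%d;", sm$partitions$gene,
                       sm$partitions$start, sm$partitions$end),
               "END;")
    writeLines(lines, f)
    written <- c(written, f)
  }
  if ("partitions" %in% formats) {
    f <- paste0(prefix, ".partitions.txt")
    writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                       sm$partitions$start, sm$partitions$end), f)
    f2 <- paste0(prefix, ".partitions.tsv")
    write.table(sm$partitions, f2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, f, f2)
  }
  invisible(written)
}

#' Read a supermatrix back from FASTA + partition TSV
#'
#' Round-trip counterpart of [write_supermatrix()].
#'
#' @param fasta Path to the FASTA alignment.
#' @param partitions Path to the partition TSV (`gene`, `start`, `end`).
#' @return A `supermatrix`.
#' @export
read_supermatrix <- function(fasta, partitions) {
  dss <- Biostrings::readDNAStringSet(fasta)
  seqs <- setNames(as.character(dss), names(dss))
  part <- read.delim(partitions, stringsAsFactors = FALSE)
  out <- list(taxa = names(seqs), seqs = seqs,
              partitions = data.frame(gene = part$gene,
                                      start = as.integer(part$start),
                                      end = as.integer(part$end),
                                      stringsAsFactors = FALSE))
  class(out) <- "supermatrix"
  out
}

#' Pairwise p-distance matrix of a supermatrix
#'
#' Proportion of differing sites over pairwise-complete (non-N, non-gap)
#' columns.
#'
#' @param sm A `supermatrix`.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
p_distance_matrix <- function(sm) {
  mat <- t(vapply(sm$seqs, function(s) seq_chars(tolower(s)),
                  character(nchar(sm$seqs[[1L]]))))
  bin <- ape::as.DNAbin(mat)
  d <- as.matrix(ape::dist.dna(bin, model = "raw",
                               pairwise.deletion = TRUE))
  if (any(!is.finite(d)))
    stop("undefined-distance error: zero comparable columns", call. = FALSE)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (deterministic for a fixed input order); a
#' smoke-test device for the pipeline, not a substitute for ML/BI inference
#' on the exported supermatrix.
#'
#' @param dm Symmetric distance matrix with taxa dimnames.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("input error: non-symmetric distance matrix", call. = FALSE)
  if (nrow(dm) < 3L) stop("need >= 3 taxa", call. = FALSE)
  ape::nj(as.dist(dm))
}

#' Is a taxon set monophyletic in an unrooted tree?
#'
#' TRUE iff some edge bipartition separates exactly the ingroup from the
#' remaining leaves.
#'
#' @param tree An `ape::phylo` tree.
#' @param ingroup Character vector of leaf names.
#' @return Logical scalar.
#' @export
check_monophyly <- function(tree, ingroup) {
  tips <- tree$tip.label
  unknown <- setdiff(ingroup, tips)
  if (length(unknown))
    stop("name error: unknown taxa: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(ingroup) %in% c(1L, length(tips) - 1L, length(tips)))
    return(TRUE)   # leaf-edge bipartitions are trivially present
  target <- sort(match(ingroup, tips))
  comp <- sort(setdiff(seq_along(tips), target))
  splits <- ape::prop.part(tree)
  any(vapply(splits, function(s) {
    s <- sort(s)
    identical(s, target) || identical(s, comp)
  }, TRUE))
}
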