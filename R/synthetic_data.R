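# Seeded generator of mitogenome-like inputs with the statistical structure
# the analysis assumes: a circular ~15.7 kb genome with the canonical
# 37-gene complement and gene order, strong regional A+T bias, incomplete
# stop codons, foldable tRNAs, and clade-structured coding divergence with
# controllable per-gene dN/dS. Also ships the expanded annotation-table
# fixtures for the five study species.

FIXTURE_SPECIES <- c("F_sunanensis", "F_amplivertica", "F_nigritibia",
                     "F_pamphagoides", "F_dingxiensis")

#' Packaged annotation-table fixture for one study species
#'
#' Returns the fully expanded annotation table (coordinates, strands,
#' anticodons, start/stop codons; 38 rows: 13 PCGs, 22 tRNAs, 2 rRNAs, one
#' control region) for one of the five study species.
#'
#' @param name One of `"F_sunanensis"`, `"F_amplivertica"`,
#'   `"F_nigritibia"`, `"F_pamphagoides"`, `"F_dingxiensis"`.
#' @return A `mito_features` table.
#' @export
emit_fixture <- function(name) {
  if (!name %in% FIXTURE_SPECIES)
    stop("name error: unknown fixture ", name, call. = FALSE)
  path <- system.file("extdata", paste0("table3_", name, ".tsv"),
                      package = "mitocompare", mustWork = TRUE)
  read_feature_table(path)
}

#' Simulation configuration
#'
#' @param seed Integer seed; every simulator stage derives its RNG state
#'   from it.
#' @param at_fraction Named A+T fractions per region class. Defaults follow
#'   the compositional profile typical of pamphagid mitogenomes (PCGs about
#'   0.73, tRNAs 0.70, rRNAs 0.73, control region 0.83).
#' @param template Fixture name whose gene order/lengths/strands/codons
#'   drive the reference genome layout.
#' @param tree Newick text (or `ape::phylo`) with branch lengths in expected
#'   substitutions per site; default a 12-ingroup / 4-outgroup clade tree.
#' @param omega Per-gene dN/dS: scalar or named vector over PCG names;
#'   default 0.2 (mid-range purifying selection).
#' @param branch_length Default branch length used when building the default
#'   tree.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       at_fraction = c(PCG = 0.73, tRNA = 0.70,
                                       rRNA = 0.73, control = 0.83,
                                       spacer = 0.73),
                       template = "F_sunanensis",
                       tree = NULL, omega = 0.2,
                       branch_length = 0.03) {
  if (any(at_fraction <= 0 | at_fraction >= 1))
    stop("config error: at_fraction outside (0,1)", call. = FALSE)
  if (any(omega <= 0)) stop("config error: omega <= 0", call. = FALSE)
  if (is.null(tree))
    tree <- clade_tree(12L, 4L, brlen = branch_length)
  structure(list(seed = as.integer(seed), at_fraction = at_fraction,
                 template = template, tree = tree, omega = omega),
            class = "sim_config")
}

#' Ladder clade tree with an ingroup and an outgroup
#'
#' Deterministic newick builder used as the default simulation tree: a
#' pectinate ingroup clade of `n_ingroup` taxa (`in1`..`inN`) sister to a
#' pectinate outgroup clade (`out1`..`outM`), uniform branch lengths.
#'
#' @param n_ingroup,n_outgroup Taxon counts (ingroup >= 2).
#' @param brlen Branch length (expected substitutions/site).
#' @return Newick text.
#' @export
clade_tree <- function(n_ingroup = 12L, n_outgroup = 4L, brlen = 0.03) {
  ladder <- function(names) {
    s <- sprintf("%s:%g", names[1L], brlen)
    for (nm in names[-1L])
      s <- sprintf("(%s,%s:%g):%g", s, nm, brlen, brlen)
    s
  }
  ing <- ladder(paste0("in", seq_len(n_ingroup)))
  if (n_outgroup == 0L) return(paste0(ing, ";"))
  out <- ladder(paste0("out", seq_len(n_outgroup)))
  sprintf("(%s,%s);", ing, out)
}

sample_bases <- function(n, at) {
  if (n <= 0L) return(character(0))
  sample(BASES, n, replace = TRUE,
         prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2))
}

# n sense codons with A+T-biased bases (stop codons rejected and redrawn)
sample_sense_codons <- function(n, at) {
  if (n <= 0L) return(character(0))
  out <- character(n)
  need <- seq_len(n)
  stops <- stop_codons()
  while (length(need)) {
    b <- matrix(sample_bases(3L * length(need), at), ncol = 3L)
    cand <- paste0(b[, 1L], b[, 2L], b[, 3L])
    ok <- !(cand %in% stops)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

make_pcg_sequence <- function(len, init, term, at) {
  r <- len %% 3L
  if (nchar(term) == 3L && r != 0L)
    stop("generation error: complete stop but length not 3k", call. = FALSE)
  if (nchar(term) < 3L && nchar(term) != r)
    stop("generation error: incomplete stop inconsistent with length",
         call. = FALSE)
  n_internal <- (len - nchar(term)) %/% 3L - 1L
  paste0(init, paste(sample_sense_codons(n_internal, at), collapse = ""),
         term)
}

# first template-feasible arm combination for a tRNA of the given length
make_trna_sequence <- function(len, anticodon, dhu_absent = FALSE,
                               at = 0.5) {
  dhu_opts <- if (dhu_absent) 0L else c(4L, 3L, 2L)
  for (d in dhu_opts) for (dl in if (d > 0L) c(7L, 5L, 4L, 3L, 8L) else 0L)
    for (a in c(5L, 4L, 6L, 3L)) for (t in c(5L, 4L, 6L, 3L)) {
      des <- tryCatch(
        design_trna(anticodon, dhu = d, ac = a, tpsic = t, dhu_loop = dl,
                    conn1 = 2L, conn2 = 1L, tail = 1L, total_length = len,
                    at = at),
        error = function(e) NULL)
      if (!is.null(des)) return(des$seq)
    }
  stop("generation error: no template-consistent tRNA of length ", len,
       call. = FALSE)
}

#' Generate a reference mitogenome from a simulation configuration
#'
#' Builds a circular genome following the template fixture's gene order,
#' strands, lengths, anticodons and start/stop codons (incomplete stops
#' included). PCGs are valid table-5 open reading frames; tRNAs are
#' template-consistent (foldable); rRNA, control-region and spacer bases are
#' drawn at the configured A+T fractions. Gene overlaps in the template are
#' clipped to abutting genes (spacer 0) so that no gene overwrites
#' another's codons; lengths are preserved.
#'
#' @param config A `sim_config`.
#' @return A `mito_record`; the per-feature sense sequences are attached as
#'   attribute `"unit_seqs"` for downstream evolution.
#' @export
make_reference_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  template <- emit_fixture(config$template)
  at <- config$at_fraction
  n <- nrow(template)
  spacers <- pmax(0L, compute_spacers(template)$spacer_length)
  spacers[n] <- 0L
  feats <- character(n)
  for (i in seq_len(n)) {
    len <- template$end[i] - template$start[i] + 1L
    feats[i] <- switch(template$category[i],
      PCG = make_pcg_sequence(len, template$initiation_codon[i],
                              template$termination_codon[i], at[["PCG"]]),
      tRNA = make_trna_sequence(len, template$anticodon[i],
                                dhu_absent = grepl("AGN", template$name[i]),
                                at = at[["tRNA"]]),
      rRNA = paste(sample_bases(len, at[["rRNA"]]), collapse = ""),
      control = paste(sample_bases(len, at[["control"]]), collapse = ""))
  }
  gaps <- vapply(spacers, function(k)
    paste(sample_bases(k, at[["spacer"]]), collapse = ""), "")
  assemble_genome(feats, gaps, template, id = "sim_reference",
                  species = "simulated")
}

# build a mito_record from per-feature sense sequences + inter-feature gaps
assemble_genome <- function(feature_seqs, gap_seqs, template, id, species) {
  n <- nrow(template)
  pieces <- character(2L * n)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    s <- feature_seqs[[i]]
    strand_seq <- if (template$strand[i] == "N") rev_comp(s) else s
    starts[i] <- pos + 1L
    ends[i] <- pos + nchar(strand_seq)
    pieces[2L * i - 1L] <- strand_seq
    pieces[2L * i] <- gap_seqs[[i]]
    pos <- ends[i] + nchar(gap_seqs[[i]])
  }
  sequence <- paste(pieces, collapse = "")
  df <- data.frame(name = template$name, category = template$category,
                   strand = template$strand, start = starts, end = ends,
                   anticodon = template$anticodon,
                   initiation_codon = template$initiation_codon,
                   termination_codon = template$termination_codon,
                   stringsAsFactors = FALSE)
  rec <- mito_record(mito_genome(sequence, id = id, species = species),
                     mito_features(df, genome_length = nchar(sequence)))
  attr(rec, "unit_seqs") <- list(features = as.list(feature_seqs),
                                 gaps = as.list(gap_seqs))
  rec
}

# one branch of evolution on per-feature sense sequences
mutate_units <- function(units, template, brlen, omega) {
  gc <- code5()
  feats <- units$features
  for (i in seq_along(feats)) {
    ch <- seq_chars(feats[[i]])
    L <- length(ch)
    nmut <- rpois(1L, brlen * L)
    if (nmut == 0L) next
    cat_i <- template$category[i]
    if (cat_i == "PCG") {
      om <- if (length(omega) == 1L) omega else omega[[template$name[i]]]
      term_len <- if (L %% 3L == 0L) 3L else L %% 3L
      protected_from <- L - term_len + 1L
      for (k in seq_len(nmut)) {
        site <- sample.int(L, 1L)
        if (site <= 3L || site >= protected_from) next  # start/stop kept
        j0 <- 3L * ((site - 1L) %/% 3L) + 1L
        old_codon <- paste(ch[j0:(j0 + 2L)], collapse = "")
        new_base <- sample(setdiff(BASES, ch[site]), 1L)
        new_ch <- ch; new_ch[site] <- new_base
        new_codon <- paste(new_ch[j0:(j0 + 2L)], collapse = "")
        if (gc[[new_codon]] == "*") next
        if (gc[[new_codon]] == gc[[old_codon]] || runif(1L) < om)
          ch <- new_ch
      }
    } else {
      protected <- integer(0)
      if (cat_i == "tRNA" && !is.na(template$anticodon[i])) {
        hit <- regexpr(template$anticodon[i], feats[[i]], fixed = TRUE)
        if (hit > 0L) protected <- hit + 0:2   # anticodon stays conserved
      }
      sites <- setdiff(sample.int(L, nmut, replace = TRUE), protected)
      for (site in sites)
        ch[site] <- sample(setdiff(BASES, ch[site]), 1L)
    }
    feats[[i]] <- paste(ch, collapse = "")
  }
  gaps <- lapply(units$gaps, function(g) {
    if (!nchar(g)) return(g)
    ch <- seq_chars(g)
    nmut <- rpois(1L, brlen * length(ch))
    for (site in sample.int(length(ch), min(nmut, length(ch))))
      ch[site] <- sample(setdiff(BASES, ch[site]), 1L)
    paste(ch, collapse = "")
  })
  list(features = feats, gaps = gaps)
}

#' Evolve a reference genome along a taxon tree
#'
#' Codon-level evolution of protein-coding genes: substitutions are proposed
#' per site at the branch-length rate; synonymous proposals are always
#' accepted, nonsynonymous ones with probability omega, and proposals
#' creating stop codons (or touching the start codon / terminal stop) are
#' rejected — a deliberately simple scheme whose only job is monotone
#' control of dN/dS. tRNA/rRNA/control/spacer regions evolve under plain
#' substitution. All taxa keep the gene order and per-gene block lengths of
#' the reference (alignment-free comparability).
#'
#' @param reference A `mito_record` from [make_reference_genome()] (must
#'   carry the `"unit_seqs"` attribute).
#' @param config The `sim_config` (tree, omega, seed).
#' @return Object of class `sim_clade`: `records` (named list of
#'   `mito_record`, one per tip), `tree` (`ape::phylo`), `config`.
#' @export
evolve_clade <- function(reference, config) {
  units0 <- attr(reference, "unit_seqs")
  if (is.null(units0))
    stop("reference lacks unit sequences; use make_reference_genome()",
         call. = FALSE)
  if (any(config$omega <= 0)) stop("config error: omega <= 0", call. = FALSE)
  tree <- config$tree
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (length(tree$tip.label) < 2L)
    stop("tree must have >= 2 leaves", call. = FALSE)
  set.seed(config$seed + 1L)
  template <- reference$features
  tree <- stats::reorder(tree, "cladewise")   # parent precedes child
  ntip <- length(tree$tip.label)
  node_units <- vector("list", ntip + tree$Nnode)
  node_units[[ntip + 1L]] <- units0
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1L]; child <- tree$edge[k, 2L]
    node_units[[child]] <- mutate_units(node_units[[par]], template,
                                        tree$edge.length[k], config$omega)
  }
  records <- lapply(seq_len(ntip), function(i) {
    u <- node_units[[i]]
    assemble_genome(unlist(u$features), unlist(u$gaps), template,
                    id = tree$tip.label[i], species = tree$tip.label[i])
  })
  names(records) <- tree$tip.label
  structure(list(records = records, tree = tree, config = config),
            class = "sim_clade")
}

#' @export
print.sim_clade <- function(x, ...) {
  cat(sprintf("<sim_clade> %d taxa, genome %s bp, omega %s\n",
              length(x$records),
              format(x$records[[1L]]$genome$length, big.mark = ","),
              paste(format(x$config$omega), collapse = "/")))
  invisible(x)
}

#' Simulate a full clade in one call
#'
#' @param config A `sim_config`.
#' @return A `sim_clade`.
#' @export
simulate_clade <- function(config = sim_config()) {
  evolve_clade(make_reference_genome(config), config)
}

#' Write a feature table in the package TSV dialect
#'
#' @param table A `mito_features` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Write a simulated clade to disk
#'
#' One FASTA and one feature-table TSV per taxon, plus a plain key-value
#' truth file with the generating parameters.
#'
#' @param clade A `sim_clade`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulated <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(clade$records)) {
    rec <- clade$records[[nm]]
    writeLines(c(paste0(">", nm), rec$genome$sequence),
               file.path(dir, paste0(nm, ".fasta")))
    write_feature_table(rec$features, file.path(dir, paste0(nm, ".tsv")))
  }
  cfg <- clade$config
  truth <- c(sprintf("seed=%d", cfg$seed),
             sprintf("template=%s", cfg$template),
             sprintf("omega=%s", paste(cfg$omega, collapse = ",")),
             sprintf("at_fraction=%s",
                     paste(sprintf("%s:%g", names(cfg$at_fraction),
                                   cfg$at_fraction), collapse = ",")),
             sprintf("tree=%s", if (is.character(cfg$tree)) cfg$tree else
               ape::write.tree(cfg$tree)))
  writeLines(truth, file.path(dir, "truth.txt"))
  invisible(dir)
}
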