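# Independent oracles and small builders used across test files.

# brute-force pathway enumerator for codon differences: recursive DFS over
# the differing positions, avoiding stop codons; returns the average
# (synonymous, nonsynonymous) step counts over all stop-free paths.
oracle_count_differences <- function(a, b) {
  gc5 <- Biostrings::getGeneticCode("5")
  paths <- list()
  walk <- function(cur, sd, nd) {
    rest <- which(strsplit(cur, "")[[1]] != strsplit(b, "")[[1]])
    if (!length(rest)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (p in rest) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (gc5[[nxt]] == "*") next
      if (gc5[[cur]] == gc5[[nxt]]) walk(nxt, sd + 1L, nd)
      else walk(nxt, sd, nd + 1L)
    }
  }
  walk(a, 0L, 0L)
  if (!length(paths)) return(NULL)   # all routes through stops
  colMeans(do.call(rbind, paths))
}

# enumeration oracle for per-codon site counts (stop-excluded renormalized)
oracle_count_sites <- function(codon) {
  gc5 <- Biostrings::getGeneticCode("5")
  S <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    muts <- setdiff(c("A", "C", "G", "T"), ref)
    aas <- vapply(muts, function(m) {
      x <- codon
      substr(x, pos, pos) <- m
      gc5[[x]]
    }, "")
    aas <- aas[aas != "*"]
    if (length(aas)) S <- S + mean(aas == gc5[[codon]])
  }
  c(S = S, N = 3 - S)
}

sense_codons_t5 <- function() {
  gc5 <- Biostrings::getGeneticCode("5")
  names(gc5)[gc5 != "*"]
}

# minimal hand-built annotated record: one J PCG, one N tRNA, control span
tiny_record <- function() {
  pcg <- "ATGAAATTACCCGGGTAA"                      # 6 codons, stop TAA
  trna <- design_trna("CAT", dhu = 3, ac = 4, tpsic = 4)$seq
  ctrl <- paste(rep("AT", 30), collapse = "")
  genome_seq <- paste0(pcg, rev_comp(trna), ctrl)
  df <- data.frame(
    name = c("ND2", "trnM", "AT_rich"),
    category = c("PCG", "tRNA", "control"),
    strand = c("J", "N", "J"),
    start = c(1L, nchar(pcg) + 1L, nchar(pcg) + nchar(trna) + 1L),
    end = c(nchar(pcg), nchar(pcg) + nchar(trna), nchar(genome_seq)),
    anticodon = c(NA, "CAT", NA),
    initiation_codon = c("ATG", NA, NA),
    termination_codon = c("TAA", NA, NA),
    stringsAsFactors = FALSE)
  mito_record(mito_genome(genome_seq, id = "tiny"), mito_features(df))
}

anticodons_22 <- c("GAT", "TTG", "CAT", "TCA", "GCA", "GTA", "TAA", "GTC",
                   "CTT", "TGC", "TCG", "GTT", "GCT", "TTC", "GAA", "GTG",
                   "TGT", "TGG", "TGA", "TAG", "TAC", "TCC")
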