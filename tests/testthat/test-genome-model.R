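test_that("feature table constructor enforces coordinate and identity rules", {
  df <- data.frame(name = "g1", category = "PCG", strand = "J",
                   start = 10, end = 5)
  expect_error(mito_features(df), "coordinate error")
  df2 <- data.frame(name = c("a", "a"), category = "tRNA", strand = "J",
                    start = c(1, 50), end = c(40, 90))
  expect_error(mito_features(df2), "duplicate")
  expect_error(mito_features(df2[0, ]), "empty")
  df3 <- data.frame(name = "a", category = "tRNA", strand = "J",
                    start = 1, end = 120)
  expect_error(mito_features(df3, genome_length = 100), "beyond genome")
})

test_that("packaged fixtures load with the full 38-feature complement", {
  for (sp in c("F_sunanensis", "F_amplivertica", "F_nigritibia",
               "F_pamphagoides", "F_dingxiensis")) {
    ft <- emit_fixture(sp)
    expect_s3_class(ft, "mito_features")
    expect_identical(nrow(ft), 38L)
    counts <- summarize_gene_counts(ft)
    expect_identical(sum(counts["PCG", ]), 13L)
    expect_identical(sum(counts["tRNA", ]), 22L)
    expect_identical(sum(counts["rRNA", ]), 2L)
    expect_identical(sum(counts["control", ]), 1L)
  }
  ft <- emit_fixture("F_sunanensis")
  expect_identical(genome_length(ft), 15656L)
  expect_identical(ft$end[ft$name == "trnI"] - ft$start[ft$name == "trnI"] + 1L,
                   68L)
  expect_error(emit_fixture("F_unknown"), "name error")
})

test_that("circular accounting conserves the genome length on every fixture", {
  for (sp in c("F_sunanensis", "F_amplivertica", "F_nigritibia",
               "F_pamphagoides", "F_dingxiensis")) {
    ft <- emit_fixture(sp)
    sizes <- ft$end - ft$start + 1L
    spacers <- compute_spacers(ft)$spacer_length
    expect_identical(sum(sizes) + sum(spacers), genome_length(ft),
                     info = sp)
  }
})

test_that("spacer convention matches the annotation table (gap to next gene)", {
  ft <- emit_fixture("F_sunanensis")
  sp <- compute_spacers(ft)
  get <- function(g) sp$spacer_length[sp$upstream_gene == g]
  expect_identical(get("trnI"), 0L)
  expect_identical(get("trnK"), 17L)
  expect_identical(get("ATP8"), -7L)
  expect_identical(get("trnQ"), -1L)
  # last record wraps circularly to the first feature
  expect_identical(sp$downstream_gene[nrow(sp)], "trnI")
  shuffled <- mito_features(as.data.frame(ft)[rev(seq_len(nrow(ft))), ],
                            genome_length = genome_length(ft))
  expect_error(compute_spacers(shuffled), "ordering error")
})

test_that("strand-resolved gene counts match the study inventory", {
  ft <- emit_fixture("F_sunanensis")
  counts <- summarize_gene_counts(ft)
  expect_identical(counts["PCG", "J"], 9L)
  expect_identical(counts["PCG", "N"], 4L)
  expect_identical(counts["tRNA", "J"], 14L)
  expect_identical(counts["tRNA", "N"], 8L)
  expect_identical(counts["rRNA", "N"], 2L)
  one <- mito_features(data.frame(name = "trnX", category = "tRNA",
                                  strand = "J", start = 1, end = 70))
  m <- summarize_gene_counts(one)
  expect_identical(m["tRNA", "J"], 1L)
  expect_identical(sum(m), 1L)
})

test_that("feature extraction is strand-aware and involutive", {
  g <- mito_genome("ATGCCC", id = "t")
  j <- list(start = 1, end = 3, strand = "J")
  n <- list(start = 1, end = 3, strand = "N")
  expect_identical(extract_feature_sequence(g, j), "ATG")
  expect_identical(extract_feature_sequence(g, n), "CAT")
  expect_identical(rev_comp(rev_comp("ATGCCC")), "ATGCCC")
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    expect_identical(rev_comp(rev_comp(s)), s)
  }
  expect_error(extract_feature_sequence(g, list(start = 2, end = 9,
                                                strand = "J")),
               "coordinate error")
})

test_that("feature-table TSV round-trips and rejects degenerate input", {
  ft <- emit_fixture("F_nigritibia")
  tmp <- tempfile(fileext = ".tsv")
  write_feature_table(ft, tmp)
  back <- read_feature_table(tmp)
  expect_identical(as.data.frame(back), as.data.frame(ft))
  expect_identical(genome_length(back), genome_length(ft))
  empty <- tempfile(fileext = ".tsv")
  writeLines("name\tcategory\tstrand\tstart\tend", empty)
  expect_error(read_feature_table(empty), "empty-table")
})

test_that("genbank round-trip recovers coordinates, strands and codons", {
  rec <- tiny_record()
  tmp <- tempfile(fileext = ".gb")
  write_genbank(rec, tmp)
  back <- read_genbank(tmp)
  expect_identical(back$genome$sequence, rec$genome$sequence)
  expect_identical(back$features$start, rec$features$start)
  expect_identical(back$features$end, rec$features$end)
  expect_identical(back$features$strand, rec$features$strand)
  expect_identical(back$features$category, rec$features$category)
  # PCG codons are re-derived from the sequence slice
  expect_identical(back$features$initiation_codon[1], "ATG")
  expect_identical(back$features$termination_codon[1], "TAA")
  expect_identical(back$features$anticodon[2], "CAT")
  expect_error(suppressWarnings(read_genbank(tempfile())),
               "cannot open|parse error")
  bad <- tempfile()
  writeLines("not a genbank file", bad)
  expect_error(read_genbank(bad), "parse error")
})

test_that("genbank reader derives incomplete stops and infers the control region", {
  # PCG of length 3k+1 ending in T (incomplete stop), no control annotated
  pcg <- paste0("ATG", "AAATTACCCGGG", "T")           # 16 bp, remainder T
  trna <- design_trna("GAT", dhu = 3, ac = 4, tpsic = 4)$seq
  rrna <- paste(rep("AGTC", 20), collapse = "")
  tail_len <- 40L
  genome_seq <- paste0(pcg, trna, rrna,
                       paste(rep("TA", tail_len / 2), collapse = ""))
  df <- data.frame(
    name = c("ND2", "trnI", "srRNA"),
    category = c("PCG", "tRNA", "rRNA"),
    strand = "J",
    start = c(1L, 17L, 17L + nchar(trna)),
    end = c(16L, 16L + nchar(trna), 16L + nchar(trna) + 80L),
    anticodon = c(NA, "GAT", NA),
    initiation_codon = c("ATG", NA, NA),
    termination_codon = c("T", NA, NA), stringsAsFactors = FALSE)
  rec <- mito_record(mito_genome(genome_seq, id = "inc"), mito_features(
    df, genome_length = nchar(genome_seq)))
  tmp <- tempfile(fileext = ".gb")
  write_genbank(rec, tmp)
  back <- read_genbank(tmp)
  expect_identical(back$features$termination_codon[
    back$features$name == "ND2"], "T")
  ctrl <- back$features[back$features$category == "control", ]
  expect_identical(nrow(ctrl), 1L)
  expect_identical(ctrl$start, 16L + nchar(trna) + 80L + 1L)
  expect_identical(ctrl$end, nchar(genome_seq))
})
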