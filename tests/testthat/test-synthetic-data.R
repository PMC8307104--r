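test_that("the generator is seed-deterministic and structurally complete", {
  cfg <- sim_config(seed = 99)
  r1 <- make_reference_genome(cfg)
  r2 <- make_reference_genome(cfg)
  expect_identical(r1$genome$sequence, r2$genome$sequence)
  expect_identical(as.data.frame(r1$features), as.data.frame(r2$features))
  counts <- summarize_gene_counts(r1$features)
  expect_identical(nrow(r1$features), 38L)
  expect_identical(sum(counts["PCG", ]), 13L)
  expect_identical(sum(counts["tRNA", ]), 22L)
  expect_identical(sum(counts["rRNA", ]), 2L)
  expect_identical(sum(counts["control", ]), 1L)
  # different seed, different genome
  expect_false(identical(
    make_reference_genome(sim_config(seed = 100))$genome$sequence,
    r1$genome$sequence))
})

test_that("simulated PCGs are clean table-5 reading frames with the template codons", {
  rec <- make_reference_genome(sim_config(seed = 7))
  template <- emit_fixture("F_sunanensis")
  gc5 <- Biostrings::getGeneticCode("5")
  for (g in names(pcg_sequences(rec))) {
    s <- pcg_sequences(rec)[[g]]
    trow <- template[template$name == g, ]
    expect_identical(nchar(s), trow$end - trow$start + 1L, info = g)
    expect_identical(substr(s, 1, 3), trow$initiation_codon, info = g)
    term <- trow$termination_codon
    expect_identical(substr(s, nchar(s) - nchar(term) + 1L, nchar(s)),
                     term, info = g)
    internal <- extract_codons(s)$codons[-1]
    if (nchar(term) == 3L) internal <- internal[-length(internal)]
    expect_false(any(gc5[internal] == "*"), info = g)
  }
})

test_that("simulated tRNAs fold, with the Ser(AGN) DHU arm absent", {
  rec <- make_reference_genome(sim_config(seed = 13))
  ft <- rec$features
  for (i in which(ft$category == "tRNA")) {
    s <- extract_feature_sequence(rec$genome, ft[i, ])
    st <- fold_trna(s, ft$anticodon[i])
    if (grepl("AGN", ft$name[i])) {
      expect_false(st$dhu_present, info = ft$name[i])
    } else {
      expect_true(st$dhu_present, info = ft$name[i])
    }
  }
})

test_that("the configured control-region A+T fraction is realised", {
  cfg <- sim_config(seed = 21,
                    at_fraction = c(PCG = 0.73, tRNA = 0.70, rRNA = 0.73,
                                    control = 0.83, spacer = 0.73))
  rec <- make_reference_genome(cfg)
  rc <- region_composition(rec$genome, rec$features, "AT_rich")
  expect_lt(abs(rc$at_pct - 83), 2)
})

test_that("clade evolution is deterministic and preserves comparability", {
  cfg <- sim_config(seed = 3, tree = clade_tree(3, 1, brlen = 0.04))
  cl1 <- simulate_clade(cfg)
  cl2 <- simulate_clade(cfg)
  expect_identical(lapply(cl1$records, function(r) r$genome$sequence),
                   lapply(cl2$records, function(r) r$genome$sequence))
  lens <- vapply(cl1$records, function(r) r$genome$length, 0L)
  expect_identical(length(unique(lens)), 1L)
  ft0 <- as.data.frame(cl1$records[[1]]$features)
  for (r in cl1$records[-1])
    expect_identical(as.data.frame(r$features)[, c("name", "start", "end")],
                     ft0[, c("name", "start", "end")])
  expect_error(sim_config(omega = 0), "config error")
  expect_error(sim_config(at_fraction = c(PCG = 1.2)), "config error")
})

test_that("dN/dS control is monotone and recovers purifying selection", {
  means <- vapply(c(0.05, 0.3, 0.8), function(om) {
    cfg <- sim_config(seed = 17, tree = clade_tree(8, 2, brlen = 0.05),
                      omega = om)
    kk <- clade_kaks(simulate_clade(cfg)$records)
    mean(kk$mean_ratio, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(means) > 0))
  expect_true(all(means < 1))
  expect_lt(means[1], 0.12)
})

test_that("replicated simulations at omega 0.3 estimate within the design band", {
  reps <- vapply(1:20, function(i) {
    cfg <- sim_config(seed = 200 + i, tree = clade_tree(8, 2, brlen = 0.05),
                      omega = 0.3)
    mean(clade_kaks(simulate_clade(cfg)$records)$mean_ratio, na.rm = TRUE)
  }, 0)
  expect_gt(mean(reps), 0.15)
  expect_lt(mean(reps), 0.5)
})

test_that("simulated clades export FASTA, tables and a truth file", {
  cl <- simulate_clade(sim_config(seed = 8, tree = clade_tree(2, 1,
                                                              brlen = 0.02)))
  dir <- tempfile()
  write_simulated(cl, dir)
  files <- list.files(dir)
  expect_true(all(paste0(names(cl$records), ".fasta") %in% files))
  expect_true(all(paste0(names(cl$records), ".tsv") %in% files))
  expect_true("truth.txt" %in% files)
  truth <- readLines(file.path(dir, "truth.txt"))
  expect_true(any(grepl("^seed=8$", truth)))
  back <- read_feature_table(file.path(dir, paste0(names(cl$records)[1],
                                                   ".tsv")))
  expect_identical(nrow(back), 38L)
})
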