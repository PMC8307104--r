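test_that("a designed 7/4/5/5 cloverleaf is refolded exactly", {
  set.seed(101)
  des <- design_trna("CAT", dhu = 4, ac = 5, tpsic = 5, dhu_loop = 7,
                     total_length = 69)
  expect_identical(nchar(des$seq), 69L)
  st <- fold_trna(des$seq, "CAT")
  expect_identical(unname(st$arm_lengths), c(7L, 4L, 5L, 5L))
  expect_equal(st$score, 2 * 21)                # all pairs Watson-Crick
  cl <- classify_pairs(st, des$seq)
  expect_identical(cl$watson_crick, 21L)
  expect_identical(cl$gu_wobble, 0L)
  expect_identical(nrow(cl$mismatches), 0L)
})

test_that("the DHU-arm-free topology is detected and input bounds enforced", {
  set.seed(102)
  des0 <- design_trna("GCT", dhu = 0, ac = 5, tpsic = 5, var_loop = 5)
  st0 <- fold_trna(des0$seq, "GCT")
  expect_false(st0$dhu_present)
  expect_identical(st0$arm_lengths[["dhu"]], 0L)
  expect_error(fold_trna(paste(rep("A", 20), collapse = ""), "CAT"),
               "too-short")
  des <- design_trna("CAT")
  expect_error(fold_trna(des$seq, "GGG"), "anchor error")
})

test_that("every fold partitions the sequence and centres the anticodon", {
  set.seed(103)
  for (i in 1:40) {
    ac <- sample(anticodons_22, 1)
    des <- design_trna(ac, dhu = sample(2:4, 1), ac = sample(3:6, 1),
                       tpsic = sample(3:6, 1), dhu_loop = sample(3:8, 1),
                       tpsic_loop = sample(3:9, 1), var_loop = sample(3:9, 1))
    st <- fold_trna(des$seq, ac)
    roles <- mitocompare:::structure_roles(st)
    expect_identical(length(roles), st$length)      # partition property
    expect_false(anyNA(roles))
    expect_identical(anyDuplicated(roles), 0L)
    # anchored anticodon occupies loop positions 3-5 of the 7-nt loop
    expect_identical(st$anticodon_position - st$ac_loop_span[1] + 1L, 3L)
    expect_identical(st$ac_loop_span[2] - st$ac_loop_span[1] + 1L, 7L)
  }
})

test_that("pair classification distinguishes WC, wobble and mismatch types", {
  set.seed(104)
  des <- design_trna("CAT", dhu = 4, ac = 5, tpsic = 5)
  st <- fold_trna(des$seq, "CAT")
  chars <- strsplit(des$seq, "")[[1]]
  # flip the acceptor 3' partner of a G or C 5' base into a wobble/mismatch
  p <- st$acceptor_pairs
  mut <- chars
  mut[p[1, 2]] <- switch(chars[p[1, 1]], A = "G", C = "A", G = "T",
                         T = "G")
  cl <- classify_pairs(st, paste(mut, collapse = ""))
  expect_identical(cl$watson_crick + cl$gu_wobble + nrow(cl$mismatches),
                   cl$total)
  expect_identical(cl$watson_crick, 20L)
  if (chars[p[1, 1]] %in% c("G", "T")) {
    expect_identical(cl$gu_wobble, 1L)
  } else {
    expect_identical(nrow(cl$mismatches), 1L)
    expect_identical(cl$mismatches$type,
                     paste0(chars[p[1, 1]], "-", mut[p[1, 2]]))
  }
})

test_that("template designs are refolded to their generating arm lengths", {
  set.seed(105)
  n <- 250L; ok <- 0L
  for (i in seq_len(n)) {
    ac <- sample(anticodons_22, 1)
    des <- design_trna(ac, dhu = sample(2:4, 1), ac = sample(3:6, 1),
                       tpsic = sample(3:6, 1), dhu_loop = sample(3:8, 1),
                       tpsic_loop = sample(3:9, 1), var_loop = sample(3:9, 1))
    st <- fold_trna(des$seq, ac)
    if (identical(unname(st$arm_lengths), unname(des$arm_lengths)))
      ok <- ok + 1L
  }
  expect_gte(ok / n, 0.99)
})

test_that("cross-species comparison labels conserved and variable roles", {
  set.seed(106)
  des <- design_trna("TGC", dhu = 3, ac = 4, tpsic = 4)
  st <- fold_trna(des$seq, "TGC")
  same <- compare_structures(list(a = st, b = st, c = st),
                             list(a = des$seq, b = des$seq, c = des$seq))
  expect_true(all(same$conserved))
  # one substitution in one species -> exactly one variable role
  chars <- strsplit(des$seq, "")[[1]]
  loop_pos <- st$tpsic_loop_span[1]
  chars[loop_pos] <- setdiff(c("A", "C", "G", "T"), chars[loop_pos])[1]
  mutated <- paste(chars, collapse = "")
  st2 <- fold_trna(mutated, "TGC")
  cmp <- compare_structures(list(a = st, b = st2),
                            list(a = des$seq, b = mutated))
  expect_identical(sum(!cmp$conserved), 1L)
  # anticodon roles stay conserved across species
  ac_roles <- paste0("acL.", 3:5)
  expect_true(all(cmp$conserved[cmp$role %in% ac_roles]))
})

test_that("the relaxed anticodon loop is only used on request", {
  set.seed(107)
  # a 9-nt loop design: insert two extra loop bases around the anticodon
  des <- design_trna("TGC", dhu = 4, ac = 5, tpsic = 5)
  st7 <- fold_trna(des$seq, "TGC", relax_ac_loop = TRUE)
  expect_identical(st7$ac_loop_span[2] - st7$ac_loop_span[1] + 1L, 7L)
})
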