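test_that("activity arithmetic matches the printed survey numbers", {
  est <- estimate_activity(856, 148, 8)
  expect_equal(est$percent, 5.4)
  expect_equal(est$extrapolated_total, 46L)
  z <- estimate_activity(1000, 100, 0)
  expect_equal(c(z$percent, z$extrapolated_total), c(0, 0))
  full <- estimate_activity(100, 100, 100)
  expect_equal(c(full$percent, full$extrapolated_total), c(100, 100))
  expect_error(estimate_activity(10, 0, 0), "positive")
  expect_error(estimate_activity(10, 20, 5))
  expect_error(estimate_activity(10, 10, 11))
})

test_that("activity extrapolation scales linearly in total sites", {
  set.seed(161)
  for (i in 1:10) {
    n <- sample(50:500, 1)
    k <- sample.int(n, 1)
    total <- n + sample.int(1000, 1)
    e1 <- estimate_activity(total, n, k)
    e2 <- estimate_activity(2L * total, n, k)
    expect_lte(abs(e2$extrapolated_total - 2L * e1$extrapolated_total), 1L)
  }
})

test_that("locus alignment favors one long indel for a missing element", {
  set.seed(171)
  flank_l <- rseq(400, 0.45); flank_r <- rseq(400, 0.45)
  elem <- rseq(2000, 0.3)
  a <- paste0(flank_l, elem, flank_r)
  b <- paste0(flank_l, flank_r)
  al <- align_locus(a, b)
  runs <- rle(strsplit(al$b_aln, "")[[1]] == "-")
  big <- max(runs$lengths[runs$values])
  expect_gte(big, 1990L)  # essentially one contiguous 2 kb gap block
  ident <- align_locus(a, a)
  expect_false(grepl("-", ident$a_aln, fixed = TRUE))
  expect_equal(ident$identity, 1)
  expect_error(align_locus(a, b, max_len = 100), "cap")
})

test_that("locus alignment score equals the affine DP oracle on small instances", {
  set.seed(181)
  for (i in 1:5) {
    a <- rseq(70)
    b <- paste0(substr(a, 1, 25), rseq(sample(5:15, 1)), substr(a, 36, 70))
    expect_equal(align_locus(a, b)$score, nw_affine_oracle(a, b, 1, -2, 6, 0.5))
  }
})

test_that("identical loci with a shared element are called shared", {
  elem <- make_element(seed = 201)
  set.seed(202)
  locus <- paste0(rseq(500, 0.43), as.character(elem), rseq(500, 0.43))
  cl <- classify_locus(list(seq_a = locus, seq_b = locus, id = "L1"),
                       as.character(elem))
  expect_equal(cl$klass, "shared")
})

test_that("a bloc unit-count difference is called repeat variation", {
  elem <- make_element(seed = 203)
  blocs <- attr(elem, "blocs")
  e_var <- heliscan:::vary_bloc_units(as.character(elem), blocs[1, ], -2L)
  set.seed(204)
  fl <- rseq(500, 0.43); fr <- rseq(500, 0.43)
  cl <- classify_locus(list(seq_a = paste0(fl, as.character(elem), fr),
                            seq_b = paste0(fl, e_var, fr), id = "L1"),
                       as.character(elem))
  expect_equal(cl$klass, "repeat_variation")
})

test_that("empty orthologous loci are called empty_shared", {
  elem <- make_element(seed = 205)
  set.seed(206)
  locus <- rseq(1200, 0.43)
  cl <- classify_locus(list(seq_a = locus, seq_b = locus),
                       as.character(elem))
  expect_equal(cl$klass, "empty_shared")
})

test_that("carrier flips when the genomes are swapped", {
  spec <- divergence_spec(n_insertions = 1, n_excisions = 0,
                          excision_mix = c(incomplete = 0,
                                           flank_deletion = 0, filler = 0),
                          n_repeat_variants = 0, n_shared = 2,
                          point_mutation_rate = 0)
  pair <- simulate_pair(spec, copy_divergence = 0, seed = 207)
  loci <- orthologous_loci(pair)
  ins <- loci[loci$class == "insertion", ]
  c_ab <- classify_locus(list(seq_a = ins$seq_a, seq_b = ins$seq_b),
                         pair$consensus)
  c_ba <- classify_locus(list(seq_a = ins$seq_b, seq_b = ins$seq_a),
                         pair$consensus)
  expect_equal(c_ab$klass, "insertion")
  expect_equal(c_ba$klass, "insertion")
  expect_equal(c_ab$carrier, "a")
  expect_equal(c_ba$carrier, "b")
})

test_that("clean generator output is classified perfectly, noisy output >= 90 percent", {
  spec <- divergence_spec(n_insertions = 2, n_excisions = 4,
                          n_repeat_variants = 3, n_shared = 3,
                          point_mutation_rate = 0)
  pair <- simulate_pair(spec, copy_divergence = 0, seed = 211)
  loci <- orthologous_loci(pair)
  calls <- classify_loci(loci, pair$consensus)
  expect_equal(calls$klass, loci$class)

  spec_n <- divergence_spec(n_insertions = 3, n_excisions = 4,
                            n_repeat_variants = 5, n_shared = 5,
                            point_mutation_rate = 0.01)
  pair_n <- simulate_pair(spec_n, seed = 212)
  loci_n <- orthologous_loci(pair_n)
  calls_n <- classify_loci(loci_n, pair_n$consensus)
  expect_gte(mean(calls_n$klass == loci_n$class), 0.9)
})

test_that("summary counts classes and wires the activity estimate", {
  calls <- data.frame(
    locus_id = sprintf("L%d", 1:10),
    klass = c("shared", "shared", "repeat_variation", "insertion",
              "insertion", "excision_incomplete", "excision_filler",
              "excision_flank_deletion", "empty_shared", "unresolved"))
  s <- polymorphism_summary(calls, total_sites = 100)
  expect_equal(unname(s$counts["shared"]), 2L)
  expect_equal(unname(s$counts["insertion"]), 2L)
  expect_equal(s$activity$true_polymorphic, 5L)
  expect_equal(s$activity$percent, 50.0)
  expect_equal(s$activity$extrapolated_total, 50L)
})
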