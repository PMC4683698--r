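test_that("the default synthetic element carries the full canonical structure", {
  e <- make_element(seed = 42)
  n <- nchar(e)
  expect_lte(abs(n - 1993L), 50L)
  expect_identical(substr(as.character(e), 1, 2), "TC")
  expect_identical(substr(as.character(e), n - 3, n), "CTAG")
  hit <- find_hairpin(as.character(e), n)
  expect_equal(hit$total_len, 16L)
  expect_equal(hit$offset_3p, 13L)
  blocs <- attr(e, "blocs")
  expect_equal(blocs$label, c("A", "B"))
  expect_equal(blocs$unit_count, c(6L, 6L))
})

test_that("element generation is deterministic in the seed", {
  e1 <- make_element(seed = 314)
  e2 <- make_element(seed = 314)
  e3 <- make_element(seed = 315)
  expect_identical(as.character(e1), as.character(e2))
  expect_false(identical(as.character(e1), as.character(e3)))
})

test_that("a degenerate spec without blocs still renders termini and hairpin", {
  spec <- element_spec(
    blocA = list(unit_length = 137L, unit_count = 0L, gc = 0.2, divergence = 0),
    blocB = list(unit_length = 152L, unit_count = 0L, gc = 0.4, divergence = 0),
    target_length = NULL)
  e <- make_element(spec, seed = 9)
  n <- nchar(e)
  expect_identical(substr(as.character(e), 1, 2), "TC")
  expect_identical(substr(as.character(e), n - 3, n), "CTAG")
  expect_equal(find_hairpin(as.character(e), n)$offset_3p, 13L)
  expect_equal(nrow(attr(e, "blocs")), 0L)
})

test_that("infeasible element targets error out", {
  expect_error(make_element(element_spec(target_length = 1000L), seed = 1),
               "infeasible")
})

test_that("per-bloc GC stays within 0.05 of the targets across seeded draws", {
  gcs <- t(vapply(1:10, function(s) {
    e <- make_element(seed = 1000 + s)
    bl <- attr(e, "blocs")
    one <- function(i) {
      r <- charToRaw(substr(e, bl$start[i], bl$end[i]))
      sum(r == charToRaw("G") | r == charToRaw("C")) / length(r)
    }
    c(one(1), one(2))
  }, c(0, 0)))
  expect_true(all(abs(gcs[, 1] - 0.20) < 0.05))
  expect_true(all(abs(gcs[, 2] - 0.40) < 0.05))
})

test_that("planting places every element at a valid insertion site", {
  elems <- lapply(1:4, function(i) make_element(seed = 400 + i))
  pl <- plant_elements(40000, gc = 0.43, elements = elems, seed = 405)
  expect_equal(nrow(pl$truth), 4L)
  for (i in seq_len(nrow(pl$truth)))
    expect_true(validate_insertion_site(
      pl$genome, interval(pl$truth$record_id[i], pl$truth$start[i],
                          pl$truth$end[i])))
  # spacing respected
  expect_true(all(diff(pl$truth$start) > 1000L))
})

test_that("planting zero elements returns pure background of the right length", {
  pl <- plant_elements(5000, gc = 0.5, elements = list(), seed = 1)
  expect_equal(nchar(pl$genome[[1]]), 5000L)
  expect_equal(nrow(pl$truth), 0L)
})

test_that("a too-small genome errors", {
  elems <- lapply(1:5, function(i) make_element(seed = i))
  expect_error(plant_elements(6000, elements = elems, seed = 1), "too small")
})

test_that("truth table class counts equal the divergence spec exactly", {
  spec <- divergence_spec(n_insertions = 2, n_excisions = 4,
                          n_repeat_variants = 3, n_shared = 3)
  pair <- simulate_pair(spec, seed = 500)
  tab <- table(pair$truth$class)
  expect_equal(unname(tab[["insertion"]]), 2L)
  expect_equal(unname(tab[["excision_incomplete"]]), 2L)
  expect_equal(unname(tab[["excision_flank_deletion"]]), 1L)
  expect_equal(unname(tab[["excision_filler"]]), 1L)
  expect_equal(unname(tab[["repeat_variation"]]), 3L)
  expect_equal(unname(tab[["shared"]]), 2L + 1L)  # 3 shared
  # footprint geometry recorded for the right classes only
  expect_true(all(!is.na(pair$truth$residual_bp[
    pair$truth$class == "excision_incomplete"])))
  expect_true(all(is.na(pair$truth$residual_bp[
    pair$truth$class == "shared"])))
})

test_that("an all-zero divergence spec reproduces the genome identically", {
  z <- divergence_spec(0, 0, c(incomplete = 0, flank_deletion = 0, filler = 0),
                       0, 2, 0)
  pz <- simulate_pair(z, copy_divergence = 0, seed = 3)
  expect_identical(pz$genome_a, pz$genome_b)
})

test_that("a planted/spec mismatch errors with the shortfall", {
  elems <- lapply(1:2, function(i) make_element(seed = 600 + i))
  pl <- plant_elements(20000, elements = elems, seed = 602)
  expect_error(diverge_pair(pl, divergence_spec(n_insertions = 0,
                                                n_excisions = 0,
                                                excision_mix = c(incomplete = 0,
                                                                 flank_deletion = 0,
                                                                 filler = 0),
                                                n_repeat_variants = 0,
                                                n_shared = 5)),
               "needs exactly")
})

test_that("the full simulation is byte-identical under a fixed seed", {
  spec <- divergence_spec(n_insertions = 1, n_excisions = 2,
                          excision_mix = c(incomplete = 1,
                                           flank_deletion = 1, filler = 0),
                          n_repeat_variants = 1, n_shared = 1)
  p1 <- simulate_pair(spec, seed = 777)
  p2 <- simulate_pair(spec, seed = 777)
  expect_identical(p1$genome_a, p2$genome_a)
  expect_identical(p1$genome_b, p2$genome_b)
  expect_identical(p1$truth, p2$truth)
  p3 <- simulate_pair(spec, seed = 778)
  expect_false(identical(p1$genome_a, p3$genome_a))
})

test_that("size variants preserve the probe termini", {
  arch <- make_element(seed = 800)
  set.seed(801)
  v <- element_size_variant(as.character(arch), 5000)
  expect_equal(nchar(v), 5000L)
  expect_identical(substr(v, 1, 200), substr(as.character(arch), 1, 200))
  expect_identical(substr(v, 4801, 5000),
                   substr(as.character(arch), nchar(arch) - 199, nchar(arch)))
})
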