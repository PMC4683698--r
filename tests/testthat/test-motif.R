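test_that("IUPAC matching covers degenerate codes and is conservative on N", {
  expect_true(match_iupac("CTRR", "CTAG"))
  expect_true(match_iupac("CTRR", "CTGA"))
  expect_false(match_iupac("CTRR", "CTTT"))
  expect_true(match_iupac("TC", "ATCA", pos = 2))
  expect_false(match_iupac("N", "N"))       # sequence N matches nothing
  expect_true(match_iupac("N", "A"))
  expect_error(match_iupac("CTRR", "CTA"))  # does not fit
  expect_error(match_iupac("QQ", "ACGT"))
})

test_that("find_hairpin recovers a planted perfect stem-loop geometry", {
  set.seed(5)
  stem <- "GCGCGC"
  hp <- paste0(stem, "ATAA", reverse_complement(stem))  # 16 bp
  elem <- paste0(rseq(150, 0.3), "A", hp, "A", rseq(8, 0.3), "CTAG")
  tp <- nchar(elem)
  hit <- find_hairpin(elem, tp)
  expect_s3_class(hit, "hairpin_hit")
  expect_equal(hit$total_len, 16L)
  expect_equal(hit$offset_3p, 13L)
  expect_equal(hit$stem_len, 6L)
  expect_equal(hit$mismatches_in_stem, 0L)
  expect_gte(hit$gc_fraction, 0.6)
})

test_that("find_hairpin returns NULL without an inverted repeat", {
  polyA <- strrep("A", 60)
  expect_null(find_hairpin(polyA, 60))
})

test_that("find_hairpin agrees with exhaustive enumeration on random windows", {
  set.seed(99)
  n_hit <- 0
  for (i in 1:200) {
    w <- rseq(60, sample(c(0.4, 0.6, 0.7), 1))
    got <- find_hairpin(w, 60)
    want <- brute_hairpin(w, 60)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_hit <- n_hit + 1
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$stem_len, want$stem_len)
      expect_equal(got$loop_len, want$loop_len)
      expect_equal(got$mismatches_in_stem, want$mm)
      expect_equal(got$offset_3p, want$off)
    }
  }
  expect_gt(n_hit, 5)  # the comparison actually exercised positive cases
})

test_that("hairpin hits always respect the configured geometry ranges", {
  set.seed(3)
  p <- hairpin_params()
  for (i in 1:50) {
    w <- rseq(80, 0.65)
    hit <- find_hairpin(w, 80, p)
    if (is.null(hit)) next
    expect_gte(hit$total_len, p$total_min)
    expect_lte(hit$total_len, p$total_max)
    expect_gte(hit$offset_3p, p$offset_min)
    expect_lte(hit$offset_3p, p$offset_max)
    expect_lte(hit$mismatches_in_stem, p$max_mismatch)
  }
})

test_that("insertion-site rule accepts A^T and T^T, rejects others", {
  g <- c(chr = "GGATCCGGTACGGTCC")
  #          A[TCCGG]T  -> element 3..7 flanked by A and T
  expect_true(validate_insertion_site(g, interval("chr", 4, 8)))
  g2 <- c(chr = "GGTTCCGGTACGGTCC")
  expect_true(validate_insertion_site(g2, interval("chr", 4, 8)))   # T^T
  g3 <- c(chr = "GGGTCCGGCACGGTCC")
  expect_false(validate_insertion_site(g3, interval("chr", 4, 8)))  # G^C
  expect_warning(edge <- validate_insertion_site(g, interval("chr", 1, 5)))
  expect_false(edge)
})

test_that("insertion-site rule works on the minus strand", {
  # element on '-': flanks read A^T in element orientation means the
  # forward strand shows A [revcomp(element)] T complemented: ...A elem T...
  elem <- "GGCC"
  g <- c(chr = paste0("TTT", "A", reverse_complement(elem), "T", "CCC"))
  iv <- interval("chr", 5, 8, strand = "-")
  expect_true(validate_insertion_site(g, iv))
})

test_that("candidate scoring integrates all four structural criteria", {
  elem <- make_element(seed = 42)
  pl <- plant_elements(20000, gc = 0.43, elements = list(elem), seed = 43)
  iv <- interval(pl$truth$record_id[1], pl$truth$start[1], pl$truth$end[1])
  cc <- call_candidate(pl$genome, iv)
  expect_equal(cc$score, 4L)
  expect_true(cc$has_5p_motif && cc$has_3p_motif &&
                cc$has_hairpin && cc$has_AT_site)
  expect_equal(cc$hairpin$total_len, 16L)

  # knock out the 3' motif only
  g2 <- pl$genome
  s <- g2[[1]]
  substr(s, pl$truth$end[1] - 1L, pl$truth$end[1]) <- "TT"  # CTAG -> CTTT
  g2[[1]] <- s
  cc2 <- call_candidate(g2, iv)
  expect_false(cc2$has_3p_motif)
  expect_equal(cc2$score, 3L)
})

test_that("candidate flags are strand symmetric", {
  elem <- make_element(seed = 8)
  pl <- plant_elements(20000, gc = 0.43, elements = list(elem), seed = 9)
  iv <- interval(pl$truth$record_id[1], pl$truth$start[1], pl$truth$end[1])
  cc <- call_candidate(pl$genome, iv)
  L <- nchar(pl$genome[[1]])
  g2 <- setNames(reverse_complement(pl$genome[[1]]), names(pl$genome))
  iv2 <- interval(names(pl$genome), L - pl$truth$end[1] + 1L,
                  L - pl$truth$start[1] + 1L, strand = "-")
  cc2 <- call_candidate(g2, iv2)
  flags <- function(x) c(x$has_5p_motif, x$has_3p_motif, x$has_hairpin,
                         x$has_AT_site)
  expect_identical(flags(cc), flags(cc2))
  expect_identical(cc$hairpin$offset_3p, cc2$hairpin$offset_3p)
})

test_that("random intervals rarely satisfy three or more criteria", {
  set.seed(17)
  g <- c(chr = rseq(30000, 0.43))
  scores <- vapply(1:100, function(i) {
    st <- sample.int(30000 - 2100, 1) + 50L
    call_candidate(g, interval("chr", st, st + 1999L))$score
  }, 0L)
  expect_gte(mean(scores <= 2L), 0.95)
})

test_that("candidate export writes TSV and GFF3 with evidence attributes", {
  elem <- make_element(seed = 12)
  pl <- plant_elements(20000, gc = 0.4, elements = list(elem), seed = 13)
  iv <- interval(pl$truth$record_id[1], pl$truth$start[1], pl$truth$end[1])
  cc <- call_candidate(pl$genome, iv)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gff <- withr::local_tempfile(fileext = ".gff3")
  tab <- write_candidates(list(cc), tsv = tsv, gff3 = gff)
  expect_equal(nrow(tab), 1L)
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  expect_match(lines[2], "Helitron_candidate")
  expect_match(lines[2], "hairpin_len=16")
  expect_match(readLines(tsv)[1], "^# heliscan")
})
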