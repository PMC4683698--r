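test_that("an exact substring yields a single perfect hit with exact coordinates", {
  set.seed(21)
  subj <- rseq(5000, 0.45)
  q <- substr(subj, 2001, 2100)
  h <- seeded_local_hits(q, subj)
  expect_equal(nrow(h), 1L)
  expect_equal(h$s_start, 2001L)
  expect_equal(h$s_end, 2100L)
  expect_equal(h$q_start, 1L)
  expect_equal(h$identity, 1.0)
  expect_equal(h$aln_len, 100L)
  expect_equal(h$strand, "+")
})

test_that("a query too short for the seed errors", {
  expect_error(seeded_local_hits("ACGTAC", rseq(100)), "seed length")
})

test_that("no hits on a subject without a planted copy, confirmed by SW oracle", {
  set.seed(31)
  for (i in 1:3) {
    q <- rseq(100, 0.45)
    subj <- rseq(3000, 0.45)
    h <- seeded_local_hits(q, subj)
    expect_equal(nrow(h), 0L)
    # a hit passing the filters (len >= 80, identity >= 0.8) would need a
    # local score of at least 80*0.8 - 80*0.2 = 48 under +1/-1/-2
    expect_lt(sw_oracle_score(q, subj), 48)
    expect_lt(sw_oracle_score(reverse_complement(q), subj), 48)
  }
})

test_that("both planted diverged copies are recovered with accurate identity", {
  set.seed(41)
  q <- rseq(300, 0.45)
  n_mut <- 45  # 15 percent divergence
  copy1 <- substitute_n(q, n_mut)
  copy2 <- substitute_n(q, n_mut)
  subj <- paste0(rseq(2000, 0.45), copy1, rseq(1500, 0.45),
                 reverse_complement(copy2), rseq(2000, 0.45))
  h <- seeded_local_hits(q, subj, min_len = 80, min_identity = 0.8)
  expect_equal(nrow(h), 2L)
  expect_setequal(h$strand, c("+", "-"))
  # planted truth: 255/300 conserved; substitution-only copies, so aligned
  # identity should sit within 0.03 of the planted value
  expect_true(all(abs(h$identity - 255 / 300) < 0.03))
  expect_true(any(abs(h$s_start - 2001) <= 5))
})

test_that("recovered hits never beat the Smith-Waterman oracle score", {
  set.seed(43)
  q <- rseq(120, 0.5)
  copy <- substitute_n(q, 12)
  subj <- paste0(rseq(800), copy, rseq(800))
  h <- seeded_local_hits(q, subj, min_len = 80, min_identity = 0.8)
  expect_equal(nrow(h), 1L)
  expect_lte(h$score, sw_oracle_score(q, subj))
  # and the windowed realignment actually attains the oracle optimum here
  expect_equal(h$score, sw_oracle_score(q, subj))
})

test_that("hit merging respects the gap rule exactly at the boundary", {
  h1 <- data.frame(s_start = c(100, 451), s_end = c(300, 700), strand = "+")
  m1 <- merge_hits(h1, max_gap = 200)
  expect_equal(nrow(m1), 1L)
  expect_equal(c(m1$start, m1$end), c(100, 700))

  h2 <- data.frame(s_start = c(100, 502), s_end = c(300, 700), strand = "+")
  m2 <- merge_hits(h2, max_gap = 200)
  expect_equal(nrow(m2), 2L)

  single <- data.frame(s_start = 10, s_end = 50, strand = "-")
  expect_equal(merge_hits(single)$start, 10)
  expect_equal(nrow(merge_hits(data.frame(s_start = integer(0),
                                          s_end = integer(0),
                                          strand = character(0)))), 0L)
})

test_that("hit merging is idempotent, order-independent and strand-aware", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    st <- sort(sample.int(5000, n))
    h <- data.frame(s_start = st, s_end = st + sample(50:400, n, TRUE),
                    strand = sample(c("+", "-"), n, TRUE))
    m <- merge_hits(h)
    m_perm <- merge_hits(h[sample.int(n), ])
    expect_identical(m, m_perm)
    m2 <- merge_hits(data.frame(s_start = m$start, s_end = m$end,
                                strand = m$strand))
    expect_identical(m2[, c("start", "end", "strand")],
                     m[, c("start", "end", "strand")])
    # merged intervals on one strand never violate the gap rule
    for (sgn in unique(m$strand)) {
      ms <- m[m$strand == sgn, ]
      if (nrow(ms) > 1)
        expect_true(all(ms$start[-1] - ms$end[-nrow(ms)] - 1 > 200))
    }
  }
})

test_that("paired-termini scan recovers planted elements exactly", {
  arch <- make_element(seed = 20)
  sizes <- c(1500, 4000, 9000, 16000)
  set.seed(22)
  elems <- lapply(sizes, function(L)
    element_size_variant(as.character(arch), L))
  pl <- plant_elements(90000, gc = 0.43, elements = elems, seed = 23)
  p5 <- substr(as.character(arch), 1, 50)
  p3 <- substr(as.character(arch), nchar(arch) - 79, nchar(arch))
  loci <- paired_termini_scan(pl$genome[[1]], p5, p3)
  expect_equal(nrow(loci), length(sizes))
  expect_equal(loci$start, pl$truth$start)
  expect_equal(loci$end, pl$truth$end)
  expect_true(all(loci$span <= 25000))
})

test_that("paired-termini scan enforces span and orientation", {
  arch <- make_element(seed = 24)
  p5 <- substr(as.character(arch), 1, 50)
  p3 <- substr(as.character(arch), nchar(arch) - 79, nchar(arch))
  set.seed(25)
  # ends 30 kb apart: over the span limit
  g_far <- paste0(rseq(1000), p5, rseq(30000), p3, rseq(1000))
  expect_equal(nrow(paired_termini_scan(g_far, p5, p3)), 0L)
  # ends on opposite strands
  g_opp <- paste0(rseq(1000), p5, rseq(2000), reverse_complement(p3),
                  rseq(1000))
  expect_equal(nrow(paired_termini_scan(g_opp, p5, p3)), 0L)
})

test_that("terminal identity uses the fixed terminal-length denominator", {
  set.seed(61)
  a <- rseq(300, 0.5)
  b <- mutate_at(a, c(5, 20))             # 2 mismatches in the first 30 bp
  t30 <- terminal_identity(a, b, 30)
  expect_equal(t30$id5, 93.3)             # 28/30
  expect_equal(t30$id3, 100.0)
  ident <- terminal_identity(a, a, 30)
  expect_equal(c(ident$id5, ident$id3), c(100, 100))
  b2 <- mutate_at(a, sample(201:300, 19)) # 19 mismatches in the last 100 bp
  expect_equal(terminal_identity(a, b2, 100)$id3, 81.0)
  expect_error(terminal_identity("ACGT", a, 30), "terminal_len")
})

test_that("family classification thresholds and symmetry", {
  set.seed(71)
  a <- rseq(400, 0.5)
  expect_equal(classify_family(a, a)$verdict, "same_subfamily")

  # 2 mismatches in each terminal 30 bp, none beyond: same sub-family
  b <- mutate_at(a, c(3, 17, 385, 395))
  fb <- classify_family(a, b)
  expect_equal(fb$verdict, "same_subfamily")
  expect_equal(fb$id5_30, 93.3)

  # 8 mismatches in each terminal 30 bp (73.3 percent): near-miss, different
  cpos <- c(sample(1:30, 8), sample(371:400, 8))
  cc <- classify_family(a, mutate_at(a, cpos))
  expect_equal(cc$verdict, "different")
  expect_lt(cc$id5_30, 80)

  # family but not sub-family: clean 30-bp termini, heavy interior of the
  # terminal 100 bp windows
  dpos <- c(sample(31:100, 25), sample(301:370, 25))
  dd <- classify_family(a, mutate_at(a, dpos))
  expect_equal(dd$verdict, "same_family")

  # symmetry
  ab <- classify_family(a, b)
  ba <- classify_family(b, a)
  expect_equal(ab$verdict, ba$verdict)
  expect_equal(ab$id5_30, ba$id5_30)
  expect_error(classify_family("ACGT", a))
})
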