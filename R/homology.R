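# K-mer-seeded local homology search with length/identity hit filters, hit
# merging, paired-termini element scanning and terminal-identity family
# classification.

# Substitution matrix over {A,C,G,T,N}; N scores as a mismatch against
# everything including itself (conservative).
subst_matrix <- function(match, mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

# Pairwise alignment wrapper returning plain-R stats.
# Gap costs follow the Biostrings convention: a gap of length L costs
# gap_open + L * gap_ext.
align_pair <- function(a, b, type = "global", match = 1, mismatch = -1,
                       gap_open = 0, gap_ext = 2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = subst_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  list(score = Biostrings::score(aln),
       a_aln = pa, b_aln = sa,
       matches = Biostrings::nmatch(aln),
       columns = nchar(pa),
       a_start = Biostrings::start(Biostrings::pattern(aln)),
       a_end = Biostrings::end(Biostrings::pattern(aln)),
       b_start = Biostrings::start(Biostrings::subject(aln)),
       b_end = Biostrings::end(Biostrings::subject(aln)))
}

# All (qpos, spos) pairs of exact shared k-mers (k-mers containing N are
# skipped).
kmer_seeds <- function(query, subject, k) {
  nq <- nchar(query); ns <- nchar(subject)
  if (nq < k || ns < k) return(data.frame(qpos = integer(0), spos = integer(0)))
  qk <- substring(query, 1:(nq - k + 1L), k:nq)
  sk <- substring(subject, 1:(ns - k + 1L), k:ns)
  qok <- !grepl("N", qk, fixed = TRUE)
  qmap <- split(which(qok), qk[qok])
  hits <- qmap[sk]
  lens <- lengths(hits)
  data.frame(qpos = as.integer(unlist(hits, use.names = FALSE)),
             spos = rep.int(seq_along(sk), lens))
}

# Single-linkage clustering of seeds on the diagonal (spos - qpos) with
# threshold `band`; clusters below min_seeds are dropped; cluster subject
# windows are padded by the query length and merged when they overlap.
seed_windows <- function(seeds, nq, ns, k, band, min_seeds) {
  if (nrow(seeds) == 0L) return(NULL)
  d <- seeds$spos - seeds$qpos
  o <- order(d, seeds$spos)
  d <- d[o]; sp <- seeds$spos[o]
  brk <- c(0L, which(diff(d) > band), length(d))
  wins <- NULL
  for (i in seq_len(length(brk) - 1L)) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    if (length(idx) < min_seeds) next
    lo <- max(1L, min(sp[idx]) - nq)
    hi <- min(ns, max(sp[idx]) + k - 1L + nq)
    wins <- rbind(wins, c(lo, hi))
  }
  if (is.null(wins)) return(NULL)
  wins <- wins[order(wins[, 1L]), , drop = FALSE]
  merged <- wins[1L, , drop = FALSE]
  for (i in seq_len(nrow(wins))[-1L]) {
    last <- nrow(merged)
    if (wins[i, 1L] <= merged[last, 2L])
      merged[last, 2L] <- max(merged[last, 2L], wins[i, 2L])
    else merged <- rbind(merged, wins[i, ])
  }
  merged
}

#' K-mer-seeded local homology search
#'
#' Exact shared k-mers between query and subject are clustered on common
#' diagonals (single linkage within \code{band}); each cluster of at least
#' \code{min_seeds} seeds defines a subject window in which the query is
#' realigned by optimal local alignment (match +1, mismatch -1, gap -2).
#' Overlapping windows are merged, so each region yields one hit. Only hits
#' with alignment length >= \code{min_len} and identity
#' (matches / alignment columns) >= \code{min_identity} are returned. Both
#' strands of the subject are searched; minus-strand hits are reported on
#' forward subject coordinates with strand \code{"-"}.
#'
#' @param query Nucleotide string (the probe or consensus).
#' @param subject Nucleotide string (typically a genome sequence).
#' @param min_len Minimum alignment length in bp (default 80).
#' @param min_identity Minimum identity fraction (default 0.80).
#' @param k Seed length (default 12).
#' @param band Diagonal clustering bandwidth (default 16).
#' @param min_seeds Seeds required on a common diagonal band before a
#'   window is aligned (default 2).
#' @param both_strands Search the reverse complement of the query as well.
#' @return A data.frame of class \code{"homology_hits"} with columns
#'   q_start, q_end, s_start, s_end, strand, aln_len, matches, identity,
#'   score, sorted by subject position. Zero rows when nothing passes.
#' @export
seeded_local_hits <- function(query, subject, min_len = 80L,
                              min_identity = 0.80, k = 12L, band = 16L,
                              min_seeds = 2L, both_strands = TRUE) {
  q <- clean_seq(query, "query")
  s <- clean_seq(subject, "subject")
  if (nchar(q) < k) stop("query shorter than seed length k = ", k)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (strand in strands) {
    qs <- if (strand == "+") q else reverse_complement(q)
    wins <- seed_windows(kmer_seeds(qs, s, k), nchar(qs), nchar(s), k,
                         band, min_seeds)
    if (is.null(wins)) next
    # best local alignment per window, then recurse into the unaligned
    # sub-windows so that multiple copies / split homology in one window
    # are all reported
    emit <- function(lo, hi, depth) {
      if (hi - lo + 1L < min_len || depth > 20L) return()
      al <- align_pair(qs, substr(s, lo, hi), type = "local",
                       match = 1, mismatch = -1, gap_open = 0, gap_ext = 2)
      if (al$columns < min_len) return()
      identity <- al$matches / al$columns
      if (identity < min_identity) return()
      qr <- c(al$a_start, al$a_end)
      if (strand == "-") qr <- nchar(q) - rev(qr) + 1L
      out[[length(out) + 1L]] <<- data.frame(
        q_start = qr[1L], q_end = qr[2L],
        s_start = lo + al$b_start - 1L, s_end = lo + al$b_end - 1L,
        strand = strand, aln_len = al$columns, matches = al$matches,
        identity = identity, score = al$score, stringsAsFactors = FALSE)
      emit(lo, lo + al$b_start - 2L, depth + 1L)
      emit(lo + al$b_end, hi, depth + 1L)
    }
    for (i in seq_len(nrow(wins)))
      emit(wins[i, 1L], wins[i, 2L], 1L)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(q_start = integer(0), q_end = integer(0),
               s_start = integer(0), s_end = integer(0),
               strand = character(0), aln_len = integer(0),
               matches = integer(0), identity = numeric(0),
               score = numeric(0), stringsAsFactors = FALSE)
  res <- res[order(res$s_start, res$s_end), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("homology_hits", "data.frame")
  res
}

#' Merge nearby homology hits
#'
#' Collapses, per strand, the transitive closure of "subject-interval gap
#' <= max_gap" into single covering intervals. The gap between two hits is
#' the number of bases strictly between their subject intervals
#' (\code{next_start - prev_end - 1}); overlapping hits always merge.
#'
#' @param hits A [seeded_local_hits()] result (or any data.frame with
#'   s_start, s_end, strand).
#' @param max_gap Maximum merged gap in bp (default 200).
#' @return A data.frame with columns start, end, strand, n_hits, sorted by
#'   position. Idempotent and independent of input row order.
#' @export
merge_hits <- function(hits, max_gap = 200L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_hits = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  out <- empty
  for (strand in unique(hits$strand)) {
    h <- hits[hits$strand == strand, , drop = FALSE]
    h <- h[order(h$s_start, h$s_end), , drop = FALSE]
    cur_s <- h$s_start[1L]; cur_e <- h$s_end[1L]; n <- 1L
    for (i in seq_len(nrow(h))[-1L]) {
      if (h$s_start[i] - cur_e - 1L <= max_gap) {
        cur_e <- max(cur_e, h$s_end[i]); n <- n + 1L
      } else {
        out <- rbind(out, data.frame(start = cur_s, end = cur_e,
                                     strand = strand, n_hits = n))
        cur_s <- h$s_start[i]; cur_e <- h$s_end[i]; n <- 1L
      }
    }
    out <- rbind(out, data.frame(start = cur_s, end = cur_e,
                                 strand = strand, n_hits = n))
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a genome for paired element termini
#'
#' Emulates the mother-element search: the first ~50 bp and last ~80 bp of
#' a family consensus are used as probes; loci where both probes hit on the
#' same strand, in the correct relative order, within \code{max_span} of
#' each other are reported as candidate full-length elements. Probe hit
#' thresholds are relaxed to 80 % of the probe length. Hits are paired
#' greedily nearest-first so that each hit is used at most once.
#'
#' @param subject Genome sequence (single nucleotide string).
#' @param five_probe,three_probe Probe sequences from the element's 5' and
#'   3' termini.
#' @param max_span Maximum element span in bp (default 25000).
#' @param min_identity Minimum probe hit identity (default 0.80).
#' @param k Seed length passed to [seeded_local_hits()].
#' @return A data.frame of class \code{"element_loci"} with columns start,
#'   end, strand, span (forward-strand coordinates of the full locus, from
#'   the 5'-probe hit to the 3'-probe hit).
#' @export
paired_termini_scan <- function(subject, five_probe, three_probe,
                                max_span = 25000L, min_identity = 0.80,
                                k = 12L) {
  stopifnot(nzchar(five_probe), nzchar(three_probe))
  h5 <- seeded_local_hits(five_probe, subject,
                          min_len = ceiling(0.8 * nchar(five_probe)),
                          min_identity = min_identity, k = k)
  h3 <- seeded_local_hits(three_probe, subject,
                          min_len = ceiling(0.8 * nchar(three_probe)),
                          min_identity = min_identity, k = k)
  pairs <- NULL
  for (strand in c("+", "-")) {
    a5 <- h5[h5$strand == strand, , drop = FALSE]
    a3 <- h3[h3$strand == strand, , drop = FALSE]
    if (!nrow(a5) || !nrow(a3)) next
    for (i in seq_len(nrow(a5))) for (j in seq_len(nrow(a3))) {
      if (strand == "+") {
        st <- a5$s_start[i]; en <- a3$s_end[j]
        ok <- a5$s_end[i] < a3$s_start[j]
      } else {
        st <- a3$s_start[j]; en <- a5$s_end[i]
        ok <- a3$s_end[j] < a5$s_start[i]
      }
      span <- en - st + 1L
      if (ok && span <= max_span)
        pairs <- rbind(pairs, data.frame(
          start = st, end = en, strand = strand, span = span,
          i5 = paste0(strand, i), i3 = paste0(strand, j),
          stringsAsFactors = FALSE))
    }
  }
  out <- data.frame(start = integer(0), end = integer(0),
                    strand = character(0), span = integer(0),
                    stringsAsFactors = FALSE)
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs$span, pairs$start), , drop = FALSE]
    used5 <- character(0); used3 <- character(0)
    for (i in seq_len(nrow(pairs))) {
      if (pairs$i5[i] %in% used5 || pairs$i3[i] %in% used3) next
      used5 <- c(used5, pairs$i5[i]); used3 <- c(used3, pairs$i3[i])
      out <- rbind(out, pairs[i, c("start", "end", "strand", "span")])
    }
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("element_loci", "data.frame")
  out
}

#' Terminal sequence identity between two elements
#'
#' Globally aligns the first and last \code{terminal_len} bp of the two
#' sequences (match +1, mismatch -1, gap -2) and reports identity as
#' matches / \code{terminal_len} in percent, to one decimal. With this
#' denominator, two 30-bp termini differing at 2 positions give 28/30 =
#' 93.3 %.
#'
#' @param a,b Element sequences, each at least \code{terminal_len} long.
#' @param terminal_len Window length in bp (e.g. 30 or 100).
#' @return A list with elements \code{id5} and \code{id3} (percent).
#' @export
terminal_identity <- function(a, b, terminal_len) {
  a <- clean_seq(a, "a"); b <- clean_seq(b, "b")
  L <- as.integer(terminal_len)
  if (nchar(a) < L || nchar(b) < L)
    stop("sequence shorter than terminal_len = ", L)
  one <- function(x, y) {
    al <- align_pair(x, y, type = "global", match = 1, mismatch = -1,
                     gap_open = 0, gap_ext = 2)
    round_half_away(100 * al$matches / L, 1)
  }
  list(id5 = one(substr(a, 1L, L), substr(b, 1L, L)),
       id3 = one(substr(a, nchar(a) - L + 1L, nchar(a)),
                 substr(b, nchar(b) - L + 1L, nchar(b))))
}

#' Classify two elements into family / sub-family by terminal identity
#'
#' Family membership follows the terminal-identity criterion used for
#' Helitrons: both 30-bp terminal identities must reach
#' \code{family_thresh}. Sub-family membership additionally requires both
#' 100-bp terminal identities to reach \code{subfamily_thresh}. The verdict
#' is monotone in the identities.
#'
#' @param a,b Element sequences (>= 100 bp).
#' @param family_thresh Percent identity over the terminal 30 bp
#'   (default 80).
#' @param subfamily_thresh Percent identity over the terminal 100 bp
#'   (default 80).
#' @return A list of class \code{"family_call"} with id5_30, id3_30,
#'   id5_100, id3_100 and verdict (one of \code{same_subfamily},
#'   \code{same_family}, \code{different}).
#' @export
classify_family <- function(a, b, family_thresh = 80, subfamily_thresh = 80) {
  if (nchar(a) < 100L || nchar(b) < 100L)
    stop("family classification needs sequences of at least 100 bp")
  t30 <- terminal_identity(a, b, 30L)
  t100 <- terminal_identity(a, b, 100L)
  fam <- t30$id5 >= family_thresh && t30$id3 >= family_thresh
  sub <- fam && t100$id5 >= subfamily_thresh && t100$id3 >= subfamily_thresh
  out <- list(id5_30 = t30$id5, id3_30 = t30$id3,
              id5_100 = t100$id5, id3_100 = t100$id3,
              verdict = if (sub) "same_subfamily"
                        else if (fam) "same_family" else "different")
  class(out) <- "family_call"
  out
}

#' @export
print.family_call <- function(x, ...) {
  cat(sprintf("terminal identity 30 bp: 5' %.1f%%, 3' %.1f%%\n",
              x$id5_30, x$id3_30))
  cat(sprintf("terminal identity 100 bp: 5' %.1f%%, 3' %.1f%%\n",
              x$id5_100, x$id3_100))
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}
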