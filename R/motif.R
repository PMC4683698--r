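# Structure-based Helitron evidence: terminal IUPAC motifs, the GC-rich 3'
# hairpin, and the A^T insertion-site rule.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

check_iupac <- function(pattern) {
  p <- toupper(pattern)
  if (!nzchar(p) || grepl(sprintf("[^%s]", paste(names(IUPAC_CODES), collapse = "")), p))
    stop("invalid IUPAC pattern: ", pattern)
  p
}

#' Match an IUPAC pattern at a fixed position
#'
#' Every pattern base must match its IUPAC class. \code{N} in the
#' \emph{sequence} matches nothing (conservative), so an ambiguous sequence
#' base never satisfies a motif.
#'
#' @param pattern IUPAC pattern (e.g. \code{"CTRR"}).
#' @param seq Nucleotide string.
#' @param pos 1-based position of the first pattern base in \code{seq}.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' match_iupac("CTRR", "CTAG", 1) # TRUE: R = A or G
#' match_iupac("CTRR", "CTTT", 1) # FALSE
#' @export
match_iupac <- function(pattern, seq, pos = 1L) {
  p <- check_iupac(pattern)
  s <- clean_seq(seq)
  np <- nchar(p)
  if (pos < 1L || pos + np - 1L > nchar(s))
    stop("pattern does not fit in sequence at pos ", pos)
  pb <- strsplit(p, "")[[1L]]
  sb <- strsplit(substr(s, pos, pos + np - 1L), "")[[1L]]
  all(vapply(seq_len(np), function(i)
    sb[i] != "N" && sb[i] %in% IUPAC_CODES[[pb[i]]], NA))
}

#' Hairpin search parameters
#'
#' Defaults reflect the canonical Helitron hairpin: a GC-rich stem-loop of
#' 15-20 bp total ending a handful of bases upstream of the 3' terminus.
#' The search window (offsets 4-35 bp) is deliberately generous: published
#' elements place the hairpin 10-13 bp upstream, and the offset is reported
#' rather than filtered so that unusual geometries are not silently lost.
#'
#' @param stem_min,stem_max Stem arm length range in bp.
#' @param loop_min,loop_max Loop length range in bp.
#' @param max_mismatch Maximum non-pairing positions tolerated in the stem.
#' @param min_stem_gc Minimum GC fraction over the stem bases (both arms).
#' @param offset_min,offset_max The hairpin's last base must lie between
#'   \code{offset_min} and \code{offset_max} bp upstream of the 3' terminus
#'   (offset counts the terminal base itself).
#' @param total_min,total_max Accepted total hairpin length (2*stem + loop).
#' @return A list of parameters for [find_hairpin()].
#' @export
hairpin_params <- function(stem_min = 5L, stem_max = 9L,
                           loop_min = 3L, loop_max = 8L,
                           max_mismatch = 1L, min_stem_gc = 0.6,
                           offset_min = 4L, offset_max = 35L,
                           total_min = 15L, total_max = 20L) {
  as.list(environment())
}

WC_PAIR <- c(A = "T", C = "G", G = "C", T = "A")

#' Find the 3'-subterminal hairpin of a Helitron
#'
#' Enumerates all stem/loop placements whose last base falls in the
#' configured window upstream of \code{three_prime_pos}, requiring the left
#' stem arm to reverse-complement-match the right arm (Watson-Crick pairs
#' only, no G:U) with at most \code{max_mismatch} non-pairing positions and
#' a stem GC fraction of at least \code{min_stem_gc}. Among passing
#' placements the hit maximizing (stem G:C pairs, fewest mismatches, total
#' length, proximity to the 3' end, longer stem) is returned -- a
#' deterministic, parsimony-first ranking; the final stem-length criterion
#' only resolves equivalent stem/loop decompositions of the same window.
#'
#' @param seq Nucleotide string containing the element.
#' @param three_prime_pos Position of the element's 3' terminal base in
#'   \code{seq}.
#' @param params See [hairpin_params()].
#' @return A list of class \code{"hairpin_hit"} with elements \code{start},
#'   \code{end}, \code{stem_len}, \code{loop_len}, \code{total_len},
#'   \code{gc_fraction}, \code{mismatches_in_stem}, \code{gc_pairs},
#'   \code{offset_3p}; or \code{NULL} when no placement passes.
#' @export
find_hairpin <- function(seq, three_prime_pos, params = hairpin_params()) {
  s <- clean_seq(seq)
  n <- nchar(s)
  stopifnot(three_prime_pos >= 1L, three_prime_pos <= n)
  x <- strsplit(s, "")[[1L]]
  p <- params
  best <- NULL
  best_key <- rep(-Inf, 5L)
  ends <- seq.int(max(1L, three_prime_pos - p$offset_max),
                  three_prime_pos - p$offset_min)
  for (e in ends) {
    if (e < 1L) next
    for (stem in p$stem_min:p$stem_max) {
      for (loop in p$loop_min:p$loop_max) {
        total <- 2L * stem + loop
        if (total < p$total_min || total > p$total_max) next
        st <- e - total + 1L
        if (st < 1L) next
        left <- x[st:(st + stem - 1L)]
        right <- x[(e - stem + 1L):e]
        paired <- left == WC_PAIR[rev(right)] & left != "N"
        paired[is.na(paired)] <- FALSE
        mm <- stem - sum(paired)
        if (mm > p$max_mismatch) next
        stem_bases <- c(left, right)
        gc <- mean(stem_bases %in% c("G", "C"))
        if (gc < p$min_stem_gc) next
        gc_pairs <- sum(paired & left %in% c("G", "C"))
        off <- three_prime_pos - e
        key <- c(gc_pairs, -mm, total, -off, stem)
        cmp <- key - best_key
        nz <- which(cmp != 0)
        if (length(nz) && cmp[nz[1L]] > 0) {
          best <- list(start = st, end = e, stem_len = stem,
                       loop_len = loop, total_len = total,
                       gc_fraction = gc, mismatches_in_stem = mm,
                       gc_pairs = gc_pairs, offset_3p = off)
          best_key <- key
        }
      }
    }
  }
  if (!is.null(best)) class(best) <- "hairpin_hit"
  best
}

#' @export
print.hairpin_hit <- function(x, ...) {
  cat(sprintf(
    "hairpin: %d bp (stem %d + loop %d), %d G:C pairs, %d mismatch(es),\n  stem GC %.2f, ends %d bp upstream of the 3' terminus [%d-%d]\n",
    x$total_len, x$stem_len, x$loop_len, x$gc_pairs, x$mismatches_in_stem,
    x$gc_fraction, x$offset_3p, x$start, x$end))
  invisible(x)
}

#' Check the Helitron A^T insertion-site rule
#'
#' Helitrons insert between an A and a T (or between two Ts) and create no
#' target site duplication; the bases immediately flanking an element are
#' therefore expected to read A^T (or T^T) on the element's strand.
#'
#' @param genome Named character vector of sequences.
#' @param iv Single-row interval of the element.
#' @return \code{TRUE} or \code{FALSE}; an element at the sequence edge
#'   returns \code{FALSE} with a warning.
#' @export
validate_insertion_site <- function(genome, iv) {
  check_interval(iv, genome)
  s <- genome[[iv$record_id[1L]]]
  if (iv$start == 1L || iv$end == nchar(s)) {
    warning("element at sequence edge; insertion site not assessable")
    return(FALSE)
  }
  before <- substr(s, iv$start - 1L, iv$start - 1L)
  after <- substr(s, iv$end + 1L, iv$end + 1L)
  if (iv$strand == "-") {
    tmp <- before
    before <- unname(WC_PAIR[after])
    after <- unname(WC_PAIR[tmp])
  }
  isTRUE(paste0(before, after) %in% c("AT", "TT"))
}

#' Terminal motif specification
#'
#' @param five_prime IUPAC pattern expected at the 5' terminus (default
#'   \code{"TC"}).
#' @param three_prime IUPAC pattern expected at the 3' terminus (default
#'   \code{"CTRR"}; the high-copy rice family ends in the CTRR instance
#'   CTAG).
#' @param hairpin Hairpin search parameters, see [hairpin_params()].
#' @return A list of class \code{"terminal_motif_spec"}.
#' @export
terminal_motif_spec <- function(five_prime = "TC", three_prime = "CTRR",
                                hairpin = hairpin_params()) {
  out <- list(five_prime = check_iupac(five_prime),
              three_prime = check_iupac(three_prime),
              hairpin = hairpin)
  class(out) <- "terminal_motif_spec"
  out
}

#' Evaluate all four structural Helitron criteria at an interval
#'
#' Scores the interval for (1) the 5' terminal motif, (2) the 3' terminal
#' motif, (3) a subterminal hairpin, and (4) the A^T insertion-site rule,
#' on the strand of \code{iv}. The candidate is never rejected here;
#' filtering on the score is the caller's choice.
#'
#' @param genome Named character vector of sequences.
#' @param iv Single-row interval.
#' @param spec See [terminal_motif_spec()].
#' @return A list of class \code{"helitron_candidate"} with the interval,
#'   the four evidence flags, the hairpin hit (or NULL) and \code{score}
#'   (0-4, the number of satisfied criteria).
#' @export
call_candidate <- function(genome, iv, spec = terminal_motif_spec()) {
  check_interval(iv, genome)
  s <- genome[[iv$record_id[1L]]]
  elem <- substr(s, iv$start, iv$end)
  if (iv$strand == "-") elem <- reverse_complement(elem)
  n <- nchar(elem)
  has_5p <- n >= nchar(spec$five_prime) &&
    match_iupac(spec$five_prime, elem, 1L)
  n3 <- nchar(spec$three_prime)
  has_3p <- n >= n3 && match_iupac(spec$three_prime, elem, n - n3 + 1L)
  hairpin <- find_hairpin(elem, n, spec$hairpin)
  has_AT <- suppressWarnings(validate_insertion_site(genome, iv))
  out <- list(interval = iv,
              has_5p_motif = has_5p, has_3p_motif = has_3p,
              has_hairpin = !is.null(hairpin), has_AT_site = has_AT,
              hairpin = hairpin,
              score = sum(has_5p, has_3p, !is.null(hairpin), has_AT))
  class(out) <- "helitron_candidate"
  out
}

#' @export
print.helitron_candidate <- function(x, ...) {
  iv <- x$interval
  cat(sprintf("Helitron candidate %s:%d-%d(%s)  score %d/4\n",
              iv$record_id, iv$start, iv$end, iv$strand, x$score))
  cat(sprintf("  5' motif %s | 3' motif %s | hairpin %s | A^T site %s\n",
              x$has_5p_motif, x$has_3p_motif, x$has_hairpin, x$has_AT_site))
  if (!is.null(x$hairpin)) print(x$hairpin)
  invisible(x)
}

# Candidates -> flat table (one row each).
candidates_to_table <- function(candidates) {
  rows <- lapply(candidates, function(cc) {
    hp <- cc$hairpin
    data.frame(record_id = cc$interval$record_id, start = cc$interval$start,
               end = cc$interval$end, strand = cc$interval$strand,
               score = cc$score,
               has_5p_motif = cc$has_5p_motif, has_3p_motif = cc$has_3p_motif,
               has_hairpin = cc$has_hairpin, has_AT_site = cc$has_AT_site,
               hairpin_total_len = if (is.null(hp)) NA_integer_ else hp$total_len,
               hairpin_offset_3p = if (is.null(hp)) NA_integer_ else hp$offset_3p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export Helitron candidates
#'
#' Writes candidates as TSV and/or GFF3 (feature type
#' \code{Helitron_candidate}; attributes carry the four evidence flags and
#' the hairpin geometry).
#'
#' @param candidates A list of [call_candidate()] results.
#' @param tsv,gff3 Output paths (either may be NULL).
#' @return Invisibly, the candidate table.
#' @export
write_candidates <- function(candidates, tsv = NULL, gff3 = NULL) {
  tab <- candidates_to_table(candidates)
  if (!is.null(tsv)) write_tsv_hash(tab, tsv)
  if (!is.null(gff3)) {
    feats <- tab
    feats$type <- "Helitron_candidate"
    feats$score <- tab$score
    feats$attributes <- sprintf(
      "ID=cand%d;five_prime=%s;three_prime=%s;hairpin=%s;AT_site=%s;hairpin_len=%s;hairpin_offset=%s",
      seq_len(nrow(tab)), tab$has_5p_motif, tab$has_3p_motif,
      tab$has_hairpin, tab$has_AT_site, tab$hairpin_total_len,
      tab$hairpin_offset_3p)
    write_gff3(feats, gff3)
  }
  invisible(tab)
}
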