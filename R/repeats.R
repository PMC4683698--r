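# Self-comparison (dot-plot) analysis, tandem-bloc segmentation with
# per-bloc GC, and repeat fingerprints used for polymorphism typing.

#' Maximal exact self-matches of a sequence
#'
#' Enumerates all maximal exact direct-repeat match runs of length >= k
#' between a sequence and itself, reported as (i, j, length) with i < j.
#' Runs are maximal per lag (not extendable in either direction), so a
#' homopolymer is reported once per lag, not once per position. N matches
#' nothing. The (i, j, length) table is the text equivalent of a self
#' dot-plot and can be exported for external rendering.
#'
#' @param seq Nucleotide string, at least k long.
#' @param k Minimum match run length (default 10).
#' @param max_lag Restrict to lags (j - i) up to this value; NULL for all.
#' @return A data.frame of class \code{"self_matches"} with columns i, j,
#'   length, lag.
#' @seealso [write_self_matches()]
#' @export
self_matches <- function(seq, k = 10L, max_lag = NULL) {
  s <- clean_seq(seq)
  n <- nchar(s)
  stopifnot(n >= k)
  r <- charToRaw(s)
  rawN <- charToRaw("N")
  top_lag <- min(max_lag %||% (n - k), n - k)
  res_i <- list(); res_len <- list(); res_lag <- list()
  for (lag in seq_len(top_lag)) {
    m <- n - lag
    eq <- r[1:m] == r[(lag + 1L):n] & r[1:m] != rawN
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    sel <- rl$values & rl$lengths >= k
    if (any(sel)) {
      res_i[[length(res_i) + 1L]] <- ends[sel] - rl$lengths[sel] + 1L
      res_len[[length(res_len) + 1L]] <- rl$lengths[sel]
      res_lag[[length(res_lag) + 1L]] <- rep.int(lag, sum(sel))
    }
  }
  i <- as.integer(unlist(res_i)); len <- as.integer(unlist(res_len))
  lag <- as.integer(unlist(res_lag))
  out <- data.frame(i = i, j = i + lag, length = len, lag = lag)
  out <- out[order(out$i, out$lag), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("self_matches", "data.frame")
  out
}

#' Export self-matches as a 3-column TSV
#'
#' Columns i, j, length -- suitable for external dot-plot rendering.
#'
#' @param matches A [self_matches()] result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_self_matches <- function(matches, path) {
  write_tsv_hash(as.data.frame(matches)[, c("i", "j", "length")], path)
}

# Candidate blocs at one lag: matches clustered by position (split where
# the next match starts more than one unit beyond the current region).
lag_candidates <- function(sm, lag) {
  m <- sm[sm$lag == lag, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  m <- m[order(m$i), , drop = FALSE]
  starts <- m$i
  ends <- m$j + m$length - 1L
  out <- NULL
  # covered = matched bp only (union over both copies of each match run),
  # so large lags do not get credit for the unmatched span between copies
  mk_cov <- function(q) list(c(m$i[q], m$i[q] + m$length[q] - 1L),
                             c(m$j[q], ends[q]))
  cs <- starts[1L]; ce <- ends[1L]; cov <- mk_cov(1L)
  flush <- function(cs, ce, cov) {
    ivs <- do.call(rbind, cov)
    ivs <- ivs[order(ivs[, 1L]), , drop = FALSE]
    covered <- 0L; pe <- 0L
    for (q in seq_len(nrow(ivs))) {
      a <- max(ivs[q, 1L], pe + 1L); b <- ivs[q, 2L]
      if (b >= a) covered <- covered + b - a + 1L
      pe <- max(pe, b)
    }
    data.frame(start = cs, end = ce, lag = lag, covered = covered)
  }
  for (q in seq_len(nrow(m))[-1L]) {
    if (starts[q] > ce + lag) {
      out <- rbind(out, flush(cs, ce, cov))
      cs <- starts[q]; ce <- ends[q]; cov <- mk_cov(q)
    } else {
      ce <- max(ce, ends[q]); cov <- c(cov, mk_cov(q))
    }
  }
  rbind(out, flush(cs, ce, cov))
}

#' Detect tandem-repeat blocs
#'
#' Clusters self-matches by lag: matches at a common lag that tile a region
#' define a candidate periodic bloc with unit length equal to the lag.
#' Overlapping candidates (e.g. harmonics at multiples of the true unit)
#' are resolved in favor of the largest covered span, preferring the
#' smallest lag whose coverage reaches 80 % of the best -- so a bloc of six
#' 137-bp units is reported at lag 137, not 274, and a dinucleotide
#' microsatellite at lag 2. Blocs whose refined unit length falls below
#' \code{min_unit} are labeled \code{"microsatellite"} (degenerate period
#' <= 2 only); others \code{"tandem"}.
#'
#' @param seq Nucleotide string.
#' @param min_unit,max_unit Accepted unit length range in bp (defaults 20
#'   and 500).
#' @param min_units Minimum number of units (default 2).
#' @param min_span Minimum covered span in bp (default 100).
#' @param k Minimum exact-match run used for the self-comparison
#'   (default 10).
#' @return A data.frame of class \code{"tandem_blocs"} with columns start,
#'   end, unit_length, unit_count, mean_gc, covered, label, sorted by
#'   position. Zero rows when no qualifying periodicity exists.
#' @export
detect_tandem_blocs <- function(seq, min_unit = 20L, max_unit = 500L,
                                min_units = 2, min_span = 100L, k = 10L) {
  s <- clean_seq(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit_length = integer(0), unit_count = numeric(0),
                      mean_gc = numeric(0), covered = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("tandem_blocs", "data.frame")
  if (nchar(s) < k) return(empty)
  sm <- self_matches(s, k = k, max_lag = max_unit)
  if (!nrow(sm)) return(empty)
  cand <- do.call(rbind, lapply(unique(sm$lag), function(L) lag_candidates(sm, L)))
  cand$span <- cand$end - cand$start + 1L
  cand <- cand[cand$covered >= min_span & cand$span / cand$lag >= min_units, ,
               drop = FALSE]
  # only plausible unit lengths compete: full tandem units, or degenerate
  # microsatellite periods
  cand <- cand[cand$lag >= min_unit | cand$lag <= 2L, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(-cand$covered, cand$lag), , drop = FALSE]
  ovl <- function(a_s, a_e, b_s, b_e) {
    inter <- min(a_e, b_e) - max(a_s, b_s) + 1L
    if (inter <= 0L) return(0)
    inter / min(a_e - a_s + 1L, b_e - b_s + 1L)
  }
  blocs <- empty
  while (nrow(cand)) {
    top <- cand[1L, ]
    grp <- vapply(seq_len(nrow(cand)), function(q)
      ovl(top$start, top$end, cand$start[q], cand$end[q]) >= 0.5, NA)
    grp_cand <- cand[grp, , drop = FALSE]
    good <- grp_cand[grp_cand$covered >= 0.8 * top$covered, , drop = FALSE]
    pick <- good[which.min(good$lag), ]
    region <- substr(s, pick$start, pick$end)
    blocs <- rbind(blocs, data.frame(
      start = pick$start, end = pick$end, unit_length = pick$lag,
      unit_count = round((pick$end - pick$start + 1L) / pick$lag, 2),
      mean_gc = gc_fraction(region), covered = pick$covered,
      label = if (pick$lag < min_unit) "microsatellite" else "tandem",
      stringsAsFactors = FALSE))
    keep <- vapply(seq_len(nrow(cand)), function(q)
      ovl(pick$start, pick$end, cand$start[q], cand$end[q]) < 0.5, NA)
    cand <- cand[keep, , drop = FALSE]
  }
  blocs <- blocs[order(blocs$start), , drop = FALSE]
  rownames(blocs) <- NULL
  class(blocs) <- c("tandem_blocs", "data.frame")
  blocs
}

#' Create an empty repeat-fingerprint label library
#'
#' A label library maps bloc unit consensi to stable labels ("A", "B", ...)
#' across multiple [fingerprint()] calls within one run, so that blocs of
#' different element copies can be compared by name.
#'
#' @return An environment holding the library state.
#' @export
fingerprint_library <- function() {
  lib <- new.env(parent = emptyenv())
  lib$units <- list()
  lib
}

#' Repeat fingerprint of an element
#'
#' Runs [detect_tandem_blocs()] and labels each bloc by matching a
#' representative unit against the label library (built from the first
#' element fingerprinted with that library), in element order 5' to 3'.
#' Orientation is the strand of the best unit match. The fingerprint is
#' the (label, unit_length, unit_count, orientation) sequence used for
#' repeat-variation typing; it is invariant under appending non-repetitive
#' flanking sequence.
#'
#' @param element Element nucleotide string.
#' @param library A [fingerprint_library()]; a fresh one is created when
#'   NULL (labels then start at "A" for this element).
#' @param label_identity Minimum percent identity between a bloc's
#'   representative unit and a library unit to reuse its label
#'   (default 60).
#' @param ... Passed to [detect_tandem_blocs()].
#' @return A data.frame of class \code{"repeat_fingerprint"} with columns
#'   label, start, end, unit_length, unit_count, orientation; the library
#'   is attached as attribute \code{"library"}.
#' @export
fingerprint <- function(element, library = NULL, label_identity = 60, ...) {
  lib <- library %||% fingerprint_library()
  blocs <- detect_tandem_blocs(element, ...)
  out <- data.frame(label = character(0), start = integer(0),
                    end = integer(0), unit_length = integer(0),
                    unit_count = numeric(0), orientation = character(0),
                    stringsAsFactors = FALSE)
  for (q in seq_len(nrow(blocs))) {
    unit <- substr(element, blocs$start[q],
                   min(blocs$end[q], blocs$start[q] + blocs$unit_length[q] - 1L))
    label <- NA_character_; orientation <- "+"; best <- -Inf
    # tandem phase differs between copies, so a unit is compared against
    # the doubled library unit by local alignment (rotation-tolerant)
    rot_id <- function(u1, u2) {
      if (nchar(u1) < 5L || nchar(u2) < 5L) return(0)
      al <- align_pair(u1, paste0(u2, u2), type = "local", match = 1,
                       mismatch = -1, gap_open = 0, gap_ext = 2)
      100 * al$matches / nchar(u1)
    }
    for (u in lib$units) {
      fwd <- rot_id(unit, u$unit)
      rev <- rot_id(reverse_complement(unit), u$unit)
      if (max(fwd, rev) > best && max(fwd, rev) >= label_identity) {
        best <- max(fwd, rev)
        label <- u$label
        orientation <- if (fwd >= rev) "+" else "-"
      }
    }
    if (is.na(label)) {
      label <- LETTERS[length(lib$units) + 1L]
      lib$units[[length(lib$units) + 1L]] <- list(label = label, unit = unit)
    }
    out <- rbind(out, data.frame(
      label = label, start = blocs$start[q], end = blocs$end[q],
      unit_length = blocs$unit_length[q], unit_count = blocs$unit_count[q],
      orientation = orientation, stringsAsFactors = FALSE))
  }
  attr(out, "library") <- lib
  class(out) <- c("repeat_fingerprint", "data.frame")
  out
}

# Are two fingerprints the same architecture (same labels, order,
# orientation, unit counts within tol)?
same_fingerprint <- function(fa, fb, tol = 0.5) {
  if (nrow(fa) != nrow(fb)) return(FALSE)
  if (nrow(fa) == 0L) return(TRUE)
  all(fa$label == fb$label) && all(fa$orientation == fb$orientation) &&
    all(abs(fa$unit_count - fb$unit_count) <= tol)
}
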