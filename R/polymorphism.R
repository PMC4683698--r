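# Classification of orthologous locus pairs between two genomes into
# shared / repeat-variation / insertion / excision-footprint calls, and the
# activity extrapolation.

#' Globally align an orthologous locus pair
#'
#' Global alignment with affine gap costs (match +1, mismatch -2, gap of
#' length L costs 6 + 0.5 L), chosen so that a whole missing element is
#' explained by one long indel rather than scattered gaps.
#'
#' @param seq_a,seq_b Locus sequences (element with flanks), each at most
#'   \code{max_len} bp.
#' @param max_len Size cap (default 50000 bp).
#' @return A list of class \code{"locus_alignment"}: a_aln, b_aln (aligned
#'   strings with \code{-} gaps), score, identity (matches / columns).
#' @export
align_locus <- function(seq_a, seq_b, max_len = 50000L) {
  a <- clean_seq(seq_a, "seq_a"); b <- clean_seq(seq_b, "seq_b")
  if (nchar(a) > max_len || nchar(b) > max_len)
    stop("locus sequence exceeds the ", max_len, " bp size cap")
  al <- align_pair(a, b, type = "global", match = 1, mismatch = -2,
                   gap_open = 6, gap_ext = 0.5)
  out <- list(a_aln = al$a_aln, b_aln = al$b_aln, score = al$score,
              matches = al$matches, columns = al$columns,
              identity = al$matches / al$columns)
  class(out) <- "locus_alignment"
  out
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("locus alignment: %d columns, %.1f%% identity, score %.1f\n",
              x$columns, 100 * x$identity, x$score))
  invisible(x)
}

#' Parameters for polymorphism classification
#'
#' All thresholds of the locus decision tree. The qualitative footprint
#' patterns come from comparative TE biology (residual element fragments,
#' flank deletions, filler DNA); the numeric cut-offs are package defaults
#' and are all adjustable.
#'
#' @param min_residual Minimum consensus-homologous fragment (bp) at an
#'   empty site to call an incomplete excision (default 30).
#' @param min_residual_identity Identity the residual must reach against
#'   the consensus (default 0.8).
#' @param flank_del_min Minimum missing flank (bp) adjacent to the site to
#'   call a flank-deletion footprint (default 5).
#' @param filler_max Maximum non-homologous insert (bp) still called filler
#'   DNA (default 500).
#' @param flank_window Flank window (bp) used for junction/identity checks
#'   (default 50).
#' @param flank_min_identity Minimum flank identity outside the polymorphic
#'   region; loci below it are "unresolved" (default 0.9).
#' @param element_min_frac Fraction of the consensus length that must be
#'   covered by homology to count the element as present (default 0.5).
#' @param hit_min_len,hit_min_identity Filters for the consensus-vs-locus
#'   homology search (defaults 30 bp, 0.8).
#' @param clean_junction_tol Residual bases at the junction still treated
#'   as a clean junction, absorbing alignment end-trimming jitter
#'   (default 3, below the smallest footprint the classifier reports).
#' @param fingerprint_tol Unit-count tolerance when comparing repeat
#'   fingerprints of a shared element (default 0.5).
#' @param k Seed length for the homology searches (default 12).
#' @return A list of parameters for [classify_locus()].
#' @export
polymorphism_params <- function(min_residual = 30L, min_residual_identity = 0.8,
                                flank_del_min = 5L, filler_max = 500L,
                                flank_window = 50L, flank_min_identity = 0.9,
                                element_min_frac = 0.5, hit_min_len = 30L,
                                hit_min_identity = 0.8,
                                clean_junction_tol = 3L,
                                fingerprint_tol = 0.5, k = 12L) {
  as.list(environment())
}

# Element evidence in one locus sequence: covered bp of consensus homology
# and the main homologous block.
element_evidence <- function(locus_seq, consensus, params) {
  hits <- seeded_local_hits(consensus, locus_seq,
                            min_len = params$hit_min_len,
                            min_identity = params$hit_min_identity,
                            k = params$k)
  if (!nrow(hits))
    return(list(covered = 0L, block = NULL))
  blocks <- merge_hits(hits, max_gap = 200L)
  covered <- sum(blocks$end - blocks$start + 1L)
  # homology to one element can split into several blocks (e.g. extra
  # repeat units force the local alignment apart); the element region is
  # the overall extent
  list(covered = covered, block = c(min(blocks$start), max(blocks$end)))
}

# Local alignment of a flank probe against the partner locus; returns the
# b-range it maps to, the number of junction-side probe bases left
# unaligned, and the identity of the aligned part.
anchor_flank <- function(flank, partner, junction_side) {
  if (!nzchar(flank)) return(NULL)
  al <- align_pair(flank, partner, type = "local", match = 1, mismatch = -1,
                   gap_open = 0, gap_ext = 2)
  missing <- if (junction_side == "right") nchar(flank) - al$a_end
             else al$a_start - 1L
  list(b_start = al$b_start, b_end = al$b_end,
       missing = missing,
       identity = if (al$columns > 0L) al$matches / al$columns else 0,
       aligned = al$columns)
}

#' Classify one orthologous locus pair
#'
#' Decision tree over an orthologous locus pair and the family consensus:
#' \enumerate{
#'   \item element homology present in both loci: repeat fingerprints are
#'     compared -- identical architecture within the unit-count tolerance
#'     gives \code{shared}, otherwise \code{repeat_variation};
#'   \item element in exactly one locus: the empty site is inspected. A
#'     clean junction whose flanking bases read A^T (or T^T) with no target
#'     site duplication is an \code{insertion} (the carrier genome is
#'     reported); a consensus-homologous fragment of >= \code{min_residual}
#'     bp left at the site is \code{excision_incomplete}; missing flank
#'     sequence adjacent to the site is \code{excision_flank_deletion}; a
#'     non-homologous insert up to \code{filler_max} bp is
#'     \code{excision_filler};
#'   \item element in neither locus: \code{empty_shared};
#'   \item anything failing the flank-alignment checks: \code{unresolved}.
#' }
#'
#' Insertion-versus-excision polarity is read from site morphology alone
#' (clean A^T junction vs. repair footprint); without an outgroup genome
#' this is a documented heuristic, not a strict inference.
#'
#' @param locus A list with \code{seq_a}, \code{seq_b} and optionally
#'   \code{id} and \code{element_iv_a} (c(start, end) of the annotated
#'   element within \code{seq_a}).
#' @param consensus Family consensus sequence (non-empty).
#' @param params See [polymorphism_params()].
#' @return A list of class \code{"polymorphism_call"}: id, klass, carrier
#'   (\code{"a"}, \code{"b"} or NA), residual_bp, deleted_flank_bp,
#'   filler_bp, note.
#' @export
classify_locus <- function(locus, consensus, params = polymorphism_params()) {
  stopifnot(nzchar(consensus))
  a <- clean_seq(locus$seq_a, "seq_a")
  b <- clean_seq(locus$seq_b, "seq_b")
  id <- locus$id %||% "locus"
  call <- function(klass, carrier = NA_character_, residual = NA_integer_,
                   deleted = NA_integer_, filler = NA_integer_, note = "") {
    out <- list(id = id, klass = klass, carrier = carrier,
                residual_bp = residual, deleted_flank_bp = deleted,
                filler_bp = filler, note = note)
    class(out) <- "polymorphism_call"
    out
  }
  min_present <- params$element_min_frac * nchar(consensus)
  ev_a <- element_evidence(a, consensus, params)
  ev_b <- element_evidence(b, consensus, params)
  in_a <- ev_a$covered >= min_present
  in_b <- ev_b$covered >= min_present

  if (in_a && in_b) {
    ea <- substr(a, ev_a$block[1L], ev_a$block[2L])
    eb <- substr(b, ev_b$block[1L], ev_b$block[2L])
    lib <- fingerprint_library()
    fa <- fingerprint(ea, lib)
    fb <- fingerprint(eb, lib)
    if (same_fingerprint(fa, fb, params$fingerprint_tol))
      return(call("shared"))
    return(call("repeat_variation",
                note = sprintf("fingerprints a=%s b=%s",
                               paste0(fa$label, round(fa$unit_count, 1), collapse = "/"),
                               paste0(fb$label, round(fb$unit_count, 1), collapse = "/"))))
  }

  if (!in_a && !in_b) {
    al <- align_pair(a, b, type = "global", match = 1, mismatch = -1,
                     gap_open = 3, gap_ext = 1)
    if (al$matches / al$columns >= params$flank_min_identity)
      return(call("empty_shared"))
    return(call("unresolved", note = "no element, loci poorly alignable"))
  }

  carrier <- if (in_a) "a" else "b"
  cs <- if (in_a) a else b       # carrier locus
  es <- if (in_a) ev_a$block[1L] else ev_b$block[1L]
  ee <- if (in_a) ev_a$block[2L] else ev_b$block[2L]
  em <- if (in_a) b else a       # empty locus
  left <- substr(cs, 1L, es - 1L)
  right <- substr(cs, ee + 1L, nchar(cs))
  if (nchar(left) < 20L || nchar(right) < 20L)
    return(call("unresolved", carrier, note = "element at locus edge"))
  anc_l <- anchor_flank(left, em, junction_side = "right")
  anc_r <- anchor_flank(right, em, junction_side = "left")
  ok <- function(anc) !is.null(anc) && anc$aligned >= 20L &&
    anc$identity >= params$flank_min_identity
  if (!ok(anc_l) || !ok(anc_r))
    return(call("unresolved", carrier, note = "flank alignment failed"))

  d_left <- if (anc_l$missing >= params$flank_del_min) anc_l$missing else 0L
  d_right <- if (anc_r$missing >= params$flank_del_min) anc_r$missing else 0L
  if (d_left + d_right > 0L)
    return(call("excision_flank_deletion", carrier,
                deleted = d_left + d_right))
  if (anc_r$b_start <= anc_l$b_end - params$clean_junction_tol)
    return(call("unresolved", carrier, note = "flank anchors overlap"))

  p <- anc_l$b_end                       # last empty-locus base of the left flank
  q <- anc_r$b_start                     # first empty-locus base of the right flank
  g <- q - p - 1L                        # bases at the empty site
  if (g <= params$clean_junction_tol) {
    # clean junction: Helitron insertions land between A and T (or T^T)
    # without a target site duplication
    jw <- substr(em, max(1L, p - 1L), min(nchar(em), q + 1L))
    dins <- vapply(seq_len(max(0L, nchar(jw) - 1L)), function(t)
      substr(jw, t, t + 1L), "")
    has_at <- any(dins %in% c("AT", "TT"))
    tsd <- any(vapply(4:10, function(r)
      es - r >= 1L && ee + r <= nchar(cs) &&
        substr(cs, es - r, es - 1L) == substr(cs, ee + 1L, ee + r), NA))
    if (has_at && !tsd)
      return(call("insertion", carrier))
    return(call("unresolved", carrier,
                note = if (tsd) "target site duplication at junction"
                       else "clean junction without A^T"))
  }
  inner <- substr(em, p + 1L, q - 1L)
  resid <- align_pair(inner, consensus, type = "local", match = 1,
                      mismatch = -1, gap_open = 0, gap_ext = 2)
  resid_len <- resid$a_end - resid$a_start + 1L
  resid_id <- if (resid$columns > 0L) resid$matches / resid$columns else 0
  if (resid$columns >= params$min_residual &&
      resid_id >= params$min_residual_identity)
    return(call("excision_incomplete", carrier, residual = resid_len))
  if (g <= params$filler_max && resid$matches < 0.5 * g)
    return(call("excision_filler", carrier, filler = g))
  call("unresolved", carrier,
       note = sprintf("%d bp at empty site, neither residual nor filler", g))
}

#' @export
print.polymorphism_call <- function(x, ...) {
  extra <- c(
    if (!is.na(x$residual_bp)) sprintf("residual %d bp", x$residual_bp),
    if (!is.na(x$deleted_flank_bp)) sprintf("flank deleted %d bp", x$deleted_flank_bp),
    if (!is.na(x$filler_bp)) sprintf("filler %d bp", x$filler_bp),
    if (!is.na(x$carrier)) sprintf("element in genome %s", x$carrier))
  cat(sprintf("%s: %s%s\n", x$id, x$klass,
              if (length(extra)) paste0(" (", paste(extra, collapse = ", "), ")") else ""))
  invisible(x)
}

#' Classify a table of orthologous loci
#'
#' @param loci A data.frame with columns \code{locus_id}, \code{seq_a},
#'   \code{seq_b} (as produced by [orthologous_loci()]).
#' @param consensus Family consensus sequence.
#' @param params See [polymorphism_params()].
#' @return A data.frame of per-locus calls (locus_id, klass, carrier,
#'   residual_bp, deleted_flank_bp, filler_bp, note).
#' @export
classify_loci <- function(loci, consensus, params = polymorphism_params()) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    cl <- classify_locus(list(id = loci$locus_id[i], seq_a = loci$seq_a[i],
                              seq_b = loci$seq_b[i]), consensus, params)
    data.frame(locus_id = cl$id, klass = cl$klass, carrier = cl$carrier,
               residual_bp = cl$residual_bp,
               deleted_flank_bp = cl$deleted_flank_bp,
               filler_bp = cl$filler_bp, note = cl$note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

TRUE_POLYMORPHIC_CLASSES <- c("insertion", "excision_incomplete",
                              "excision_flank_deletion", "excision_filler")

#' Summarize polymorphism calls
#'
#' Counts calls per class and, when \code{total_sites} is given,
#' extrapolates family activity from the manually typed subset via
#' [estimate_activity()] (true polymorphisms = insertions plus the three
#' excision-footprint classes).
#'
#' @param calls A [classify_loci()] result.
#' @param total_sites Total number of candidate polymorphic sites the
#'   inspected loci were drawn from (optional).
#' @return A list with \code{counts} (named integer vector) and, if
#'   \code{total_sites} was given, \code{activity} (an
#'   [estimate_activity()] result).
#' @export
polymorphism_summary <- function(calls, total_sites = NULL) {
  klasses <- c("shared", "repeat_variation", TRUE_POLYMORPHIC_CLASSES,
               "empty_shared", "unresolved")
  counts <- vapply(klasses, function(k) sum(calls$klass == k), 0L)
  out <- list(counts = counts)
  if (!is.null(total_sites))
    out$activity <- estimate_activity(
      total_sites, nrow(calls),
      sum(calls$klass %in% TRUE_POLYMORPHIC_CLASSES))
  out
}

#' Extrapolate element activity from a typed subset
#'
#' Given \code{total_sites} candidate polymorphic sites of which
#' \code{inspected} were manually typed and \code{true_polymorphic} turned
#' out to be genuine presence/absence polymorphisms, reports the percentage
#' of truly polymorphic sites (one decimal) and the extrapolated number of
#' mobilized copies \code{round(total_sites * true_polymorphic /
#' inspected)}, both rounded half away from zero.
#'
#' @param total_sites,inspected,true_polymorphic Counts with
#'   \code{0 < inspected <= total_sites} and
#'   \code{0 <= true_polymorphic <= inspected}.
#' @return A list of class \code{"activity_estimate"}: total_sites,
#'   inspected, true_polymorphic, percent, extrapolated_total.
#' @examples
#' estimate_activity(856, 148, 8)  # 5.4 %, 46 mobilized copies
#' @export
estimate_activity <- function(total_sites, inspected, true_polymorphic) {
  if (inspected <= 0) stop("inspected must be positive")
  stopifnot(inspected <= total_sites,
            true_polymorphic >= 0, true_polymorphic <= inspected)
  out <- list(
    total_sites = as.integer(total_sites),
    inspected = as.integer(inspected),
    true_polymorphic = as.integer(true_polymorphic),
    percent = round_half_away(100 * true_polymorphic / inspected, 1),
    extrapolated_total = as.integer(
      round_half_away(total_sites * true_polymorphic / inspected)))
  class(out) <- "activity_estimate"
  out
}

#' @export
print.activity_estimate <- function(x, ...) {
  cat(sprintf("%d of %d inspected sites are true polymorphisms (%.1f%%)\n",
              x$true_polymorphic, x$inspected, x$percent))
  cat(sprintf("extrapolated over %d candidate sites: ~%d mobilized copies\n",
              x$total_sites, x$extrapolated_total))
  invisible(x)
}
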