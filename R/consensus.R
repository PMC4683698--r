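# Copy clustering into sub-types and majority-rule consensus building via
# center-star multiple alignment.

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap of length
#' L costs 3 + L, i.e. -4 for the first gap base and -1 for each further
#' one); identity is matches / alignment columns, in percent to one
#' decimal. Symmetric in its arguments.
#'
#' @param a,b Nucleotide strings (non-empty).
#' @return Percent identity (numeric scalar).
#' @export
pairwise_identity <- function(a, b) {
  a <- clean_seq(a, "a"); b <- clean_seq(b, "b")
  stopifnot(nzchar(a), nzchar(b))
  al <- align_pair(a, b, type = "global", match = 1, mismatch = -1,
                   gap_open = 3, gap_ext = 1)
  round_half_away(100 * al$matches / al$columns, 1)
}

#' Greedy center-based clustering of element copies
#'
#' Copies are ordered by length (longest first), ties broken by id
#' lexicographically; the first unassigned copy becomes a cluster center
#' and all unassigned copies with global identity >= threshold to the
#' center join it. The procedure repeats until all copies are assigned, so
#' the output is a partition and is deterministic given the ordering rule.
#'
#' @param copies Named character vector of copy sequences.
#' @param threshold Percent identity to the center required for membership
#'   (default 80).
#' @return A list of class \code{"copy_clusters"}; each cluster is a list
#'   with members (ids), center (id) and mean_identity (mean over all
#'   member pairs, 100 for singletons).
#' @export
cluster_copies <- function(copies, threshold = 80) {
  stopifnot(length(copies) >= 1L)
  if (is.null(names(copies)))
    names(copies) <- sprintf("copy%03d", seq_along(copies))
  ord <- order(-nchar(copies), names(copies))
  copies <- copies[ord]
  unassigned <- names(copies)
  clusters <- list()
  while (length(unassigned)) {
    center <- unassigned[1L]
    ids <- vapply(unassigned, function(id)
      if (id == center) 100 else pairwise_identity(copies[[center]], copies[[id]]),
      0)
    members <- unassigned[ids >= threshold]
    mean_id <- if (length(members) == 1L) 100 else {
      pr <- utils::combn(members, 2L)
      mean(vapply(seq_len(ncol(pr)), function(q)
        pairwise_identity(copies[[pr[1L, q]]], copies[[pr[2L, q]]]), 0))
    }
    clusters[[length(clusters) + 1L]] <-
      list(members = members, center = center,
           mean_identity = round_half_away(mean_id, 1))
    unassigned <- setdiff(unassigned, members)
  }
  class(clusters) <- "copy_clusters"
  clusters
}

#' @export
print.copy_clusters <- function(x, ...) {
  cat(length(x), "cluster(s)\n")
  for (i in seq_along(x))
    cat(sprintf("  %d: %d member(s), center %s, mean identity %.1f%%\n",
                i, length(x[[i]]$members), x[[i]]$center, x[[i]]$mean_identity))
  invisible(x)
}

# Center-star MSA: align every member to the center, then merge pairwise
# alignments into one multiple alignment ("once a gap, always a gap").
center_star_msa <- function(members, center_idx) {
  center <- members[[center_idx]]
  L <- nchar(center)
  alns <- lapply(members, function(m) {
    if (identical(m, center)) {
      list(c_aln = center, m_aln = m)
    } else {
      al <- align_pair(center, m, type = "global", match = 1, mismatch = -1,
                       gap_open = 3, gap_ext = 1)
      list(c_aln = al$a_aln, m_aln = al$b_aln)
    }
  })
  # ins[[m]][i + 1]: gaps in the center row before center base i+1
  # (slot 0 = before the first base, slot L = after the last)
  ins <- lapply(alns, function(al) {
    cc <- strsplit(al$c_aln, "")[[1L]]
    slot <- integer(L + 1L)
    pos <- 0L
    for (ch in cc) {
      if (ch == "-") slot[pos + 1L] <- slot[pos + 1L] + 1L
      else pos <- pos + 1L
    }
    slot
  })
  maxins <- Reduce(pmax, ins)
  rows <- vapply(seq_along(alns), function(mi) {
    cc <- strsplit(alns[[mi]]$c_aln, "")[[1L]]
    mm <- strsplit(alns[[mi]]$m_aln, "")[[1L]]
    out <- character(0)
    pos <- 0L
    pending <- character(0)
    flush_slot <- function(out, pending, pos)
      c(out, pending, rep("-", maxins[pos + 1L] - length(pending)))
    for (q in seq_along(cc)) {
      if (cc[q] == "-") {
        pending <- c(pending, mm[q])
      } else {
        out <- flush_slot(out, pending, pos)
        pending <- character(0)
        pos <- pos + 1L
        out <- c(out, mm[q])
      }
    }
    out <- flush_slot(out, pending, pos)
    paste(out, collapse = "")
  }, "")
  # center row in the same layout: slot-0 pad, then base+pad pairs
  center_row <- paste0(paste(rep("-", maxins[1L]), collapse = ""),
                       paste(vapply(seq_len(L), function(i)
                         paste0(substr(center, i, i),
                                paste(rep("-", maxins[i + 1L]), collapse = "")),
                         ""), collapse = ""))
  list(rows = rows, center_row = center_row)
}

#' Majority-rule consensus of a cluster
#'
#' Builds a center-star multiple alignment (center = the representative,
#' by default the longest member) and takes the per-column majority symbol.
#' Columns where the gap is the strict majority are dropped; ties among
#' bases are broken toward the center's symbol, then alphabetically.
#'
#' @param members Character vector of member sequences (>= 1).
#' @param center Index or id of the representative; default the longest
#'   member (ties by order).
#' @return A list of class \code{"consensus_sequence"}: seq, support
#'   (fraction of members agreeing with each kept consensus column) and
#'   n_members.
#' @export
build_consensus <- function(members, center = NULL) {
  stopifnot(length(members) >= 1L)
  members <- vapply(members, clean_seq, "", USE.NAMES = FALSE)
  if (length(members) == 1L) {
    out <- list(seq = members, support = rep(1, nchar(members)),
                n_members = 1L)
    class(out) <- "consensus_sequence"
    return(out)
  }
  center_idx <- if (is.null(center)) which.max(nchar(members))
                else if (is.character(center)) match(center, names(members))
                else as.integer(center)
  msa <- center_star_msa(as.list(members), center_idx)
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  crow <- strsplit(msa$center_row, "")[[1L]]
  m <- nrow(mat)
  keep_seq <- character(0)
  support <- numeric(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    n_gap <- sum(col == "-")
    if (n_gap > m / 2) next
    tab <- table(col[col != "-"])
    top <- max(tab)
    tied <- names(tab)[tab == top]
    sym <- if (crow[j] %in% tied) crow[j] else sort(tied)[1L]
    keep_seq <- c(keep_seq, sym)
    support <- c(support, sum(col == sym) / m)
  }
  out <- list(seq = paste(keep_seq, collapse = ""), support = support,
              n_members = m)
  class(out) <- "consensus_sequence"
  out
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat(sprintf("consensus of %d member(s), %d bp, mean column support %.2f\n",
              x$n_members, nchar(x$seq), mean(x$support)))
  invisible(x)
}

#' Cluster copies and build one consensus per cluster
#'
#' Convenience wrapper: [cluster_copies()] then [build_consensus()] per
#' cluster (center = the cluster representative).
#'
#' @inheritParams cluster_copies
#' @return A list with elements \code{clusters} and \code{consensi}
#'   (named character vector, one consensus per cluster).
#' @export
consensus_by_cluster <- function(copies, threshold = 80) {
  if (is.null(names(copies)))
    names(copies) <- sprintf("copy%03d", seq_along(copies))
  cl <- cluster_copies(copies, threshold)
  consensi <- vapply(seq_along(cl), function(i) {
    mem <- copies[cl[[i]]$members]
    build_consensus(mem, center = match(cl[[i]]$center, names(mem)))$seq
  }, "")
  names(consensi) <- sprintf("cluster%02d", seq_along(cl))
  list(clusters = cl, consensi = consensi)
}
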