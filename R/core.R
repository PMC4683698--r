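# Core sequence/coordinate types and elementary statistics.
#
# A "genome" is a named character vector of upper-case nucleotide sequences
# over {A,C,G,T,N}; an "interval" is a data.frame with columns record_id,
# start, end, strand, using 1-based inclusive coordinates on the forward
# strand (strand "-" marks reverse-strand features, GFF3 style).

#' Reverse complement of a nucleotide sequence
#'
#' N maps to N. Applying the function twice returns the input.
#'
#' @param seq A nucleotide string over \code{A,C,G,T,N} (case-insensitive;
#'   \code{U} is accepted with a warning and treated as \code{T}).
#' @return The reverse complement, upper-case.
#' @examples
#' reverse_complement("TC")      # "GA"
#' reverse_complement("GAATTC")  # palindrome
#' @export
reverse_complement <- function(seq) {
  s <- clean_seq(seq)
  if (nchar(s) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Sliding-window GC profile
#'
#' Computes the GC fraction \code{(#G + #C) / (window - #N)} in windows
#' placed at offsets 0, step, 2*step, ... for as long as the window fits
#' entirely inside the sequence. Windows consisting only of N yield
#' \code{NA}.
#'
#' @param seq Nucleotide string.
#' @param window Window size in bp (default 50).
#' @param step Step between window starts in bp (default 10).
#' @return A data.frame of class \code{"gc_profile"} with columns
#'   \code{window_start} (1-based) and \code{gc_fraction}; attributes
#'   \code{window} and \code{step}. Empty (with a warning) when
#'   \code{window > nchar(seq)}.
#' @seealso [write_gc_profile()]
#' @export
gc_profile <- function(seq, window = 50, step = 10) {
  s <- clean_seq(seq)
  stopifnot(window >= 1, step >= 1)
  n <- nchar(s)
  if (window > n) {
    warning("window larger than sequence; empty profile")
    out <- data.frame(window_start = integer(0), gc_fraction = numeric(0))
  } else {
    r <- charToRaw(s)
    is_gc <- as.integer(r == charToRaw("G") | r == charToRaw("C"))
    is_n <- as.integer(r == charToRaw("N"))
    cgc <- c(0L, cumsum(is_gc))
    cn <- c(0L, cumsum(is_n))
    starts <- seq.int(1L, n - window + 1L, by = step)
    gc <- cgc[starts + window] - cgc[starts]
    nn <- cn[starts + window] - cn[starts]
    denom <- window - nn
    out <- data.frame(window_start = starts,
                      gc_fraction = ifelse(denom == 0L, NA_real_, gc / denom))
  }
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("gc_profile", "data.frame")
  out
}

#' Construct a genomic interval table
#'
#' @param record_id Sequence record name(s).
#' @param start,end 1-based inclusive coordinates, \code{start <= end}.
#' @param strand \code{"+"} or \code{"-"}.
#' @return A data.frame with columns record_id, start, end, strand.
#' @export
interval <- function(record_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(all(start >= 1L), all(end >= start), all(strand %in% c("+", "-")))
  data.frame(record_id = as.character(record_id), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Inclusive length of an interval
#'
#' \code{end - start + 1}, independent of strand.
#'
#' @param iv An interval data.frame from [interval()].
#' @return Integer vector of lengths in bp.
#' @examples
#' interval_length(interval("chr11", 26619399, 26634911)) # 15513
#' @export
interval_length <- function(iv) {
  stopifnot(all(c("start", "end") %in% names(iv)))
  as.integer(iv$end) - as.integer(iv$start) + 1L
}

# Check an interval against a genome; errors on violation.
check_interval <- function(iv, genome) {
  stopifnot(iv$record_id %in% names(genome))
  len <- nchar(genome[[iv$record_id[1L]]])
  if (any(iv$start < 1L) || any(iv$end > len))
    stop("interval outside sequence bounds [1, ", len, "]")
  invisible(iv)
}

#' Read a genome from a FASTA file
#'
#' Sequences are upper-cased and validated (only \code{A,C,G,T,N} allowed;
#' \code{U} is converted to \code{T} with a warning). Record ids are the
#' first whitespace-delimited token of each FASTA header and must be unique
#' and non-empty.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("empty FASTA record id in ", path)
  if (anyDuplicated(ids)) stop("duplicate FASTA record ids in ", path)
  seqs <- vapply(seq_along(set), function(i)
    clean_seq(as.character(set[[i]]), what = ids[i]), "")
  setNames(seqs, ids)
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Export a GC profile as two-column TSV
#'
#' Columns: \code{window_start}, \code{gc_fraction}. A leading \code{#}
#' header line names the columns.
#'
#' @param profile A [gc_profile()] result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gc_profile <- function(profile, path) {
  stopifnot(inherits(profile, "gc_profile"))
  write_tsv_hash(as.data.frame(profile), path)
}

#' Load a printed element-coordinate table
#'
#' Reads a TSV with columns \code{genome}, \code{chromosome},
#' \code{start_pos}, \code{end_pos}, \code{comment}, where reverse-strand
#' copies may be printed in element orientation (start > end), and
#' normalizes to forward-strand intervals with a strand column.
#'
#' A copy of the published coordinates of the sister-family elements ships
#' with the package: \code{system.file("extdata",
#' "sister_family_copies.tsv", package = "heliscan")}.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns genome, record_id, start, end, strand,
#'   comment, length.
#' @export
read_coord_table <- function(path) {
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("genome", "chromosome", "start_pos", "end_pos") %in% names(x)))
  rev <- x$start_pos > x$end_pos
  out <- data.frame(
    genome = x$genome,
    record_id = as.character(x$chromosome),
    start = ifelse(rev, x$end_pos, x$start_pos),
    end = ifelse(rev, x$start_pos, x$end_pos),
    strand = ifelse(rev, "-", "+"),
    comment = if ("comment" %in% names(x)) x$comment else "",
    stringsAsFactors = FALSE)
  out$length <- interval_length(out)
  out
}
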