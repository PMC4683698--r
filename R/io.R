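# Tabular and GFF3 output. All tables carry a single "#" header line naming
# the columns and the tool version, so downstream parsers can skip it
# uniformly.

heliscan_version <- function() {
  as.character(utils::packageVersion("heliscan"))
}

# data.frame -> TSV with "# heliscan <ver>: col1 col2 ..." header line.
write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# heliscan %s: %s", heliscan_version(),
                     paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Read back a hash-headered TSV.
read_tsv_hash <- function(path, col.names) {
  first <- readLines(path, n = 1L)
  if (missing(col.names) && startsWith(first, "#"))
    col.names <- strsplit(sub("^#[^:]*:\\s*", "", first), "\t")[[1L]]
  read.delim(path, comment.char = "#", header = FALSE,
             col.names = col.names, stringsAsFactors = FALSE)
}

#' Write features as GFF3
#'
#' Coordinates are 1-based inclusive on the forward strand; reverse-strand
#' features carry strand \code{"-"} (GFF3 convention).
#'
#' @param features A data.frame with columns \code{record_id}, \code{start},
#'   \code{end}, \code{strand}, and optionally \code{type}, \code{score},
#'   \code{attributes} (a character column of \code{key=value} pairs joined
#'   by \code{;}).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @param type Default feature type when no \code{type} column is present.
#' @return Invisibly, \code{path}.
#' @export
write_gff3 <- function(features, path, source = "heliscan",
                       type = "sequence_feature") {
  stopifnot(all(c("record_id", "start", "end", "strand") %in% names(features)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                     features$record_id, source,
                     features$type %||% rep(type, nrow(features)),
                     as.integer(features$start), as.integer(features$end),
                     as.character(features$score %||% rep(".", nrow(features))),
                     features$strand,
                     features$attributes %||% sprintf("ID=feat%d", seq_len(nrow(features))))
    writeLines(lines, con)
  }
  invisible(path)
}

# Flat key = value config files mirroring CLI flags.
read_config <- function(path, allowed = NULL) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop(sprintf("cannot parse config %s line %d: '%s'", path, bad[1L], lines[bad[1L]]))
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  if (!is.null(allowed)) {
    unknown <- setdiff(names(vals), allowed)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  as.list(vals)
}
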