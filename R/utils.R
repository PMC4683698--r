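# Internal helpers shared across modules. Nothing here is exported.

BASES <- c("A", "C", "G", "T")

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate and normalize a nucleotide string: upper-case, U -> T (warned),
# anything outside {A,C,G,T,N} is a hard error.
clean_seq <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (grepl("U", s, fixed = TRUE)) {
    warning(sprintf("%s contains U; normalized to T (RNA input?)", what))
    s <- chartr("U", "T", s)
  }
  if (grepl("[^ACGTN]", s))
    stop(sprintf("%s contains characters outside {A,C,G,T,N,U}", what))
  s
}

# i.i.d. background sequence at a target GC fraction.
random_seq <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Substitute each position independently with probability `rate`,
# always to a different base. N positions are left untouched.
mutate_seq <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(x)) < rate & x != "N")
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1L), "")
    seq <- paste(x, collapse = "")
  }
  seq
}

# GC fraction of a whole sequence, N-aware (N excluded from the denominator).
gc_fraction <- function(seq) {
  r <- charToRaw(seq)
  n_gc <- sum(r == charToRaw("G") | r == charToRaw("C"))
  n_n <- sum(r == charToRaw("N"))
  denom <- length(r) - n_n
  if (denom == 0L) return(NA_real_)
  n_gc / denom
}

# round() uses banker's rounding; printed values in this field round half
# away from zero.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
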