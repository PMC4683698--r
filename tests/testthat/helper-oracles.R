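# Independent brute-force / dynamic-programming oracles used to validate
# the package's search heuristics on small instances, plus small sequence
# helpers. Oracles are deliberately naive re-derivations, kept separate
# from the implementation code paths.

rseq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

mutate_at <- function(seq, positions, comp = c(A = "C", C = "A", G = "T", T = "G")) {
  x <- strsplit(seq, "")[[1]]
  x[positions] <- comp[x[positions]]
  paste(x, collapse = "")
}

substitute_n <- function(seq, n_subs) {
  pos <- sample.int(nchar(seq), n_subs)
  mutate_at(seq, pos)
}

# --- hairpin: exhaustive enumeration over all placements -------------------
brute_hairpin <- function(seq, three_prime_pos, p = hairpin_params()) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  x <- strsplit(seq, "")[[1]]
  cand <- list()
  grid <- expand.grid(off = p$offset_min:p$offset_max,
                      stem = p$stem_min:p$stem_max,
                      loop = p$loop_min:p$loop_max)
  for (r in seq_len(nrow(grid))) {
    off <- grid$off[r]; stem <- grid$stem[r]; loop <- grid$loop[r]
    tot <- 2 * stem + loop
    if (tot < p$total_min || tot > p$total_max) next
    e <- three_prime_pos - off
    st <- e - tot + 1
    if (st < 1 || e < 1) next
    left <- x[st:(st + stem - 1)]
    right <- x[(e - stem + 1):e]
    ok <- vapply(seq_len(stem), function(i)
      left[i] %in% names(comp) && comp[[left[i]]] == right[stem + 1 - i], NA)
    mm <- stem - sum(ok)
    if (mm > p$max_mismatch) next
    gc <- mean(c(left, right) %in% c("G", "C"))
    if (gc < p$min_stem_gc) next
    gcp <- sum(ok & left %in% c("G", "C"))
    cand[[length(cand) + 1]] <- data.frame(
      start = st, end = e, stem_len = stem, loop_len = loop,
      total_len = tot, mm = mm, gc = gc, gcp = gcp, off = off)
  }
  if (!length(cand)) return(NULL)
  tab <- do.call(rbind, cand)
  tab[order(-tab$gcp, tab$mm, -tab$total_len, tab$off, -tab$stem_len), ][1, ]
}

# --- local alignment: full Smith-Waterman best score (linear gaps) ---------
sw_oracle_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  prev <- numeric(m + 1); best <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    s <- ifelse(B == A[i] & A[i] != "N", match, mismatch)
    for (j in seq_len(m))
      cur[j + 1] <- max(0, prev[j] + s[j], prev[j + 1] + gap, cur[j] + gap)
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

# --- global alignment score with affine gaps (Gotoh) -----------------------
nw_affine_oracle <- function(a, b, match, mismatch, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Global affine alignment with traceback, for identity checks on tiny
# strings (matches / alignment columns).
nw_affine_identity <- function(a, b, match, mismatch, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (A[i - 1] == B[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  matches <- 0; cols <- 0
  while (i > 1 || j > 1) {
    cols <- cols + 1
    if (state == 1) {
      if (A[i - 1] == B[j - 1]) matches <- matches + 1
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      state <- which(abs(prev + s - M[i, j]) < 1e-9)[1]
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      from_m <- abs(M[i - 1, j] - open - ext - X[i, j]) < 1e-9
      state <- if (i - 1 == 1 && j == 1) 1 else if (from_m) 1 else 2
      i <- i - 1
    } else {
      from_m <- abs(M[i, j - 1] - open - ext - Y[i, j]) < 1e-9
      state <- if (i == 1 && j - 1 == 1) 1 else if (from_m) 1 else 3
      j <- j - 1
    }
  }
  list(matches = matches, columns = cols,
       identity = 100 * matches / cols)
}

# --- maximal exact self matches: all-pairs scan ----------------------------
brute_self_matches <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]; n <- length(x)
  res <- NULL
  for (i in 1:(n - k)) {
    for (j in (i + 1):(n - k + 1)) {
      if (x[i] != x[j] || x[i] == "N") next
      if (i > 1 && x[i - 1] == x[j - 1] && x[i - 1] != "N") next  # not maximal left
      L <- 0
      while (j + L <= n && x[i + L] == x[j + L] && x[i + L] != "N") L <- L + 1
      if (L >= k) res <- rbind(res, data.frame(i = i, j = j, length = L))
    }
  }
  if (is.null(res)) res <- data.frame(i = integer(0), j = integer(0),
                                      length = integer(0))
  res[order(res$i, res$j), , drop = FALSE]
}
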