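# Independent brute-force segmentation oracle. Recomputes everything from
# scratch per window / per subinterval (no incremental counts), so it shares
# no code path with the compiled implementation it checks.

oracle_entropy <- function(chars) {
  cnt <- table(chars)
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

oracle_window_entropies <- function(seq, W) {
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  if (L < W) return(numeric(0))
  vapply(1:(L - W + 1L), function(p)
    oracle_entropy(chars[p:(p + W - 1L)]), numeric(1))
}

oracle_triggers <- function(seq, W, K1) {
  which(oracle_window_entropies(seq, W) <= K1)
}

# exhaustive scan over all subintervals of [a, b] minimizing
# len * (H - log2(omega)); ties -> longer, then smaller start
oracle_refine <- function(chars, a, b, omega) {
  eps <- 1e-9
  best <- Inf; bi <- a; bj <- a
  for (i in a:b) for (j in i:b) {
    len <- j - i + 1L
    h <- oracle_entropy(chars[i:j])
    score <- len * (h - log2(omega))
    blen <- bj - bi + 1L
    if (score < best - eps ||
        (score < best + eps && (len > blen || (len == blen && i < bi)))) {
      best <- score; bi <- i; bj <- j
    }
  }
  c(bi, bj)
}

oracle_segment <- function(seq, W, K1, K2, refine = TRUE, omega = 20) {
  W <- as.integer(W)
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  empty <- data.frame(start = integer(), end = integer())
  if (L < W) return(empty)
  H <- oracle_window_entropies(seq, W)
  ext <- H <= K2
  trig <- H <= K1
  r <- rle(ext)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regs <- list()
  for (k in seq_along(r$values))
    if (r$values[k] && any(trig[starts[k]:ends[k]]))
      regs[[length(regs) + 1L]] <- c(starts[k], ends[k] + W - 1L)
  if (!length(regs)) return(empty)
  merged <- list(regs[[1L]])
  for (rg in regs[-1L]) {
    last <- merged[[length(merged)]]
    if (rg[1L] <= last[2L] + 1L)
      merged[[length(merged)]][2L] <- max(last[2L], rg[2L])
    else
      merged[[length(merged) + 1L]] <- rg
  }
  if (refine)
    merged <- lapply(merged, function(rg)
      oracle_refine(chars, rg[1L], rg[2L], omega))
  data.frame(start = vapply(merged, `[`, integer(1), 1L),
             end = vapply(merged, `[`, integer(1), 2L))
}

# deterministic random sequences over a restricted alphabet
random_seqs <- function(n, alphabet, len_range = c(15L, 60L), seed = 42L) {
  set.seed(seed)
  replicate(n, {
    L <- sample(len_range[1L]:len_range[2L], 1L)
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  })
}
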