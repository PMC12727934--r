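# Independent brute-force oracles, deliberately implemented with a different
# algorithmic structure than the package kernels.

# Lempel-Ziv 1976 exhaustive-history parse via literal substring search:
# each phrase is extended while it can be copied from the prefix that ends
# one symbol before the phrase's current end, and closed at the first symbol
# that makes it novel.  A reproducible trailing remainder counts as one
# final phrase.
lz76_oracle <- function(s) {
  if (is.character(s)) s <- as.integer(strsplit(s, "")[[1]])
  n <- length(s)
  stopifnot(n >= 1)
  str <- paste(s, collapse = "")
  cnt <- 0L
  i <- 1L
  while (i <= n) {
    k <- 1L
    while (i + k - 1L <= n) {
      cand <- substr(str, i, i + k - 1L)
      hist <- substr(str, 1L, i + k - 2L)
      if (grepl(cand, hist, fixed = TRUE)) k <- k + 1L else break
    }
    cnt <- cnt + 1L
    i <- i + k
  }
  cnt
}

# Plain O(N^2) double-loop sample entropy (Chebyshev distance, self-matches
# excluded, r as a fraction of the epoch SD).
sampen_oracle <- function(x, m = 2, r_frac = 0.2) {
  r <- r_frac * stats::sd(x)
  N <- length(x)
  nt <- N - m
  A <- 0
  B <- 0
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# All binary strings of length n as rows of a matrix.
all_binary_strings <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  storage.mode(m) <- "integer"
  m
}

# Small fast cohort for structural tests.
make_test_cohort <- function(n_per_group = 2, duration_s = 10, fs = 250,
                             master_seed = 1) {
  generate_cohort(sim_config(n_subjects_per_group = n_per_group,
                             duration_s = duration_s, fs = fs,
                             master_seed = master_seed))
}
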