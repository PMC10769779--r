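# Independent reference implementations used only as test oracles.  They are
# deliberately written with different algorithms from the package code:
# a plain-matrix Gotoh alignment with explicit traceback, and brute-force
# enumeration of permutations / sign patterns for the exact tests.

# Local affine-gap alignment (Gotoh), forward strand only.  Gap of length L
# costs open + L * extend.  N mismatches everything including itself.
# Returns score, identity_pct, query_coverage_pct, aligned_length.
oracle_align_fwd <- function(query, ref, match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # best ending in a substitution column
  X <- matrix(NEG, n + 1, m + 1)     # gap in reference (query residue vs -)
  Y <- matrix(NEG, n + 1, m + 1)     # gap in query
  sub <- function(a, b) {
    if (a == "N" || b == "N") mismatch else if (a == b) match else mismatch
  }
  best <- 0; bi <- 0; bj <- 0; bmat <- "M"
  for (i in 1:n) {
    for (j in 1:m) {
      s <- sub(q[i], r[j])
      M[i + 1, j + 1] <- max(0, M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i; bj <- j; bmat <- "M"
      }
    }
  }
  if (best <= 0) {
    return(list(score = 0, identity_pct = 0, query_coverage_pct = 0,
                aligned_length = 0L))
  }
  # traceback from (bi, bj) in M until a 0 cell is reached
  i <- bi; j <- bj; mat <- bmat
  cols <- 0L; matches <- 0L; q_used <- 0L
  repeat {
    if (mat == "M") {
      s <- sub(q[i], r[j])
      cols <- cols + 1L; q_used <- q_used + 1L
      if (q[i] == r[j] && q[i] != "N") matches <- matches + 1L
      prev <- c(M[i, j], X[i, j], Y[i, j])
      from <- which.max(prev)
      i <- i - 1L; j <- j - 1L
      if (prev[from] <= 0) break
      mat <- c("M", "X", "Y")[from]
    } else if (mat == "X") {
      cols <- cols + 1L; q_used <- q_used + 1L
      if (abs(X[i + 1, j + 1] -
              (M[i, j + 1] - gap_open - gap_extend)) < 1e-9) {
        mat <- "M"
      }
      i <- i - 1L
    } else {
      cols <- cols + 1L
      if (abs(Y[i + 1, j + 1] -
              (M[i + 1, j] - gap_open - gap_extend)) < 1e-9) {
        mat <- "M"
      }
      j <- j - 1L
    }
  }
  list(score = best,
       identity_pct = 100 * matches / cols,
       query_coverage_pct = 100 * q_used / n,
       aligned_length = cols)
}

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

oracle_align <- function(query, ref, ...) {
  fwd <- oracle_align_fwd(query, ref, ...)
  rev <- oracle_align_fwd(revcomp_chr(query), ref, ...)
  if (rev$score > fwd$score) rev else fwd
}

# Brute-force exact rank-sum p: enumerate every assignment of nx of the
# pooled observations to group x.
oracle_rank_sum_p <- function(x, y, alternative = "two.sided") {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(pooled), nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  p_lower <- mean(ws <= w_obs + eps)
  p_upper <- mean(ws >= w_obs - eps)
  switch(alternative,
         two.sided = min(1, 2 * min(p_lower, p_upper)),
         less = p_lower,
         greater = p_upper)
}

# Brute-force exact signed-rank p: enumerate all 2^m sign patterns of the
# nonzero differences.
oracle_signed_rank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  ws <- as.vector(signs %*% r)
  eps <- 1e-9
  p_lower <- mean(ws <= w_obs + eps)
  p_upper <- mean(ws >= w_obs - eps)
  switch(alternative,
         two.sided = min(1, 2 * min(p_lower, p_upper)),
         less = p_lower,
         greater = p_upper)
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna_chr <- function(seq, rate) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  paste(s, collapse = "")
}
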