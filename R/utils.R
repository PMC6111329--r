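# internal numerical helpers

sigmoid <- function(z) 1 / (1 + exp(-z))

# power (linear, per Hz) -> dB/Hz with a floor for zero/negative power
DB_FLOOR <- -300

powerToDb <- function(p, floor_db = DB_FLOOR) {
  out <- rep(floor_db, length(p))
  pos <- p > 0
  out[pos] <- pmax(10 * log10(p[pos]), floor_db)
  out
}

# minimum-norm least-squares solve of A x = B via SVD pseudoinverse,
# singular values below rcond * max(sv) treated as zero
pinvSolve <- function(A, B, rcond = 1e-10) {
  s <- svd(A)
  keep <- s$d > rcond * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), ncol(B)))
  dinv <- ifelse(keep, 1 / s$d, 0)
  s$v %*% (dinv * (t(s$u) %*% B))
}

# uniform integer draw in [lo, hi] from the global RNG
drawInt <- function(lo, hi) {
  if (hi <= lo) return(as.integer(lo))
  as.integer(lo + floor(runif(1) * (hi - lo + 1)))
}
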