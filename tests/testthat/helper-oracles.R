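# Independent brute-force transcriptions of the five closed-form measures,
# written as plain loops so they share no code path with the package.

oracle_pm <- function(I) {
  m <- 0
  for (v in I) m <- m + v
  m <- m / length(I)
  ss <- 0
  for (v in I) ss <- ss + (v - m)^2
  s <- sqrt(ss / (length(I) - 1))
  100 - 100 * s / m
}

oracle_hjorth <- function(x) {
  N <- length(x)
  s0 <- 0
  for (v in x) s0 <- s0 + v^2
  s0 <- sqrt(s0 / N)
  d <- numeric(N - 1)
  for (j in 1:(N - 1)) d[j] <- x[j + 1] - x[j]
  s1 <- 0
  for (v in d) s1 <- s1 + v^2
  s1 <- sqrt(s1 / (N - 1))
  s2 <- 0
  for (j in 1:(N - 2)) s2 <- s2 + (d[j + 1] - d[j])^2
  s2 <- sqrt(s2 / (N - 2))
  c(mobility = s1 / s0, complexity = s2)
}

oracle_entropy <- function(x, M = 32L) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  counts <- rep(0, M)
  for (v in x) {
    b <- floor((v - lo) / (hi - lo) * M) + 1
    if (b > M) b <- M
    counts[b] <- counts[b] + 1
  }
  H <- 0
  for (c in counts) {
    p <- c / length(x)
    if (p > 0) H <- H + p * log(1 / p)
  }
  H
}

oracle_kte <- function(s) {
  out <- numeric(length(s) - 2)
  for (i in 2:(length(s) - 1)) out[i - 1] <- s[i]^2 - s[i + 1] * s[i - 1]
  out
}

# Yule-Walker by explicit normal equations on biased autocovariances
oracle_ar <- function(x, order = 5L) {
  n <- length(x)
  x <- x - mean(x)
  acv <- numeric(order + 1)
  for (k in 0:order) {
    s <- 0
    for (i in 1:(n - k)) s <- s + x[i] * x[i + k]
    acv[k + 1] <- s / n
  }
  R <- matrix(0, order, order)
  for (i in 1:order) for (j in 1:order) R[i, j] <- acv[abs(i - j) + 1]
  solve(R, acv[2:(order + 1)])
}
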