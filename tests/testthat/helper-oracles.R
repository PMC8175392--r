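# Independent brute-force oracles used across test files. These deliberately
# re-derive each quantity with a different mechanism than the implementation.

# per-minute window-scan non-wear oracle (plain loops, no rle)
choi_oracle <- function(counts, window = 90, spike_tolerance = 2, flank = 30) {
  n <- length(counts)
  zero <- counts == 0
  cand <- zero
  j <- 1L
  while (j <= n) {
    if (!zero[j]) {
      e <- j
      while (e < n && !zero[e + 1L]) e <- e + 1L
      if (e - j + 1L <= spike_tolerance) {
        nb <- 0L; k <- j - 1L
        while (k >= 1L && zero[k]) { nb <- nb + 1L; k <- k - 1L }
        na_ <- 0L; k <- e + 1L
        while (k <= n && zero[k]) { na_ <- na_ + 1L; k <- k + 1L }
        if (nb >= flank && na_ >= flank) cand[j:e] <- TRUE
      }
      j <- e + 1L
    } else {
      j <- j + 1L
    }
  }
  wear <- rep(TRUE, n)
  j <- 1L
  while (j <= n) {
    if (cand[j]) {
      e <- j
      while (e < n && cand[e + 1L]) e <- e + 1L
      if (e - j + 1L >= window) wear[j:e] <- FALSE
      j <- e + 1L
    } else {
      j <- j + 1L
    }
  }
  wear
}

# run-length bout oracle via explicit minute-by-minute scan
bouts_oracle <- function(posture, wear = rep(TRUE, length(posture))) {
  out <- integer(0)
  cur <- 0L
  for (i in seq_along(posture)) {
    if (posture[i] == "sit" && wear[i]) {
      cur <- cur + 1L
    } else if (cur > 0L) {
      out <- c(out, cur); cur <- 0L
    }
  }
  if (cur > 0L) out <- c(out, cur)
  out
}

# quantile-by-hand quartile assignment (sort and interpolate)
quartile_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  qp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q <- c(qp(0.25), qp(0.5), qp(0.75))
  1L + (x > q[1]) + (x > q[2]) + (x > q[3])
}

# hypergeometric upper-tail by explicit summation of choose() products
fisher_tail_oracle <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + b       # pathway size
  n <- a + c_      # target size
  ks <- max(a, 0):min(K, n)
  if (!length(ks)) return(1)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# simple weighted mean difference for ATE cross-checks
wmd_oracle <- function(y, t, w) {
  sum(w[t == 1] * y[t == 1]) / sum(w[t == 1]) -
    sum(w[t == 0] * y[t == 0]) / sum(w[t == 0])
}
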