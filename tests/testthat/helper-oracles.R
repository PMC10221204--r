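# Independent oracles, kept deliberately naive.

# Exhaustive pairwise-slope median with the shifted-median offset, written
# as plain double loops (independent of the vectorised implementation).
pb_oracle <- function(x, y) {
  n <- length(x)
  s <- numeric(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      sl <- if (dx == 0) sign(dy) * Inf else dy / dx
      if (sl == -1) next
      s <- c(s, sl)
    }
  }
  s <- sort(s)
  ns <- length(s)
  k <- 0
  for (v in s) if (v < -1) k <- k + 1
  b <- if (ns %% 2 == 1) {
    s[min(max((ns + 1) / 2 + k, 1), ns)]
  } else {
    (s[min(max(ns / 2 + k, 1), ns)] + s[min(max(ns / 2 + 1 + k, 1), ns)]) / 2
  }
  list(slope = b, intercept = stats::median(y - b * x))
}

# Direct solution of the 2x2 weighted normal equations.
wls_oracle <- function(x, y, w) {
  sw <- sum(w)
  sx <- sum(w * x)
  sy <- sum(w * y)
  sxx <- sum(w * x^2)
  sxy <- sum(w * x * y)
  b <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
  a <- (sy - b * sx) / sw
  c(intercept = a, slope = b)
}

rel_err <- function(est, truth) {
  abs(est - truth) / pmax(abs(truth), 1e-12)
}
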