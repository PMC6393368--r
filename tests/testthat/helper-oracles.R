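# Brute-force peak oracle: an exhaustive sample-by-sample scan for local
# extrema with the same prominence rule as the detector, written
# independently (no run-length encoding, no subpixel refinement). Plateaus
# are reported at their integer-midpoint position.
oracle_peaks <- function(pos, v, frac = 0.15, zero_tol = 1e-9) {
  n <- length(v)
  out <- data.frame(position = numeric(0), sign = numeric(0))
  if (n < 3L || max(abs(v)) <= zero_tol) return(out)
  thr <- frac * max(abs(v))
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L   # plateau [i, j]
    if (j <= n - 1L) {
      for (s in c(1, -1)) {
        w <- s * v
        if (w[i] > w[i - 1L] && w[i] > w[j + 1L]) {
          k <- i - 1L; lmin <- w[i]
          while (k >= 1L && w[k] <= w[i]) { lmin <- min(lmin, w[k]); k <- k - 1L }
          k <- j + 1L; rmin <- w[i]
          while (k <= n && w[k] <= w[i]) { rmin <- min(rmin, w[k]); k <- k + 1L }
          if (w[i] - max(lmin, rmin) >= thr) {
            out <- rbind(out, data.frame(position = mean(pos[i:j]), sign = s))
          }
        }
      }
    }
    i <- j + 1L
  }
  out[order(out$position), , drop = FALSE]
}

# random wiggly profiles for the oracle-equivalence property
random_profile <- function(len) {
  v <- cumsum(rnorm(len))
  tibble::tibble(pos = seq_len(len) - 1L, value = v)
}
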