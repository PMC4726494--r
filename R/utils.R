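logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Inverse of the cumulative normalized-weight function; ties (a probability
# atom straddling the target) resolved by the midpoint of the bracketing
# values.
weightedQuantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p - 1e-12)[1L]
    if (abs(cw[i] - p) <= 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2
    else x[i]
  }, numeric(1L))
}

# Effective sample size from the autocorrelation time, truncating the
# lag sum at the first non-positive autocorrelation (initial positive
# sequence style, first-lag variant).
essAutocorr <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(as.numeric(n))
  rho <- as.vector(acf(x, lag.max = min(n - 1L, 1000L),
                       plot = FALSE)$acf)[-1L]
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

deterministicJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
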