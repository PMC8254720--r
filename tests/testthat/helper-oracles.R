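# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops and textbook formulas only.

# Straight-line re-implementation of the cleaning chain (gross filter ->
# velocity excision -> 100 ms binning). Returns removed index sets and the
# binned pupil series so the production chain can be checked sample for
# sample.
oracle_clean_chain <- function(trace, median_dev = 1.0, pupil_min = 0.1,
                               speed_max = 2.5, excision_ms = 20,
                               bin_ms = 100, dur_ms = 4000) {
  p <- trace$pupil_mm
  t <- trace$t_ms
  med <- median(p, na.rm = TRUE)
  removed_gross <- integer(0)
  for (i in seq_along(p)) {
    if (is.na(p[i]) || p[i] < pupil_min || abs(p[i] - med) > median_dev) {
      removed_gross <- c(removed_gross, i)
    }
  }
  keep <- setdiff(seq_along(p), removed_gross)
  # speeds between consecutive retained samples
  offend_t <- c()
  if (length(keep) >= 2) {
    for (j in 2:length(keep)) {
      i0 <- keep[j - 1]; i1 <- keep[j]
      sp <- abs(p[i1] - p[i0]) / ((t[i1] - t[i0]) / 1000)
      if (sp > speed_max) offend_t <- c(offend_t, t[i1])
    }
  }
  removed_speed <- integer(0)
  if (length(offend_t)) {
    for (j in seq_along(keep)) {
      i <- keep[j]
      if (any(abs(t[i] - offend_t) <= excision_ms / 2)) {
        removed_speed <- c(removed_speed, i)
      }
    }
  }
  keep2 <- setdiff(keep, removed_speed)
  n_bins <- ceiling(dur_ms / bin_ms)
  bins <- rep(NA_real_, n_bins)
  for (k in seq_len(n_bins)) {
    lo <- (k - 1) * bin_ms; hi <- k * bin_ms
    sel <- keep2[t[keep2] >= lo & t[keep2] < hi]
    if (length(sel)) bins[k] <- sum(p[sel]) / length(sel)
  }
  list(removed_gross = removed_gross, removed_speed = removed_speed,
       bins = bins)
}

# JZS correlation Bayes factor by fixed-grid Simpson quadrature on the
# substitution g = s/(1-s), independent of stats::integrate.
oracle_lgbf_corr <- function(r, n, n_grid = 400001) {
  s <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  g <- s / (1 - s)
  # log-space evaluation (the direct product overflows for n >~ 100)
  lf <- (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g) -
    1.5 * log(g) - n / (2 * g) - 2 * log1p(-s)
  m <- max(lf)
  h <- s[2] - s[1]
  w <- rep(c(4, 2), length.out = n_grid)
  w[1] <- w[n_grid] <- 1
  int <- exp(m) * h / 3 * sum(w * exp(lf - m))
  log10(sqrt(n / 2) / gamma(0.5) * int)
}

# Textbook first-order partial correlation.
oracle_partial_r <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Random 500 Hz-style trace with planted blink runs, spikes and drift.
# Returns the trace; artifacts are whatever the thresholds say they are
# (the oracle chain defines truth).
make_random_trace <- function(n = 2000, base = 4.26) {
  t_ms <- seq(0, by = 2, length.out = n)
  p <- base + cumsum(rnorm(n, 0, 0.0005)) + 0.2 * sin(t_ms / 700)
  n_blinks <- rpois(1, 1.5)
  for (b in seq_len(n_blinks)) {
    o <- sample(n, 1)
    len <- sample(30:120, 1)
    idx <- o:min(n, o + len - 1)
    p[idx] <- runif(1, 0, 0.09)
  }
  n_spikes <- rpois(1, 3)
  if (n_spikes > 0) {
    idx <- sample(n, n_spikes)
    p[idx] <- p[idx] + sample(c(-1, 1), n_spikes, TRUE) * runif(n_spikes, 0.5, 2.5)
  }
  # a few isolated missing samples
  p[sample(n, rpois(1, 2))] <- NA
  data.frame(t_ms = t_ms, pupil_mm = p)
}

# Quiet lme4 fits in simulation loops
fit_lmm_quiet <- function(...) suppressMessages(suppressWarnings(fit_lmm(...)))
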