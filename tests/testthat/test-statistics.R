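balanced_data <- function(n_part = 6, reps = 4, part_sd = 0,
                          size_eff = 0.1, loc_eff = 0.2, noise = 1,
                          seed = 1) {
  set.seed(seed)
  d <- expand.grid(participant_id = factor(seq_len(n_part)),
                   size = factor(1:5), location = c("near", "far"),
                   rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
  b_part <- rnorm(n_part, 0, part_sd)
  d$y <- b_part[as.integer(d$participant_id)] +
    as.numeric(d$size) * size_eff + (d$location == "far") * loc_eff +
    rnorm(nrow(d), 0, noise)
  d
}

test_that("LMM F tests match classical ANOVA in the zero-variance limit", {
  d <- balanced_data()
  # force exactly-zero between-participant variance in sample
  d$y <- d$y - ave(d$y, d$participant_id) + mean(d$y)
  res <- fit_lmm_quiet(d, "y", "size * location")
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  a <- anova(aov(y ~ size * location, d))
  expect_equal(res$anova$F, a$`F value`[1:3], tolerance = 1e-6)
  expect_equal(res$anova$df1, a$Df[1:3])
  expect_equal(res$anova$df2, rep(nrow(d) - 10L, 3))
  expect_lt(res$varcomp[["participant_id"]], 1e-10)
})

test_that("LMM detects a planted location shift (scaled-down power check)", {
  # spec-scale is 100 runs at 50 x 98 trials; scaled to 15 runs at
  # 20 x 60 trials with the same shift/noise ratio to keep the default
  # suite fast -- power is higher, not lower, than the spec's setting
  # (more trials per noise unit would be the reverse; here 0.1 mm shift
  # against 0.1 mm noise is detectable at tiny n)
  hits <- 0L
  for (s in 1:15) {
    d <- balanced_data(n_part = 20, reps = 6, part_sd = 0.1,
                       size_eff = 0, loc_eff = 0.1, noise = 0.1, seed = s)
    res <- fit_lmm_quiet(d, "y", "size * location")
    p_loc <- res$anova$p[res$anova$term == "location"]
    if (p_loc < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 15L * 0.95)
})

test_that("LMM p-values are null-uniform under response permutation", {
  d <- balanced_data(n_part = 8, reps = 3, part_sd = 0,
                     size_eff = 0, loc_eff = 0, noise = 1, seed = 99)
  set.seed(100)
  pvals <- replicate(150, {
    d$y <- sample(d$y)
    res <- fit_lmm_quiet(d, "y", "size * location")
    res$anova$p
  })
  for (i in 1:3) {
    ks <- suppressWarnings(ks.test(pvals[i, ], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("LMM rejects degenerate designs with a named factor", {
  d <- balanced_data()
  d1 <- d[d$location == "near", ]
  expect_error(fit_lmm_quiet(d1, "y", "size * location"), "location")
  d$z <- NA_real_
  d2 <- d[as.integer(d$participant_id) == 1L, ]
  expect_error(fit_lmm_quiet(d2, "y", "size * location"), "participants")
})

test_that("context effects equal direct re-filtering and re-averaging", {
  mk <- function(v) data.frame(
    participant_id = rep(1:3, each = 100),
    size_level = rep(rep(1:5, each = 10), 6),
    location = rep(rep(c("near", "far"), each = 50), 3),
    valid = TRUE, pupil_response_mm = v, report_mm = v * 10)
  aq <- data.frame(participant_id = 1:3, aq = c(5, 16, 28))

  # all-identical values: every effect is 0
  eff <- context_effects(mk(rep(-0.2, 300)), aq)
  expect_equal(eff$pupil_effect_mm, rep(0, 3))
  expect_equal(eff$report_effect_mm, rep(0, 3))

  # forced arithmetic: far -0.3, near -0.2 -> effect -0.1
  s <- mk(rep(0, 300))
  s$pupil_response_mm <- ifelse(s$location == "far", -0.3, -0.2)
  s$report_mm <- ifelse(s$location == "far", 90, 80)
  eff <- context_effects(s, aq)
  expect_equal(eff$pupil_effect_mm, rep(-0.1, 3))
  expect_equal(eff$report_effect_mm, rep(10, 3))
  # per-size variants average to the pooled value on balanced data
  per_size <- as.matrix(eff[paste0("pupil_effect_s", 1:5)])
  expect_equal(rowMeans(per_size), eff$pupil_effect_mm, ignore_attr = TRUE)

  # random validity masks vs independent recomputation
  set.seed(9)
  for (i in 1:5) {
    s <- mk(rnorm(300))
    s$valid <- runif(300) < 0.8
    eff <- context_effects(s, aq)
    for (pid in 1:3) {
      sub <- s[s$valid & s$participant_id == pid, ]
      expect_equal(eff$pupil_effect_mm[eff$participant_id == pid],
                   mean(sub$pupil_response_mm[sub$location == "far"]) -
                     mean(sub$pupil_response_mm[sub$location == "near"]))
    }
  }

  # a participant with an empty cell is NA and logged
  s <- mk(rnorm(300))
  s$valid[s$participant_id == 2 & s$location == "far"] <- FALSE
  eff <- context_effects(s, aq)
  expect_true(is.na(eff$pupil_effect_mm[eff$participant_id == 2]))
  expect_match(attr(eff, "log"), "participant 2")
})

test_that("Pearson machinery: perfect fit, closed form, errors", {
  x <- 1:10
  expect_equal(pearson_ci(x, 2 * x + 1)$r, 1)
  # hand-computed covariance ratio on printed pairs
  px <- c(1, 2, 3, 4, 5); py <- c(2, 1, 4, 3, 6)
  r_hand <- sum((px - 3) * (py - mean(py))) /
    sqrt(sum((px - 3)^2) * sum((py - mean(py))^2))
  res <- pearson_ci(px, py)
  expect_equal(res$r, r_hand)
  expect_true(res$ci95[1] <= res$r && res$r <= res$ci95[2])
  expect_error(pearson_ci(1:2, 2:1), "3")
  expect_error(pearson_ci(rep(1, 5), 1:5), "variance")
})

test_that("correlation Bayes factor matches an independent quadrature oracle", {
  for (r in c(0, 0.1, 0.38, 0.6, -0.38, 0.9)) {
    for (n in c(10, 50, 200)) {
      expect_equal(lgbf_correlation(r, n), oracle_lgbf_corr(r, n),
                   tolerance = 1e-4)
    }
  }
})

test_that("correlation Bayes factor: symmetry, monotonicity, null behavior", {
  rs <- seq(0.05, 0.9, by = 0.05)
  for (n in c(10, 50)) {
    lg <- sapply(rs, lgbf_correlation, n = n)
    expect_equal(lg, sapply(-rs, lgbf_correlation, n = n))
    expect_true(all(diff(lg) > 0))       # increasing in |r|
  }
  # evidence for the null accumulates with n at r = 0
  lg0 <- sapply(c(10, 25, 50, 100, 200), lgbf_correlation, r = 0)
  expect_true(all(diff(lg0) < 0))
  expect_lt(lgbf_correlation(0, 50), -0.5)
  # the convention's substantial-evidence threshold at the published
  # operating point: r = 0.38 at n = 50 clears +0.5
  expect_gt(lgbf_correlation(0.38, 50), 0.5)
  expect_equal(lgbf_correlation(0.38, 50), 0.62, tolerance = 0.05)
  expect_equal(lgbf_correlation(0.04, 50), -0.94, tolerance = 0.01)
})

test_that("partial correlation matches the textbook formula", {
  set.seed(21)
  # z orthogonalized against x and y: partial equals plain
  x <- rnorm(50); y <- rnorm(50); z0 <- rnorm(50)
  z <- resid(lm(z0 ~ x + y))
  expect_equal(partial_correlation(x, y, z)$r, pearson_ci(x, y)$r,
               tolerance = 1e-10)
  # shared-covariate structure: partial near 0 (scaled-down simulation)
  rs <- replicate(200, {
    z <- rnorm(40)
    partial_correlation(z + rnorm(40), z + rnorm(40), z)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
  # 6-point worked set vs the closed form
  x6 <- c(1, 2, 4, 3, 6, 5); y6 <- c(2, 4, 3, 6, 5, 8); z6 <- c(1, 3, 2, 5, 4, 6)
  expect_equal(partial_correlation(x6, y6, z6)$r,
               oracle_partial_r(x6, y6, z6), tolerance = 1e-10)
  # exactly zero when y is a deterministic function of z alone
  zz <- rnorm(30)
  expect_lt(abs(partial_correlation(rnorm(30), 2 * zz + 1, zz)$r), 1e-10)
})

test_that("median split assigns ties to the low group and averages correctly", {
  eff <- data.frame(participant_id = 1:30, aq = c(2:16, 16, 17:30),
                    pupil_effect_mm = rnorm(30, -0.05, 0.02))
  med <- median(eff$aq)
  ms <- median_split(eff)
  expect_equal(ms$median_aq, rep(med, 2))
  expect_equal(ms$n[ms$group == "low"], sum(eff$aq <= med))
  expect_equal(ms$n[ms$group == "high"], sum(eff$aq > med))
  # independent split-and-average oracle
  expect_equal(ms$mean_effect[ms$group == "low"],
               mean(eff$pupil_effect_mm[eff$aq <= med]))
  expect_equal(ms$mean_effect[ms$group == "high"],
               mean(eff$pupil_effect_mm[eff$aq > med]))
  # degenerate: identical effects give zero-width intervals
  eff$pupil_effect_mm <- -0.1
  ms2 <- median_split(eff)
  expect_equal(ms2$mean_effect, c(-0.1, -0.1))
  expect_equal(ms2$ci_lo, ms2$ci_hi)
  expect_error(median_split(eff[1:2, ]), "fewer than 2")
})

test_that("two-sample t with JZS Bayes factor behaves and matches anchors", {
  set.seed(31)
  a <- rnorm(20)
  res <- two_sample_bf_t(a, a)
  expect_equal(res$t, 0)
  expect_lt(res$lgbf, 0)
  # textbook-formula cross-check on a printed 5-vs-5 table
  g1 <- c(4.1, 3.9, 4.5, 4.0, 4.3); g2 <- c(3.6, 3.8, 3.5, 4.0, 3.7)
  res <- two_sample_bf_t(g1, g2)
  sp <- sqrt((4 * var(g1) + 4 * var(g2)) / 8)
  expect_equal(res$t, (mean(g1) - mean(g2)) / (sp * sqrt(2 / 5)))
  expect_equal(res$df, 8)
  # published operating points at printed precision: t(48) = 0.18 ->
  # lgBF -0.52 and t(48) = 0.75 -> lgBF -0.43 at 33 vs 17
  expect_equal(round(log10(jzs_bf_t(0.18, 33, 17)), 2), -0.52)
  expect_equal(round(log10(jzs_bf_t(0.75, 33, 17)), 2), -0.43)
  # planted 2-pooled-sd shift at 17 vs 33: substantial H1 in most runs
  hits <- mean(replicate(50, {
    two_sample_bf_t(rnorm(17, 2), rnorm(33, 0))$lgbf > 0.5
  }))
  expect_gte(hits, 0.95)
  expect_error(two_sample_bf_t(1, 1:5), ">= 2")
})

test_that("full inference is deterministic and recovers the planted coupling", {
  cfg <- sim_config(n_participants = 50, seed = 202)
  ss <- simulate_summaries(cfg)
  rep1 <- run_full_inference(ss$trials, ss$participants)
  rep2 <- run_full_inference(ss$trials, ss$participants)
  expect_identical(rep1, rep2)
  # pupil contextual effect correlates positively with AQ (less negative
  # effect at higher AQ) while the AQ-independent report channel shows
  # substantial evidence for the null
  expect_gt(rep1$aq_correlations$pupil$r, 0)
  expect_lt(rep1$aq_correlations$pupil$p, 0.05)
  expect_lt(rep1$aq_correlations$report$lgbf, -0.5)
  # AQ x location interaction present for pupil in the trial-level model
  pup <- rep1$lmm_aq_location$pupil
  expect_lt(pup$p[pup$term == "aq:location"], 0.05)
  # bundle completeness
  expect_named(rep1$median_split, c("pupil", "report"))
  expect_true(is.finite(rep1$aq_pupil_loo$r))
  expect_length(rep1$aq_correlations_per_size, 5)
})

test_that("size x location models recover main effects on summary data", {
  cfg <- sim_config(n_participants = 30, seed = 77)
  ss <- simulate_summaries(cfg)
  d <- merge(ss$trials[ss$trials$valid, ], ss$participants,
             by = "participant_id")
  d$size <- factor(d$size_level)
  rep_fit <- fit_lmm_quiet(d, "report_mm", "size * location")$anova
  pup_fit <- fit_lmm_quiet(d, "pupil_response_mm", "size * location")$anova
  # physical size and location both drive reports and pupil responses
  expect_lt(rep_fit$p[rep_fit$term == "size"], 1e-5)
  expect_lt(rep_fit$p[rep_fit$term == "location"], 1e-5)
  expect_lt(pup_fit$p[pup_fit$term == "size"], 1e-5)
  # the contextual pupil effect is deliberately subtle; at this scaled-down
  # n it is still unambiguous at the 0.001 level
  expect_lt(pup_fit$p[pup_fit$term == "location"], 1e-3)
})
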