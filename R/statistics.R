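#' Linear mixed model with participant random intercept
#'
#' Fits `response ~ fixed effects + (1 | participant)` by REML (via
#' \pkg{lme4}) and reports marginal (Type-III-style) Wald F tests for each
#' fixed term, using sum-to-zero contrasts for nominal factors and a
#' residual-based denominator df equal to the number of observations minus
#' the number of fixed-effect parameters. With zero between-participant
#' variance on balanced data these F statistics coincide with the classical
#' fixed-effects ANOVA.
#'
#' @param data data.frame of trial-level rows.
#' @param response Name of the response column (e.g. `"pupil_response_mm"`,
#'   `"report_mm"`, `"gaze_x_deg"`, `"baseline_pupil_mm"`).
#' @param fixed Right-hand-side formula string for the fixed effects, e.g.
#'   `"size * location"` or `"aq * location"`. Nominal variables must
#'   already be factors; numeric covariates (AQ) stay numeric.
#' @param participant Name of the grouping column (default
#'   `"participant_id"`).
#' @return Object of class `lmm_result`: list with `anova` (data.frame:
#'   term, F, df1, df2, p), `fit` (the `lmerMod`), `varcomp` (participant
#'   and residual variances), `n` (rows used).
#' @export
fit_lmm <- function(data, response, fixed, participant = "participant_id") {
  stopifnot(response %in% names(data))
  data <- data[is.finite(data[[response]]), , drop = FALSE]
  if (length(unique(data[[participant]])) < 2L) {
    stop("fit_lmm needs at least 2 participants", call. = FALSE)
  }
  fml_fixed <- stats::as.formula(paste("~", fixed))
  vars <- all.vars(fml_fixed)
  for (v in vars) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L) {
      stop("degenerate design: factor `", v,
           "` has fewer than 2 observed levels", call. = FALSE)
    }
    if (is.factor(data[[v]])) data[[v]] <- droplevels(data[[v]])
  }
  contr <- lapply(data[vars], function(x) if (is.factor(x)) "contr.sum")
  contr <- contr[!vapply(contr, is.null, logical(1))]
  fml <- stats::as.formula(
    paste(response, "~", fixed, "+ (1 |", participant, ")"))
  fit <- lme4::lmer(fml, data = data, REML = TRUE,
                    contrasts = if (length(contr)) contr,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  X <- lme4::getME(fit, "X")
  if (qr(X)$rank < ncol(X)) {
    stop("degenerate design: fixed-effect model matrix is rank deficient",
         call. = FALSE)
  }
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  asg <- attr(X, "assign")
  labs <- attr(stats::terms(fml_fixed), "term.labels")
  n <- nrow(data)
  df2 <- n - ncol(X)
  tab <- do.call(rbind, lapply(seq_along(labs), function(j) {
    idx <- which(asg == j)
    q <- length(idx)
    Fj <- drop(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE], b[idx])) / q
    data.frame(term = labs[j], F = Fj, df1 = q, df2 = df2,
               p = stats::pf(Fj, q, df2, lower.tail = FALSE))
  }))
  rownames(tab) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(anova = tab, fit = fit,
                 varcomp = stats::setNames(vc$vcov, vc$grp), n = n),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Linear mixed model (random participant intercept), n =", x$n, "\n")
  tab <- x$anova
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-18s F(%d,%d) = %.2f, p = %.3g\n", tab$term[i],
                tab$df1[i], tab$df2[i], tab$F[i], tab$p[i]))
  }
  invisible(x)
}

#' Per-participant contextual (far minus near) effects
#'
#' For each participant, the pooled effect is the mean over valid far
#' trials minus the mean over valid near trials, for both the pupil
#' response and the verbal report; per-size-level effects are the same
#' contrast within each size level. Participants lacking valid trials in a
#' pooled cell get NA and are reported in the attached log.
#'
#' @param summaries Trial summaries (as from [preprocess_session()] or
#'   [simulate_summaries()]): needs `participant_id`, `size_level`,
#'   `location`, `valid`, `pupil_response_mm`, `report_mm`.
#' @param aq data.frame `participant_id`, `aq` (and optionally `gender`).
#' @return data.frame, one row per participant: `aq`, `pupil_effect_mm`,
#'   `report_effect_mm`, `pupil_effect_s1..s5`, `report_effect_s1..s5`;
#'   attribute `"log"` lists participants with missing cells.
#' @export
context_effects <- function(summaries, aq) {
  d <- summaries[summaries$valid, , drop = FALSE]
  ids <- sort(unique(summaries$participant_id))
  log <- character(0)
  eff <- function(sub) {
    far <- sub$location == "far"
    c(pupil = mean(sub$pupil_response_mm[far]) -
        mean(sub$pupil_response_mm[!far]),
      report = mean(sub$report_mm[far]) - mean(sub$report_mm[!far]))
  }
  rows <- lapply(ids, function(id) {
    sub <- d[d$participant_id == id, , drop = FALSE]
    if (sum(sub$location == "far") == 0L || sum(sub$location == "near") == 0L) {
      log <<- c(log, paste0("participant ", id,
                            ": no valid trials in a location cell"))
      pooled <- c(pupil = NA_real_, report = NA_real_)
    } else {
      pooled <- eff(sub)
    }
    per_size <- sapply(1:5, function(s) {
      ss <- sub[sub$size_level == s, , drop = FALSE]
      if (sum(ss$location == "far") == 0L || sum(ss$location == "near") == 0L) {
        c(pupil = NA_real_, report = NA_real_)
      } else eff(ss)
    })
    out <- data.frame(participant_id = id,
                      pupil_effect_mm = pooled[["pupil"]],
                      report_effect_mm = pooled[["report"]])
    for (s in 1:5) {
      out[[paste0("pupil_effect_s", s)]] <- per_size["pupil", s]
      out[[paste0("report_effect_s", s)]] <- per_size["report", s]
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- merge(out, aq, by = "participant_id", sort = TRUE)
  attr(out, "log") <- log
  out
}

#' Pearson correlation with t-based p and Fisher-z confidence interval
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return Object of class `cor_result`: `n`, `r`, `ci95` (length 2), `p`
#'   (two-sided), `lgbf = NA` (fill via [lgbf_correlation()]).
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(c(z - zc * se, z + zc * se))
  structure(list(n = n, r = r, ci95 = ci, p = p, lgbf = NA_real_),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("r = %.3f [%.3f %.3f], n = %d, p = %.3g", x$r, x$ci95[1],
              x$ci95[2], x$n, x$p))
  if (is.finite(x$lgbf)) cat(sprintf(", lgBF = %.2f", x$lgbf))
  cat("\n")
  invisible(x)
}

#' Base-10 log JZS Bayes factor for a Pearson correlation
#'
#' Default Bayes factor H1/H0 for a correlation (Wetzels & Wagenmakers
#' convention, unit prior scale), computed by numerical integration over
#' the g-prior:
#' `BF10 = sqrt(n/2)/gamma(1/2) * integral_0^inf (1+g)^((n-2)/2) *
#' (1 + (1-r^2) g)^(-(n-1)/2) * g^(-3/2) * exp(-n/(2g)) dg`.
#' Symmetric in `r`; `|lgBF| > 0.5` is conventionally read as substantial
#' evidence.
#'
#' @param r Observed Pearson correlation, in `[-1, 1]`.
#' @param n Number of pairs (>= 3).
#' @return Base-10 logarithm of BF10.
#' @export
lgbf_correlation <- function(r, n) {
  stopifnot(is.finite(r), abs(r) <= 1, n >= 3)
  f <- function(g) {
    exp((n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g) -
          1.5 * log(g) - n / (2 * g))
  }
  int <- tryCatch(
    stats::integrate(f, 0, Inf, rel.tol = 1e-10, subdivisions = 500L),
    error = function(e) stop("Bayes-factor integration failed: ",
                             conditionMessage(e), call. = FALSE))
  if (int$message != "OK") {
    stop("Bayes-factor integration failed: ", int$message, call. = FALSE)
  }
  log10(sqrt(n / 2) / gamma(0.5) * int$value)
}

#' Partial Pearson correlation controlling for a covariate
#'
#' Correlates the residuals of `x` on `z` with the residuals of `y` on `z`
#' (equivalently the textbook formula); inherits the CI and p machinery of
#' [pearson_ci()].
#'
#' If either variable is (numerically) a deterministic function of the
#' covariate, its residuals are pure floating-point noise; the partial
#' correlation is then defined as exactly 0 (with p = 1) rather than the
#' correlation of rounding errors.
#'
#' @param x,y,z Numeric vectors (z may be a matrix of covariates).
#' @return A `cor_result` (with `n` the number of complete triples).
#' @export
partial_correlation <- function(x, y, z) {
  z <- as.matrix(z)
  ok <- is.finite(x) & is.finite(y) & apply(is.finite(z), 1, all)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  rx <- stats::resid(stats::lm.fit(cbind(1, z), x))
  ry <- stats::resid(stats::lm.fit(cbind(1, z), y))
  degenerate <- stats::sd(rx) < 1e-10 * max(stats::sd(x), 1e-300) ||
    stats::sd(ry) < 1e-10 * max(stats::sd(y), 1e-300)
  if (degenerate) {
    return(structure(list(n = length(x), r = 0, ci95 = c(-1, 1), p = 1,
                          lgbf = NA_real_),
                     class = "cor_result"))
  }
  pearson_ci(rx, ry)
}

#' Median-split group summaries of a contextual effect
#'
#' Splits participants at the sample median of their AQ scores: the high
#' group is strictly above the median, ties go to the low group. For each
#' group, the mean effect and a t-based 95% confidence interval of the
#' mean, plus whether the interval excludes zero.
#'
#' @param effects data.frame from [context_effects()].
#' @param on Effect column to summarize (default `"pupil_effect_mm"`).
#' @param conf_level Confidence level.
#' @return data.frame with rows `low`/`high`: `n`, `median_aq`,
#'   `mean_effect`, `ci_lo`, `ci_hi`, `excludes_zero`.
#' @export
median_split <- function(effects, on = "pupil_effect_mm", conf_level = 0.95) {
  med <- stats::median(effects$aq)
  grp <- ifelse(effects$aq > med, "high", "low")
  out <- lapply(c("low", "high"), function(g) {
    v <- effects[[on]][grp == g]
    v <- v[is.finite(v)]
    if (length(v) < 2L) {
      stop("median-split group `", g, "` has fewer than 2 participants",
           call. = FALSE)
    }
    m <- mean(v)
    se <- stats::sd(v) / sqrt(length(v))
    tc <- stats::qt(1 - (1 - conf_level) / 2, length(v) - 1)
    ci <- c(m - tc * se, m + tc * se)
    data.frame(group = g, n = length(v), median_aq = med, mean_effect = m,
               ci_lo = ci[1], ci_hi = ci[2],
               excludes_zero = ci[1] > 0 || ci[2] < 0)
  })
  do.call(rbind, out)
}

#' Pooled-variance two-sample t test with JZS Bayes factor
#'
#' Classical two-sample t on independent groups plus the default JZS Bayes
#' factor for the t statistic (Rouder et al. convention), reported as a
#' base-10 logarithm.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param rscale Cauchy prior scale on the standardized effect (default
#'   `sqrt(2)/2`, the two-sample default).
#' @return List: `t`, `df`, `p`, `lgbf`.
#' @export
two_sample_bf_t <- function(a, b, rscale = sqrt(2) / 2) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 values", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(t = tstat, df = df, p = p,
       lgbf = log10(jzs_bf_t(tstat, n1, n2, rscale)))
}

# JZS Bayes factor BF10 for a two-sample t statistic (Rouder et al. 2009),
# by numerical integration over the g prior.
jzs_bf_t <- function(t, n1, n2, rscale = sqrt(2) / 2) {
  nu <- n1 + n2 - 2
  N <- n1 * n2 / (n1 + n2)
  h0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  f <- function(g) {
    (1 + N * g * rscale^2)^(-0.5) *
      (1 + t^2 / ((1 + N * g * rscale^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  }
  int <- tryCatch(
    stats::integrate(f, 0, Inf, rel.tol = 1e-10, subdivisions = 500L),
    error = function(e) stop("Bayes-factor integration failed: ",
                             conditionMessage(e), call. = FALSE))
  int$value / h0
}

# helper: pearson_ci + lgbf in one object
cor_with_bf <- function(x, y) {
  res <- pearson_ci(x, y)
  res$lgbf <- lgbf_correlation(res$r, res$n)
  res
}

#' Run the complete inferential analysis
#'
#' Executes, in order: (1) mixed models with size-by-location fixed effects
#' on reports and pupil responses; (2) mixed models with AQ-by-location
#' effects on both; (3) per-participant contextual (far - near) effects and
#' their AQ correlations, pooled and per size level; (4) the pupil-versus-
#' report correlation across participant-by-cell means, plain and with
#' physical size partialled out; (5) controls: baseline-pupil mixed models
#' and AQ correlation, gaze mixed models, correlations of gaze contextual
#' effects with pupil effects and with AQ; (6) gender comparisons of both
#' contextual effects; (7) leave-one-out robustness of the pupil-versus-AQ
#' correlation after removing the participant with the most extreme pupil
#' effect. Deterministic: same inputs, same bundle.
#'
#' @param summaries Valid-trial summaries (see [context_effects()]); gaze
#'   and baseline columns are used when present.
#' @param participants data.frame `participant_id`, `aq`, optional
#'   `gender`.
#' @return A nested list of class `inference_report` (serializable with
#'   [write_report()]).
#' @export
run_full_inference <- function(summaries, participants) {
  d <- summaries[summaries$valid, , drop = FALSE]
  d <- merge(d, participants, by = "participant_id", sort = TRUE)
  d$size <- factor(d$size_level)
  d$location <- factor(d$location, levels = c("near", "far"))
  has_gaze <- all(c("gaze_x_deg", "gaze_y_deg") %in% names(d)) &&
    any(is.finite(d$gaze_x_deg))
  has_baseline <- "baseline_pupil_mm" %in% names(d) &&
    any(is.finite(d$baseline_pupil_mm))

  res <- list()
  res$lmm_size_location <- list(
    report = fit_lmm(d, "report_mm", "size * location")$anova,
    pupil = fit_lmm(d, "pupil_response_mm", "size * location")$anova)
  res$lmm_aq_location <- list(
    report = fit_lmm(d, "report_mm", "aq * location")$anova,
    pupil = fit_lmm(d, "pupil_response_mm", "aq * location")$anova)

  eff <- context_effects(summaries, participants)
  res$effects <- eff
  res$effects_log <- attr(eff, "log")
  res$aq_correlations <- list(
    pupil = cor_with_bf(eff$aq, eff$pupil_effect_mm),
    report = cor_with_bf(eff$aq, eff$report_effect_mm))
  res$aq_correlations_per_size <- lapply(stats::setNames(1:5, paste0("s", 1:5)),
    function(s) list(
      pupil = cor_with_bf(eff$aq, eff[[paste0("pupil_effect_s", s)]]),
      report = cor_with_bf(eff$aq, eff[[paste0("report_effect_s", s)]])))

  # participant x cell means (up to 10 points each)
  cell <- stats::aggregate(
    d[c("pupil_response_mm", "report_mm")],
    by = d[c("participant_id", "size_level", "location")], FUN = mean)
  cell$height_deg <- stimulus_heights()[cell$size_level]
  res$cell_means <- cell
  res$pupil_vs_report <- cor_with_bf(cell$pupil_response_mm, cell$report_mm)
  pr_part <- partial_correlation(cell$pupil_response_mm, cell$report_mm,
                                 cell$height_deg)
  pr_part$lgbf <- lgbf_correlation(pr_part$r, pr_part$n)
  res$pupil_vs_report_partial <- pr_part

  res$median_split <- list(
    pupil = median_split(eff, "pupil_effect_mm"),
    report = median_split(eff, "report_effect_mm"))

  if (has_baseline) {
    res$controls$baseline_lmm <- fit_lmm(d, "baseline_pupil_mm",
                                         "size * location")$anova
    base_pp <- stats::aggregate(baseline_pupil_mm ~ participant_id, d, mean)
    base_pp <- merge(base_pp, participants, by = "participant_id")
    res$controls$baseline_vs_aq <- cor_with_bf(base_pp$aq,
                                               base_pp$baseline_pupil_mm)
  }
  if (has_gaze) {
    res$controls$gaze_lmm <- list(
      x = fit_lmm(d, "gaze_x_deg", "size * location")$anova,
      y = fit_lmm(d, "gaze_y_deg", "size * location")$anova)
    geff <- lapply(c(x = "gaze_x_deg", y = "gaze_y_deg"), function(ch) {
      far <- stats::aggregate(d[[ch]][d$location == "far"],
                              by = list(participant_id =
                                          d$participant_id[d$location == "far"]),
                              FUN = mean)
      near <- stats::aggregate(d[[ch]][d$location == "near"],
                               by = list(participant_id =
                                           d$participant_id[d$location == "near"]),
                               FUN = mean)
      m <- merge(far, near, by = "participant_id")
      data.frame(participant_id = m$participant_id, effect = m$x.x - m$x.y)
    })
    for (ch in c("x", "y")) {
      m <- merge(geff[[ch]], eff, by = "participant_id")
      res$controls[[paste0("gaze_", ch, "_effect_vs_pupil")]] <-
        cor_with_bf(m$effect, m$pupil_effect_mm)
      res$controls[[paste0("gaze_", ch, "_effect_vs_aq")]] <-
        cor_with_bf(m$effect, m$aq)
    }
  }

  if ("gender" %in% names(eff) && length(unique(eff$gender)) == 2L &&
      min(table(eff$gender)) >= 2L) {
    f <- eff$gender == "F"
    res$gender <- list(
      report = two_sample_bf_t(eff$report_effect_mm[f],
                               eff$report_effect_mm[!f]),
      pupil = two_sample_bf_t(eff$pupil_effect_mm[f],
                              eff$pupil_effect_mm[!f]))
  }

  # leave-one-out robustness of the headline correlation
  ok <- is.finite(eff$pupil_effect_mm)
  extreme <- which(ok)[which.max(abs(
    eff$pupil_effect_mm[ok] - mean(eff$pupil_effect_mm[ok])))]
  loo <- eff[-extreme, , drop = FALSE]
  res$aq_pupil_loo <- c(cor_with_bf(loo$aq, loo$pupil_effect_mm),
                        removed_participant =
                          eff$participant_id[extreme])
  structure(res, class = "inference_report")
}
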