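#' Select a Box-Cox power transform by profile likelihood
#'
#' The synthetic post-prandial descriptors are typically right-skewed and
#' non-Gaussian; before mixed-model analysis each is power-transformed.
#' This selects the exponent \eqn{\lambda} maximising the Box-Cox profile
#' log-likelihood on a grid (default \eqn{[-2, 2]} in steps of 0.01) for an
#' intercept-only model.
#'
#' @param values Positive numeric vector, n >= 10.
#' @param grid Candidate exponents; default `seq(-2, 2, by = 0.01)`.
#' @return The selected exponent (numeric scalar).
#' @export
boxcox_lambda <- function(values, grid = seq(-2, 2, by = 0.01)) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) {
    stop("need at least 10 finite values to profile lambda", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("Box-Cox requires strictly positive values", call. = FALSE)
  }
  df <- data.frame(v = values)
  bc <- MASS::boxcox(v ~ 1, data = df, lambda = grid, plotit = FALSE)
  bc$x[which.max(bc$y)]
}

#' Apply a power transform
#'
#' Plain power transform \eqn{v^\lambda} (natural log when
#' \eqn{\lambda = 0}). The scaled Box-Cox form
#' \eqn{(v^\lambda - 1)/\lambda} differs from this only by a monotone affine
#' map at fixed \eqn{\lambda}, which leaves mixed-model tests unchanged;
#' the plain power keeps the transformed values on the conventional
#' reporting scale.
#'
#' @param values Positive numeric vector.
#' @param lambda Exponent.
#' @return Transformed values.
#' @export
apply_boxcox <- function(values, lambda) {
  if (any(values[is.finite(values)] <= 0)) {
    stop("power transform requires strictly positive values", call. = FALSE)
  }
  if (lambda == 0) log(values) else values^lambda
}

#' Shapiro-Wilk normality screen
#'
#' Checks a raw descriptor for normality before deciding on a power
#' transform. Non-normality (p < `alpha`) triggers a warning suggesting a
#' transform; the decision itself is left to the analyst.
#'
#' @param values Numeric vector.
#' @param alpha Warning threshold, default 0.05.
#' @return The `htest` object from [stats::shapiro.test()], invisibly.
#' @export
shapiro_check <- function(values, alpha = 0.05) {
  ht <- stats::shapiro.test(values[is.finite(values)])
  if (ht$p.value < alpha) {
    warning(sprintf(
      "Shapiro-Wilk rejects normality (W = %.3f, p = %.3g); consider a power transform",
      unname(ht$statistic), ht$p.value), call. = FALSE)
  }
  invisible(ht)
}

# Shared model frame: week as factor, day covariate already indicator-gated
# (days_since_change is 0 outside the first post-change week).
mixed_model_frame <- function(var_table, variable, lambda) {
  needed <- c("animal_id", "week", "days_since_change", variable)
  missing_cols <- setdiff(needed, names(var_table))
  if (length(missing_cols)) {
    stop("var_table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ok <- is.finite(var_table[[variable]])
  df <- data.frame(
    animal_id = factor(var_table$animal_id[ok]),
    week = factor(var_table$week[ok]),
    days = as.numeric(var_table$days_since_change[ok]),
    y = apply_boxcox(var_table[[variable]][ok], lambda)
  )
  if (nlevels(df$animal_id) < 2L) {
    stop("random intercept unidentifiable with a single animal",
         call. = FALSE)
  }
  if (nlevels(df$week) < 2L) {
    stop("need at least 2 weeks to estimate week effects", call. = FALSE)
  }
  df
}

lmer_quiet <- function(formula, data, REML) {
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  withCallingHandlers(
    suppressMessages(lme4::lmer(formula, data = data, REML = REML,
                                control = ctrl)),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' Fit the longitudinal mixed model to one synthetic variable
#'
#' Fits the random-intercept linear mixed model
#' \deqn{v_{ijk} = \alpha_j + G_i + \beta \, (days_k \, 1_{j=2}) + \epsilon_{ijk}}
#' on the power-transformed descriptor: fixed means \eqn{\alpha_j} for the
#' five experimental weeks, a fixed day slope \eqn{\beta} active only in the
#' first week after the diet change (via the indicator-gated day covariate),
#' a Gaussian random intercept \eqn{G_i} per animal
#' (\eqn{\sigma_A^2}, between-animal) and i.i.d. Gaussian residuals
#' (\eqn{\sigma^2}, within-animal).
#'
#' The model is fitted twice: by REML, from which the reported variance
#' components and the intraclass correlation
#' \eqn{\rho = \sigma_A^2/(\sigma^2 + \sigma_A^2)} are taken, and by ML,
#' whose log-likelihood feeds the nested likelihood-ratio tests of the
#' fixed effects (REML likelihoods are not comparable across fixed-effect
#' structures).
#'
#' @param var_table Annotated descriptor table (see [fit_all()]), or any
#'   data frame with columns `animal_id`, `week`, `days_since_change` and
#'   the response.
#' @param variable Name of the response column.
#' @param lambda Power-transform exponent; `NULL` (default) selects it with
#'   [boxcox_lambda()].
#' @return Object of class `mixed_model_result`: list with
#'   `variable_name`, `lambda`, `alpha` (named week means, transformed
#'   scale), `beta`, `sigma_A2`, `sigma2`, `rho`, `loglik_ml`, `n_obs`,
#'   `n_animals`, `blups` (per-animal random-intercept estimates), and the
#'   underlying `fit_reml` / `fit_ml` / `frame` for downstream use.
#' @export
fit_mixed <- function(var_table, variable, lambda = NULL) {
  if (is.null(lambda)) lambda <- boxcox_lambda(var_table[[variable]])
  df <- mixed_model_frame(var_table, variable, lambda)
  fml <- y ~ 0 + week + days + (1 | animal_id)
  fit_reml <- lmer_quiet(fml, df, REML = TRUE)
  fit_ml <- lmer_quiet(fml, df, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit_reml))
  sigma_A2 <- vc$vcov[vc$grp == "animal_id"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  fe <- lme4::fixef(fit_reml)
  alpha <- fe[grep("^week", names(fe))]
  names(alpha) <- sub("^week", "W", names(alpha))
  blups <- lme4::ranef(fit_reml)$animal_id
  structure(
    list(variable_name = variable,
         lambda = lambda,
         alpha = alpha,
         beta = unname(fe["days"]),
         sigma_A2 = sigma_A2,
         sigma2 = sigma2,
         rho = sigma_A2 / (sigma_A2 + sigma2),
         loglik_ml = as.numeric(stats::logLik(fit_ml)),
         n_obs = nrow(df),
         n_animals = nlevels(df$animal_id),
         blups = stats::setNames(blups[["(Intercept)"]], rownames(blups)),
         fit_reml = fit_reml,
         fit_ml = fit_ml,
         frame = df),
    class = "mixed_model_result"
  )
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("Mixed model for %s (lambda = %.2f): %d obs, %d animals\n",
              x$variable_name, x$lambda, x$n_obs, x$n_animals))
  cat("  week means (transformed scale):\n")
  print(round(x$alpha, 4))
  cat(sprintf("  day slope beta = %.4g\n", x$beta))
  cat(sprintf("  sigma_A^2 = %.4g, sigma^2 = %.4g, rho = %.3f\n",
              x$sigma_A2, x$sigma2, x$rho))
  invisible(x)
}

#' Likelihood-ratio tests of the fixed effects
#'
#' Tests the two fixed effects of the longitudinal model by nested ML
#' likelihood-ratio tests: the week effect by comparing the full model to
#' one with a single common intercept replacing the five week means
#' (4 constrained parameters, so df = 4), and the day effect by dropping
#' the indicator-gated slope (df = 1). The statistic is
#' \eqn{\chi^2 = 2 \Delta \ell} (clipped at 0) with p-values from the
#' \eqn{\chi^2} reference distribution.
#'
#' @inheritParams fit_mixed
#' @param effects Which effects to test; default both.
#' @return Data frame with columns `effect`, `chi2`, `df`, `p_value`,
#'   `method`.
#' @export
lrt_fixed_effects <- function(var_table, variable, lambda = NULL,
                              effects = c("week", "days")) {
  effects <- match.arg(effects, several.ok = TRUE)
  if (is.null(lambda)) lambda <- boxcox_lambda(var_table[[variable]])
  df <- mixed_model_frame(var_table, variable, lambda)
  ll <- function(fml) {
    as.numeric(stats::logLik(lmer_quiet(fml, df, REML = FALSE)))
  }
  ll_full <- ll(y ~ 0 + week + days + (1 | animal_id))
  out <- list()
  if ("week" %in% effects) {
    chi2 <- max(0, 2 * (ll_full - ll(y ~ 1 + days + (1 | animal_id))))
    k <- nlevels(df$week) - 1L
    out$week <- data.frame(effect = "week", chi2 = chi2, df = k,
                           p_value = stats::pchisq(chi2, k, lower.tail = FALSE),
                           method = "LRT-ML", stringsAsFactors = FALSE)
  }
  if ("days" %in% effects) {
    chi2 <- max(0, 2 * (ll_full - ll(y ~ 0 + week + (1 | animal_id))))
    out$days <- data.frame(effect = "days", chi2 = chi2, df = 1L,
                           p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
                           method = "LRT-ML", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Compact letter display by insert-and-absorb: start from one group holding
# all levels; each significant pair splits every group containing both;
# groups that become subsets of others are absorbed.
compact_letters <- function(levels, sig_pairs) {
  groups <- list(levels)
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs[r, 1]; j <- sig_pairs[r, 2]
      new_groups <- list()
      for (g in groups) {
        if (i %in% g && j %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, i)), list(setdiff(g, j)))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_groups))
      for (u in seq_along(new_groups)) {
        for (v in seq_along(new_groups)) {
          if (u != v && keep[u] &&
              all(new_groups[[u]] %in% new_groups[[v]]) &&
              (length(new_groups[[u]]) < length(new_groups[[v]]) || u > v)) {
            keep[u] <- FALSE
          }
        }
      }
      groups <- new_groups[keep]
    }
  }
  letters_out <- stats::setNames(rep("", length(levels)), levels)
  for (k in seq_along(groups)) {
    for (lv in groups[[k]]) {
      letters_out[lv] <- paste0(letters_out[lv], letters[k])
    }
  }
  letters_out
}

#' Pairwise week comparisons with FDR adjustment
#'
#' All ten pairwise contrasts between the five week means on the
#' transformed scale, with standard errors from the fixed-effect covariance
#' of the REML fit, normal-approximation z statistics (the effective
#' denominator df in small mixed models is ambiguous, so no t reference is
#' claimed), Benjamini-Hochberg adjusted p-values, and a compact letter
#' display: weeks sharing a letter do not differ at adjusted p < `alpha`.
#'
#' @param result A `mixed_model_result` from [fit_mixed()].
#' @param alpha Significance level for the letter display, default 0.05.
#' @return List of class `posthoc_weeks` with elements `contrasts` (data
#'   frame: `contrast`, `estimate`, `se`, `z`, `p_value`, `p_adj`) and
#'   `letters` (named character vector per week).
#' @export
posthoc_weeks <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "mixed_model_result"))
  fe <- lme4::fixef(result$fit_reml)
  V <- as.matrix(stats::vcov(result$fit_reml))
  wk_idx <- grep("^week", names(fe))
  wk_names <- sub("^week", "W", names(fe)[wk_idx])
  k <- length(wk_idx)
  pairs_idx <- utils::combn(k, 2)
  est <- se <- numeric(ncol(pairs_idx))
  lab <- character(ncol(pairs_idx))
  for (p in seq_len(ncol(pairs_idx))) {
    i <- pairs_idx[1, p]; j <- pairs_idx[2, p]
    cvec <- rep(0, length(fe))
    cvec[wk_idx[i]] <- 1; cvec[wk_idx[j]] <- -1
    est[p] <- sum(cvec * fe)
    se[p] <- sqrt(drop(t(cvec) %*% V %*% cvec))
    lab[p] <- paste(wk_names[i], "-", wk_names[j])
  }
  z <- est / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  sig <- which(p_adj < alpha)
  sig_pairs <- cbind(wk_names[pairs_idx[1, sig]], wk_names[pairs_idx[2, sig]])
  letters_out <- compact_letters(wk_names, sig_pairs)
  structure(
    list(contrasts = data.frame(contrast = lab, estimate = est, se = se,
                                z = z, p_value = p_raw, p_adj = p_adj,
                                stringsAsFactors = FALSE),
         letters = letters_out,
         alpha = alpha,
         method = "normal approximation, BH adjustment"),
    class = "posthoc_weeks"
  )
}

#' @export
print.posthoc_weeks <- function(x, ...) {
  print(transform(x$contrasts,
                  estimate = signif(estimate, 4), se = signif(se, 3),
                  z = round(z, 2), p_value = signif(p_value, 3),
                  p_adj = signif(p_adj, 3)))
  cat("letters:", paste(names(x$letters), x$letters, sep = ":",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Intraclass correlation (between-animal variance share)
#'
#' \eqn{\rho = \sigma_A^2 / (\sigma^2 + \sigma_A^2)}: the fraction of total
#' variance of a descriptor attributable to stable between-animal
#' differences, from the REML variance components.
#'
#' @param result A `mixed_model_result`.
#' @return Numeric in \[0, 1\].
#' @export
icc <- function(result) {
  stopifnot(inherits(result, "mixed_model_result"))
  result$sigma_A2 / (result$sigma_A2 + result$sigma2)
}

#' Simulate descriptor tables from the longitudinal model
#'
#' Draws a descriptor table directly from the random-intercept model at a
#' given truth: per-animal Gaussian intercepts, week means, the
#' indicator-gated day slope, and i.i.d. residuals, on the study design
#' given by `schedule`. Used by [power_simulation()] and for calibration
#' tests.
#'
#' @param truth List with `alpha` (week means, length matching the
#'   schedule's weeks), `beta` (day slope), `sigma_A2`, `sigma2`.
#' @param n_animals Number of animals, default 8.
#' @param schedule A [sampling_schedule()].
#' @return Data frame with `animal_id`, `day_label`, `week`,
#'   `days_since_change`, `value`.
#' @export
simulate_mixed <- function(truth, n_animals = 8L,
                           schedule = sampling_schedule()) {
  stopifnot(is.list(truth),
            all(c("alpha", "beta", "sigma_A2", "sigma2") %in% names(truth)))
  if (truth$sigma_A2 < 0 || truth$sigma2 < 0) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  base <- annotate_schedule(
    data.frame(day_label = 1:9), schedule)
  if (max(base$week) > length(truth$alpha)) {
    stop("truth$alpha shorter than the number of weeks in the schedule",
         call. = FALSE)
  }
  n_days <- nrow(base)
  G <- stats::rnorm(n_animals, 0, sqrt(truth$sigma_A2))
  out <- base[rep(seq_len(n_days), n_animals), ]
  out$animal_id <- rep(sprintf("a%02d", seq_len(n_animals)), each = n_days)
  mu <- truth$alpha[out$week] + truth$beta * out$days_since_change
  out$value <- mu + G[rep(seq_len(n_animals), each = n_days)] +
    stats::rnorm(nrow(out), 0, sqrt(truth$sigma2))
  rownames(out) <- NULL
  out
}

#' Simulation-based power for the fixed-effect tests
#'
#' Estimates the power of the likelihood-ratio test of a fixed effect
#' (`"week"` or `"days"`) by Monte Carlo: datasets are simulated from the
#' longitudinal model at the supplied truth and design, the test is run on
#' each, and the rejection fraction at level `alpha` is returned with its
#' binomial standard error. With the effect set to zero this estimates the
#' type-I error, which should sit near `alpha`.
#'
#' @param truth As in [simulate_mixed()] (a `mixed_model_result` also
#'   works).
#' @param n_animals Number of animals in the simulated design.
#' @param n_sims Number of Monte Carlo replicates (>= 100).
#' @param alpha Test level, default 0.05.
#' @param effect `"days"` (default) or `"week"`.
#' @param schedule Study design, default [sampling_schedule()].
#' @param seed Optional RNG seed for reproducibility.
#' @return List of class `power_estimate`: `power`, `se`, `n_sims`,
#'   `n_animals`, `effect`, `alpha`.
#' @export
power_simulation <- function(truth, n_animals = 8L, n_sims = 500L,
                             alpha = 0.05, effect = c("days", "week"),
                             schedule = sampling_schedule(), seed = NULL) {
  effect <- match.arg(effect)
  if (n_sims < 100L) stop("n_sims must be >= 100", call. = FALSE)
  if (inherits(truth, "mixed_model_result")) {
    truth <- list(alpha = unname(truth$alpha), beta = truth$beta,
                  sigma_A2 = truth$sigma_A2, sigma2 = truth$sigma2)
  }
  if (truth$sigma_A2 < 0 || truth$sigma2 <= 0) {
    stop("invalid truth: need sigma_A2 >= 0, sigma2 > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  reject <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    tab <- simulate_mixed(truth, n_animals, schedule)
    tst <- lrt_fixed_effects_gaussian(tab, effect)
    reject[s] <- tst$p_value < alpha
  }
  pow <- mean(reject)
  structure(
    list(power = pow,
         se = sqrt(pow * (1 - pow) / n_sims),
         n_sims = n_sims, n_animals = n_animals,
         effect = effect, alpha = alpha),
    class = "power_estimate"
  )
}

# LRT on an identity-scale simulated table (no power transform): shared by
# power_simulation to avoid re-profiling lambda on data generated Gaussian.
lrt_fixed_effects_gaussian <- function(tab, effect) {
  tab$v <- tab$value
  lrt_fixed_effects(tab, "v", lambda = 1, effects = effect)
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Power of the %s-effect LRT at alpha = %.2f: %.3f (SE %.3f), %d animals, %d sims\n",
              x$effect, x$alpha, x$power, x$se, x$n_animals, x$n_sims))
  invisible(x)
}
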