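#' Parameters for the synthetic cohort generator
#'
#' Bundles the generating truth for [generate_cohort()]. The generative
#' skeleton mirrors the analysis assumptions: per-animal Gaussian random
#' intercepts and week means act on the power-transformed scale of each
#' descriptor (exponents `lambda_v0`, `lambda_A`), values are
#' back-transformed, combined with an independently drawn recovery
#' percentage into a concave-down quadratic \eqn{[H^+]} curve via
#' [inverse_reparametrise()], sampled at the post-prandial time points, and
#' perturbed with multiplicative lognormal measurement noise (additive on
#' the pH scale, reflecting the logarithmic nature of the measurement).
#'
#' Defaults emulate a cohort of 8 animals on the canonical 9-day challenge
#' design, with week-mean patterns (baseline dip after the diet change and
#' a rise in the final week), transform exponents, and variance components
#' chosen so that the between-animal variance share is about 0.56 for v0
#' and 0.17 for A, and simulated pH stays in a physiologically plausible
#' band (about 5-7.5).
#'
#' @param n_animals Number of animals, default 8.
#' @param schedule A [sampling_schedule()].
#' @param alpha_v0,alpha_A Week means of the transformed descriptors
#'   (length 5).
#' @param lambda_v0,lambda_A Generating power-transform exponents
#'   (defaults 0.20 and 0.28).
#' @param beta_v0,beta_A Day slopes active in the first post-change week
#'   (transformed units per day), default 0.
#' @param sigma_A2_v0,sigma2_v0 Between-animal and residual variances of
#'   transformed v0.
#' @param sigma_A2_A,sigma2_A Same for transformed A.
#' @param R_mean,R_sd Mean and SD of the recovery percentage, drawn from a
#'   normal truncated to (5, 100] and further restricted to draws whose
#'   curve is feasible (see `vlast_floor`).
#' @param vlast_floor Minimum end-of-window concentration as a fraction of
#'   the baseline `v0`, default 0.5 (about 0.3 pH units above baseline):
#'   post-prandial recovery is near-complete physiologically, and recovery
#'   draws violating the floor are resampled.
#' @param meas_noise_cv Coefficient of variation of the multiplicative
#'   measurement noise on \eqn{[H^+]}, default 0.03.
#' @param dropout Fraction of records dropped uniformly at random,
#'   default 0.
#' @param times Post-prandial sampling times (hours), default
#'   `c(0, 1, 2, 4, 6)`.
#' @param seed Integer RNG seed used by [generate_cohort()], or `NULL`.
#' @return List of class `generator_params`.
#' @export
generator_params <- function(n_animals = 8L,
                             schedule = sampling_schedule(),
                             alpha_v0 = c(0.052, 0.046, 0.049, 0.047, 0.054),
                             alpha_A = c(0.016, 0.017, 0.018, 0.020, 0.023),
                             lambda_v0 = 0.20,
                             lambda_A = 0.28,
                             beta_v0 = 0,
                             beta_A = 0,
                             sigma2_v0 = 4e-6,
                             sigma_A2_v0 = 4e-6 * 0.56 / 0.44,
                             sigma2_A = 6.25e-6,
                             sigma_A2_A = 6.25e-6 * 0.17 / 0.83,
                             R_mean = 85,
                             R_sd = 10,
                             vlast_floor = 0.5,
                             meas_noise_cv = 0.03,
                             dropout = 0,
                             times = c(0, 1, 2, 4, 6),
                             seed = NULL) {
  p <- list(n_animals = as.integer(n_animals), schedule = schedule,
            alpha_v0 = alpha_v0, alpha_A = alpha_A,
            lambda_v0 = lambda_v0, lambda_A = lambda_A,
            beta_v0 = beta_v0, beta_A = beta_A,
            sigma2_v0 = sigma2_v0, sigma_A2_v0 = sigma_A2_v0,
            sigma2_A = sigma2_A, sigma_A2_A = sigma_A2_A,
            R_mean = R_mean, R_sd = R_sd, vlast_floor = vlast_floor,
            meas_noise_cv = meas_noise_cv, dropout = dropout,
            times = times, seed = seed)
  if (p$n_animals < 2L) stop("need at least 2 animals", call. = FALSE)
  if (any(c(p$sigma2_v0, p$sigma_A2_v0, p$sigma2_A, p$sigma_A2_A) < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (p$meas_noise_cv < 0) stop("meas_noise_cv must be >= 0", call. = FALSE)
  if (p$dropout < 0 || p$dropout >= 1) {
    stop("dropout must be in [0, 1)", call. = FALSE)
  }
  structure(p, class = "generator_params")
}

#' Default generator parameters
#'
#' @return The default [generator_params()] set.
#' @export
default_params <- function() generator_params()

# Exact truncated-normal draw by inverse CDF; robust even when the
# feasible interval sits far in the tail.
rtrunc_norm <- function(mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi <= plo) return((lower + upper) / 2)
  x <- stats::qnorm(stats::runif(1, plo, phi), mean, sd)
  min(max(x, lower + (upper - lower) * 1e-12), upper)
}

#' Generate a synthetic measurement cohort with known ground truth
#'
#' Simulates a full diet-challenge cohort: per animal-day descriptor truth
#' from the longitudinal model on the transformed scale, back-transformed
#' and converted to a quadratic \eqn{[H^+]} curve, sampled at the
#' post-prandial time points with multiplicative lognormal noise. Recovery
#' percentages producing an infeasible curve (non-positive concentration
#' somewhere in the window) are resampled up to a retry cap.
#'
#' Deterministic given `params$seed`.
#'
#' @param params A [generator_params()] object.
#' @return List of class `synthetic_cohort` with elements `measurements`
#'   (a validated measurement table: `animal_id`, `day_label`,
#'   `day_offset`, `time_h`, `h_conc`, `ph`) and `truth` (one row per
#'   animal-day with the generating `v0`, `A`, `R`, quadratic
#'   coefficients, random intercepts and transformed-scale values), plus
#'   `params`.
#' @examples
#' cohort <- generate_cohort(generator_params(seed = 1))
#' nrow(cohort$measurements)  # 360
#' @export
generate_cohort <- function(params = default_params()) {
  stopifnot(inherits(params, "generator_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  sch <- params$schedule
  base <- annotate_schedule(data.frame(day_label = 1:9), sch)
  animals <- sprintf("g%02d", seq_len(params$n_animals))
  G_v0 <- stats::rnorm(params$n_animals, 0, sqrt(params$sigma_A2_v0))
  G_A <- stats::rnorm(params$n_animals, 0, sqrt(params$sigma_A2_A))

  truth_rows <- list()
  meas_rows <- list()
  inv_lambda_v0 <- 1 / params$lambda_v0
  inv_lambda_A <- 1 / params$lambda_A
  sdlog <- sqrt(log(1 + params$meas_noise_cv^2))

  for (i in seq_len(params$n_animals)) {
    for (k in seq_len(nrow(base))) {
      wk <- base$week[k]
      dsc <- base$days_since_change[k]
      w_v0 <- params$alpha_v0[wk] + G_v0[i] + params$beta_v0 * dsc +
        stats::rnorm(1, 0, sqrt(params$sigma2_v0))
      w_A <- params$alpha_A[wk] + G_A[i] + params$beta_A * dsc +
        stats::rnorm(1, 0, sqrt(params$sigma2_A))
      if (w_v0 <= 0 || w_A <= 0) {
        stop("transformed descriptor drawn non-positive; ",
             "reduce variances or raise week means", call. = FALSE)
      }
      v0 <- w_v0^inv_lambda_v0
      A <- w_A^inv_lambda_A
      # the recovery floor bounds R from below: v_last > floor * v0 iff
      # R > 100 A / (A + (1 - floor) v0); draw from the feasible interval
      r_min <- max(5, 100 * A / (A + (1 - params$vlast_floor) * v0))
      if (r_min >= 100) {
        stop("no feasible recovery percentage for v0 = ", signif(v0, 3),
             ", A = ", signif(A, 3), call. = FALSE)
      }
      R <- rtrunc_norm(params$R_mean, params$R_sd, r_min, 100)
      coefs <- inverse_reparametrise(v0, A, R)
      h_true <- quad_eval(coefs$a, coefs$b, coefs$c, params$times)
      noise <- if (params$meas_noise_cv > 0) {
        exp(stats::rnorm(length(h_true), -sdlog^2 / 2, sdlog))
      } else rep(1, length(h_true))
      h_obs <- h_true * noise
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        animal_id = animals[i], day_label = base$day_label[k],
        day_offset = base$day_offset[k], week = wk,
        days_since_change = dsc,
        v0 = v0, A = A, R = R,
        a = coefs$a, b = coefs$b, c = coefs$c,
        G_v0 = G_v0[i], G_A = G_A[i],
        w_v0 = w_v0, w_A = w_A,
        stringsAsFactors = FALSE)
      meas_rows[[length(meas_rows) + 1L]] <- data.frame(
        animal_id = animals[i], day_label = base$day_label[k],
        day_offset = base$day_offset[k],
        time_h = params$times, h_conc = h_obs,
        ph = -log10(h_obs), stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  meas <- do.call(rbind, meas_rows)
  if (params$dropout > 0) {
    keep <- stats::runif(nrow(meas)) >= params$dropout
    meas <- meas[keep, ]
  }
  rownames(truth) <- rownames(meas) <- NULL
  structure(
    list(measurements = validate_measurements(meas),
         truth = truth, params = params),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals, %d records, pH range %.2f-%.2f\n",
              x$params$n_animals, nrow(x$measurements),
              min(x$measurements$ph), max(x$measurements$ph)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the measurement CSV (same dialect [read_measurements()] consumes),
#' the ground-truth CSV, and the generator parameters as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(measurements = file.path(dir, "measurements.csv"),
             truth = file.path(dir, "ground_truth.csv"),
             params = file.path(dir, "generator_params.json"))
  utils::write.csv(cohort$measurements, files["measurements"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth, files["truth"],
                   row.names = FALSE, quote = FALSE)
  p <- cohort$params
  p$schedule <- unclass(p$schedule)
  jsonlite::write_json(unclass(p), files["params"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(files)
}
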