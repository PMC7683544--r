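#' Fit a quadratic to one post-prandial curve
#'
#' Fits \eqn{y(t) = a t^2 + b t + c} by ordinary least squares to the
#' sampled post-prandial values of one animal-day. The model is linear in
#' its parameters, so OLS gives the global least-squares optimum directly;
#' the re-parametrised form used downstream (baseline, amplitude, recovery)
#' is an exact transformation of the same optimum.
#'
#' @param times Numeric vector of sampling times (hours post feed delivery).
#' @param y Numeric vector of responses at `times` (\eqn{[H^+]} in mol/L, or
#'   pH when fitting on the pH scale).
#' @return An object of class `quadratic_fit`: list with `a`, `b`, `c`
#'   (coefficients), `rss`, `n_points`, `converged`.
#' @examples
#' f <- fit_quadratic(c(0, 1, 2, 4, 6), c(10, 15, 18, 18, 10))
#' predict(f, 3)
#' @export
fit_quadratic <- function(times, y) {
  stopifnot(is.numeric(times), is.numeric(y))
  if (length(times) != length(y)) {
    stop("`times` and `y` must have equal length", call. = FALSE)
  }
  keep <- is.finite(times) & is.finite(y)
  times <- times[keep]
  y <- y[keep]
  if (length(unique(times)) < 3L) {
    stop("need at least 3 distinct time points to fit a quadratic",
         call. = FALSE)
  }
  X <- cbind(1, times, times^2)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < 3L) stop("singular design in quadratic fit", call. = FALSE)
  cf <- unname(fit$coefficients)
  structure(
    list(a = cf[3], b = cf[2], c = cf[1],
         rss = sum(fit$residuals^2),
         n_points = length(y),
         converged = TRUE),
    class = "quadratic_fit"
  )
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("Quadratic fit: a = %.4g, b = %.4g, c = %.4g (n = %d, rss = %.3g)\n",
              x$a, x$b, x$c, x$n_points, x$rss))
  invisible(x)
}

#' Evaluate a fitted quadratic
#'
#' @param object A `quadratic_fit`.
#' @param newdata Numeric vector of times.
#' @param ... Unused.
#' @return Fitted values at `newdata`.
#' @export
predict.quadratic_fit <- function(object, newdata, ...) {
  object$a * newdata^2 + object$b * newdata + object$c
}

quad_eval <- function(a, b, c, t) a * t^2 + b * t + c

# Location of the extremum of a*t^2+b*t+c over the closed window:
# interior vertex when it has the right curvature sign and lies inside,
# otherwise the better endpoint.
quad_arg_extremum <- function(a, b, window, direction = c("max", "min")) {
  direction <- match.arg(direction)
  cand <- window
  vertex_ok <- if (direction == "max") a < 0 else a > 0
  if (a != 0 && vertex_ok) {
    v <- -b / (2 * a)
    if (v > window[1] && v < window[2]) cand <- c(cand, v)
  }
  vals <- quad_eval(a, b, 0, cand)  # c cancels in comparisons
  if (direction == "max") cand[which.max(vals)] else cand[which.min(vals)]
}

#' Re-parametrise a quadratic fit into synthetic variables
#'
#' Converts the raw coefficients (a, b, c) of a post-prandial curve into
#' biologically meaningful descriptors over the sampling window:
#' \describe{
#'   \item{v0}{model-estimated value at the start of the window — the
#'     pre-feeding baseline acid status;}
#'   \item{A}{amplitude — the extent of the post-prandial deviation from v0,
#'     i.e. the within-window extremum minus v0 on the \eqn{[H^+]} scale
#'     (v0 minus the minimum on the pH scale, where the deviation points
#'     down); always \eqn{\ge 0};}
#'   \item{R}{recovery (percent) at the end of the window,
#'     \eqn{R = (ext - v_0)/(ext - v_{last}) \times 100} where `ext` is the
#'     within-window extremum; 100 means full return to baseline;}
#'   \item{v_last}{model-estimated value at the end of the window (6 h);}
#'   \item{t_peak}{location of the extremum (interior vertex when the
#'     curvature allows, otherwise the more extreme endpoint).}
#' }
#'
#' `R` is undefined (NA, with a warning) when the curve ends at its
#' extremum (`ext == v_last`, zero denominator) or never deviates
#' (`A == 0`). An alternative convention
#' \eqn{R = (ext - v_{last})/(ext - v_0) \times 100}, which stays bounded as
#' \eqn{v_{last} \to ext}, is available as
#' `recovery_definition = "complement"`.
#'
#' @param fit A `quadratic_fit`.
#' @param window Numeric length-2, the closed sampling window in hours;
#'   default `c(0, 6)`.
#' @param direction `"max"` when the post-prandial deviation is upward
#'   (\eqn{[H^+]} scale, the default) or `"min"` when it is downward (pH).
#' @param recovery_definition `"table1"` (default) or `"complement"`, see
#'   Details.
#' @return A list of class `synthetic_variables` with fields `v0`, `A`,
#'   `R`, `v_last`, `t_peak`, `window`, `direction`,
#'   `recovery_definition`.
#' @examples
#' t5 <- c(0, 1, 2, 4, 6)
#' reparametrise(fit_quadratic(t5, -t5^2 + 6 * t5 + 10))
#' @export
reparametrise <- function(fit, window = c(0, 6),
                          direction = c("max", "min"),
                          recovery_definition = c("table1", "complement")) {
  direction <- match.arg(direction)
  recovery_definition <- match.arg(recovery_definition)
  stopifnot(inherits(fit, "quadratic_fit"),
            length(window) == 2, window[1] < window[2])
  a <- fit$a; b <- fit$b; cc <- fit$c
  v0 <- quad_eval(a, b, cc, window[1])
  v_last <- quad_eval(a, b, cc, window[2])
  t_peak <- quad_arg_extremum(a, b, window, direction)
  ext <- quad_eval(a, b, cc, t_peak)
  A <- abs(ext - v0)
  if (A == 0 || ext == v_last) {
    warning("recovery R undefined (no deviation or curve ends at extremum)",
            call. = FALSE)
    R <- NA_real_
  } else if (recovery_definition == "table1") {
    R <- (ext - v0) / (ext - v_last) * 100
  } else {
    R <- (ext - v_last) / (ext - v0) * 100
  }
  structure(
    list(v0 = v0, A = A, R = R, v_last = v_last, t_peak = t_peak,
         window = window, direction = direction,
         recovery_definition = recovery_definition),
    class = "synthetic_variables"
  )
}

#' @export
print.synthetic_variables <- function(x, ...) {
  cat(sprintf("v0 = %.4g, A = %.4g, R = %.4g, v_last = %.4g (t_peak = %.3g h)\n",
              x$v0, x$A, x$R, x$v_last, x$t_peak))
  invisible(x)
}

#' Recover quadratic coefficients from synthetic variables
#'
#' Inverse of [reparametrise()] for the concave-down \eqn{[H^+]} case with
#' an interior peak: given baseline `v0`, amplitude `A > 0` and recovery
#' `R > 0` (table-1 definition) over a window of length \eqn{T}, returns the
#' unique coefficients (a, b, c) with \eqn{a < 0}, peak inside the window
#' and \eqn{b > 0}.
#'
#' Derivation (window starting at 0): \eqn{c = v_0}; the vertex height gives
#' \eqn{A = -b^2/(4a)}; the recovery definition fixes
#' \eqn{v_{last} - v_0 = K = A(1 - 100/R)}, and substituting
#' \eqn{a = -b^2/(4A)} into \eqn{aT^2 + bT = K} yields
#' \eqn{b = 2(A + A\sqrt{100/R})/T}, the root with a peak strictly inside
#' the window. A general window start is handled by shifting coordinates.
#'
#' @param v0,A,R Numeric vectors (recycled): baseline, amplitude (> 0) and
#'   recovery percentage (> 0).
#' @param window Numeric length-2 sampling window, default `c(0, 6)`.
#' @return A data frame with columns `a`, `b`, `c`.
#' @examples
#' inverse_reparametrise(10, 9, 100)   # a = -1, b = 6, c = 10
#' @export
inverse_reparametrise <- function(v0, A, R, window = c(0, 6)) {
  n <- max(length(v0), length(A), length(R))
  v0 <- rep_len(v0, n); A <- rep_len(A, n); R <- rep_len(R, n)
  if (any(!is.finite(v0)) || any(!is.finite(A)) || any(!is.finite(R)) ||
      any(A <= 0) || any(R <= 0) || any(v0 <= 0)) {
    stop("infeasible parameters: need finite v0 > 0, A > 0, R > 0",
         call. = FALSE)
  }
  T_len <- window[2] - window[1]
  stopifnot(T_len > 0)
  # coefficients in the shifted coordinate u = t - t0
  b_u <- 2 * (A + A * sqrt(100 / R)) / T_len
  a <- -b_u^2 / (4 * A)
  c_u <- v0
  t0 <- window[1]
  # unshift: f(t) = a (t - t0)^2 + b_u (t - t0) + c_u
  b <- b_u - 2 * a * t0
  c_out <- a * t0^2 - b_u * t0 + c_u
  data.frame(a = a, b = b, c = c_out)
}

# Lebesgue measure of {t in window : a t^2 + b t + c > thr}, analytic from
# the roots of the shifted quadratic.
interval_above_length <- function(a, b, c, thr, window) {
  lo <- window[1]; hi <- window[2]
  q <- c - thr
  clip_len <- function(l, h) max(0, min(h, hi) - max(l, lo))
  if (a == 0) {
    if (b == 0) return(if (q > 0) hi - lo else 0)
    r <- -q / b
    return(if (b > 0) clip_len(r, Inf) else clip_len(-Inf, r))
  }
  disc <- b^2 - 4 * a * q
  if (disc <= 0) {
    # no sign change: curve entirely on one side (touch point has measure 0)
    return(if (a > 0) hi - lo else 0)
  }
  r1 <- (-b - sqrt(disc)) / (2 * a)
  r2 <- (-b + sqrt(disc)) / (2 * a)
  lo_r <- min(r1, r2); hi_r <- max(r1, r2)
  if (a < 0) clip_len(lo_r, hi_r) else clip_len(-Inf, lo_r) + clip_len(hi_r, Inf)
}

#' Threshold-dependent acidosis descriptors
#'
#' Computes the two descriptors that depend on an acidosis threshold
#' \eqn{\theta}: `dur`, the time (hours) the fitted curve spends on the
#' acidotic side of the threshold within the sampling window, and `amp_ac`,
#' the peak exceedance of the threshold (negative when the curve never
#' reaches it). The threshold is specified in pH units (literature range
#' about 5.5-6.0; default 5.5) and converted internally to
#' \eqn{\theta_{[H^+]} = 10^{-\theta_{pH}}}.
#'
#' On the \eqn{[H^+]} scale acidosis means exceeding \eqn{\theta_{[H^+]}}
#' (`dur` is the measure of \{t : fitted \eqn{[H^+] > \theta}\}, computed
#' analytically from the quadratic's roots); on the pH scale it means
#' falling below \eqn{\theta_{pH}}.
#'
#' @param fit A `quadratic_fit` (on the scale indicated by `scale`).
#' @param theta_ph Acidosis threshold in pH units, default 5.5.
#' @param window Sampling window in hours, default `c(0, 6)`.
#' @param scale `"h_conc"` (default) or `"ph"`, the scale `fit` was made on.
#' @return List of class `threshold_variables`: `theta_ph`, `theta_h`,
#'   `dur` (hours), `amp_ac` (threshold-exceedance amplitude).
#' @export
derive_threshold_vars <- function(fit, theta_ph = 5.5, window = c(0, 6),
                                  scale = c("h_conc", "ph")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "quadratic_fit"), theta_ph > 0)
  theta_h <- 10^(-theta_ph)
  a <- fit$a; b <- fit$b; cc <- fit$c
  if (scale == "h_conc") {
    thr <- theta_h
    dur <- interval_above_length(a, b, cc, thr, window)
    t_ext <- quad_arg_extremum(a, b, window, "max")
    amp_ac <- quad_eval(a, b, cc, t_ext) - thr
  } else {
    # acidosis = pH below threshold; flip the curve to reuse the measure
    dur <- interval_above_length(-a, -b, -cc, -theta_ph, window)
    t_ext <- quad_arg_extremum(a, b, window, "min")
    amp_ac <- theta_ph - quad_eval(a, b, cc, t_ext)
  }
  structure(
    list(theta_ph = theta_ph, theta_h = theta_h, dur = dur, amp_ac = amp_ac),
    class = "threshold_variables"
  )
}

#' Fit all animal-day post-prandial curves and tabulate descriptors
#'
#' Applies [fit_quadratic()], [reparametrise()] and
#' [derive_threshold_vars()] to every animal-day of an annotated measurement
#' table, producing one row of synthetic variables per post-prandial curve.
#' On the default \eqn{[H^+]} scale the quadratic is fitted to hydrogen-ion
#' concentrations; with `scale = "ph"` it is fitted to pH directly and the
#' amplitude is the downward deviation `v0 - min`.
#'
#' Animal-days with fewer than `min_points` distinct time points are
#' excluded with a warning.
#'
#' @param records Annotated measurement table (see [annotate_schedule()];
#'   tables lacking the schedule columns are annotated with the default
#'   schedule).
#' @param scale `"h_conc"` (default) or `"ph"`.
#' @param theta_ph Acidosis threshold in pH units, default 5.5.
#' @param window Sampling window, default `c(0, 6)` hours.
#' @param min_points Minimum distinct time points per curve, default 4.
#' @param recovery_definition Passed to [reparametrise()].
#' @return A data frame, one row per animal-day, with columns `animal_id`,
#'   `day_label`, `day_offset`, `week`, `days_since_change`, `a`, `b`, `c`,
#'   `rss`, `n_points`, `v0`, `A`, `R`, `v_last`, `t_peak`, `dur`,
#'   `amp_ac`. Attributes `scale`, `theta_ph` and `recovery_definition`
#'   record the analysis configuration.
#' @export
fit_all <- function(records, scale = c("h_conc", "ph"), theta_ph = 5.5,
                    window = c(0, 6), min_points = 4L,
                    recovery_definition = c("table1", "complement")) {
  scale <- match.arg(scale)
  recovery_definition <- match.arg(recovery_definition)
  if (!all(c("week", "day_offset", "days_since_change") %in% names(records))) {
    records <- annotate_schedule(records)
  }
  direction <- if (scale == "h_conc") "max" else "min"
  value_col <- if (scale == "h_conc") "h_conc" else "ph"
  groups <- split(records,
                  list(records$animal_id, records$day_label), drop = TRUE)
  rows <- vector("list", length(groups))
  dropped <- character(0)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (length(unique(g$time_h)) < min_points) {
      dropped <- c(dropped,
                   paste0(g$animal_id[1], "/d", g$day_label[1]))
      next
    }
    fit <- fit_quadratic(g$time_h, g[[value_col]])
    sv <- suppressWarnings(
      reparametrise(fit, window, direction, recovery_definition))
    tv <- derive_threshold_vars(fit, theta_ph, window, scale)
    rows[[i]] <- data.frame(
      animal_id = g$animal_id[1],
      day_label = g$day_label[1],
      day_offset = g$day_offset[1],
      week = g$week[1],
      days_since_change = g$days_since_change[1],
      a = fit$a, b = fit$b, c = fit$c, rss = fit$rss,
      n_points = fit$n_points,
      v0 = sv$v0, A = sv$A, R = sv$R, v_last = sv$v_last,
      t_peak = sv$t_peak, dur = tv$dur, amp_ac = tv$amp_ac,
      stringsAsFactors = FALSE
    )
  }
  if (length(dropped)) {
    warning("excluded animal-days with < ", min_points, " time points: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$animal_id, out$day_label), ]
  rownames(out) <- NULL
  attr(out, "scale") <- scale
  attr(out, "theta_ph") <- theta_ph
  attr(out, "recovery_definition") <- recovery_definition
  out
}

#' Spearman rank-correlation screen among descriptors
#'
#' Pairwise Spearman correlations (with two-sided p-values) among candidate
#' post-prandial descriptors; the synthetic variables are generally
#' non-Gaussian, so a rank correlation is used for the screening step.
#'
#' @param var_table Descriptor table, e.g. from [fit_all()].
#' @param variables Character vector of column names to correlate; default
#'   the standard descriptor set present in the table.
#' @return List of class `spearman_matrix` with symmetric matrices `rho`,
#'   `p_value` and `n` (pairwise complete sample sizes). Constant columns
#'   give NA correlations (flagged with a warning).
#' @export
spearman_matrix <- function(var_table,
                            variables = intersect(
                              c("a", "b", "c", "v0", "A", "R",
                                "v_last", "dur", "amp_ac"),
                              names(var_table))) {
  stopifnot(length(variables) >= 2,
            all(variables %in% names(var_table)))
  k <- length(variables)
  rho <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  pv <- rho
  nn <- matrix(NA_integer_, k, k, dimnames = list(variables, variables))
  warned <- FALSE
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    pv[i, i] <- 0
    nn[i, i] <- sum(is.finite(var_table[[variables[i]]]))
    for (j in seq_len(i - 1L)) {
      x <- var_table[[variables[i]]]
      y <- var_table[[variables[j]]]
      ok <- is.finite(x) & is.finite(y)
      nn[i, j] <- nn[j, i] <- sum(ok)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warned <- TRUE
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  if (warned) {
    warning("some pairs had a constant column or < 3 complete rows; ",
            "their correlations are NA", call. = FALSE)
  }
  structure(list(rho = rho, p_value = pv, n = nn),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("Spearman rank correlations:\n")
  print(round(x$rho, digits))
  invisible(x)
}
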