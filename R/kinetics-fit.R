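#' Control settings for kinetic fitting
#'
#' Tunable knobs of the window-scan slope estimator. Defaults follow the
#' package's reference analysis; all are surfaced here rather than hard-coded.
#'
#' @param rel_se_max Maximum relative standard error of the slope for a fit to
#'   be deemed adequate (default 0.5).
#' @param t_off_early_margin Minutes before the first time point that `t_off`
#'   may fall for an adequate fit (default 30).
#' @param max_eval Maximum objective evaluations for the optimizer.
#' @param ftol Convergence tolerance on the objective.
#' @param sl_floor Lower initialisation floor for the slope on flat or
#'   degenerate curves, OD410 min^-1.
#' @return A list of class `kinetics_control`.
#' @export
kinetics_control <- function(rel_se_max = 0.5, t_off_early_margin = 30,
                             max_eval = 2000, ftol = 1e-10, sl_floor = 1e-8) {
  stopifnot(rel_se_max > 0, t_off_early_margin >= 0, max_eval > 0, ftol > 0)
  structure(list(rel_se_max = rel_se_max,
                 t_off_early_margin = t_off_early_margin,
                 max_eval = max_eval, ftol = ftol, sl_floor = sl_floor),
            class = "kinetics_control")
}

#' Initial parameter guess for a fitting window
#'
#' Data-driven optimizer initialisation over points `0..end_index` of a curve:
#' the slope starts at the ordinary least-squares slope of the steepest run of
#' three consecutive points (floored at a small positive value for flat
#' curves); the plateau starts at 1.5x the window maximum (floored at 1.1x);
#' the offset starts at the first time the signal exceeds the baseline (first
#' three points) by three baseline standard deviations, else at the first time
#' point; the smoothing width starts at the sampling interval.
#'
#' @param curve A [kinetic_curve()].
#' @param end_index 0-based index of the last point in the window (>= 5).
#' @param control A [kinetics_control()].
#' @return A [monod_params()] initial guess.
#' @export
initial_guess <- function(curve, end_index, control = kinetics_control()) {
  stopifnot(inherits(curve, "kinetic_curve"), end_index >= 5,
            end_index <= length(curve$times) - 1)
  idx <- seq_len(end_index + 1)
  tt <- curve$times[idx]
  yy <- curve$od410[idx]

  # steepest OLS slope over runs of 3 consecutive points
  run_slopes <- vapply(seq_len(length(tt) - 2), function(i) {
    ti <- tt[i:(i + 2)]; yi <- yy[i:(i + 2)]
    sum((ti - mean(ti)) * (yi - mean(yi))) / sum((ti - mean(ti))^2)
  }, numeric(1))
  sl0 <- max(max(run_slopes, na.rm = TRUE), control$sl_floor)

  mx <- max(yy)
  m0 <- max(1.5 * mx, 1.1 * mx, 1e-3)

  base <- yy[1:3]
  thr <- mean(base) + 3 * stats::sd(base)
  above <- which(yy > thr)
  t_off0 <- if (length(above)) tt[above[1]] else tt[1]

  d0 <- stats::median(diff(tt))
  monod_params(sl = sl0, m = m0, t_off = t_off0, d = d0)
}

# Standard errors from the curvature (J^T J) of the objective at the optimum.
# Parameters the data do not constrain (negligible curvature: a smoothing
# width at its zero bound, a plateau far beyond the observed range) are
# dropped before inversion and reported as NA.
.curvature_se <- function(jtj, sigma) {
  p <- ncol(jtj)
  se <- rep(NA_real_, p)
  dg <- diag(jtj)
  keep <- is.finite(dg) & dg > max(dg, na.rm = TRUE) * 1e-12
  if (!any(keep)) return(se)
  cv <- tryCatch(solve(jtj[keep, keep, drop = FALSE]) * sigma^2,
                 error = function(e) NULL)
  if (is.null(cv)) return(se)
  vr <- diag(cv)
  if (any(vr < 0)) return(se)
  se[keep] <- sqrt(vr)
  se
}

.run_nlslm <- function(tt, yy, start, lower, upper, fixed_d, control) {
  res_fn <- if (is.null(fixed_d)) {
    function(p) yy - eval_model(c(sl = p[1], m = p[2], t_off = p[3], d = p[4]), tt)
  } else {
    function(p) yy - eval_model(c(sl = p[1], m = p[2], t_off = p[3], d = fixed_d), tt)
  }
  suppressWarnings(tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = res_fn,
                       control = minpack.lm::nls.lm.control(
                         maxfev = control$max_eval, maxiter = 1000,
                         ftol = control$ftol)),
    error = function(e) NULL))
}

#' Fit the kinetic model to one data window
#'
#' Bounded Levenberg-Marquardt least-squares fit of [eval_model()] to points
#' `0..end_index` of a curve. With `fixed_d` given, the smoothing width is held
#' constant and three parameters are free. The fit error is the residual
#' standard error `sqrt(SSE / (n - n_free))`; parameter standard errors come
#' from the curvature of the objective at the optimum. Two deterministic
#' starts are tried (the data-driven [initial_guess()], and the same start
#' with the plateau scaled up 100x into the quasi-linear regime, where curves
#' that stay far below saturation often fit best) and the lower-SSE solution
#' is kept.
#'
#' A fit is deemed *adequate* when it converged, `sl > 0`, `m > 0`, the
#' relative standard error of `sl` is at most `control$rel_se_max`, and
#' `t_off` lies within `[t_0 - margin, t_k]`.
#'
#' @inheritParams initial_guess
#' @param fixed_d Optional fixed smoothing width (minutes).
#' @param control A [kinetics_control()].
#' @return A list of class `window_fit` with elements `end_index`, `params`,
#'   `param_se`, `fit_error`, `converged`, `adequate`, `d_was_fixed`.
#' @export
fit_window <- function(curve, end_index, fixed_d = NULL,
                       control = kinetics_control()) {
  stopifnot(inherits(curve, "kinetic_curve"))
  n_free <- if (is.null(fixed_d)) 4L else 3L
  if (end_index < 5 || end_index > length(curve$times) - 1)
    stop("`end_index` must lie in [5, N-1]")
  if (end_index + 1 <= n_free)
    stop("window has no residual degrees of freedom")
  if (!is.null(fixed_d) && fixed_d < 0) stop("`fixed_d` must be non-negative")

  idx <- seq_len(end_index + 1)
  tt <- curve$times[idx]
  yy <- curve$od410[idx]
  init <- initial_guess(curve, end_index, control)

  if (is.null(fixed_d)) {
    lower <- c(1e-12, 1e-12, -Inf, 0); upper <- rep(Inf, 4)
    starts <- list(unname(unclass(init)[c("sl", "m", "t_off", "d")]))
    starts[[2]] <- starts[[1]] * c(1, 100, 1, 1)
  } else {
    lower <- c(1e-12, 1e-12, -Inf); upper <- rep(Inf, 3)
    starts <- list(unname(unclass(init)[c("sl", "m", "t_off")]))
    starts[[2]] <- starts[[1]] * c(1, 100, 1)
  }

  fits <- lapply(starts, function(s)
    .run_nlslm(tt, yy, s, lower, upper, fixed_d, control))
  fits <- fits[!vapply(fits, is.null, logical(1))]

  nm <- if (is.null(fixed_d)) c("sl", "m", "t_off", "d") else c("sl", "m", "t_off")
  fail <- list(end_index = as.integer(end_index),
               params = NULL,
               param_se = stats::setNames(rep(NA_real_, length(nm)), nm),
               fit_error = NA_real_, converged = FALSE, adequate = FALSE,
               d_was_fixed = !is.null(fixed_d))
  class(fail) <- "window_fit"
  if (!length(fits)) return(fail)

  best <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]
  cf <- stats::coef(best)
  params <- c(sl = unname(cf[1]), m = unname(cf[2]), t_off = unname(cf[3]),
              d = if (is.null(fixed_d)) unname(cf[4]) else fixed_d)
  dfree <- length(yy) - n_free
  fit_error <- sqrt(best$deviance / dfree)
  se <- .curvature_se(best$hessian, fit_error)
  names(se) <- nm
  converged <- best$info %in% 1:3

  rel_se <- se[["sl"]] / params[["sl"]]
  adequate <- isTRUE(
    converged && params[["sl"]] > 0 && params[["m"]] > 0 &&
    is.finite(rel_se) && rel_se <= control$rel_se_max &&
    params[["t_off"]] >= tt[1] - control$t_off_early_margin &&
    params[["t_off"]] <= tt[length(tt)])

  structure(list(end_index = as.integer(end_index),
                 params = structure(params, class = "monod_params"),
                 param_se = se, fit_error = fit_error,
                 converged = converged, adequate = adequate,
                 d_was_fixed = !is.null(fixed_d)),
            class = "window_fit")
}

#' Scan fitting windows and select the best slope fit
#'
#' Fits the kinetic model to every window `t_0..t_k` for `k` from 5 to `N-1`,
#' locates local minima of the fit error along `k` (non-strict: a window
#' qualifies when its fit error is at most that of both neighbours; endpoints
#' qualify via their single neighbour), and among converged, adequate,
#' local-minimum fits selects the one whose slope has the smallest standard
#' error (ties resolved toward the larger window).
#'
#' @inheritParams fit_window
#' @return A list of class `fit_scan`: `window_fits` (ordered by `end_index`),
#'   `local_min_indices` (end_index values), `selected` (a `window_fit` or
#'   `NULL`), plus the curve identity fields.
#' @export
scan_and_select <- function(curve, fixed_d = NULL,
                            control = kinetics_control()) {
  stopifnot(inherits(curve, "kinetic_curve"))
  n <- length(curve$times)
  ks <- 5:(n - 1)
  fits <- lapply(ks, function(k) fit_window(curve, k, fixed_d, control))

  fe <- vapply(fits, function(f) ifelse(is.na(f$fit_error), Inf, f$fit_error),
               numeric(1))
  is_min <- vapply(seq_along(fe), function(i) {
    left_ok <- if (i > 1) fe[i] <= fe[i - 1] else TRUE
    right_ok <- if (i < length(fe)) fe[i] <= fe[i + 1] else TRUE
    isTRUE(left_ok && right_ok) && is.finite(fe[i])
  }, logical(1))

  eligible <- is_min & vapply(fits, function(f) f$converged && f$adequate,
                              logical(1))
  selected <- NULL
  if (any(eligible)) {
    se_sl <- vapply(fits, function(f) {
      s <- f$param_se[["sl"]]
      if (is.na(s)) Inf else s
    }, numeric(1))
    se_sl[!eligible] <- Inf
    # ties toward larger k: pick the last index attaining the minimum
    best_i <- max(which(se_sl == min(se_sl)))
    selected <- fits[[best_i]]
  }

  structure(list(strain_id = curve$strain_id, condition = curve$condition,
                 bio_rep = curve$bio_rep, tech_rep = curve$tech_rep,
                 window_fits = fits,
                 local_min_indices = ks[is_min],
                 selected = selected),
            class = "fit_scan")
}

#' @export
print.fit_scan <- function(x, ...) {
  sel <- if (is.null(x$selected)) "none" else
    sprintf("k=%d sl=%.4g", x$selected$end_index, x$selected$params[["sl"]])
  cat(sprintf("<fit_scan> %s/%s bio %d tech %d: %d windows, %d local minima, selected %s\n",
              x$strain_id, x$condition, x$bio_rep, x$tech_rep,
              length(x$window_fits), length(x$local_min_indices), sel))
  invisible(x)
}

# mean fitted d over adequate selected fits, preferring technical replicates
# (same biological replicate) over other biological replicates
.cohort_fixed_d <- function(cohort, bio_rep) {
  sel_ok <- Filter(function(s) !is.null(s$selected) && s$selected$adequate, cohort)
  if (!length(sel_ok)) return(NULL)
  same_bio <- Filter(function(s) identical(s$bio_rep, bio_rep), sel_ok)
  pool <- if (length(same_bio)) same_bio else sel_ok
  mean(vapply(pool, function(s) s$selected$params[["d"]], numeric(1)))
}

#' Estimate the conversion slope of one curve
#'
#' Runs the free window scan; if no adequate fit is selected, re-runs the scan
#' with the smoothing width fixed at the mean fitted `d` of the sibling
#' replicates' adequate fits (technical replicates of the same biological
#' replicate preferred over other biological replicates). Failure is encoded
#' in the `provenance` column rather than raised.
#'
#' @inheritParams fit_window
#' @param cohort List of `fit_scan` objects from sibling replicates of the
#'   same strain and condition (possibly empty).
#' @return One-row tibble: strain/condition/replicates, `slope`, `slope_se`,
#'   `fit_error`, `end_index`, `provenance` in `{"free_fit","d_fixed","failed"}`.
#' @export
estimate_slope <- function(curve, cohort = list(), control = kinetics_control()) {
  scan <- scan_and_select(curve, control = control)
  row <- tibble::tibble(strain_id = curve$strain_id, condition = curve$condition,
                        bio_rep = curve$bio_rep, tech_rep = curve$tech_rep,
                        slope = NA_real_, slope_se = NA_real_,
                        fit_error = NA_real_, end_index = NA_integer_,
                        provenance = "failed")
  fill <- function(row, fit, prov) {
    row$slope <- fit$params[["sl"]]
    row$slope_se <- fit$param_se[["sl"]]
    row$fit_error <- fit$fit_error
    row$end_index <- fit$end_index
    row$provenance <- prov
    row
  }
  if (!is.null(scan$selected)) return(fill(row, scan$selected, "free_fit"))
  d_fix <- .cohort_fixed_d(cohort, curve$bio_rep)
  if (is.null(d_fix)) return(row)
  scan2 <- scan_and_select(curve, fixed_d = d_fix, control = control)
  if (is.null(scan2$selected)) return(row)
  fill(row, scan2$selected, "d_fixed")
}

#' Estimate slopes for a whole plate of curves
#'
#' Scans every curve once, then retries inadequate curves with the cohort
#' fixed-`d` fallback drawn from sibling replicates of the same strain and
#' condition.
#'
#' @param curves List of [kinetic_curve()] objects.
#' @param control A [kinetics_control()].
#' @return Tibble with one row per curve (see [estimate_slope()]).
#' @export
estimate_slopes <- function(curves, control = kinetics_control()) {
  stopifnot(length(curves) > 0)
  scans <- lapply(curves, scan_and_select, control = control)
  keys <- vapply(curves, function(cu) paste(cu$strain_id, cu$condition, sep = "\r"),
                 character(1))
  rows <- lapply(seq_along(curves), function(i) {
    cohort <- scans[keys == keys[i]]
    cohort <- cohort[vapply(seq_along(cohort), function(j)
      !identical(cohort[[j]], scans[[i]]), logical(1))]
    cu <- curves[[i]]
    scan <- scans[[i]]
    row <- tibble::tibble(strain_id = cu$strain_id, condition = cu$condition,
                          bio_rep = cu$bio_rep, tech_rep = cu$tech_rep,
                          slope = NA_real_, slope_se = NA_real_,
                          fit_error = NA_real_, end_index = NA_integer_,
                          provenance = "failed")
    if (!is.null(scan$selected)) {
      f <- scan$selected
      row$slope <- f$params[["sl"]]; row$slope_se <- f$param_se[["sl"]]
      row$fit_error <- f$fit_error; row$end_index <- f$end_index
      row$provenance <- "free_fit"
      return(row)
    }
    d_fix <- .cohort_fixed_d(cohort, cu$bio_rep)
    if (is.null(d_fix)) return(row)
    scan2 <- scan_and_select(cu, fixed_d = d_fix, control = control)
    if (is.null(scan2$selected)) return(row)
    f <- scan2$selected
    row$slope <- f$params[["sl"]]; row$slope_se <- f$param_se[["sl"]]
    row$fit_error <- f$fit_error; row$end_index <- f$end_index
    row$provenance <- "d_fixed"
    row
  })
  dplyr::bind_rows(rows)
}

#' Aggregate replicate slopes into a per-strain activity summary
#'
#' The strain/condition activity is the geometric mean of the replicate
#' slopes, with the geometric standard error `exp(sd(log slopes)/sqrt(n))`.
#' The reported error escalates on the natural-log (relative) scale to the
#' largest of: the log geometric SE, the mean relative per-fit slope SE, and
#' the within-biological-replicate standard deviation of log slopes across
#' technical replicates.
#'
#' @param estimates Tibble as returned by [estimate_slopes()]; failed rows are
#'   dropped. Must retain at least one usable row per strain/condition.
#' @return Tibble with `strain_id`, `condition`, `geo_mean_slope`, `geo_se`,
#'   `reported_error` (log scale), `n_replicates`.
#' @export
aggregate_activity <- function(estimates) {
  est <- dplyr::filter(estimates, .data$provenance != "failed", !is.na(.data$slope))
  if (nrow(est) == 0)
    stop("no successful slope estimates to aggregate")
  dropped <- dplyr::anti_join(
    dplyr::distinct(estimates, .data$strain_id, .data$condition),
    dplyr::distinct(est, .data$strain_id, .data$condition),
    by = c("strain_id", "condition"))
  if (nrow(dropped) > 0)
    stop(sprintf("all replicates failed for: %s",
                 paste(dropped$strain_id, dropped$condition, sep = "/",
                       collapse = ", ")))

  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  est |>
    dplyr::group_by(.data$strain_id, .data$condition) |>
    dplyr::summarise(
      geo_mean_slope = exp(mean(log(.data$slope))),
      geo_se = exp(sd0(log(.data$slope)) / sqrt(dplyr::n())),
      mean_rel_se = mean(.data$slope_se / .data$slope, na.rm = TRUE),
      tech_sd_log = {
        per_bio <- tapply(log(.data$slope), .data$bio_rep, sd0)
        mean(per_bio)
      },
      n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      mean_rel_se = ifelse(is.finite(.data$mean_rel_se), .data$mean_rel_se, 0),
      reported_error = pmax(log(.data$geo_se), .data$mean_rel_se,
                            .data$tech_sd_log)) |>
    dplyr::select("strain_id", "condition", "geo_mean_slope", "geo_se",
                  "reported_error", "n_replicates")
}
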