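#' Simple linear regression with two-tailed slope test
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, intercept,
#' coefficient of determination `R^2 = 1 - SSE/SST`, and the two-tailed
#' p-value for slope != 0 from `t = slope / SE(slope)` with `n - 2` degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, `x` not constant.
#' @return One-row tibble with `slope`, `intercept`, `r_squared`,
#'   `p_two_tailed`, `n`.
#' @export
#' @examples
#' fit_linear(c(1, 2, 3), c(1, 2, 2))  # slope 0.5, R^2 0.75
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("linear regression needs at least 3 complete points")
  if (stats::sd(x) == 0) stop("`x` is constant; slope is undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_two_tailed = unname(sm$coefficients[2, 4]),
                 n = length(x))
}

#' Cross-level correlation report
#'
#' Joins the genome-context, activity and expression tables on strain id and
#' fits the three pairwise regressions on raw (untransformed) values:
#' translation on transcription (`activity ~ expression`), transcription on
#' origin distance (`expression ~ ori_distance`), and translation on origin
#' distance (`activity ~ ori_distance`). Strains missing from any table are
#' dropped (complete-case join) with a message.
#'
#' @param site_table Output of [build_site_table()]; site names double as
#'   strain ids.
#' @param activity Output of [aggregate_activity()] (one condition).
#' @param expression Output of [fold_change_ddct()] (one condition).
#' @param log_scale Regress on log10 values instead of raw (default `FALSE`).
#' @return List with `regressions` (tibble: `response`, `predictor` + the
#'   [fit_linear()] columns), `scatter` (the joined per-strain data) and
#'   `n_dropped`.
#' @export
correlation_report <- function(site_table, activity, expression,
                               log_scale = FALSE) {
  act <- dplyr::select(activity, "strain_id",
                       activity = "geo_mean_slope")
  expr <- dplyr::select(expression, "strain_id",
                        expression = "fold_change")
  ctx <- dplyr::select(site_table, strain_id = "site", "ori_distance")
  joined <- ctx |>
    dplyr::inner_join(act, by = "strain_id") |>
    dplyr::inner_join(expr, by = "strain_id")
  n_dropped <- length(unique(c(ctx$strain_id, act$strain_id,
                               expr$strain_id))) - nrow(joined)
  if (nrow(joined) < 3)
    stop("fewer than 3 strains present in all three tables")
  if (n_dropped > 0)
    message(sprintf("correlation_report: dropped %d strain(s) missing from some table",
                    n_dropped))
  tf <- if (log_scale) log10 else identity
  pairs <- list(
    c("activity", "expression"),
    c("expression", "ori_distance"),
    c("activity", "ori_distance"))
  regs <- purrr::map_dfr(pairs, function(p) {
    dplyr::bind_cols(
      tibble::tibble(response = p[1], predictor = p[2]),
      fit_linear(tf(joined[[p[2]]]), tf(joined[[p[1]]])))
  })
  list(regressions = regs, scatter = joined, n_dropped = n_dropped)
}
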