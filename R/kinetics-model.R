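#' Smoothed reaction time
#'
#' Smoothed ramp mapping clock time onto effective reaction time. Before the
#' lag offset `t_off` the effective time is ~0, afterwards it grows with unit
#' slope; `d` sets the width (in minutes) of the smooth transition between the
#' two regimes:
#' \deqn{dt = \frac{(t - t_{off}) + \sqrt{(t - t_{off})^2 + d^2}}{2}}
#' As `d -> 0` this converges to the hinge `max(0, t - t_off)`, and at
#' `t = t_off` it equals `d / 2`.
#'
#' @param t Time in minutes (vectorised).
#' @param t_off Lag offset in minutes.
#' @param d Non-negative transition width in minutes.
#' @return Non-negative effective reaction time, same length as `t`.
#' @export
#' @examples
#' smoothed_time(20, t_off = 10, d = 0)  # hinge limit: 10
#' smoothed_time(10, t_off = 10, d = 5)  # at the offset: d/2
smoothed_time <- function(t, t_off, d) {
  stopifnot(is.numeric(t), is.numeric(t_off), is.numeric(d), all(d >= 0))
  u <- t - t_off
  (u + sqrt(u^2 + d^2)) / 2
}

#' Construct Monod-type kinetic model parameters
#'
#' Parameter set of the saturating conversion model used for ONPG
#' time courses: `sl` is the initial conversion rate (OD410 per minute),
#' `m` the plateau absorbance, `t_off` the lag offset and `d` the transition
#' smoothing width (minutes).
#'
#' @param sl Positive initial slope, OD410 min^-1.
#' @param m Positive plateau OD410.
#' @param t_off Lag offset in minutes.
#' @param d Non-negative smoothing width in minutes.
#' @return Named numeric vector of class `monod_params`.
#' @export
monod_params <- function(sl, m, t_off, d) {
  stopifnot(is.numeric(sl), is.numeric(m), is.numeric(t_off), is.numeric(d))
  if (sl <= 0) stop("`sl` must be positive")
  if (m <= 0) stop("`m` must be positive")
  if (d < 0) stop("`d` must be non-negative")
  structure(c(sl = sl, m = m, t_off = t_off, d = d), class = "monod_params")
}

#' Evaluate the Monod-type smoothed conversion model
#'
#' Predicted OD410 at time `t`:
#' \deqn{OD_{410}(t) = \frac{sl \cdot dt \cdot m}{sl \cdot dt + m}}
#' with `dt` the [smoothed_time()]. The curve rises linearly with rate `sl`
#' while `sl * dt << m` and saturates below the plateau `m`.
#'
#' @param params A [monod_params()] object (or named vector with elements
#'   `sl`, `m`, `t_off`, `d`).
#' @param t Times in minutes (vectorised).
#' @return Predicted OD410 values in `[0, m)`.
#' @export
#' @examples
#' p <- monod_params(sl = 1e-3, m = 1, t_off = 0, d = 0)
#' eval_model(p, 1000)  # 0.5: halfway to the plateau when sl*dt == m
eval_model <- function(params, t) {
  p <- unclass(params)
  stopifnot(all(c("sl", "m", "t_off", "d") %in% names(p)))
  dt <- smoothed_time(t, p[["t_off"]], p[["d"]])
  p[["sl"]] * dt * p[["m"]] / (p[["sl"]] * dt + p[["m"]])
}

#' Construct a kinetic curve
#'
#' One replicate's ONPG conversion time series: strictly increasing times
#' (minutes) and matching OD410 readings. At least six points are required so
#' that the minimal fitting window exists.
#'
#' @param strain_id,condition Identifiers.
#' @param bio_rep,tech_rep Positive integer replicate indices.
#' @param times Strictly increasing times in minutes.
#' @param od410 Absorbances, same length as `times`.
#' @return A list of class `kinetic_curve`.
#' @export
kinetic_curve <- function(strain_id, condition, bio_rep, tech_rep, times, od410) {
  stopifnot(length(times) == length(od410), length(times) >= 6)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (bio_rep < 1 || tech_rep < 1) stop("replicate indices must be >= 1")
  structure(
    list(strain_id = as.character(strain_id), condition = as.character(condition),
         bio_rep = as.integer(bio_rep), tech_rep = as.integer(tech_rep),
         times = as.numeric(times), od410 = as.numeric(od410)),
    class = "kinetic_curve")
}

#' @export
print.kinetic_curve <- function(x, ...) {
  cat(sprintf("<kinetic_curve> %s / %s bio %d tech %d: %d points, %g-%g min\n",
              x$strain_id, x$condition, x$bio_rep, x$tech_rep,
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}
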