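# Brute-force evaluation of the outcome measures as functions of a candidate
# type 2 criterion, and grid-search maximization. Serves as the independent
# check on every closed-form optimum, and as the only route to optima under
# the process models, where no closed forms exist.

#' Default criterion grid for one response
#'
#' The response-side interval `[c1, c1 + 6]` (mirrored to `[c1 - 6, c1]` for
#' "S1" responses) at the given step. Six decision-axis units cover the
#' optima at typical parameters; widen the interval when `d_prime` is small
#' and the priors or the context strength (`Q2`, `O_T`) are extreme, since
#' the optimum sits about `|c1_A - c1| + ln(max(Q2, 1/Q2)) / d_prime` from
#' `c1`.
#'
#' @param params An [sdt_params()] object.
#' @param response `"S2"` or `"S1"`.
#' @param step Grid step (default `1e-3`).
#' @param width Half-width of the interval (default 6).
#' @return Numeric grid, increasing, starting or ending at `c1`.
#' @export
c2_grid <- function(params, response = c("S2", "S1"), step = 1e-3, width = 6) {
  response <- match.arg(response)
  if (response == "S2") seq(params$c1, params$c1 + width, by = step)
  else seq(params$c1 - width, params$c1, by = step)
}

# Outcome values over a grid of c2 candidates for one response, standard
# model, fully vectorized. `extras` is a reward_matrix2 (reward context) or
# calibration_target (calibration context).
outcome_values_standard <- function(context, params, extras, response, grid) {
  d <- params$d_prime; c1 <- params$c1
  mu <- c(S1 = -d / 2, S2 = d / 2)
  if (context == "calibration") {
    post_S2 <- stats::plogis(log(params$p_S2 / params$p_S1) + grid * d)
    return(if (response == "S2") post_S2 else 1 - post_S2)
  }
  if (response == "S2") {
    r  <- c(S1 = tail_above(c1, mu[["S1"]]), S2 = tail_above(c1, mu[["S2"]]))
    hc <- list(S1 = tail_above(grid, mu[["S1"]]),
               S2 = tail_above(grid, mu[["S2"]]))
  } else {
    r  <- c(S1 = tail_below(c1, mu[["S1"]]), S2 = tail_below(c1, mu[["S2"]]))
    hc <- list(S1 = tail_below(grid, mu[["S1"]]),
               S2 = tail_below(grid, mu[["S2"]]))
  }
  corr <- response; inc <- setdiff(c("S1", "S2"), response)
  combine_outcome(context, params, extras, r, hc, corr, inc, response)
}

#' Outcome measure as a function of a candidate type 2 criterion
#'
#' Evaluates the outcome of the requested context at every grid point for one
#' response, holding the type 1 criterion fixed: type 2 accuracy
#' (response-conditional), expected type 2 reward (response-conditional),
#' `HR2 - FAR2` for that response, or — for the calibration context — the
#' posterior probability that the response is correct at evidence value `x`
#' (whose crossing with the target accuracy, not whose maximum, defines the
#' calibration criterion). With a [process_model()] other than the standard
#' one, outcomes are computed from exact bivariate-normal masses
#' (`engine = "exact"`) or from one common set of simulated trials reused
#' across all grid points (`engine = "mc"`).
#'
#' @param context One of `"accuracy"`, `"reward"`, `"calibration"`, `"hf"`.
#' @param params An [sdt_params()] object.
#' @param extras A [reward_matrix2()] for the reward context, a
#'   [calibration_target()] for calibration, otherwise `NULL`.
#' @param response `"S2"` or `"S1"`.
#' @param grid Criterion grid on the response's side of `c1`; defaults to
#'   [c2_grid()].
#' @param pm Optional [process_model()]; `NULL` or the standard model gives
#'   the closed-form evaluation.
#' @param engine `"exact"` or `"mc"` (only relevant under a process model).
#' @param n Number of Monte-Carlo trials for `engine = "mc"`.
#' @param seed RNG seed, required for `engine = "mc"`.
#' @return An object of class `outcome_curve`: list with `context`,
#'   `response`, `grid`, `values`, `c1`.
#' @export
outcome_curve <- function(context = c("accuracy", "reward", "calibration", "hf"),
                          params, extras = NULL, response = c("S2", "S1"),
                          grid = NULL, pm = NULL,
                          engine = c("exact", "mc"), n = 1e6, seed = NULL) {
  context <- match.arg(context)
  response <- match.arg(response)
  engine <- match.arg(engine)
  stopifnot(inherits(params, "sdt_params"))
  if (is.null(grid)) grid <- c2_grid(params, response)
  if (length(grid) == 0) stop("empty criterion grid", call. = FALSE)
  if (is.unsorted(grid)) stop("`grid` must be increasing", call. = FALSE)
  if (response == "S2" && any(grid < params$c1))
    stop("grid for \"S2\" responses must lie at or above c1", call. = FALSE)
  if (response == "S1" && any(grid > params$c1))
    stop("grid for \"S1\" responses must lie at or below c1", call. = FALSE)
  if (context == "reward" && !inherits(extras, "reward_matrix2"))
    stop("reward context requires a reward_matrix2 in `extras`", call. = FALSE)
  if (context == "calibration" && !is.null(extras) && is.numeric(extras))
    extras <- calibration_target(extras)

  standard <- is.null(pm) || (pm$sigma2 == 0 && pm$k == 0)
  values <- if (standard) {
    outcome_values_standard(context, params, extras, response, grid)
  } else if (engine == "exact") {
    outcome_values_pm_exact(context, pm, params, extras, response, grid)
  } else {
    if (is.null(seed)) stop("`seed` is required for engine = \"mc\"", call. = FALSE)
    outcome_values_pm_mc(context, pm, params, extras, response, grid, n, seed)
  }
  structure(list(context = context, response = response, grid = grid,
                 values = as.numeric(values),
                 varying = attr(values, "varying"), c1 = params$c1),
            class = "outcome_curve")
}

#' @export
print.outcome_curve <- function(x, ...) {
  cat(sprintf("Outcome curve (%s, response \"%s\"): %d grid points in [%g, %g]\n",
              x$context, x$response, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Grid-search argmax of an outcome curve
#'
#' Returns the grid point with the maximal outcome value. Exact ties are
#' broken toward the point closest to `c1` (the liberal end), so that a flat
#' curve yields the most liberal policy. When the curve carries its
#' criterion-dependent component separately (accuracy and reward values are
#' a constant plus a tail-mass term), the argmax is taken on that component:
#' the two orderings agree analytically, but the component is free of the
#' cancellation that flattens the summed value when the optimum lies far
#' into a tail.
#'
#' @param curve An [outcome_curve()] result.
#' @return List with `c2` (the argmax) and `value` (the outcome value
#'   there).
#' @export
argmax_c2 <- function(curve) {
  stopifnot(inherits(curve, "outcome_curve"))
  vv <- if (is.null(curve$varying)) curve$values else curve$varying
  ok <- !is.na(vv)
  if (!any(ok)) stop("outcome curve is all NA", call. = FALSE)
  v <- vv[ok]; g <- curve$grid[ok]
  top <- which(v == max(v))
  pick <- top[which.min(abs(g[top] - curve$c1))]
  list(c2 = g[pick], value = curve$values[ok][pick])
}

#' Calibration criterion by root finding
#'
#' Locates the evidence value where the posterior probability of a correct
#' response crosses the target accuracy, on the requested response's side of
#' `c1`, by bisection ([stats::uniroot()]). If the posterior already exceeds
#' the target at `c1`, the criterion is clipped at `c1`; if the target is
#' never reached the criterion is `+/-Inf` (never report high confidence).
#' Serves as the independent numerical check on the closed-form calibration
#' criteria.
#'
#' @param params An [sdt_params()] with `d_prime > 0`.
#' @param target A [calibration_target()] or threshold accuracy.
#' @param response `"S2"` or `"S1"`.
#' @param pm Optional [process_model()] under which the posterior is
#'   evaluated (on the type 2 evidence axis).
#' @param tol Root tolerance (default `1e-9`).
#' @return The criterion value.
#' @export
calibration_crossing <- function(params, target, response = c("S2", "S1"),
                                 pm = NULL, tol = 1e-9) {
  response <- match.arg(response)
  if (is.numeric(target)) target <- calibration_target(target)
  stopifnot(inherits(params, "sdt_params"), params$d_prime > 0)
  post <- function(v) {
    if (is.null(pm) || (pm$sigma2 == 0 && pm$k == 0)) {
      p2 <- stats::plogis(log(params$p_S2 / params$p_S1) + v * params$d_prime)
      if (response == "S2") p2 else 1 - p2
    } else {
      pm_posterior_correct(pm, params, v, response)
    }
  }
  g <- function(v) post(v) - target$p_correct_T
  sgn <- if (response == "S2") 1 else -1
  if (g(params$c1) >= 0) return(params$c1)
  hi <- params$c1 + sgn * 50
  if (g(hi) < 0) return(sgn * Inf)
  stats::uniroot(function(u) g(params$c1 + sgn * u), c(0, 50),
                 tol = tol)$root * sgn + params$c1
}
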