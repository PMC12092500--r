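# Closed-form optimal criteria for the four optimization contexts.
#
# All four share one backbone: the accuracy-optimal type 1 criterion
# c1_A = ln(p(S1)/p(S2)) / d'. Reward and calibration optima sit
# symmetrically around it at a distance ln(Q2)/d' resp. ln(O_T)/d', clipped
# to the response's side of the actual c1; the HR2 - FAR2 optima instead use
# the model-implied type 1 rates and are independent of the priors.

#' Optimal type 1 criterion for maximizing type 1 accuracy
#'
#' `c1_A = ln(p(S1)/p(S2)) / d'`. With equal priors the optimum is 0 for any
#' `d_prime`. With `d_prime = 0` and unequal priors the formula diverges: the
#' observer should always give the response favoured by the prior, and the
#' signed infinity expressing that policy is returned.
#'
#' @param d_prime Sensitivity (>= 0).
#' @param p_S2 Prior probability of S2.
#' @return The optimal criterion (possibly infinite when `d_prime = 0`).
#' @examples
#' c1_opt_accuracy(1, 1/3) # log(2)
#' @export
c1_opt_accuracy <- function(d_prime, p_S2) {
  stopifnot(is.numeric(d_prime), d_prime >= 0, p_S2 > 0, p_S2 < 1)
  lr <- log((1 - p_S2) / p_S2)
  if (d_prime == 0) {
    if (lr == 0) return(0)        # flat accuracy surface: conventional 0
    return(sign(lr) * Inf)
  }
  lr / d_prime
}

#' Optimal type 1 criterion for maximizing expected type 1 reward
#'
#' `c1_R = [ln(p(S1)/p(S2)) + ln Q1] / d'` where
#' `Q1 = (R_CR1 - R_FA1)/(R_hit1 - R_miss1)`. Errors if `Q1` is undefined
#' (see [reward_quotient()]) or `d_prime = 0`.
#'
#' @inheritParams c1_opt_accuracy
#' @param rm A [reward_matrix1()].
#' @export
c1_opt_reward <- function(d_prime, p_S2, rm) {
  stopifnot(inherits(rm, "reward_matrix1"))
  Q1 <- reward_quotient(rm)
  if (d_prime == 0)
    stop("d_prime = 0: the reward-optimal criterion is not defined", call. = FALSE)
  (log((1 - p_S2) / p_S2) + log(Q1)) / d_prime
}

#' Optimal type 1 criterion for maximizing HR1 - FAR1
#'
#' Always 0, independent of sensitivity and priors (at `d_prime = 0` the
#' difference is identically zero and 0 is returned as the conventional
#' representative of the plateau).
#'
#' @return 0.
#' @export
c1_opt_hf <- function() 0

new_optimal_criteria <- function(context, c1, c1_star, raw_S1, raw_S2) {
  c2_S2 <- max(raw_S2, c1)
  c2_S1 <- min(raw_S1, c1)
  structure(list(
    context = context, c1 = c1, c1_star = c1_star,
    c2_S1_star = c2_S1, c2_S2_star = c2_S2,
    clipped_S1 = raw_S1 > c1, clipped_S2 = raw_S2 < c1
  ), class = "optimal_criteria")
}

#' @export
print.optimal_criteria <- function(x, ...) {
  cat(sprintf("Optimal type 2 criteria (%s context):\n", x$context))
  cat(sprintf("  c2_S1* = %g%s, c2_S2* = %g%s\n",
              x$c2_S1_star, if (x$clipped_S1) " [clipped at c1]" else "",
              x$c2_S2_star, if (x$clipped_S2) " [clipped at c1]" else ""))
  if (!is.na(x$c1_star)) cat(sprintf("  c1* = %g (actual c1 = %g)\n", x$c1_star, x$c1))
  invisible(x)
}

#' Optimal type 2 criteria for maximizing type 2 accuracy
#'
#' `c2_S2* = max(c1_A, c1)` and `c2_S1* = min(c1_A, c1)`: both confidence
#' criteria sit as close as possible to the accuracy-optimal type 1
#' criterion, subject to the consistency constraint. When `c1 = c1_A` both
#' equal `c1` and the observer never reports low confidence.
#'
#' @param params An [sdt_params()] object with `d_prime > 0` (required
#'   unless the priors are equal).
#' @return An object of class `optimal_criteria` with fields `c2_S1_star`,
#'   `c2_S2_star`, `c1_star`, and clipping flags `clipped_S1`, `clipped_S2`
#'   marking whether the consistency bound at `c1` was active.
#' @export
c2_opt_accuracy <- function(params) {
  stopifnot(inherits(params, "sdt_params"))
  c1A <- c1_opt_accuracy(params$d_prime, params$p_S2)
  new_optimal_criteria("accuracy", params$c1, c1A, c1A, c1A)
}

#' Optimal type 2 criteria for maximizing expected type 2 reward
#'
#' `c2_S2* = max(c1_A + ln(Q2)/d', c1)` and
#' `c2_S1* = min(c1_A - ln(Q2)/d', c1)`, with
#' `Q2 = (R_CR2 - R_FA2)/(R_hit2 - R_miss2)`. `Q2 = 1` reduces to
#' [c2_opt_accuracy()]. Supply either a payoff matrix or `Q2` directly.
#'
#' @param params An [sdt_params()] with `d_prime > 0`.
#' @param rm A [reward_matrix2()]; ignored when `Q2` is given.
#' @param Q2 The relative reward quotient (> 0).
#' @return An `optimal_criteria` object (see [c2_opt_accuracy()]).
#' @export
c2_opt_reward <- function(params, rm = NULL, Q2 = NULL) {
  stopifnot(inherits(params, "sdt_params"))
  if (is.null(Q2)) {
    if (!inherits(rm, "reward_matrix2"))
      stop("supply a reward_matrix2 or Q2", call. = FALSE)
    Q2 <- reward_quotient(rm)
  }
  stopifnot(is.numeric(Q2), Q2 > 0)
  if (params$d_prime == 0)
    stop("d_prime = 0: reward-optimal type 2 criteria are not defined",
         call. = FALSE)
  c1A <- c1_opt_accuracy(params$d_prime, params$p_S2)
  off <- log(Q2) / params$d_prime
  new_optimal_criteria("reward", params$c1, NA_real_, c1A - off, c1A + off)
}

#' Type 2 criteria that calibrate confidence to a threshold accuracy
#'
#' The observer reports high confidence only where the posterior probability
#' of a correct response exceeds `p_correct_T`. The criteria solve
#' `p(correct1 | x) = p_correct_T` on each response's side of `c1`:
#' `c2_S2* = max(c1_A + ln(O_T)/d', c1)`,
#' `c2_S1* = min(c1_A - ln(O_T)/d', c1)`, with odds
#' `O_T = p_correct_T / (1 - p_correct_T)`. `p_correct_T = 0.5` reduces to
#' [c2_opt_accuracy()]; `O_T` plays exactly the role `Q2` plays for reward.
#'
#' @param params An [sdt_params()] with `d_prime > 0`.
#' @param target A [calibration_target()] or the threshold accuracy itself.
#' @return An `optimal_criteria` object; `c1_star` is `NA` (calibration
#'   prescribes no type 1 criterion).
#' @export
c2_opt_calibration <- function(params, target) {
  stopifnot(inherits(params, "sdt_params"))
  if (is.numeric(target)) target <- calibration_target(target)
  stopifnot(inherits(target, "calibration_target"))
  if (params$d_prime == 0)
    stop("d_prime = 0: calibration criteria are not defined", call. = FALSE)
  c1A <- c1_opt_accuracy(params$d_prime, params$p_S2)
  off <- log(target$O_T) / params$d_prime
  new_optimal_criteria("calibration", params$c1, NA_real_,
                       c1A - off, c1A + off)
}

#' Optimal type 2 criteria for maximizing HR2 - FAR2
#'
#' `c2_S2* = max(ln(HR1/FAR1)/d', c1)` and
#' `c2_S1* = min(ln((1 - HR1)/(1 - FAR1))/d', c1)`. By default the
#' model-implied type 1 rates from [type1_summary()] are used; externally
#' measured rates may be supplied instead (both must be given together).
#' For `d_prime > 0` the unclipped optima are strictly positive ("S2") and
#' strictly negative ("S1") regardless of `c1`.
#'
#' @param params An [sdt_params()] with `d_prime > 0`.
#' @param HR1,FAR1 Optional externally supplied type 1 rates in (0, 1).
#' @return An `optimal_criteria` object; `c1_star` is the HR1 - FAR1 optimum
#'   0.
#' @export
c2_opt_hf <- function(params, HR1 = NULL, FAR1 = NULL) {
  stopifnot(inherits(params, "sdt_params"))
  if (params$d_prime == 0)
    stop("d_prime = 0: HR2 - FAR2 is identically zero, optimum undefined",
         call. = FALSE)
  if (is.null(HR1) != is.null(FAR1))
    stop("supply both HR1 and FAR1, or neither", call. = FALSE)
  if (is.null(HR1)) {
    t1 <- type1_summary(params)
    HR1 <- t1$HR1; FAR1 <- t1$FAR1
  }
  stopifnot(HR1 > 0, HR1 < 1, FAR1 > 0, FAR1 < 1)
  d <- params$d_prime
  new_optimal_criteria("hf", params$c1, 0,
                       log((1 - HR1) / (1 - FAR1)) / d,
                       log(HR1 / FAR1) / d)
}

#' Over/under-confidence ratio of actual relative to optimal type 2 criteria
#'
#' Normalizes the distance of each actual type 2 criterion from `c1` by the
#' distance of the optimal criterion from `c1`:
#' `ratio = (c2 - c1) / (c2* - c1)`. A ratio below 1 flags over-confidence
#' (the actual criterion is too close to `c1`), above 1 under-confidence,
#' exactly 1 optimal placement. Undefined when the optimal criterion sits at
#' `c1` (e.g. clipped by the consistency constraint).
#'
#' @param c1 The actual type 1 criterion.
#' @param actual A [type2_criteria()] object.
#' @param optimal An `optimal_criteria` object for the same `c1`.
#' @return List with `ratio_S1` and `ratio_S2`.
#' @export
confidence_bias_ratio <- function(c1, actual, optimal) {
  stopifnot(inherits(actual, "type2_criteria"),
            inherits(optimal, "optimal_criteria"))
  den_S1 <- optimal$c2_S1_star - c1
  den_S2 <- optimal$c2_S2_star - c1
  if (den_S1 == 0 || den_S2 == 0)
    stop("bias ratio undefined: an optimal type 2 criterion equals c1",
         call. = FALSE)
  list(ratio_S1 = (actual$c2_S1 - c1) / den_S1,
       ratio_S2 = (actual$c2_S2 - c1) / den_S2)
}
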