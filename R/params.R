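#' Type 1 generative parameters of the equal-variance SDT observer
#'
#' Bundles the three quantities that define the type 1 world: sensitivity
#' `d_prime`, type 1 criterion `c1`, and the prior probability `p_S2` of an
#' S2 stimulus. The package-wide coordinate convention places the S1 evidence
#' distribution at `-d_prime/2` and the S2 distribution at `+d_prime/2`, both
#' with unit variance, so that the likelihood ratio of S2 to S1 at decision
#' axis value `x` is `exp(x * d_prime)`.
#'
#' @param d_prime Sensitivity in SD units; must be >= 0.
#' @param c1 Type 1 criterion on the decision axis ("S2" response iff
#'   evidence exceeds `c1`). May be infinite to express always/never
#'   policies.
#' @param p_S2 Prior probability of an S2 stimulus, strictly between 0 and 1.
#' @return An object of class `sdt_params`: a list with elements `d_prime`,
#'   `c1`, `p_S1`, `p_S2`.
#' @examples
#' sdt_params(d_prime = 2, c1 = 0, p_S2 = 0.5)
#' @export
sdt_params <- function(d_prime, c1 = 0, p_S2 = 0.5) {
  stopifnot(is.numeric(d_prime), length(d_prime) == 1L,
            is.numeric(c1), length(c1) == 1L,
            is.numeric(p_S2), length(p_S2) == 1L)
  if (is.na(d_prime) || d_prime < 0)
    stop("`d_prime` must be a non-negative number", call. = FALSE)
  if (is.na(p_S2) || p_S2 <= 0 || p_S2 >= 1)
    stop("`p_S2` must lie strictly between 0 and 1", call. = FALSE)
  if (is.na(c1)) stop("`c1` must not be NA", call. = FALSE)
  structure(list(d_prime = d_prime, c1 = c1,
                 p_S1 = 1 - p_S2, p_S2 = p_S2),
            class = "sdt_params")
}

#' @export
print.sdt_params <- function(x, ...) {
  cat(sprintf("SDT parameters: d' = %g, c1 = %g, p(S2) = %g\n",
              x$d_prime, x$c1, x$p_S2))
  invisible(x)
}

#' Response-specific type 2 (confidence) criteria
#'
#' The criterion `c2_S1` governs confidence for "S1" responses (high
#' confidence iff evidence falls below it) and `c2_S2` governs "S2" responses
#' (high confidence iff evidence exceeds it). The consistency constraint
#' `c2_S1 <= c1 <= c2_S2` is checked here when `params` is supplied, and
#' always checked by the functions that consume the criteria.
#'
#' @param c2_S1,c2_S2 Confidence criteria on the decision axis; infinities
#'   are allowed (never report high confidence for that response).
#' @param params Optional [sdt_params()] against which the consistency
#'   constraint is validated.
#' @return An object of class `type2_criteria`.
#' @export
type2_criteria <- function(c2_S1, c2_S2, params = NULL) {
  stopifnot(is.numeric(c2_S1), length(c2_S1) == 1L,
            is.numeric(c2_S2), length(c2_S2) == 1L)
  if (is.na(c2_S1) || is.na(c2_S2))
    stop("type 2 criteria must not be NA", call. = FALSE)
  out <- structure(list(c2_S1 = c2_S1, c2_S2 = c2_S2),
                   class = "type2_criteria")
  if (!is.null(params)) check_consistency(out, params)
  out
}

#' @export
print.type2_criteria <- function(x, ...) {
  cat(sprintf("Type 2 criteria: c2_S1 = %g, c2_S2 = %g\n", x$c2_S1, x$c2_S2))
  invisible(x)
}

check_consistency <- function(crit, params) {
  if (crit$c2_S1 > params$c1 || crit$c2_S2 < params$c1)
    stop(sprintf(
      "consistency constraint violated: need c2_S1 <= c1 <= c2_S2 (got c2_S1 = %g, c1 = %g, c2_S2 = %g)",
      crit$c2_S1, params$c1, crit$c2_S2), call. = FALSE)
  invisible(TRUE)
}

#' Payoff matrices for type 1 and type 2 outcomes
#'
#' A type 1 payoff matrix assigns points to hits, misses, correct rejections
#' and false alarms of the stimulus classification; a type 2 matrix assigns
#' points to high/low confidence on correct/incorrect type 1 responses
#' (type 2 hit = high-confidence correct, type 2 false alarm =
#' high-confidence error, type 2 correct rejection = low-confidence error,
#' type 2 miss = low-confidence correct). Entries may be any real number.
#'
#' @param R_hit,R_miss,R_CR,R_FA Payoff points for the four outcome cells.
#' @return Object of class `reward_matrix1` or `reward_matrix2`.
#' @seealso [reward_quotient()] for the derived quotients Q1 and Q2.
#' @export
reward_matrix1 <- function(R_hit, R_miss, R_CR, R_FA) {
  new_reward_matrix(R_hit, R_miss, R_CR, R_FA, "reward_matrix1")
}

#' @rdname reward_matrix1
#' @export
reward_matrix2 <- function(R_hit, R_miss, R_CR, R_FA) {
  new_reward_matrix(R_hit, R_miss, R_CR, R_FA, "reward_matrix2")
}

new_reward_matrix <- function(R_hit, R_miss, R_CR, R_FA, class) {
  vals <- c(R_hit = R_hit, R_miss = R_miss, R_CR = R_CR, R_FA = R_FA)
  if (!is.numeric(vals) || length(vals) != 4L || anyNA(vals))
    stop("all four payoff entries must be finite numbers", call. = FALSE)
  structure(as.list(vals), class = class)
}

#' Calibration target: threshold accuracy for high confidence
#'
#' @param p_correct_T Threshold type 1 accuracy (strictly between 0 and 1)
#'   above which the observer wishes to report high confidence.
#' @return Object of class `calibration_target` with the threshold and its
#'   odds form `O_T = p_correct_T / (1 - p_correct_T)`.
#' @export
calibration_target <- function(p_correct_T) {
  stopifnot(is.numeric(p_correct_T), length(p_correct_T) == 1L)
  if (is.na(p_correct_T) || p_correct_T <= 0 || p_correct_T >= 1)
    stop("`p_correct_T` must lie strictly between 0 and 1", call. = FALSE)
  structure(list(p_correct_T = p_correct_T,
                 O_T = p_correct_T / (1 - p_correct_T)),
            class = "calibration_target")
}

#' Relative reward quotients and the calibration odds
#'
#' For a type 1 payoff matrix, `Q1 = (R_CR1 - R_FA1) / (R_hit1 - R_miss1)`;
#' for a type 2 matrix the analogous `Q2`; for a calibration target the odds
#' `O_T`. The quotients are defined only when both payoff differences are
#' strictly positive: a zero or mixed-sign pair leaves the optimal criterion
#' undefined, and a both-negative pair turns the reward function upside down
#' so the criterion formula would pick out its minimum. Both pathologies are
#' reported as errors.
#'
#' @param x A [reward_matrix1()], [reward_matrix2()] or
#'   [calibration_target()].
#' @return The quotient (a positive number).
#' @examples
#' reward_quotient(reward_matrix2(1, 0, 5.37, 0)) # 5.37
#' @export
reward_quotient <- function(x) UseMethod("reward_quotient")

#' @export
reward_quotient.reward_matrix1 <- function(x) quotient_or_stop(x, "Q1")

#' @export
reward_quotient.reward_matrix2 <- function(x) quotient_or_stop(x, "Q2")

#' @export
reward_quotient.calibration_target <- function(x) x$O_T

quotient_or_stop <- function(rm, label) {
  num <- rm$R_CR - rm$R_FA
  den <- rm$R_hit - rm$R_miss
  if (num < 0 && den < 0)
    stop(label, " undefined: both payoff differences are negative, so the ",
         "criterion formula would pick out the minimum of the reward ",
         "function, not its maximum", call. = FALSE)
  if (num <= 0 || den <= 0)
    stop(label, " undefined: both (R_CR - R_FA) and (R_hit - R_miss) must ",
         "be strictly positive", call. = FALSE)
  num / den
}

#' Process model of the type 2 evidence stream
#'
#' In the standard SDT model the confidence judgment reuses the type 1
#' evidence sample `x1`. The type 2 noise model adds independent Gaussian
#' noise before the confidence judgment, `x2 = x1 + e`, `e ~ N(0, sigma2^2)`;
#' the type 2 signal loss model additionally attenuates the signal,
#' `x2 = (1 - k) x1 + e` with `0 <= k <= 1`. Both degrade metacognitive
#' sensitivity (meta-d' < d') while leaving type 1 behaviour untouched.
#'
#' @param model One of `"standard"`, `"noise"`, `"loss"`.
#' @param sigma2 SD of the additional type 2 noise (>= 0). Defaults to 0 for
#'   the standard and noise models and 0.1 for the loss model.
#' @param k Signal-loss fraction in `[0, 1]`; forced to 0 unless
#'   `model = "loss"`.
#' @return Object of class `process_model`.
#' @export
process_model <- function(model = c("standard", "noise", "loss"),
                          sigma2 = NULL, k = 0) {
  model <- match.arg(model)
  if (is.null(sigma2)) sigma2 <- if (model == "loss") 0.1 else 0
  stopifnot(is.numeric(sigma2), length(sigma2) == 1L,
            is.numeric(k), length(k) == 1L)
  if (is.na(sigma2) || sigma2 < 0)
    stop("`sigma2` must be >= 0", call. = FALSE)
  if (is.na(k) || k < 0 || k > 1)
    stop("`k` must lie in [0, 1]", call. = FALSE)
  if (model == "standard" && (sigma2 != 0 || k != 0))
    stop("the standard model requires sigma2 = 0 and k = 0", call. = FALSE)
  if (model == "noise" && k != 0)
    stop("the type 2 noise model requires k = 0", call. = FALSE)
  if (k == 1 && sigma2 == 0)
    stop("degenerate model: k = 1 with sigma2 = 0 makes x2 deterministic",
         call. = FALSE)
  structure(list(model = model, sigma2 = sigma2, k = k),
            class = "process_model")
}

#' @export
print.process_model <- function(x, ...) {
  cat(sprintf("Process model '%s': sigma2 = %g, k = %g\n",
              x$model, x$sigma2, x$k))
  invisible(x)
}
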