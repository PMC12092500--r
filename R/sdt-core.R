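# Forward model of the equal-variance SDT observer.
#
# Coordinate convention: S1 evidence ~ N(-d'/2, 1), S2 evidence ~ N(+d'/2, 1),
# so the likelihood ratio f(x|S2)/f(x|S1) equals exp(x * d'). Tail masses are
# taken through the complementary CDF (lower.tail = FALSE) so that rates stay
# accurate for criteria many SDs into a tail.

# P(x > q | stimulus), with mu the stimulus mean. Vectorized over q.
tail_above <- function(q, mu) stats::pnorm(q, mean = mu, lower.tail = FALSE)
tail_below <- function(q, mu) stats::pnorm(q, mean = mu, lower.tail = TRUE)

#' Type 1 summary: hit rate, false alarm rate, accuracy, likelihood ratio
#'
#' Computes `HR1 = P("S2" | S2) = 1 - Phi(c1 - d'/2)`,
#' `FAR1 = P("S2" | S1) = 1 - Phi(c1 + d'/2)`, the prior-weighted accuracy
#' `p(correct1) = p(S2) HR1 + p(S1) (1 - FAR1)`, and the likelihood ratio of
#' the criterion, `beta1 = exp(c1 * d')`.
#'
#' @param params An [sdt_params()] object.
#' @return A list of class `type1_summary` with elements `HR1`, `FAR1`,
#'   `p_correct1`, `beta1`.
#' @examples
#' type1_summary(sdt_params(2, 0, 0.5)) # HR1 = Phi(1) ~ 0.841
#' @export
type1_summary <- function(params) {
  stopifnot(inherits(params, "sdt_params"))
  d <- params$d_prime; c1 <- params$c1
  HR1  <- tail_above(c1, d / 2)
  FAR1 <- tail_above(c1, -d / 2)
  structure(list(
    HR1 = HR1, FAR1 = FAR1,
    p_correct1 = params$p_S2 * HR1 + params$p_S1 * (1 - FAR1),
    beta1 = exp(c1 * d)
  ), class = "type1_summary")
}

#' Posterior probability that the criterion-dictated response is correct
#'
#' For evidence `x` above `c1` the response is "S2" and the value returned is
#' the posterior `p(S2 | x)`; at or below `c1` it is `p(S1 | x)` (ties go to
#' the "S1" response, matching the package-wide discretization rule). The
#' posterior is evaluated through the log-odds
#' `log(p(S2)/p(S1)) + x * d'`, which is exact under the coordinate
#' convention and immune to density underflow for large `|x|`.
#'
#' @param params An [sdt_params()] object.
#' @param x Decision-axis value(s); vectorized.
#' @return Posterior probability of a correct response, same length as `x`.
#' @examples
#' p_correct_given_x(sdt_params(2, 0, 0.5), 1) # ~0.881
#' @export
p_correct_given_x <- function(params, x) {
  stopifnot(inherits(params, "sdt_params"))
  post_S2 <- stats::plogis(log(params$p_S2 / params$p_S1) + x * params$d_prime)
  ifelse(x > params$c1, post_S2, 1 - post_S2)
}

# Probability masses of the eight stimulus x response x confidence cells,
# standard model (x2 = x1). Returned per stimulus: total response mass and
# high-confidence mass for each response. Shared backbone for summaries,
# rewards and outcome curves; `joint_type2_rates_exact()` produces the same
# structure for the process models.
t2_cells_standard <- function(params, crit) {
  check_consistency(crit, params)
  d <- params$d_prime; c1 <- params$c1
  mus <- c(S1 = -d / 2, S2 = d / 2)
  list(
    r_S2  = tail_above(c1, mus),          # P(resp "S2" | stim)
    r_S1  = tail_below(c1, mus),
    hc_S2 = tail_above(crit$c2_S2, mus),  # P(resp "S2" & high | stim)
    hc_S1 = tail_below(crit$c2_S1, mus)
  )
}

# Build a full type 2 summary from per-stimulus cell masses.
t2_summary_from_cells <- function(cells, params) {
  pS <- c(S1 = params$p_S1, S2 = params$p_S2)
  r_S2 <- cells$r_S2; r_S1 <- cells$r_S1
  hc_S2 <- cells$hc_S2; hc_S1 <- cells$hc_S1

  if (r_S2[["S1"]] == 0 && r_S2[["S2"]] == 0)
    stop("degenerate: the \"S2\" response has probability 0; type 2 rates undefined",
         call. = FALSE)
  if (r_S1[["S1"]] == 0 && r_S1[["S2"]] == 0)
    stop("degenerate: the \"S1\" response has probability 0; type 2 rates undefined",
         call. = FALSE)

  rate <- function(num, den) {
    if (den == 0)
      stop("degenerate response cell (probability 0); type 2 rate undefined",
           call. = FALSE)
    num / den
  }
  HR2_S2  <- rate(hc_S2[["S2"]], r_S2[["S2"]])
  FAR2_S2 <- rate(hc_S2[["S1"]], r_S2[["S1"]])
  HR2_S1  <- rate(hc_S1[["S1"]], r_S1[["S1"]])
  FAR2_S1 <- rate(hc_S1[["S2"]], r_S1[["S2"]])

  # overall rates: prior-weighted numerators over prior-weighted denominators
  p_corr_hi <- pS[["S2"]] * hc_S2[["S2"]] + pS[["S1"]] * hc_S1[["S1"]]
  p_corr    <- pS[["S2"]] * r_S2[["S2"]]  + pS[["S1"]] * r_S1[["S1"]]
  p_inc_hi  <- pS[["S1"]] * hc_S2[["S1"]] + pS[["S2"]] * hc_S1[["S2"]]
  p_inc     <- pS[["S1"]] * r_S2[["S1"]]  + pS[["S2"]] * r_S1[["S2"]]
  HR2  <- rate(p_corr_hi, p_corr)
  FAR2 <- rate(p_inc_hi, p_inc)

  p_resp_S2 <- pS[["S1"]] * r_S2[["S1"]] + pS[["S2"]] * r_S2[["S2"]]
  p_resp_S1 <- 1 - p_resp_S2
  p_corr_g_S2 <- pS[["S2"]] * r_S2[["S2"]] / p_resp_S2
  p_corr_g_S1 <- pS[["S1"]] * r_S1[["S1"]] / p_resp_S1

  structure(list(
    HR2_S2 = HR2_S2, FAR2_S2 = FAR2_S2,
    HR2_S1 = HR2_S1, FAR2_S1 = FAR2_S1,
    HR2 = HR2, FAR2 = FAR2,
    p_correct2 = p_corr * HR2 + p_inc * (1 - FAR2),
    p_correct2_S1 = p_corr_g_S1 * HR2_S1 + (1 - p_corr_g_S1) * (1 - FAR2_S1),
    p_correct2_S2 = p_corr_g_S2 * HR2_S2 + (1 - p_corr_g_S2) * (1 - FAR2_S2),
    D2 = HR2 - FAR2, D2_S1 = HR2_S1 - FAR2_S1, D2_S2 = HR2_S2 - FAR2_S2,
    p_high = unname(pS["S1"] * (hc_S1[["S1"]] + hc_S2[["S1"]]) +
                    pS["S2"] * (hc_S1[["S2"]] + hc_S2[["S2"]])),
    p_high_S1 = rate(pS[["S1"]] * hc_S1[["S1"]] + pS[["S2"]] * hc_S1[["S2"]],
                     p_resp_S1),
    p_high_S2 = rate(pS[["S1"]] * hc_S2[["S1"]] + pS[["S2"]] * hc_S2[["S2"]],
                     p_resp_S2),
    p_resp_S1 = p_resp_S1, p_resp_S2 = p_resp_S2
  ), class = "type2_summary")
}

#' Type 2 summary: response-specific and overall confidence rates
#'
#' Response-specific type 2 rates are truncated-normal mass ratios, e.g.
#' `HR2_S2 = P(x > c2_S2 | S2) / P(x > c1 | S2)`: the probability of high
#' confidence given a correct "S2" response. Overall rates weight the
#' response-specific numerators and denominators by the stimulus priors.
#' Also returned are the type 2 accuracies (overall and per response), the
#' differences `D2 = HR2 - FAR2`, and the marginal high-confidence and
#' response probabilities (`p_high`, `p_high_S1`, `p_high_S2`, `p_resp_S1`,
#' `p_resp_S2`) used when average confidence serves as a proxy measure of
#' criterion setting.
#'
#' @param params An [sdt_params()] object.
#' @param crit A [type2_criteria()] object satisfying the consistency
#'   constraint `c2_S1 <= c1 <= c2_S2`.
#' @return A list of class `type2_summary`; see Details for fields.
#' @examples
#' s <- type2_summary(sdt_params(2, 0, 0.5), type2_criteria(-1, 1))
#' s$p_high # ~0.52
#' @export
type2_summary <- function(params, crit) {
  stopifnot(inherits(params, "sdt_params"), inherits(crit, "type2_criteria"))
  t2_summary_from_cells(t2_cells_standard(params, crit), params)
}

#' @export
print.type2_summary <- function(x, ...) {
  cat(sprintf("Type 2 summary:\n  HR2 = %.4f, FAR2 = %.4f, p(correct2) = %.4f\n",
              x$HR2, x$FAR2, x$p_correct2))
  cat(sprintf("  \"S1\": HR2 = %.4f, FAR2 = %.4f;  \"S2\": HR2 = %.4f, FAR2 = %.4f\n",
              x$HR2_S1, x$FAR2_S1, x$HR2_S2, x$FAR2_S2))
  cat(sprintf("  p(high) = %.4f (\"S1\": %.4f, \"S2\": %.4f)\n",
              x$p_high, x$p_high_S1, x$p_high_S2))
  invisible(x)
}

#' Expected type 1 reward under a payoff matrix
#'
#' `E(reward1) = p(S2)[R_hit1 HR1 + R_miss1 (1 - HR1)] +
#'  p(S1)[R_CR1 (1 - FAR1) + R_FA1 FAR1]`.
#'
#' @param params An [sdt_params()] object.
#' @param rm A [reward_matrix1()].
#' @return Expected points per trial.
#' @export
expected_reward1 <- function(params, rm) {
  stopifnot(inherits(params, "sdt_params"), inherits(rm, "reward_matrix1"))
  t1 <- type1_summary(params)
  params$p_S2 * (rm$R_hit * t1$HR1 + rm$R_miss * (1 - t1$HR1)) +
    params$p_S1 * (rm$R_CR * (1 - t1$FAR1) + rm$R_FA * t1$FAR1)
}

#' Expected type 2 reward, per response and overall
#'
#' For each response the four joint outcome probabilities (stimulus by
#' confidence region, conditional on the response being given) are combined
#' with the type 2 payoffs: e.g. for "S2" responses,
#' `E(reward2,"S2") = p(hit1, LC | "S2") R_miss2 + p(hit1, HC | "S2") R_hit2
#'  + p(FA1, LC | "S2") R_CR2 + p(FA1, HC | "S2") R_FA2`.
#' The overall expectation weights the response-conditional expectations by
#' the response probabilities.
#'
#' @param params An [sdt_params()] object.
#' @param crit A [type2_criteria()] object.
#' @param rm A [reward_matrix2()].
#' @return List with `E_S1`, `E_S2` (response-conditional expectations) and
#'   `E_overall`.
#' @export
expected_reward2 <- function(params, crit, rm) {
  stopifnot(inherits(params, "sdt_params"), inherits(crit, "type2_criteria"),
            inherits(rm, "reward_matrix2"))
  cells <- t2_cells_standard(params, crit)
  reward2_from_cells(cells, params, rm)
}

reward2_from_cells <- function(cells, params, rm) {
  pS <- c(S1 = params$p_S1, S2 = params$p_S2)
  p_resp_S2 <- sum(pS * cells$r_S2)
  p_resp_S1 <- sum(pS * cells$r_S1)
  if (p_resp_S2 == 0 || p_resp_S1 == 0)
    stop("zero-probability response: conditional type 2 reward undefined",
         call. = FALSE)
  lc_S2 <- cells$r_S2 - cells$hc_S2
  lc_S1 <- cells$r_S1 - cells$hc_S1
  # "S2" responses: stim S2 -> type 1 hit (correct), stim S1 -> false alarm
  E_S2 <- (pS[["S2"]] * (lc_S2[["S2"]] * rm$R_miss + cells$hc_S2[["S2"]] * rm$R_hit) +
           pS[["S1"]] * (lc_S2[["S1"]] * rm$R_CR  + cells$hc_S2[["S1"]] * rm$R_FA)) /
    p_resp_S2
  # "S1" responses: stim S1 -> correct rejection, stim S2 -> miss
  E_S1 <- (pS[["S1"]] * (lc_S1[["S1"]] * rm$R_miss + cells$hc_S1[["S1"]] * rm$R_hit) +
           pS[["S2"]] * (lc_S1[["S2"]] * rm$R_CR  + cells$hc_S1[["S2"]] * rm$R_FA)) /
    p_resp_S1
  list(E_S1 = unname(E_S1), E_S2 = unname(E_S2),
       E_overall = unname(p_resp_S1 * E_S1 + p_resp_S2 * E_S2))
}

#' ROC points for the type 1 task or a response-specific type 2 task
#'
#' Type 1 points are obtained by sweeping the type 1 criterion over
#' `criteria`; type 2 points by sweeping the confidence criterion of the
#' requested response while `c1` stays fixed at its value in `params`.
#'
#' @param params An [sdt_params()] object.
#' @param criteria Strictly increasing criterion grid.
#' @param type `1` for the type 1 ROC, `2` for a type 2 ROC.
#' @param response For `type = 2`, which response's ROC (`"S2"` or `"S1"`).
#' @return A data.frame with columns `criterion`, `FAR`, `HR`.
#' @export
roc_points <- function(params, criteria, type = 1, response = c("S2", "S1")) {
  stopifnot(inherits(params, "sdt_params"), is.numeric(criteria))
  if (is.unsorted(criteria, strictly = TRUE))
    stop("`criteria` must be strictly increasing", call. = FALSE)
  d <- params$d_prime
  if (type == 1) {
    return(data.frame(criterion = criteria,
                      FAR = tail_above(criteria, -d / 2),
                      HR  = tail_above(criteria, d / 2)))
  }
  response <- match.arg(response)
  c1 <- params$c1
  if (response == "S2") {
    if (any(criteria < c1))
      stop("type 2 criteria for \"S2\" responses must be >= c1", call. = FALSE)
    den_hr <- tail_above(c1, d / 2); den_far <- tail_above(c1, -d / 2)
    if (den_hr == 0 || den_far == 0)
      stop("degenerate response cell: \"S2\" response has probability 0",
           call. = FALSE)
    HR  <- tail_above(criteria, d / 2) / den_hr
    FAR <- tail_above(criteria, -d / 2) / den_far
  } else {
    if (any(criteria > c1))
      stop("type 2 criteria for \"S1\" responses must be <= c1", call. = FALSE)
    den_hr <- tail_below(c1, -d / 2); den_far <- tail_below(c1, d / 2)
    if (den_hr == 0 || den_far == 0)
      stop("degenerate response cell: \"S1\" response has probability 0",
           call. = FALSE)
    HR  <- tail_below(criteria, -d / 2) / den_hr
    FAR <- tail_below(criteria, d / 2) / den_far
  }
  data.frame(criterion = criteria, FAR = FAR, HR = HR)
}
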