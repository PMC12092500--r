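# Generative models in which the evidence feeding the confidence judgment
# differs from the type 1 evidence: type 2 noise (x2 = x1 + e) and type 2
# signal loss (x2 = (1 - k) x1 + e). Under either model (x1, x2) are jointly
# normal per stimulus, so every confidence-cell probability is a bivariate
# normal rectangle mass; optima, for which no closed forms exist, come from
# grid search over those masses or over simulated trials.

# Per-stimulus joint moments of (x1, x2). mu is the stimulus mean of x1.
pm_moments <- function(pm, mu) {
  a <- 1 - pm$k
  list(mean = c(mu, a * mu),
       var2 = a^2 + pm$sigma2^2,
       cov = a)
}

# P(x1 > a, x2 > b | stimulus mean mu), vectorized over b.
pm_upper_mass <- function(pm, mu, a, b) {
  m <- pm_moments(pm, mu)
  if (pm$sigma2 == 0) {                       # x2 = (1-k) x1, monotone
    thr <- pmax(a, b / (1 - pm$k))
    return(stats::pnorm(thr, mean = mu, lower.tail = FALSE))
  }
  if (pm$k == 1) {                            # x2 independent of x1
    return(stats::pnorm(a, mean = mu, lower.tail = FALSE) *
             stats::pnorm(b, mean = 0, sd = pm$sigma2, lower.tail = FALSE))
  }
  sigma <- matrix(c(1, m$cov, m$cov, m$var2), 2)
  vapply(b, function(bi)
    mvtnorm::pmvnorm(lower = c(a, bi), upper = c(Inf, Inf),
                     mean = m$mean, sigma = sigma)[1],
    numeric(1))
}

# P(x1 <= a, x2 < b | stimulus mean mu), vectorized over b.
pm_lower_mass <- function(pm, mu, a, b) {
  m <- pm_moments(pm, mu)
  if (pm$sigma2 == 0) {
    thr <- pmin(a, b / (1 - pm$k))
    return(stats::pnorm(thr, mean = mu))
  }
  if (pm$k == 1) {
    return(stats::pnorm(a, mean = mu) *
             stats::pnorm(b, mean = 0, sd = pm$sigma2))
  }
  sigma <- matrix(c(1, m$cov, m$cov, m$var2), 2)
  vapply(b, function(bi)
    mvtnorm::pmvnorm(lower = c(-Inf, -Inf), upper = c(a, bi),
                     mean = m$mean, sigma = sigma)[1],
    numeric(1))
}

pm_cells <- function(pm, params, crit) {
  check_consistency(crit, params)
  d <- params$d_prime; c1 <- params$c1
  mus <- c(S1 = -d / 2, S2 = d / 2)
  list(
    r_S2  = vapply(mus, function(mu) tail_above(c1, mu), numeric(1)),
    r_S1  = vapply(mus, function(mu) tail_below(c1, mu), numeric(1)),
    hc_S2 = vapply(mus, function(mu) pm_upper_mass(pm, mu, c1, crit$c2_S2),
                   numeric(1)),
    hc_S1 = vapply(mus, function(mu) pm_lower_mass(pm, mu, c1, crit$c2_S1),
                   numeric(1))
  )
}

#' Simulate trials from a type 2 process model
#'
#' Draws `n` i.i.d. trials: stimulus from the prior, type 1 evidence
#' `x1 ~ N(+/- d'/2, 1)`, type 2 evidence `x2 = (1 - k) x1 + e` with
#' `e ~ N(0, sigma2^2)`, the response from `x1` versus `c1`, and confidence
#' from `x2` versus the response's type 2 criterion (high iff `x2 > c2_S2`
#' for "S2" responses, `x2 < c2_S1` for "S1" responses). The response's
#' criterion is compared against `x2` even when `x2` falls on the far side of
#' `c1` from the response; such trials are simply low confidence.
#'
#' @param pm A [process_model()].
#' @param params An [sdt_params()] object.
#' @param crit A [type2_criteria()] object.
#' @param n Number of trials (>= 1).
#' @param seed Integer seed; the output is fully reproducible from it.
#' @return A data.frame of class `trial_table` with columns `stimulus`
#'   ("S1"/"S2"), `x1`, `x2`, `response`, `confidence` ("low"/"high"),
#'   `correct` (logical), and a `meta` attribute recording model, parameters
#'   and seed.
#' @export
simulate_trials <- function(pm, params, crit, n, seed) {
  stopifnot(inherits(pm, "process_model"), inherits(params, "sdt_params"),
            inherits(crit, "type2_criteria"), n >= 1)
  if (missing(seed) || is.null(seed))
    stop("`seed` is required for reproducible simulation", call. = FALSE)
  check_consistency(crit, params)
  set.seed(seed)
  d <- params$d_prime
  is_S2 <- stats::runif(n) < params$p_S2
  x1 <- stats::rnorm(n, mean = ifelse(is_S2, d / 2, -d / 2))
  x2 <- (1 - pm$k) * x1
  if (pm$sigma2 > 0) x2 <- x2 + stats::rnorm(n, sd = pm$sigma2)
  resp_S2 <- x1 > params$c1
  high <- ifelse(resp_S2, x2 > crit$c2_S2, x2 < crit$c2_S1)
  out <- data.frame(
    stimulus = ifelse(is_S2, "S2", "S1"),
    x1 = x1, x2 = x2,
    response = ifelse(resp_S2, "S2", "S1"),
    confidence = ifelse(high, "high", "low"),
    correct = is_S2 == resp_S2,
    stringsAsFactors = FALSE
  )
  attr(out, "meta") <- list(model = pm$model, d_prime = d, c1 = params$c1,
                            p_S2 = params$p_S2, sigma2 = pm$sigma2, k = pm$k,
                            c2_S1 = crit$c2_S1, c2_S2 = crit$c2_S2,
                            seed = seed)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Exact type 2 rates under a process model
#'
#' Deterministic counterpart to Monte-Carlo simulation: per stimulus,
#' `(x1, x2)` are jointly normal with mean `(mu, (1 - k) mu)`, variances
#' `(1, (1 - k)^2 + sigma2^2)` and covariance `1 - k`, so every
#' stimulus-response-confidence cell is a bivariate normal rectangle mass
#' (computed with \pkg{mvtnorm}; the `sigma2 = 0` and `k = 1` boundary cases
#' reduce to univariate masses). Returns the same summary structure as
#' [type2_summary()], which it equals exactly under the standard model.
#'
#' @inheritParams simulate_trials
#' @return A `type2_summary` object.
#' @export
joint_type2_rates_exact <- function(pm, params, crit) {
  stopifnot(inherits(pm, "process_model"), inherits(params, "sdt_params"),
            inherits(crit, "type2_criteria"))
  if (pm$sigma2 == 0 && pm$k == 0)
    return(type2_summary(params, crit))
  t2_summary_from_cells(pm_cells(pm, params, crit), params)
}

# Outcome values over a c2 grid under a process model, exact engine.
outcome_values_pm_exact <- function(context, pm, params, extras, response, grid) {
  if (context == "calibration")
    return(pm_posterior_correct(pm, params, grid, response))
  d <- params$d_prime; c1 <- params$c1
  mus <- c(S1 = -d / 2, S2 = d / 2)
  if (response == "S2") {
    r  <- vapply(mus, function(mu) tail_above(c1, mu), numeric(1))
    hc <- lapply(mus, function(mu) pm_upper_mass(pm, mu, c1, grid))
    corr <- "S2"; inc <- "S1"
  } else {
    r  <- vapply(mus, function(mu) tail_below(c1, mu), numeric(1))
    hc <- lapply(mus, function(mu) pm_lower_mass(pm, mu, c1, grid))
    corr <- "S1"; inc <- "S2"
  }
  combine_outcome(context, params, extras, r, hc, corr, inc, response)
}

# Shared combination of response masses into the outcome measure. The value
# splits into a constant term (fixed by c1) plus a criterion-dependent term
# built from the high-confidence tail masses. The two are kept separate and
# the varying term attached as an attribute: far into a tail the varying
# term can be ~1e-16 of the constant, so maximizing the sum would drown the
# signal in rounding error, while the varying term alone is exact.
combine_outcome <- function(context, params, extras, r, hc, corr, inc, response) {
  pC <- c(S1 = params$p_S1, S2 = params$p_S2)
  p_resp <- pC[["S1"]] * r[["S1"]] + pC[["S2"]] * r[["S2"]]
  if (p_resp == 0 || any(r == 0))
    stop("degenerate response cell (probability 0) for response \"",
         response, "\"", call. = FALSE)
  parts <- switch(context,
    accuracy = list(
      const = pC[[inc]] * r[[inc]] / p_resp,
      vary = (pC[[corr]] * hc[[corr]] - pC[[inc]] * hc[[inc]]) / p_resp),
    hf = list(
      const = 0,
      vary = hc[[corr]] / r[[corr]] - hc[[inc]] / r[[inc]]),
    reward = {
      stopifnot(inherits(extras, "reward_matrix2"))
      list(
        const = (pC[[corr]] * r[[corr]] * extras$R_miss +
                 pC[[inc]] * r[[inc]] * extras$R_CR) / p_resp,
        vary = (pC[[corr]] * hc[[corr]] * (extras$R_hit - extras$R_miss) -
                pC[[inc]] * hc[[inc]] * (extras$R_CR - extras$R_FA)) / p_resp)
    },
    stop("unknown context: ", context, call. = FALSE))
  structure(parts$const + parts$vary, varying = parts$vary)
}

# Monte-Carlo outcome values with common random numbers: one simulated
# sample is reused for every grid point, so curves are smooth in the grid
# and the argmax is stable under the fixed seed.
outcome_values_pm_mc <- function(context, pm, params, extras, response, grid,
                                 n, seed) {
  if (context == "calibration")
    stop("the calibration crossing is found analytically; use engine = \"exact\"",
         call. = FALSE)
  set.seed(seed)
  d <- params$d_prime
  is_S2 <- stats::runif(n) < params$p_S2
  x1 <- stats::rnorm(n, mean = ifelse(is_S2, d / 2, -d / 2))
  x2 <- (1 - pm$k) * x1
  if (pm$sigma2 > 0) x2 <- x2 + stats::rnorm(n, sd = pm$sigma2)
  n_stim <- c(S1 = sum(!is_S2), S2 = sum(is_S2))
  in_resp <- if (response == "S2") x1 > params$c1 else x1 <= params$c1
  r <- c(S1 = sum(in_resp & !is_S2) / n_stim[["S1"]],
         S2 = sum(in_resp & is_S2) / n_stim[["S2"]])
  hc <- lapply(c(S1 = FALSE, S2 = TRUE), function(s2) {
    xs <- sort(x2[in_resp & (is_S2 == s2)])
    cnt_le <- findInterval(grid, xs)
    cnt <- if (response == "S2") length(xs) - cnt_le else cnt_le
    cnt / n_stim[[if (s2) "S2" else "S1"]]
  })
  corr <- response; inc <- setdiff(c("S1", "S2"), response)
  combine_outcome(context, params, extras, r, hc, corr, inc, response)
}

# Posterior probability that the type 1 response is correct given the type 2
# evidence x2 = v, under a process model. Vectorized over v.
pm_posterior_correct <- function(pm, params, v, response) {
  d <- params$d_prime; c1 <- params$c1
  mus <- c(S1 = -d / 2, S2 = d / 2)
  pC <- c(S1 = params$p_S1, S2 = params$p_S2)
  w <- lapply(c("S1", "S2"), function(s) {
    mu <- mus[[s]]
    m <- pm_moments(pm, mu)
    if (pm$sigma2 == 0) {             # x2 determines x1 = v / (1 - k)
      x1v <- v / (1 - pm$k)
      dens <- stats::dnorm(v, mean = m$mean[2], sd = sqrt(m$var2))
      reg <- if (response == "S2") as.numeric(x1v > c1) else as.numeric(x1v <= c1)
      return(pC[[s]] * dens * reg)
    }
    sd2 <- sqrt(m$var2)
    dens <- stats::dnorm(v, mean = m$mean[2], sd = sd2)
    cond_mean <- mu + (m$cov / m$var2) * (v - m$mean[2])
    cond_sd <- sqrt(1 - m$cov^2 / m$var2)
    reg <- if (response == "S2")
      stats::pnorm(c1, mean = cond_mean, sd = cond_sd, lower.tail = FALSE)
    else stats::pnorm(c1, mean = cond_mean, sd = cond_sd)
    pC[[s]] * dens * reg
  })
  names(w) <- c("S1", "S2")
  tot <- w$S1 + w$S2
  if (response == "S2") w$S2 / tot else w$S1 / tot
}

#' Model-aware optimal type 2 criteria by grid search
#'
#' Evaluates the outcome measure per grid point under the process model
#' (exact bivariate masses, or Monte-Carlo with one common sample across all
#' grid points) and returns the argmax for each response together with the
#' full curves. For the calibration context the criterion is the posterior
#' crossing found by root finding, not an argmax. With `sigma2 = 0, k = 0`
#' the result recovers the closed-form optimum within one grid step.
#'
#' @inheritParams outcome_curve
#' @param step,width Grid spec passed to [c2_grid()] when `grid` is `NULL`.
#' @return List with `optimal` (an `optimal_criteria` object, clipping flags
#'   set when the argmax sits at `c1`) and `curves` (list of
#'   [outcome_curve()] objects per response; `NULL` for calibration).
#' @export
optimize_c2_under_model <- function(context = c("reward", "hf", "accuracy", "calibration"),
                                    pm, params, extras = NULL,
                                    grid = NULL, engine = c("exact", "mc"),
                                    n = 1e6, seed = NULL,
                                    step = 1e-3, width = 6) {
  context <- match.arg(context)
  engine <- match.arg(engine)
  stopifnot(inherits(pm, "process_model"), inherits(params, "sdt_params"))
  if (context == "calibration") {
    if (is.numeric(extras)) extras <- calibration_target(extras)
    stopifnot(inherits(extras, "calibration_target"))
    c2_S2 <- calibration_crossing(params, extras, "S2", pm = pm)
    c2_S1 <- calibration_crossing(params, extras, "S1", pm = pm)
    opt <- new_optimal_criteria("calibration", params$c1, NA_real_, c2_S1, c2_S2)
    return(list(optimal = opt, curves = NULL))
  }
  curves <- lapply(c(S1 = "S1", S2 = "S2"), function(resp) {
    g <- if (is.null(grid)) c2_grid(params, resp, step = step, width = width)
         else grid[[resp]]
    outcome_curve(context, params, extras, resp, g, pm, engine, n, seed)
  })
  am <- lapply(curves, argmax_c2)
  opt <- new_optimal_criteria(context, params$c1, NA_real_,
                              am$S1$c2, am$S2$c2)
  opt$value_S1 <- am$S1$value
  opt$value_S2 <- am$S2$value
  list(optimal = opt, curves = curves)
}

#' Outcome cost of ignoring metacognitive suboptimality
#'
#' Compares, under the process model, the outcome at the model-aware optimal
#' type 2 criteria with the outcome at the criteria an observer would use if
#' they ignored the type 2 noise or signal loss (the standard-model closed
#' forms). The difference is non-negative by construction (up to grid
#' resolution).
#'
#' @inheritParams optimize_c2_under_model
#' @param context One of `"reward"`, `"hf"`, `"accuracy"` (contexts with a
#'   maximand; calibration prescribes a crossing, not a maximum).
#' @return List per response (`S1`, `S2`) with elements `aware`, `naive`
#'   (criterion and outcome value each) and `cost = aware - naive` on the
#'   outcome scale.
#' @export
cost_of_ignoring_suboptimality <- function(context = c("reward", "hf", "accuracy"),
                                           pm, params, extras = NULL,
                                           step = 1e-3, width = 6) {
  context <- match.arg(context)
  aware <- optimize_c2_under_model(context, pm, params, extras,
                                   engine = "exact", step = step, width = width)
  naive <- switch(context,
    accuracy = c2_opt_accuracy(params),
    reward = {
      Q2 <- if (inherits(extras, "reward_matrix2")) reward_quotient(extras)
            else stop("reward context requires a reward_matrix2", call. = FALSE)
      c2_opt_reward(params, Q2 = Q2)
    },
    hf = c2_opt_hf(params))
  val_at <- function(resp, c2) {
    outcome_values_pm_exact(context, pm, params, extras, resp, c2)
  }
  out <- lapply(c(S1 = "S1", S2 = "S2"), function(resp) {
    c2_aware <- if (resp == "S1") aware$optimal$c2_S1_star else aware$optimal$c2_S2_star
    v_aware  <- if (resp == "S1") aware$optimal$value_S1 else aware$optimal$value_S2
    c2_naive <- if (resp == "S1") naive$c2_S1_star else naive$c2_S2_star
    v_naive <- val_at(resp, c2_naive)
    list(aware = list(c2 = c2_aware, value = v_aware),
         naive = list(c2 = c2_naive, value = v_naive),
         cost = v_aware - v_naive)
  })
  out
}

#' Sweep a process-model parameter: M-ratio and model-aware optima
#'
#' For each process model in `pm_list`, computes the metacognitive
#' efficiency M-ratio (by fitting meta-d' to exact expected confidence
#' counts at the policy criteria) and the model-aware optimal type 2
#' criteria for each requested context.
#'
#' @param pm_list List of [process_model()] objects.
#' @param params An [sdt_params()] object.
#' @param crit_policy Function `params -> type2_criteria` giving the
#'   criteria under which the M-ratio is measured; default `c1 +/- 1`.
#' @param contexts Optimization contexts to sweep (default reward and hf).
#' @param extras Named list of per-context extras (e.g.
#'   `list(reward = reward_matrix2(1, 0, 3, 0))`).
#' @param step Grid step for the optimizations.
#' @return A tidy data.frame: one row per model and context with columns
#'   `model`, `sigma2`, `k`, `m_ratio`, `context`, `c2_S1_star`,
#'   `c2_S2_star`.
#' @export
sweep_parameter <- function(pm_list, params, crit_policy = NULL,
                            contexts = c("reward", "hf"), extras = list(),
                            step = 1e-3) {
  stopifnot(is.list(pm_list), all(vapply(pm_list, inherits, logical(1),
                                         "process_model")))
  if (is.null(crit_policy))
    crit_policy <- function(p) type2_criteria(p$c1 - 1, p$c1 + 1)
  rows <- lapply(pm_list, function(pm) {
    crit <- crit_policy(params)
    fit <- fit_metad(expected_counts(pm, params, crit, n = 1e5))
    do.call(rbind, lapply(contexts, function(ctx) {
      ex <- extras[[ctx]]
      opt <- optimize_c2_under_model(ctx, pm, params, ex, engine = "exact",
                                     step = step)$optimal
      data.frame(model = pm$model, sigma2 = pm$sigma2, k = pm$k,
                 m_ratio = fit$m_ratio, context = ctx,
                 c2_S1_star = opt$c2_S1_star, c2_S2_star = opt$c2_S2_star,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
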