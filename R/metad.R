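# Meta-d' and M-ratio estimation from binary-confidence count data.
#
# meta-d' answers: what d' would a hypothetical SDT-ideal observer need in
# order to reproduce the observed type 2 (confidence) data? It is fitted by
# maximum likelihood on the confidence counts conditional on each response,
# with the type 1 criterion carried over in relative units
# (meta_c = (c1 / d') * meta_d). M_ratio = meta_d / d' equals 1 when the
# standard SDT model holds and drops below 1 under type 2 noise or signal
# loss.

counts_template <- function() {
  expand.grid(stimulus = c("S1", "S2"), response = c("S1", "S2"),
              confidence = c("low", "high"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Binary-confidence count table
#'
#' Validates and normalizes an 8-row stimulus x response x confidence count
#' table (non-negative, possibly fractional when derived from expected cell
#' masses).
#'
#' @param df Data.frame with columns `stimulus` ("S1"/"S2"), `response`
#'   ("S1"/"S2"), `confidence` ("low"/"high") and `count`.
#' @return The table in canonical row order, class `confidence_counts`.
#' @export
confidence_counts <- function(df) {
  need <- c("stimulus", "response", "confidence", "count")
  if (!all(need %in% names(df)))
    stop("counts need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(df$stimulus %in% c("S1", "S2")) ||
      !all(df$response %in% c("S1", "S2")) ||
      !all(df$confidence %in% c("low", "high")))
    stop("unknown category labels in counts table", call. = FALSE)
  if (any(df$count < 0) || anyNA(df$count))
    stop("counts must be non-negative", call. = FALSE)
  tmpl <- counts_template()
  key <- function(d) paste(d$stimulus, d$response, d$confidence)
  agg <- tapply(df$count, key(df), sum)
  tmpl$count <- as.numeric(agg[key(tmpl)])
  tmpl$count[is.na(tmpl$count)] <- 0
  if (sum(tmpl$count) <= 0) stop("empty counts table", call. = FALSE)
  structure(tmpl, class = c("confidence_counts", "data.frame"))
}

#' Cross-tabulate a simulated trial table into confidence counts
#'
#' @param trials A `trial_table` from [simulate_trials()] (or any data.frame
#'   with `stimulus`, `response`, `confidence` columns).
#' @return A [confidence_counts()] table; counts sum to `nrow(trials)`.
#' @export
counts_from_trials <- function(trials) {
  if (nrow(trials) == 0) stop("empty trial table", call. = FALSE)
  df <- data.frame(stimulus = trials$stimulus, response = trials$response,
                   confidence = trials$confidence, count = 1,
                   stringsAsFactors = FALSE)
  confidence_counts(df)
}

#' Expected confidence counts under a process model
#'
#' Exact cell masses times `n`: the deterministic stand-in for simulating
#' and tabulating `n` trials, useful for noise-free parameter sweeps.
#'
#' @inheritParams simulate_trials
#' @param n Notional trial count scaling the cell masses.
#' @return A [confidence_counts()] table with fractional counts.
#' @export
expected_counts <- function(pm, params, crit, n = 1e5) {
  cells <- if (pm$sigma2 == 0 && pm$k == 0) t2_cells_standard(params, crit)
           else pm_cells(pm, params, crit)
  pS <- c(S1 = params$p_S1, S2 = params$p_S2)
  tmpl <- counts_template()
  mass <- mapply(function(s, r, conf) {
    hc <- if (r == "S2") cells$hc_S2[[s]] else cells$hc_S1[[s]]
    tot <- if (r == "S2") cells$r_S2[[s]] else cells$r_S1[[s]]
    pS[[s]] * if (conf == "high") hc else tot - hc
  }, tmpl$stimulus, tmpl$response, tmpl$confidence)
  tmpl$count <- n * as.numeric(mass)
  structure(tmpl, class = c("confidence_counts", "data.frame"))
}

counts_array <- function(counts) {
  a <- array(0, dim = c(2, 2, 2),
             dimnames = list(stimulus = c("S1", "S2"),
                             response = c("S1", "S2"),
                             confidence = c("low", "high")))
  for (i in seq_len(nrow(counts)))
    a[counts$stimulus[i], counts$response[i], counts$confidence[i]] <-
      counts$count[i]
  a
}

#' Fit meta-d' to a binary-confidence count table
#'
#' Type 1 quantities come from the type 1 marginals:
#' `d' = z(HR1) - z(FAR1)`, `c1 = -(z(HR1) + z(FAR1)) / 2`. meta-d' and one
#' type 2 criterion per response are then fitted by maximizing the
#' multinomial likelihood of the confidence counts conditional on each
#' response, under the equal-variance model with the relative type 1
#' criterion preserved: `meta_c = (c1 / d') * meta_d`. The 3-parameter
#' search is bounded (`meta_d` in `[0, 5 d']`) and multi-started from
#' `{0.5, 1, 1.5} d'` to avoid local optima.
#'
#' If any cell is zero and `zero_correction` is `TRUE` (default), 0.5 is
#' added to every cell before fitting (the standard log-linear correction).
#'
#' @param counts A [confidence_counts()] table (both response cells must be
#'   non-empty, and both confidence levels must occur).
#' @param zero_correction Apply the add-0.5 correction when any cell is 0.
#' @return A list of class `metad_fit`: `meta_d`, `meta_c`, `meta_c2_S1`,
#'   `meta_c2_S2`, `m_ratio`, `logL`, `d_prime`, `c1`.
#' @export
fit_metad <- function(counts, zero_correction = TRUE) {
  counts <- confidence_counts(counts)
  a <- counts_array(counts)
  if (zero_correction && any(a == 0)) a <- a + 0.5
  n_resp <- apply(a, "response", sum)
  if (any(n_resp == 0))
    stop("both response cells must be non-empty to fit meta-d'", call. = FALSE)
  n_conf <- apply(a, "confidence", sum)
  if (any(n_conf == 0))
    stop("confidence is constant across trials: type 2 data are uninformative",
         call. = FALSE)

  n_stim <- apply(a, "stimulus", sum)
  HR1  <- sum(a["S2", "S2", ]) / n_stim[["S2"]]
  FAR1 <- sum(a["S1", "S2", ]) / n_stim[["S1"]]
  zH <- stats::qnorm(HR1); zF <- stats::qnorm(FAR1)
  d_prime <- zH - zF
  c1 <- -(zH + zF) / 2
  if (!is.finite(d_prime) || d_prime <= 0)
    stop("type 1 marginals give d' <= 0; meta-d' and M-ratio are not ",
         "interpretable for this table", call. = FALSE)
  c_rel <- c1 / d_prime

  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  nll <- function(theta) {
    md <- theta[1]; off1 <- theta[2]; off2 <- theta[3]
    mc <- c_rel * md
    mus <- c(S1 = -md / 2, S2 = md / 2)
    ll <- 0
    for (s in c("S1", "S2")) {
      den2 <- tail_above(mc, mus[[s]])
      den1 <- 1 - den2
      p_hi2 <- clamp(tail_above(mc + off2, mus[[s]]) / clamp(den2))
      p_hi1 <- clamp(tail_below(mc - off1, mus[[s]]) / clamp(den1))
      ll <- ll +
        a[s, "S2", "high"] * log(p_hi2) + a[s, "S2", "low"] * log1p(-p_hi2) +
        a[s, "S1", "high"] * log(p_hi1) + a[s, "S1", "low"] * log1p(-p_hi1)
    }
    -ll
  }

  starts <- lapply(c(0.5, 1, 1.5), function(f) c(f * d_prime, 0.5, 0.5))
  fits <- lapply(starts, function(s0) {
    tryCatch(
      stats::optim(s0, nll, method = "L-BFGS-B",
                   lower = c(0, 0, 0), upper = c(5 * d_prime, 10, 10)),
      error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (length(fits) == 0)
    stop("meta-d' fit did not converge from any start", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  md <- best$par[1]; mc <- c_rel * md
  structure(list(
    meta_d = md, meta_c = mc,
    meta_c2_S1 = mc - best$par[2], meta_c2_S2 = mc + best$par[3],
    m_ratio = md / d_prime, logL = -best$value,
    d_prime = d_prime, c1 = c1
  ), class = "metad_fit")
}

#' @export
print.metad_fit <- function(x, ...) {
  cat(sprintf("meta-d' fit: meta-d' = %.3f, d' = %.3f, M-ratio = %.3f\n",
              x$meta_d, x$d_prime, x$m_ratio))
  cat(sprintf("  meta-c = %.3f, meta-c2 = (%.3f, %.3f), logL = %.2f\n",
              x$meta_c, x$meta_c2_S1, x$meta_c2_S2, x$logL))
  invisible(x)
}

#' M-ratio across a grid of process models
#'
#' For each model, either computes exact expected confidence counts
#' (`engine = "exact"`, deterministic) or simulates `n` trials
#' (`engine = "mc"`), then fits meta-d' and tabulates the M-ratio.
#'
#' @inheritParams sweep_parameter
#' @param n Trials per model (notional for the exact engine).
#' @param seed Base seed for `engine = "mc"` (incremented per model).
#' @param engine `"exact"` or `"mc"`.
#' @return Data.frame with columns `model`, `sigma2`, `k`, `meta_d`,
#'   `d_prime`, `m_ratio`.
#' @export
sweep_mratio <- function(pm_list, params, crit_policy = NULL, n = 1e5,
                         seed = NULL, engine = c("exact", "mc")) {
  engine <- match.arg(engine)
  if (is.null(crit_policy))
    crit_policy <- function(p) type2_criteria(p$c1 - 1, p$c1 + 1)
  if (engine == "mc" && is.null(seed))
    stop("`seed` is required for engine = \"mc\"", call. = FALSE)
  rows <- lapply(seq_along(pm_list), function(i) {
    pm <- pm_list[[i]]
    crit <- crit_policy(params)
    counts <- if (engine == "exact") expected_counts(pm, params, crit, n)
              else counts_from_trials(simulate_trials(pm, params, crit, n,
                                                      seed + i - 1L))
    fit <- fit_metad(counts)
    data.frame(model = pm$model, sigma2 = pm$sigma2, k = pm$k,
               meta_d = fit$meta_d, d_prime = fit$d_prime,
               m_ratio = fit$m_ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
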