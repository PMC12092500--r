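test_that("process model constructor enforces the model taxonomy", {
  expect_equal(process_model("standard")$sigma2, 0)
  expect_equal(process_model("loss")$sigma2, 0.1)   # small default type 2 noise
  expect_error(process_model("standard", sigma2 = 0.5), "standard")
  expect_error(process_model("noise", sigma2 = 0.5, k = 0.2), "noise")
  expect_error(process_model("loss", sigma2 = 0, k = 1), "degenerate")
})

test_that("simulated trials follow the generative rules and the seed", {
  p <- p_unbiased()
  crit <- type2_criteria(-1, 1)
  tr <- simulate_trials(process_model("standard"), p, crit, 5000, seed = 11)
  expect_identical(tr$x1, tr$x2)   # no type 2 noise: same evidence
  expect_identical(tr$response, ifelse(tr$x1 > 0, "S2", "S1"))
  expect_identical(tr$correct, tr$stimulus == tr$response)
  expect_identical(tr$confidence,
                   ifelse(tr$response == "S2",
                          ifelse(tr$x2 > 1, "high", "low"),
                          ifelse(tr$x2 < -1, "high", "low")))
  # reproducible from the seed alone
  tr2 <- simulate_trials(process_model("standard"), p, crit, 5000, seed = 11)
  expect_identical(tr, tr2)
  # stimulus frequencies converge to the prior
  big <- simulate_trials(process_model("standard"), sdt_params(1, 0, 0.3),
                         crit, 2e5, seed = 3)
  expect_within_3se(mean(big$stimulus == "S2"), 0.3, 2e5, "p(S2)")
})

test_that("pure-noise confidence (k = 1) carries no information about accuracy", {
  p <- p_unbiased()
  crit <- type2_criteria(-0.5, 0.5)
  pm <- process_model("loss", sigma2 = 0.5, k = 1)
  # exact: high-confidence rate identical for correct and incorrect trials
  ex <- joint_type2_rates_exact(pm, p, crit)
  expect_equal(ex$HR2_S2, ex$FAR2_S2, tolerance = 1e-12)
  expect_equal(ex$HR2_S1, ex$FAR2_S1, tolerance = 1e-12)
  # Monte-Carlo confirms
  tr <- simulate_trials(pm, p, crit, 2e5, seed = 5)
  emp <- empirical_t2(tr)
  expect_lt(abs(emp$HR2 - emp$FAR2), 0.015)
})

test_that("exact bivariate rates reduce to the standard model and match Monte-Carlo", {
  p <- p_unbiased()
  crit <- type2_criteria(-0.84, 0.84)
  std <- joint_type2_rates_exact(process_model("standard"), p, crit)
  ref <- type2_summary(p, crit)
  for (f in names(ref)) expect_equal(std[[f]], ref[[f]], tolerance = 1e-12)

  set.seed(21)
  cases <- list(process_model("noise", sigma2 = 0.8),
                process_model("loss", sigma2 = 0.1, k = 0.5),
                process_model("loss", sigma2 = 0.6, k = 0.3))
  for (i in seq_along(cases)) {
    pm <- cases[[i]]
    n <- 3e5
    ex <- joint_type2_rates_exact(pm, p, crit)
    tr <- simulate_trials(pm, p, crit, n, seed = 300 + i)
    emp <- empirical_t2(tr)
    expect_within_3se(emp$p_high, ex$p_high, n, "p_high")
    expect_within_3se(emp$HR2, ex$HR2, sum(tr$correct), "HR2")
    expect_within_3se(emp$FAR2, ex$FAR2, sum(!tr$correct), "FAR2")
    expect_within_3se(emp$HR2_S2, ex$HR2_S2,
                      sum(tr$correct & tr$response == "S2"), "HR2_S2")
  }
})

test_that("grid search under the standard model recovers the closed forms", {
  p <- p_unbiased()
  opt <- optimize_c2_under_model("reward", process_model("standard"), p,
                                 reward_matrix2(1, 0, 3, 0), engine = "exact",
                                 step = 1e-3, width = 3)
  expect_lt(abs(opt$optimal$c2_S2_star - log(3) / 2), 1e-3 + 1e-9)
  expect_lt(abs(opt$optimal$c2_S1_star + log(3) / 2), 1e-3 + 1e-9)
})

test_that("type 2 noise shifts reward optima inward and HF optima outward", {
  p <- p_unbiased()
  pm <- process_model("noise", sigma2 = 0.8)
  rm <- reward_matrix2(1, 0, 3, 0)
  step <- 2e-3
  cv_r <- outcome_curve("reward", p, rm, "S2",
                        grid = c2_grid(p, "S2", step = step, width = 3),
                        pm = pm, engine = "exact")
  expect_lt(argmax_c2(cv_r)$c2, log(3) / 2 - step)   # strictly more liberal

  cv_h <- outcome_curve("hf", p, NULL, "S2",
                        grid = c2_grid(p, "S2", step = step, width = 3),
                        pm = pm, engine = "exact")
  hf0 <- c2_opt_hf(p)$c2_S2_star
  expect_gt(argmax_c2(cv_h)$c2, hf0 + step)          # strictly more conservative
})

test_that("signal loss shifts both reward and HF optima inward", {
  p <- p_unbiased()
  pm <- process_model("loss", sigma2 = 0.1, k = 0.5)
  step <- 2e-3
  cv_r <- outcome_curve("reward", p, reward_matrix2(1, 0, 3, 0), "S2",
                        grid = c2_grid(p, "S2", step = step, width = 3),
                        pm = pm, engine = "exact")
  expect_lt(argmax_c2(cv_r)$c2, log(3) / 2 - step)
  cv_h <- outcome_curve("hf", p, NULL, "S2",
                        grid = c2_grid(p, "S2", step = step, width = 3),
                        pm = pm, engine = "exact")
  expect_lt(argmax_c2(cv_h)$c2, c2_opt_hf(p)$c2_S2_star - step)
})

test_that("Monte-Carlo curves reuse one sample and approximate the exact argmax", {
  p <- p_unbiased()
  pm <- process_model("noise", sigma2 = 0.8)
  rm <- reward_matrix2(1, 0, 3, 0)
  g <- c2_grid(p, "S2", step = 0.01, width = 3)
  c1v <- outcome_curve("reward", p, rm, "S2", g, pm, "mc", n = 2e5, seed = 9)
  c2v <- outcome_curve("reward", p, rm, "S2", g, pm, "mc", n = 2e5, seed = 9)
  expect_identical(c1v$values, c2v$values)   # common random numbers
  cex <- outcome_curve("reward", p, rm, "S2", g, pm, "exact")
  expect_lt(abs(argmax_c2(c1v)$c2 - argmax_c2(cex)$c2), 0.25)
  expect_error(outcome_curve("reward", p, rm, "S2", g, pm, "mc", n = 100),
               "seed")
})

test_that("ignoring metacognitive suboptimality costs outcome, more so under signal loss", {
  p <- p_unbiased()
  rm <- reward_matrix2(1, 0, 3, 0)
  # no suboptimality: no cost
  c0 <- cost_of_ignoring_suboptimality("reward", process_model("standard"),
                                       p, rm, step = 5e-3, width = 3)
  expect_lt(abs(c0$S2$cost), 1e-4)   # zero up to grid quantization

  cn <- cost_of_ignoring_suboptimality("hf", process_model("noise", sigma2 = 0.8),
                                       p, step = 5e-3, width = 3)
  cl <- cost_of_ignoring_suboptimality("hf", process_model("loss", sigma2 = 0.1,
                                                           k = 0.5),
                                       p, step = 5e-3, width = 3)
  expect_gte(cn$S2$cost, 0)
  expect_gt(cl$S2$cost, 0)
  expect_gt(cl$S2$cost, cn$S2$cost)   # signal loss hurts much more than noise

  cr <- cost_of_ignoring_suboptimality("reward", process_model("noise", sigma2 = 0.8),
                                       p, rm, step = 5e-3, width = 3)
  expect_gte(cr$S2$cost, 0)
  expect_lt(cr$S2$cost, 0.1)          # the reward loss is comparatively small
})

test_that("parameter sweep tabulates decreasing M-ratio with model-aware optima", {
  p <- p_unbiased()
  pms <- list(process_model("standard"), process_model("noise", sigma2 = 0.8))
  sw <- sweep_parameter(pms, p, contexts = "reward",
                        extras = list(reward = reward_matrix2(1, 0, 3, 0)),
                        step = 5e-3)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$m_ratio[1], 1, tolerance = 1e-3)
  expect_lt(sw$m_ratio[2], sw$m_ratio[1])
  expect_lt(sw$c2_S2_star[2], sw$c2_S2_star[1])
})
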