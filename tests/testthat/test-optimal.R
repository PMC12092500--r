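test_that("accuracy-optimal type 1 criterion follows the prior log-odds", {
  expect_equal(c1_opt_accuracy(1.7, 0.5), 0)
  expect_equal(c1_opt_accuracy(1, 1/3), log(2))
  expect_gt(c1_opt_accuracy(2, 0.15), 0)   # rare S2: conservative
  # d' = 0 edge: flat with equal priors, prior-dominated otherwise
  expect_equal(c1_opt_accuracy(0, 0.5), 0)
  expect_equal(c1_opt_accuracy(0, 0.3), Inf)
  expect_equal(c1_opt_accuracy(0, 0.7), -Inf)
})

test_that("reward-optimal type 1 criterion shifts by log Q1 and errors when Q1 undefined", {
  p <- 0.5
  expect_equal(c1_opt_reward(2, p, reward_matrix1(1, 0, 1, 0)),
               c1_opt_accuracy(2, p))
  expect_equal(c1_opt_reward(2, 0.5, reward_matrix1(1, 0, 2, 0)), log(2) / 2)
  # grid-search confirmation
  cgrid <- seq(-2, 2, by = 1e-3)
  er <- vapply(cgrid, function(cc)
    expected_reward1(sdt_params(2, cc, 0.5), reward_matrix1(1, 0, 2, 0)),
    numeric(1))
  expect_lt(abs(cgrid[which.max(er)] - log(2) / 2), 1.5e-3)
  # Q1 = 3 overrides a 2:1 prior in favour of S2
  expect_gt(c1_opt_reward(1, 2/3, reward_matrix1(1, 0, 3, 0)), 0)
  # pathologies
  expect_error(c1_opt_reward(2, 0.5, reward_matrix1(1, 1, 2, 0)), "undefined")
  expect_error(c1_opt_reward(2, 0.5, reward_matrix1(0, 1, 0, 2)), "minimum")
})

test_that("HF-optimal type 1 criterion is zero and is the numeric argmax", {
  expect_identical(c1_opt_hf(), 0)
  cgrid <- seq(-3, 3, by = 1e-3)
  for (d in c(0.8, 2)) {
    hf <- vapply(cgrid, function(cc) {
      t <- type1_summary(sdt_params(d, cc, 0.5)); t$HR1 - t$FAR1
    }, numeric(1))
    expect_lt(abs(cgrid[which.max(hf)]), 1.5e-3)
  }
})

test_that("accuracy-optimal type 2 criteria hug c1_A with consistency clipping", {
  # optimal type 1 criterion: never report low confidence
  o0 <- c2_opt_accuracy(p_unbiased())
  expect_equal(o0$c2_S1_star, 0)
  expect_equal(o0$c2_S2_star, 0)
  expect_false(o0$clipped_S1 || o0$clipped_S2)

  # liberal c1 = -1: the "S1" criterion is pinned at c1
  om <- c2_opt_accuracy(sdt_params(2, -1, 0.5))
  expect_equal(om$c2_S1_star, -1)
  expect_true(om$clipped_S1)
  expect_equal(om$c2_S2_star, 0)
  expect_false(om$clipped_S2)

  # conservative mirror
  op <- c2_opt_accuracy(sdt_params(2, 0.7, 0.5))
  expect_equal(op$c2_S1_star, 0)
  expect_equal(op$c2_S2_star, 0.7)
  expect_true(op$clipped_S2)
})

test_that("reward- and calibration-optimal type 2 criteria coincide when Q2 = O_T", {
  p <- p_unbiased()
  # Q2 = 1 reduces to the accuracy optimum
  expect_equal(c2_opt_reward(p, Q2 = 1)$c2_S2_star,
               c2_opt_accuracy(p)$c2_S2_star)
  r3 <- c2_opt_reward(p, Q2 = 3)
  expect_equal(r3$c2_S2_star, log(3) / 2, tolerance = 1e-12)
  expect_equal(r3$c2_S1_star, -log(3) / 2, tolerance = 1e-12)
  expect_equal(c2_opt_reward(p, Q2 = 5.37)$c2_S2_star, log(5.37) / 2)

  # calibration: p_T = 0.5 reduces to accuracy; p_T = 0.8 gives ln(4)/d'
  expect_equal(c2_opt_calibration(p, 0.5)$c2_S2_star,
               c2_opt_accuracy(p)$c2_S2_star)
  c8 <- c2_opt_calibration(p, 0.8)
  expect_equal(c8$c2_S2_star, log(4) / 2, tolerance = 1e-12)

  # the posterior at the unclipped calibration criterion equals the target
  for (pt in c(0.6, 0.8, 0.95)) {
    pr <- sdt_params(1.5, -0.3, 0.4)
    cc <- c2_opt_calibration(pr, pt)
    expect_equal(p_correct_given_x(pr, cc$c2_S2_star), pt, tolerance = 1e-12)
  }

  # Q2 <-> O_T equivalence for arbitrary parameters
  pr <- sdt_params(1.2, 0.4, 0.3)
  tg <- calibration_target(0.75)
  rq <- c2_opt_reward(pr, Q2 = tg$O_T)
  cq <- c2_opt_calibration(pr, tg)
  expect_equal(rq$c2_S2_star, cq$c2_S2_star)
  expect_equal(rq$c2_S1_star, cq$c2_S1_star)

  # symmetry about c1_A when unclipped
  pr2 <- sdt_params(2, 0, 0.35)
  c1A <- c1_opt_accuracy(2, 0.35)
  rr <- c2_opt_reward(sdt_params(2, c1A, 0.35), Q2 = 2)
  expect_equal(rr$c2_S2_star - c1A, c1A - rr$c2_S1_star, tolerance = 1e-12)
})

test_that("HF-optimal type 2 criteria use the type 1 rates and keep their signs", {
  p <- p_unbiased()
  h <- c2_opt_hf(p)
  expect_equal(h$c2_S2_star, log(pnorm(1) / pnorm(-1)) / 2, tolerance = 1e-12)
  expect_equal(h$c2_S1_star, -h$c2_S2_star, tolerance = 1e-12)

  # equivalent to calibrating at the observer's own overall accuracy
  ceq <- c2_opt_calibration(p, type1_summary(p)$p_correct1)
  expect_equal(h$c2_S2_star, ceq$c2_S2_star, tolerance = 1e-12)

  # unclipped optima stay positive/negative across d' and c1
  for (d in c(0.5, 1, 2, 4)) for (c1 in c(-1, 0, 1)) {
    hh <- c2_opt_hf(sdt_params(d, c1, 0.5))
    raw_S2 <- log(type1_summary(sdt_params(d, c1, 0.5))$HR1 /
                  type1_summary(sdt_params(d, c1, 0.5))$FAR1) / d
    expect_gt(raw_S2, 0)
    expect_gte(hh$c2_S2_star, max(0, c1) - 1e-12)
  }
  expect_error(c2_opt_hf(sdt_params(0, 0, 0.5)), "d_prime = 0")

  # externally supplied rates are honoured
  hx <- c2_opt_hf(p, HR1 = 0.9, FAR1 = 0.2)
  expect_equal(hx$c2_S2_star, log(0.9 / 0.2) / 2)
})

test_that("HF optima are nearly constant in d' (range below 0.25 axis units)", {
  dgrid <- seq(0.5, 5, by = 0.05)
  vals <- vapply(dgrid, function(d)
    c2_opt_hf(sdt_params(d, 0, 0.5))$c2_S2_star, numeric(1))
  expect_lt(diff(range(vals)), 0.25)
})

test_that("reward optima move out with Q2 and in with d'", {
  off <- function(d, Q2) {
    p <- sdt_params(d, 0, 0.5)
    c2_opt_reward(p, Q2 = Q2)$c2_S2_star - c1_opt_accuracy(d, 0.5)
  }
  q <- c(1.5, 2, 3, 5, 8)
  expect_true(all(diff(vapply(q, function(qq) off(2, qq), numeric(1))) > 0))
  ds <- c(0.5, 1, 2, 4)
  expect_true(all(diff(vapply(ds, function(d) off(d, 3), numeric(1))) < 0))
})

test_that("closed-form optima match the grid-search oracle on random parameters", {
  set.seed(7)
  step <- 1e-3
  for (i in 1:20) {
    d <- runif(1, 0.25, 4); c1 <- runif(1, -2, 2); pS2 <- runif(1, 0.1, 0.9)
    strength <- runif(1, 0.5, 10)
    p <- sdt_params(d, c1, pS2)
    for (ctx in c("accuracy", "reward", "hf")) {
      extras <- if (ctx == "reward") reward_matrix2(1, 0, strength, 0) else NULL
      closed <- switch(ctx,
        accuracy = c2_opt_accuracy(p),
        reward = c2_opt_reward(p, Q2 = strength),
        hf = c2_opt_hf(p))
      # widen the grid so extreme optima (small d', skewed priors) stay interior
      w <- abs(c1_opt_accuracy(d, pS2) - c1) + log(10) / d + 1
      for (resp in c("S1", "S2")) {
        cv <- outcome_curve(ctx, p, extras, resp,
                            c2_grid(p, resp, step = step, width = max(6, w)))
        got <- argmax_c2(cv)$c2
        want <- if (resp == "S1") closed$c2_S1_star else closed$c2_S2_star
        expect_lt(abs(got - want), step + 1e-9,
                  label = sprintf("%s/%s at d=%.2f c1=%.2f p=%.2f q=%.2f",
                                  ctx, resp, d, c1, pS2, strength))
      }
    }
    # calibration via the bisection oracle
    pt <- strength / (1 + strength)
    cc <- c2_opt_calibration(p, pt)
    expect_equal(calibration_crossing(p, pt, "S2"), cc$c2_S2_star,
                 tolerance = 1e-6)
    expect_equal(calibration_crossing(p, pt, "S1"), cc$c2_S1_star,
                 tolerance = 1e-6)
  }
})

test_that("confidence bias ratio flags over- and under-confidence", {
  p <- p_unbiased()
  opt <- c2_opt_reward(p, Q2 = 5.37)
  at_opt <- type2_criteria(opt$c2_S1_star, opt$c2_S2_star)
  r <- confidence_bias_ratio(0, at_opt, opt)
  expect_equal(r$ratio_S1, 1)
  expect_equal(r$ratio_S2, 1)

  r0 <- confidence_bias_ratio(0, type2_criteria(opt$c2_S1_star, 0), opt)
  expect_equal(r0$ratio_S2, 0)   # maximal over-confidence

  expect_equal(confidence_bias_ratio(0, type2_criteria(-0.1, 0.42),
                                     c2_opt_reward(p, Q2 = exp(2 * 0.84)))$ratio_S2,
               0.5)

  # optimal criterion at c1 (clipped): ratio undefined
  expect_error(confidence_bias_ratio(0, at_opt, c2_opt_accuracy(p)),
               "undefined")
})
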