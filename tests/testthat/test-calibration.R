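test_that("model curves evaluate their defining forms", {
  th <- c(Finf = 100, tau = 4, c = 1.7)
  expect_identical(model_curve("mf_kink", th, 0), 0)
  expect_equal(model_curve("mf_kink", th, 4), 100 * tanh(1))
  expect_equal(model_curve("higuchi", c(k = 5), c(1, 4)), c(5, 10))
  expect_equal(model_curve("zero_order", c(k = 2), 3), 6)
  expect_equal(model_curve("first_order", c(Finf = 80, k = 0.5), 2),
               80 * (1 - exp(-1)))
  expect_equal(model_curve("korsmeyer_peppas", c(k = 3, n = 0.5), 4), 6)
  # Hixson-Crowell clips at complete dissolution
  hc <- model_curve("hixson_crowell", c(Finf = 90, k = 0.1), c(5, 10, 20))
  expect_equal(hc[1], 90 * (1 - 0.5^3))
  expect_equal(hc[2:3], c(90, 90))
  expect_equal(model_curve("mf_logistic", c(Finf = 100, f = 1, w0 = 0.5), 0),
               50)
  expect_equal(model_curve("mf_antikink", c(Vres = 0.1, tau = 4, c = 1), 0), 1)
  expect_error(model_curve("mf_kink", c(Finf = 100, tau = -1, c = 1), 1),
               "positive")
  expect_error(model_curve("mf_kink", c(Finf = 200, tau = 1, c = 1), 1),
               "Finf")
})

test_that("monotone release models are non-decreasing and the kink plateaus", {
  t <- seq(0, 24, 0.25)
  curves <- list(
    model_curve("mf_kink", c(Finf = 95, tau = 4, c = 1.7), t),
    model_curve("mf_logistic", c(Finf = 95, f = 0.4, w0 = 0.05), t),
    model_curve("first_order", c(Finf = 95, k = 0.3), t),
    model_curve("higuchi", c(k = 10), t),
    model_curve("zero_order", c(k = 2), t))
  for (f in curves) expect_true(all(diff(f) >= 0))
  expect_lt(max(curves[[1]]), 95 + 1e-9)
  expect_equal(model_curve("mf_kink", c(Finf = 95, tau = 4, c = 1.7), 1e4),
               95)
})

test_that("burst property: tau <= 4 h and c >= 1 gives >= tanh(1) by 4 h", {
  for (tau in c(1, 2.5, 4)) for (cc in c(1, 1.7, 3)) {
    th <- c(Finf = 100, tau = tau, c = cc)
    expect_gte(model_curve("mf_kink", th, 4) / 100, tanh(1) - 1e-12)
  }
})

test_that("noiseless roundtrip recovers every model family to < 1e-6", {
  truths <- list(
    mf_kink = c(Finf = 100, tau = 4, c = 1.7),
    mf_logistic = c(Finf = 90, f = 0.35, w0 = 0.08),
    zero_order = c(k = 3),
    first_order = c(Finf = 85, k = 0.25),
    higuchi = c(k = 12),
    hixson_crowell = c(Finf = 95, k = 0.03),
    korsmeyer_peppas = c(k = 8, n = 0.6))
  t <- sample_times(25, 24)
  for (m in names(truths)) {
    y <- model_curve(m, truths[[m]], t)
    fit <- release_fit(data.frame(time_h = t, value = y), model = m,
                       seed = 11)
    expect_true(fit$converged)
    rel <- abs(coef(fit) - truths[[m]]) / abs(truths[[m]])
    expect_lt(max(rel), 1e-6)
  }
})

test_that("kill fit recovers the antikink observable; V(0) = 1", {
  truth <- c(Vres = 0.05, tau = 6, c = 1.4)
  t <- sample_times(25, 24)
  v <- model_curve("mf_antikink", truth, t)
  fit <- kill_fit(data.frame(time_h = t, value = v), seed = 3)
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit) - truth) / pmax(abs(truth), 1e-6)), 1e-6)
  expect_equal(predict(fit, 0), 1)
})

test_that("degenerate and underdetermined inputs are refused", {
  expect_error(release_fit(data.frame(time_h = 1, value = 10)),
               "insufficient data")
  expect_error(release_fit(data.frame(time_h = 1:3, value = c(1, 2, 3))),
               "insufficient data")   # mf_kink needs 5 points
  flat <- data.frame(time_h = seq(0, 24, length.out = 10),
                     value = rep(50, 10))
  expect_error(release_fit(flat), "degenerate")
  expect_error(kill_fit(data.frame(time_h = seq(0, 24, length.out = 10),
                                   value = rep(1, 10))), "degenerate")
  dup <- data.frame(time_h = c(0, 1, 1, 2, 3, 4), value = c(0, 1, 2, 3, 4, 5))
  expect_error(release_fit(dup), "duplicate")
})

test_that("fits are deterministic given data and seed", {
  curve <- generate_release(seed = 21)
  f1 <- release_fit(curve, seed = 9)
  f2 <- release_fit(curve, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$aicc, f2$aicc)
})

test_that("fit object supports the standard modelling methods", {
  curve <- generate_release(seed = 4)
  fit <- release_fit(curve)
  expect_s3_class(fit, "release_fit")
  expect_named(coef(fit), c("Finf", "tau", "c"))
  expect_length(residuals(fit), nrow(curve))
  expect_equal(fitted(fit) + residuals(fit), curve$value)
  expect_equal(predict(fit, newdata = data.frame(time_h = curve$time_h)),
               fitted(fit))
  expect_identical(dim(vcov(fit)), c(3L, 3L))
  expect_true(all(fit$se > 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.release_fit")
  expect_output(print(fit), "mf_kink")
  expect_output(print(s), "R-squared")
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(dim(sims), c(nrow(curve), 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 5))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("model comparison ranks the generating model first at low noise", {
  t <- sample_times(20, 24)
  hig <- data.frame(time_h = t,
                    value = model_curve("higuchi", c(k = 12), t))
  tab <- compare_release_models(hig, models = c("higuchi", "zero_order",
                                                "first_order", "mf_kink"),
                                seed = 2)
  expect_identical(tab$model[1], "higuchi")
  # a plateauing kink curve cannot be captured by a straight line
  kink <- generate_release(seed = 6, noise_sd = 1)
  tab2 <- compare_release_models(kink, models = c("mf_kink", "zero_order"),
                                 seed = 2)
  expect_identical(tab2$model[1], "mf_kink")
  expect_error(compare_release_models(kink, models = "mf_kink"),
               "at least two")
})

test_that("information criterion penalises an unneeded parameter", {
  # data truly zero-order: Korsmeyer-Peppas adds an exponent it cannot use.
  # The extra parameter buys a chi-square-distributed RSS improvement, so
  # the penalised score prefers the smaller model in the clear majority of
  # replicates and on the median score difference.
  wins <- 0L
  diffs <- numeric(10)
  for (seed in 1:10) {
    curve <- generate_release(truth = list(model = "zero_order",
                                           theta = c(k = 3)),
                              noise_sd = 0.5, seed = seed)
    tab <- compare_release_models(curve,
                                  models = c("zero_order",
                                             "korsmeyer_peppas"),
                                  seed = 1)
    wins <- wins + (tab$model[1] == "zero_order")
    diffs[seed] <- tab$aicc[tab$model == "korsmeyer_peppas"] -
      tab$aicc[tab$model == "zero_order"]
  }
  expect_gte(wins, 7L)
  expect_gt(stats::median(diffs), 0)
})

test_that("fractality report: exponents, ratio, ordering, refusals", {
  t <- sample_times(25, 24)
  mk <- function(theta) release_fit(
    data.frame(time_h = t, value = model_curve("mf_kink", theta, t)),
    seed = 8)
  fit_same <- mk(c(Finf = 100, tau = 4, c = 1.7))
  rep_same <- fractality_report(fit_same, fit_same)
  expect_equal(rep_same$ratio, 1)
  fit_lo <- mk(c(Finf = 100, tau = 4, c = 1.7))
  fit_hi <- mk(c(Finf = 100, tau = 4, c = 5.44))
  rep <- fractality_report(fit_hi, fit_lo)
  expect_equal(rep$ratio, 3.2, tolerance = 1e-4)
  expect_identical(rep$higher_fractality, "a")
  broken <- fit_lo; broken$converged <- FALSE
  expect_error(fractality_report(broken, fit_hi), "refusing")
  zo <- release_fit(data.frame(time_h = t,
                               value = model_curve("zero_order", c(k = 2), t)),
                    model = "zero_order")
  expect_error(fractality_report(zo, fit_hi), "exponent")
  expect_output(print(rep), "ratio")
})
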