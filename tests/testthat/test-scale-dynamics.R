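test_that("log scale variable is ln(eps/eps0) with domain checks", {
  expect_equal(log_scale_variable(1, 1), 0)
  expect_equal(log_scale_variable(exp(1), 1), 1)
  expect_equal(log_scale_variable(exp(2), 1), 2)
  expect_equal(log_scale_variable(2, 4), log(0.5))
  expect_error(log_scale_variable(-1, 1), "positive")
  expect_error(log_scale_variable(1, 0), "positive")
})

test_that("characteristic frequency and roots follow the stationary quadratic", {
  expect_equal(characteristic_frequency(scale_gauge(1, 0, 1)), 1 + 0i)
  expect_equal(characteristic_frequency(scale_gauge(1, 1, 0)), 0 + 1i)
  expect_equal(characteristic_frequency(scale_gauge(2, 2, 4)), 1 + 0i)
  expect_error(scale_gauge(0, 1, 1), "M must be finite and nonzero")

  expect_equal(riccati_roots(scale_gauge(1, 0, 1)), c(1i, -1i))
  expect_equal(riccati_roots(scale_gauge(1, 0, 0)), c(0i, 0i))

  # roots must be the zeros of w^2/M - (2R/M) w + K (brute-force cross-check)
  g <- scale_gauge(1, 2, 5)
  pol <- function(w) w^2 / g$M - (2 * g$R / g$M) * w + g$K
  for (w in riccati_roots(g)) expect_lt(Mod(pol(w)), 1e-12)
  expect_equal(Re(riccati_roots(g)), c(2, 2))
})

test_that("principal branch convention: Re(Omega) >= 0, Im >= 0 on the axis", {
  for (fx in fixture_gauge_params(11L, "oscillatory", n = 5)) {
    expect_gte(Re(fx$gauge$Omega), 0)
    expect_identical(Im(fx$gauge$Omega), 0)
  }
  for (fx in fixture_gauge_params(12L, "damped", n = 5)) {
    expect_identical(Re(fx$gauge$Omega), 0)
    expect_gt(Im(fx$gauge$Omega), 0)
  }
})

test_that("closed-form solution: r = 0 is the fixed point, r = 1 at s = 0 gives R", {
  g <- scale_gauge(1.5, 0.7, 2)
  sol0 <- riccati_solution(g, r = 0, grid = scale_grid(n = 50))
  expect_true(all(sol0$w == g$w0))
  sol1 <- riccati_solution(g, r = 1, grid = scale_grid(s = c(0, 0.1)))
  expect_equal(sol1$w[1], complex(real = g$R, imaginary = 0))
})

test_that("closed form satisfies the gauge ODE (adaptive integration oracle)", {
  g <- scale_gauge(1, 0, 1)
  s <- seq(0, 10, length.out = 201)
  sol <- riccati_solution(g, r = 0.5, grid = scale_grid(s = s))
  w_num <- integrate_riccati(g, sol$w[1], s)
  expect_lt(max(Mod(sol$w - w_num)), 1e-6)
})

test_that("real form matches the complex closed form to machine precision", {
  g <- scale_gauge(1, 0, 1)
  grid <- scale_grid(n = 1000L)
  sol <- riccati_solution(g, 0.5, grid)
  rf <- riccati_real_form(g, 0.5, grid)
  expect_lt(max(Mod(complex(real = rf$re, imaginary = rf$im) - sol$w)), 1e-12)

  rf0 <- riccati_real_form(g, 0, scale_grid(n = 10L))
  expect_true(all(rf0$re == g$R))
  expect_true(all(rf0$im == g$M * Re(g$Omega)))
})

test_that("poles are flagged then rejected as r -> 1 with cos(2 Omega s) -> -1", {
  g <- scale_gauge(1, 0, 1)        # Omega = 1; real-form denominator vanishes at s = pi/2 when r = 1
  near <- riccati_real_form(g, r = 0.999,
                            grid = scale_grid(s = c(0, pi / 2, 3)))
  expect_true(near$flag[2])
  expect_false(near$flag[1])
  expect_error(riccati_real_form(g, r = 1, grid = scale_grid(s = c(0, pi / 2))),
               "singular")
  expect_error(riccati_solution(g, r = 1, grid = scale_grid(s = c(0, pi / 2))),
               "singular")
})

test_that("boundedness and periodicity of the oscillatory solution", {
  for (fx in fixture_gauge_params(21L, "oscillatory", n = 20, r_max = 0.9)) {
    g <- fx$gauge; r <- fx$r; Om <- Re(g$Omega)
    sol <- riccati_solution(g, r, scale_grid(n = 400L))
    bound <- abs(g$R) + abs(g$M * Om) * (1 + abs(r)) / (1 - abs(r))
    expect_lte(max(Mod(sol$w)), bound + 1e-9)
    # period pi/Omega
    s <- seq(0, 2, length.out = 50)
    w1 <- riccati_solution(g, r, scale_grid(s = s))$w
    w2 <- riccati_solution(g, r, scale_grid(s = s + pi / Om))$w
    expect_lt(max(Mod(w1 - w2)), 1e-10)
  }
})

test_that("regime classification follows the threshold taxonomy and is pure", {
  g <- scale_gauge(1, 0, 1)
  expect_identical(mode_classify(g, 0), "fixed_point")
  expect_identical(mode_classify(g, 0.2), "harmonic_modulation")
  expect_identical(mode_classify(g, 0.5), "period_doubled")
  expect_identical(mode_classify(g, 0.8), "strongly_modulated")
  expect_identical(mode_classify(g, 0.96, scale_grid(s = seq(0, 1, 0.01))),
                   "quasi_chaotic")
  # a grid hitting the near-pole makes it intermittent
  expect_identical(mode_classify(g, 0.999, scale_grid(s = seq(0, 4, 0.001))),
                   "intermittent")
  gd <- scale_gauge(1, 1, 0)  # Omega = i
  expect_identical(mode_classify(gd, 0.5), "damped")
  # purity: identical inputs, identical label
  expect_identical(mode_classify(g, 0.5), mode_classify(g, 0.5))
})

test_that("damped regime decays toward the attracting root", {
  gd <- scale_gauge(1, 1, 0)   # Omega = i: hyperbolic relaxation
  sol <- riccati_solution(gd, 0.5, scale_grid(from = 0, to = 6, n = 200L))
  # envelope |w - w_limit| must decay monotonically (damped, not oscillatory)
  w_lim <- sol$w[length(sol$w)]
  env <- Mod(sol$w - w_lim)
  late <- env[101:199]
  expect_true(all(diff(late) <= 1e-12))
})

test_that("bifurcation scan counts extremum levels and skips none when regular", {
  g <- scale_gauge(1, 0, 1)
  sc0 <- bifurcation_scan(g, r = 0, omega = c(1, 2))
  expect_true(all(sc0$index$pseudo_chaos_index == 1))
  sc <- bifurcation_scan(g, r = 0.3, omega = 1)
  expect_identical(sc$index$pseudo_chaos_index, 2)
  expect_identical(sc$n_skipped, 0L)
  # brute-force oracle: max/min of the periodic orbit on a dense grid
  rf <- riccati_real_form(g, 0.3, scale_grid(from = 2, to = 10, n = 20000L))
  expect_equal(sort(sc$levels$extremum_level),
               c(min(rf$re), max(rf$re)), tolerance = 1e-6)
})

test_that("phase parameter: mu = 0 freezes h at -i; large-mu limit; poles flagged", {
  pp0 <- phase_parameter(0, r = 0.7, Omega = 1, grid = scale_grid(n = 20L))
  expect_true(all(pp0$h == -1i))
  pp_inf <- phase_parameter(20, r = 1, Omega = 1, grid = scale_grid(s = 0))
  expect_equal(pp_inf$h, (1 - 1i) / 2, tolerance = 1e-12)
  # r = coth(mu) convenience constructor
  mu <- 0.8
  ppc <- phase_parameter_coth(mu, Omega = 1, grid = scale_grid(s = c(0, 1)))
  expect_equal(ppc$r, 1 / tanh(mu))
  expect_error(phase_parameter_coth(0, 1), "undefined")
  # pole: cosh(mu) + r e sinh(mu) = 0 at e = -coth(mu)/r; pick r = coth(mu),
  # then the pole sits where e^{2 i Omega s} = -1, i.e. s = pi/2
  expect_error(phase_parameter(mu, 1 / tanh(mu), 1,
                               grid = scale_grid(s = c(0, pi / 2))),
               "singular")
})

test_that("phase parameter is bounded on nonsingular grids", {
  for (mu in c(-1.2, 0.4, 2)) {
    pp <- phase_parameter(mu, r = 0.5, Omega = 1, grid = scale_grid(n = 300L))
    expect_true(all(is.finite(Mod(pp$h))))
    expect_false(any(pp$flag))
  }
})
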