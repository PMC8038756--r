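# Homographic (Mobius) machinery of the usual-space dynamics: group
# elements, coframe 1-forms, the metric discriminant, and the geodesic
# Riccati equation.

#' SL(2,R)-type group element
#'
#' @param alpha,beta,gamma,delta real matrix entries; the determinant
#'   Delta = alpha delta - gamma beta must be nonzero.
#' @return object of class `"mobius_element"`.
#' @examples
#' g <- mobius_element(0, 1, 1, 0)   # inversion t -> 1/t
#' mobius_apply(g, 2)
#' @export
mobius_element <- function(alpha, beta, gamma, delta) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            is.numeric(gamma), is.numeric(delta))
  Delta <- alpha * delta - gamma * beta
  if (!is.finite(Delta) || Delta == 0)
    stop("degenerate element: determinant must be nonzero", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 Delta = Delta),
            class = "mobius_element")
}

#' Homographic action t -> (alpha t + beta) / (gamma t + delta)
#'
#' @param g a [mobius_element()].
#' @param t numeric (or complex) value(s); `gamma t + delta` must not vanish.
#' @return transformed value(s).
#' @export
mobius_apply <- function(g, t) {
  stopifnot(inherits(g, "mobius_element"))
  den <- g$gamma * t + g$delta
  if (any(abs(den) < 1e-12))
    stop("singular point of the homographic action (gamma t + delta = 0)",
         call. = FALSE)
  (g$alpha * t + g$beta) / den
}

#' Compose two homographies (matrix product)
#'
#' @param g1,g2 [mobius_element()] objects.
#' @return the element representing `g1` after `g2`, i.e.
#'   `mobius_apply(mobius_compose(g1, g2), t) == mobius_apply(g1, mobius_apply(g2, t))`.
#' @export
mobius_compose <- function(g1, g2) {
  stopifnot(inherits(g1, "mobius_element"), inherits(g2, "mobius_element"))
  mobius_element(g1$alpha * g2$alpha + g1$beta * g2$gamma,
                 g1$alpha * g2$beta + g1$beta * g2$delta,
                 g1$gamma * g2$alpha + g1$delta * g2$gamma,
                 g1$gamma * g2$beta + g1$delta * g2$delta)
}

#' Coframe 1-forms of a parameter step
#'
#' For a group element (alpha, beta, gamma, delta) with differentials
#' (dalpha, dbeta, dgamma, ddelta), the left-invariant coframe is
#' omega1 = (gamma dalpha - alpha dgamma)/Delta,
#' omega2 = (delta dalpha - alpha ddelta + gamma dbeta - beta dgamma)/Delta,
#' omega3 = (delta dbeta - beta ddelta)/Delta.
#'
#' @param g a [mobius_element()].
#' @param dalpha,dbeta,dgamma,ddelta differentials of the entries.
#' @return named numeric vector `c(omega1, omega2, omega3)`.
#' @export
coframe_forms <- function(g, dalpha, dbeta, dgamma, ddelta) {
  stopifnot(inherits(g, "mobius_element"))
  D <- g$Delta
  c(omega1 = (g$gamma * dalpha - g$alpha * dgamma) / D,
    omega2 = (g$delta * dalpha - g$alpha * ddelta +
                g$gamma * dbeta - g$beta * dgamma) / D,
    omega3 = (g$delta * dbeta - g$beta * ddelta) / D)
}

#' Metric discriminant of a coframe step
#'
#' ds^2 = (omega2^2 - 4 omega1 omega3) / 4, the discriminant form of the
#' quadratic attached to the step.  The equivalent direct expression
#' (delta dalpha + alpha ddelta - gamma dbeta - beta dgamma)^2 / (4 Delta^2)
#' - (dalpha ddelta - dbeta dgamma) / Delta is available via
#' `form = "direct"` as an algebraic cross-check.
#'
#' @inheritParams coframe_forms
#' @param form `"coframe"` (default) or `"direct"`.
#' @return the scalar ds^2 (any sign: the metric is Lorentzian).
#' @export
metric_discriminant <- function(g, dalpha, dbeta, dgamma, ddelta,
                                form = c("coframe", "direct")) {
  form <- match.arg(form)
  stopifnot(inherits(g, "mobius_element"))
  if (form == "coframe") {
    om <- coframe_forms(g, dalpha, dbeta, dgamma, ddelta)
    unname(0.25 * (om["omega2"]^2 - 4 * om["omega1"] * om["omega3"]))
  } else {
    D <- g$Delta
    (g$delta * dalpha + g$alpha * ddelta -
       g$gamma * dbeta - g$beta * dgamma)^2 / (4 * D^2) -
      (dalpha * ddelta - dbeta * dgamma) / D
  }
}

#' Solve the geodesic Riccati equation
#'
#' Along a metric geodesic the homographic dynamics reduce to
#' dt/dtau = a1 t^2 + 2 a2 t + a3 with constant coefficients.  For a1 != 0
#' this is the scale gauge with M = 1/a1, R = -a2/a1, K = a3, and the
#' closed-form solution is reused with the modulation constant chosen to
#' match the initial condition t(0) = t0; a1 = 0 is solved exactly as a
#' linear ODE.
#'
#' @param a1,a2,a3 real coefficients.
#' @param t0 initial value at the first grid point.
#' @param tau numeric grid of the geodesic parameter (strictly increasing).
#' @return list of class `"geodesic_solution"` with `tau`, real `t`, `flag`.
#' @examples
#' sol <- geodesic_riccati_solve(1, 0, -1, t0 = 0, tau = seq(0, 3, 0.1))
#' all.equal(sol$t, -tanh(sol$tau))
#' @export
geodesic_riccati_solve <- function(a1, a2, a3, t0, tau) {
  stopifnot(is.numeric(tau), length(tau) >= 1L, all(is.finite(tau)))
  if (length(tau) > 1L && any(diff(tau) <= 0))
    stop("tau grid must be strictly increasing", call. = FALSE)
  tau0 <- tau[1]
  u <- tau - tau0
  if (a1 == 0) {
    t <- if (a2 == 0) t0 + a3 * u
         else (t0 + a3 / (2 * a2)) * exp(2 * a2 * u) - a3 / (2 * a2)
    flag <- rep(FALSE, length(tau))
  } else {
    gauge <- scale_gauge(M = 1 / a1, R = -a2 / a1, K = a3)
    if (abs(t0 - gauge$w0) < 1e-14 || abs(t0 - gauge$w0_bar) < 1e-14) {
      t <- rep(t0, length(tau))
      flag <- rep(FALSE, length(tau))
    } else {
      r0 <- (gauge$w0 - t0) / (t0 - gauge$w0_bar)
      e <- r0 * exp(2i * gauge$Omega * u)
      den <- 1 + e
      flag <- check_denominator(den, tau, "geodesic Riccati solution")
      w <- (gauge$w0 + e * gauge$w0_bar) / den
      if (max(abs(Im(w))) > 1e-8 * max(1, max(abs(Re(w)))))
        warning("solution has a nontrivial imaginary part; returning Re(t)")
      t <- Re(w)
    }
  }
  structure(list(tau = tau, t = t, flag = flag,
                 a = c(a1 = a1, a2 = a2, a3 = a3), t0 = t0),
            class = "geodesic_solution")
}
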