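# Kink/antikink and logistic release laws: the bounded soliton-type
# solutions of the scale gauge in its hyperbolic parametrisation.

#' Kink / antikink parameters
#'
#' The gauge rewritten as 2 mu dw/ds = w^2 - 2 c w - d admits, when
#' d + c^2 > 0, bounded front solutions
#' w(s) = c +/- A tanh(A (s - s_center) / (2 mu)) with amplitude
#' A = sqrt(d + c^2).  The rising kink describes cumulative release; the
#' falling antikink describes the decline of the viable fungal population.
#'
#' @param c real offset (the front's midpoint level).
#' @param d real constant; the restriction d + c^2 > 0 must hold.
#' @param mu_width positive width scale (the "2 mu" of the hyperbolic form).
#' @param branch `"kink"` (rising) or `"antikink"` (falling).
#' @param s_center real center shift (default 0).
#' @return object of class `"kink_params"`.
#' @examples
#' kp <- kink_params(c = 0, d = 1, mu_width = 0.5)
#' soliton_amplitude(kp)
#' @export
kink_params <- function(c = 0, d = 1, mu_width = 0.5,
                        branch = c("kink", "antikink"), s_center = 0) {
  branch <- match.arg(branch)
  stopifnot(is.numeric(c), is.numeric(d), is.numeric(mu_width),
            is.numeric(s_center), mu_width > 0, is.finite(c), is.finite(d))
  if (d + c^2 <= 0)
    stop("restriction violated: need d + c^2 > 0 (got ",
         signif(d + c^2, 6), ")", call. = FALSE)
  structure(list(c = c, d = d, A = sqrt(d + c^2), mu_width = mu_width,
                 branch = branch, s_center = s_center),
            class = "kink_params")
}

#' Soliton amplitude
#'
#' @param kp a [kink_params()] object.
#' @return A = sqrt(d + c^2).
#' @export
soliton_amplitude <- function(kp) {
  stopifnot(inherits(kp, "kink_params"))
  kp$A
}

#' Kink / antikink front profile
#'
#' @param kp a [kink_params()] object.
#' @param s numeric vector of scale values.
#' @return numeric vector w(s) = c +/- A tanh(A (s - s_center) / (2 mu)),
#'   strictly monotone with range (c - A, c + A).
#' @export
kink_profile <- function(kp, s) {
  stopifnot(inherits(kp, "kink_params"), is.numeric(s))
  sgn <- if (kp$branch == "kink") 1 else -1
  kp$c + sgn * kp$A * tanh(kp$A * (s - kp$s_center) / (2 * kp$mu_width))
}

#' Analytic inverse of the front profile
#'
#' @param kp a [kink_params()] object.
#' @param w_level level strictly inside the open range (c - A, c + A).
#' @return the unique s with `kink_profile(kp, s) == w_level`.
#' @export
kink_inverse <- function(kp, w_level) {
  stopifnot(inherits(kp, "kink_params"), is.numeric(w_level))
  if (any(w_level <= kp$c - kp$A) || any(w_level >= kp$c + kp$A))
    stop("level outside the open range (c - A, c + A)", call. = FALSE)
  sgn <- if (kp$branch == "kink") 1 else -1
  kp$s_center + (2 * kp$mu_width / kp$A) * atanh(sgn * (w_level - kp$c) / kp$A)
}

#' Logistic release-law parameters
#'
#' Specialising the gauge constants (M = -1/f, R = 1/2, K = 0) turns it into
#' the logistic equation dw/ds = f w (1 - w) whose solution, with w(0) = w0,
#' is w(s) = 1 / (1 - (1 - 1/w0) e^{-f s}).
#'
#' @param f positive rate constant.
#' @param w0 initial value in (0, 1].
#' @return object of class `"logistic_params"`.
#' @export
logistic_params <- function(f, w0) {
  stopifnot(is.numeric(f), is.numeric(w0), length(f) == 1L, length(w0) == 1L)
  if (!is.finite(f) || f <= 0) stop("rate f must be positive", call. = FALSE)
  if (!is.finite(w0) || w0 <= 0 || w0 > 1)
    stop("w0 must lie in (0, 1]", call. = FALSE)
  structure(list(f = f, w0 = w0), class = "logistic_params")
}

#' Logistic release profile
#'
#' @param lp a [logistic_params()] object.
#' @param s numeric vector of scale values.
#' @return w(s) in (0, 1], non-decreasing, with w(0) = w0 exactly.
#' @export
logistic_profile <- function(lp, s) {
  stopifnot(inherits(lp, "logistic_params"), is.numeric(s))
  1 / (1 - (1 - 1 / lp$w0) * exp(-lp$f * s))
}

#' Logistic growth rate
#'
#' @param lp a [logistic_params()] object.
#' @param w numeric state value(s).
#' @return f w (1 - w).
#' @export
logistic_rate <- function(lp, w) {
  stopifnot(inherits(lp, "logistic_params"))
  lp$f * w * (1 - w)
}

#' Kink-antikink pair parameters
#'
#' A localized release pulse built from a kink at -s0 and an antikink at
#' +s0 sharing amplitude and width:
#' w(s) = [c + A tanh(A (s + s0)/(2 mu))] + [c - A tanh(A (s - s0)/(2 mu))] - c.
#' The superposition is even in s (for s_center = 0), returns to the
#' baseline c at both infinities, and peaks at s = 0 with pulse amplitude
#' 2 A tanh(A s0 / (2 mu)) above baseline.
#'
#' @param kp shared [kink_params()] (its `branch` is ignored).
#' @param s0 nonnegative half-separation of the pair.
#' @return object of class `"pair_params"`.
#' @export
pair_params <- function(kp, s0) {
  stopifnot(inherits(kp, "kink_params"), is.numeric(s0), length(s0) == 1L,
            is.finite(s0), s0 >= 0)
  structure(list(kp = kp, s0 = s0), class = "pair_params")
}

#' Kink-antikink pair profile
#'
#' @param pp a [pair_params()] object.
#' @param s numeric vector of scale values.
#' @return numeric pulse profile (see [pair_params()]).
#' @export
pair_profile <- function(pp, s) {
  stopifnot(inherits(pp, "pair_params"), is.numeric(s))
  kp <- pp$kp
  u <- (s - kp$s_center)
  arg <- kp$A / (2 * kp$mu_width)
  kp$c + kp$A * (tanh(arg * (u + pp$s0)) - tanh(arg * (u - pp$s0)))
}
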