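# Closed-form scale-space dynamics of the Riccati gauge, regime
# classification, and bifurcation-style scans.

# singularity handling shared by the closed-form evaluators:
# |denominator| < hard_tol  -> error; < flag_tol -> flagged sample
.hard_tol <- 1e-9
.flag_tol <- 1e-3

check_denominator <- function(den, s, what) {
  a <- Mod(den)
  if (any(a < .hard_tol)) {
    bad <- s[a < .hard_tol]
    stop(sprintf("singular evaluation of %s at s = %s",
                 what, paste(signif(bad, 6), collapse = ", ")),
         call. = FALSE)
  }
  a < .flag_tol
}

#' Closed-form solution of the scale-space Riccati gauge
#'
#' General solution w(s) = (w0 + r e^{2 i Omega s} w0_bar) /
#' (1 + r e^{2 i Omega s}) of dw/ds = w^2/M - (2R/M) w + K, where r is an
#' integration constant setting the modulation depth.  r = 0 freezes the
#' dynamics at the root w0 (unbroken scale symmetry); |r| -> 1 drives the
#' solution toward its poles.
#'
#' @param gauge a [scale_gauge()] object.
#' @param r modulation constant (real in the oscillatory scenarios; complex
#'   values are accepted, e.g. when matching an initial condition).
#' @param grid a [scale_grid()] or numeric vector of s values.
#' @return object of class `"riccati_solution"`: list with `s`, complex `w`,
#'   logical `flag` marking near-singular samples, plus `gauge` and `r`.
#' @examples
#' g <- scale_gauge(1, 0, 1)
#' sol <- riccati_solution(g, r = 0.5, grid = scale_grid(n = 200))
#' range(Mod(sol$w))
#' @export
riccati_solution <- function(gauge, r, grid = scale_grid()) {
  stopifnot(inherits(gauge, "scale_gauge"))
  s <- as.numeric(scale_grid(s = unclass(grid)))
  e <- r * exp(2i * gauge$Omega * s)
  den <- 1 + e
  flag <- check_denominator(den, s, "Riccati closed form")
  w <- (gauge$w0 + e * gauge$w0_bar) / den
  structure(list(s = s, w = w, flag = flag, gauge = gauge, r = r),
            class = "riccati_solution")
}

#' @export
print.riccati_solution <- function(x, ...) {
  cat(sprintf("Riccati scale-space solution: %d samples, r = %s\n",
              length(x$s), format(x$r)))
  cat(sprintf("  s in [%g, %g]; %d flagged near-singular\n",
              min(x$s), max(x$s), sum(x$flag)))
  invisible(x)
}

#' Real form of the oscillatory solution
#'
#' For real Omega and real r the solution separates into
#' Re w = R + M Omega 2 r sin(2 Omega s) / D and
#' Im w = M Omega (1 - r^2) / D with D = 1 + r^2 + 2 r cos(2 Omega s).
#' Algebraically identical to [riccati_solution()]; exposed separately
#' because the real/imaginary decomposition is what displays the scale
#' symmetry-breaking modes.
#'
#' @inheritParams riccati_solution
#' @return list of class `"riccati_real_form"` with `s`, `re`, `im`, `flag`.
#' @export
riccati_real_form <- function(gauge, r, grid = scale_grid()) {
  stopifnot(inherits(gauge, "scale_gauge"))
  if (Im(gauge$Omega) != 0)
    stop("real form requires real Omega (K/M >= (R/M)^2)", call. = FALSE)
  if (!is.numeric(r)) stop("real form requires real r", call. = FALSE)
  Om <- Re(gauge$Omega)
  s <- as.numeric(scale_grid(s = unclass(grid)))
  den <- 1 + r^2 + 2 * r * cos(2 * Om * s)
  flag <- check_denominator(den, s, "real-form solution")
  re <- gauge$R + gauge$M * Om * 2 * r * sin(2 * Om * s) / den
  im <- gauge$M * Om * (1 - r^2) / den
  structure(list(s = s, re = re, im = im, flag = flag, gauge = gauge, r = r),
            class = "riccati_real_form")
}

#' Classify the scale symmetry-breaking regime
#'
#' Deterministic taxonomy of the modulation regimes the closed-form solution
#' can display: a fixed point at r = 0, hyperbolic damping when Omega is
#' non-real, intermittent spiking when the real-form denominator approaches
#' its pole, and otherwise harmonic modulation, period doubling, strong
#' modulation or quasi-chaotic behaviour as |r| grows toward 1.  A genuinely
#' chaotic label does not exist: the dynamics approach but never reach chaos.
#'
#' @inheritParams riccati_solution
#' @return a single character label.
#' @export
mode_classify <- function(gauge, r, grid = scale_grid()) {
  stopifnot(inherits(gauge, "scale_gauge"))
  if (is.complex(r) && Im(r) == 0) r <- Re(r)
  if (identical(r, 0) || identical(r, 0L) || (is.numeric(r) && r == 0))
    return("fixed_point")
  if (Im(gauge$Omega) != 0) return("damped")
  Om <- Re(gauge$Omega)
  if (Om == 0) return("fixed_point")
  s <- as.numeric(scale_grid(s = unclass(grid)))
  den_min <- min(Mod(1 + r * exp(2i * Om * s))^2)
  if (den_min < .flag_tol) return("intermittent")
  a <- Mod(r)
  if (a <= 0.3) "harmonic_modulation"
  else if (a <= 0.7) "period_doubled"
  else if (a <= 0.95) "strongly_modulated"
  else "quasi_chaotic"
}

# local extrema of y with parabolic refinement; returns refined levels
local_extremum_levels <- function(y) {
  n <- length(y)
  if (n < 3L) return(numeric(0))
  d1 <- diff(y)
  idx <- which(d1[-1] * d1[-(n - 1L)] < 0) + 1L   # strict sign change
  if (!length(idx)) return(numeric(0))
  # 3-point parabola through (i-1, i, i+1) -> extremum value
  vapply(idx, function(i) {
    y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
    den <- y0 - 2 * y1 + y2
    if (den == 0) return(y1)
    delta <- 0.5 * (y0 - y2) / den
    y1 - 0.25 * (y0 - y2) * delta
  }, numeric(1))
}

cluster_levels <- function(levels, tol) {
  if (!length(levels)) return(numeric(0))
  lv <- sort(levels)
  reps <- lv[1]
  for (v in lv[-1]) if (v - reps[length(reps)] > tol) reps <- c(reps, v)
  reps
}

#' Bifurcation-style scan over the characteristic frequency
#'
#' Sweeps Omega over a range (holding M, R and the modulation constant r
#' fixed, with K adjusted so each gauge realises the requested Omega),
#' records the local-extremum levels of Re w after discarding an initial
#' transient, and summarises each Omega by a pseudo-chaos index: the number
#' of distinct extremum levels after tolerance clustering.  A high index
#' flags a high density of oscillation levels without genuine chaos.
#'
#' @param gauge base [scale_gauge()] supplying M and R.
#' @param r modulation constant.
#' @param omega numeric vector of positive frequencies to scan.
#' @param grid evaluation grid in s.
#' @param transient_frac fraction of the grid discarded before extremum
#'   detection (default 0.2).
#' @param cluster_tol_factor clustering tolerance as a fraction of the
#'   post-transient range of Re w (default 1e-4).
#' @return list with `levels` (data.frame omega/extremum_level), `index`
#'   (data.frame omega/pseudo_chaos_index) and `n_skipped` singular samples.
#' @export
bifurcation_scan <- function(gauge, r, omega, grid = scale_grid(n = 4000L),
                             transient_frac = 0.2,
                             cluster_tol_factor = 1e-4) {
  stopifnot(inherits(gauge, "scale_gauge"), is.numeric(omega),
            all(is.finite(omega)), all(omega > 0))
  s <- as.numeric(scale_grid(s = unclass(grid)))
  keep <- s >= s[1] + transient_frac * (s[length(s)] - s[1])
  rows <- list(); idx <- numeric(length(omega)); skipped <- 0L
  for (j in seq_along(omega)) {
    Om <- omega[j]
    gj <- scale_gauge(gauge$M, gauge$R,
                      K = gauge$M * (Om^2 + (gauge$R / gauge$M)^2))
    den <- 1 + r^2 + 2 * r * cos(2 * Om * s)
    ok <- abs(den) >= .flag_tol
    skipped <- skipped + sum(!ok)
    re <- gj$R + gj$M * Om * 2 * r * sin(2 * Om * s) / den
    y <- re[keep & ok]
    levels <- local_extremum_levels(y)
    if (!length(levels)) levels <- if (length(y)) y[1] else numeric(0)
    rng <- diff(range(y))
    tol <- cluster_tol_factor * if (rng > 0) rng else 1
    reps <- cluster_levels(levels, tol)
    idx[j] <- length(reps)
    rows[[j]] <- data.frame(omega = Om, extremum_level = reps)
  }
  list(levels = do.call(rbind, rows),
       index = data.frame(omega = omega, pseudo_chaos_index = idx),
       n_skipped = skipped)
}

#' Phase parameter of the large-scale dynamics
#'
#' Evaluates h(s) = (-i cosh(mu) + r e^{2 i Omega s} sinh(mu)) /
#' (cosh(mu) + r e^{2 i Omega s} sinh(mu)), the phase-modulation parameter
#' of the large-scale implementation of the gauge.  The hyperbolic
#' parameter mu and the modulation constant r are kept independent;
#' [phase_parameter_coth()] enforces the coupling r = coth(mu).
#'
#' @param mu real hyperbolic parameter.
#' @param r modulation constant.
#' @param Omega real characteristic frequency.
#' @param grid a [scale_grid()] or numeric vector of s values.
#' @return list of class `"phase_parameter"` with `s`, complex `h`, `flag`,
#'   `mu`, `r`, `Omega`.
#' @export
phase_parameter <- function(mu, r, Omega, grid = scale_grid()) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  s <- as.numeric(scale_grid(s = unclass(grid)))
  e <- r * exp(2i * Omega * s)
  den <- cosh(mu) + e * sinh(mu)
  flag <- check_denominator(den, s, "phase parameter")
  h <- (-1i * cosh(mu) + e * sinh(mu)) / den
  structure(list(s = s, h = h, flag = flag, mu = mu, r = r, Omega = Omega),
            class = "phase_parameter")
}

#' @rdname phase_parameter
#' @export
phase_parameter_coth <- function(mu, Omega, grid = scale_grid()) {
  if (mu == 0) stop("r = coth(mu) undefined at mu = 0", call. = FALSE)
  phase_parameter(mu, r = 1 / tanh(mu), Omega = Omega, grid = grid)
}
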