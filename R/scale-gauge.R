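#' Logarithmic scale variable
#'
#' The natural independent variable of the scale-space dynamics is the
#' logarithm of the resolution ratio, \eqn{s = \ln(\epsilon/\epsilon_0)},
#' where \eqn{\epsilon} is the resolution at which a multifractal observable
#' is evaluated and \eqn{\epsilon_0} a fixed reference resolution.
#'
#' @param eps positive resolution (same units as `eps0`).
#' @param eps0 positive reference resolution.
#' @return the dimensionless scale variable `s`.
#' @examples
#' log_scale_variable(exp(1), 1)  # 1
#' @export
log_scale_variable <- function(eps, eps0) {
  if (!is.numeric(eps) || !is.numeric(eps0))
    stop("`eps` and `eps0` must be numeric", call. = FALSE)
  if (any(eps <= 0) || any(eps0 <= 0))
    stop("resolutions must be strictly positive", call. = FALSE)
  log(eps / eps0)
}

#' Multifractal gauge parameters
#'
#' Bundles the three dimensionless constants (M, R, K) of the Riccati-type
#' scale gauge dw/ds = w^2/M - (2R/M) w + K together with the derived
#' characteristic frequency Omega and the stationary roots.
#'
#' Omega satisfies Omega^2 = K/M - (R/M)^2 and is stored as a complex number
#' under the principal-branch convention Re(Omega) >= 0, with Im(Omega) >= 0
#' when Re(Omega) = 0.  Real Omega gives oscillatory scale dynamics;
#' purely imaginary Omega gives hyperbolically damped dynamics.
#'
#' @param M,R,K real gauge constants; `M` must be nonzero.
#' @return an object of class `"scale_gauge"` with elements `M`, `R`, `K`,
#'   `Omega` (complex), and the root pair `w0`, `w0_bar` = R +/- i M Omega.
#' @examples
#' g <- scale_gauge(M = 1, R = 0, K = 1)
#' g$Omega        # 1+0i
#' riccati_roots(g)
#' @export
scale_gauge <- function(M, R = 0, K = 1) {
  stopifnot(is.numeric(M), is.numeric(R), is.numeric(K),
            length(M) == 1L, length(R) == 1L, length(K) == 1L)
  if (!is.finite(M) || M == 0)
    stop("degenerate gauge: M must be finite and nonzero", call. = FALSE)
  Omega <- characteristic_frequency_num(M, R, K)
  w0 <- R + 1i * M * Omega
  w0_bar <- R - 1i * M * Omega
  structure(list(M = M, R = R, K = K, Omega = Omega,
                 w0 = w0, w0_bar = w0_bar),
            class = "scale_gauge")
}

# principal square root of Omega^2 = K/M - (R/M)^2 with Re >= 0,
# and Im >= 0 on the imaginary axis
characteristic_frequency_num <- function(M, R, K) {
  om2 <- K / M - (R / M)^2
  Omega <- sqrt(as.complex(om2))
  if (Re(Omega) < 0 || (Re(Omega) == 0 && Im(Omega) < 0)) Omega <- -Omega
  # drop numerically-zero parts so downstream realness tests are exact
  if (abs(Im(Omega)) < .Machine$double.eps * max(1, abs(Re(Omega))))
    Omega <- complex(real = Re(Omega), imaginary = 0)
  if (abs(Re(Omega)) < .Machine$double.eps * max(1, abs(Im(Omega))))
    Omega <- complex(real = 0, imaginary = Im(Omega))
  Omega
}

#' Characteristic frequency of the scale gauge
#'
#' @param gauge a [scale_gauge()] object.
#' @return complex Omega with Omega^2 = K/M - (R/M)^2 (principal branch).
#' @export
characteristic_frequency <- function(gauge) {
  stopifnot(inherits(gauge, "scale_gauge"))
  gauge$Omega
}

#' Stationary roots of the Riccati gauge
#'
#' The stationary points of dw/ds = w^2/M - (2R/M) w + K are
#' w0 = R + i M Omega and its mirror R - i M Omega (a complex-conjugate
#' pair when Omega is real).
#'
#' @param gauge a [scale_gauge()] object.
#' @return complex vector `c(w0, w0_bar)`.
#' @export
riccati_roots <- function(gauge) {
  stopifnot(inherits(gauge, "scale_gauge"))
  c(gauge$w0, gauge$w0_bar)
}

#' @export
print.scale_gauge <- function(x, ...) {
  cat("Multifractal scale gauge  dw/ds = w^2/M - (2R/M) w + K\n")
  cat(sprintf("  M = %g, R = %g, K = %g\n", x$M, x$R, x$K))
  cat(sprintf("  Omega = %s  (%s)\n", format(x$Omega),
              if (Im(x$Omega) == 0) "oscillatory" else
                if (Re(x$Omega) == 0) "damped" else "mixed"))
  cat(sprintf("  roots: %s, %s\n", format(x$w0), format(x$w0_bar)))
  invisible(x)
}

#' Ordered grid of scale values
#'
#' @param s numeric vector of scale values, strictly increasing and finite;
#'   or use `from`/`to`/`n` to build a regular grid.
#' @param from,to,n regular-grid specification used when `s` is missing.
#' @return numeric vector of class `"scale_grid"`.
#' @export
scale_grid <- function(s = NULL, from = 0, to = 10, n = 1000L) {
  if (is.null(s)) s <- seq(from, to, length.out = n)
  if (!is.numeric(s) || length(s) == 0L)
    stop("scale grid must be a nonempty numeric vector", call. = FALSE)
  if (any(!is.finite(s)))
    stop("scale grid must be finite", call. = FALSE)
  if (length(s) > 1L && any(diff(s) <= 0))
    stop("scale grid must be strictly increasing", call. = FALSE)
  structure(as.numeric(s), class = "scale_grid")
}
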