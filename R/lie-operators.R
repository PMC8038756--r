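# The two isomorphic SL(2,R)-type operator algebras and their joint
# invariants.  Operators act on functions of five coordinates
# (z, zb, h, hb, k), with z/zb and h/hb treated as independent
# holomorphic/antiholomorphic variables:
#   A1 = d/dh + d/dhb
#   A2 = h d/dh + hb d/dhb
#   A3 = h^2 d/dh + hb^2 d/dhb + (h - hb) k d/dk      (scale space)
#   B1 = d/dz + d/dzb
#   B2 = z d/dz + zb d/dzb
#   B3 = z^2 d/dz + zb^2 d/dzb                        (usual space)
# Polynomial test functions are handled exactly through a tiny multivariate
# polynomial type; arbitrary differentiable functions through central
# finite differences.

.lie_vars <- c("z", "zb", "h", "hb", "k")

#' Multivariate polynomial test functions
#'
#' Minimal exact polynomial arithmetic over the coordinates
#' `z, zb, h, hb, k` with complex coefficients, used so that operator
#' identities (commutation relations) can be verified symbolically rather
#' than numerically.
#'
#' @param coef complex coefficient vector.
#' @param powers integer matrix, one row per term, columns named
#'   `z, zb, h, hb, k`.
#' @return object of class `"lie_poly"`.
#' @export
lie_poly <- function(coef, powers) {
  powers <- matrix(as.integer(powers), ncol = 5L,
                   dimnames = list(NULL, .lie_vars))
  p <- structure(list(coef = as.complex(coef), powers = powers),
                 class = "lie_poly")
  lie_poly_canon(p)
}

#' @rdname lie_poly
#' @param var one of `"z", "zb", "h", "hb", "k"`.
#' @export
lie_monomial <- function(var) {
  pow <- matrix(0L, 1L, 5L, dimnames = list(NULL, .lie_vars))
  pow[1L, var] <- 1L
  lie_poly(1 + 0i, pow)
}

lie_poly_zero <- function() {
  lie_poly(complex(0), matrix(0L, 0L, 5L))
}

lie_poly_canon <- function(p) {
  if (!nrow(p$powers)) return(p)
  key <- apply(p$powers, 1L, paste, collapse = ",")
  agg <- tapply(p$coef, key, sum)
  keep <- abs(agg) > 1e-13
  agg <- agg[keep]
  if (!length(agg)) return(lie_poly_zero())
  pw <- do.call(rbind, lapply(strsplit(names(agg), ","), as.integer))
  colnames(pw) <- .lie_vars
  ord <- do.call(order, as.data.frame(pw))
  structure(list(coef = as.complex(agg[ord]),
                 powers = pw[ord, , drop = FALSE]),
            class = "lie_poly")
}

lie_poly_add <- function(p, q) {
  lie_poly(c(p$coef, q$coef), rbind(p$powers, q$powers))
}

lie_poly_scale <- function(p, a) {
  p$coef <- p$coef * a
  lie_poly_canon(p)
}

# multiply by a single variable raised to `n`
lie_poly_mul_var <- function(p, var, n = 1L) {
  p$powers[, var] <- p$powers[, var] + as.integer(n)
  p
}

lie_poly_deriv <- function(p, var) {
  keep <- p$powers[, var] > 0L
  if (!any(keep)) return(lie_poly_zero())
  pw <- p$powers[keep, , drop = FALSE]
  cf <- p$coef[keep] * pw[, var]
  pw[, var] <- pw[, var] - 1L
  lie_poly(cf, pw)
}

lie_poly_equal <- function(p, q, tol = 1e-12) {
  d <- lie_poly_add(p, lie_poly_scale(q, -1))
  !nrow(d$powers) || all(abs(d$coef) <= tol)
}

#' @export
print.lie_poly <- function(x, ...) {
  if (!nrow(x$powers)) { cat("0\n"); return(invisible(x)) }
  terms <- vapply(seq_along(x$coef), function(i) {
    vars <- .lie_vars[x$powers[i, ] > 0L]
    pows <- x$powers[i, x$powers[i, ] > 0L]
    mono <- paste0(vars, ifelse(pows > 1L, paste0("^", pows), ""),
                   collapse = " ")
    cf <- x$coef[i]
    cfs <- if (Im(cf) == 0) format(Re(cf)) else format(cf)
    if (nzchar(mono)) paste(cfs, mono) else cfs
  }, character(1))
  cat(paste(terms, collapse = " + "), "\n")
  invisible(x)
}

#' Evaluate a polynomial test function
#'
#' @param p a [lie_poly()].
#' @param point named list/vector with complex entries `z, zb, h, hb, k`.
#' @return complex scalar.
#' @export
lie_poly_eval <- function(p, point) {
  if (!nrow(p$powers)) return(0 + 0i)
  vals <- vapply(.lie_vars, function(v) as.complex(point[[v]]), complex(1))
  sum(p$coef * apply(p$powers, 1L, function(pw) prod(vals^pw)))
}

# vector-field description: list of (coefficient poly in the 5 vars, var)
lie_vector_field <- function(id) {
  one <- lie_poly(1 + 0i, matrix(0L, 1L, 5L))
  sq <- function(v) lie_poly_mul_var(lie_poly_mul_var(one, v), v)
  lin <- function(v) lie_poly_mul_var(one, v)
  switch(id,
    A1 = list(list(one, "h"), list(one, "hb")),
    A2 = list(list(lin("h"), "h"), list(lin("hb"), "hb")),
    A3 = list(list(sq("h"), "h"), list(sq("hb"), "hb"),
              list(lie_poly_mul_var(
                     lie_poly_add(lin("h"), lie_poly_scale(lin("hb"), -1)),
                     "k"), "k")),
    B1 = list(list(one, "z"), list(one, "zb")),
    B2 = list(list(lin("z"), "z"), list(lin("zb"), "zb")),
    B3 = list(list(sq("z"), "z"), list(sq("zb"), "zb")),
    stop("unknown operator id: ", id, call. = FALSE))
}

lie_apply_poly <- function(id, p) {
  out <- lie_poly_zero()
  for (term in lie_vector_field(id)) {
    d <- lie_poly_deriv(p, term[[2]])
    if (nrow(d$powers)) {
      prod_cf <- lie_poly_mul_poly(term[[1]], d)
      out <- lie_poly_add(out, prod_cf)
    }
  }
  out
}

lie_poly_mul_poly <- function(p, q) {
  if (!nrow(p$powers) || !nrow(q$powers)) return(lie_poly_zero())
  cf <- as.vector(outer(p$coef, q$coef))
  pw <- do.call(rbind, lapply(seq_len(nrow(p$powers)), function(i)
    sweep(q$powers, 2L, p$powers[i, ], "+")))
  lie_poly(cf, pw)
}

#' Apply an SL(2,R)-type Lie operator
#'
#' Applies one of the six generators `A1, A2, A3, B1, B2, B3` to a test
#' function.  Polynomial functions ([lie_poly()]) are differentiated
#' exactly; plain R functions of signature `f(z, zb, h, hb, k)` are
#' differentiated by central finite differences, each complex coordinate
#' being treated as an independent variable.
#'
#' @param id operator identifier.
#' @param f a [lie_poly()] or a function `f(z, zb, h, hb, k)`.
#' @param point named list with entries `z, zb, h, hb, k` (complex allowed).
#'   Required when `f` is a plain function or when a value (not a
#'   polynomial) is wanted.
#' @param step finite-difference step for plain functions.
#' @return if `f` is a polynomial and `point` is `NULL`, the image
#'   polynomial; otherwise the complex value of the image at `point`.
#' @examples
#' lie_apply("B1", lie_monomial("z"))            # the constant 1
#' lie_apply("B2", function(z, zb, h, hb, k) z^2,
#'           point = list(z = 2, zb = 0, h = 1i, hb = -1i, k = 1))
#' @export
lie_apply <- function(id, f, point = NULL, step = 1e-4) {
  id <- match.arg(id, c("A1", "A2", "A3", "B1", "B2", "B3"))
  if (inherits(f, "lie_poly")) {
    img <- lie_apply_poly(id, f)
    if (is.null(point)) return(img)
    return(lie_poly_eval(img, point))
  }
  stopifnot(is.function(f), !is.null(point))
  pt <- lapply(point[.lie_vars], as.complex)
  names(pt) <- .lie_vars
  # fourth-order central stencil keeps residuals well under test tolerances
  dnum <- function(var) {
    fat <- function(d) {
      p1 <- pt
      p1[[var]] <- p1[[var]] + d
      do.call(f, p1)
    }
    (-fat(2 * step) + 8 * fat(step) - 8 * fat(-step) + fat(-2 * step)) /
      (12 * step)
  }
  val <- 0 + 0i
  for (term in lie_vector_field(id)) {
    cf <- lie_poly_eval(term[[1]], pt)
    val <- val + cf * dnum(term[[2]])
  }
  val
}

#' Verify the commutation relations of the operator algebra
#'
#' Checks, exactly on all monomials in (z, zb, h, hb, k) up to a total
#' degree, that the brackets close as
#' `[A1,A2] = A1`, `[A2,A3] = A3`, `[A3,A1] = -2 A2` and identically for
#' the B copy.
#'
#' @param max_degree highest total monomial degree tested (default 3).
#' @param tol coefficient tolerance for exact polynomial comparison.
#' @return list with logical `pass` and a data.frame `report` of each
#'   bracket's worst-case violation.
#' @export
commutator_check <- function(max_degree = 3L, tol = 1e-12) {
  rel <- list(
    list(x = "A1", y = "A2", expect = "A1", sign = 1),
    list(x = "A2", y = "A3", expect = "A3", sign = 1),
    list(x = "A3", y = "A1", expect = "A2", sign = -2),
    list(x = "B1", y = "B2", expect = "B1", sign = 1),
    list(x = "B2", y = "B3", expect = "B3", sign = 1),
    list(x = "B3", y = "B1", expect = "B2", sign = -2))
  monos <- lie_monomial_basis(max_degree)
  rows <- lapply(rel, function(rl) {
    ok <- TRUE
    for (p in monos) {
      lhs <- lie_poly_add(lie_apply_poly(rl$x, lie_apply_poly(rl$y, p)),
                          lie_poly_scale(
                            lie_apply_poly(rl$y, lie_apply_poly(rl$x, p)), -1))
      rhs <- lie_poly_scale(lie_apply_poly(rl$expect, p), rl$sign)
      if (!lie_poly_equal(lhs, rhs, tol)) { ok <- FALSE; break }
    }
    data.frame(bracket = sprintf("[%s,%s]", rl$x, rl$y),
               expected = sprintf("%+g %s", rl$sign, rl$expect),
               pass = ok)
  })
  report <- do.call(rbind, rows)
  list(pass = all(report$pass), report = report)
}

lie_monomial_basis <- function(max_degree) {
  grid <- expand.grid(rep(list(0:max_degree), 5L))
  grid <- grid[rowSums(grid) <= max_degree, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    pw <- matrix(as.integer(grid[i, ]), 1L, 5L,
                 dimnames = list(NULL, .lie_vars))
    lie_poly(1 + 0i, pw)
  })
}

#' Joint invariants of the two isomorphic group actions
#'
#' The functions annihilated by all three combined generators
#' (A_i + B_i) f = 0 link the scale-space coordinate h to the usual-space
#' coordinate z.  The primary invariant is the two-point cross-ratio
#' rho^2 = ((h - z)(hb - zb)) / ((h - zb)(hb - z)); the second,
#' k-dependent invariant is k^2 (hb - z)(hb - zb) / ((h - z)(h - zb)),
#' the unique translation-invariant, scaling-balanced form annihilated by
#' A3's (h - hb) k d/dk term.  Evaluated at physical points, `zb` and `hb`
#' are the complex conjugates of `z` and `h`.
#'
#' @param z,h complex points (z in the usual space, h in the scale space);
#'   z must differ from Conj(h).
#' @param k positive unidimensional factor.
#' @return list of class `"joint_invariant"` with elements `rho2`
#'   (real), `aux` (complex second invariant), and the input point.
#' @examples
#' joint_invariant(z = 1i, h = 2i, k = 1)$rho2   # 1/9
#' @export
joint_invariant <- function(z, h, k = 1) {
  stopifnot(length(z) == 1L, length(h) == 1L, is.numeric(k), k > 0)
  z <- as.complex(z); h <- as.complex(h)
  zb <- Conj(z); hb <- Conj(h)
  if (abs(h - zb) < 1e-12 || abs(hb - z) < 1e-12)
    stop("singular configuration: z coincides with Conj(h)", call. = FALSE)
  rho2 <- ((h - z) * (hb - zb)) / ((h - zb) * (hb - z))
  aux <- k^2 * (hb - z) * (hb - zb) / ((h - z) * (h - zb))
  structure(list(rho2 = Re(rho2), aux = aux,
                 point = list(z = z, h = h, k = k)),
            class = "joint_invariant")
}

# the two invariants as plain functions of five independent coordinates,
# used by the Stoka-system residual tests
joint_invariant_fn <- function(which = c("rho2", "aux")) {
  which <- match.arg(which)
  if (which == "rho2")
    function(z, zb, h, hb, k) ((h - z) * (hb - zb)) / ((h - zb) * (hb - z))
  else
    function(z, zb, h, hb, k) k^2 * (hb - z) * (hb - zb) / ((h - z) * (h - zb))
}

# random five-coordinate point kept clear of the invariants' poles so
# finite-difference residuals stay well below the 1e-8 test tolerance
random_invariant_point <- function(min_sep = 0.4) {
  repeat {
    p <- list(z = stats::rnorm(1) + 1i * stats::rnorm(1),
              zb = stats::rnorm(1) + 1i * stats::rnorm(1),
              h = stats::rnorm(1) + 1i * stats::rnorm(1),
              hb = stats::rnorm(1) + 1i * stats::rnorm(1),
              k = stats::runif(1, 0.5, 2))
    v <- c(p$z, p$zb, p$h, p$hb)
    if (min(Mod(outer(v, v, "-")[upper.tri(diag(4))])) >= min_sep) return(p)
  }
}

#' Residuals of the Stoka system on the joint invariants
#'
#' Evaluates |(A_i + B_i) f| for i = 1, 2, 3 on either implemented
#' invariant at a given point of the five-coordinate space (independent
#' variables; no conjugacy is imposed).
#'
#' @param which `"rho2"` or `"aux"`.
#' @param point named list with `z, zb, h, hb, k`.
#' @return numeric vector of three absolute residuals.
#' @export
stoka_residuals <- function(which = c("rho2", "aux"), point) {
  f <- joint_invariant_fn(which)
  vapply(1:3, function(i) {
    Mod(lie_apply(paste0("A", i), f, point) +
          lie_apply(paste0("B", i), f, point))
  }, numeric(1))
}

#' Link between the invariant and the hyperbolic parameter
#'
#' The cross-ratio invariant and the hyperbolic phase parameter are tied by
#' rho = tanh(mu); these helpers convert between the two.
#'
#' @param rho value in (-1, 1).
#' @param mu real value.
#' @return the converted parameter.
#' @export
mu_from_rho <- function(rho) {
  stopifnot(is.numeric(rho), all(abs(rho) < 1))
  atanh(rho)
}

#' @rdname mu_from_rho
#' @export
rho_from_mu <- function(mu) {
  stopifnot(is.numeric(mu))
  tanh(mu)
}

#' Map a scale-space phase series into the usual space
#'
#' The linear relation z(s) = u + v h0(s) carries the phase parameter h0
#' (from [phase_parameter()]) into the usual-space coordinate.
#'
#' @param h0 a [phase_parameter()] object or a complex vector.
#' @param u real offset.
#' @param v positive scale factor.
#' @return complex vector z(s) (with the grid attached when `h0` carries one).
#' @export
scale_to_usual_map <- function(h0, u, v) {
  stopifnot(is.numeric(u), is.numeric(v), length(v) == 1L)
  if (!is.finite(v) || v <= 0) stop("v must be positive", call. = FALSE)
  h <- if (inherits(h0, "phase_parameter")) h0$h else as.complex(h0)
  z <- u + v * h
  if (inherits(h0, "phase_parameter")) attr(z, "s") <- h0$s
  z
}
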