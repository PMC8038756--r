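# Independent numerical oracles used across the suite.

# adaptive numeric integration of the scale gauge dw/ds = w^2/M - (2R/M) w + K
# as a real 2-component system (deSolve), independent of the closed form
integrate_riccati <- function(gauge, w_init, s_grid, rtol = 1e-12,
                              atol = 1e-12) {
  rhs <- function(s, y, parms) {
    w <- complex(real = y[1], imaginary = y[2])
    dw <- w^2 / gauge$M - (2 * gauge$R / gauge$M) * w + gauge$K
    list(c(Re(dw), Im(dw)))
  }
  out <- deSolve::ode(y = c(Re(w_init), Im(w_init)), times = s_grid,
                      func = rhs, parms = NULL, rtol = rtol, atol = atol)
  complex(real = out[, 2], imaginary = out[, 3])
}

# numeric central derivative of a scalar function
num_deriv <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# random Mobius element with determinant bounded away from zero
random_mobius <- function() {
  repeat {
    v <- stats::rnorm(4)
    if (abs(v[1] * v[4] - v[3] * v[2]) > 0.3)
      return(mobius_element(v[1], v[2], v[3], v[4]))
  }
}
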