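# Calibration of release and kill curves: bounded Levenberg-Marquardt
# least squares with seeded Latin-hypercube multi-start.

curve_columns <- function(data) {
  if (is.list(data) && !is.data.frame(data)) data <- as.data.frame(data)
  nm <- names(data)
  tcol <- intersect(c("time_h", "t", "time"), nm)[1]
  ycol <- intersect(c("value", "F", "V", "y"), nm)[1]
  if (is.na(tcol) || is.na(ycol))
    stop("data must have a time column (time_h/t) and a response column ",
         "(value/F/V)", call. = FALSE)
  t <- as.numeric(data[[tcol]]); y <- as.numeric(data[[ycol]])
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop("non-finite values in the curve", call. = FALSE)
  ord <- order(t)
  list(t = t[ord], y = y[ord])
}

model_bounds <- function(model, t, y) {
  t_max <- max(t); y_max <- max(abs(y), 1e-8)
  k_hi <- 100 * y_max / max(t_max, 1e-6)
  b <- switch(model,
    mf_kink          = list(lo = c(Finf = 1e-3, tau = 1e-3, c = 1e-2),
                            hi = c(Finf = 110, tau = 10 * t_max, c = 10)),
    mf_logistic      = list(lo = c(Finf = 1e-3, f = 1e-4, w0 = 1e-6),
                            hi = c(Finf = 110, f = 100, w0 = 1)),
    zero_order       = list(lo = c(k = 1e-8), hi = c(k = k_hi)),
    first_order      = list(lo = c(Finf = 1e-3, k = 1e-6),
                            hi = c(Finf = 110, k = 100)),
    higuchi          = list(lo = c(k = 1e-8), hi = c(k = k_hi)),
    hixson_crowell   = list(lo = c(Finf = 1e-3, k = 1e-8),
                            hi = c(Finf = 110, k = 10 / max(t_max, 1e-6))),
    korsmeyer_peppas = list(lo = c(k = 1e-8, n = 0.05),
                            hi = c(k = k_hi, n = 10)),
    mf_antikink      = list(lo = c(Vres = 0, tau = 1e-3, c = 1e-2),
                            hi = c(Vres = 0.999, tau = 10 * t_max, c = 10)),
    stop("unknown model: ", model, call. = FALSE))
  b
}

# deterministic, data-informed central start appended to the LHS draws
model_heuristic_start <- function(model, t, y) {
  t_max <- max(t); y_end <- y[length(y)]
  pos <- function(x, lo = 1e-3) max(x, lo)
  switch(model,
    mf_kink = c(Finf = min(pos(max(y)), 110), tau = pos(t_max / 4), c = 1),
    mf_logistic = c(Finf = min(pos(max(y)), 110), f = pos(2 / t_max),
                    w0 = min(max(y[1] / pos(max(y)), 1e-3), 1)),
    zero_order = c(k = pos(y_end / pos(t_max))),
    first_order = c(Finf = min(pos(max(y)), 110), k = pos(2 / t_max)),
    higuchi = c(k = pos(y_end / sqrt(pos(t_max)))),
    hixson_crowell = c(Finf = min(pos(max(y)), 110), k = pos(0.5 / t_max)),
    korsmeyer_peppas = c(k = pos(y_end / pos(t_max)), n = 0.5),
    mf_antikink = c(Vres = max(min(y), 0), tau = pos(t_max / 4), c = 1))
}

lm_single_fit <- function(model, start, t, y, w, lo, hi) {
  resid_fn <- function(par) {
    names(par) <- names(start)
    sqrt(w) * (model_curve(model, par, t) - y)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lo, upper = hi, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(par = stats::setNames(as.numeric(fit$par), names(start)),
       ssr = fit$deviance, info = fit$info, message = fit$message,
       hessian = fit$hessian)
}

#' Fit a release model to a cumulative-release curve
#'
#' The package's central calibration routine: weighted nonlinear least
#' squares (Levenberg-Marquardt with box bounds) with a seeded
#' Latin-hypercube multi-start, fitting any model from [release_models()]
#' to a time series of cumulative release.  The default `mf_kink` model
#' F(t) = Finf tanh((t/tau)^c) exposes the fitted exponent `c` as the
#' sample's fractality degree.
#'
#' @param data a data.frame with a time column (`time_h` or `t`, hours) and
#'   a response column (`value` or `F`, percent released) — e.g. the output
#'   of [read_timeseries_csv()] or [generate_release()].
#' @param model model id (see [release_models()]); internally
#'   `"mf_antikink"` is also accepted for kill curves (see [kill_fit()]).
#' @param weights `"none"` (ordinary least squares, default) or
#'   `"inverse_f"` (weights proportional to 1/max(F, 1), stabilising the
#'   early-time burst points).
#' @param n_starts number of Latin-hypercube starting points (default 16);
#'   a deterministic data-driven start is always added.
#' @param seed integer seed controlling the multi-start draw.
#' @return an object of class `"release_fit"` with components
#'   `coefficients`, `se`, `vcov`, `fitted.values`, `residuals`,
#'   `r_squared`, `sigma`, `aicc`, `converged`, `model`, `data`, `seed`.
#'   Supported methods: `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' curve <- generate_release(seed = 7)
#' fit <- release_fit(curve)
#' coef(fit)
#' @export
release_fit <- function(data, model = "mf_kink",
                        weights = c("none", "inverse_f"),
                        n_starts = 16L, seed = 1L) {
  weights <- match.arg(weights)
  xy <- curve_columns(data)
  t <- xy$t; y <- xy$y
  p <- length(model_par_names(model))
  if (length(t) < p + 2L)
    stop("insufficient data: need at least ", p + 2L, " points for model '",
         model, "'", call. = FALSE)
  if (anyDuplicated(t))
    stop("duplicate time points in the curve", call. = FALSE)
  if (diff(range(y)) == 0)
    stop("degenerate data: response is constant", call. = FALSE)
  w <- if (weights == "inverse_f") 1 / pmax(abs(y), 1) else rep(1, length(y))

  b <- model_bounds(model, t, y)
  lo <- b$lo; hi <- b$hi
  nms <- names(lo)
  starts <- list(model_heuristic_start(model, t, y)[nms])
  if (n_starts > 0L) {
    u <- with_seed(seed, lhs::randomLHS(as.integer(n_starts), length(nms)))
    # log-uniform over the box for scale-like parameters
    for (i in seq_len(nrow(u))) {
      span <- log(hi / pmax(lo, 1e-10))
      st <- pmax(lo, 1e-10) * exp(u[i, ] * span)
      names(st) <- nms
      starts[[length(starts) + 1L]] <- pmin(pmax(st, lo), hi)
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- lm_single_fit(model, st, t, y, w, lo, hi)
    if (!is.null(fit) && (is.null(best) || fit$ssr < best$ssr)) best <- fit
  }
  if (is.null(best))
    stop("all optimisation starts failed for model '", model, "'",
         call. = FALSE)

  theta <- best$par
  fitted <- model_curve(model, theta, t)
  res <- y - fitted
  n <- length(y)
  rss <- sum(w * res^2)
  dof <- n - p
  sigma <- sqrt(rss / max(dof, 1))
  tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
  r2 <- 1 - rss / tss
  # small-sample corrected information criterion (Gaussian likelihood)
  aicc <- n * log(rss / n) + 2 * p +
    if (n - p - 1 > 0) 2 * p * (p + 1) / (n - p - 1) else Inf
  vcov <- fit_vcov(best$hessian, sigma, nms)
  # nls.lm info 1-3: ftol/ptol criteria met; 4: gradient orthogonality met
  converged <- best$info %in% 1:4
  structure(list(coefficients = theta,
                 se = sqrt(pmax(diag(vcov), 0)),
                 vcov = vcov,
                 fitted.values = fitted,
                 residuals = res,
                 r_squared = r2, sigma = sigma, aicc = aicc,
                 converged = converged, optim_info = best$info,
                 optim_message = best$message,
                 model = model, weights_mode = weights,
                 data = data.frame(time_h = t, value = y, weight = w),
                 n_starts = n_starts, seed = seed,
                 response = if (model == "mf_antikink") "kill" else "release"),
            class = "release_fit")
}

fit_vcov <- function(hessian, sigma, nms) {
  # nls.lm hessian approximates J'J (unit weights absorbed in residual fn)
  v <- tryCatch(sigma^2 * solve(hessian), error = function(e)
    matrix(NA_real_, length(nms), length(nms)))
  dimnames(v) <- list(nms, nms)
  v
}

#' Fit the antikink kill law to a viable-fraction curve
#'
#' Calibrates V(t) = Vres + (1 - Vres)(1 - tanh((t/tau)^c)), the
#' antikink-type observable describing the decline of the viable fungal
#' population under drug release; V(0) = 1 by construction.
#'
#' @param data a data.frame with time (`time_h`/`t`, hours) and viable
#'   fraction (`value`/`V`).
#' @inheritParams release_fit
#' @return a `"release_fit"` object with `response = "kill"`.
#' @export
kill_fit <- function(data, weights = c("none", "inverse_f"),
                     n_starts = 16L, seed = 1L) {
  release_fit(data, model = "mf_antikink", weights = match.arg(weights),
              n_starts = n_starts, seed = seed)
}

#' @export
print.release_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s curve fit: model '%s'%s\n",
              if (x$response == "kill") "Kill" else "Release", x$model,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(signif(x$coefficients, digits))
  cat(sprintf("R-squared %.4f, sigma %.4g, AICc %.4g, n = %d\n",
              x$r_squared, x$sigma, x$aicc, nrow(x$data)))
  invisible(x)
}

#' @export
summary.release_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se)
  structure(list(model = object$model, coefficients = tab,
                 r_squared = object$r_squared, sigma = object$sigma,
                 aicc = object$aicc, converged = object$converged,
                 n = nrow(object$data), response = object$response),
            class = "summary.release_fit")
}

#' @export
print.summary.release_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Model: %s (%s observable), n = %d%s\n", x$model, x$response,
              x$n, if (x$converged) "" else "  [NOT CONVERGED]"))
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("R-squared %.4f, residual sigma %.4g, AICc %.4g\n",
              x$r_squared, x$sigma, x$aicc))
  invisible(x)
}

#' @export
coef.release_fit <- function(object, ...) object$coefficients

#' @export
vcov.release_fit <- function(object, ...) object$vcov

#' @export
fitted.release_fit <- function(object, ...) object$fitted.values

#' @export
residuals.release_fit <- function(object, ...) object$residuals

#' @export
predict.release_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_h
       else curve_columns_time(newdata)
  model_curve(object$model, object$coefficients, t)
}

curve_columns_time <- function(newdata) {
  if (is.numeric(newdata)) return(as.numeric(newdata))
  nm <- names(newdata)
  tcol <- intersect(c("time_h", "t", "time"), nm)[1]
  if (is.na(tcol)) stop("newdata must contain a time column", call. = FALSE)
  as.numeric(newdata[[tcol]])
}

#' @export
plot.release_fit <- function(x, ...) {
  t <- x$data$time_h; y <- x$data$value
  tt <- seq(min(t), max(t), length.out = 200)
  graphics::plot(t, y, xlab = "time [h]",
                 ylab = if (x$response == "kill") "viable fraction"
                        else "cumulative release [%]",
                 main = sprintf("model '%s'", x$model), ...)
  graphics::lines(tt, model_curve(x$model, x$coefficients, tt))
  invisible(x)
}

#' @export
simulate.release_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- object$fitted.values
  n <- length(mu)
  draw <- function() pmax(mu + stats::rnorm(n, 0, object$sigma), 0)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "time_h") <- object$data$time_h
  out
}

#' Fit and rank several release models on one curve
#'
#' @param data as in [release_fit()].
#' @param models character vector of at least two model ids.
#' @param weights,n_starts,seed passed to [release_fit()].
#' @return data.frame (one row per model, ranked by small-sample
#'   information criterion) with the fitted objects in attribute `"fits"`.
#' @export
compare_release_models <- function(data, models = release_models(),
                                   weights = "none", n_starts = 16L,
                                   seed = 1L) {
  if (length(models) < 2L)
    stop("need at least two candidate models to compare", call. = FALSE)
  fits <- lapply(models, function(m)
    tryCatch(release_fit(data, model = m, weights = weights,
                         n_starts = n_starts, seed = seed),
             error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  tab <- data.frame(
    model = models,
    converged = vapply(fits, function(f)
      if (inherits(f, "error")) NA else f$converged, logical(1)),
    r_squared = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$r_squared, numeric(1)),
    aicc = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$aicc, numeric(1)),
    error = vapply(fits, function(f)
      if (inherits(f, "error")) conditionMessage(f) else "", character(1)))
  tab$rank <- rank(tab$aicc, na.last = "keep", ties.method = "first")
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- stats::setNames(fits, models)
  tab
}

#' Fractality-degree report for a sample pair
#'
#' Summarises two converged kink-type fits by their fitted exponents
#' (fractality degrees), the exponent ratio, and the release-rate ordering
#' judged from the fractional release predicted at a reference time.
#' Purely descriptive: no ground truth is asserted.
#'
#' @param fit_a,fit_b converged `"release_fit"` objects whose models carry
#'   a `c` exponent (`mf_kink` or `mf_antikink`).
#' @param t_ref reference time in hours for the rate ordering (default 4,
#'   the end of the burst window).
#' @return list of class `"fractality_report"`: exponents `c_a`, `c_b`,
#'   `ratio` (= larger/smaller), `higher_fractality` (`"a"` or `"b"`),
#'   `faster_release` at `t_ref`.
#' @export
fractality_report <- function(fit_a, fit_b, t_ref = 4) {
  for (f in list(fit_a, fit_b)) {
    stopifnot(inherits(f, "release_fit"))
    if (!f$converged)
      stop("refusing report: a fit did not converge", call. = FALSE)
    if (!"c" %in% names(f$coefficients))
      stop("refusing report: fit has no fractality exponent", call. = FALSE)
  }
  c_a <- unname(fit_a$coefficients["c"])
  c_b <- unname(fit_b$coefficients["c"])
  frac_rel <- function(f) {
    th <- f$coefficients
    v <- model_curve(f$model, th, t_ref)
    if ("Finf" %in% names(th)) v / th[["Finf"]] else v
  }
  ra <- frac_rel(fit_a); rb <- frac_rel(fit_b)
  structure(list(c_a = c_a, c_b = c_b,
                 ratio = max(c_a, c_b) / min(c_a, c_b),
                 higher_fractality = if (c_a >= c_b) "a" else "b",
                 faster_release = if (ra >= rb) "a" else "b",
                 t_ref = t_ref),
            class = "fractality_report")
}

#' @export
print.fractality_report <- function(x, ...) {
  cat("Fractality-degree report\n")
  cat(sprintf("  exponent a: %.4g   exponent b: %.4g   ratio: %.4g\n",
              x$c_a, x$c_b, x$ratio))
  cat(sprintf("  higher fractality: sample %s; faster release at %g h: sample %s\n",
              x$higher_fractality, x$t_ref, x$faster_release))
  invisible(x)
}
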