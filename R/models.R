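# Release-model library: the multifractal kink and logistic observables
# plus the classical dissolution models they are compared against.

#' Available release-model identifiers
#' @return character vector of model ids.
#' @export
release_models <- function() {
  c("mf_kink", "mf_logistic", "zero_order", "first_order",
    "higuchi", "hixson_crowell", "korsmeyer_peppas")
}

model_par_names <- function(model) {
  switch(model,
    mf_kink          = c("Finf", "tau", "c"),
    mf_logistic      = c("Finf", "f", "w0"),
    zero_order       = "k",
    first_order      = c("Finf", "k"),
    higuchi          = "k",
    hixson_crowell   = c("Finf", "k"),
    korsmeyer_peppas = c("k", "n"),
    mf_antikink      = c("Vres", "tau", "c"),
    stop("unknown model: ", model, call. = FALSE))
}

validate_theta <- function(model, theta) {
  nm <- model_par_names(model)
  if (!all(nm %in% names(theta)))
    stop("model '", model, "' needs parameters ",
         paste(nm, collapse = ", "), call. = FALSE)
  theta <- theta[nm]
  if (any(!is.finite(theta))) stop("non-finite parameters", call. = FALSE)
  if (any(theta[names(theta) %in% c("tau", "c", "k", "n", "f")] <= 0))
    stop("scale and exponent parameters must be positive", call. = FALSE)
  if ("Finf" %in% nm && (theta["Finf"] <= 0 || theta["Finf"] > 110))
    stop("Finf must lie in (0, 110]", call. = FALSE)
  if ("w0" %in% nm && (theta["w0"] <= 0 || theta["w0"] > 1))
    stop("w0 must lie in (0, 1]", call. = FALSE)
  if ("Vres" %in% nm && (theta["Vres"] < 0 || theta["Vres"] >= 1))
    stop("Vres must lie in [0, 1)", call. = FALSE)
  theta
}

#' Evaluate a release (or kill) model curve
#'
#' The in-house observable maps the kink's scale variable to laboratory
#' time through s = (t/tau)^c, giving the cumulative-release law
#' F(t) = Finf tanh((t/tau)^c); the exponent c plays the role of the
#' sample's fractality degree and c = 1 recovers a pure tanh law.  The
#' classical comparators use their standard forms; Hixson-Crowell is
#' clipped at complete dissolution (k t >= 1).
#'
#' Model forms (t in hours, F in % released):
#' \itemize{
#'   \item `mf_kink`: `Finf * tanh((t/tau)^c)`
#'   \item `mf_logistic`: `Finf / (1 - (1 - 1/w0) exp(-f t))`
#'   \item `zero_order`: `k t`
#'   \item `first_order`: `Finf (1 - exp(-k t))`
#'   \item `higuchi`: `k sqrt(t)`
#'   \item `hixson_crowell`: `Finf (1 - (1 - k t)^3)`, clipped at `Finf`
#'   \item `korsmeyer_peppas`: `k t^n`
#'   \item `mf_antikink` (kill observable): `Vres + (1 - Vres)(1 - tanh((t/tau)^c))`
#' }
#'
#' @param model a model id from [release_models()] or `"mf_antikink"`.
#' @param theta named parameter vector (see Details).
#' @param t nonnegative time grid in hours.
#' @return numeric response series.
#' @examples
#' model_curve("mf_kink", c(Finf = 100, tau = 4, c = 1.7), t = c(0, 4, 24))
#' @export
model_curve <- function(model, theta, t) {
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0))
  theta <- validate_theta(model, theta)
  th <- as.list(theta)
  switch(model,
    mf_kink = th$Finf * tanh((t / th$tau)^th$c),
    mf_logistic = {
      lp <- logistic_params(th$f, th$w0)
      th$Finf * logistic_profile(lp, t)
    },
    zero_order = th$k * t,
    first_order = th$Finf * (1 - exp(-th$k * t)),
    higuchi = th$k * sqrt(t),
    hixson_crowell = ifelse(th$k * t < 1,
                            th$Finf * (1 - (1 - th$k * t)^3), th$Finf),
    korsmeyer_peppas = th$k * t^th$n,
    mf_antikink = th$Vres + (1 - th$Vres) * (1 - tanh((t / th$tau)^th$c)))
}
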