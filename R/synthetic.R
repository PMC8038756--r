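# Seeded generators emulating the study's laboratory observables: a burst
# release within the first ~4 h followed by a plateau below 100%, a
# monotonically declining viable-fungi curve, and a two-sample design in
# which the higher-loading hydrogel releases faster and kills faster.

#' Time sampling schemes for synthetic curves
#'
#' `"front_loaded"` (default) places 8 points in the burst window [0, 4] h
#' and spreads the remainder uniformly to `t_max`, mirroring the sampling
#' density needed to resolve a burst; `"uniform"` is equispaced on
#' [0, t_max].
#'
#' @param n_points number of time points (>= 2).
#' @param t_max final time in hours (default 24).
#' @param sampling `"front_loaded"` or `"uniform"`.
#' @return strictly increasing numeric time grid starting at 0.
#' @export
sample_times <- function(n_points = 25L, t_max = 24,
                         sampling = c("front_loaded", "uniform")) {
  sampling <- match.arg(sampling)
  stopifnot(n_points >= 2L, t_max > 0)
  if (sampling == "uniform" || t_max <= 4 || n_points <= 8L)
    return(seq(0, t_max, length.out = n_points))
  n_burst <- 8L
  burst <- seq(0, 4, length.out = n_burst)
  late <- seq(4, t_max, length.out = n_points - n_burst + 1L)[-1]
  c(burst, late)
}

#' Generate a synthetic cumulative-release curve
#'
#' Draws F(t_i) = model_curve(truth) + N(0, noise_sd), clipped below at 0
#' (no upper clip, so fits must handle slight overshoot as real UV-Vis
#' readings do).  The default truth (Finf = 100, tau = 4 h, c = 1.7)
#' produces the study's canonical morphology: a burst over the first four
#' hours followed by a prolonged approach to a plateau at or below 100%.
#'
#' @param truth list with elements `model` and named `theta`
#'   (default `mf_kink` with Finf = 100, tau = 4, c = 1.7).
#' @param n_points,t_max,sampling see [sample_times()].
#' @param noise_sd Gaussian noise standard deviation in % units (default 2).
#' @param seed integer seed; identical seeds give identical curves.
#' @param sample_id label attached to the curve (default "C0.142-like").
#' @param monotone if `TRUE`, apply an isotonic post-clip (cumulative
#'   maximum) so the noisy curve is non-decreasing.
#' @return data.frame with columns `time_h`, `value`, `sample_id`.
#' @examples
#' head(generate_release(seed = 1))
#' @export
generate_release <- function(truth = list(model = "mf_kink",
                                          theta = c(Finf = 100, tau = 4,
                                                    c = 1.7)),
                             n_points = 25L, t_max = 24,
                             sampling = "front_loaded",
                             noise_sd = 2, seed = 1L,
                             sample_id = "C0.142-like",
                             monotone = FALSE) {
  stopifnot(noise_sd >= 0)
  t <- sample_times(n_points, t_max, sampling)
  mu <- model_curve(truth$model, truth$theta, t)   # validates truth
  y <- if (noise_sd > 0)
    with_seed(seed, pmax(mu + stats::rnorm(length(t), 0, noise_sd), 0))
  else mu
  if (monotone) y <- cummax(y)
  data.frame(time_h = t, value = y, sample_id = sample_id)
}

#' Generate a synthetic fungal-kill curve
#'
#' Draws the viable fraction around the antikink observable
#' V(t) = Vres + (1 - Vres)(1 - tanh((t/tau)^c)); Vres near 0 encodes the
#' almost-complete-extinction scenario.
#'
#' @param truth named vector `c(Vres, tau, c)` (default Vres = 0.02,
#'   tau = 6 h, c = 1.7).
#' @param noise_sd Gaussian noise sd in viable-fraction units (default 0.02).
#' @inheritParams generate_release
#' @return data.frame with columns `time_h`, `value`, `sample_id`.
#' @export
generate_kill <- function(truth = c(Vres = 0.02, tau = 6, c = 1.7),
                          n_points = 25L, t_max = 24,
                          sampling = "front_loaded",
                          noise_sd = 0.02, seed = 1L,
                          sample_id = "strain-A") {
  stopifnot(noise_sd >= 0)
  t <- sample_times(n_points, t_max, sampling)
  mu <- model_curve("mf_antikink", truth, t)
  y <- if (noise_sd > 0)
    with_seed(seed, pmax(mu + stats::rnorm(length(t), 0, noise_sd), 0))
  else mu
  data.frame(time_h = t, value = y, sample_id = sample_id)
}

#' Generate a paired two-sample release/kill study
#'
#' Emulates the study's two hydrogel loadings: the higher-loading sample
#' must dominate the lower one in cumulative release at every time
#' (checked on the noiseless curves), and kills faster (lower kill tau).
#'
#' @param truth_low,truth_high release truths as in [generate_release()];
#'   defaults give a slower (tau = 6 h) and faster (tau = 3 h) sample.
#' @param kill_low,kill_high kill truths as in [generate_kill()].
#' @param noise_sd,kill_noise_sd noise levels for the two observables.
#' @param n_points,t_max,sampling shared sampling scheme.
#' @param seed integer master seed (sub-seeds are derived per curve).
#' @return list with data.frames `release` and `kill`, each stacking the
#'   low- and high-loading samples (labels "C0.071-like", "C0.142-like").
#' @export
generate_two_sample_study <- function(
    truth_low = list(model = "mf_kink",
                     theta = c(Finf = 90, tau = 6, c = 1.7)),
    truth_high = list(model = "mf_kink",
                      theta = c(Finf = 98, tau = 3, c = 1.7)),
    kill_low = c(Vres = 0.10, tau = 9, c = 1.7),
    kill_high = c(Vres = 0.02, tau = 5, c = 1.7),
    noise_sd = 2, kill_noise_sd = 0.02,
    n_points = 25L, t_max = 24, sampling = "front_loaded",
    seed = 1L) {
  t_dense <- seq(0, t_max, length.out = 241L)
  f_lo <- model_curve(truth_low$model, truth_low$theta, t_dense)
  f_hi <- model_curve(truth_high$model, truth_high$theta, t_dense)
  if (any(f_hi < f_lo - 1e-12))
    stop("invalid design: the high-loading release truth must dominate the ",
         "low-loading truth at every time", call. = FALSE)
  v_lo <- model_curve("mf_antikink", kill_low, t_dense)
  v_hi <- model_curve("mf_antikink", kill_high, t_dense)
  if (any(v_hi > v_lo + 1e-12))
    stop("invalid design: the high-loading kill truth must lie below the ",
         "low-loading truth at every time", call. = FALSE)
  seed <- as.integer(seed)
  rel <- rbind(
    generate_release(truth_low, n_points, t_max, sampling, noise_sd,
                     seed = seed, sample_id = "C0.071-like"),
    generate_release(truth_high, n_points, t_max, sampling, noise_sd,
                     seed = seed + 1L, sample_id = "C0.142-like"))
  kil <- rbind(
    generate_kill(kill_low, n_points, t_max, sampling, kill_noise_sd,
                  seed = seed + 2L, sample_id = "C0.071-like"),
    generate_kill(kill_high, n_points, t_max, sampling, kill_noise_sd,
                  seed = seed + 3L, sample_id = "C0.142-like"))
  list(release = rel, kill = kil,
       truths = list(release_low = truth_low, release_high = truth_high,
                     kill_low = kill_low, kill_high = kill_high))
}

#' Deterministic gauge-parameter fixtures
#'
#' Emits seeded (M, R, K, r) sets constructed so the characteristic
#' frequency is real (`"oscillatory"`: K/M > (R/M)^2) or purely imaginary
#' (`"damped"`: K/M < (R/M)^2), for use in scale-dynamics test suites.
#'
#' @param seed integer seed.
#' @param regime `"oscillatory"` or `"damped"`.
#' @param n number of parameter sets.
#' @param r_max largest |r| drawn (default 0.9, inside the bounded band).
#' @return list of lists, each with a `gauge` ([scale_gauge()]) and `r`.
#' @export
fixture_gauge_params <- function(seed = 1L,
                                 regime = c("oscillatory", "damped"),
                                 n = 10L, r_max = 0.9) {
  regime <- match.arg(regime)
  with_seed(seed, lapply(seq_len(n), function(i) {
    M <- stats::runif(1, 0.5, 3) * sample(c(-1, 1), 1)
    R <- stats::runif(1, -1, 1)
    ratio2 <- (R / M)^2
    # choose Omega^2 = K/M - (R/M)^2 with the requested sign, then solve for K
    target <- if (regime == "oscillatory") stats::runif(1, 0.25, 4)
              else -stats::runif(1, 0.25, 4)
    K <- M * (target + ratio2)
    r <- stats::runif(1, 0.05, r_max) * sample(c(-1, 1), 1)
    list(gauge = scale_gauge(M, R, K), r = r)
  }))
}
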