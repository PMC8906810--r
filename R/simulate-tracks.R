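#' Parameters for the persistent-random-walk track simulator
#'
#' The simulator models each coordinate of the cell velocity as a stationary
#' Ornstein--Uhlenbeck (OU) process with relaxation time `P` (the directional
#' persistence time) and stationary per-axis velocity variance `D / P`.  The
#' position is the exact time integral of that velocity, so the ensemble
#' two-dimensional mean squared displacement has expectation
#' \deqn{MSD(t) = 4 D \left( t - P (1 - e^{-t/P}) \right)}
#' at every lag, with no step-size bias.
#'
#' @param D Diffusion coefficient, um^2/min.
#' @param P Directional persistence time, minutes.
#' @param frame_interval Sampling interval, seconds.
#' @param duration Track duration, seconds.  Must be at least
#'   `10 * frame_interval`.
#' @param n_tracks Number of tracks to simulate.
#' @param seed Integer seed; identical parameters and seed give identical
#'   tracks.
#'
#' @return A list of class `prw_params`.
#' @export
prw_params <- function(D = 5, P = 2, frame_interval = 15, duration = 3600,
                       n_tracks = 500, seed = NULL) {
  check_positive_scalar(D, "D")
  check_positive_scalar(P, "P")
  check_positive_scalar(frame_interval, "frame_interval")
  check_positive_scalar(duration, "duration")
  if (duration < 10 * frame_interval) {
    abort("`duration` must be at least 10 frame intervals.",
          class = "mgca_parameter_error")
  }
  if (n_tracks < 1L) {
    abort("`n_tracks` must be at least 1.", class = "mgca_parameter_error")
  }
  structure(list(D = D, P = P, frame_interval = frame_interval,
                 duration = duration, n_tracks = as.integer(n_tracks),
                 seed = seed),
            class = "prw_params")
}

# Exact one-step discretization of the integrated OU velocity process
# (Gillespie 1996).  Returns the constant step covariance pieces for velocity
# update v' = mu * v + eps_v and displacement dx = v * P * (1 - mu) + eps_x.
ou_step_moments <- function(D, P, dt_min) {
  s2 <- D / P                      # stationary per-axis velocity variance
  mu <- exp(-dt_min / P)
  var_v <- s2 * (1 - mu^2)
  var_x <- s2 * P^2 * (2 * dt_min / P - 3 + 4 * mu - mu^2)
  cov_vx <- s2 * P * (1 - mu)^2
  # Cholesky factor of [[var_v, cov], [cov, var_x]]
  a <- sqrt(var_v)
  b <- cov_vx / a
  c <- sqrt(max(var_x - b^2, 0))
  list(mu = mu, s2 = s2, a = a, b = b, c = c)
}

#' Simulate persistent-random-walk cell tracks
#'
#' @param params A [prw_params()] object.
#'
#' @return A tibble with columns `track_id`, `frame`, `time_s`, `x_um`,
#'   `y_um`; one row per track per frame.
#' @examples
#' tracks <- simulate_prw_tracks(prw_params(D = 5, P = 2, n_tracks = 10,
#'                                          duration = 600, seed = 1))
#' @export
simulate_prw_tracks <- function(params) {
  stopifnot(inherits(params, "prw_params"))
  dt_min <- params$frame_interval / 60
  n_steps <- floor(params$duration / params$frame_interval)
  n_tracks <- params$n_tracks
  mom <- ou_step_moments(params$D, params$P, dt_min)

  with_seed_if(params$seed, {
    # state: per-track, per-axis velocity (um/min) and position (um)
    v <- matrix(rnorm(n_tracks * 2L, sd = sqrt(mom$s2)), n_tracks, 2L)
    x <- matrix(0, n_tracks, 2L)
    pos <- array(NA_real_, c(n_tracks, n_steps + 1L, 2L))
    pos[, 1L, ] <- x
    for (k in seq_len(n_steps)) {
      z1 <- matrix(rnorm(n_tracks * 2L), n_tracks, 2L)
      z2 <- matrix(rnorm(n_tracks * 2L), n_tracks, 2L)
      eps_v <- mom$a * z1
      eps_x <- mom$b * z1 + mom$c * z2
      x <- x + v * params$P * (1 - mom$mu) + eps_x
      v <- mom$mu * v + eps_v
      pos[, k + 1L, ] <- x
    }
    tibble::tibble(
      track_id = rep(seq_len(n_tracks), each = n_steps + 1L),
      frame = rep(seq_len(n_steps + 1L), times = n_tracks),
      time_s = (rep(seq_len(n_steps + 1L), times = n_tracks) - 1L) *
        params$frame_interval,
      x_um = as.vector(t(pos[, , 1L, drop = TRUE])),
      y_um = as.vector(t(pos[, , 2L, drop = TRUE]))
    )
  })
}

#' Closed-form persistent-random-walk mean squared displacement
#'
#' @param t Lag, minutes.
#' @param D Diffusion coefficient, um^2/min.
#' @param P Persistence time, minutes.
#' @return MSD in um^2.
#' @export
prw_msd <- function(t, D, P) {
  4 * D * (t - P * (1 - exp(-t / P)))
}

#' Parameters coupling instantaneous speed to a simulated calcium ratio
#'
#' Each cell carries a bounded, autocorrelated G/R ratio signal (an OU process
#' clipped to `[ratio_min, ratio_max]`); its target speed at frame `k` is
#' `max(0, speed_at_zero_ratio + coupling_slope * ratio_k + noise)`, and the
#' cell moves that far (per minute) along a direction that evolves as in the
#' persistent random walk.  A negative `coupling_slope` makes calcium slow
#' cells down.
#'
#' @param speed_at_zero_ratio Target speed at ratio 0, um/min.
#' @param coupling_slope Speed change per ratio unit, um/min.
#' @param ratio_mean,ratio_sd,ratio_tau Mean, stationary SD and relaxation
#'   time (seconds) of the latent ratio process.
#' @param ratio_min,ratio_max Bounds the ratio signal is clipped to.
#' @param speed_noise_sd SD of the per-frame speed noise, um/min.
#' @param seed Integer seed.
#' @return A list of class `coupling_params`.
#' @export
coupling_params <- function(speed_at_zero_ratio = 14, coupling_slope = -4,
                            ratio_mean = 1.2, ratio_sd = 0.5, ratio_tau = 60,
                            ratio_min = 0.05, ratio_max = 3,
                            speed_noise_sd = 1, seed = NULL) {
  check_nonneg_scalar(speed_at_zero_ratio, "speed_at_zero_ratio")
  check_positive_scalar(ratio_sd, "ratio_sd")
  check_positive_scalar(ratio_tau, "ratio_tau")
  check_nonneg_scalar(speed_noise_sd, "speed_noise_sd")
  if (ratio_min <= 0 || ratio_max <= ratio_min) {
    abort("require 0 < ratio_min < ratio_max.", class = "mgca_parameter_error")
  }
  structure(list(speed_at_zero_ratio = speed_at_zero_ratio,
                 coupling_slope = coupling_slope, ratio_mean = ratio_mean,
                 ratio_sd = ratio_sd, ratio_tau = ratio_tau,
                 ratio_min = ratio_min, ratio_max = ratio_max,
                 speed_noise_sd = speed_noise_sd, seed = seed),
            class = "coupling_params")
}

#' Simulate tracks whose speed is coupled to a calcium ratio signal
#'
#' @param prw A [prw_params()] object (supplies persistence time, frame
#'   interval, duration and track count; its seed is ignored in favour of
#'   `coupling$seed`).
#' @param coupling A [coupling_params()] object.
#'
#' @return A list with elements `tracks` (tibble: `track_id`, `frame`,
#'   `time_s`, `x_um`, `y_um`), `ratios` (tibble: `cell_id`, `frame`,
#'   `time_s`, `ratio`, sharing timestamps with the tracks), and `truth`
#'   (the generating parameters, including `coupling_slope`).
#' @export
simulate_coupled_tracks <- function(prw, coupling) {
  stopifnot(inherits(prw, "prw_params"), inherits(coupling, "coupling_params"))
  dt_min <- prw$frame_interval / 60
  n_steps <- floor(prw$duration / prw$frame_interval)
  n <- prw$n_tracks
  mom <- ou_step_moments(prw$D, prw$P, dt_min)
  # ratio OU: exact discretization at the track frame interval
  rmu <- exp(-prw$frame_interval / coupling$ratio_tau)
  rsd_step <- coupling$ratio_sd * sqrt(1 - rmu^2)

  with_seed_if(coupling$seed, {
    v <- matrix(rnorm(n * 2L, sd = sqrt(mom$s2)), n, 2L)
    r <- pmin(pmax(rnorm(n, coupling$ratio_mean, coupling$ratio_sd),
                   coupling$ratio_min), coupling$ratio_max)
    x <- matrix(0, n, 2L)
    pos <- array(NA_real_, c(n, n_steps + 1L, 2L))
    rat <- matrix(NA_real_, n, n_steps + 1L)
    pos[, 1L, ] <- x
    rat[, 1L] <- r
    for (k in seq_len(n_steps)) {
      speed <- pmax(0, coupling$speed_at_zero_ratio +
                      coupling$coupling_slope * r +
                      rnorm(n, sd = coupling$speed_noise_sd))
      vn <- row_norm(v)
      u <- v / ifelse(vn > 0, vn, 1)     # unit direction; degenerate v stays put
      x <- x + u * (speed * dt_min)
      v <- mom$mu * v + mom$a * matrix(rnorm(n * 2L), n, 2L)
      r <- pmin(pmax(rmu * (r - coupling$ratio_mean) + coupling$ratio_mean +
                       rnorm(n, sd = rsd_step),
                     coupling$ratio_min), coupling$ratio_max)
      pos[, k + 1L, ] <- x
      rat[, k + 1L] <- r
    }
    frames <- seq_len(n_steps + 1L)
    tracks <- tibble::tibble(
      track_id = rep(seq_len(n), each = n_steps + 1L),
      frame = rep(frames, times = n),
      time_s = (rep(frames, times = n) - 1L) * prw$frame_interval,
      x_um = as.vector(t(pos[, , 1L, drop = TRUE])),
      y_um = as.vector(t(pos[, , 2L, drop = TRUE]))
    )
    ratios <- tibble::tibble(
      cell_id = rep(seq_len(n), each = n_steps + 1L),
      frame = rep(frames, times = n),
      time_s = (rep(frames, times = n) - 1L) * prw$frame_interval,
      ratio = as.vector(t(rat))
    )
    list(tracks = tracks, ratios = ratios,
         truth = list(coupling_slope = coupling$coupling_slope,
                      speed_at_zero_ratio = coupling$speed_at_zero_ratio))
  })
}
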