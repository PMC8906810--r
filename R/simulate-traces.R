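#' Parameters for the biphasic calcium trace simulator
#'
#' Models an agonist-evoked cytosolic Ca2+ ratio trace as a baseline plus,
#' after the stimulus, a fast store-release peak (difference-of-exponentials
#' kernel, normalized so its maximum equals `peak_amplitude`) and a sustained
#' store-operated plateau (saturating exponential of amplitude
#' `plateau_amplitude`).  Setting `plateau_amplitude = 0` emulates the
#' Ca2+-free (store-release-only) condition.
#'
#' @param frame_interval Imaging interval, seconds.
#' @param duration Trace duration, seconds.
#' @param stim_time Agonist application time, seconds (must be < `duration`).
#' @param baseline_ratio Resting ratio (dimensionless).
#' @param peak_amplitude Peak height above baseline (delta ratio).
#' @param peak_rise_tau,peak_decay_tau Rise and decay time constants of the
#'   peak kernel, seconds.
#' @param plateau_amplitude Sustained-phase amplitude (delta ratio); 0 in the
#'   store-release-only mode.
#' @param plateau_rise_tau Plateau rise time constant, seconds.
#' @param noise_sd SD of the multiplicative ratio noise entering through the
#'   green channel (dimensionless, per frame).
#' @param red_mean,red_noise_sd Mean and noise SD of the red (expression
#'   control) channel, arbitrary fluorescence units.
#' @param background_green,background_red Scalar channel backgrounds.
#' @param readd_time Optional Ca2+ add-back time, seconds; when set, the
#'   plateau rises from `readd_time` instead of `stim_time` (SOCE add-back
#'   protocol).
#' @param seed Integer seed.
#' @return A list of class `ca_trace_params`.
#' @export
ca_trace_params <- function(frame_interval = 2, duration = 420, stim_time = 60,
                            baseline_ratio = 0.4, peak_amplitude = 1.2,
                            peak_rise_tau = 3, peak_decay_tau = 25,
                            plateau_amplitude = 0.4, plateau_rise_tau = 60,
                            noise_sd = 0.02, red_mean = 600, red_noise_sd = 6,
                            background_green = 20, background_red = 30,
                            readd_time = NULL, seed = NULL) {
  check_positive_scalar(frame_interval, "frame_interval")
  check_positive_scalar(duration, "duration")
  check_positive_scalar(peak_rise_tau, "peak_rise_tau")
  check_positive_scalar(peak_decay_tau, "peak_decay_tau")
  check_positive_scalar(plateau_rise_tau, "plateau_rise_tau")
  check_nonneg_scalar(peak_amplitude, "peak_amplitude")
  check_nonneg_scalar(plateau_amplitude, "plateau_amplitude")
  check_nonneg_scalar(noise_sd, "noise_sd")
  check_positive_scalar(baseline_ratio, "baseline_ratio")
  check_positive_scalar(red_mean, "red_mean")
  if (stim_time >= duration || stim_time <= 0) {
    abort("`stim_time` must lie inside (0, duration).", class = "mgca_parameter_error")
  }
  if (peak_rise_tau >= peak_decay_tau) {
    abort("`peak_rise_tau` must be smaller than `peak_decay_tau`.",
          class = "mgca_parameter_error")
  }
  structure(as.list(environment()), class = "ca_trace_params")
}

# Noiseless ratio kernel R(t) for one trace; t in seconds from recording start.
ca_ratio_kernel <- function(t, p) {
  s <- t - p$stim_time
  peak <- ifelse(s > 0,
                 (exp(-s / p$peak_decay_tau) - exp(-s / p$peak_rise_tau)), 0)
  # normalize the difference-of-exponentials to unit maximum
  tstar <- log(p$peak_decay_tau / p$peak_rise_tau) *
    p$peak_rise_tau * p$peak_decay_tau / (p$peak_decay_tau - p$peak_rise_tau)
  knorm <- exp(-tstar / p$peak_decay_tau) - exp(-tstar / p$peak_rise_tau)
  plateau_t0 <- p$readd_time %||% p$stim_time
  sp <- t - plateau_t0
  plateau <- ifelse(sp > 0, 1 - exp(-sp / p$plateau_rise_tau), 0)
  p$baseline_ratio + p$peak_amplitude * peak / knorm +
    p$plateau_amplitude * plateau
}

#' Simulate two-channel fluorescence traces with known ground truth
#'
#' The green channel is the red signal times the ratio kernel plus
#' multiplicative noise and background; the red channel is a noisy constant
#' plus background (the ratiometric expression control does not respond to
#' stimulation).  Ground truth is returned alongside: the analytic peak
#' response (`peak_amplitude` by kernel normalization, evaluated at the
#' kernel's analytic maximum) and the noiseless response 5 min
#' post-stimulus.
#'
#' @param params A [ca_trace_params()] object.
#' @param n_cells Number of independent cells to simulate (shared kernel,
#'   independent noise).
#' @return A list with `trace` (tibble: `cell_id`, `time_s`, `green`, `red`),
#'   `truth` (tibble: `cell_id`, `baseline`, `peak_response`,
#'   `response_5min`), and `meta` (stim/readd times and backgrounds, the
#'   per-file metadata the readers carry).
#' @export
simulate_ca_trace <- function(params, n_cells = 1L) {
  stopifnot(inherits(params, "ca_trace_params"))
  time_s <- seq(0, params$duration, by = params$frame_interval)
  kernel <- ca_ratio_kernel(time_s, params)
  # ground truth: maximum of the continuous kernel (peak + rising plateau)
  # above baseline, and the noiseless response 5 min post-stimulus
  peak_true <- if (params$peak_amplitude > 0 || params$plateau_amplitude > 0) {
    stats::optimize(function(t) ca_ratio_kernel(t, params),
                    interval = c(params$stim_time,
                                 min(params$duration, params$stim_time + 120)),
                    maximum = TRUE)$objective - params$baseline_ratio
  } else 0
  t5 <- params$stim_time + 300
  resp5 <- if (t5 <= params$duration) {
    ca_ratio_kernel(t5, params) - params$baseline_ratio
  } else NA_real_
  with_seed_if(params$seed, {
    per_cell <- lapply(seq_len(n_cells), function(cid) {
      red_sig <- params$red_mean *
        (1 + rnorm(length(time_s), sd = params$red_noise_sd / params$red_mean))
      green <- red_sig * (kernel + rnorm(length(time_s), sd = params$noise_sd)) +
        params$background_green
      red <- red_sig + params$background_red
      tibble::tibble(cell_id = cid, time_s = time_s, green = green, red = red)
    })
    trace <- dplyr::bind_rows(per_cell)
    truth <- tibble::tibble(cell_id = seq_len(n_cells),
                            baseline = params$baseline_ratio,
                            peak_response = peak_true,
                            response_5min = resp5)
    meta <- list(stim_time_s = params$stim_time,
                 readd_time_s = params$readd_time,
                 background_green = params$background_green,
                 background_red = params$background_red)
    list(trace = trace, truth = truth, meta = meta)
  })
}

#' Hill (four-parameter logistic) dose-response curve
#'
#' `bottom + (top - bottom) / (1 + (ec50 / dose)^hill)`; evaluates to
#' `bottom` at dose 0.
#'
#' @param dose Dose(s), nM.
#' @param bottom,top Lower and upper asymptotes (delta ratio).
#' @param ec50 Half-maximal dose, nM.
#' @param hill Hill coefficient.
#' @return Response values.
#' @export
hill_response <- function(dose, bottom, top, ec50, hill) {
  ifelse(dose <= 0, bottom, bottom + (top - bottom) / (1 + (ec50 / dose)^hill))
}

#' Simulate a per-cell dose-response population
#'
#' At each dose, a fraction of cells respond; responders' baseline-subtracted
#' peak responses follow a Hill curve plus Gaussian noise, non-responders get
#' baseline noise only.
#'
#' @param doses Vector of doses, nM.  Should span at least 2 log units around
#'   `ec50` (a warning is raised otherwise); dose 0 is allowed.
#' @param ec50 Half-maximal dose, nM.
#' @param hill_coef Hill coefficient.
#' @param max_response Saturating response (delta ratio).
#' @param responder_fraction Either a single fraction in \[0, 1\] applied at
#'   all positive doses, or a function `dose -> fraction`.  Dose 0 always has
#'   responder fraction 0.
#' @param n_cells_per_dose Cells simulated per dose.
#' @param noise_sd Per-cell response noise SD (delta ratio).
#' @param seed Integer seed.
#' @return A list with `cells` (tibble: `dose`, `cell_id`, `responder`,
#'   `response`) and `truth` (list of the generating parameters).
#' @export
simulate_dose_response <- function(doses, ec50 = 100, hill_coef = 1.5,
                                   max_response = 1.5, responder_fraction = 1,
                                   n_cells_per_dose = 200, noise_sd = 0.05,
                                   seed = NULL) {
  if (length(doses) == 0L) {
    abort("`doses` must not be empty.", class = "mgca_parameter_error")
  }
  if (any(doses < 0)) {
    abort("doses must be non-negative.", class = "mgca_parameter_error")
  }
  pos <- doses[doses > 0]
  if (length(pos) > 0L && (log10(max(pos)) - log10(min(pos))) < 2) {
    warn("doses span fewer than 2 log units; EC50 may be poorly constrained.")
  }
  frac_fun <- if (is.function(responder_fraction)) {
    responder_fraction
  } else {
    function(d) rep(responder_fraction, length(d))
  }
  with_seed_if(seed, {
    cells <- purrr::map_dfr(doses, function(d) {
      f <- if (d <= 0) 0 else min(max(frac_fun(d), 0), 1)
      responder <- runif(n_cells_per_dose) < f
      mu <- ifelse(responder, hill_response(d, 0, max_response, ec50, hill_coef), 0)
      tibble::tibble(dose = d,
                     cell_id = seq_len(n_cells_per_dose),
                     responder = responder,
                     response = mu + rnorm(n_cells_per_dose, sd = noise_sd))
    })
    list(cells = cells,
         truth = list(ec50 = ec50, hill_coef = hill_coef,
                      max_response = max_response))
  })
}
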