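# The generators are pure functions of their parameters and seed, and their
# outputs carry the ground truth the downstream stages must recover.

test_that("every generator is deterministic under a fixed seed", {
  p <- ca_trace_params(seed = 7)
  expect_identical(simulate_ca_trace(p, n_cells = 3),
                   simulate_ca_trace(p, n_cells = 3))
  expect_identical(
    simulate_dose_response(c(10, 100, 1000, 10000), seed = 7),
    simulate_dose_response(c(10, 100, 1000, 10000), seed = 7))
  pp <- prw_params(n_tracks = 5, duration = 300, seed = 7)
  expect_identical(simulate_prw_tracks(pp), simulate_prw_tracks(pp))
  cp <- coupling_params(seed = 7)
  expect_identical(simulate_coupled_tracks(pp, cp),
                   simulate_coupled_tracks(pp, cp))
  expect_identical(simulate_ramified_field(n_cells = 3, seed = 7),
                   simulate_ramified_field(n_cells = 3, seed = 7))
})

test_that("signal-free noiseless trace reduces to a constant baseline ratio", {
  p <- ca_trace_params(noise_sd = 0, red_noise_sd = 0, peak_amplitude = 0,
                       plateau_amplitude = 0, baseline_ratio = 0.4)
  sim <- simulate_ca_trace(p)
  ratio <- compute_ratio_trace(sim$trace, p$background_green, p$background_red)
  expect_equal(ratio$ratio, rep(0.4, nrow(ratio)), tolerance = 1e-12)
})

test_that("noiseless biphasic trace yields the analytic kernel maximum", {
  p <- ca_trace_params(noise_sd = 0, red_noise_sd = 0, peak_amplitude = 1.2,
                       plateau_amplitude = 0.4)
  sim <- simulate_ca_trace(p)
  ratio <- compute_ratio_trace(sim$trace, p$background_green, p$background_red)
  pk <- peak_response(ratio, stim_time = p$stim_time)
  # discretization + 3-frame smoothing round the kernel peak slightly
  expect_equal(pk$peak_response, sim$truth$peak_response, tolerance = 0.05)
  r5 <- response_at(ratio, stim_time = p$stim_time)
  expect_equal(r5$response_at, sim$truth$response_5min, tolerance = 0.02)
})

test_that("trace parameter validation rejects impossible kernels", {
  expect_error(ca_trace_params(peak_rise_tau = 30, peak_decay_tau = 3),
               class = "mgca_parameter_error")
  expect_error(ca_trace_params(stim_time = 1000, duration = 400),
               class = "mgca_parameter_error")
  expect_error(ca_trace_params(frame_interval = -1),
               class = "mgca_parameter_error")
})

test_that("dose-response generator honours the Hill midpoint and dose zero", {
  doses <- c(0, 10, 100, 1000, 10000)
  sim <- simulate_dose_response(doses, ec50 = 100, hill_coef = 1.5,
                                max_response = 1.5, responder_fraction = 1,
                                noise_sd = 0, seed = 1)
  at <- function(d) mean(sim$cells$response[sim$cells$dose == d])
  expect_equal(at(100), 1.5 / 2, tolerance = 1e-12)   # exact Hill midpoint
  expect_equal(at(0), 0, tolerance = 1e-12)           # all non-responders
  expect_error(simulate_dose_response(numeric(0)), class = "mgca_parameter_error")
  # saturation: response at a very large dose approaches max_response
  expect_equal(at(10000), 1.5, tolerance = 1e-3)
})

test_that("PRW velocity process is stationary with per-axis variance D / P", {
  # at a frame interval much shorter than P, displacement/dt estimates the
  # velocity; its variance must sit at D/P (s^2 of the OU process)
  p <- prw_params(D = 5, P = 2, frame_interval = 1, duration = 100,
                  n_tracks = 500, seed = 5)
  tr <- simulate_prw_tracks(p)
  sp <- instantaneous_speeds(tr)
  # per-axis: reconstruct dx, dy from steps
  d <- tr |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(dx = list(diff(x_um)), dy = list(diff(y_um)))
  vx <- unlist(d$dx) / (1 / 60)  # um/min
  vy <- unlist(d$dy) / (1 / 60)
  expect_equal(stats::var(vx), 5 / 2, tolerance = 0.05)
  expect_equal(stats::var(vy), 5 / 2, tolerance = 0.05)
})

test_that("ensemble MSD of simulated tracks matches the closed form", {
  p <- prw_params(D = 5, P = 2, frame_interval = 15, duration = 3600,
                  n_tracks = 500, seed = 11)
  cur <- msd_curve(simulate_prw_tracks(p))
  sel <- cur$lag_min > 0 & cur$lag_min <= 15
  expect_lt(max(abs(cur$msd_um2[sel] - prw_msd(cur$lag_min[sel], 5, 2)) /
                  prw_msd(cur$lag_min[sel], 5, 2)), 0.10)
})

test_that("vanishing persistence reduces to Brownian MSD", {
  p <- prw_params(D = 5, P = 0.01, frame_interval = 15, duration = 1800,
                  n_tracks = 300, seed = 3)
  cur <- msd_curve(simulate_prw_tracks(p))
  dat <- cur[cur$lag_min > 0, ]
  slope <- coef(lm(msd_um2 ~ lag_min, data = dat))[2]
  expect_equal(unname(slope) / 4, 5, tolerance = 0.10)
})

test_that("coupled tracks clip speeds at zero and share timestamps", {
  pp <- prw_params(n_tracks = 20, duration = 900, frame_interval = 15)
  cp <- coupling_params(speed_at_zero_ratio = 2, coupling_slope = -4,
                        speed_noise_sd = 2, seed = 2)  # forces clipping
  sim <- simulate_coupled_tracks(pp, cp)
  sp <- instantaneous_speeds(sim$tracks)
  expect_true(all(sp$speed_um_min >= 0))
  expect_setequal(unique(sim$tracks$time_s), unique(sim$ratios$time_s))
  expect_true(all(sim$ratios$ratio >= cp$ratio_min - 1e-12 &
                    sim$ratios$ratio <= cp$ratio_max + 1e-12))
})

test_that("mismatched coupling construction is rejected", {
  expect_error(coupling_params(ratio_min = 2, ratio_max = 1),
               class = "mgca_parameter_error")
})

test_that("ramified ground truth reflects constructed geometry", {
  # one straight 50 px branch at 0.5 um/px -> 1 branch of 25 um
  sp <- ramified_cell_spec(c(100, 100), 3,
                           list(rbind(c(100, 100), c(100, 150))))
  out <- generate_ramified_image(list(sp), field_size = 200L, pixel_size = 0.5)
  expect_identical(out$truth$n_branches, 1L)
  expect_equal(out$truth$total_length_um, 25)
  # T-shaped cell: stem + two arms = 3 branches
  tee <- ramified_cell_spec(c(60, 60), 3,
                            list(rbind(c(60, 60), c(60, 100)),
                                 rbind(c(60, 100), c(30, 100)),
                                 rbind(c(60, 100), c(90, 100))))
  out2 <- generate_ramified_image(list(tee), field_size = 200L, pixel_size = 0.5)
  expect_identical(out2$truth$n_branches, 3L)
  # a branch detached from soma and earlier branches is rejected
  expect_error(
    ramified_cell_spec(c(60, 60), 3, list(rbind(c(10, 10), c(10, 30)))),
    class = "mgca_parameter_error")
})

test_that("overlapping cells are rejected", {
  a <- ramified_cell_spec(c(50, 50), 3, list(rbind(c(50, 50), c(50, 90))),
                          cell_id = 1)
  b <- ramified_cell_spec(c(50, 80), 3, list(rbind(c(50, 80), c(50, 120))),
                          cell_id = 2)
  expect_error(generate_ramified_image(list(a, b), field_size = 200L),
               class = "mgca_parameter_error")
})

test_that("speckles are isolated single-pixel components the cleanup removes", {
  f <- simulate_ramified_field(n_cells = 3, n_stubs = 0, speckle_density = 0.001,
                               seed = 21)
  mask <- binarize(f$field, 100)
  n_before <- bf_component_count(mask)
  cleaned <- remove_outliers(despeckle(mask))
  n_after <- bf_component_count(cleaned)
  expect_gt(n_before, nrow(f$truth))        # speckles present
  expect_identical(n_after, nrow(f$truth))  # exactly the cells remain
})
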