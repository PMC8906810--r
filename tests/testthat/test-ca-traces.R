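# Ratio construction and the per-trace metrics.

test_that("ratio of identical channels is one, of a dark green channel zero", {
  raw <- tibble::tibble(cell_id = 1, time_s = 0:9, green = 50, red = 50)
  expect_equal(compute_ratio_trace(raw)$ratio, rep(1, 10))
  raw2 <- dplyr::mutate(raw, green = 0, red = 100)
  expect_equal(compute_ratio_trace(raw2)$ratio, rep(0, 10))
})

test_that("rolling average shrinks at the edges and matches the loop oracle", {
  raw <- tibble::tibble(cell_id = 1, time_s = 0:3,
                        green = c(100, 130, 160, 190), red = 100)
  expect_equal(compute_ratio_trace(raw)$ratio,
               c(115, 130, 160, 175) / 100)
  withr::with_seed(1, {
    g <- runif(40, 50, 150); r <- runif(40, 80, 120)
  })
  raw3 <- tibble::tibble(cell_id = 1, time_s = seq(0, 78, 2), green = g, red = r)
  for (w in c(1L, 3L, 5L)) {
    expect_equal(compute_ratio_trace(raw3, smooth_window = w)$ratio,
                 bf_movavg(g, w) / bf_movavg(r, w), tolerance = 1e-12)
  }
})

test_that("ratio is invariant to scaling both channels by the same factor", {
  withr::with_seed(2, {
    g <- runif(30, 50, 150); r <- runif(30, 80, 120)
  })
  raw <- tibble::tibble(cell_id = 1, time_s = 0:29, green = g, red = r)
  for (sc in c(0.5, 3, 117)) {
    scaled <- dplyr::mutate(raw, green = green * sc, red = red * sc)
    expect_equal(compute_ratio_trace(scaled)$ratio,
                 compute_ratio_trace(raw)$ratio, tolerance = 1e-12)
  }
})

test_that("a red channel at or below background names the offending frame", {
  raw <- tibble::tibble(cell_id = 1, time_s = 0:3, green = 10,
                        red = c(50, 50, 5, 50))
  expect_error(compute_ratio_trace(raw, background_red = 10),
               regexp = "frame 3", class = "mgca_degenerate_channel_error")
})

test_that("baseline averages the k smallest pre-stimulus ratios", {
  tr <- ratio_trace(0:29, c(rep(0.5, 20), rep(2, 10)))
  expect_equal(baseline_value(tr, stim_time = 20)$baseline, 0.5)
  tr2 <- ratio_trace(0:24, c(1:20, rep(3, 5)))
  expect_equal(baseline_value(tr2, stim_time = 20)$baseline, mean(1:10))
  # sort-based oracle on noisy traces
  withr::with_seed(3, {
    for (i in 1:20) {
      vals <- runif(60, 0.3, 0.9)
      tr3 <- ratio_trace(0:59, vals)
      expect_identical(baseline_value(tr3, stim_time = 40)$baseline,
                       mean(sort(vals[1:40])[1:10]))
    }
  })
  expect_error(baseline_value(ratio_trace(0:8, runif(9)), stim_time = 9),
               class = "mgca_insufficient_baseline_error")
})

test_that("peak response floors at zero and honours the search window", {
  tr <- ratio_trace(0:99, rep(0.5, 100))
  expect_equal(peak_response(tr, stim_time = 50)$peak_response, 0)
  # strictly decreasing after stimulus from baseline: floored at 0
  dec <- ratio_trace(0:99, c(rep(0.5, 50), 0.5 - seq(0.001, 0.05, length.out = 50)))
  expect_equal(peak_response(dec, stim_time = 50)$peak_response, 0)
  # a late plateau outside the window must not count as peak
  late <- ratio_trace(0:299, c(rep(0.5, 50), rep(0.6, 150), rep(2, 100)))
  expect_equal(peak_response(late, stim_time = 50, peak_window = 120)$peak_response,
               0.1, tolerance = 1e-12)
  expect_error(peak_response(ratio_trace(0:49, runif(50, 1, 2)), stim_time = 60),
               class = "mgca_window_error")
})

test_that("sustained response reads the frame nearest the offset", {
  tr <- ratio_trace(seq(0, 400, 2), rep(0.5, 201))
  expect_equal(response_at(tr, stim_time = 60)$response_at, 0)
  expect_error(response_at(ratio_trace(0:100, runif(101, 1, 2)), stim_time = 60),
               class = "mgca_window_error")
})

test_that("SOCE rate equals the slope on a ramp and the sliding-window oracle", {
  t <- seq(0, 200, 2)
  ramp <- ifelse(t >= 100, 0.5 + 0.01 * (t - 100), 0.5)
  expect_equal(soce_rate(ratio_trace(t, ramp), readd_time = 100)$soce_rate, 0.01)
  expect_equal(soce_rate(ratio_trace(t, rep(0.7, length(t))),
                         readd_time = 100)$soce_rate, 0)
  # sigmoidal rise: exhaustive all-windows oracle
  sig <- 0.5 + 1 / (1 + exp(-(t - 150) / 8))
  got <- soce_rate(ratio_trace(t, sig), readd_time = 100)$soce_rate
  post <- which(t >= 100)
  span <- 5L   # 10 s at 2 s frames
  bf <- max(vapply(seq_len(length(post) - span), function(i) {
    (sig[post[i + span]] - sig[post[i]]) / (t[post[i + span]] - t[post[i]])
  }, numeric(1)))
  expect_identical(got, bf)
  # monotone non-decreasing traces never give a negative rate
  withr::with_seed(4, {
    for (i in 1:10) {
      mono <- cumsum(runif(length(t), 0, 0.01)) + 0.5
      expect_gte(soce_rate(ratio_trace(t, mono), readd_time = 100)$soce_rate, 0)
    }
  })
  expect_error(soce_rate(ratio_trace(t, ramp), readd_time = NULL),
               class = "mgca_contract_error")
})

test_that("AUC integrates the clipped baseline-subtracted trace", {
  t <- seq(0, 200, 2)
  flat <- ratio_trace(t, rep(0.5, length(t)))
  expect_equal(trace_auc(flat, stim_time = 60, t_a = 60, t_b = 180)$auc, 0)
  # triangle of height 1 over 60 s above baseline: area 30
  tri <- 0.5 + pmax(0, 1 - abs(t - 120) / 30)
  expect_equal(trace_auc(ratio_trace(t, tri), stim_time = 60,
                         t_a = 90, t_b = 150)$auc, 30, tolerance = 1e-9)
  # refined-grid oracle on a synthetic biphasic trace
  p <- ca_trace_params(noise_sd = 0, red_noise_sd = 0)
  fine <- seq(60, 400, 0.01)
  oracle <- sum(diff(fine) * (head(pmax(mgca:::ca_ratio_kernel(fine, p) - 0.4, 0), -1) +
                              tail(pmax(mgca:::ca_ratio_kernel(fine, p) - 0.4, 0), -1)) / 2)
  sim <- simulate_ca_trace(p)
  ratio <- compute_ratio_trace(sim$trace, p$background_green, p$background_red)
  got <- trace_auc(ratio, stim_time = 60, t_a = 60, t_b = 400)$auc
  expect_equal(got, oracle, tolerance = 0.01)
  expect_error(trace_auc(flat, stim_time = 60, t_a = 100, t_b = 50),
               class = "mgca_contract_error")
})

test_that("responder classification uses an inclusive robust threshold", {
  t <- 0:199
  flat <- ratio_trace(t, rep(0.5, 200))
  expect_false(classify_responder(flat, stim_time = 100)$responder)
  withr::with_seed(5, {
    noisy <- 0.5 + rnorm(200, sd = 0.02)
  })
  spike <- noisy; spike[120] <- spike[120] + 1
  expect_true(classify_responder(ratio_trace(t, spike), stim_time = 100)$responder)
  # peak exactly at the floor threshold is a responder (inclusive)
  boundary <- rep(0.5, 200); boundary[120] <- 0.55
  cls <- classify_responder(ratio_trace(t, boundary), stim_time = 100)
  expect_equal(cls$peak_response, cls$threshold)
  expect_true(cls$responder)
})

test_that("dFF matches elementwise arithmetic and flags bad baselines", {
  f <- tibble::tibble(cell_id = 1, time_s = 0:9, f = rep(100, 10))
  expect_equal(dff(f, c(0, 4))$dff, rep(0, 10))
  f2 <- dplyr::mutate(f, f = ifelse(time_s > 4, 200, 100))
  expect_equal(dff(f2, c(0, 4))$dff, c(rep(0, 5), rep(1, 5)))
  withr::with_seed(6, {
    vals <- runif(30, 10, 90)
  })
  f3 <- tibble::tibble(cell_id = 1, time_s = 0:29, f = vals)
  f0 <- mean(vals[1:10])
  expect_equal(dff(f3, c(0, 9))$dff, (vals - f0) / f0, tolerance = 1e-12)
  f4 <- dplyr::mutate(f, f = 0)
  expect_error(dff(f4, c(0, 4)), class = "mgca_degenerate_baseline_error")
})

test_that("Hill fit is exact on noiseless data and honest on flat data", {
  d <- c(1, 10, 30, 100, 300, 1000, 10000)
  resp <- hill_response(d, 0, 1.5, 100, 1)
  fit <- fit_hill(tibble::tibble(dose = d, response = resp))
  expect_true(fit$converged)
  expect_equal(fit$ec50, 100, tolerance = 1e-3)
  expect_equal(fit$hill_coef, 1, tolerance = 1e-3)
  expect_equal(fit$bottom, 0, tolerance = 1e-5)
  expect_equal(fit$top, 1.5, tolerance = 1e-3)
  flat <- fit_hill(tibble::tibble(dose = d, response = 0.7))
  expect_false(flat$converged)
  expect_true(is.na(flat$ec50))
  expect_error(fit_hill(tibble::tibble(dose = c(1, 10, 10, 1), response = 1:4)),
               class = "mgca_parameter_error")
  # tidiers
  expect_named(tidy(fit), c("term", "estimate"))
  expect_true(glance(fit)$converged)
})

test_that("generator-to-metrics recovery holds across a seeded population", {
  p <- ca_trace_params(seed = 17)
  sim <- simulate_ca_trace(p, n_cells = 30)
  ratio <- compute_ratio_trace(sim$trace, p$background_green, p$background_red)
  m <- trace_metrics(ratio, stim_time = p$stim_time)
  expect_equal(mean(m$peak_response), sim$truth$peak_response[1],
               tolerance = 0.05)
  expect_equal(mean(m$response_at), sim$truth$response_5min[1],
               tolerance = 0.05)
  expect_true(all(m$responder))
})
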