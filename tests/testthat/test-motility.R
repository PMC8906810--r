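# Track statistics, MSD estimation, PRW fitting, autocorrelation, linking.

make_track <- function(id, x, y, dt = 15) {
  tibble::tibble(track_id = id, time_s = (seq_along(x) - 1) * dt,
                 x_um = x, y_um = y)
}

test_that("track filter boundary is inclusive at the minimum duration", {
  short <- make_track(1, seq(0, 17.9, 1), rep(0, 18), dt = 179 / 17) # TD 179 s
  exact <- make_track(2, 0:12, rep(0, 13), dt = 15)                  # TD 180 s
  both <- dplyr::bind_rows(short, exact)
  kept <- filter_tracks(both, min_duration = 180)
  expect_setequal(unique(kept$track_id), 2)
  withr::with_seed(10, {
    lens <- c(5, 8, 13, 14, 20, 30, 6, 40, 13, 3)  # frames at 15 s
  })
  tracks <- dplyr::bind_rows(lapply(seq_along(lens), function(i) {
    make_track(i, rnorm(lens[i]), rnorm(lens[i]))
  }))
  kept2 <- filter_tracks(tracks)   # TD >= 180 s means >= 13 frames
  expect_identical(sort(unique(kept2$track_id)),
                   which(lens >= 13))
})

test_that("instantaneous speeds match the Euclidean oracle", {
  still <- make_track(1, rep(3, 10), rep(-2, 10))
  expect_equal(instantaneous_speeds(still)$speed_um_min, rep(0, 9))
  const <- make_track(1, seq(0, 4.5, 0.5), rep(0, 10), dt = 15) # 2 um/min
  expect_equal(instantaneous_speeds(const)$speed_um_min, rep(2, 9))
  withr::with_seed(11, {
    tr <- random_track(1, n = 100)
  })
  sp <- instantaneous_speeds(tr)
  expect_equal(sp$speed_um_min,
               sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / 15 * 60,
               tolerance = 1e-12)
})

test_that("track metrics agree with the brute-force oracle and invariants", {
  # straight line at 2 um/min for 10 min
  straight <- make_track(1, seq(0, 20, 0.5), rep(0, 41), dt = 15)
  m <- track_metrics(straight)
  expect_equal(m$TDL_um, 20)
  expect_equal(m$TL_um, 20)
  expect_equal(m$straightness, 1)
  expect_equal(m$displacement_10min_um, 20)
  expect_equal(m$mean_speed_um_min, 2)
  # closed square loop
  loop <- make_track(1, c(0, 5, 5, 0, 0), c(0, 0, 5, 5, 0))
  m2 <- track_metrics(loop)
  expect_equal(m2$TDL_um, 0)
  expect_equal(m2$straightness, 0)
  expect_equal(m2$displacement_10min_um, 0)
  # random tracks vs oracle at 1e-9 relative, plus the triangle inequality
  withr::with_seed(12, {
    for (i in 1:20) {
      tr <- random_track(i, n = 200)
      m3 <- track_metrics(tr)
      bf <- bf_track_metrics(tr$time_s, tr$x_um, tr$y_um)
      expect_equal(m3$TDL_um, bf$TDL, tolerance = 1e-9)
      expect_equal(m3$TL_um, bf$TL, tolerance = 1e-9)
      expect_equal(m3$TD_s, bf$TD, tolerance = 1e-9)
      expect_equal(m3$mean_speed_um_min, bf$mean_speed, tolerance = 1e-9)
      expect_equal(m3$displacement_10min_um, bf$displacement_10min,
                   tolerance = 1e-9)
      expect_equal(m3$straightness, bf$straightness, tolerance = 1e-9)
      expect_lte(m3$TDL_um, m3$TL_um + 1e-12)
      expect_gte(m3$straightness, 0)
      expect_lte(m3$straightness, 1)
    }
  })
})

test_that("metrics are invariant under translation and rotation", {
  withr::with_seed(13, {
    tr <- random_track(1, n = 80)
  })
  m0 <- track_metrics(tr)
  shifted <- dplyr::mutate(tr, x_um = x_um + 120, y_um = y_um - 45)
  th <- 0.6
  rotated <- dplyr::mutate(tr,
                           x0 = x_um, y0 = y_um,
                           x_um = cos(th) * x0 - sin(th) * y0,
                           y_um = sin(th) * x0 + cos(th) * y0)
  for (variant in list(shifted, rotated)) {
    m1 <- track_metrics(variant)
    expect_equal(m1$TDL_um, m0$TDL_um, tolerance = 1e-9)
    expect_equal(m1$TL_um, m0$TL_um, tolerance = 1e-9)
    expect_equal(m1$straightness, m0$straightness, tolerance = 1e-9)
    expect_equal(m1$mean_speed_um_min, m0$mean_speed_um_min, tolerance = 1e-9)
  }
})

test_that("translation to the origin is exact and idempotent", {
  withr::with_seed(14, {
    tr <- dplyr::bind_rows(random_track(1), random_track(2))
  })
  t1 <- translate_to_origin(tr)
  starts <- t1 |> dplyr::group_by(track_id) |> dplyr::slice(1)
  expect_true(all(starts$x_um == 0 & starts$y_um == 0))
  expect_equal(translate_to_origin(t1), t1)
  d0 <- instantaneous_speeds(tr)$speed_um_min
  expect_equal(instantaneous_speeds(t1)$speed_um_min, d0, tolerance = 1e-12)
})

test_that("MSD matches closed forms and the double-loop oracle", {
  still <- dplyr::bind_rows(make_track(1, rep(0, 20), rep(0, 20)),
                            make_track(2, rep(1, 20), rep(5, 20)))
  expect_true(all(msd_curve(still)$msd_um2 == 0))
  # ballistic: msd(tau) = (v tau)^2 exactly
  v <- 3 # um/min
  bal <- make_track(1, seq(0, by = v * 0.25, length.out = 41), rep(0, 41), dt = 15)
  cur <- msd_curve(bal)
  expect_equal(cur$msd_um2, (v * cur$lag_min)^2, tolerance = 1e-9)
  # brute-force double loop on a random single track
  withr::with_seed(15, {
    tr <- random_track(1, n = 60)
  })
  cur2 <- msd_curve(tr)
  bf <- bf_msd_single(tr$x_um, tr$y_um, max(cur2$lag_s) / 15)
  expect_equal(cur2$msd_um2[-1], bf, tolerance = 1e-12)
  expect_error(msd_curve(tibble::tibble(track_id = integer(),
                                        time_s = numeric(), x_um = numeric(),
                                        y_um = numeric())),
               class = "mgca_empty_input_error")
})

test_that("PRW fit is self-consistent and degrades gracefully", {
  lag <- seq(0.25, 15, by = 0.25)
  exact <- tibble::tibble(lag_min = lag, msd_um2 = prw_msd(lag, 5, 2),
                          n_pairs = 500)
  fit <- fit_prw(exact)
  expect_true(fit$converged)
  expect_equal(fit$D, 5, tolerance = 1e-3)
  expect_equal(fit$P, 2, tolerance = 1e-3)
  expect_named(tidy(fit), c("term", "estimate", "unit"))
  # exactly linear MSD: persistence indistinguishable from zero
  lin <- tibble::tibble(lag_min = lag, msd_um2 = 4 * 5 * lag, n_pairs = 500)
  fit2 <- fit_prw(lin)
  expect_lte(fit2$P, 0.25)
  expect_error(fit_prw(exact[1:3, ]), class = "mgca_parameter_error")
})

test_that("direction autocorrelation handles constructed geometries", {
  straight <- make_track(1, seq(0, 10, 0.5), seq(0, 5, 0.25))
  ac <- velocity_autocorrelation(straight)
  expect_equal(ac$mean_cos, rep(1, nrow(ac)), tolerance = 1e-12)
  # strict back-and-forth: -1 at lag 1, +1 at lag 2
  bf_x <- rep(c(0, 1), 10)
  zig <- make_track(1, bf_x, rep(0, length(bf_x)))
  ac2 <- velocity_autocorrelation(zig)
  expect_equal(ac2$mean_cos[ac2$lag_s == 15], -1)
  expect_equal(ac2$mean_cos[ac2$lag_s == 30], 1)
  expect_true(all(ac2$mean_cos >= -1 & ac2$mean_cos <= 1))
  # zero-length steps are skipped and counted
  paused <- make_track(1, c(0, 1, 1, 2, 3), c(0, 0, 0, 0, 0))
  ac3 <- velocity_autocorrelation(paused)
  expect_identical(attr(ac3, "n_zero_steps"), 1)
})

test_that("OU tracks decorrelate on the persistence timescale", {
  p <- prw_params(D = 5, P = 2, frame_interval = 60, duration = 1800,
                  n_tracks = 300, seed = 16)
  ac <- velocity_autocorrelation(simulate_prw_tracks(p))
  sel <- ac$lag_min > 0 & ac$lag_min <= 4
  expect_lt(max(abs(ac$mean_cos[sel] - exp(-ac$lag_min[sel] / 2))), 0.05)
})

test_that("spot linking respects the jump threshold and identity", {
  # two well-separated constant-velocity spots
  det <- dplyr::bind_rows(
    tibble::tibble(frame = 1:20, time_s = (1:20) * 15, x_um = (1:20) * 0.8,
                   y_um = 0),
    tibble::tibble(frame = 1:20, time_s = (1:20) * 15, x_um = (1:20) * 0.8,
                   y_um = 50))
  linked <- link_spots(det)
  expect_identical(dplyr::n_distinct(linked$track_id), 2L)
  expect_true(all(table(linked$track_id) == 20))
  # a 5 um jump in one frame breaks the track
  jump <- tibble::tibble(frame = 1:10, time_s = (1:10) * 15,
                         x_um = c(1:5, 5 + 5 + 1:5), y_um = 0)
  linked2 <- link_spots(jump, max_jump = 4, max_missing_frames = 2)
  expect_identical(dplyr::n_distinct(linked2$track_id), 2L)
  # paths whose x-ranges cross but that always stay farther apart than the
  # jump limit keep their identities
  a <- tibble::tibble(frame = 1:21, time_s = (1:21) * 15,
                      x_um = seq(0, 20, 1), y_um = 0, truth = "a")
  b <- tibble::tibble(frame = 1:21, time_s = (1:21) * 15,
                      x_um = seq(20, 0, -1), y_um = 6, truth = "b")
  det3 <- dplyr::bind_rows(a, b)
  linked3 <- link_spots(det3[, 1:4])
  joined <- dplyr::left_join(linked3, det3,
                             by = c("frame", "time_s", "x_um", "y_um"))
  purity <- joined |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(p = max(table(truth)) / dplyr::n())
  expect_true(all(purity$p == 1))
})

test_that("gapped tracks split into uniform segments", {
  gappy <- tibble::tibble(track_id = 1,
                          time_s = c(0, 15, 30, 90, 105, 120),
                          x_um = 1:6, y_um = 0)
  out <- split_track_gaps(gappy)
  expect_identical(dplyr::n_distinct(out$track_id), 2L)
  segs <- split(out$time_s, out$track_id)
  for (s in segs) expect_true(all(diff(s) == 15))
})
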