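#' Drop tracks shorter than a minimum duration
#'
#' Mirrors the tracking QC rule that tracks shorter than 3 min are eliminated
#' from analysis; the boundary is inclusive (a track lasting exactly
#' `min_duration` is retained).
#'
#' @param tracks A tibble with columns `track_id`, `time_s`, `x_um`, `y_um`.
#' @param min_duration Minimum track duration in seconds (default 180).
#' @return The filtered tibble.
#' @export
filter_tracks <- function(tracks, min_duration = 180) {
  check_columns(tracks, c("track_id", "time_s"), "`tracks`")
  dplyr::group_by(tracks, .data$track_id) |>
    dplyr::filter(max(.data$time_s) - min(.data$time_s) >= min_duration) |>
    dplyr::ungroup()
}

# Split one track's columns into a validated position matrix + times.
track_xy <- function(time_s, x_um, y_um) {
  ord <- order(time_s)
  time_s <- time_s[ord]
  check_uniform_time(time_s, what = "time_s")
  if (!all(is.finite(x_um)) || !all(is.finite(y_um))) {
    abort("track coordinates must be finite.", class = "mgca_parameter_error")
  }
  list(t = time_s, p = cbind(x_um[ord], y_um[ord]))
}

#' Instantaneous speeds along each track
#'
#' Speed over each frame-to-frame interval,
#' `|p(k+1) - p(k)| / dt`, reported in um/min.
#'
#' @inheritParams filter_tracks
#' @return A tibble with one row per displacement interval: `track_id`,
#'   `frame` (index of the interval start), `time_s` (interval start),
#'   `speed_um_min`, and the frame-to-frame displacement `step_um`.
#' @export
instantaneous_speeds <- function(tracks) {
  check_columns(tracks, c("track_id", "time_s", "x_um", "y_um"), "`tracks`")
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(d, key) {
      tr <- track_xy(d$time_s, d$x_um, d$y_um)
      step <- row_norm(diff(tr$p))
      dt <- diff(tr$t)
      tibble::tibble(frame = seq_along(step),
                     time_s = tr$t[-length(tr$t)],
                     step_um = step,
                     speed_um_min = step / dt * 60)
    }) |>
    dplyr::ungroup()
}

#' Per-track motility metrics
#'
#' Computes, per track: track displacement length `TDL = |p(n) - p(1)|` (um),
#' track length `TL = sum |p(t) - p(t-1)|` (um), track duration
#' `TD = T(n) - T(1)` (s), mean speed (mean of instantaneous speeds, um/min),
#' 10-min displacement `600 * TDL / TD` (um per 10 min), and straightness
#' `TDL / TL` (0 when `TL = 0`).
#'
#' @inheritParams filter_tracks
#' @return A tibble with one row per track: `track_id`, `n_frames`, `TD_s`,
#'   `TDL_um`, `TL_um`, `mean_speed_um_min`, `displacement_10min_um`,
#'   `straightness`.
#' @export
track_metrics <- function(tracks) {
  check_columns(tracks, c("track_id", "time_s", "x_um", "y_um"), "`tracks`")
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(d, key) {
      tr <- track_xy(d$time_s, d$x_um, d$y_um)
      n <- nrow(tr$p)
      if (n < 2L) {
        abort("each track needs at least 2 frames.", class = "mgca_parameter_error")
      }
      step <- row_norm(diff(tr$p))
      dt <- diff(tr$t)
      tdl <- sqrt(sum((tr$p[n, ] - tr$p[1L, ])^2))
      tl <- sum(step)
      td <- tr$t[n] - tr$t[1L]
      tibble::tibble(
        n_frames = n,
        TD_s = td,
        TDL_um = tdl,
        TL_um = tl,
        mean_speed_um_min = mean(step / dt * 60),
        displacement_10min_um = 600 * tdl / td,
        straightness = if (tl > 0) tdl / tl else 0
      )
    }) |>
    dplyr::ungroup()
}

#' Translate every track to the origin
#'
#' Subtracts each track's first position from all of its positions (the
#' "plot at origin" transform); timestamps are unchanged.  Idempotent.
#'
#' @inheritParams filter_tracks
#' @return The translated tibble.
#' @export
translate_to_origin <- function(tracks) {
  check_columns(tracks, c("track_id", "time_s", "x_um", "y_um"), "`tracks`")
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::mutate(x_um = .data$x_um - .data$x_um[1L],
                  y_um = .data$y_um - .data$y_um[1L]) |>
    dplyr::ungroup()
}

#' Ensemble time-averaged mean squared displacement
#'
#' For each track the MSD at lag `l` frames is averaged over all overlapping
#' start points; the ensemble curve is the unweighted mean across tracks.
#' Lags run up to `max_lag_fraction` of the shortest track's duration.
#'
#' @inheritParams filter_tracks
#' @param max_lag_fraction Longest lag as a fraction of the shortest track
#'   duration (default 0.5, limiting estimator variance at long lags).
#' @return A tibble of class `msd_curve`: `lag_s`, `lag_min`, `msd_um2`,
#'   `n_tracks`, `n_pairs` (total overlapping displacement pairs).  The
#'   zero-lag row (`msd = 0`) is included.
#' @export
msd_curve <- function(tracks, max_lag_fraction = 0.5) {
  check_columns(tracks, c("track_id", "time_s", "x_um", "y_um"), "`tracks`")
  if (nrow(tracks) == 0L) {
    abort("no tracks supplied.", class = "mgca_empty_input_error")
  }
  split_tracks <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(d, key) track_xy(d$time_s, d$x_um, d$y_um))
  n_frames <- vapply(split_tracks, function(tr) length(tr$t), integer(1))
  if (any(n_frames < 2L)) {
    abort("each track needs at least 2 frames.", class = "mgca_parameter_error")
  }
  dt <- diff(split_tracks[[1L]]$t[1:2])
  max_lag <- max(1L, floor(max_lag_fraction * (min(n_frames) - 1L)))
  per_lag <- function(l) {
    per_track <- vapply(split_tracks, function(tr) {
      n <- nrow(tr$p)
      if (n <= l) return(c(NA_real_, 0))
      idx <- seq_len(n - l)
      d2 <- (tr$p[idx + l, 1L] - tr$p[idx, 1L])^2 +
            (tr$p[idx + l, 2L] - tr$p[idx, 2L])^2
      c(mean(d2), length(idx))
    }, numeric(2))
    c(mean(per_track[1L, ], na.rm = TRUE), sum(per_track[2L, ]))
  }
  vals <- vapply(seq_len(max_lag), per_lag, numeric(2))
  out <- tibble::tibble(
    lag_s = c(0, seq_len(max_lag) * dt),
    lag_min = c(0, seq_len(max_lag) * dt) / 60,
    msd_um2 = c(0, vals[1L, ]),
    n_tracks = c(length(split_tracks),
                 vapply(seq_len(max_lag), function(l) sum(n_frames > l), integer(1))),
    n_pairs = c(sum(n_frames), vals[2L, ])
  )
  class(out) <- c("msd_curve", class(out))
  out
}

#' Fit the persistent-random-walk model to an MSD curve
#'
#' Weighted least squares fit of `MSD(t) = 4 D (t - P (1 - exp(-t/P)))` over
#' the positive lags of the curve.  Each lag is weighted by
#' `n_pairs / lag` (the estimator variance grows roughly linearly with lag);
#' positivity of `D` and `P` is enforced by fitting on the log scale.
#'
#' @param curve An [msd_curve()] result (or any tibble with `lag_min`,
#'   `msd_um2` and optionally `n_pairs`).
#' @return An object of class `prw_fit` with elements `D` (um^2/min), `P`
#'   (min), `converged`, `resid_norm`, `curve`, and the underlying `fit`.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @export
fit_prw <- function(curve) {
  check_columns(curve, c("lag_min", "msd_um2"), "`curve`")
  dat <- dplyr::filter(curve, .data$lag_min > 0, .data$msd_um2 > 0)
  if (nrow(dat) < 5L) {
    abort("need at least 5 positive-MSD lags to fit.", class = "mgca_parameter_error")
  }
  w <- if ("n_pairs" %in% names(dat)) dat$n_pairs / dat$lag_min else 1 / dat$lag_min
  # starting values: D from the late-lag secant slope, P from the grid
  n <- nrow(dat)
  d0 <- max((dat$msd_um2[n] - dat$msd_um2[ceiling(n / 2)]) /
              (dat$lag_min[n] - dat$lag_min[ceiling(n / 2)]) / 4, 1e-6)
  p0 <- max(dat$lag_min[max(1L, ceiling(n / 5))], dat$lag_min[1L])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      msd_um2 ~ 4 * exp(logD) * (lag_min - exp(logP) * (1 - exp(-lag_min / exp(logP)))),
      data = dat, weights = w,
      start = list(logD = log(d0), logP = log(p0)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # P -> 0 limit: an (almost) exactly linear MSD drives log P unbounded
    # below; fall back to the Brownian line msd = 4 D (lag - P)
    lf <- lm(msd_um2 ~ lag_min, data = dat, weights = w)
    d_lin <- unname(coef(lf)[2L]) / 4
    p_lin <- if (d_lin > 0) max(-unname(coef(lf)[1L]) / (4 * d_lin), 0) else NA_real_
    out <- list(D = if (d_lin > 0) d_lin else NA_real_, P = p_lin,
                converged = d_lin > 0,
                resid_norm = sqrt(sum(stats::residuals(lf)^2)),
                curve = dat, fit = NULL)
  } else {
    cf <- coef(fit)
    out <- list(D = unname(exp(cf["logD"])), P = unname(exp(cf["logP"])),
                converged = fit$convInfo$isConv,
                resid_norm = sqrt(sum(stats::residuals(fit)^2)),
                curve = dat, fit = fit)
  }
  class(out) <- "prw_fit"
  out
}

#' @export
print.prw_fit <- function(x, ...) {
  cat("Persistent-random-walk fit\n")
  cat(sprintf("  D = %.4g um^2/min, P = %.4g min (converged: %s)\n",
              x$D, x$P, x$converged))
  invisible(x)
}

#' @rdname fit_prw
#' @param x,object A `prw_fit` object.
#' @param ... Unused.
#' @export
tidy.prw_fit <- function(x, ...) {
  tibble::tibble(term = c("D", "P"),
                 estimate = c(x$D, x$P),
                 unit = c("um^2/min", "min"))
}

#' @rdname fit_prw
#' @export
glance.prw_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, resid_norm = x$resid_norm,
                 n_lags = nrow(x$curve))
}

#' Direction (vector) autocorrelation of cell tracks
#'
#' Mean cosine of the angle between frame-to-frame displacement vectors
#' separated by a given lag, pooled over all tracks and start points --- an
#' analysis of directional persistence.  Zero-length displacement vectors
#' have no direction; the pairs involving them are skipped and counted.
#'
#' @inheritParams filter_tracks
#' @param max_lag_fraction Longest lag as a fraction of the shortest track's
#'   displacement count (default 0.5).
#' @return A tibble of class `autocorr_curve`: `lag_s`, `lag_min`,
#'   `mean_cos`, `n_pairs`; the lag-0 row is 1 by convention.  The number of
#'   skipped zero-length displacements is in `attr(, "n_zero_steps")`.
#' @export
velocity_autocorrelation <- function(tracks, max_lag_fraction = 0.5) {
  check_columns(tracks, c("track_id", "time_s", "x_um", "y_um"), "`tracks`")
  split_tracks <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(d, key) track_xy(d$time_s, d$x_um, d$y_um))
  n_disp <- vapply(split_tracks, function(tr) nrow(tr$p) - 1L, integer(1))
  if (all(n_disp < 2L)) {
    abort("need tracks with at least 3 frames.", class = "mgca_parameter_error")
  }
  dt <- diff(split_tracks[[1L]]$t[1:2])
  max_lag <- max(1L, floor(max_lag_fraction * min(n_disp[n_disp >= 2L])))
  units <- lapply(split_tracks, function(tr) {
    d <- diff(tr$p)
    len <- row_norm(d)
    u <- d / ifelse(len > 0, len, NA_real_)  # NA direction for zero steps
    u
  })
  n_zero <- sum(vapply(units, function(u) sum(is.na(u[, 1L])), numeric(1)))
  per_lag <- function(l) {
    tot <- 0; cnt <- 0L
    for (u in units) {
      n <- nrow(u)
      if (n <= l) next
      idx <- seq_len(n - l)
      dots <- u[idx, 1L] * u[idx + l, 1L] + u[idx, 2L] * u[idx + l, 2L]
      dots <- dots[!is.na(dots)]
      tot <- tot + sum(dots); cnt <- cnt + length(dots)
    }
    c(if (cnt > 0) tot / cnt else NA_real_, cnt)
  }
  vals <- vapply(seq_len(max_lag), per_lag, numeric(2))
  out <- tibble::tibble(
    lag_s = c(0, seq_len(max_lag) * dt),
    lag_min = c(0, seq_len(max_lag) * dt) / 60,
    mean_cos = c(1, vals[1L, ]),
    n_pairs = c(sum(n_disp), vals[2L, ])
  )
  attr(out, "n_zero_steps") <- n_zero
  class(out) <- c("autocorr_curve", class(out))
  out
}

#' Link per-frame spot detections into tracks
#'
#' Greedy mutual-nearest-neighbour frame-to-frame assignment: at each frame,
#' detections are matched to open tracks in order of increasing distance,
#' subject to a maximum jump; a track that goes unmatched for more than
#' `max_missing_frames` consecutive frames is closed.  No positions are ever
#' interpolated (no gap filling): a re-acquired track simply resumes at the
#' detected frame.
#'
#' @param detections A tibble with columns `frame`, `time_s`, `x_um`, `y_um`.
#' @param max_jump Maximum allowed displacement between a track's last
#'   detected position and a new detection, um (default 4).
#' @param max_missing_frames Number of consecutive undetected frames after
#'   which a track is closed (default 10).
#' @return A tibble `track_id`, `frame`, `time_s`, `x_um`, `y_um`.
#' @export
link_spots <- function(detections, max_jump = 4, max_missing_frames = 10) {
  check_columns(detections, c("frame", "time_s", "x_um", "y_um"), "`detections`")
  frames <- sort(unique(detections$frame))
  open <- list()   # each: list(id, x, y, last_frame, rows)
  closed <- list()
  next_id <- 1L
  rows <- vector("list", 0L)
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    assigned_det <- rep(FALSE, nrow(det))
    if (length(open) > 0L && nrow(det) > 0L) {
      ox <- vapply(open, `[[`, numeric(1), "x")
      oy <- vapply(open, `[[`, numeric(1), "y")
      dmat <- sqrt(outer(ox, det$x_um, "-")^2 + outer(oy, det$y_um, "-")^2)
      dmat[dmat > max_jump] <- NA_real_
      # greedy global-minimum matching
      while (any(is.finite(dmat))) {
        ij <- arrayInd(which.min(dmat), dim(dmat))
        i <- ij[1L]; j <- ij[2L]
        open[[i]]$x <- det$x_um[j]; open[[i]]$y <- det$y_um[j]
        open[[i]]$last_frame <- f
        open[[i]]$rows <- c(open[[i]]$rows, list(
          tibble::tibble(track_id = open[[i]]$id, frame = f,
                         time_s = det$time_s[j], x_um = det$x_um[j],
                         y_um = det$y_um[j])))
        assigned_det[j] <- TRUE
        dmat[i, ] <- NA_real_; dmat[, j] <- NA_real_
      }
    }
    # start new tracks from unassigned detections
    for (j in which(!assigned_det)) {
      open[[length(open) + 1L]] <- list(
        id = next_id, x = det$x_um[j], y = det$y_um[j], last_frame = f,
        rows = list(tibble::tibble(track_id = next_id, frame = f,
                                   time_s = det$time_s[j], x_um = det$x_um[j],
                                   y_um = det$y_um[j])))
      next_id <- next_id + 1L
    }
    # close stale tracks
    stale <- vapply(open, function(tr) f - tr$last_frame > max_missing_frames,
                    logical(1))
    closed <- c(closed, open[stale])
    open <- open[!stale]
  }
  closed <- c(closed, open)
  if (length(closed) == 0L) {
    return(tibble::tibble(track_id = integer(), frame = numeric(),
                          time_s = numeric(), x_um = numeric(), y_um = numeric()))
  }
  dplyr::bind_rows(lapply(closed, function(tr) dplyr::bind_rows(tr$rows))) |>
    dplyr::arrange(.data$track_id, .data$frame)
}
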