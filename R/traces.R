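#' Ratiometric trace from two-channel fluorescence
#'
#' Background-subtracts both channels, applies a centered rolling average
#' (window shrinking at the trace edges), and divides:
#' `ratio(t) = movavg(green - bg_g) / movavg(red - bg_r)`.
#'
#' @param raw A tibble with columns `cell_id`, `time_s`, `green`, `red` (one
#'   or more cells; each cell's timestamps must be uniform).
#' @param background_green,background_red Scalar channel backgrounds.
#' @param smooth_window Rolling-average width in frames (odd; default 3).
#' @return A tibble `cell_id`, `time_s`, `ratio`.
#' @examples
#' raw <- tibble::tibble(cell_id = 1, time_s = 0:3,
#'                       green = c(100, 130, 160, 190), red = 100)
#' compute_ratio_trace(raw)
#' @export
compute_ratio_trace <- function(raw, background_green = 0, background_red = 0,
                                smooth_window = 3L) {
  check_columns(raw, c("cell_id", "time_s", "green", "red"), "`raw`")
  raw |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      check_uniform_time(d$time_s, what = "time_s")
      red_sub <- d$red - background_red
      if (any(red_sub <= 0)) {
        bad <- which(red_sub <= 0)[1L]
        abort(sprintf(
          "red channel does not exceed background at frame %d (cell %s).",
          bad, format(key$cell_id)), class = "mgca_degenerate_channel_error")
      }
      tibble::tibble(
        time_s = d$time_s,
        ratio = rolling_mean_centered(d$green - background_green, smooth_window) /
          rolling_mean_centered(red_sub, smooth_window))
    }) |>
    dplyr::ungroup()
}

# Per-cell application of a scalar summary f(time_s, ratio) -> named list.
per_cell <- function(trace, f) {
  check_columns(trace, c("cell_id", "time_s", "ratio"), "`trace`")
  trace |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) tibble::as_tibble(f(d$time_s, d$ratio))) |>
    dplyr::ungroup()
}

#' Baseline ratio: mean of the k minimum pre-stimulus values
#'
#' @param trace A ratio-trace tibble (`cell_id`, `time_s`, `ratio`).
#' @param stim_time Agonist application time, seconds.
#' @param k Number of minimum pre-stimulus ratio values averaged (default 10).
#' @return A tibble `cell_id`, `baseline`.
#' @export
baseline_value <- function(trace, stim_time, k = 10L) {
  per_cell(trace, function(time_s, ratio) {
    pre <- ratio[time_s < stim_time]
    if (length(pre) < k) {
      abort(sprintf("only %d pre-stimulus frames; %d required for the baseline.",
                    length(pre), k), class = "mgca_insufficient_baseline_error")
    }
    list(baseline = mean(sort(pre)[seq_len(k)]))
  })
}

#' Baseline-subtracted peak response
#'
#' Maximum ratio in the post-stimulus search window minus the baseline,
#' floored at zero.  The window ends `peak_window` seconds after the
#' stimulus, to avoid scoring a late sustained plateau as the peak.
#'
#' @inheritParams baseline_value
#' @param peak_window Search-window length after the stimulus, seconds
#'   (default 120; `Inf` searches to the end of the trace).
#' @return A tibble `cell_id`, `baseline`, `peak_response`.
#' @export
peak_response <- function(trace, stim_time, peak_window = 120, k = 10L) {
  per_cell(trace, function(time_s, ratio) {
    base <- mean(sort(ratio[time_s < stim_time])[seq_len(k)])
    if (length(ratio[time_s < stim_time]) < k) {
      abort("insufficient pre-stimulus frames for the baseline.",
            class = "mgca_insufficient_baseline_error")
    }
    win <- time_s >= stim_time & time_s <= stim_time + peak_window
    if (!any(win)) {
      abort("empty post-stimulus window.", class = "mgca_window_error")
    }
    list(baseline = base,
         peak_response = max(max(ratio[win]) - base, 0))
  })
}

#' Baseline-subtracted response at a fixed time after the stimulus
#'
#' Ratio at the frame nearest `stim_time + offset` minus the baseline (the
#' sustained, store-operated phase; default offset 5 min).
#'
#' @inheritParams baseline_value
#' @param offset Seconds after the stimulus (default 300).
#' @return A tibble `cell_id`, `response_at`.
#' @export
response_at <- function(trace, stim_time, offset = 300, k = 10L) {
  per_cell(trace, function(time_s, ratio) {
    if (max(time_s) < stim_time + offset) {
      abort(sprintf("trace ends %.1f s before stim_time + offset.",
                    stim_time + offset - max(time_s)), class = "mgca_window_error")
    }
    base <- mean(sort(ratio[time_s < stim_time])[seq_len(k)])
    idx <- which.min(abs(time_s - (stim_time + offset)))
    list(response_at = ratio[idx] - base)
  })
}

#' Store-operated Ca2+ entry rate
#'
#' Maximum rise rate after Ca2+ add-back: the largest
#' `(ratio(t0 + w) - ratio(t0)) / w` over all frame-aligned windows starting
#' at or after `readd_time`, where `w` is the smallest whole-frame span of at
#' least `window` seconds (the rate divides by the true span).
#'
#' @inheritParams baseline_value
#' @param readd_time Ca2+ add-back time, seconds.
#' @param window Nominal rise-window length, seconds (default 10).
#' @return A tibble `cell_id`, `soce_rate` (delta ratio per second).
#' @export
soce_rate <- function(trace, readd_time, window = 10) {
  if (is.null(readd_time) || !is.finite(readd_time)) {
    abort("`readd_time` is required for the SOCE rate.", class = "mgca_contract_error")
  }
  per_cell(trace, function(time_s, ratio) {
    post <- time_s >= readd_time
    t <- time_s[post]; r <- ratio[post]
    dt <- diff(t[1:2])
    span <- ceiling(window / dt - 1e-9)    # frames covering >= `window` s
    if (length(t) < span + 1L) {
      abort(sprintf("need at least %.0f s of data after `readd_time`.", window),
            class = "mgca_contract_error")
    }
    idx <- seq_len(length(r) - span)
    rates <- (r[idx + span] - r[idx]) / (t[idx + span] - t[idx])
    list(soce_rate = max(rates))
  })
}

#' Area under the baseline-subtracted trace
#'
#' Trapezoidal integral of `max(ratio - baseline, 0)` over `[t_a, t_b]`
#' (store release quantified as area under the curve).
#'
#' @inheritParams baseline_value
#' @param t_a,t_b Integration window, seconds (must satisfy `t_a < t_b` and
#'   lie within the trace).
#' @return A tibble `cell_id`, `auc` (ratio x seconds).
#' @export
trace_auc <- function(trace, stim_time, t_a, t_b, k = 10L) {
  if (t_b <= t_a) {
    abort("`t_b` must exceed `t_a`.", class = "mgca_contract_error")
  }
  per_cell(trace, function(time_s, ratio) {
    if (t_a < min(time_s) || t_b > max(time_s)) {
      abort("integration window extends beyond the trace.",
            class = "mgca_contract_error")
    }
    base <- mean(sort(ratio[time_s < stim_time])[seq_len(k)])
    win <- time_s >= t_a & time_s <= t_b
    y <- pmax(ratio[win] - base, 0)
    t <- time_s[win]
    list(auc = sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2))
  })
}

#' Classify responding cells
#'
#' A cell responds when its baseline-subtracted peak reaches
#' `max(n_sd * robust SD of pre-stimulus residuals, floor)`; the comparison
#' is inclusive.  The robust SD is the scaled median absolute deviation of
#' the pre-stimulus ratios about their median, and the absolute floor guards
#' noiseless traces.
#'
#' @inheritParams peak_response
#' @param n_sd Multiple of the robust pre-stimulus SD (default 3).
#' @param floor Absolute minimum threshold, delta ratio (default 0.05).
#' @return A tibble `cell_id`, `baseline`, `peak_response`, `threshold`,
#'   `responder`.
#' @export
classify_responder <- function(trace, stim_time, peak_window = 120, k = 10L,
                               n_sd = 3, floor = 0.05) {
  per_cell(trace, function(time_s, ratio) {
    pre <- ratio[time_s < stim_time]
    if (length(pre) < k) {
      abort("insufficient pre-stimulus frames.", class = "mgca_insufficient_baseline_error")
    }
    base <- mean(sort(pre)[seq_len(k)])
    win <- time_s >= stim_time & time_s <= stim_time + peak_window
    pk <- max(max(ratio[win]) - base, 0)
    thr <- max(n_sd * mad(pre), floor)
    list(baseline = base, peak_response = pk, threshold = thr,
         responder = pk >= thr)
  })
}

#' Delta-F over F0
#'
#' `(F(t) - F0) / F0` with `F0` the mean fluorescence over a baseline window.
#'
#' @param f A tibble with columns `cell_id`, `time_s`, `f` (fluorescence).
#' @param f0_window Two-element numeric `[t_a, t_b]` baseline window, seconds.
#' @return A tibble `cell_id`, `time_s`, `dff`.
#' @export
dff <- function(f, f0_window) {
  check_columns(f, c("cell_id", "time_s", "f"), "`f`")
  f |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      win <- d$time_s >= f0_window[1L] & d$time_s <= f0_window[2L]
      f0 <- mean(d$f[win])
      if (!is.finite(f0) || f0 <= 0) {
        abort("baseline F0 must be positive.", class = "mgca_degenerate_baseline_error")
      }
      tibble::tibble(time_s = d$time_s, dff = (d$f - f0) / f0)
    }) |>
    dplyr::ungroup()
}

#' All single-trace metrics in one table
#'
#' Convenience wrapper computing baseline, peak response, sustained response,
#' responder status, and (when a window is given) AUC and (when `readd_time`
#' is given) the SOCE rate, per cell.
#'
#' @inheritParams classify_responder
#' @param offset Sustained-response offset, seconds (default 300); skipped
#'   when the trace is too short.
#' @param readd_time Optional Ca2+ add-back time for the SOCE rate.
#' @param auc_window Optional two-element window for the AUC.
#' @return One row per cell.
#' @export
trace_metrics <- function(trace, stim_time, peak_window = 120, offset = 300,
                          k = 10L, n_sd = 3, floor = 0.05, readd_time = NULL,
                          auc_window = NULL) {
  out <- classify_responder(trace, stim_time, peak_window, k, n_sd, floor)
  if (max(trace$time_s) >= stim_time + offset) {
    out <- dplyr::left_join(out, response_at(trace, stim_time, offset, k),
                            by = "cell_id")
  }
  if (!is.null(readd_time)) {
    out <- dplyr::left_join(out, soce_rate(trace, readd_time), by = "cell_id")
  }
  if (!is.null(auc_window)) {
    out <- dplyr::left_join(
      out, trace_auc(trace, stim_time, auc_window[1L], auc_window[2L], k),
      by = "cell_id")
  }
  out
}
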