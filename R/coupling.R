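#' Pair instantaneous Ca2+ ratio with instantaneous speed
#'
#' For each cell and each frame-to-frame displacement interval, emits one
#' sample pairing the speed over that interval with the ratio at the frame
#' nearest the interval midpoint (ties resolved to the earlier frame), if
#' one lies within `align_tolerance`; unmatched intervals are dropped and
#' counted in `attr(, "n_dropped")`.
#'
#' @param ratio_traces A tibble `cell_id`, `time_s`, `ratio`.
#' @param tracks A tibble `track_id`, `time_s`, `x_um`, `y_um`, where
#'   `track_id` matches `cell_id` (cells are tracked as surfaces, so one
#'   track per cell).
#' @param align_tolerance Maximum |ratio timestamp - interval midpoint| in
#'   seconds; defaults to half the ratio frame interval.
#' @return A tibble of coupled samples: `cell_id`, `frame`, `time_s`
#'   (interval start), `ratio`, `speed_um_min`.
#' @export
pair_ca_speed <- function(ratio_traces, tracks, align_tolerance = NULL) {
  check_columns(ratio_traces, c("cell_id", "time_s", "ratio"), "`ratio_traces`")
  check_columns(tracks, c("track_id", "time_s", "x_um", "y_um"), "`tracks`")
  shared <- intersect(unique(ratio_traces$cell_id), unique(tracks$track_id))
  if (length(shared) == 0L) {
    abort("no shared cell ids between traces and tracks.",
          class = "mgca_contract_error")
  }
  if (is.null(align_tolerance)) {
    align_tolerance <- median(diff(sort(unique(ratio_traces$time_s)))) / 2
  }
  speeds <- instantaneous_speeds(dplyr::filter(tracks, .data$track_id %in% shared))
  dropped <- 0L
  out <- purrr::map_dfr(shared, function(cid) {
    sp <- dplyr::filter(speeds, .data$track_id == cid)
    rt <- dplyr::filter(ratio_traces, .data$cell_id == cid) |>
      dplyr::arrange(.data$time_s)
    if (nrow(sp) == 0L || nrow(rt) == 0L) return(NULL)
    dt <- if (nrow(sp) > 1L) sp$time_s[2L] - sp$time_s[1L] else
      max(diff(rt$time_s), 1)
    mid <- sp$time_s + dt / 2
    # nearest ratio frame; ties (midpoint equidistant) take the earlier frame
    idx <- vapply(mid, function(m) {
      d <- abs(rt$time_s - m)
      which(d <= min(d) + 1e-9)[1L]
    }, integer(1))
    ok <- abs(rt$time_s[idx] - mid) <= align_tolerance + 1e-9
    dropped <<- dropped + sum(!ok)
    tibble::tibble(cell_id = cid, frame = sp$frame[ok], time_s = sp$time_s[ok],
                   ratio = rt$ratio[idx[ok]], speed_um_min = sp$speed_um_min[ok])
  })
  attr(out, "n_dropped") <- dropped
  out
}

#' Spearman rank correlation of coupled samples
#'
#' Rank correlation with average-rank tie handling; the two-sided p-value
#' uses the t approximation `t = r sqrt((n-2)/(1-r^2))` for n > 30 and
#' [stats::cor.test()] otherwise.  Constant input yields an undefined,
#' flagged result rather than an error.
#'
#' @param samples A tibble with columns `ratio` and `speed_um_min` (or any
#'   two columns named by `x`, `y`).
#' @param x,y Column names to correlate.
#' @return A one-row tibble: `spearman_r`, `p_value`, `n_pairs`, `defined`.
#' @export
spearman_correlation <- function(samples, x = "ratio", y = "speed_um_min") {
  check_columns(samples, c(x, y), "`samples`")
  xv <- samples[[x]]; yv <- samples[[y]]
  n <- length(xv)
  if (n < 3L) {
    abort("need at least 3 samples.", class = "mgca_parameter_error")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    return(tibble::tibble(spearman_r = NA_real_, p_value = NA_real_,
                          n_pairs = n, defined = FALSE))
  }
  r <- cor(xv, yv, method = "spearman")
  p <- if (n > 30L) {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  } else {
    suppressWarnings(stats::cor.test(xv, yv, method = "spearman"))$p.value
  }
  tibble::tibble(spearman_r = r, p_value = p, n_pairs = n, defined = TRUE)
}

ratio_bins <- function(ratio, bin_width) {
  bin <- floor(ratio / bin_width + 1e-12)
  tibble::tibble(bin_lo = bin * bin_width,
                 bin_mid = (bin + 0.5) * bin_width)
}

#' Mean speed binned by Ca2+ ratio
#'
#' Half-open bins `[m w, (m+1) w)` anchored at 0 (a ratio exactly on an edge
#' falls in the upper bin); empty bins are absent from the output rather
#' than reported as zero.
#'
#' @inheritParams spearman_correlation
#' @param bin_width Ratio bin increment (default 0.5).
#' @return A tibble `bin_lo`, `bin_mid`, `n`, `mean_speed_um_min`.
#' @export
bin_speed_by_ratio <- function(samples, bin_width = 0.5) {
  check_columns(samples, c("ratio", "speed_um_min"), "`samples`")
  dplyr::bind_cols(samples, ratio_bins(samples$ratio, bin_width)) |>
    dplyr::group_by(.data$bin_lo, .data$bin_mid) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_speed_um_min = mean(.data$speed_um_min),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin_lo)
}

#' Percentage of fast-moving samples per Ca2+ ratio bin
#'
#' A sample is fast when its speed strictly exceeds `threshold` (default
#' 10 um/min).
#'
#' @inheritParams bin_speed_by_ratio
#' @param threshold Fast-speed threshold, um/min.
#' @return A tibble `bin_lo`, `bin_mid`, `n`, `fast_pct`.
#' @export
fast_fraction <- function(samples, threshold = 10, bin_width = 0.5) {
  check_columns(samples, c("ratio", "speed_um_min"), "`samples`")
  dplyr::bind_cols(samples, ratio_bins(samples$ratio, bin_width)) |>
    dplyr::group_by(.data$bin_lo, .data$bin_mid) |>
    dplyr::summarise(n = dplyr::n(),
                     fast_pct = 100 * mean(.data$speed_um_min > threshold),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin_lo)
}

#' Full coupling summary
#'
#' Correlation, binned mean speeds and fast fractions in one object.
#'
#' @inheritParams bin_speed_by_ratio
#' @inheritParams fast_fraction
#' @return A list of class `coupling_summary`: `correlation` (one-row
#'   tibble), `bins` (joined bin table), `fast_threshold`, `bin_width`.
#' @export
coupling_summary <- function(samples, bin_width = 0.5, threshold = 10) {
  out <- list(
    correlation = spearman_correlation(samples),
    bins = dplyr::full_join(bin_speed_by_ratio(samples, bin_width),
                            fast_fraction(samples, threshold, bin_width),
                            by = c("bin_lo", "bin_mid", "n")),
    fast_threshold = threshold,
    bin_width = bin_width)
  class(out) <- "coupling_summary"
  out
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat(sprintf("Ca2+-speed coupling: Spearman r = %.4f (p = %.3g, n = %d pairs)\n",
              x$correlation$spearman_r, x$correlation$p_value,
              x$correlation$n_pairs))
  cat(sprintf("  %d ratio bins of width %.2f; fast threshold %.1f um/min\n",
              nrow(x$bins), x$bin_width, x$fast_threshold))
  invisible(x)
}
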