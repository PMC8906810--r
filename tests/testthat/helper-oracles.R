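# Independent brute-force oracles used to cross-check the implementation.

# windowed mean by explicit loop (centered, shrinking at edges)
bf_movavg <- function(x, w) {
  h <- (w - 1) %/% 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - h):min(length(x), i + h)])
  }, numeric(1))
}

# track metrics by direct formula evaluation
bf_track_metrics <- function(time_s, x, y) {
  n <- length(x)
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  tdl <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  tl <- sum(steps)
  td <- time_s[n] - time_s[1]
  list(TDL = tdl, TL = tl, TD = td,
       mean_speed = mean(steps / diff(time_s) * 60),
       displacement_10min = 600 * tdl / td,
       straightness = if (tl > 0) tdl / tl else 0)
}

# time-averaged MSD of one track by the O(n^2) double loop
bf_msd_single <- function(x, y, max_lag) {
  vapply(seq_len(max_lag), function(l) {
    n <- length(x)
    acc <- 0
    for (i in seq_len(n - l)) {
      acc <- acc + (x[i + l] - x[i])^2 + (y[i + l] - y[i])^2
    }
    acc / (n - l)
  }, numeric(1))
}

# random uniform-interval track as a tibble
random_track <- function(id, n = 50, dt = 15) {
  tibble::tibble(track_id = id,
                 time_s = (seq_len(n) - 1) * dt,
                 x_um = cumsum(rnorm(n)),
                 y_um = cumsum(rnorm(n)))
}

# 8-connected component count by simple flood fill (independent of igraph)
bf_component_count <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cnt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cnt <- cnt + 1L
    queue <- start
    lab[start] <- cnt
    while (length(queue) > 0L) {
      cur <- queue[1L]; queue <- queue[-1L]
      r <- ((cur - 1L) %% nrow(mask)) + 1L
      c <- ((cur - 1L) %/% nrow(mask)) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          idx <- (cc - 1L) * nrow(mask) + rr
          lab[rr, cc] <- cnt
          queue <- c(queue, idx)
        }
      }
    }
  }
  cnt
}

# single-cell ratio trace tibble
ratio_trace <- function(time_s, ratio, cell_id = 1) {
  tibble::tibble(cell_id = cell_id, time_s = time_s, ratio = ratio)
}
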