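#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `bottom + (top - bottom) / (1 + (ec50/dose)^hill)` on
#' the log-dose axis.  The fit is performed on per-dose mean responses,
#' weighted by inverse squared SEM when every dose has at least three cells,
#' unweighted otherwise.  `ec50` and `hill` are fitted on the log scale to
#' enforce positivity.  A flat response profile yields a fit flagged
#' non-convergent rather than an error.
#'
#' @param data A tibble with columns `dose` (nM) and `response` (delta
#'   ratio), one row per cell.  At least 4 distinct doses are required.
#' @return An object of class `hill_fit` with elements `ec50`, `hill_coef`,
#'   `bottom`, `top`, `converged`, `resid_norm`, `means` (the per-dose table
#'   used), and `fit`.  Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' pop <- simulate_dose_response(c(10, 30, 100, 300, 1000, 3000), seed = 1)
#' fit_hill(pop$cells)
#' @export
fit_hill <- function(data) {
  check_columns(data, c("dose", "response"), "`data`")
  if (dplyr::n_distinct(data$dose) < 4L) {
    abort("need at least 4 distinct doses.", class = "mgca_parameter_error")
  }
  means <- data |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(mean_response = mean(.data$response),
                     n = dplyr::n(),
                     sem = sd(.data$response) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::arrange(.data$dose)
  use_weights <- all(means$n >= 3L) && all(is.finite(means$sem)) &&
    all(means$sem > 0)
  w <- if (use_weights) 1 / means$sem^2 else rep(1, nrow(means))
  rng <- diff(range(means$mean_response))
  pos <- means$dose[means$dose > 0]
  start <- list(bottom = min(means$mean_response),
                top = max(means$mean_response),
                log_ec50 = log(exp(mean(log(pos)))),
                log_hill = log(1))
  fit <- if (rng <= .Machine$double.eps^0.5) NULL else tryCatch(
    minpack.lm::nlsLM(
      mean_response ~ hill_response(dose, bottom, top, exp(log_ec50), exp(log_hill)),
      data = means, weights = w, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(ec50 = NA_real_, hill_coef = NA_real_,
                bottom = mean(means$mean_response), top = mean(means$mean_response),
                converged = FALSE, resid_norm = NA_real_, means = means, fit = NULL)
  } else {
    cf <- coef(fit)
    out <- list(ec50 = unname(exp(cf["log_ec50"])),
                hill_coef = unname(exp(cf["log_hill"])),
                bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                converged = fit$convInfo$isConv,
                resid_norm = sqrt(sum(stats::residuals(fit)^2)),
                means = means, fit = fit)
  }
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill dose-response fit\n")
  cat(sprintf("  EC50 = %.4g nM, Hill = %.3g, bottom = %.3g, top = %.3g (converged: %s)\n",
              x$ec50, x$hill_coef, x$bottom, x$top, x$converged))
  invisible(x)
}

#' @rdname fit_hill
#' @param x,object A `hill_fit` object.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = c("ec50", "hill_coef", "bottom", "top"),
                 estimate = c(x$ec50, x$hill_coef, x$bottom, x$top))
}

#' @rdname fit_hill
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, resid_norm = x$resid_norm,
                 n_doses = nrow(x$means))
}
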