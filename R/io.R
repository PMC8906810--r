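# Readers and writers for the pipeline's CSV/TIFF/JSON dialects.  CSV files
# may open with a `# key: value` metadata block (stimulus times, channel
# backgrounds), which round-trips through the writers.

read_metadata_block <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      val <- type.convert(trimws(m[3L]), as.is = TRUE)
      meta[[m[2L]]] <- val
    }
  }
  meta
}

format_metadata_block <- function(meta) {
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta) == 0L) return(character(0))
  sprintf("# %s: %s", names(meta), vapply(meta, format, character(1)))
}

read_csv_body <- function(path, col_aliases = NULL) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!is.null(col_aliases)) {
    for (canonical in names(col_aliases)) {
      hit <- intersect(col_aliases[[canonical]], names(df))
      if (length(hit) > 0L && !(canonical %in% names(df))) {
        names(df)[names(df) == hit[1L]] <- canonical
      }
    }
  }
  df
}

#' Read a two-channel fluorescence trace CSV
#'
#' Expects columns `cell_id`, `time_s`, `green`, `red` (header aliases
#' configurable) and an optional leading `# key: value` metadata block
#' carrying `stim_time_s`, `readd_time_s`, `background_green`,
#' `background_red`.
#'
#' @param path File path.
#' @param col_aliases Named list mapping canonical column names to accepted
#'   header aliases.
#' @return A tibble with the metadata in `attr(, "meta")`.
#' @export
read_traces <- function(path, col_aliases = NULL) {
  df <- read_csv_body(path, col_aliases)
  check_columns(df, c("cell_id", "time_s", "green", "red"),
                sprintf("'%s'", basename(path)))
  bad <- which(!is.finite(df$green) | !is.finite(df$red))
  if (length(bad) > 0L) {
    abort(sprintf("non-numeric fluorescence in '%s' at data row %d.",
                  basename(path), bad[1L]), class = "mgca_schema_error")
  }
  attr(df, "meta") <- read_metadata_block(path)
  df
}

#' @rdname read_traces
#' @param trace The trace tibble to write.
#' @param meta Named list written as the `# key: value` header block.
#' @export
write_traces <- function(trace, path, meta = attr(trace, "meta")) {
  body <- sub("\n+$", "", readr::format_csv(trace))
  writeLines(c(format_metadata_block(meta %||% list()), body), path)
  invisible(path)
}

# header dialects of common commercial tracker exports
default_track_aliases <- function() {
  list(track_id = c("TrackID", "Track ID", "Parent", "id"),
       frame = c("Time", "frame_index", "Slice"),
       time_s = c("time", "Time (s)", "t"),
       x_um = c("Position X", "x", "X"),
       y_um = c("Position Y", "y", "Y"))
}

#' Read and write cell-track CSVs
#'
#' Canonical columns `track_id`, `frame`, `time_s`, `x_um`, `y_um`; common
#' commercial-tracker header aliases are mapped automatically and further
#' aliases can be supplied.
#'
#' @param path File path.
#' @param col_aliases Named list of extra header aliases, merged over the
#'   defaults.
#' @return A tibble.
#' @export
read_tracks <- function(path, col_aliases = NULL) {
  aliases <- modifyList(default_track_aliases(), col_aliases %||% list())
  df <- read_csv_body(path, aliases)
  check_columns(df, c("track_id", "time_s", "x_um", "y_um"),
                sprintf("'%s'", basename(path)))
  df
}

#' @rdname read_tracks
#' @param tracks The track tibble to write.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tracks, path, progress = FALSE)
  invisible(path)
}

#' Read an image field from TIFF
#'
#' Multi-page TIFFs (z-stacks) are reduced to their maximum intensity
#' projection.
#'
#' @param path TIFF path.
#' @param pixel_size Pixel size, um/pixel.
#' @inheritParams image_field
#' @return An [image_field()].
#' @export
read_field <- function(path, pixel_size, field_id = basename(path),
                       condition = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- simplify2array(pages)
  image_field(stack, pixel_size, field_id, condition)
}

#' @rdname read_field
#' @param field The [image_field()] (or matrix) to write; intensities are
#'   scaled to 16-bit.
#' @export
write_field <- function(field, path) {
  m <- if (inherits(field, "image_field")) field$data else field
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Split tracks at internal time gaps
#'
#' Tracks linked with allowed missing frames contain internal gaps; MSD and
#' autocorrelation need uniform sampling, so gapped tracks are split into
#' uniform sub-tracks (suffixing the track id) rather than interpolated.
#'
#' @inheritParams filter_tracks
#' @return A tibble with uniform-interval tracks.
#' @export
split_track_gaps <- function(tracks) {
  check_columns(tracks, c("track_id", "time_s"), "`tracks`")
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::mutate(.dt = c(0, diff(.data$time_s)),
                  .seg = cumsum(.data$.dt > min(.data$.dt[.data$.dt > 0],
                                                Inf) * 1.5)) |>
    dplyr::ungroup() |>
    dplyr::mutate(track_id = ifelse(.data$.seg > 0,
                                    paste0(.data$track_id, ".", .data$.seg),
                                    as.character(.data$track_id))) |>
    dplyr::select(-".dt", -".seg")
}
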