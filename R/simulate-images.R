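# Rasterization helpers -------------------------------------------------------

# 8-connected Bresenham line between pixel centers; returns a 2-column matrix
# of (row, col) pixels, endpoints included.
raster_line <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc)
  if (n == 0L) return(cbind(r0, c0))
  err <- dc - dr
  r <- r0; c <- c0
  out <- matrix(0L, n + 1L, 2L)
  out[1L, ] <- c(r0, c0)
  for (k in seq_len(n)) {
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
    out[k + 1L, ] <- c(r, c)
  }
  out
}

# Geodesic length, in pixel steps, of an 8-connected polyline: orthogonal
# step = 1, diagonal step = sqrt(2).
polyline_length_px <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  total <- 0
  for (k in seq_len(nrow(pts) - 1L)) {
    dr <- abs(pts[k + 1L, 1L] - pts[k, 1L])
    dc <- abs(pts[k + 1L, 2L] - pts[k, 2L])
    n_diag <- min(dr, dc)
    total <- total + (max(dr, dc) - n_diag) + n_diag * sqrt(2)
  }
  total
}

# Dilate a mask with a 3x3 square structuring element, `iter` times.
dilate3 <- function(m, iter = 1L) {
  for (i in seq_len(iter)) m <- neighbourhood_sum(m * 1L) > 0L
  m
}

draw_disk <- function(mask, r0, c0, radius) {
  rr <- max(1L, r0 - radius):min(nrow(mask), r0 + radius)
  cc <- max(1L, c0 - radius):min(ncol(mask), c0 + radius)
  for (r in rr) for (c in cc) {
    if ((r - r0)^2 + (c - c0)^2 <= radius^2) mask[r, c] <- TRUE
  }
  mask
}

#' Specification of one synthetic ramified cell
#'
#' A filled soma plus branch polylines.  Branches must start on the soma (or
#' on an earlier branch, to form secondary processes); vertex-to-vertex
#' steps along each polyline are rasterized 8-connected, and the ground
#' truth branch length is the polyline's geodesic step length (orthogonal
#' step = 1 px, diagonal = sqrt(2) px) times the pixel size.
#'
#' @param soma_center Integer `(row, col)` pixel coordinates.
#' @param soma_radius Soma radius, pixels.
#' @param branches A list of polylines, each an n x 2 matrix of `(row, col)`
#'   vertices; the first vertex must lie within the soma or on a previous
#'   branch.
#' @param cell_id Identifier carried into the ground-truth table.
#' @return A list of class `ramified_cell_spec` with the per-branch ground
#'   truth lengths (px) attached.
#' @export
ramified_cell_spec <- function(soma_center, soma_radius, branches,
                               cell_id = 1L) {
  stopifnot(length(soma_center) == 2L, soma_radius >= 1)
  on_soma_or_branch <- function(pt, k) {
    if (sum((pt - soma_center)^2) <= (soma_radius + 1)^2) return(TRUE)
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        ras <- raster_line_polyline(branches[[j]])
        if (any(abs(ras[, 1L] - pt[1L]) <= 1L & abs(ras[, 2L] - pt[2L]) <= 1L)) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (k in seq_along(branches)) {
    if (!on_soma_or_branch(branches[[k]][1L, ], k)) {
      abort("every branch must start on the soma or on an earlier branch.",
            class = "mgca_parameter_error")
    }
  }
  structure(list(soma_center = as.integer(soma_center),
                 soma_radius = soma_radius,
                 branches = branches,
                 branch_lengths_px = vapply(branches, polyline_length_px,
                                            numeric(1)),
                 cell_id = cell_id),
            class = "ramified_cell_spec")
}

raster_line_polyline <- function(pts) {
  do.call(rbind, lapply(seq_len(nrow(pts) - 1L), function(k) {
    raster_line(pts[k, 1L], pts[k, 2L], pts[k + 1L, 1L], pts[k + 1L, 2L])
  }))
}

cell_extent_px <- function(spec, stroke_width) {
  pts <- do.call(rbind, spec$branches)
  max(spec$soma_radius,
      max(abs(sweep(pts, 2L, spec$soma_center)))) + stroke_width
}

#' Render ramified cells into a grayscale image with ground truth
#'
#' Somata are filled disks; branches are strokes of the requested width
#' (width 3 survives the binary 3x3 median despeckle stage).  Optional
#' speckle noise sets isolated background pixels (kept clear of the cells)
#' to the foreground intensity.
#'
#' @param specs A list of [ramified_cell_spec()]s.  Cells must not overlap.
#' @param field_size Image side, pixels (square field).
#' @param pixel_size Pixel size, um/pixel (default 0.5).
#' @param stroke_width Branch stroke width, 1 or 3 pixels (default 3).
#' @param fg_intensity,bg_intensity Foreground / background gray levels.
#' @param speckle_density Fraction of background pixels set as speckles.
#' @param seed Integer seed (speckle placement).
#' @return A list with `field` (an [image_field()]), `truth` (tibble:
#'   `cell_id`, `n_branches`, `total_length_um`, `centroid_row`,
#'   `centroid_col`, list column `branch_lengths_um`), and `n_speckles`.
#' @export
generate_ramified_image <- function(specs, field_size = 256L, pixel_size = 0.5,
                                    stroke_width = 3L, fg_intensity = 200,
                                    bg_intensity = 10, speckle_density = 0,
                                    seed = NULL, field_id = "field",
                                    condition = NA_character_) {
  stopifnot(all(vapply(specs, inherits, logical(1), "ramified_cell_spec")))
  if (!stroke_width %in% c(1L, 3L)) {
    abort("`stroke_width` must be 1 or 3.", class = "mgca_parameter_error")
  }
  masks <- lapply(specs, function(sp) {
    m <- matrix(FALSE, field_size, field_size)
    for (br in sp$branches) {
      ras <- raster_line_polyline(br)
      ras <- ras[ras[, 1L] >= 1L & ras[, 1L] <= field_size &
                 ras[, 2L] >= 1L & ras[, 2L] <= field_size, , drop = FALSE]
      m[ras] <- TRUE
    }
    if (stroke_width == 3L) m <- dilate3(m)
    draw_disk(m, sp$soma_center[1L], sp$soma_center[2L], sp$soma_radius)
  })
  # overlap check on dilated masks (cells must stay separable)
  occupied <- matrix(FALSE, field_size, field_size)
  for (m in masks) {
    if (any(occupied & dilate3(m, 2L))) {
      abort("cells overlap (or come within 2 px of each other).",
            class = "mgca_parameter_error")
    }
    occupied <- occupied | dilate3(m, 2L)
  }
  cells <- Reduce(`|`, masks)
  img <- matrix(bg_intensity, field_size, field_size)
  img[cells] <- fg_intensity
  n_speckles <- 0L
  if (speckle_density > 0) {
    img <- with_seed_if(seed, {
      candidates <- which(!dilate3(cells, 2L))
      n_speckles <- stats::rbinom(1L, length(candidates), speckle_density)
      chosen <- sample(candidates, n_speckles)
      # keep speckles isolated from each other so each is a 1-px component
      keep <- logical(length(chosen))
      taken <- matrix(FALSE, field_size, field_size)
      for (i in seq_along(chosen)) {
        r <- ((chosen[i] - 1L) %% field_size) + 1L
        c <- ((chosen[i] - 1L) %/% field_size) + 1L
        rr <- max(1L, r - 2L):min(field_size, r + 2L)
        cc <- max(1L, c - 2L):min(field_size, c + 2L)
        if (!any(taken[rr, cc])) { keep[i] <- TRUE; taken[r, c] <- TRUE }
      }
      chosen <- chosen[keep]
      n_speckles <- length(chosen)
      img[chosen] <- fg_intensity
      img
    })
  }
  truth <- purrr::map_dfr(specs, function(sp) {
    tibble::tibble(cell_id = sp$cell_id,
                   n_branches = length(sp$branches),
                   total_length_um = sum(sp$branch_lengths_px) * pixel_size,
                   centroid_row = sp$soma_center[1L],
                   centroid_col = sp$soma_center[2L],
                   branch_lengths_um = list(sp$branch_lengths_px * pixel_size))
  })
  list(field = image_field(img, pixel_size, field_id, condition),
       truth = truth, n_speckles = n_speckles)
}

# Directions on the 45-degree compass, as unit steps (row, col).
compass8 <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                  c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

#' Simulate a field of random ramified cells with known ground truth
#'
#' Cells are stars of 3-4 straight branches leaving the soma center along
#' 45-degree-compass directions separated by at least 90 degrees (so that
#' neighbouring strokes never merge near the soma and each ground-truth
#' branch maps to exactly one skeleton branch); branch directions on the
#' compass make the rasterized geodesic equal the polyline length exactly.
#' Optionally, single-branch "stub" cells whose total skeleton is shorter
#' than the process filter are added to exercise the > 8 um rule.
#'
#' @param n_cells Ramified cells per field.
#' @param n_stubs Short single-branch cells per field (default 1).
#' @param field_size Image side, pixels.
#' @param pixel_size Pixel size, um/pixel.
#' @param branch_length_px Integer range branch lengths are drawn from.
#' @param stub_length_px Stub branch length, pixels.
#' @param length_scale Multiplier applied to all branch lengths (models
#'   process extension; a paired post-stimulus field uses the same seed with
#'   a scale > 1).
#' @param soma_radius Soma radius, pixels.
#' @param speckle_density Fraction of background pixels speckled.
#' @param seed Integer seed; layout (positions, directions, base lengths) is
#'   a function of the seed alone, so paired fields with different
#'   `length_scale` share their layout.
#' @inheritParams generate_ramified_image
#' @return As [generate_ramified_image()], with `truth` gaining a
#'   `is_stub` column.
#' @export
simulate_ramified_field <- function(n_cells = 5L, n_stubs = 1L,
                                    field_size = 400L, pixel_size = 0.5,
                                    branch_length_px = c(16L, 36L),
                                    stub_length_px = 8L, length_scale = 1,
                                    soma_radius = 3L, speckle_density = 0,
                                    stroke_width = 3L, seed = NULL,
                                    field_id = "field",
                                    condition = NA_character_) {
  layout <- ramified_layout(n_cells, n_stubs, field_size, branch_length_px,
                            stub_length_px, soma_radius, stroke_width,
                            placement_scale = max(1, length_scale),
                            seed = seed)
  specs <- layout_specs(layout, length_scale)
  out <- generate_ramified_image(specs, field_size, pixel_size,
                                 stroke_width, speckle_density = speckle_density,
                                 seed = if (is.null(seed)) NULL else seed + 1L,
                                 field_id = field_id, condition = condition)
  out$truth$is_stub <- layout$is_stub
  out
}

# Random cell layout: centers, branch slots and base lengths.  Placement
# reserves room for branches scaled by `placement_scale`, so a paired field
# rendered at a larger length scale shares the identical layout (the RNG
# draws never depend on the rendering scale).
ramified_layout <- function(n_cells, n_stubs, field_size, branch_length_px,
                            stub_length_px, soma_radius, stroke_width,
                            placement_scale = 1, seed = NULL) {
  # rejection sampling can exhaust a crowded layout; retry with derived
  # seeds so any given seed still yields a deterministic field
  for (attempt in 0:19) {
    s <- if (is.null(seed)) NULL else (seed + attempt * 100003L) %% 2000000000L
    out <- tryCatch(
      ramified_layout_once(n_cells, n_stubs, field_size, branch_length_px,
                           stub_length_px, soma_radius, stroke_width,
                           placement_scale, s),
      mgca_parameter_error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  abort("could not place all cells; reduce `n_cells` or enlarge the field.",
        class = "mgca_parameter_error")
}

ramified_layout_once <- function(n_cells, n_stubs, field_size, branch_length_px,
                                 stub_length_px, soma_radius, stroke_width,
                                 placement_scale = 1, seed = NULL) {
  with_seed_if(seed, {
    total <- n_cells + n_stubs
    centers <- matrix(numeric(0), 0L, 2L)
    extents <- numeric(0)
    cells <- list()
    max_ext <- (max(branch_length_px) * placement_scale * sqrt(2) +
                  soma_radius + stroke_width + 2)
    for (i in seq_len(total)) {
      is_stub <- i > n_cells
      k <- if (is_stub) 1L else sample(3:4, 1L)
      # >= 90 degree separation: k of the 4 slots of a rotated orthogonal cross
      rot <- sample(0:1, 1L)
      slots <- sort(sample(c(1L, 3L, 5L, 7L), k)) + rot
      lens <- if (is_stub) rep(stub_length_px, k) else
        sample(seq(branch_length_px[1L], branch_length_px[2L]), k, replace = TRUE)
      # Euclidean reach: a diagonal branch of n steps spans n * sqrt(2)
      diag_slot <- slots %% 2L == 0L
      reach <- max(lens * placement_scale * ifelse(diag_slot, sqrt(2), 1))
      ext <- reach + soma_radius + stroke_width + 2
      # rejection-sample a center keeping full separation from placed cells
      placed <- FALSE
      for (try in seq_len(500L)) {
        ctr <- round(runif(2L, 1 + max_ext, field_size - max_ext))
        if (nrow(centers) == 0L ||
            all(sqrt(rowSums(sweep(centers, 2L, ctr)^2)) >
                  extents + ext + 4)) {
          placed <- TRUE; break
        }
      }
      if (!placed) {
        abort("could not place all cells; reduce `n_cells` or enlarge the field.",
              class = "mgca_parameter_error")
      }
      centers <- rbind(centers, ctr)
      extents <- c(extents, ext)
      cells[[i]] <- list(center = ctr, slots = slots, lens = lens,
                         is_stub = is_stub)
    }
    list(cells = cells, soma_radius = soma_radius,
         is_stub = vapply(cells, `[[`, logical(1), "is_stub"))
  })
}

# Deterministic specs from a layout at a given branch-length scale.
layout_specs <- function(layout, length_scale = 1) {
  lapply(seq_along(layout$cells), function(i) {
    cl <- layout$cells[[i]]
    lens <- pmax(4L, round(cl$lens * length_scale))
    branches <- lapply(seq_along(cl$slots), function(j) {
      d <- compass8[cl$slots[j], ]
      rbind(cl$center, cl$center + d * lens[j])
    })
    ramified_cell_spec(cl$center, layout$soma_radius, branches, cell_id = i)
  })
}

#' Simulate a paired pre/post process-extension field
#'
#' Renders the same cell layout twice: once at the base branch lengths
#' ("pre") and once with every branch length multiplied by `length_scale`
#' ("post"), emulating stimulus-evoked process extension with an exactly
#' known fold change.
#'
#' @inheritParams simulate_ramified_field
#' @param length_scale Branch-length fold change applied to the post field.
#' @return A list with `pre` and `post` (each as returned by
#'   [simulate_ramified_field()]) and `truth_fold_length` (the realized
#'   ground-truth total-length fold change over non-stub cells, accounting
#'   for integer rounding of scaled lengths).
#' @export
simulate_process_extension_pair <- function(n_cells = 5L, n_stubs = 0L,
                                            length_scale = 1.6,
                                            field_size = 560L, pixel_size = 0.5,
                                            branch_length_px = c(16L, 36L),
                                            stub_length_px = 8L,
                                            soma_radius = 3L,
                                            speckle_density = 0,
                                            stroke_width = 3L, seed = NULL,
                                            field_id = "field") {
  layout <- ramified_layout(n_cells, n_stubs, field_size, branch_length_px,
                            stub_length_px, soma_radius, stroke_width,
                            placement_scale = max(1, length_scale), seed = seed)
  render <- function(scale, condition, seed_off) {
    out <- generate_ramified_image(
      layout_specs(layout, scale), field_size, pixel_size, stroke_width,
      speckle_density = speckle_density,
      seed = if (is.null(seed)) NULL else seed + seed_off,
      field_id = field_id, condition = condition)
    out$truth$is_stub <- layout$is_stub
    out
  }
  pre <- render(1, "pre", 1L)
  post <- render(length_scale, "post", 2L)
  keep <- !layout$is_stub
  list(pre = pre, post = post,
       truth_fold_length = sum(post$truth$total_length_um[keep]) /
         sum(pre$truth$total_length_um[keep]))
}
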