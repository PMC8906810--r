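#' Image field container
#'
#' A light wrapper around a 2-D intensity matrix with its pixel size and
#' identifiers, the unit of the process-morphology analysis.  A 3-D array
#' (z-stack) is reduced to its maximum intensity projection.
#'
#' @param data A numeric matrix (rows = y, columns = x) or 3-D array
#'   (z-stack, third dimension = slice).
#' @param pixel_size Pixel size, um/pixel.
#' @param field_id Field identifier.
#' @param condition Condition label (e.g. "pre" / "post").
#' @return An object of class `image_field`.
#' @export
image_field <- function(data, pixel_size, field_id = "field", condition = NA_character_) {
  check_positive_scalar(pixel_size, "pixel_size")
  if (length(dim(data)) == 3L) {
    data <- apply(data, c(1L, 2L), max)   # maximum intensity projection
  }
  if (!is.matrix(data) || length(data) == 0L) {
    abort("`data` must be a non-empty matrix or 3-D array.",
          class = "mgca_parameter_error")
  }
  structure(list(data = data, pixel_size = pixel_size, field_id = field_id,
                 condition = condition),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("image_field '%s' (%s): %d x %d px at %.3g um/px\n",
              x$field_id, x$condition, nrow(x$data), ncol(x$data),
              x$pixel_size))
  invisible(x)
}

as_mask <- function(x) {
  m <- if (inherits(x, "image_field")) x$data else x
  if (!is.matrix(m)) abort("expected a matrix.", class = "mgca_parameter_error")
  m != 0
}

#' Threshold an image field to a binary mask
#'
#' Foreground is `intensity >= threshold`.  For paired pre/post sets use
#' [binarize_fields()], which enforces the identical threshold across the
#' set.
#'
#' @param image An [image_field()] or matrix.
#' @param threshold Intensity threshold (scalar).
#' @return A logical matrix.
#' @export
binarize <- function(image, threshold) {
  check_positive_scalar(threshold, "threshold")
  m <- if (inherits(image, "image_field")) image$data else image
  m >= threshold
}

#' @rdname binarize
#' @param fields A list of [image_field()]s forming one paired set.
#' @export
binarize_fields <- function(fields, threshold) {
  if (length(threshold) != 1L) {
    abort("a paired image set must share a single threshold.",
          class = "mgca_contract_error")
  }
  lapply(fields, binarize, threshold = threshold)
}

# Sum of the 3x3 neighbourhood (self included), zero-padded borders.
neighbourhood_sum <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out + p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  out
}

#' Despeckle a binary mask (3x3 binary median)
#'
#' The binary 3x3 median: a pixel is foreground in the output when at least
#' 5 of the 9 pixels in its neighbourhood (borders zero-padded) are
#' foreground.  Removes isolated set pixels and fills isolated holes; like
#' any median filter it also rounds single-pixel convex corners, but never
#' thins strokes of width >= 3.
#'
#' @param mask A logical/binary matrix.
#' @return A logical matrix.
#' @export
despeckle <- function(mask) {
  m <- as_mask(mask)
  neighbourhood_sum(m * 1L) >= 5L
}

# 8-connected component labels of a binary mask; 0 = background.
label_components <- function(mask) {
  m <- as_mask(mask)
  lab <- matrix(0L, nrow(m), ncol(m))
  fg <- which(m)
  if (length(fg) == 0L) return(lab)
  idx <- matrix(0L, nrow(m), ncol(m))
  idx[fg] <- seq_along(fg)
  nr <- nrow(m)
  edges <- integer(0)
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    dr <- sh[1L]; dc <- sh[2L]
    rows <- seq(max(1L, 1L - dr), min(nr, nr - dr))
    cols <- seq(max(1L, 1L - dc), min(ncol(m), ncol(m) - dc))
    a <- m[rows, cols, drop = FALSE] & m[rows + dr, cols + dc, drop = FALSE]
    hit <- which(a)
    if (length(hit) > 0L) {
      r0 <- rows[1L]; c0 <- cols[1L]
      hr <- ((hit - 1L) %% length(rows)) + r0
      hc <- ((hit - 1L) %/% length(rows)) + c0
      e1 <- idx[cbind(hr, hc)]
      e2 <- idx[cbind(hr + dr, hc + dc)]
      edges <- c(edges, rbind(e1, e2))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab[fg] <- comp
  lab
}

#' Remove small foreground components (outlier elimination)
#'
#' Drops 8-connected foreground components with area below `area_max`
#' pixels; the deterministic re-specification of an outlier-removal noise
#' filter.
#'
#' @param mask A logical/binary matrix.
#' @param area_max Components with area `< area_max` are removed (default 4).
#' @return A logical matrix.
#' @export
remove_outliers <- function(mask, area_max = 4L) {
  m <- as_mask(mask)
  lab <- label_components(m)
  if (max(lab) == 0L) return(m)
  sizes <- tabulate(lab)
  keep <- which(sizes >= area_max)
  matrix(lab %in% keep, nrow(m), ncol(m))
}

# One Zhang-Suen subiteration; `step` is 1 or 2.  Returns the updated mask.
zs_subiter <- function(m, step) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  sh <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  # neighbours clockwise from north: P2..P9 (rows grow downward -> north = dr -1)
  P2 <- sh(-1L, 0L); P3 <- sh(-1L, 1L); P4 <- sh(0L, 1L); P5 <- sh(1L, 1L)
  P6 <- sh(1L, 0L); P7 <- sh(1L, -1L); P8 <- sh(0L, -1L); P9 <- sh(-1L, -1L)
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) + (P4 == 0L & P5 == 1L) +
       (P5 == 0L & P6 == 1L) + (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
       (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
  if (step == 1L) {
    cond <- P2 * P4 * P6 == 0L & P4 * P6 * P8 == 0L
  } else {
    cond <- P2 * P4 * P8 == 0L & P2 * P6 * P8 == 0L
  }
  del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
  m[del] <- 0L
  m
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Topology-preserving 2-D thinning to curves of width 1 under
#' 8-connectivity.
#'
#' @param mask A logical/binary matrix.
#' @return A logical matrix.
#' @export
skeletonize <- function(mask) {
  m <- as_mask(mask) * 1L
  repeat {
    before <- sum(m)
    m <- zs_subiter(m, 1L)
    m <- zs_subiter(m, 2L)
    if (sum(m) == before) break
  }
  m == 1L
}

# --- skeleton graph machinery ------------------------------------------------

# Adjacency among skeleton pixels with diagonal-shortcut pruning: a diagonal
# link is dropped when either of its orthogonal "corner" pixels is also
# foreground (the path then runs through the corner pixel instead).
skeleton_edges <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m)
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_along(fg)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  at <- function(r, c) pad[cbind(r + 1L, c + 1L)]
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  e_from <- integer(0); e_to <- integer(0); e_w <- numeric(0)
  for (sh in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))) {
    dr <- sh[1L]; dc <- sh[2L]; w <- sh[3L]
    ok <- at(rr + dr, cc + dc)
    if (w > 1) {  # diagonal: prune when a corner pixel carries the path
      ok <- ok & !(at(rr + dr, cc) | at(rr, cc + dc))
    }
    keep <- which(ok)
    if (length(keep) > 0L) {
      e_from <- c(e_from, idx[cbind(rr[keep], cc[keep])])
      e_to <- c(e_to, idx[cbind(rr[keep] + dr, cc[keep] + dc)])
      e_w <- c(e_w, rep(w, length(keep)))
    }
  }
  list(fg = fg, row = rr, col = cc, from = e_from, to = e_to, w = e_w)
}

# Decompose one skeleton mask into branches.  Returns a list with per-pixel
# component labels and a tibble of branches (component, length_px, n_px).
trace_branches <- function(m, spur_min_px = 3) {
  ed <- skeleton_edges(m)
  n <- length(ed$fg)
  if (n == 0L) {
    return(list(components = integer(0),
                branches = tibble::tibble(component = integer(0),
                                          length_px = numeric(0),
                                          n_px = integer(0))))
  }
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (k in seq_along(ed$from)) {
    a <- ed$from[k]; b <- ed$to[k]; w <- ed$w[k]
    adj[[a]] <- c(adj[[a]], b); wts[[a]] <- c(wts[[a]], w)
    adj[[b]] <- c(adj[[b]], a); wts[[b]] <- c(wts[[b]], w)
  }
  deg <- lengths(adj)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ed$from) > 0L) g <- igraph::add_edges(g, rbind(ed$from, ed$to))
  comp <- igraph::components(g)$membership

  # junction clusters: adjacent junction pixels act as one node
  is_junction <- deg >= 3L
  jcluster <- rep(NA_integer_, n)
  if (any(is_junction)) {
    jidx <- which(is_junction)
    sub <- igraph::induced_subgraph(g, jidx)
    jcluster[jidx] <- igraph::components(sub)$membership
  }
  is_node <- deg != 2L   # endpoints, isolated pixels, junctions

  # walk slab chains between node pixels
  edge_key <- function(a, b) paste0(pmin(a, b), "-", pmax(a, b))
  visited <- new.env(hash = TRUE, parent = emptyenv())
  branches <- list()
  walk <- function(start, nb_i) {
    # follow the chain leaving `start` through its nb_i-th neighbour
    prev <- start
    cur <- adj[[start]][nb_i]
    len <- wts[[start]][nb_i]
    pixels <- c(start, cur)
    key <- edge_key(prev, cur)
    if (!is.null(visited[[key]])) return(NULL)
    assign(key, TRUE, envir = visited)
    while (!is_node[cur]) {
      nxt_i <- which(adj[[cur]] != prev)
      if (length(nxt_i) == 0L) break     # dead end (shouldn't happen for deg 2)
      nxt <- adj[[cur]][nxt_i[1L]]
      assign(edge_key(cur, nxt), TRUE, envir = visited)
      len <- len + wts[[cur]][nxt_i[1L]]
      prev <- cur; cur <- nxt
      pixels <- c(pixels, cur)
    }
    list(from = start, to = cur, length_px = len, pixels = pixels)
  }
  for (v in which(is_node)) {
    for (i in seq_along(adj[[v]])) {
      br <- walk(v, i)
      if (!is.null(br)) branches[[length(branches) + 1L]] <- br
    }
  }
  # pure cycles (every pixel degree 2): trace each once
  in_branch <- rep(FALSE, n)
  for (br in branches) in_branch[br$pixels] <- TRUE
  loop_start <- which(deg == 2L & !in_branch)
  while (length(loop_start) > 0L) {
    v <- loop_start[1L]
    br <- list(from = v, to = v, pixels = v, length_px = 0)
    prev <- v; cur <- adj[[v]][1L]
    br$length_px <- wts[[v]][1L]
    while (cur != v) {
      br$pixels <- c(br$pixels, cur)
      nxt_i <- which(adj[[cur]] != prev)[1L]
      br$length_px <- br$length_px + wts[[cur]][nxt_i]
      prev <- cur; cur <- adj[[cur]][nxt_i]
    }
    branches[[length(branches) + 1L]] <- br
    in_branch[br$pixels] <- TRUE
    loop_start <- which(deg == 2L & !in_branch)
  }

  node_of <- function(v) {
    if (is_junction[v]) paste0("J", jcluster[v]) else paste0("P", v)
  }
  keep <- vapply(branches, function(br) {
    # drop intra-cluster stubs and short junction-junction thinning artifacts
    a <- is_junction[br$from]; b <- is_junction[br$to]
    if (a && b && node_of(br$from) == node_of(br$to)) return(FALSE)
    if (a && b && br$length_px < spur_min_px) return(FALSE)
    # spur pruning: short endpoint twigs off a junction
    endpoint_side <- (!a && deg[br$from] <= 1L) || (!b && deg[br$to] <= 1L)
    junction_side <- a || b
    if (endpoint_side && junction_side && br$length_px < spur_min_px) return(FALSE)
    TRUE
  }, logical(1))
  branches <- branches[keep]
  list(components = comp,
       branches = tibble::tibble(
         component = vapply(branches, function(br) as.integer(comp[br$from]), integer(1)),
         length_px = vapply(branches, `[[`, numeric(1), "length_px"),
         n_px = vapply(branches, function(br) length(br$pixels), integer(1))),
       pixel_component = comp, fg = ed$fg, row = ed$row, col = ed$col)
}

#' Branch and length metrics of a skeletonized mask
#'
#' Skeleton pixels are classified by their pruned 8-neighbour count
#' (endpoint < 2, slab = 2, junction > 2); branches are maximal slab paths
#' between endpoint/junction pixels, with orthogonal steps counting
#' `pixel_size` and diagonal steps `sqrt(2) * pixel_size`.  Adjacent
#' junction pixels act as a single junction, and spurs shorter than
#' `spur_min_px` pixels emanating from junctions (thinning artifacts) are
#' pruned.
#'
#' @param skeleton A logical/binary matrix as produced by [skeletonize()].
#' @param pixel_size Pixel size, um/pixel.
#' @param spur_min_px Minimum branch length in pixel steps (default 3).
#' @return A list of class `skeleton_metrics` with `skeletons` (tibble: one
#'   row per connected skeleton: `skeleton_id`, `n_branches`,
#'   `total_length_um`, `centroid_row`, `centroid_col`, and the per-branch
#'   lengths in the list column `branch_lengths_um`) and `pixel_size`.
#' @export
analyze_skeleton <- function(skeleton, pixel_size, spur_min_px = 3) {
  check_positive_scalar(pixel_size, "pixel_size")
  m <- as_mask(skeleton)
  tb <- trace_branches(m, spur_min_px)
  if (length(tb$components) == 0L) {
    out <- list(skeletons = tibble::tibble(
      skeleton_id = integer(0), n_branches = integer(0),
      total_length_um = numeric(0), centroid_row = numeric(0),
      centroid_col = numeric(0), branch_lengths_um = list()),
      pixel_size = pixel_size)
    class(out) <- "skeleton_metrics"
    return(out)
  }
  comps <- sort(unique(tb$pixel_component))
  skeletons <- purrr::map_dfr(comps, function(cid) {
    br <- tb$branches[tb$branches$component == cid, , drop = FALSE]
    px <- tb$pixel_component == cid
    tibble::tibble(
      skeleton_id = cid,
      n_branches = nrow(br),
      total_length_um = sum(br$length_px) * pixel_size,
      centroid_row = mean(tb$row[px]),
      centroid_col = mean(tb$col[px]),
      branch_lengths_um = list(br$length_px * pixel_size))
  })
  out <- list(skeletons = skeletons, pixel_size = pixel_size)
  class(out) <- "skeleton_metrics"
  out
}

#' @export
print.skeleton_metrics <- function(x, ...) {
  cat(sprintf("skeleton_metrics: %d skeletons, %d branches, %.1f um total\n",
              nrow(x$skeletons), sum(x$skeletons$n_branches),
              sum(x$skeletons$total_length_um)))
  invisible(x)
}

#' Per-field process summary
#'
#' Skeleton components whose total length strictly exceeds
#' `min_process_length` count as processes; branch and length totals over
#' qualifying processes are normalized to the number of cells in the field.
#'
#' @param metrics An [analyze_skeleton()] result.
#' @param n_cells Number of cells in the field (>= 1).
#' @param min_process_length Minimum process length, um (default 8; strict
#'   inequality, a skeleton of exactly 8 um is excluded).
#' @return A one-row tibble: `n_cells`, `n_processes`, `processes_per_cell`,
#'   `branches_per_cell`, `length_per_cell_um`.
#' @export
process_summary <- function(metrics, n_cells, min_process_length = 8) {
  stopifnot(inherits(metrics, "skeleton_metrics"))
  if (!is.numeric(n_cells) || n_cells < 1) {
    abort("`n_cells` must be at least 1.", class = "mgca_contract_error")
  }
  qual <- dplyr::filter(metrics$skeletons,
                        .data$total_length_um > min_process_length)
  tibble::tibble(
    n_cells = n_cells,
    n_processes = nrow(qual),
    processes_per_cell = nrow(qual) / n_cells,
    branches_per_cell = sum(qual$n_branches) / n_cells,
    length_per_cell_um = sum(qual$total_length_um) / n_cells)
}

#' Pre/post field comparison
#'
#' Fold changes (post / pre) of branches per cell and process length per
#' cell, paired by imaging field.  A zero pre-stimulus metric flags the fold
#' change as undefined (`NA`) rather than infinite.
#'
#' @param pre_summary,post_summary One-row tibbles from [process_summary()]
#'   for the same field.
#' @return A one-row tibble: `fold_change_branches`, `fold_change_length`,
#'   plus the pre/post per-cell metrics.
#' @export
compare_fields <- function(pre_summary, post_summary) {
  fold <- function(post, pre) if (pre > 0) post / pre else NA_real_
  tibble::tibble(
    pre_branches_per_cell = pre_summary$branches_per_cell,
    post_branches_per_cell = post_summary$branches_per_cell,
    pre_length_per_cell_um = pre_summary$length_per_cell_um,
    post_length_per_cell_um = post_summary$length_per_cell_um,
    fold_change_branches = fold(post_summary$branches_per_cell,
                                pre_summary$branches_per_cell),
    fold_change_length = fold(post_summary$length_per_cell_um,
                              pre_summary$length_per_cell_um))
}

#' Full morphology pipeline for one field
#'
#' Binarize, despeckle, remove small components, skeletonize, analyze, and
#' summarize.
#'
#' @param image An [image_field()].
#' @param threshold Binarization threshold (shared across a paired set).
#' @param n_cells Number of cells in the field.
#' @param area_max Minimum retained component area, pixels.
#' @param min_process_length Process filter, um.
#' @param spur_min_px Spur-pruning length, pixel steps.
#' @return A list with `mask`, `skeleton`, `metrics`, `summary`.
#' @export
morphology_pipeline <- function(image, threshold, n_cells, area_max = 4L,
                                min_process_length = 8, spur_min_px = 3) {
  stopifnot(inherits(image, "image_field"))
  mask <- binarize(image, threshold) |>
    despeckle() |>
    remove_outliers(area_max = area_max)
  skel <- skeletonize(mask)
  metrics <- analyze_skeleton(skel, image$pixel_size, spur_min_px)
  list(mask = mask, skeleton = skel, metrics = metrics,
       summary = process_summary(metrics, n_cells, min_process_length))
}
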