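#' Per-frame nearest-neighbour distance of the focal fish
#'
#' Distance from the focal individual to its nearest detected neighbour in
#' one frame. Ties are broken toward the lowest individual index (the
#' reported distance is unaffected).
#'
#' @param positions `n_fish` x 2 matrix of positions (mm); lost detections
#'   are `NA` rows.
#' @param focal Row index of the focal individual.
#' @return Distance in mm, or `NA` when the focal fish or every neighbour
#'   is missing (the frame is excluded, not an error).
#' @export
frame_nearest_neighbour <- function(positions, focal) {
  positions <- as.matrix(positions)
  if (anyNA(positions[focal, ])) return(NA_real_)
  others <- setdiff(seq_len(nrow(positions)), focal)
  ok <- others[!is.na(positions[others, 1]) & !is.na(positions[others, 2])]
  if (!length(ok)) return(NA_real_)
  d <- sqrt((positions[ok, 1] - positions[focal, 1])^2 +
              (positions[ok, 2] - positions[focal, 2])^2)
  d[which.min(d)]
}

#' Per-frame group geometry
#'
#' Centroid (mean of all detected positions, focal included), group radius
#' (distance from the centroid to the individual farthest from it), convex
#' hull circumference and the focal fish's distance to the centroid.
#' A collinear point set has a degenerate hull whose circumference is twice
#' its path length; a single repeated point gives 0.
#'
#' @inheritParams frame_nearest_neighbour
#' @return Named list `centroid` (length-2), `radius`,
#'   `hull_circumference`, `focal_to_centroid` (NA when the focal fish is
#'   missing). All-`NA` when fewer than 2 individuals are detected.
#' @export
frame_group_stats <- function(positions, focal) {
  positions <- as.matrix(positions)
  ok <- which(!is.na(positions[, 1]) & !is.na(positions[, 2]))
  if (length(ok) < 2) {
    return(list(centroid = c(NA_real_, NA_real_), radius = NA_real_,
                hull_circumference = NA_real_,
                focal_to_centroid = NA_real_))
  }
  pts <- positions[ok, , drop = FALSE]
  cen <- colMeans(pts)
  radius <- max(sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2))
  hull <- grDevices::chull(pts)
  circumference <- polygon_perimeter(pts[hull, , drop = FALSE])
  f2c <- if (focal %in% ok) dist2(positions[focal, ], cen) else NA_real_
  list(centroid = cen, radius = radius, hull_circumference = circumference,
       focal_to_centroid = f2c)
}

#' Per-frame upstream and field-of-flow nearest neighbours
#'
#' A neighbour is upstream when its x coordinate is strictly less than the
#' focal fish's (the x axis points downstream); it is additionally in the
#' focal fish's field of flow sensing when its y coordinate lies within
#' `band_halfwidth` (inclusive) of the focal fish's. Hydrodynamic cues
#' cannot travel upstream, so only such neighbours are detectable by the
#' lateral line. When no neighbour qualifies the metric is excluded for the
#' frame (`NA`).
#'
#' @inheritParams frame_nearest_neighbour
#' @param band_halfwidth Cross-stream half-width of the field-of-flow band
#'   (mm; default 50).
#' @return Named numeric `c(upstream_nn, fof_nn)` with `NA` for excluded
#'   metrics.
#' @export
frame_directional_nn <- function(positions, focal, band_halfwidth = 50) {
  positions <- as.matrix(positions)
  if (anyNA(positions[focal, ])) {
    return(c(upstream_nn = NA_real_, fof_nn = NA_real_))
  }
  others <- setdiff(seq_len(nrow(positions)), focal)
  ok <- others[!is.na(positions[others, 1]) & !is.na(positions[others, 2])]
  up <- ok[positions[ok, 1] < positions[focal, 1]]
  dist_to <- function(idx) {
    sqrt((positions[idx, 1] - positions[focal, 1])^2 +
           (positions[idx, 2] - positions[focal, 2])^2)
  }
  upstream_nn <- if (length(up)) min(dist_to(up)) else NA_real_
  fof <- up[abs(positions[up, 2] - positions[focal, 2]) <= band_halfwidth]
  fof_nn <- if (length(fof)) min(dist_to(fof)) else NA_real_
  c(upstream_nn = upstream_nn, fof_nn = fof_nn)
}

#' Summarize a trial's collective-behaviour metrics
#'
#' Computes, per frame, the focal nearest-neighbour distance, group radius,
#' hull circumference, focal-to-centroid distance and the upstream /
#' field-of-flow nearest-neighbour distances, then averages each metric
#' over the frames where it is defined (a simple unweighted mean). Frames
#' where a metric is excluded (missing focal fish, fewer than two
#' detections, or no qualifying neighbour) reduce that metric's
#' `frames_used` count; a metric with zero valid frames is `NA`.
#'
#' @param frames A [frame_set()].
#' @param band_halfwidth Field-of-flow band half-width in mm.
#' @return One-row tibble: `mean_nn`, `mean_group_radius`,
#'   `mean_upstream_nn`, `mean_fof_nn`, `mean_hull_circumference`,
#'   `mean_focal_to_centroid`, and `frames_used_*` counts per metric.
#' @export
summarize_trial <- function(frames, band_halfwidth = 50) {
  stopifnot(inherits(frames, "frame_set"))
  per_frame <- frame_metrics(frames, band_halfwidth)
  mean_or_na <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
  tibble::tibble(
    mean_nn = mean_or_na(per_frame$nn),
    mean_group_radius = mean_or_na(per_frame$radius),
    mean_upstream_nn = mean_or_na(per_frame$upstream_nn),
    mean_fof_nn = mean_or_na(per_frame$fof_nn),
    mean_hull_circumference = mean_or_na(per_frame$hull_circumference),
    mean_focal_to_centroid = mean_or_na(per_frame$focal_to_centroid),
    frames_used_nn = sum(!is.na(per_frame$nn)),
    frames_used_group_radius = sum(!is.na(per_frame$radius)),
    frames_used_upstream_nn = sum(!is.na(per_frame$upstream_nn)),
    frames_used_fof_nn = sum(!is.na(per_frame$fof_nn)),
    frames_used_hull_circumference = sum(!is.na(per_frame$hull_circumference)),
    frames_used_focal_to_centroid = sum(!is.na(per_frame$focal_to_centroid))
  )
}

#' Per-frame metric table
#'
#' The frame-by-frame metrics behind [summarize_trial()], useful for
#' plotting and for auditing exclusions.
#'
#' @inheritParams summarize_trial
#' @return Tibble with one row per frame: `frame`, `nn`, `radius`,
#'   `hull_circumference`, `focal_to_centroid`, `upstream_nn`, `fof_nn`.
#' @export
frame_metrics <- function(frames, band_halfwidth = 50) {
  stopifnot(inherits(frames, "frame_set"))
  pos <- frames$positions
  ids <- sort(unique(pos$individual))
  focal <- match(frames$focal_id, ids)
  frame_ids <- unique(pos$frame)
  n_fish <- length(ids)
  # positions arrive sorted by (frame, individual); reshape once
  xs <- matrix(pos$x, nrow = n_fish)
  ys <- matrix(pos$y, nrow = n_fish)
  rows <- purrr::map(seq_along(frame_ids), function(f) {
    p <- cbind(xs[, f], ys[, f])
    gs <- frame_group_stats(p, focal)
    dnn <- frame_directional_nn(p, focal, band_halfwidth)
    tibble::tibble(
      frame = frame_ids[f],
      nn = frame_nearest_neighbour(p, focal),
      radius = gs$radius,
      hull_circumference = gs$hull_circumference,
      focal_to_centroid = gs$focal_to_centroid,
      upstream_nn = dnn[["upstream_nn"]],
      fof_nn = dnn[["fof_nn"]]
    )
  })
  dplyr::bind_rows(rows)
}
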