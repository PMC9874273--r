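#' Per-trial tracked positions (frame set)
#'
#' A `frame_set` holds the per-frame 2-D positions of all individuals of one
#' trial, together with the recording and arena conventions used throughout
#' the package: the origin sits at the most upstream, furthest-left point of
#' the arena, the x axis points downstream and the y axis cross-stream, and
#' all lengths are millimetres. Lost detections are kept as explicit `NA`
#' coordinates so that downstream metrics can exclude the affected frames.
#'
#' @param positions Data frame with columns `frame`, `individual`, `x`, `y`
#'   (mm). Every `(frame, individual)` pair appears exactly once; missing
#'   detections have `NA` coordinates.
#' @param fps Frames per second (Hz), positive.
#' @param arena Length-2 numeric, arena size `(length_x, width_y)` in mm.
#' @param focal_id Index (in `individual`) of the focal fish.
#'
#' @return An object of class `frame_set`: a list with elements `positions`
#'   (tibble), `fps`, `arena`, `focal_id` and `n_individuals`.
#' @seealso [read_trajectory_table()], [summarize_trial()]
#' @export
frame_set <- function(positions, fps, arena = c(1210, 557.8), focal_id = 1L) {
  positions <- tibble::as_tibble(positions)
  req <- c("frame", "individual", "x", "y")
  if (!all(req %in% names(positions))) {
    abort("`positions` needs columns frame, individual, x, y.")
  }
  check_number(fps, "fps", lower = 0, strict = TRUE)
  if (length(arena) != 2L || any(!is.finite(arena)) || any(arena <= 0)) {
    abort("`arena` must be two positive lengths (mm).")
  }
  ids <- sort(unique(positions$individual))
  if (!focal_id %in% ids) abort("`focal_id` is not among the individuals.")
  if (anyDuplicated(positions[c("frame", "individual")])) {
    abort("duplicate (frame, individual) rows in `positions`.")
  }
  # complete the frame x individual grid, keeping lost detections explicit
  positions <- tidyr::complete(
    positions,
    frame = tidyr::full_seq(.data$frame, 1),
    individual = ids
  )
  positions <- dplyr::arrange(positions, .data$frame, .data$individual)
  out_of_arena <- !is.na(positions$x) &
    (positions$x < 0 | positions$x > arena[1] |
       positions$y < 0 | positions$y > arena[2])
  if (any(out_of_arena)) {
    warn(sprintf(
      "%d detections fall outside the arena; kept but flagged.",
      sum(out_of_arena)
    ))
  }
  structure(
    list(
      positions = positions, fps = fps, arena = as.numeric(arena),
      focal_id = focal_id, n_individuals = length(ids)
    ),
    class = "frame_set"
  )
}

#' @export
print.frame_set <- function(x, ...) {
  nf <- length(unique(x$positions$frame))
  miss <- sum(is.na(x$positions$x) | is.na(x$positions$y))
  cat(sprintf(
    "<frame_set> %d frames x %d individuals @ %g fps (focal %s), %d missing detections\n",
    nf, x$n_individuals, x$fps, format(x$focal_id), miss
  ))
  cat(sprintf(
    "  arena %g x %g mm, origin upstream-left, +x downstream\n",
    x$arena[1], x$arena[2]
  ))
  invisible(x)
}

#' Read a long-format trajectory table
#'
#' Reads an idTracker-style coordinate export into a [frame_set()]. The
#' native dialect is a long CSV with columns `frame`, `individual`, `x`, `y`
#' (mm); rows with empty coordinates mark lost detections, and absent
#' `(frame, individual)` combinations are completed as missing. A wide
#' matrix export (`x1, y1, x2, y2, ...` per frame) is accepted via
#' `wide = TRUE`.
#'
#' @param path CSV file path.
#' @param fps,arena,focal_id Passed to [frame_set()].
#' @param wide Is the file a wide per-frame matrix export?
#'
#' @return A [frame_set()].
#' @export
read_trajectory_table <- function(path, fps = 25, arena = c(1210, 557.8),
                                  focal_id = 1L, wide = FALSE) {
  # base read.csv: strtod parsing is correctly rounded, so the writer's
  # shortest-representation output round-trips bit-exactly
  tab <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (wide) {
    xcols <- grep("^x[0-9]+$", names(tab), value = TRUE)
    if (!"frame" %in% names(tab)) tab$frame <- seq_len(nrow(tab))
    tab <- tidyr::pivot_longer(
      tab, cols = -"frame",
      names_to = c(".value", "individual"),
      names_pattern = "([xy])([0-9]+)"
    )
    tab$individual <- as.integer(tab$individual)
    stopifnot(length(xcols) > 0)
  }
  req <- c("frame", "individual", "x", "y")
  if (!all(req %in% names(tab))) {
    abort("trajectory table needs columns frame, individual, x, y.")
  }
  for (cc in c("frame", "x", "y")) {
    if (!is.numeric(tab[[cc]])) {
      abort(sprintf("column `%s` is not numeric.", cc))
    }
  }
  if (anyDuplicated(tab[c("frame", "individual")])) {
    abort("duplicate (frame, individual) rows.")
  }
  frame_set(tab[req], fps = fps, arena = arena, focal_id = focal_id)
}

#' Write a frame set back to the long CSV dialect
#'
#' Missing detections are written as empty fields. Finite coordinates
#' round-trip bit-exactly through [read_trajectory_table()].
#'
#' @param frames A [frame_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(frames, path) {
  stopifnot(inherits(frames, "frame_set"))
  readr::write_csv(frames$positions, path, na = "")
  invisible(path)
}
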