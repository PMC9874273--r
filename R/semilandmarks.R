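#' Resample a pore outline to 10 equidistant semilandmarks
#'
#' Places `n` semilandmarks at equal arc-length spacing along the
#' piecewise-linear closed outline, starting at the anchor (the curve's
#' first point). The last semilandmark closes the loop and coincides with
#' the first, so the `n` points delimit `n - 1` equal arc-length gaps of
#' `perimeter / (n - 1)` each.
#'
#' @param curve A [pore_curve()] with at least 10 points.
#' @param n Number of semilandmarks including the closing duplicate
#'   (default 10).
#' @return Object of class `semilandmark_set`: list with `points`
#'   (`n` x 2 matrix), `curve_perimeter`, and the provenance fields of
#'   `curve`.
#' @export
resample_semilandmarks <- function(curve, n = 10) {
  stopifnot(inherits(curve, "pore_curve"))
  if (nrow(curve$points) < 10) abort("outline has fewer than 10 points.")
  pts <- rbind(curve$points, curve$points[1, ]) # close the polyline
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  perim <- sum(seg)
  if (perim <= 0) abort("zero-length outline.")
  s <- c(0, cumsum(seg))
  targets <- seq(0, perim, length.out = n)
  ix <- findInterval(targets, s, rightmost.closed = TRUE)
  t_frac <- (targets - s[ix]) / ifelse(seg[ix] > 0, seg[ix], 1)
  out <- pts[ix, , drop = FALSE] +
    t_frac * (pts[ix + 1L, , drop = FALSE] - pts[ix, , drop = FALSE])
  out[n, ] <- out[1, ] # exact closure
  structure(
    list(points = unname(out), curve_perimeter = perim,
         specimen = curve$specimen, canal = curve$canal, pore = curve$pore),
    class = "semilandmark_set"
  )
}

#' @export
print.semilandmark_set <- function(x, ...) {
  cat(sprintf("<semilandmark_set> %d points (closing point duplicated), perimeter %.4g mm\n",
              nrow(x$points), x$curve_perimeter))
  invisible(x)
}

# Does the closed polygon (matrix of vertices, no closing duplicate)
# self-intersect? Checks non-adjacent edge pairs.
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (seg_int(xy[i, ], xy[i %% n + 1L, ], xy[j, ], xy[j %% n + 1L, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Polygonal pore area from semilandmarks
#'
#' Shoelace area of the polygon through the distinct semilandmarks: the
#' closing duplicate (10th point) is discounted and the remaining 9
#' vertices form the polygon. Being inscribed in the outline, the polygon
#' slightly underestimates the true pore area; the bias is consistent
#' across specimens. A self-intersecting polygon triggers a warning and
#' the magnitude of the signed area is returned.
#'
#' @param slm A [semilandmark_set()] (or an n x 2 matrix whose last row
#'   repeats the first).
#' @return Area in mm^2 (>= 0; 0 for collinear points).
#' @export
pore_area <- function(slm) {
  pts <- if (inherits(slm, "semilandmark_set")) slm$points else as.matrix(slm)
  poly <- pts[-nrow(pts), , drop = FALSE] # drop closing duplicate
  if (polygon_self_intersects(poly)) {
    warn("semilandmark polygon self-intersects; |signed area| returned.")
  }
  abs(shoelace_area(poly))
}

#' Mean pore area per cranial canal
#'
#' Averages per-pore polygon areas into the four canal-level variables used
#' as model predictors: dentary (mandibular pores 2-5), preopercular
#' (pores 1-4 from the ventral view pooled with 5-7 from the lateral view),
#' otic (2 pores) and infraorbital (digitized pore count varies between
#' datasets, so no fixed inventory is enforced). Missing pores reduce the
#' denominator and set the `complete` flag to `FALSE`.
#'
#' @param records Tibble with columns `specimen`, `canal`, `pore`, `area`.
#' @param expected_pores Named expected pore counts per canal (`NA` = no
#'   expectation).
#' @return Tibble: `specimen`, `canal`, `mean_area`, `n_pores`, `complete`.
#' @export
mean_canal_areas <- function(records,
                             expected_pores = c(dentary = 4,
                                                preopercular = 7,
                                                otic = 2,
                                                infraorbital = NA)) {
  stopifnot(all(c("specimen", "canal", "area") %in% names(records)))
  records |>
    dplyr::filter(!is.na(.data$area)) |>
    dplyr::group_by(.data$specimen, .data$canal) |>
    dplyr::summarise(
      mean_area = mean(.data$area),
      n_pores = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      complete = is.na(expected_pores[.data$canal]) |
        .data$n_pores == expected_pores[.data$canal]
    )
}
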