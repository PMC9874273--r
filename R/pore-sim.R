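#' Generate a synthetic closed pore outline of known area
#'
#' Draws a smooth, star-shaped (hence simple) closed curve of prescribed
#' enclosed area, as a stand-in for a digitized canal-pore circumference.
#' The radius about the shape centre is a truncated Fourier series
#' \eqn{r(\phi) = r_0 (1 + \sum_k a_k \cos(k\phi + \psi_k))}, with harmonic
#' amplitudes scaled by `irregularity`; \eqn{r_0} is chosen so the area of
#' the continuous shape, \eqn{\tfrac12 \int r^2 d\phi} (evaluated on a
#' 20000-point grid), equals `true_area` exactly. Vertices are placed at
#' `n_points` equal angles, and the point order is rotated so the curve
#' starts at its most anterior vertex (minimum x — the homologous anchor).
#' With `irregularity = 0` and `true_area = pi` the vertices lie on the
#' unit circle. The polygon through the vertices is an inscribed
#' approximation; at the default `n_points` its area is within 0.5% of
#' `true_area`.
#'
#' @param true_area Enclosed area (mm^2), positive.
#' @param n_points Number of outline vertices (>= 10; default 100).
#' @param irregularity Relative amplitude of the radial harmonics
#'   (0 = circle). Draws whose radius would collapse or self-intersect are
#'   rejected and redrawn; an error is raised after 100 attempts.
#' @param n_harmonics Highest harmonic used (default 6).
#' @param seed Integer seed.
#' @inheritParams pore_curve
#' @return A [pore_curve()].
#' @export
generate_pore_curve <- function(true_area, n_points = 100,
                                irregularity = 0.05, n_harmonics = 6,
                                seed = NULL, specimen = NA_character_,
                                canal = NA_character_, pore = NA_integer_) {
  check_number(true_area, "true_area", 0, strict = TRUE)
  if (n_points < 10) abort("`n_points` must be at least 10.")
  check_number(irregularity, "irregularity", 0)
  with_seed(seed, {
    for (attempt in 1:100) {
      ks <- seq(2, n_harmonics)
      amp <- rnorm(length(ks), 0, irregularity / ks)
      phase <- runif(length(ks), 0, 2 * pi)
      g <- function(phi) {
        1 + Reduce(`+`, purrr::map(seq_along(ks), function(i) {
          amp[i] * cos(ks[i] * phi + phase[i])
        }), accumulate = FALSE)
      }
      phi_fine <- seq(0, 2 * pi, length.out = 20001L)[-20001L]
      gf <- g(phi_fine)
      if (min(gf) > 0.2) break
      if (attempt == 100) abort("irregularity too large: radius collapses.")
    }
    # continuous enclosed area = r0^2/2 * integral of g^2
    int_g2 <- mean(gf^2) * 2 * pi
    r0 <- sqrt(2 * true_area / int_g2)
    phi <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
    r <- r0 * g(phi)
    xy <- cbind(r * cos(phi), r * sin(phi))
    anchor <- which.min(xy[, 1])
    idx <- c(seq(anchor, n_points), seq_len(anchor - 1L))
    pore_curve(xy[idx, , drop = FALSE], specimen = specimen, canal = canal,
               pore = pore)
  })
}
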