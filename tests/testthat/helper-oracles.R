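# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# exhaustive nearest neighbour of `focal` over all pairwise distances
oracle_nn <- function(pos, focal) {
  best <- Inf
  for (j in seq_len(nrow(pos))) {
    if (j == focal) next
    if (anyNA(pos[j, ]) || anyNA(pos[focal, ])) next
    d <- sqrt(sum((pos[j, ] - pos[focal, ])^2))
    if (d < best) best <- d
  }
  if (is.finite(best)) best else NA_real_
}

oracle_radius <- function(pos) {
  ok <- pos[stats::complete.cases(pos), , drop = FALSE]
  if (nrow(ok) < 2) return(NA_real_)
  cen <- colMeans(ok)
  best <- 0
  for (j in seq_len(nrow(ok))) {
    d <- sqrt(sum((ok[j, ] - cen)^2))
    if (d > best) best <- d
  }
  best
}

# hull perimeter by enumerating candidate vertex orders (n <= 5): the hull
# perimeter is the shortest closed tour that contains all points inside;
# for <= 5 points enumerate all cyclic orders of all subsets and keep the
# shortest tour whose polygon contains every point.
oracle_hull_perimeter <- function(pos) {
  ok <- pos[stats::complete.cases(pos), , drop = FALSE]
  n <- nrow(ok)
  if (n < 2) return(NA_real_)
  if (n == 2) return(2 * sqrt(sum((ok[1, ] - ok[2, ])^2)))
  in_hull <- function(pt, poly) {
    # point-in-convex-polygon via consistent cross-product signs
    m <- nrow(poly)
    sgn <- 0
    for (i in seq_len(m)) {
      a <- poly[i, ]; b <- poly[i %% m + 1, ]
      cr <- (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
      if (abs(cr) < 1e-9) next
      s <- sign(cr)
      if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
    }
    TRUE
  }
  tour_len <- function(poly) {
    m <- nrow(poly)
    sum(sqrt(rowSums((poly[c(2:m, 1), , drop = FALSE] - poly)^2)))
  }
  is_convex_order <- function(poly) {
    m <- nrow(poly)
    sgn <- 0
    for (i in seq_len(m)) {
      a <- poly[i, ]; b <- poly[i %% m + 1, ]; cc <- poly[(i + 1) %% m + 1, ]
      cr <- (b[1] - a[1]) * (cc[2] - b[2]) - (b[2] - a[2]) * (cc[1] - b[1])
      if (abs(cr) < 1e-12) next
      s <- sign(cr)
      if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
    }
    TRUE
  }
  best <- Inf
  idx <- seq_len(n)
  for (k in 2:n) {
    subsets <- utils::combn(idx, k, simplify = FALSE)
    for (sub in subsets) {
      perms <- perms_of(sub)
      for (pp in perms) {
        poly <- ok[pp, , drop = FALSE]
        if (!is_convex_order(poly)) next
        if (!all(vapply(idx, function(j) in_hull(ok[j, ], poly), TRUE))) next
        len <- if (k == 2) 2 * sqrt(sum((poly[1, ] - poly[2, ])^2)) else tour_len(poly)
        if (len < best) best <- len
      }
    }
  }
  best
}

perms_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_directional <- function(pos, focal, band = 50) {
  if (anyNA(pos[focal, ])) return(c(NA_real_, NA_real_))
  up <- fof <- Inf
  for (j in seq_len(nrow(pos))) {
    if (j == focal || anyNA(pos[j, ])) next
    if (pos[j, 1] < pos[focal, 1]) {
      d <- sqrt(sum((pos[j, ] - pos[focal, ])^2))
      up <- min(up, d)
      if (abs(pos[j, 2] - pos[focal, 2]) <= band) fof <- min(fof, d)
    }
  }
  c(ifelse(is.finite(up), up, NA_real_), ifelse(is.finite(fof), fof, NA_real_))
}

# high-resolution shoelace area of a star-shaped curve given as vertices:
# refine by dense linear interpolation along the polygon edges (polygon
# area is invariant to adding collinear points, so this checks consistency)
shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# brute-force trapezoid marginal log-likelihood for the NB random-intercept
# model, integrating each group's likelihood over [-8 sigma, 8 sigma]
oracle_marginal_loglik <- function(beta, theta, sigma_b, y, X, group,
                                   n_grid = 1e4) {
  eta0 <- drop(X %*% beta)
  total <- 0
  for (g in unique(group)) {
    i <- which(group == g)
    b <- seq(-8 * sigma_b, 8 * sigma_b, length.out = n_grid)
    lh <- matrix(dnbinom(rep(y[i], each = n_grid),
                         mu = exp(outer(b, eta0[i], `+`)),
                         size = theta, log = TRUE), nrow = n_grid)
    h <- rowSums(lh) + dnorm(b, 0, sigma_b, log = TRUE)
    m <- max(h)
    total <- total + m + log(pracma::trapz(b, exp(h - m)))
  }
  total
}

# small simulated study: design + morphology + one response
sim_study <- function(seed, effects = effect_spec(), n = c(10, 10, 96)) {
  d <- generate_design(n[1], n[2], n[3], seed = seed)
  m <- generate_morphology(d, seed = seed + 1000L)
  generate_behaviour_summaries(d, m, effects, seed = seed + 2000L)
}
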