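#' Generalized Procrustes alignment and shape PCA
#'
#' Aligns landmark configurations by translating each to its centroid,
#' scaling to unit centroid size, and iteratively rotating (SVD-based
#' orthogonal Procrustes) to the current mean shape until the mean shape
#' changes by less than `tol` between iterations (partial Procrustes — no
#' reflection). A principal component analysis of the aligned coordinates
#' (covariance of the flattened configurations) gives shape scores and
#' per-component variance fractions.
#'
#' @param shapes List of `k` x 2 landmark matrices with a common `k`.
#' @param tol Convergence tolerance on the mean shape (default 1e-8).
#' @param max_iter Iteration cap.
#' @return A list of class `gpa_fit`: `aligned` (list of aligned
#'   matrices), `mean_shape`, `scores` (n x p PC score matrix),
#'   `variance_explained` (fractions summing to 1 when any variance
#'   remains), `sdev`, `iterations`.
#' @export
gpa_pca <- function(shapes, tol = 1e-8, max_iter = 200) {
  if (length(shapes) < 2) abort("need at least two configurations.")
  k <- nrow(shapes[[1]])
  if (!all(vapply(shapes, nrow, 0L) == k)) {
    abort("landmark counts differ across configurations.")
  }
  norm_shape <- function(m) {
    m <- sweep(as.matrix(m), 2, colMeans(m))
    cs <- sqrt(sum(m^2))
    if (cs <= .Machine$double.eps) abort("degenerate configuration: zero centroid size.")
    m / cs
  }
  rotate_to <- function(m, ref) {
    sv <- svd(crossprod(m, ref))
    # constrain to a proper rotation (no reflection)
    d <- sign(det(sv$v %*% t(sv$u)))
    rot <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
    m %*% rot
  }
  aligned <- lapply(shapes, norm_shape)
  mean_shape <- aligned[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(aligned, rotate_to, ref = mean_shape)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  # canonical orientation: principal axes of the mean shape (proper
  # rotation only), so the output does not depend on input order
  sv2 <- svd(crossprod(mean_shape))
  R <- sv2$u
  if (det(R) < 0) R[, 2] <- -R[, 2]
  m_rot <- mean_shape %*% R
  if (m_rot[which.max(abs(m_rot[, 1])), 1] < 0) R <- -R
  mean_shape <- mean_shape %*% R
  aligned <- lapply(aligned, function(m) m %*% R)
  flat <- t(vapply(aligned, as.vector, numeric(2 * k)))
  centred <- sweep(flat, 2, colMeans(flat))
  pc <- prcomp(centred, center = FALSE)
  tot <- sum(pc$sdev^2)
  structure(
    list(
      aligned = aligned, mean_shape = mean_shape,
      scores = unname(pc$x),
      variance_explained = if (tot > 0) pc$sdev^2 / tot else pc$sdev^2 * 0,
      sdev = pc$sdev, iterations = it
    ),
    class = "gpa_fit"
  )
}

#' Procrustes distance between two configurations
#'
#' Root-sum-of-squares distance after translation, unit-size scaling and
#' optimal rotation of `b` onto `a`.
#'
#' @param a,b `k` x 2 landmark matrices.
#' @return Non-negative distance; 0 (within tolerance) for shapes differing
#'   only by similarity transform.
#' @export
procrustes_distance <- function(a, b) {
  norm_shape <- function(m) {
    m <- sweep(as.matrix(m), 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- norm_shape(a)
  b <- norm_shape(b)
  sv <- svd(crossprod(b, a))
  d <- sign(det(sv$v %*% t(sv$u)))
  b <- b %*% (sv$u %*% diag(c(1, d)) %*% t(sv$v))
  sqrt(sum((a - b)^2))
}

#' Digitization-error ANOVA for repeated landmarking
#'
#' Fixed-effects two-way analysis of variance, without interaction, of a
#' mean pore area measured in two landmarking events (original and repeat)
#' on each of `n` individuals: `area ~ event + individual`. With a complete
#' 2 x n design the event effect is tested on (1, n-1) degrees of freedom
#' and the individual effect on (n-1, n-1).
#'
#' @param areas Tibble with columns `individual`, `event`, `area`; exactly
#'   one area per individual x event cell, two events.
#' @return Tibble with one row per term: `term`, `df`, `df_residual`,
#'   `statistic` (F), `p.value`.
#' @export
digitization_anova <- function(areas) {
  stopifnot(all(c("individual", "event", "area") %in% names(areas)))
  areas$individual <- factor(areas$individual)
  areas$event <- factor(areas$event)
  if (nlevels(areas$event) != 2) abort("exactly two landmarking events required.")
  counts <- table(areas$individual, areas$event)
  if (any(counts != 1)) abort("design incomplete: need one area per individual x event cell.")
  fit <- aov(area ~ event + individual, data = areas)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  df_res <- tab["Residuals", "Df"]
  ss <- tab[c("event", "individual"), "Sum Sq"]
  fstat <- tab[c("event", "individual"), "F value"]
  pval <- tab[c("event", "individual"), "Pr(>F)"]
  # a term with (numerically) zero sum of squares has no effect: F = 0,
  # even when a perfectly fitting model leaves a zero residual MS
  zero <- ss <= 1e-12 * sum(tab[, "Sum Sq"])
  fstat[zero] <- 0
  pval[zero] <- 1
  tibble::tibble(
    term = c("event", "individual"),
    df = tab[c("event", "individual"), "Df"],
    df_residual = df_res,
    statistic = fstat,
    p.value = pval
  )
}
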