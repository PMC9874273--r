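# Internal helpers shared across modules.

# Euclidean distance between two points given as length-2 vectors.
dist2 <- function(p, q) sqrt(sum((p - q)^2))

# Shoelace (signed) area of a polygon given as an n x 2 matrix of vertices.
# Vertices are taken in order; the polygon is closed implicitly.
shoelace_area <- function(xy) {
  x <- xy[, 1]
  y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Perimeter of a closed polygon (n x 2 matrix), closing edge included.
polygon_perimeter <- function(xy) {
  if (nrow(xy) < 2) return(0)
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2))
}

# Check a numeric scalar argument.
check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort(sprintf(
      "`%s` must be %s %s.", name, if (strict) ">" else ">=", format(lower)
    ))
  }
  invisible(x)
}

species_levels <- function() c("parentA", "parentB", "hybrid")

# The ten focal morphology variables used throughout model selection:
# six neuromast counts and four mean canal pore areas.
morphology_variables <- function() {
  c(
    "anterior_superficial", "posterior_superficial", "posterior_canal",
    "lower_posterior_superficial", "lower_posterior_canal", "tail_neuromasts",
    "otic_area", "preopercular_area", "dentary_area", "infraorbital_area"
  )
}

behaviour_responses <- function() {
  c("mean_nn", "mean_group_radius", "mean_upstream_nn", "mean_fof_nn")
}
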