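#' Parameters of the synthetic morphology generator
#'
#' Species centroids and noise levels for the ten focal lateral-line
#' variables: six neuromast counts (negative-binomial integers) and four
#' mean canal pore areas (mm\eqn{^2}, lognormal). The wide-canal parent
#' (`parentA`) centres on larger pore areas and fewer superficial
#' neuromasts, the narrow-canal parent (`parentB`) on the opposite;
#' hybrids centre on the parental midpoint (arithmetic for counts,
#' geometric for areas) with variance inflated to span both parents.
#' Both counts and areas scale positively with body length through
#' power-law allometry about `ref_length`.
#'
#' @param sdlog_area Lognormal log-SD of pore areas for the parents
#'   (\eqn{\ge 0}).
#' @param count_dispersion Negative-binomial size parameter for parental
#'   neuromast counts (> 0; larger = closer to Poisson).
#' @param hybrid_inflation Hybrid variance inflation relative to the
#'   mid-parent variance (default 2).
#' @param allometry_count,allometry_area Allometric exponents on
#'   `body_length / ref_length` for counts and areas.
#' @param ref_length Reference body length (mm).
#' @param centroids Tibble with columns `variable`, `parentA`, `parentB`
#'   overriding the built-in species centroids.
#' @return A list of class `morphology_params`.
#' @export
morphology_params <- function(sdlog_area = 0.25, count_dispersion = 60,
                              hybrid_inflation = 2, allometry_count = 0.5,
                              allometry_area = 2, ref_length = 117,
                              centroids = NULL) {
  if (sdlog_area < 0) abort("`sdlog_area` must be non-negative.")
  check_number(count_dispersion, "count_dispersion", 0, strict = TRUE)
  check_number(hybrid_inflation, "hybrid_inflation", 0, strict = TRUE)
  if (is.null(centroids)) {
    centroids <- tibble::tribble(
      ~variable,                     ~parentA, ~parentB,
      "anterior_superficial",              60,      120,
      "posterior_superficial",             40,       80,
      "posterior_canal",                   25,       25,
      "lower_posterior_superficial",       20,       40,
      "lower_posterior_canal",             15,       15,
      "tail_neuromasts",                   30,       50,
      "otic_area",                        2.0,      0.5,
      "preopercular_area",                1.5,      0.4,
      "dentary_area",                     1.2,     0.35,
      "infraorbital_area",                1.0,      0.3
    )
  }
  stopifnot(setequal(centroids$variable, morphology_variables()))
  structure(
    list(sdlog_area = sdlog_area, count_dispersion = count_dispersion,
         hybrid_inflation = hybrid_inflation,
         allometry_count = allometry_count, allometry_area = allometry_area,
         ref_length = ref_length, centroids = centroids),
    class = "morphology_params"
  )
}

#' Generate synthetic lateral-line morphology records
#'
#' Draws one morphology record per focal fish in `design` (see
#' [morphology_params()] for the generative model). Head size is emitted as
#' a fixed fraction (0.3) of body length plus noise; in real data it is
#' measured on images.
#'
#' @param design Output of [generate_design()] (or any table with one
#'   `fish_id`/`species`/`body_length` triple per fish).
#' @param params A [morphology_params()] object.
#' @param seed Integer seed.
#' @return Tibble with one row per fish: `fish_id`, `species`,
#'   `body_length`, `head_size`, the six neuromast counts and the four mean
#'   pore areas (mm^2).
#' @export
generate_morphology <- function(design, params = morphology_params(),
                                seed = NULL) {
  stopifnot(inherits(params, "morphology_params"))
  fish <- dplyr::distinct(design, .data$fish_id, .data$species,
                          .data$body_length)
  if (anyDuplicated(fish$fish_id)) {
    abort("`design` carries inconsistent fish-level data.")
  }
  count_vars <- morphology_variables()[1:6]
  area_vars <- morphology_variables()[7:10]
  cen <- params$centroids
  with_seed(seed, {
    rel <- fish$body_length / params$ref_length
    draw_one <- function(variable) {
      cA <- cen$parentA[match(variable, cen$variable)]
      cB <- cen$parentB[match(variable, cen$variable)]
      if (variable %in% count_vars) {
        mid <- (cA + cB) / 2
        mu <- dplyr::case_match(as.character(fish$species),
                                "parentA" ~ cA, "parentB" ~ cB,
                                "hybrid" ~ mid) * rel^params$allometry_count
        # hybrid NB size scaled down so count variance inflates ~2x mid-parent
        size <- ifelse(fish$species == "hybrid",
                       params$count_dispersion / params$hybrid_inflation,
                       params$count_dispersion)
        rnbinom(nrow(fish), mu = mu, size = size)
      } else {
        midlog <- (log(cA) + log(cB)) / 2
        mulog <- dplyr::case_match(as.character(fish$species),
                                   "parentA" ~ log(cA), "parentB" ~ log(cB),
                                   "hybrid" ~ midlog) +
          params$allometry_area * log(rel)
        sdlog <- ifelse(fish$species == "hybrid",
                        params$sdlog_area * sqrt(params$hybrid_inflation),
                        params$sdlog_area)
        rlnorm(nrow(fish), meanlog = mulog, sdlog = sdlog)
      }
    }
    draws <- purrr::map(setNames(morphology_variables(),
                                 morphology_variables()), draw_one)
    dplyr::bind_cols(
      fish,
      tibble::tibble(head_size = 0.3 * fish$body_length *
                       exp(rnorm(nrow(fish), 0, 0.03))),
      tibble::as_tibble(draws)
    )
  })
}
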