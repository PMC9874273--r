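#' Ground-truth effect specification for simulated behaviour responses
#'
#' Describes the generative model behind [generate_behaviour_summaries()]:
#' a log-link linear predictor over the study covariates with a per-fish
#' Gaussian random intercept and negative-binomial (NB2) observation noise,
#' the generative mirror of the model fitted by [nb_glmm()]. The study
#' reports no effect sizes, so every default here is a free parameter of
#' the generator, chosen to give distances on the scale observed in shoals
#' of ~110-120 mm fish.
#'
#' @param intercept Intercept \eqn{\beta_0} on the log scale (response in
#'   mm; default `log(120)`).
#' @param slopes Named vector of slopes per unit of each morphology
#'   variable (log scale). Unnamed variables have slope 0.
#' @param species_offsets Named log-scale offsets for `parentB` and
#'   `hybrid` relative to `parentA`.
#' @param body_length_slope Log-scale slope per mm of body length.
#' @param treatment_offset Log-scale offset of the turbulent treatment.
#' @param order_offset Log-scale offset of the second trial.
#' @param interaction_slopes Named vector: slope of morphology x turbulent
#'   interaction per unit predictor.
#' @param sigma_b Random-intercept SD (log scale, \eqn{\ge 0}).
#' @param theta NB2 dispersion (> 0; variance \eqn{\mu + \mu^2/\theta}).
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(intercept = log(120),
                        slopes = c(otic_area = -0.25),
                        species_offsets = c(parentB = 0.10, hybrid = 0.05),
                        body_length_slope = 0.002,
                        treatment_offset = 0.05,
                        order_offset = -0.02,
                        interaction_slopes = numeric(),
                        sigma_b = 0.25,
                        theta = 8) {
  check_number(sigma_b, "sigma_b", 0)
  check_number(theta, "theta", 0, strict = TRUE)
  bad <- setdiff(names(slopes), morphology_variables())
  if (length(bad)) abort(paste("unknown morphology variable:", bad[1]))
  structure(
    list(intercept = intercept, slopes = slopes,
         species_offsets = species_offsets,
         body_length_slope = body_length_slope,
         treatment_offset = treatment_offset, order_offset = order_offset,
         interaction_slopes = interaction_slopes,
         sigma_b = sigma_b, theta = theta),
    class = "effect_spec"
  )
}

# Log-scale linear predictor of an effect_spec on design+morphology rows,
# excluding the random intercept.
effect_linear_predictor <- function(trials, effects) {
  eta <- rep(effects$intercept, nrow(trials)) +
    effects$body_length_slope * trials$body_length +
    effects$treatment_offset * (trials$treatment == "turbulent") +
    effects$order_offset * (trials$order == "second")
  for (sp in names(effects$species_offsets)) {
    eta <- eta + effects$species_offsets[[sp]] * (trials$species == sp)
  }
  for (v in names(effects$slopes)) {
    eta <- eta + effects$slopes[[v]] * trials[[v]]
  }
  for (v in names(effects$interaction_slopes)) {
    eta <- eta + effects$interaction_slopes[[v]] * trials[[v]] *
      (trials$treatment == "turbulent")
  }
  eta
}

#' Simulate trial-level behaviour responses with known effects
#'
#' For every trial row of `design` (joined to its fish's morphology) the
#' generator evaluates the log-link linear predictor of `effects`, adds a
#' per-fish random intercept \eqn{b_i \sim N(0, \sigma_b^2)} drawn once per
#' fish, and draws an integer response in mm from the NB2 distribution with
#' mean \eqn{\mu = \exp(\eta + b_i)} and dispersion \eqn{\theta}. Responses
#' are integer mm so the negative-binomial likelihood of the downstream
#' model is proper.
#'
#' @param design Output of [generate_design()].
#' @param morphology Output of [generate_morphology()] (one row per fish).
#' @param effects An [effect_spec()].
#' @param response Name given to the simulated response column.
#' @param seed Integer seed.
#' @return A list of class `behaviour_sim`: `trials` (design + morphology +
#'   response tibble), `truth` (the `effect_spec`), and
#'   `random_intercepts` (tibble `fish_id`, `b`).
#' @export
generate_behaviour_summaries <- function(design, morphology,
                                         effects = effect_spec(),
                                         response = "mean_nn", seed = NULL) {
  stopifnot(inherits(effects, "effect_spec"))
  trials <- dplyr::inner_join(
    design,
    dplyr::select(morphology, -dplyr::any_of(c("species", "body_length"))),
    by = "fish_id"
  )
  if (nrow(trials) != nrow(design)) {
    abort("every design row needs exactly one morphology record.")
  }
  with_seed(seed, {
    fish <- unique(trials$fish_id)
    b <- setNames(rnorm(length(fish), 0, effects$sigma_b), fish)
    eta <- effect_linear_predictor(trials, effects) + b[trials$fish_id]
    mu <- exp(eta)
    if (any(!is.finite(mu)) || any(mu > 1e12)) {
      bad <- which(!is.finite(mu) | mu > 1e12)[1]
      abort(sprintf("mean overflow at trial row %d (fish %s).",
                    bad, trials$fish_id[bad]))
    }
    trials[[response]] <- rnbinom(nrow(trials), mu = mu,
                                  size = effects$theta)
    structure(
      list(trials = trials, truth = effects,
           random_intercepts = tibble::tibble(fish_id = fish, b = unname(b))),
      class = "behaviour_sim"
    )
  })
}
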