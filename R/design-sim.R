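#' Generate a repeated-measures trial design
#'
#' Builds the trial design of the study the package emulates: each focal
#' fish (two parental species plus their second-generation hybrids) is
#' observed once under laminar and once under turbulent flow, with treatment
#' order counterbalanced within species — half of the fish (plus/minus one
#' when a species count is odd) meet laminar flow first, assigned at random
#' under `seed`. Body lengths are drawn per species from the study
#' populations' reported mean and spread.
#'
#' @param n_parentA,n_parentB,n_hybrids Number of focal fish per group.
#'   Defaults give the full design: 116 fish, 232 trial rows.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param body_length_mean,body_length_sd Named per-species body-length
#'   distributions (mm).
#'
#' @return Tibble with one row per trial: `fish_id`, `species`
#'   (`parentA` = wide-canal, `parentB` = narrow-canal, `hybrid`),
#'   `treatment` (`laminar`/`turbulent`), `order` (`first`/`second`) and
#'   `body_length` (mm).
#' @examples
#' d <- generate_design(seed = 1)
#' nrow(d) # 232
#' @export
generate_design <- function(n_parentA = 10, n_parentB = 10, n_hybrids = 96,
                            seed = NULL,
                            body_length_mean = c(parentA = 110.50,
                                                 parentB = 117.10,
                                                 hybrid = 117.31),
                            body_length_sd = c(parentA = 10.28,
                                               parentB = 13.41,
                                               hybrid = 17.71)) {
  counts <- c(parentA = n_parentA, parentB = n_parentB, hybrid = n_hybrids)
  if (any(counts < 0)) abort("group sizes must be non-negative.")
  with_seed(seed, {
    fish <- purrr::map_dfr(species_levels(), function(sp) {
      n <- counts[[sp]]
      if (n == 0) return(tibble::tibble())
      bl <- rnorm(n, body_length_mean[[sp]], body_length_sd[[sp]])
      while (any(bl <= 0)) bl[bl <= 0] <- rnorm(sum(bl <= 0),
                                                body_length_mean[[sp]],
                                                body_length_sd[[sp]])
      # counterbalance: half laminar-first, half turbulent-first
      n_lam <- floor(n / 2) + rbinom(1, 1, 0.5) * (n %% 2)
      first <- sample(rep(c("laminar", "turbulent"), c(n_lam, n - n_lam)))
      tibble::tibble(
        fish_id = sprintf("%s_%02d", sp, seq_len(n)),
        species = sp, body_length = bl, first_treatment = first
      )
    })
    tidyr::crossing(fish, treatment = c("laminar", "turbulent")) |>
      dplyr::mutate(
        order = ifelse(.data$treatment == .data$first_treatment,
                       "first", "second"),
        species = factor(.data$species, levels = species_levels())
      ) |>
      dplyr::select("fish_id", "species", "treatment", "order",
                    "body_length") |>
      dplyr::arrange(.data$fish_id, .data$treatment)
  })
}

#' Minimum companion-fish pool size
#'
#' With a fixed number of companion fish per trial and a daily trial quota,
#' and no companion used more than once per day, the smallest pool that can
#' staff a full day is simply their product.
#'
#' @param companions_per_trial Companions in each trial group (default 4).
#' @param trials_per_day Trials run per day (default 7).
#' @return Integer pool size (28 under the defaults).
#' @export
companion_pool_min <- function(companions_per_trial = 4, trials_per_day = 7) {
  check_number(companions_per_trial, "companions_per_trial", 0)
  check_number(trials_per_day, "trials_per_day", 0)
  as.integer(companions_per_trial * trials_per_day)
}
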