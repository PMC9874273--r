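#' AICc support table over a response x predictor grid
#'
#' For every combination of behaviour response, focal morphology predictor
#' and dataset (`all` fish or `hybrids` only), fits the null model
#' (covariates only), the main-effects model (+ focal predictor) and the
#' interaction model (+ predictor x treatment), and codes the outcome:
#' `"+"` / `"-"` is the sign of the focal-predictor coefficient when the
#' main-effects model is strongly supported (\eqn{\Delta AICc \ge 2} below
#' the null), `"U"` otherwise, with a `"*"` appended when the interaction
#' model both undercuts the null by \eqn{\ge 2} AICc units and improves on
#' the main-effects model's AICc. Cells whose fits fail or do not converge
#' are coded `NA` and the run continues.
#'
#' @param data Trial-level tibble: one row per fish x treatment with the
#'   response columns, `fish_id`, `species`, `body_length`, `treatment`,
#'   `order` and the morphology columns.
#' @param responses Response columns (default the four behaviour means
#'   present in `data`).
#' @param predictors Focal morphology columns (default the ten standard
#'   variables present in `data`).
#' @param datasets Subset selectors among `"all"` and `"hybrids"`.
#' @param nodes Gauss-Hermite nodes passed to [nb_glmm()].
#' @return Tibble with one row per cell: `response`, `dataset`,
#'   `predictor`, `code`, `delta_aicc`, `delta_aicc_interaction`,
#'   `estimate` (focal slope, original scale) and `supported` /
#'   `interaction_supported` flags.
#' @export
build_support_table <- function(data,
                                responses = intersect(behaviour_responses(),
                                                      names(data)),
                                predictors = intersect(morphology_variables(),
                                                       names(data)),
                                datasets = c("all", "hybrids"),
                                nodes = 20) {
  datasets <- match.arg(datasets, several.ok = TRUE)
  grid <- tidyr::expand_grid(dataset = datasets, response = responses)
  purrr::pmap_dfr(grid, function(dataset, response) {
    dat <- if (dataset == "hybrids") {
      dplyr::filter(data, .data$species == "hybrid")
    } else {
      data
    }
    null_fit <- tryCatch(nb_glmm(dat, response, NULL, nodes = nodes),
                         error = function(e) NULL)
    purrr::map_dfr(predictors, function(pred) {
      row <- tibble::tibble(
        response = response, dataset = dataset, predictor = pred,
        code = NA_character_, delta_aicc = NA_real_,
        delta_aicc_interaction = NA_real_, estimate = NA_real_,
        supported = NA, interaction_supported = NA
      )
      if (is.null(null_fit) || !null_fit$converged) return(row)
      main <- tryCatch(nb_glmm(dat, response, pred, nodes = nodes),
                       error = function(e) NULL)
      inter <- tryCatch(
        nb_glmm(dat, response, pred, interaction = TRUE, nodes = nodes),
        error = function(e) NULL
      )
      if (is.null(main) || !main$converged) return(row)
      cmp <- compare_to_null(main, null_fit)
      slope <- main$coefficients$estimate[main$coefficients$term == pred]
      code <- if (cmp$supported) (if (slope >= 0) "+" else "-") else "U"
      inter_ok <- FALSE
      d_inter <- NA_real_
      if (!is.null(inter) && inter$converged) {
        d_inter <- null_fit$aicc - inter$aicc
        inter_ok <- d_inter >= 2 && inter$aicc < main$aicc
      }
      if (code != "U" && inter_ok) code <- paste0(code, "*")
      row$code <- code
      row$delta_aicc <- cmp$delta_aicc
      row$delta_aicc_interaction <- d_inter
      row$estimate <- slope
      row$supported <- cmp$supported
      row$interaction_supported <- inter_ok
      row
    })
  })
}

#' Pivot a support table to a wide summary layout
#'
#' Reshapes [build_support_table()] output to one row per morphology
#' variable and one column per response x dataset cell of support codes.
#'
#' @param support Output of [build_support_table()].
#' @return Wide tibble of codes.
#' @export
support_table_wide <- function(support) {
  support |>
    dplyr::mutate(column = paste(.data$response, .data$dataset, sep = ".")) |>
    dplyr::select("predictor", "column", "code") |>
    tidyr::pivot_wider(names_from = "column", values_from = "code")
}
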