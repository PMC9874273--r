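#' Write a results table as CSV
#'
#' Writes any per-trial or per-specimen results table (behaviour summaries,
#' pore-area records, support tables) as a UTF-8 CSV with a header and a
#' stable column order, so that `readr::read_csv()` reproduces it. A list of
#' records is row-bound first and must share one schema.
#'
#' @param records Data frame, or list of single-row data frames / named
#'   lists sharing a schema.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.data.frame(records)) {
    tab <- tibble::as_tibble(records)
  } else {
    if (length(records)) {
      schemas <- lapply(records, function(r) sort(names(r)))
      if (!all(vapply(schemas, identical, logical(1), y = schemas[[1]]))) {
        abort("records do not share a common schema.")
      }
    }
    tab <- dplyr::bind_rows(lapply(records, tibble::as_tibble))
  }
  readr::write_csv(tab, path, na = "")
  invisible(tab)
}
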