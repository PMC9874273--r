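#' Closed canal-pore outline
#'
#' A `pore_curve` is the digitized circumference of one lateral-line canal
#' pore: an ordered set of points, in mm, beginning at a homologous anchor
#' (the anterior limit of the pore). The curve is closed implicitly — the
#' last stored point connects back to the first; a duplicated closing point
#' in the input is dropped.
#'
#' @param points Two-column matrix or data frame of `(x, y)` in mm, in
#'   drawing order, starting at the anchor.
#' @param specimen Specimen identifier.
#' @param canal Canal name (e.g. `"dentary"`, `"preopercular"`).
#' @param pore Pore number within the canal.
#' @return Object of class `pore_curve`.
#' @export
pore_curve <- function(points, specimen = NA_character_,
                       canal = NA_character_, pore = NA_integer_) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) abort("`points` must have two columns (x, y).")
  if (nrow(points) >= 2L && all(points[1, ] == points[nrow(points), ])) {
    points <- points[-nrow(points), , drop = FALSE]
  }
  if (nrow(points) < 3L) abort("a pore outline needs at least 3 points.")
  if (any(!is.finite(points))) abort("non-finite outline coordinates.")
  structure(
    list(points = unname(points), specimen = specimen, canal = canal,
         pore = as.integer(pore)),
    class = "pore_curve"
  )
}

#' @export
print.pore_curve <- function(x, ...) {
  cat(sprintf(
    "<pore_curve> %d points, specimen %s, canal %s, pore %s\n",
    nrow(x$points), format(x$specimen), format(x$canal), format(x$pore)
  ))
  invisible(x)
}

tps_keyword <- function(line) {
  m <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
  if (length(m) == 0) NULL else list(key = toupper(m[2]), value = trimws(m[3]))
}

#' Read pore outlines from a TPS outline file
#'
#' Parses the TPS dialect used by outline digitizers: per-specimen records
#' with `LM`, `CURVES`, `POINTS`, `ID`, `SCALE` and `IMAGE` keywords
#' (case-insensitive; other keywords are ignored). Each `POINTS=n` block
#' lists `n` whitespace-separated coordinate pairs. When a `SCALE` record is
#' present, pixel coordinates are multiplied by it to give mm.
#'
#' @param path TPS file path.
#' @return List of [pore_curve()] objects, one per outline curve, labelled
#'   by specimen `ID` (auto-numbered with a warning when absent) and curve
#'   index.
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L
  specimen_n <- 0L
  curves <- list()
  while (i <= length(lines)) {
    kw <- tps_keyword(lines[i])
    if (is.null(kw) || kw$key != "LM") {
      abort(sprintf("TPS parse error at line %d: expected LM=.", i))
    }
    specimen_n <- specimen_n + 1L
    n_lm <- as.integer(kw$value)
    i <- i + 1L
    i <- i + n_lm # fixed landmarks are skipped (outline files carry curves)
    spec_curves <- list()
    spec_id <- NA_character_
    scale <- NA_real_
    n_curves_declared <- 0L
    while (i <= length(lines)) {
      kw <- tps_keyword(lines[i])
      if (is.null(kw)) abort(sprintf("TPS parse error at line %d.", i))
      if (kw$key == "LM") break
      i <- i + 1L
      if (kw$key == "CURVES") {
        n_curves_declared <- as.integer(kw$value)
      } else if (kw$key == "POINTS") {
        n_pts <- as.integer(kw$value)
        block <- lines[seq.int(i, length.out = n_pts)]
        if (i + n_pts - 1L > length(lines) || any(!is.na(sapply(block, function(l) {
          k <- tps_keyword(l); if (is.null(k)) NA_character_ else k$key
        })))) {
          abort("POINTS count does not match listed coordinates.")
        }
        xy <- do.call(rbind, lapply(block, function(l) {
          as.numeric(strsplit(trimws(l), "\\s+")[[1]])
        }))
        if (ncol(xy) != 2 || any(is.na(xy))) {
          abort("malformed coordinate line in POINTS block.")
        }
        spec_curves[[length(spec_curves) + 1L]] <- xy
        i <- i + n_pts
      } else if (kw$key == "ID") {
        spec_id <- kw$value
      } else if (kw$key == "SCALE") {
        scale <- as.numeric(kw$value)
      } else if (kw$key == "IMAGE") {
        # carried for provenance only
      } # unknown keywords ignored
    }
    if (n_curves_declared && length(spec_curves) != n_curves_declared) {
      abort("CURVES count does not match the number of POINTS blocks.")
    }
    if (is.na(spec_id)) {
      warn("TPS record without ID; auto-numbered.")
      spec_id <- sprintf("specimen_%d", specimen_n)
    }
    for (k in seq_along(spec_curves)) {
      xy <- spec_curves[[k]]
      if (!is.na(scale)) xy <- xy * scale
      curves[[length(curves) + 1L]] <-
        pore_curve(xy, specimen = spec_id, pore = k)
    }
  }
  curves
}

#' Write pore outlines to a TPS outline file
#'
#' Inverse of [read_tps()]: one record per specimen, coordinates written in
#' mm (no `SCALE` record), full double precision. `write_tps()` followed by
#' [read_tps()] reproduces the coordinates up to float formatting.
#'
#' @param curves List of [pore_curve()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(curves, path) {
  if (inherits(curves, "pore_curve")) curves <- list(curves)
  by_spec <- split(curves, vapply(curves, function(cv) {
    if (is.na(cv$specimen)) "specimen_1" else cv$specimen
  }, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  for (spec_id in names(by_spec)) {
    cvs <- by_spec[[spec_id]]
    writeLines("LM=0", con)
    writeLines(sprintf("CURVES=%d", length(cvs)), con)
    for (cv in cvs) {
      writeLines(sprintf("POINTS=%d", nrow(cv$points)), con)
      writeLines(
        paste(
          format(cv$points[, 1], digits = 17, trim = TRUE, scientific = FALSE),
          format(cv$points[, 2], digits = 17, trim = TRUE, scientific = FALSE)
        ),
        con
      )
    }
    writeLines(sprintf("ID=%s", spec_id), con)
  }
  invisible(path)
}
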