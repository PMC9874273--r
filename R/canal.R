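#' Configuration of the artificial canal-sensor lumped model
#'
#' Quasi-steady lumped-parameter model of the macro-scale canal sensor: a
#' 25 x 25 x 50 mm cuboid with two identical pores on the upstream-facing
#' side, evenly spaced along the flow axis, and a compliant haircell in
#' the internal channel. The internal flow responds to the external
#' pressure differential across the pores,
#' \deqn{u(t) = \Delta p(t) / (A_c (R_{ch} + 2 R_{pore}(d))),}
#' with a Poiseuille-type pore resistance
#' \eqn{R_{pore} = 128 \mu L_p / (\pi d^4)} and a fixed effective channel
#' resistance \eqn{R_{ch}} that lumps the channel itself with the haircell
#' obstruction. The default \eqn{R_{ch}} is set from the free-stream
#' dynamic-pressure scale (see the package vignette), not from any
#' simulation output, so that background pressure heads drive internal
#' flow of at most a few per cent of the free-stream speed.
#'
#' @param body Sensor body dimensions (m).
#' @param pore_diameters Candidate pore diameters (m; default 5-25 mm).
#' @param pore_spacing Pore spacing along the flow axis (m; default 25 mm,
#'   even spacing on the 50 mm face).
#' @param pore_length Pore length = wall thickness (m; default 5 mm).
#' @param channel_area Internal channel cross-section (m^2).
#' @param channel_resistance Effective channel resistance (Pa s m^-3).
#' @param viscosity Dynamic viscosity of the fluid (Pa s; water).
#' @return List of class `canal_sensor_config`.
#' @export
canal_sensor_config <- function(body = c(0.025, 0.025, 0.050),
                                pore_diameters = c(5, 10, 15, 20, 25) / 1000,
                                pore_spacing = 0.025,
                                pore_length = 0.005,
                                channel_area = 0.015^2,
                                channel_resistance = 2e6,
                                viscosity = 1.0e-3) {
  if (any(pore_diameters <= 0)) abort("pore diameters must be positive.")
  check_number(pore_spacing, "pore_spacing", 0, strict = TRUE)
  # two pores, evenly spaced along the 50 mm face: they must fit the face
  # width and must not overlap each other
  if (any(pore_diameters > min(body[1:2])) ||
        any(pore_diameters > pore_spacing)) {
    abort("pore diameter must fit the sensor face and spacing.")
  }
  check_number(channel_resistance, "channel_resistance", 0)
  structure(
    list(body = body, pore_diameters = sort(pore_diameters),
         pore_spacing = pore_spacing, pore_length = pore_length,
         channel_area = channel_area,
         channel_resistance = channel_resistance, viscosity = viscosity),
    class = "canal_sensor_config"
  )
}

pore_resistance <- function(sensor, diameter) {
  128 * sensor$viscosity * sensor$pore_length / (pi * diameter^4)
}

new_sensor_response <- function(series, diameter) {
  q <- quantile(series$u_internal, c(0.025, 0.25, 0.5, 0.75, 0.975),
                names = FALSE)
  structure(
    list(series = series, diameter = diameter,
         mean = mean(series$u_internal), median = q[3],
         iqr = q[4] - q[2], q25 = q[2], q75 = q[4],
         q025 = q[1], q975 = q[5]),
    class = "sensor_response"
  )
}

#' @export
print.sensor_response <- function(x, ...) {
  cat(sprintf(
    "<sensor_response> pore %s: mean %.4g m/s, IQR %.4g m/s (%d samples)\n",
    if (is.finite(x$diameter)) sprintf("%.0f mm", x$diameter * 1000) else "open",
    x$mean, x$iqr, nrow(x$series)
  ))
  invisible(x)
}

#' Internal canal velocity from the pore pressure differential
#'
#' Applies the quasi-steady lumped model of [canal_sensor_config()] to a
#' two-pore pressure record: the signed internal velocity is the pressure
#' difference (upstream pore minus downstream pore) divided by the channel
#' area times the total resistance. The model is linear — doubling the
#' pressure differential doubles the velocity — and the internal velocity
#' vanishes as the pore diameter shrinks.
#'
#' @param pressures Tibble with columns `time`, `p_up`, `p_down` (Pa) on a
#'   common time base.
#' @param sensor A [canal_sensor_config()].
#' @param diameter Pore diameter (m), positive.
#' @return Object of class `sensor_response` (series, mean, IQR,
#'   quantiles).
#' @export
canal_response <- function(pressures, sensor = canal_sensor_config(),
                           diameter) {
  stopifnot(inherits(sensor, "canal_sensor_config"))
  check_number(diameter, "diameter", 0, strict = TRUE)
  req <- c("time", "p_up", "p_down")
  if (!all(req %in% names(pressures))) {
    abort("`pressures` needs columns time, p_up, p_down.")
  }
  if (anyNA(pressures$p_up) || anyNA(pressures$p_down)) {
    abort("pressure series contain missing values (mismatched time bases?).")
  }
  r_tot <- sensor$channel_resistance + 2 * pore_resistance(sensor, diameter)
  series <- tibble::tibble(
    time = pressures$time,
    dp = pressures$p_up - pressures$p_down,
    u_internal = (pressures$p_up - pressures$p_down) /
      (sensor$channel_area * r_tot)
  )
  new_sensor_response(series, diameter)
}

# Assemble the two-pore pressure record from a flow field's probe series.
pore_pressures <- function(field) {
  pr <- field$probes
  need <- c("pore_up", "pore_down")
  if (!all(need %in% pr$name)) {
    abort("field probes must include `pore_up` and `pore_down`; simulate with sensor_probe_points().")
  }
  up <- dplyr::filter(pr, .data$name == "pore_up")
  dn <- dplyr::filter(pr, .data$name == "pore_down")
  if (!identical(up$time, dn$time)) abort("pore probe time bases differ.")
  tibble::tibble(time = up$time, p_up = up$p, p_down = dn$p)
}

#' Pore-size sweep of the canal sensor on one wake
#'
#' Drives the lumped canal model with the same wake stimulus for every
#' pore diameter (plus, optionally, the open-pore condition, where the
#' pore-bearing face is absent and the haircell sees the external flow
#' directly: the response is then the external streamwise velocity at the
#' haircell). Returns per-size responses and a summary table suitable for
#' violin-style plotting.
#'
#' @param field A [simulate_wake()] result with the sensor probes.
#' @param sensor A [canal_sensor_config()].
#' @param sizes Pore diameters (m; default from `sensor`).
#' @param include_open Include the open-pore condition?
#' @param transient_frac Initial fraction of the record discarded.
#' @return List of class `pore_sweep`: `responses` (named list of
#'   `sensor_response`), `summary` tibble (`pore`, `diameter`, `mean`,
#'   `abs_mean`, `median`, `iqr`, `q25`, `q75`).
#' @export
pore_size_sweep <- function(field, sensor = canal_sensor_config(),
                            sizes = NULL, include_open = TRUE,
                            transient_frac = 0.2) {
  stopifnot(inherits(field, "flow_field"))
  sizes <- sort(sizes %||% sensor$pore_diameters)
  if (any(duplicated(sizes))) abort("pore sizes must be distinct.")
  pp <- pore_pressures(field)
  keep <- pp$time > max(pp$time) * transient_frac
  pp <- pp[keep, ]
  responses <- lapply(sizes, function(d) canal_response(pp, sensor, d))
  names(responses) <- sprintf("%.0fmm", sizes * 1000)
  if (include_open) {
    hc <- dplyr::filter(field$probes, .data$name == "haircell")
    hc <- hc[hc$time > max(hc$time) * transient_frac, ]
    open_series <- tibble::tibble(time = hc$time, dp = NA_real_,
                                  u_internal = hc$u)
    responses$open <- new_sensor_response(open_series, Inf)
  }
  summary <- purrr::imap_dfr(responses, function(r, nm) {
    tibble::tibble(pore = nm, diameter = r$diameter, mean = r$mean,
                   abs_mean = abs(r$mean), median = r$median, iqr = r$iqr,
                   q25 = r$q25, q75 = r$q75)
  })
  structure(list(responses = responses, summary = summary,
                 sensor = sensor),
            class = "pore_sweep")
}

#' @export
print.pore_sweep <- function(x, ...) {
  cat("<pore_sweep>\n")
  print(x$summary)
  invisible(x)
}

#' Discrete divergence of a stored velocity snapshot
#'
#' Central-difference divergence of snapshot `k`, normalised by U/dx.
#' The solver is weakly compressible, so the divergence is small but not
#' exactly zero; this diagnostic backs the incompressibility contract.
#'
#' @param field A [simulate_wake()] result.
#' @param k Snapshot index (default last).
#' @return Median of `|div u| * dx / U` over interior fluid cells.
#' @export
field_divergence <- function(field, k = NULL) {
  stopifnot(inherits(field, "flow_field"))
  k <- k %||% dim(field$u)[3]
  u <- field$u[, , k]
  v <- field$v[, , k]
  nx <- nrow(u)
  ny <- ncol(u)
  dudx <- (u[3:nx, 2:(ny - 1)] - u[1:(nx - 2), 2:(ny - 1)]) / (2 * field$dx)
  dvdy <- (v[2:(nx - 1), 3:ny] - v[2:(nx - 1), 1:(ny - 2)]) / (2 * field$dx)
  div <- abs(dudx + dvdy) * field$dx / field$config$u_inf
  median(div, na.rm = TRUE)
}
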