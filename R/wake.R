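#' Configuration for the cylinder-wake simulation
#'
#' Desk-scale hydrodynamic study: unsteady 2-D flow past a
#' circular cylinder of diameter `diameter` at free-stream speed `u_inf`.
#' The solver is a D2Q9 lattice-Boltzmann scheme run at a reduced Reynolds
#' number (default 150: periodic laminar shedding, no turbulence model
#' required) and rescaled to physical units via `u_inf` and `diameter`.
#' The duration is expressed in expected shedding periods (using
#' `strouhal_guess` only to size the run); defaults give 75 periods of
#' which the first 20% are treated as transient downstream.
#'
#' @param diameter Cylinder diameter (m; default 0.1).
#' @param u_inf Free-stream speed (m s^-1; default 0.5).
#' @param re_sim Solver Reynolds number (>= 60 for the shedding regime).
#' @param resolution Lattice cells per diameter (default 20).
#' @param domain_length,domain_width Domain size in diameters (cylinder at
#'   `5 D` from the inlet, on the centreline).
#' @param u_lattice Lattice inflow speed (Mach control; default 0.1).
#' @param n_periods Simulated duration in expected shedding periods.
#' @param strouhal_guess Nominal Strouhal number used only to convert
#'   periods to time steps.
#' @param sample_every Steps between stored speed-field samples.
#' @param field_every Steps between stored full (u, v, p) snapshots.
#' @param probe_every Steps between probe-series records.
#' @param perturb Relative amplitude of the deterministic initial
#'   cross-stream perturbation that seeds the shedding instability.
#' @param cylinder Set `FALSE` for a free-stream (no cylinder) run.
#' @return A list of class `wake_config`.
#' @export
wake_config <- function(diameter = 0.1, u_inf = 0.5, re_sim = 150,
                        resolution = 20, domain_length = 22,
                        domain_width = 10, u_lattice = 0.1,
                        n_periods = 75, strouhal_guess = 0.18,
                        sample_every = 250, field_every = 2500,
                        probe_every = 2, perturb = 0.1, cylinder = TRUE) {
  check_number(diameter, "diameter", 0, strict = TRUE)
  check_number(u_inf, "u_inf", 0, strict = TRUE)
  if (cylinder && re_sim < 60) {
    abort("`re_sim` must be >= 60 (vortex-shedding regime).")
  }
  if (u_lattice > 0.25) abort("`u_lattice` too large: lattice Mach limit.")
  nu <- u_lattice * resolution / re_sim
  tau <- 3 * nu + 0.5
  if (tau <= 0.505) {
    abort("unstable configuration: relaxation time too close to 1/2; raise `resolution` or lower `re_sim`.")
  }
  structure(
    list(diameter = diameter, u_inf = u_inf, re_sim = re_sim,
         resolution = resolution, domain_length = domain_length,
         domain_width = domain_width, u_lattice = u_lattice,
         n_periods = n_periods, strouhal_guess = strouhal_guess,
         sample_every = sample_every, field_every = field_every,
         probe_every = probe_every, perturb = perturb, cylinder = cylinder,
         tau = tau),
    class = "wake_config"
  )
}

#' Default sensor-station probe points
#'
#' The artificial-sensor station sits 200 mm downstream of the cylinder
#' centre and 40 mm to one side; the two canal pores flank it along the
#' flow axis at the sensor's pore spacing.
#'
#' @param config A [wake_config()].
#' @param offset Station offset from the cylinder centre (m).
#' @param pore_spacing Pore spacing along the flow axis (m).
#' @return Tibble `name`, `x`, `y` in metres (tank frame: origin at the
#'   inlet, bottom wall; x downstream).
#' @export
sensor_probe_points <- function(config, offset = c(0.2, 0.04),
                                pore_spacing = 0.025) {
  cyl <- cylinder_centre(config)
  tibble::tibble(
    name = c("haircell", "pore_up", "pore_down"),
    x = cyl[1] + offset[1] + c(0, -pore_spacing / 2, pore_spacing / 2),
    y = cyl[2] + offset[2]
  )
}

cylinder_centre <- function(config) {
  c(5, config$domain_width / 2) * config$diameter
}

#' Simulate the unsteady cylinder wake
#'
#' Runs the lattice-Boltzmann solver of [wake_config()] and returns a
#' `flow_field`: a regular grid with subsampled speed fields (for variance
#' mapping), sparse full (u, v, p) snapshots (for interpolation and
#' plotting) and dense probe time series at `probe_points`. Deterministic
#' for a fixed configuration.
#'
#' @param config A [wake_config()].
#' @param probe_points Tibble `name`, `x`, `y` (m); default
#'   [sensor_probe_points()].
#' @return Object of class `flow_field`: grid coordinates `x`, `y` (m),
#'   `speed` array `[nx, ny, n_samples]` (m s^-1, `NA` inside the
#'   cylinder), `speed_times`, snapshot arrays `u`, `v`, `p` and
#'   `snap_times`, `probes` (long tibble `time`, `name`, `x`, `y`, `u`,
#'   `v`, `p`, `speed`), `solid` mask, the time step `dt` and cell size
#'   `dx`, and `config`.
#' @export
simulate_wake <- function(config = wake_config(), probe_points = NULL) {
  stopifnot(inherits(config, "wake_config"))
  D <- config$resolution
  nx <- as.integer(round(config$domain_length * D))
  ny <- as.integer(round(config$domain_width * D))
  dx <- config$diameter / D
  dt <- dx * config$u_lattice / config$u_inf
  steps_per_period <- D / (config$strouhal_guess * config$u_lattice)
  n_steps <- as.integer(ceiling(config$n_periods * steps_per_period))
  cyl <- cylinder_centre(config)
  cx <- cyl[1] / dx
  cy <- cyl[2] / dx
  if (is.null(probe_points)) probe_points <- sensor_probe_points(config)
  if (any(probe_points$x < 0 | probe_points$x > nx * dx |
            probe_points$y < 0 | probe_points$y > ny * dx)) {
    abort("probe point outside the flow domain.")
  }
  res <- lbm_run(
    nx = nx, ny = ny, cx = cx, cy = cy,
    radius = if (config$cylinder) D / 2 else 0,
    u_in = config$u_lattice, tau = config$tau, n_steps = n_steps,
    sample_every = config$sample_every, field_every = config$field_every,
    probe_xy = cbind(probe_points$x / dx, probe_points$y / dx),
    probe_every = config$probe_every, perturb = config$perturb
  )
  c_u <- config$u_inf / config$u_lattice          # lattice -> m/s
  c_p <- 1000 * (dx / dt)^2                        # lattice rho -> Pa (water)
  n_samples <- length(res$sample_steps)
  n_snaps <- length(res$snap_steps)
  to_arr <- function(v, nt) aperm(array(v, c(ny, nx, nt)), c(2, 1, 3))
  n_probes <- nrow(probe_points)
  probe_t <- res$probe_steps * dt
  probes <- tibble::tibble(
    time = rep(probe_t, each = n_probes),
    name = rep(probe_points$name, length(probe_t)),
    x = rep(probe_points$x, length(probe_t)),
    y = rep(probe_points$y, length(probe_t)),
    u = res$probe_u * c_u,
    v = res$probe_v * c_u,
    p = (res$probe_rho - 1) / 3 * c_p
  )
  probes$speed <- sqrt(probes$u^2 + probes$v^2)
  structure(
    list(
      x = (seq_len(nx) - 0.5) * dx, y = (seq_len(ny) - 0.5) * dx,
      speed = to_arr(res$speed, n_samples) * c_u,
      speed_times = res$sample_steps * dt,
      u = to_arr(res$u_snap, n_snaps) * c_u,
      v = to_arr(res$v_snap, n_snaps) * c_u,
      p = (to_arr(res$rho_snap, n_snaps) - 1) / 3 * c_p,
      snap_times = res$snap_steps * dt,
      probes = probes,
      solid = t(matrix(res$solid == 1L, ny, nx)),
      dx = dx, dt = dt, n_steps = n_steps,
      cylinder_centre = cyl, config = config
    ),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %d x %d cells (dx = %.4g m), %d speed samples over %.3g s, Re_sim = %g\n",
    length(x$x), length(x$y), x$dx, length(x$speed_times),
    max(x$speed_times), x$config$re_sim
  ))
  invisible(x)
}

#' Temporal variance map of flow speed
#'
#' Per-cell variance of flow speed over the stored post-transient samples,
#' and the location where it peaks. In a shedding wake the peak lies
#' downstream of the cylinder and off its centreline.
#'
#' @param field A [simulate_wake()] result.
#' @param transient_frac Fraction of samples (from the start) discarded as
#'   transient (default 0.2).
#' @return List of class `variance_map`: `variance` matrix `[nx, ny]`,
#'   `x`, `y`, `argmax` (named vector, m), `argmax_rel` (relative to the
#'   cylinder centre), `n_samples_used`.
#' @export
variance_map <- function(field, transient_frac = 0.2) {
  stopifnot(inherits(field, "flow_field"))
  nt <- dim(field$speed)[3]
  keep <- seq_len(nt) > floor(nt * transient_frac)
  if (sum(keep) < 10) abort("fewer than 10 post-transient samples.")
  sp <- field$speed[, , keep, drop = FALSE]
  m1 <- rowMeans(sp, dims = 2)
  v <- rowMeans(sp^2, dims = 2) - m1^2
  v <- v * sum(keep) / (sum(keep) - 1) # unbiased
  vmax <- which(v == max(v, na.rm = TRUE), arr.ind = TRUE)[1, ]
  argmax <- c(x = field$x[vmax[1]], y = field$y[vmax[2]])
  structure(
    list(variance = v, x = field$x, y = field$y, argmax = argmax,
         argmax_rel = argmax - setNames(field$cylinder_centre, c("x", "y")),
         n_samples_used = sum(keep)),
    class = "variance_map"
  )
}

#' Interpolate stored wake snapshots at arbitrary points
#'
#' Bilinear interpolation of the stored (u, v, p) snapshots at the given
#' points, at every stored snapshot time. At a grid node the stored value
#' is returned exactly.
#'
#' @param field A [simulate_wake()] result.
#' @param points Tibble/data frame with columns `x`, `y` (m) and
#'   optionally `name`.
#' @return Tibble `time`, `name`, `x`, `y`, `u`, `v`, `p`, `speed`.
#' @export
probe <- function(field, points) {
  stopifnot(inherits(field, "flow_field"))
  points <- tibble::as_tibble(points)
  if (!"name" %in% names(points)) {
    points$name <- sprintf("p%d", seq_len(nrow(points)))
  }
  if (any(points$x < min(field$x) | points$x > max(field$x) |
            points$y < min(field$y) | points$y > max(field$y))) {
    abort("probe point outside the stored grid.")
  }
  interp_one <- function(mat, px, py) {
    ix <- findInterval(px, field$x, all.inside = TRUE)
    iy <- findInterval(py, field$y, all.inside = TRUE)
    fx <- (px - field$x[ix]) / (field$x[ix + 1] - field$x[ix])
    fy <- (py - field$y[iy]) / (field$y[iy + 1] - field$y[iy])
    mat[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
      mat[cbind(ix + 1, iy)] * fx * (1 - fy) +
      mat[cbind(ix, iy + 1)] * (1 - fx) * fy +
      mat[cbind(ix + 1, iy + 1)] * fx * fy
  }
  purrr::map_dfr(seq_along(field$snap_times), function(k) {
    tibble::tibble(
      time = field$snap_times[k], name = points$name,
      x = points$x, y = points$y,
      u = interp_one(field$u[, , k], points$x, points$y),
      v = interp_one(field$v[, , k], points$x, points$y),
      p = interp_one(field$p[, , k], points$x, points$y)
    )
  }) |>
    dplyr::mutate(speed = sqrt(.data$u^2 + .data$v^2))
}

#' Shedding (Strouhal) frequency from a probe series
#'
#' Dominant frequency of the post-transient cross-stream velocity at the
#' sensor station, from the discrete Fourier transform, expressed as the
#' dimensionless Strouhal number f D / U.
#'
#' @param field A [simulate_wake()] result with a `haircell` probe.
#' @param transient_frac Initial fraction discarded.
#' @param probe_name Which probe series to use.
#' @return List: `frequency` (Hz), `strouhal`, `bin_width` (Hz).
#' @export
wake_strouhal <- function(field, transient_frac = 0.2,
                          probe_name = "haircell") {
  stopifnot(inherits(field, "flow_field"))
  ser <- dplyr::filter(field$probes, .data$name == probe_name)
  if (!nrow(ser)) abort(sprintf("no probe named `%s`.", probe_name))
  keep <- ser$time > max(ser$time) * transient_frac
  v <- ser$v[keep]
  tt <- ser$time[keep]
  dtp <- tt[2] - tt[1]
  v <- v - mean(v)
  spec <- Mod(fft(v))^2
  n <- length(v)
  freqs <- (seq_len(n) - 1) / (n * dtp)
  half <- 2:floor(n / 2)
  fpeak <- freqs[half][which.max(spec[half])]
  list(frequency = fpeak,
       strouhal = fpeak * field$config$diameter / field$config$u_inf,
       bin_width = 1 / (n * dtp))
}
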