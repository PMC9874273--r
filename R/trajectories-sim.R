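#' Parameters of the agent-based trajectory generator
#'
#' The trajectory generator is a deliberately simple stand-in for real
#' shoaling fish: it is not a hydrodynamic model, it only needs to produce
#' trajectories whose spacing statistics are controllable. Each fish swims
#' toward the group centroid when farther from it than `spacing` and away
#' when closer, drifts downstream with the flow while station-holding
#' against it (the two cancel, so net mean displacement is ~0), and receives
#' Gaussian positional jitter.
#'
#' @param spacing Preferred distance to the group centroid (mm). A regular
#'   polygon of circumradius `spacing` is a noise-free equilibrium.
#' @param gain_attract,gain_repulse Restoring gains (s^-1) applied outside /
#'   inside the preferred distance.
#' @param flow_speed Downstream drift speed, cancelled by station-holding
#'   (mm s^-1; default 70, the tank's mean flow).
#' @param noise_sd Per-frame positional noise SD (mm).
#' @param fps Frames per second.
#' @return A list of class `swimmer_params`.
#' @export
swimmer_params <- function(spacing = 100, gain_attract = 1.5,
                           gain_repulse = 1.5, flow_speed = 70,
                           noise_sd = 6, fps = 25) {
  check_number(spacing, "spacing", 0, strict = TRUE)
  check_number(gain_attract, "gain_attract", 0)
  check_number(gain_repulse, "gain_repulse", 0)
  check_number(noise_sd, "noise_sd", 0)
  check_number(fps, "fps", 0, strict = TRUE)
  structure(
    list(spacing = spacing, gain_attract = gain_attract,
         gain_repulse = gain_repulse, flow_speed = flow_speed,
         noise_sd = noise_sd, fps = fps),
    class = "swimmer_params"
  )
}

#' Generate synthetic shoal trajectories
#'
#' Simulates a 5-fish group (one focal + four companions) in the arena with
#' the dynamics of [swimmer_params()]. Positions are clipped to the arena.
#' Expected mean nearest-neighbour distance increases with the preferred
#' spacing.
#'
#' @param n_frames Number of frames (>= 1).
#' @param params A [swimmer_params()].
#' @param start Optional `n_fish` x 2 matrix of starting positions (mm);
#'   default places the fish on a regular polygon of circumradius
#'   `params$spacing` at the arena centre.
#' @param n_fish Number of individuals (default 5).
#' @param arena Arena size (mm).
#' @param focal_id Focal individual index.
#' @param seed Integer seed.
#' @return A [frame_set()].
#' @export
generate_trajectories <- function(n_frames, params = swimmer_params(),
                                  start = NULL, n_fish = 5,
                                  arena = c(1210, 557.8), focal_id = 1L,
                                  seed = NULL) {
  check_number(n_frames, "n_frames", 1)
  if (is.null(start)) {
    ang <- 2 * pi * (seq_len(n_fish) - 1) / n_fish
    start <- cbind(arena[1] / 2 + params$spacing * cos(ang),
                   arena[2] / 2 + params$spacing * sin(ang))
  }
  start <- as.matrix(start)
  stopifnot(nrow(start) == n_fish, ncol(start) == 2)
  dt <- 1 / params$fps
  with_seed(seed, {
    pos <- start
    out <- array(NA_real_, c(n_frames, n_fish, 2))
    for (f in seq_len(n_frames)) {
      out[f, , ] <- pos
      cen <- colMeans(pos)
      dx <- cen[1] - pos[, 1]
      dy <- cen[2] - pos[, 2]
      d <- sqrt(dx^2 + dy^2)
      gain <- ifelse(d > params$spacing, params$gain_attract,
                     params$gain_repulse)
      # restoring speed toward/away from the centroid; zero at d == spacing
      speed <- gain * (d - params$spacing)
      ux <- ifelse(d > 0, dx / d, 0)
      uy <- ifelse(d > 0, dy / d, 0)
      # downstream drift and upstream station-holding cancel exactly
      drift_x <- (params$flow_speed - params$flow_speed) * dt
      pos <- pos + cbind(speed * ux * dt + drift_x, speed * uy * dt)
      if (params$noise_sd > 0) {
        pos <- pos + matrix(rnorm(2 * n_fish, 0, params$noise_sd),
                            n_fish, 2)
      }
      if (any(!is.finite(pos))) abort("trajectory dynamics produced NaN.")
      pos[, 1] <- pmin(pmax(pos[, 1], 0), arena[1])
      pos[, 2] <- pmin(pmax(pos[, 2], 0), arena[2])
    }
    positions <- tibble::tibble(
      frame = rep(seq_len(n_frames), each = n_fish),
      individual = rep(seq_len(n_fish), n_frames),
      x = as.vector(t(out[, , 1])),
      y = as.vector(t(out[, , 2]))
    )
    frame_set(positions, fps = params$fps, arena = arena,
              focal_id = focal_id)
  })
}
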