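#' Run a phase-field simulation
#'
#' Integrates the coupled dynamics from `init_state(grid, ic, params)` to
#' `t_end`, saving snapshots, the free energy and total masses every
#' `save_every` time units. The trajectory is deterministic given the
#' seeds in `ic` and `params`.
#'
#' @param grid A `grid_spec`.
#' @param ic An `initial_condition`.
#' @param params A `model_params`.
#' @param t_end Final time (> 0).
#' @param save_every Interval between saved snapshots, in time units.
#' @param steady_stop If `TRUE`, stop early once the relative free-energy
#'   change over the trailing 10 percent of the elapsed run falls below
#'   `steady_tol` (the operational steady-state criterion).
#' @param steady_tol Steady-state tolerance (relative energy change).
#' @param state Optional pre-built `field_state` to start from instead of
#'   `init_state()` (used by fixtures and resumed runs).
#' @return A `pf_trajectory`: list with `snapshots` (list of
#'   `field_state`), `times`, `energy`, `mass_eta`, `mass_chi` (matrix,
#'   one column per species), `clipped_chi`, plus the `grid`, `ic` and
#'   `params` used.
#' @examples
#' \donttest{
#' g <- grid_spec(64, 64)
#' tr <- run_simulation(g, initial_condition(droplet_radius = 14),
#'                      model_params(), t_end = 10, save_every = 5)
#' }
#' @export
run_simulation <- function(grid, ic, params, t_end = 500, save_every = 25,
                           steady_stop = FALSE, steady_tol = 1e-5,
                           state = NULL) {
  if (t_end <= 0) stop("t_end must be positive")
  if (save_every <= 0) stop("save_every must be positive")
  st <- if (is.null(state)) init_state(grid, ic, params) else state
  n_steps <- ceiling(t_end / params$dt)
  save_stride <- max(1L, round(save_every / params$dt))

  times <- st$t
  energy <- free_energy(st, params)
  mass_eta <- field_mass(st$eta, grid)
  mass_chi <- matrix(vapply(st$chi, field_mass, numeric(1), grid = grid),
                     nrow = 1)
  snapshots <- list(st)
  clipped <- numeric(length(st$chi))

  for (i in seq_len(n_steps)) {
    st <- tryCatch(step_state(st, params),
                   error = function(e) stop(sprintf("%s (run failed at step %d)",
                                                    conditionMessage(e), i),
                                            call. = FALSE))
    cl <- attr(st, "clipped_chi")
    if (!is.null(cl) && length(cl)) {
      clipped <- clipped + cl
      tot <- vapply(st$chi, field_mass, numeric(1), grid = grid)
      if (any(clipped > 1e-6 * pmax(tot, .Machine$double.eps)))
        stop(sprintf("chi positivity clipping exceeded 1e-6 of total mass at t = %g; reduce dt",
                     st$t))
    }
    if (i %% save_stride == 0 || i == n_steps) {
      times <- c(times, st$t)
      energy <- c(energy, free_energy(st, params))
      mass_eta <- c(mass_eta, field_mass(st$eta, grid))
      mass_chi <- rbind(mass_chi,
                        vapply(st$chi, field_mass, numeric(1), grid = grid))
      snapshots[[length(snapshots) + 1L]] <- st
      if (steady_stop && length(times) >= 3) {
        t_now <- st$t
        j <- max(which(times <= 0.9 * t_now))
        de <- abs(energy[length(energy)] - energy[j])
        if (j < length(times) && de < steady_tol * abs(energy[length(energy)]))
          break
      }
    }
  }
  traj <- list(snapshots = snapshots, times = times, energy = energy,
               mass_eta = mass_eta, mass_chi = mass_chi,
               clipped_chi = clipped, grid = grid, ic = ic, params = params)
  class(traj) <- "pf_trajectory"
  traj
}

#' @export
print.pf_trajectory <- function(x, ...) {
  cat(sprintf("<pf_trajectory> %d snapshots, t in [%g, %g] on %d x %d grid\n",
              length(x$snapshots), x$times[1], x$times[length(x$times)],
              x$grid$nx, x$grid$ny))
  cat(sprintf("  final energy %.6g; eta mass %.6g\n",
              x$energy[length(x$energy)], x$mass_eta[length(x$mass_eta)]))
  invisible(x)
}

#' Final snapshot of a trajectory
#' @param traj A `pf_trajectory`.
#' @return The last saved `field_state`.
#' @export
final_state <- function(traj) traj$snapshots[[length(traj$snapshots)]]
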