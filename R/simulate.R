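#' Simulation settings
#'
#' Fixed-step integration settings mirroring the system-dynamics runs:
#' start time 0, final time 15, step 0.05, forward Euler (the Vensim PLE
#' default method), with classical RK4 available for verification.
#'
#' @param t_initial start time (model time units).
#' @param t_final end time; must exceed `t_initial`.
#' @param dt step size, `0 < dt <= t_final - t_initial`.
#' @param method `"euler"` or `"rk4"`.
#' @param variant enterprise replicator variant, see [replicator_rate()].
#' @return A list of class `simulation_settings`.
#' @export
simulation_settings <- function(t_initial = 0, t_final = 15, dt = 0.05,
                                method = c("euler", "rk4"),
                                variant = c("as_printed",
                                            "table2_consistent")) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  if (!is.finite(t_initial) || !is.finite(t_final) || t_final <= t_initial)
    stop("need t_final > t_initial", call. = FALSE)
  if (!is.finite(dt) || dt <= 0 || dt > t_final - t_initial)
    stop("need 0 < dt <= t_final - t_initial", call. = FALSE)
  structure(list(t_initial = t_initial, t_final = t_final, dt = dt,
                 method = method, variant = variant),
            class = "simulation_settings")
}

#' Intervention schedule
#'
#' Mid-run policy events applied at step boundaries: `set_value` assigns a
#' coordinate once; `clamp` assigns it and holds it fixed for the rest of
#' the run (e.g. cancelling regulation: clamp `x` at 0).
#'
#' @param time event times within the simulation horizon.
#' @param coordinate `"x"`, `"y"` or `"z"` per event.
#' @param action `"set_value"` or `"clamp"` per event.
#' @param value target proportion in \[0, 1\] per event.
#' @return A data frame of class `intervention_schedule` (zero rows allowed).
#' @examples
#' cancel_regulation <- intervention_schedule(7.5, "x", "clamp", 0)
#' @export
intervention_schedule <- function(time = numeric(), coordinate = character(),
                                  action = character(), value = numeric()) {
  ev <- data.frame(time = as.numeric(time), coordinate = coordinate,
                   action = action, value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (nrow(ev) > 0) {
    stopifnot(all(ev$coordinate %in% c("x", "y", "z")),
              all(ev$action %in% c("set_value", "clamp")),
              all(ev$value >= 0 & ev$value <= 1),
              all(is.finite(ev$time)))
  }
  class(ev) <- c("intervention_schedule", "data.frame")
  ev
}

#' Integrate the replicator system
#'
#' Fixed-step integration of [replicator_field()] from an initial state.
#' After each step every coordinate is clamped to \[0, 1\] (guards against
#' Euler overshoot near corners).  Scheduled interventions are applied at
#' the first step boundary at or after their event time; clamped
#' coordinates are held for the remainder of the run.  The result is
#' deterministic given identical inputs.
#'
#' @param params a [game_parameters()] object.
#' @param initial initial state, a [strategy_state()] or numeric
#'   `c(x, y, z)`.
#' @param settings a [simulation_settings()] object.
#' @param schedule an [intervention_schedule()], or `NULL` for none.
#' @return A data frame of class `game_trajectory` with columns `time`,
#'   `x`, `y`, `z`, and attributes `settings` and `schedule`.
#' @examples
#' traj <- simulate_game(game_parameters(), c(0.1, 0.1, 0.1))
#' tail(traj, 1)   # near the ESS (0, 1, 1)
#' @export
simulate_game <- function(params, initial,
                          settings = simulation_settings(),
                          schedule = NULL) {
  params <- validate_parameters(params)
  if (!inherits(settings, "simulation_settings"))
    stop("settings must come from simulation_settings()", call. = FALSE)
  if (is.null(schedule)) schedule <- intervention_schedule()
  if (!inherits(schedule, "intervention_schedule"))
    stop("schedule must come from intervention_schedule()", call. = FALSE)
  if (nrow(schedule) > 0 &&
      (any(schedule$time < settings$t_initial) ||
       any(schedule$time > settings$t_final)))
    stop("intervention times must lie within the simulation horizon",
         call. = FALSE)

  s <- as.vector(unclass(as_strategy_state(initial)))
  n_steps <- ceiling((settings$t_final - settings$t_initial) /
                       settings$dt - 1e-9)
  times <- settings$t_initial + settings$dt * (0:n_steps)
  states <- matrix(NA_real_, nrow = n_steps + 1, ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  clamped <- c(x = NA_real_, y = NA_real_, z = NA_real_)
  pending <- schedule[order(schedule$time), , drop = FALSE]
  coord_idx <- c(x = 1L, y = 2L, z = 3L)

  apply_events <- function(s, t_now) {
    while (nrow(pending) > 0 && pending$time[1] <= t_now + 1e-12) {
      ev <- pending[1, ]
      pending <<- pending[-1, , drop = FALSE]
      s[coord_idx[[ev$coordinate]]] <- ev$value
      if (ev$action == "clamp") clamped[[ev$coordinate]] <<- ev$value
    }
    s
  }
  hold <- function(s) {
    for (cn in c("x", "y", "z"))
      if (!is.na(clamped[[cn]])) s[coord_idx[[cn]]] <- clamped[[cn]]
    s
  }
  # inlined field: params validated once, no per-step re-validation
  pv <- unclass(params)
  f <- function(s) {
    sc <- pmin(pmax(s, 0), 1)
    ss <- c(x = sc[[1]], y = sc[[2]], z = sc[[3]])
    c(ss[[1]] * (1 - ss[[1]]) * rate_factor(pv, ss, "government",
                                            settings$variant),
      ss[[2]] * (1 - ss[[2]]) * rate_factor(pv, ss, "enterprise",
                                            settings$variant),
      ss[[3]] * (1 - ss[[3]]) * rate_factor(pv, ss, "institution",
                                            settings$variant))
  }

  s <- hold(apply_events(s, times[1]))
  states[1, ] <- s
  for (k in seq_len(n_steps)) {
    h <- settings$dt
    if (settings$method == "euler") {
      s <- s + h * f(s)
    } else {
      k1 <- f(s); k2 <- f(s + h / 2 * k1); k3 <- f(s + h / 2 * k2)
      k4 <- f(s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(s)))
      stop(sprintf("non-finite state at step %d (t = %g)", k, times[k + 1]),
           call. = FALSE)
    s <- pmin(pmax(s, 0), 1)
    s <- hold(apply_events(s, times[k + 1]))
    states[k + 1, ] <- s
  }
  traj <- data.frame(time = times, x = states[, "x"], y = states[, "y"],
                     z = states[, "z"])
  attr(traj, "settings") <- settings
  attr(traj, "schedule") <- schedule
  class(traj) <- c("game_trajectory", "data.frame")
  traj
}

#' Detect convergence to a pure-strategy corner
#'
#' Finds the corner of the unit cube whose max-coordinate distance to the
#' trajectory stays below `tol` over the final `dwell` steps.
#'
#' @param traj a [simulate_game()] trajectory.
#' @param tol distance tolerance (> 0); default 0.01, far below the unit
#'   inter-corner distance.
#' @param dwell number of consecutive final steps required (>= 1).
#' @return The limiting corner as a [strategy_state()], or `NULL` if no
#'   corner qualifies.
#' @export
detect_convergence <- function(traj, tol = 0.01, dwell = 20) {
  stopifnot(tol > 0, dwell >= 1)
  if (!is.data.frame(traj) || nrow(traj) == 0)
    stop("empty trajectory", call. = FALSE)
  n <- nrow(traj)
  tailrows <- as.matrix(traj[max(1, n - dwell + 1):n, c("x", "y", "z")])
  for (i in seq_len(nrow(PURE_CORNERS))) {
    corner <- PURE_CORNERS[i, ]
    dists <- apply(abs(sweep(tailrows, 2, corner)), 1, max)
    if (all(dists < tol))
      return(strategy_state(corner[["x"]], corner[["y"]], corner[["z"]]))
  }
  NULL
}

#' First global maximum of a trajectory coordinate
#'
#' Used to verify rise-then-fall shapes, e.g. the regulation proportion
#' peaking before the system settles at the deregulation ESS.
#'
#' @param traj a [simulate_game()] trajectory.
#' @param coordinate `"x"`, `"y"` or `"z"`.
#' @return A list with `time` and `value` of the first global maximum.
#' @export
peak_time <- function(traj, coordinate = c("x", "y", "z")) {
  coordinate <- match.arg(coordinate)
  if (!is.data.frame(traj) || nrow(traj) == 0)
    stop("empty trajectory", call. = FALSE)
  v <- traj[[coordinate]]
  i <- which.max(v)  # first index attaining the maximum
  list(time = traj$time[i], value = v[i])
}

#' Write a trajectory as CSV
#'
#' Plain CSV with header `time,x,y,z`, one row per step, full float
#' precision.
#'
#' @param traj a [simulate_game()] trajectory.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[, c("time", "x", "y", "z")]
  lines <- c("time,x,y,z",
             sprintf("%.17g,%.17g,%.17g,%.17g", df$time, df$x, df$y, df$z))
  writeLines(lines, path)
  invisible(path)
}
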