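#' Baseline scenario
#'
#' The packaged calibration of the Chinese mask market: parameters
#' R=0.8, H=1.8, GC=2, GH=0.2, P=1, C=0.5, CG=0.05, CS=0.3, d=0.05, rc=2,
#' f1=0.1, f2=0.2, q=1, alpha=1.5, beta=1.5; initial state (0.1, 0.1, 0.1);
#' default simulation settings (Euler, t in \[0, 15\], dt = 0.05); empty
#' intervention schedule.  Under this calibration the unique ESS is
#' (0, 1, 1): deregulation, increased EFM production, EFM use.
#'
#' @return A list of class `game_scenario` with components `name`,
#'   `params`, `initial`, `settings`, `schedule`.
#' @export
baseline_scenario <- function() {
  scenario(name = "baseline", params = game_parameters(),
           initial = strategy_state(0.1, 0.1, 0.1))
}

#' @rdname baseline_scenario
#' @param name scenario label.
#' @param params a [game_parameters()] object.
#' @param initial a [strategy_state()].
#' @param settings a [simulation_settings()].
#' @param schedule an [intervention_schedule()].
#' @export
scenario <- function(name, params = game_parameters(),
                     initial = strategy_state(0.1, 0.1, 0.1),
                     settings = simulation_settings(),
                     schedule = intervention_schedule()) {
  params <- validate_parameters(params)
  initial <- as_strategy_state(initial)
  stopifnot(inherits(settings, "simulation_settings"),
            inherits(schedule, "intervention_schedule"))
  structure(list(name = name, params = params, initial = initial,
                 settings = settings, schedule = schedule),
            class = "game_scenario")
}

#' Parameter-sweep presets
#'
#' Named sweep specifications emulating the published simulation
#' experiments.  Level values for `alpha`, `beta`, `H` and `f2` are not
#' printed in the source figures; the presets use the artifact convention
#' of half, baseline, and double the baseline value.  The `rc_levels`
#' preset spans large positive, normal positive, zero, large negative and
#' normal negative cost benefits; `rc_GH_grid` crosses negative `rc` with
#' use-subsidy levels to probe whether subsidies can rescue adoption when
#' reuse is costly.
#'
#' @return A named list of sweep specs, each a list with `name`,
#'   `parameter` (a parameter field, `"initial_x"`, or a character vector
#'   of fields for grids), `values` (vector, or data frame for grids) and
#'   `base` (the [baseline_scenario()]).
#' @export
figure_presets <- function() {
  base <- baseline_scenario()
  spec <- function(name, parameter, values)
    list(name = name, parameter = parameter, values = values, base = base)
  list(
    regulation_comparison = spec("regulation_comparison", "initial_x",
                                 c(0, 0.1)),
    initial_x = spec("initial_x", "initial_x", c(0.1, 0.5)),
    alpha_levels = spec("alpha_levels", "alpha", c(0.75, 1.5, 3)),
    beta_levels = spec("beta_levels", "beta", c(0.75, 1.5, 3)),
    H_levels = spec("H_levels", "H", c(0.9, 1.8, 3.6)),
    rc_levels = spec("rc_levels", "rc", c(4, 2, 0, -4, -2)),
    rc_GH_grid = spec("rc_GH_grid", c("rc", "GH"),
                      expand.grid(rc = c(-2, -4), GH = c(0.2, 1, 2))),
    f2_levels = spec("f2_levels", "f2", c(0.1, 0.2, 0.4))
  )
}

#' Materialise a sweep spec into scenarios
#'
#' @param spec one element of [figure_presets()], or a compatible list.
#' @return A list of `game_scenario` objects, one per level, named by
#'   level label.
#' @export
sweep_scenarios <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$parameter))
  base <- if (is.null(spec$base)) baseline_scenario() else spec$base
  if (is.data.frame(spec$values)) {
    levels <- spec$values
    if (nrow(levels) == 0) stop("empty sweep values", call. = FALSE)
    labs <- apply(levels, 1, function(r)
      paste(sprintf("%s=%g", names(levels), r), collapse = ","))
  } else {
    if (length(spec$values) == 0) stop("empty sweep values", call. = FALSE)
    levels <- data.frame(v = spec$values)
    names(levels) <- if (identical(spec$parameter, "initial_x")) "initial_x"
                     else spec$parameter
    labs <- sprintf("%s=%g", names(levels), spec$values)
  }
  out <- lapply(seq_len(nrow(levels)), function(i) {
    params <- unclass(base$params)
    initial <- base$initial
    for (field in names(levels)) {
      val <- levels[i, field]
      if (field == "initial_x") {
        initial <- strategy_state(val, initial[["y"]], initial[["z"]])
      } else {
        params[[field]] <- val
      }
    }
    class(params) <- "game_parameters"
    scenario(name = sprintf("%s[%s]", spec$name, labs[i]),
             params = validate_parameters(params), initial = initial,
             settings = base$settings, schedule = base$schedule)
  })
  names(out) <- labs
  out
}

#' Run a sweep
#'
#' Integrates every scenario of a sweep spec and stacks the trajectories.
#'
#' @param spec a sweep spec (see [figure_presets()]).
#' @param tol,dwell convergence-detection settings, see
#'   [detect_convergence()].
#' @return A list with `trajectories` (long data frame
#'   `scenario, level, time, x, y, z`) and `summary` (one row per level:
#'   final state and detected limit corner, `NA`s when none).
#' @export
run_sweep <- function(spec, tol = 0.01, dwell = 20) {
  scens <- sweep_scenarios(spec)
  long <- list(); summ <- list()
  for (lab in names(scens)) {
    sc <- scens[[lab]]
    traj <- simulate_game(sc$params, sc$initial, sc$settings, sc$schedule)
    long[[lab]] <- data.frame(scenario = sc$name, level = lab,
                              as.data.frame(traj))
    lim <- detect_convergence(traj, tol = tol, dwell = dwell)
    fin <- traj[nrow(traj), ]
    summ[[lab]] <- data.frame(
      scenario = sc$name, level = lab,
      final_x = fin$x, final_y = fin$y, final_z = fin$z,
      limit_x = if (is.null(lim)) NA_real_ else lim[["x"]],
      limit_y = if (is.null(lim)) NA_real_ else lim[["y"]],
      limit_z = if (is.null(lim)) NA_real_ else lim[["z"]],
      converged = !is.null(lim))
  }
  list(trajectories = do.call(rbind, c(long, make.row.names = FALSE)),
       summary = do.call(rbind, c(summ, make.row.names = FALSE)))
}

# Default sampling ranges: uniform within +/-50% of the baseline value;
# rc additionally allowed down to minus its baseline.
default_parameter_ranges <- function() {
  base <- unclass(game_parameters())
  lo <- base * 0.5
  hi <- base * 1.5
  lo[["rc"]] <- -base[["rc"]]
  Map(c, lo, hi)
}

#' Seeded random parameter sets
#'
#' Draws a reproducible random parameter set for property testing: each
#' field uniform within +/-50% of its baseline value, except `rc`, which
#' ranges from minus the baseline to 1.5x the baseline (reuse may be
#' costly).  Custom ranges may narrow or widen any field subject to the
#' sign rules of [validate_parameters()].
#'
#' @param seed integer seed; identical seeds give identical draws.  The
#'   draw uses a private RNG state and does not disturb the session RNG.
#' @param ranges optional named list of `c(lower, upper)` per field;
#'   defaults as above.
#' @return A validated [game_parameters()] object.
#' @export
random_parameters <- function(seed, ranges = NULL) {
  if (is.null(ranges)) ranges <- default_parameter_ranges()
  bad <- names(ranges)[!vapply(ranges, function(r)
    length(r) == 2 && all(is.finite(r)) && r[1] <= r[2], TRUE)]
  if (length(bad) > 0)
    stop("invalid range for: ", paste(bad, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(ranges), PARAMETER_FIELDS)
  if (length(extra) > 0)
    stop("unknown field in ranges: ", paste(extra, collapse = ", "),
         call. = FALSE)
  full <- default_parameter_ranges()
  full[names(ranges)] <- ranges
  vals <- withr_seed(seed, function()
    vapply(PARAMETER_FIELDS,
           function(f) stats::runif(1, full[[f]][1], full[[f]][2]),
           numeric(1)))
  p <- vals
  class(p) <- "game_parameters"
  validate_parameters(p)
  p
}

# Run fn under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Read or write a scenario file
#'
#' Scenarios round-trip through JSON: the flat parameter block of
#' [write_parameters()] extended with `initial`, `settings` and `schedule`
#' blocks.
#'
#' @param path JSON file path.
#' @return [read_scenario()]: a `game_scenario`; [write_scenario()]:
#'   `path`, invisibly.
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- validate_parameters(unlist(obj$params))
  initial <- strategy_state(obj$initial$x, obj$initial$y, obj$initial$z)
  st <- obj$settings
  settings <- simulation_settings(st$t_initial, st$t_final, st$dt,
                                  st$method, st$variant)
  schedule <- if (is.null(obj$schedule) || length(obj$schedule) == 0) {
    intervention_schedule()
  } else {
    sch <- as.data.frame(obj$schedule)
    intervention_schedule(sch$time, sch$coordinate, sch$action, sch$value)
  }
  scenario(name = obj$name %||% "scenario", params = params,
           initial = initial, settings = settings, schedule = schedule)
}

#' @rdname read_scenario
#' @param sc a `game_scenario`.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "game_scenario"))
  obj <- list(
    name = sc$name,
    params = as.list(unclass(sc$params)),
    initial = as.list(unclass(sc$initial)),
    settings = unclass(sc$settings),
    schedule = as.data.frame(unclass(sc$schedule))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
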