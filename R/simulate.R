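#' Right-hand side of the compartmental system
#'
#' Evaluates the derivative of the full state vector (compartments plus
#' cumulative-flow counters) at time `t`: births into the youngest band split
#' by the sex ratio at birth, aging between adjacent bands, background
#' mortality with the DM excess-mortality multiplier, risk-factor
#' onset/reversal flows (obesity onset scaled by the calendar trend), and
#' T2DM incidence flows into the same-profile DM compartment. There is no
#' DM-to-nonDM flow.
#'
#' @param t Calendar year.
#' @param state Numeric state vector (length `32 B + 4 + 2 B`).
#' @param params A `t2dm_params` object.
#' @return Derivative vector of the same length.
#' @export
rhs <- function(t, state, params) {
  rhs_cpp(t, state, .c_parms(params))
}

# deSolve-style wrapper: parms is the pre-flattened C list
.rhs_desolve <- function(t, y, parms) list(rhs_cpp(t, y, parms))

#' Integrate the model over calendar time
#'
#' Integrates the compartmental system with an adaptive explicit Runge-Kutta
#' scheme (Dormand-Prince 5(4)), recording states at every requested output
#' year. Flow counters are cumulative since `t0`; the number of new T2DM
#' cases credited to year `Y` is the counter difference between `Y + 1` and
#' `Y`.
#'
#' @param params A `t2dm_params` object.
#' @param t0,t1 Start and end years (default 1950-2050).
#' @param output_years Years at which states are recorded (default every
#'   whole year from `t0` to `t1`).
#' @param state0 Optional initial state (default [initial_state()]).
#' @param rtol,atol Relative / absolute integration tolerances (defaults
#'   `1e-8` and `1e-6` persons).
#' @param engine `"native"` (compiled Dormand-Prince, the default) or
#'   `"desolve"` (\pkg{deSolve} `lsoda` on the identical right-hand side,
#'   used as an independent cross-check).
#' @return A `t2dm_trajectory`: list with `years`, `state` (matrix years x
#'   states), `space`, `params`, and accessors below. All compartments, and
#'   the cumulative births/deaths/new-case counters, are retained.
#' @export
simulate_model <- function(params, t0 = 1950, t1 = 2050, output_years = NULL,
                     state0 = NULL, rtol = 1e-8, atol = 1e-6,
                     engine = c("native", "desolve")) {
  validate_params(params)
  engine <- match.arg(engine)
  if (t0 >= t1) stop("`t0` must be earlier than `t1`", call. = FALSE)
  if (is.null(output_years)) output_years <- seq(floor(t0), floor(t1))
  output_years <- sort(unique(c(t0, output_years[output_years >= t0 &
                                                   output_years <= t1])))
  space <- build_state_space(params$n_age_bands)
  if (is.null(state0)) state0 <- initial_state(params, space)
  stopifnot(length(state0) == 32L * space$n_age_bands + 4L +
              2L * space$n_age_bands)
  parms <- .c_parms(params)
  if (engine == "native") {
    st <- integrate_cpp(as.numeric(state0), as.numeric(output_years), parms,
                        rtol, atol)
  } else {
    sol <- deSolve::ode(y = as.numeric(state0), times = as.numeric(output_years),
                        func = .rhs_desolve, parms = parms, method = "lsoda",
                        rtol = rtol, atol = atol)
    st <- unname(sol[, -1, drop = FALSE])
  }
  structure(
    list(years = output_years, state = st, space = space, params = params),
    class = "t2dm_trajectory"
  )
}

#' @export
print.t2dm_trajectory <- function(x, ...) {
  cat(sprintf("<t2dm_trajectory> %d output years (%g-%g), %d compartments\n",
              length(x$years), min(x$years), max(x$years),
              x$space$n_compartments))
  invisible(x)
}

.year_row <- function(traj, year) {
  i <- match(year, traj$years)
  if (is.na(i)) stop(sprintf("year %s is not in the trajectory", year),
                     call. = FALSE)
  i
}

#' Compartment occupancies at a year
#'
#' @param traj A `t2dm_trajectory`.
#' @param year An output year of the trajectory.
#' @return Array `[status, profile, band, sex]` of persons.
#' @export
occupancy <- function(traj, year) {
  .state_array(traj$space, traj$state[.year_row(traj, year), ])
}

#' Cumulative flow counters at a year
#'
#' @param traj A `t2dm_trajectory`.
#' @param year An output year.
#' @return List with `births` and `deaths` (named per sex, persons since
#'   `t0`) and `new_cases` (matrix sex x band, cumulative incident T2DM).
#' @export
cumulative_flows <- function(traj, year) {
  B <- traj$space$n_age_bands
  row <- traj$state[.year_row(traj, year), ]
  aux <- row[(32L * B + 1L):length(row)]
  list(
    births = setNames(aux[1:2], .sexes),
    deaths = setNames(aux[3:4], .sexes),
    new_cases = matrix(aux[-(1:4)], nrow = 2, byrow = TRUE,
                       dimnames = list(.sexes, NULL))
  )
}

#' Total population at a year
#'
#' @inheritParams occupancy
#' @param sex `"male"`, `"female"` or `"both"`.
#' @return Persons.
#' @export
total_population <- function(traj, year, sex = "both") {
  occ <- occupancy(traj, year)
  s <- if (sex == "both") .sexes else sex
  sum(occ[, , , s, drop = FALSE])
}
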