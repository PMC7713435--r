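#' Bounded Nelder-Mead simplex minimization
#'
#' Minimizes `f` over a box by running an unconstrained Nelder-Mead simplex
#' (standard reflection/expansion/contraction/shrink coefficients 1, 2, 1/2,
#' 1/2) on transformed coordinates. Each coordinate is mapped from the real
#' line into its bounds through the periodic sinusoidal transform
#' `x = lo + (hi - lo) (sin(u) + 1) / 2`, so `f` is never evaluated outside
#' the box and boundary optima are reachable through transform saturation.
#' Coordinates with `lo == hi` are held fixed.
#'
#' Termination: the spread of function values across the simplex
#' (`max f - min f`) falls below `tol`, or `max_iter` iterations are
#' reached (in which case the best point found is still returned, flagged
#' `converged = FALSE`).
#'
#' @param f Objective: function of a numeric vector, returning a scalar.
#' @param x0 Start point, within bounds.
#' @param lower,upper Bound vectors (finite), recycled to `length(x0)`.
#' @param tol Absolute tolerance on the simplex spread of `f` values
#'   (default `1e-4`).
#' @param max_iter Iteration cap (default `200 * length(x0)`).
#' @return List with `par` (within bounds, exactly), `value`, `iterations`,
#'   `evaluations`, `converged`.
#' @export
#' @examples
#' nelder_mead_bounded(function(x) (x - 0.3)^2, 0.9, 0, 1)$par
nelder_mead_bounded <- function(f, x0, lower, upper, tol = 1e-4,
                                max_iter = NULL) {
  n_all <- length(x0)
  lower <- rep_len(lower, n_all)
  upper <- rep_len(upper, n_all)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("bounds must be finite with lower <= upper", call. = FALSE)
  if (any(x0 < lower | x0 > upper))
    stop("`x0` must lie within the bounds", call. = FALSE)
  free <- which(upper > lower)
  n <- length(free)
  if (is.null(max_iter)) max_iter <- 200L * max(n, 1L)

  to_x <- function(u) {
    x <- x0
    x[free] <- lower[free] +
      (upper[free] - lower[free]) * (sin(u) + 1) / 2
    x
  }
  evals <- 0L
  fu <- function(u) {
    evals <<- evals + 1L
    val <- f(to_x(u))
    if (!is.finite(val)) val <- .Machine$double.xmax
    val
  }

  if (n == 0L) {
    v <- f(x0)
    return(list(par = x0, value = v, iterations = 0L, evaluations = 1L,
                converged = TRUE))
  }

  # inverse transform for the start point (principal branch)
  frac <- (x0[free] - lower[free]) / (upper[free] - lower[free])
  u0 <- asin(pmin(1, pmax(-1, 2 * frac - 1)))

  # initial simplex: perturb each coordinate by a fixed angular step
  step <- 0.25
  simplex <- matrix(rep(u0, n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) simplex[i + 1, i] <- simplex[i + 1, i] + step
  fv <- apply(simplex, 1, fu)

  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]
    fv <- fv[ord]
    if (fv[n + 1] - fv[1] < tol) {
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    centroid <- colMeans(simplex[seq_len(n), , drop = FALSE])
    worst <- simplex[n + 1, ]
    xr <- centroid + (centroid - worst)
    fr <- fu(xr)
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - worst)
      fe <- fu(xe)
      if (fe < fr) {
        simplex[n + 1, ] <- xe; fv[n + 1] <- fe
      } else {
        simplex[n + 1, ] <- xr; fv[n + 1] <- fr
      }
    } else if (fr < fv[n]) {
      simplex[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      if (fr < fv[n + 1]) {
        xc <- centroid + 0.5 * (xr - centroid)
        fc <- fu(xc)
        accept <- fc <= fr
      } else {
        xc <- centroid - 0.5 * (centroid - worst)
        fc <- fu(xc)
        accept <- fc < fv[n + 1]
      }
      if (accept) {
        simplex[n + 1, ] <- xc; fv[n + 1] <- fc
      } else {
        for (i in 2:(n + 1)) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          fv[i] <- fu(simplex[i, ])
        }
      }
    }
  }
  ord <- order(fv)
  best_u <- simplex[ord[1], ]
  list(par = to_x(best_u), value = fv[ord[1]], iterations = iter,
       evaluations = evals, converged = converged)
}
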