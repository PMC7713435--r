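#' Risk-profile definitions
#'
#' The population is stratified by three binary risk factors: obesity,
#' smoking and physical inactivity. Their eight combinations form the risk
#' profiles; the all-`FALSE` profile is "healthy".
#'
#' @return A data frame with one row per profile: `profile` (1-8, bit code
#'   obesity = 1, smoking = 2, inactivity = 4, plus 1), and logical columns
#'   `obese`, `smoker`, `inactive`.
#' @export
#' @examples
#' risk_profiles()
risk_profiles <- function() {
  p <- 0:7
  data.frame(
    profile = p + 1L,
    obese = bitwAnd(p, 1L) > 0L,
    smoker = bitwAnd(p, 2L) > 0L,
    inactive = bitwAnd(p, 4L) > 0L
  )
}

.factors <- c("obesity", "smoking", "inactivity")
.sexes <- c("male", "female")

# bit value of a factor within the profile code
.factor_bit <- c(obesity = 1L, smoking = 2L, inactivity = 4L)

# profiles (1..8) carrying a given factor
.profiles_with <- function(factor) {
  which(bitwAnd(0:7, .factor_bit[[factor]]) > 0L)
}

#' Build the compartmental state space
#'
#' Compartments are the cross of 2 sexes, `n_age_bands` equal-width age bands
#' spanning ages 0-100, 8 risk profiles, and T2DM status (nonDM/DM). With the
#' default 20 five-year bands this yields the 640 coupled state equations of
#' the full model.
#'
#' @param n_age_bands Number of age bands (>= 1); bands have width
#'   `100 / n_age_bands` years.
#' @return An object of class `t2dm_space`: a list with `n_age_bands`,
#'   `band_width`, `n_compartments`, band edges/midpoints, and `index_map`,
#'   a data frame giving the bijection compartment -> state-vector index.
#' @export
#' @examples
#' sp <- build_state_space(20)
#' sp$n_compartments # 640
build_state_space <- function(n_age_bands = 20) {
  if (length(n_age_bands) != 1 || !is.finite(n_age_bands) ||
      n_age_bands < 1 || n_age_bands != round(n_age_bands)) {
    stop("`n_age_bands` must be a positive whole number", call. = FALSE)
  }
  B <- as.integer(n_age_bands)
  w <- 100 / B
  grid <- expand.grid(
    status = c("nonDM", "DM"),
    profile = 1:8,
    band = seq_len(B),
    sex = .sexes,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  grid$index <- seq_len(nrow(grid))
  grid <- grid[, c("sex", "band", "profile", "status", "index")]
  structure(
    list(
      n_age_bands = B,
      band_width = w,
      n_compartments = 32L * B,
      band_lower = (seq_len(B) - 1) * w,
      band_upper = seq_len(B) * w,
      band_mid = (seq_len(B) - 0.5) * w,
      index_map = grid
    ),
    class = "t2dm_space"
  )
}

#' Compartment index within the state vector
#'
#' @param space A `t2dm_space`.
#' @param sex `"male"` or `"female"`.
#' @param band Age band (1-based).
#' @param profile Risk profile code 1-8.
#' @param status `"nonDM"` or `"DM"`.
#' @return Integer position in the state vector (vectorised over arguments).
#' @export
state_index <- function(space, sex, band, profile, status) {
  B <- space$n_age_bands
  s <- match(sex, .sexes)
  d <- match(status, c("nonDM", "DM"))
  stopifnot(!anyNA(s), !anyNA(d), all(band >= 1 & band <= B),
            all(profile >= 1 & profile <= 8))
  (((s - 1L) * B + (band - 1L)) * 8L + (profile - 1L)) * 2L + d
}

#' @export
print.t2dm_space <- function(x, ...) {
  cat(sprintf(
    "<t2dm_space> 2 sexes x %d age bands (width %g y) x 8 profiles x 2 statuses = %d compartments\n",
    x$n_age_bands, x$band_width, x$n_compartments
  ))
  invisible(x)
}

# reshape the main block of a state vector into [sex, band, profile, status]
.state_array <- function(space, y) {
  B <- space$n_age_bands
  array(y[seq_len(32L * B)],
        dim = c(2L, 8L, B, 2L),
        dimnames = list(status = c("nonDM", "DM"), profile = NULL,
                        band = NULL, sex = .sexes))
}
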