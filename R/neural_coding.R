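# Circular-angle utilities and the generic Gaussian-tuned population code.
# Every directional signal in the model (head direction, allocentric and
# egocentric goal direction, egocentric cue direction) is carried by a
# population of units with equally spaced preferred angles and a shared
# Gaussian tuning curve.

#' Wrap an angle into (-180, 180]
#'
#' All angular arithmetic in the package is circular; this fixes the single
#' wrapping convention used throughout (degrees, half-open on the left).
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Angles congruent mod 360, each in (-180, 180].
#' @examples
#' wrap_angle(190)   # -170
#' wrap_angle(-540)  # 180
#' @export
wrap_angle <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("wrap_angle: angle must be finite numeric")
  }
  w <- angle %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Gaussian tuning-curve activation
#'
#' Activation of a unit with preferred direction `preferred` to an input
#' direction, `exp(-d^2 / sigma^2)` with `d` the wrapped circular difference.
#' The raw difference of the textbook form misbehaves for units near the
#' 0/360 seam, so the wrapped difference is used.
#'
#' @param preferred Preferred direction(s), degrees.
#' @param input Input direction, degrees.
#' @param sigma Tuning width, degrees (> 0). The model-wide default is 10.
#' @return Activation(s) in (0, 1]; exactly 1 when `preferred == input`.
#' @export
gaussian_tuning <- function(preferred, input, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("gaussian_tuning: sigma must be a single positive number")
  }
  d <- wrap_angle(preferred - input)
  exp(-d^2 / sigma^2)
}

#' Construct a Gaussian-tuned cell population
#'
#' Unit `i` (1-based) has preferred angle `(i - 1) * 360 / n_units` and raw
#' activity given by the Gaussian tuning curve. No noise or normalization is
#' applied here; see [add_noise_and_normalize()].
#'
#' @param input Encoded direction, degrees.
#' @param sigma Tuning width, degrees.
#' @param n_units Number of units (default 360, i.e. 1 degree spacing).
#' @return A `cell_population`: list with `preferred_angles`, `activities`,
#'   `sigma`.
#' @export
encode_population <- function(input, sigma = 10, n_units = 360L) {
  if (n_units < 1) stop("encode_population: n_units must be >= 1")
  pref <- (seq_len(n_units) - 1) * 360 / n_units
  cell_population(pref, gaussian_tuning(pref, input, sigma), sigma)
}

#' @rdname encode_population
#' @param preferred_angles Preferred angles, degrees.
#' @param activities Unit activities.
#' @export
cell_population <- function(preferred_angles, activities, sigma = 10) {
  if (length(preferred_angles) != length(activities)) {
    stop("cell_population: preferred_angles and activities lengths differ")
  }
  structure(list(preferred_angles = preferred_angles,
                 activities = activities,
                 sigma = sigma),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d units, sigma = %g, peak at %g deg (act %.3f)\n",
              length(x$activities), x$sigma,
              population_peak(x), max(x$activities)))
  invisible(x)
}

#' Noise model for population activity
#'
#' Zero-mean Gaussian perturbation applied unit-wise before normalization.
#' `literal = TRUE` switches to the alternative reading in which the
#' perturbation is centred on the unit's own activity with variance 5; it is
#' kept only for exploration, the zero-mean form is the package default.
#'
#' @param noise_sd Standard deviation (>= 0); default 0.05.
#' @param literal Use the activity-centred, variance-5 form.
#' @export
noise_model <- function(noise_sd = 0.05, literal = FALSE) {
  if (noise_sd < 0) stop("noise_model: noise_sd must be >= 0")
  structure(list(noise_sd = noise_sd, literal = literal), class = "noise_model")
}

#' Perturb a population and normalize it to peak 1
#'
#' Adds unit-wise Gaussian noise, clamps negative activities to zero (firing
#' rates are non-negative), and divides by the population maximum so the most
#' active unit reads exactly 1. With `noise_sd = 0` only the normalization
#' applies. Draws come from the current R RNG stream, so seeding the session
#' seeds the noise.
#'
#' @param pop A `cell_population`.
#' @param noise A `noise_model` (default: no noise).
#' @return The normalized `cell_population`.
#' @export
add_noise_and_normalize <- function(pop, noise = noise_model(0)) {
  a <- pop$activities
  if (noise$literal) {
    a <- a + stats::rnorm(length(a), mean = a, sd = sqrt(5))
  } else if (noise$noise_sd > 0) {
    a <- a + stats::rnorm(length(a), mean = 0, sd = noise$noise_sd)
  }
  a[a < 0] <- 0
  m <- max(a)
  if (m <= 0) {
    stop("add_noise_and_normalize: degenerate population (no positive activity)")
  }
  pop$activities <- a / m
  pop
}

#' Decode the peak direction of a population
#'
#' Preferred angle of the maximally active unit; ties broken toward the
#' lowest preferred angle (lowest index).
#'
#' @param pop A `cell_population`.
#' @return Peak preferred angle, degrees.
#' @export
population_peak <- function(pop) {
  if (length(pop$activities) == 0L) stop("population_peak: empty population")
  pop$preferred_angles[which.max(pop$activities)]
}

#' Activity of the unit nearest a given preferred angle
#'
#' Convenience read-out used by conjunctive cells: the activity of the unit
#' whose preferred angle is circularly closest to `angle`.
#'
#' @param pop A `cell_population`.
#' @param angle Query angle, degrees.
#' @export
population_activity_at <- function(pop, angle) {
  i <- which.min(abs(wrap_angle(pop$preferred_angles - angle)))
  pop$activities[i]
}
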