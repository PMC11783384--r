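#' Glass-pattern geometry constants
#'
#' Square aperture of 7.7 x 7.7 degrees of visual angle, 2.3 x 2.3 arcmin
#' dots at 3% density, and a 16.2 arcmin Glass shift (intra-dipole dot
#' distance). Density is interpreted as (number of dots x dot area) /
#' aperture area, which fixes the dipole count deterministically.
#'
#' @param aperture_deg aperture side length, degrees.
#' @param shift_arcmin distance between the two dots of a dipole, arcmin.
#' @param dot_arcmin dot side length, arcmin.
#' @param density fraction of the aperture area covered by dots.
#' @return a list of class `glass_geometry`.
#' @export
glassGeometry <- function(aperture_deg = 7.7, shift_arcmin = 16.2,
                          dot_arcmin = 2.3, density = 0.03) {
  structure(list(aperture_deg = aperture_deg, shift_arcmin = shift_arcmin,
                 dot_arcmin = dot_arcmin, density = density),
            class = "glass_geometry")
}

#' Number of dipoles implied by a Glass geometry
#'
#' @param geometry a [glassGeometry()].
#' @return integer dipole count, `round(n_dots / 2)` with
#'   `n_dots = density * (aperture / dot)^2`.
#' @export
dipoleCount <- function(geometry = glassGeometry()) {
  n_dots <- geometry$density *
    (geometry$aperture_deg * 60 / geometry$dot_arcmin)^2
  as.integer(round(n_dots / 2))
}

#' Generate a Glass-pattern dipole field for one trial
#'
#' Produces dipole center positions and orientations (geometry only, no
#' rasterization). Signal dipoles are oriented at the local radial
#' direction plus the spiral angle (0 deg = radial pattern, 90 deg =
#' concentric); noise dipoles get independent uniform random orientations.
#' Dipoles whose dots would fall outside the aperture are redrawn, keeping
#' the dipole count exact. A fresh pattern is generated per call.
#'
#' @param angle_deg spiral angle in [0, 90] degrees.
#' @param signal_prop fraction of signal dipoles.
#' @param geometry a [glassGeometry()].
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `dipole_set`: data frame `dipoles` with
#'   columns `x`, `y` (center, degrees from aperture center), `orientation`
#'   (degrees), `is_signal`, plus the geometry and spiral angle.
#' @export
generatePattern <- function(angle_deg, signal_prop = 0.6,
                            geometry = glassGeometry(), seed = NULL) {
  if (length(angle_deg) != 1 || !is.finite(angle_deg) || angle_deg < 0 ||
      angle_deg > 90) {
    stop_config("spiral angle must be a finite value in [0, 90] degrees")
  }
  if (signal_prop < 0 || signal_prop > 1) {
    stop_config("signal_prop must lie in [0, 1]")
  }
  gen <- function() {
    n <- dipoleCount(geometry)
    n_signal <- round(signal_prop * n)
    half <- geometry$aperture_deg / 2
    shift_deg <- geometry$shift_arcmin / 60
    xs <- numeric(n); ys <- numeric(n); ors <- numeric(n)
    is_signal <- c(rep(TRUE, n_signal), rep(FALSE, n - n_signal))
    for (i in seq_len(n)) {
      repeat {
        x <- runif(1, -half, half)
        y <- runif(1, -half, half)
        th <- if (is_signal[i]) {
          atan2(y, x) * 180 / pi + angle_deg
        } else {
          runif(1, 0, 180)
        }
        dx <- cos(th * pi / 180) * shift_deg / 2
        dy <- sin(th * pi / 180) * shift_deg / 2
        if (abs(x + dx) <= half && abs(x - dx) <= half &&
            abs(y + dy) <= half && abs(y - dy) <= half) {
          xs[i] <- x; ys[i] <- y; ors[i] <- th %% 180
          break
        }
      }
    }
    data.frame(x = xs, y = ys, orientation = ors, is_signal = is_signal)
  }
  dip <- if (is.null(seed)) gen() else with_seed(seed, gen())
  structure(list(dipoles = dip, geometry = geometry, angle_deg = angle_deg,
                 signal_prop = signal_prop),
            class = "dipole_set")
}

#' Dot coordinates of a dipole set
#'
#' Expands each dipole into its two dots, placed `shift_arcmin` apart along
#' the dipole orientation and centered on the dipole position.
#'
#' @param pattern a `dipole_set` from [generatePattern()].
#' @return data frame with columns `dipole`, `x`, `y`, `is_signal`.
#' @export
dipoleDots <- function(pattern) {
  stopifnot(inherits(pattern, "dipole_set"))
  d <- pattern$dipoles
  shift_deg <- pattern$geometry$shift_arcmin / 60
  dx <- cos(d$orientation * pi / 180) * shift_deg / 2
  dy <- sin(d$orientation * pi / 180) * shift_deg / 2
  data.frame(dipole = rep(seq_len(nrow(d)), 2),
             x = c(d$x + dx, d$x - dx), y = c(d$y + dy, d$y - dy),
             is_signal = rep(d$is_signal, 2))
}

#' Export a dipole set as a plain-text coordinate table
#'
#' @param pattern a `dipole_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "dipole_set"))
  write.csv(pattern$dipoles, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.dipole_set <- function(x, ...) {
  cat(sprintf(
    "Glass pattern: %d dipoles, spiral angle %.1f deg, %.0f%% signal\n",
    nrow(x$dipoles), x$angle_deg, 100 * x$signal_prop))
  invisible(x)
}
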