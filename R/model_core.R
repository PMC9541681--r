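#' @useDynLib drivewave, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois rnorm runif rbinom lm glm coef uniroot median
#'   quantile sd binomial aggregate
#' @importFrom utils write.csv read.csv write.table
NULL

INV_SQRT_2PI <- 1 / sqrt(2 * pi)

DRIVE_SYSTEMS <- c("X_SHREDDER", "W_SHREDDER", "NONE")

#' Scenario configuration
#'
#' Bundles every parameter of one simulated scenario: the drive system, the
#' demographic parameters of the Beverton-Holt / Gaussian-kernel model, the
#' landscape, the introduction scheme and the stopping rules.
#'
#' @param drive_system one of `"X_SHREDDER"` (driving-Y on an XY system),
#'   `"W_SHREDDER"` (Z-linked on a ZW system) or `"NONE"` (wild-type control).
#' @param R maximum female fecundity (expected offspring per female at zero
#'   density). Must be >= 2 so the density-response coefficient is
#'   non-negative.
#' @param sigma dispersal scale: offspring displacements are Normal(0, sigma^2),
#'   so sigma is the root-mean-square dispersal distance (spatial units).
#' @param N_star equilibrium density per spatial unit (default 5).
#' @param c shredding efficiency in `[0, 1]`; 1 is the ideal drive (default).
#' @param landscape_length extent of the bounded 1D landscape (default 2500).
#' @param wt_init_range interval initially occupied by wild-types
#'   (default `c(250, 1250)`).
#' @param intro_fraction drive carriers introduced as a fraction of the initial
#'   wild-type count (default 0.01).
#' @param intro_position release point of the drive carriers (default 250, the
#'   left edge of the initial wild-type block).
#' @param intro_scatter if `TRUE`, scatter the introduced carriers uniformly
#'   over `wt_init_range` instead of releasing them at a point. Useful for
#'   near-panmictic comparisons with the deterministic recursions.
#' @param mate_radius mating neighbourhood radius (fixed at 3 spatial units in
#'   all published scenarios).
#' @param max_generations stopping horizon (default 1000).
#' @param post_loss_generations extra generations simulated after the drive
#'   allele is lost (default 10).
#' @param seed optional RNG seed applied by [run_simulation()].
#'
#' @return an object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(drive_system = c("X_SHREDDER", "W_SHREDDER", "NONE"),
                            R = 6,
                            sigma = 10,
                            N_star = 5,
                            c = 1,
                            landscape_length = 2500,
                            wt_init_range = c(250, 1250),
                            intro_fraction = 0.01,
                            intro_position = 250,
                            intro_scatter = FALSE,
                            mate_radius = 3,
                            max_generations = 1000,
                            post_loss_generations = 10,
                            seed = NULL) {
  drive_system <- match.arg(drive_system)
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R))
  if (R < 2) {
    stop("R must be >= 2: the density-response coefficient a = (R - 2)/(2 N*) ",
         "must be non-negative", call. = FALSE)
  }
  stopifnot(
    is.numeric(sigma), length(sigma) == 1L, sigma > 0,
    is.numeric(N_star), length(N_star) == 1L, N_star > 0,
    is.numeric(c), length(c) == 1L, c >= 0, c <= 1,
    is.numeric(landscape_length), landscape_length > 0,
    is.numeric(wt_init_range), length(wt_init_range) == 2L,
    is.numeric(intro_fraction), intro_fraction >= 0,
    is.numeric(mate_radius), mate_radius > 0,
    max_generations >= 1, post_loss_generations >= 0
  )
  wt_init_range <- sort(wt_init_range)
  if (wt_init_range[1] < 0 || wt_init_range[2] > landscape_length) {
    stop("wt_init_range must lie within [0, landscape_length]", call. = FALSE)
  }
  if (intro_position < 0 || intro_position > landscape_length) {
    stop("intro_position must lie within [0, landscape_length]", call. = FALSE)
  }
  structure(
    list(
      drive_system = drive_system,
      R = R,
      sigma = sigma,
      N_star = N_star,
      c = c,
      landscape_length = landscape_length,
      wt_init_range = wt_init_range,
      intro_fraction = intro_fraction,
      intro_position = intro_position,
      intro_scatter = isTRUE(intro_scatter),
      mate_radius = mate_radius,
      max_generations = as.integer(max_generations),
      post_loss_generations = as.integer(post_loss_generations),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  drive system : %s (c = %g)\n", x$drive_system, x$c))
  cat(sprintf("  R = %g, sigma = %g, N* = %g\n", x$R, x$sigma, x$N_star))
  cat(sprintf("  landscape [0, %g], WT init [%g, %g]\n",
              x$landscape_length, x$wt_init_range[1], x$wt_init_range[2]))
  cat(sprintf("  introduction: %g%% of WT at x = %g%s\n",
              100 * x$intro_fraction, x$intro_position,
              if (x$intro_scatter) " (scattered)" else ""))
  cat(sprintf("  stop: %d generations max, +%d after drive loss\n",
              x$max_generations, x$post_loss_generations))
  invisible(x)
}

#' Read scenario configurations from a YAML file
#'
#' The file holds either a single mapping of `scenario_config` fields or a
#' sequence of such mappings; unspecified fields take the package defaults.
#'
#' @param path path to a YAML file.
#' @return a list of `scenario_config` objects.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(names(raw))) raw <- list(raw)
  lapply(raw, function(block) do.call(scenario_config, block))
}

#' Local density experienced at a point
#'
#' Every individual spreads a unit of density over space as a standard normal
#' kernel; the density at a focal location is the sum of kernel contributions
#' of all supplied positions. If the focal individual's own position is among
#' `positions`, its own term (1/sqrt(2*pi)) is part of the sum; callers that
#' want a neighbours-only competition density subtract that constant.
#' Contributions from positions more than 6 units away (< 1e-8 each) are
#' dropped for speed.
#'
#' @param focal_x numeric vector of focal locations.
#' @param positions numeric vector of individual positions (may be empty).
#' @return numeric vector of densities (individuals-equivalent), same length
#'   as `focal_x`.
#' @export
local_density <- function(focal_x, positions) {
  stopifnot(is.numeric(focal_x))
  if (length(positions) == 0L) return(numeric(length(focal_x)))
  kernel_density_sorted(as.numeric(focal_x), sort(as.numeric(positions)))
}

#' Beverton-Holt density-response coefficient
#'
#' `a = (R - 2) / (2 N*)`, chosen so that a female at the equilibrium density
#' `N*` expects exactly 2 offspring (replacement, given an equal sex ratio).
#'
#' @param R maximum female fecundity (>= 2).
#' @param N_star equilibrium density per spatial unit (> 0).
#' @return the coefficient `a` (per individuals-equivalent), >= 0.
#' @export
density_response_coefficient <- function(R, N_star) {
  stopifnot(is.numeric(R), is.numeric(N_star), N_star > 0)
  if (any(R < 2)) stop("R must be >= 2", call. = FALSE)
  (R - 2) / (2 * N_star)
}

#' Expected brood size under Beverton-Holt regulation
#'
#' @param N_i local density experienced by the mother.
#' @param R maximum female fecundity.
#' @param a density-response coefficient (see
#'   [density_response_coefficient()]).
#' @return expected offspring count `R / (1 + a * N_i)`.
#' @export
expected_offspring <- function(N_i, R, a) {
  if (any(N_i < 0)) stop("local density must be non-negative", call. = FALSE)
  R / (1 + a * N_i)
}

#' Realized brood size
#'
#' A Poisson draw around the Beverton-Holt expectation. Uses R's global RNG.
#'
#' @param expectation expected offspring count(s), >= 0.
#' @return non-negative integer vector of the same length.
#' @export
draw_offspring_count <- function(expectation) {
  stopifnot(all(expectation >= 0))
  rpois(length(expectation), expectation)
}
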