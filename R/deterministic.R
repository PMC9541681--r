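# Aspatial recursions and Fisher-KPP wave-speed theory for the two
# sex-distorter drives. All functions are pure; frequencies q and shredding
# efficiencies c live in [0, 1].

check_qc <- function(q, c) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  if (any(c < 0 | c > 1)) stop("c must lie in [0, 1]", call. = FALSE)
}

#' Deterministic one-generation drive-frequency recursion
#'
#' W-shredder: `q' = (8q - 3cq - cq^2) / (8 - 4c)`;
#' X-shredder: `q' = 2q / (2 - c + cq)`.
#' Both fix q = 0 and q = 1 and are strictly increasing in q for c > 0; the
#' X-shredder gains frequency at least as fast as the W-shredder everywhere.
#'
#' @param q drive allele frequency in `[0, 1]`.
#' @param c shredding efficiency in `[0, 1]`.
#' @param system `"X_SHREDDER"` or `"W_SHREDDER"`.
#' @return next-generation frequency.
#' @export
next_drive_frequency <- function(q, c, system = c("X_SHREDDER", "W_SHREDDER")) {
  system <- match.arg(system)
  check_qc(q, c)
  if (system == "X_SHREDDER") 2 * q / (2 - c + c * q)
  else (8 * q - 3 * c * q - c * q^2) / (8 - 4 * c)
}

#' Female fraction under sex-ratio distortion
#'
#' `phi = (2 - c - c q) / (4 - 2c)`: one half at c = 0, `(1 - q)/2` at c = 1.
#' The same expression holds for both drive systems.
#'
#' @inheritParams next_drive_frequency
#' @return expected female fraction among offspring.
#' @export
female_fraction <- function(q, c) {
  check_qc(q, c)
  (2 - c - c * q) / (4 - 2 * c)
}

#' Deterministic population-density recursion
#'
#' `N' = N * phi(q, c) * R / (1 + a N)` with `a = (R - 2) / (2 N*)`: Beverton-
#' Holt growth thinned by the female fraction. Without the drive (q = 0,
#' c = 0) the fixed point is `N = N*`.
#'
#' @param N population density (per spatial unit), >= 0.
#' @param q drive allele frequency.
#' @param R maximum female fecundity.
#' @param N_star equilibrium density.
#' @param c shredding efficiency.
#' @return next-generation density.
#' @export
next_population_density <- function(N, q, R, N_star, c) {
  stopifnot(all(N >= 0))
  a <- density_response_coefficient(R, N_star)
  N * female_fraction(q, c) * expected_offspring(N, R, a)
}

#' Intrinsic fitness of the drive
#'
#' The logistic coefficient m of `dq/dt = m q (1 - q)` implied by the
#' recursions (with `dq/dt` identified with the per-generation change):
#' W-shredder `m = c / (8 - 4c)` (frequency-independent); X-shredder
#' `m = c / (2 - c + cq)`.
#'
#' @inheritParams next_drive_frequency
#' @return m, per generation.
#' @export
intrinsic_fitness <- function(q, c, system = c("X_SHREDDER", "W_SHREDDER")) {
  system <- match.arg(system)
  check_qc(q, c)
  if (system == "X_SHREDDER") c / (2 - c + c * q)
  else rep(c / (8 - 4 * c), length.out = max(length(q), 1L))
}

#' Fisher-KPP wild-type wave speed
#'
#' `v = 2 sqrt(D r)` for a population diffusing with coefficient D and growing
#' at low-density rate r.
#'
#' @param D diffusion coefficient (spatial units^2 per generation), >= 0.
#' @param r intrinsic low-density growth rate (per generation), >= 0.
#' @return asymptotic spreading speed.
#' @export
wt_wave_speed <- function(D, r) {
  if (any(D < 0) || any(r < 0)) {
    stop("D and r must be non-negative", call. = FALSE)
  }
  2 * sqrt(D * r)
}

#' Upper bound on the drive wave speed
#'
#' `v = 2 sqrt(D m)` with m the intrinsic drive fitness at the wave front
#' (q ~ 0). This ignores advection (the asymmetric gene flow caused by
#' suppression), so it is an upper bound. At c = 1 it is `sqrt(D)` for the
#' W-shredder and `2 sqrt(D)` for the X-shredder.
#'
#' @param D diffusion coefficient, >= 0.
#' @param c shredding efficiency.
#' @param system drive system.
#' @return upper-bound wave speed.
#' @export
drive_wave_speed_bound <- function(D, c = 1,
                                   system = c("X_SHREDDER", "W_SHREDDER")) {
  system <- match.arg(system)
  if (any(D < 0)) stop("D must be non-negative", call. = FALSE)
  2 * sqrt(D * intrinsic_fitness(0, c, system))
}

#' Map maximum fecundity to the low-density growth rate
#'
#' With an unskewed sex ratio (phi = 1/2) and no density regulation
#' (b = R_max), per-capita growth over one generation is `phi * b`, so
#' `r = R_max / 2 - 1`. Negative values (declining populations) are allowed.
#'
#' @param R_max maximum female fecundity, >= 0.
#' @return r, per generation.
#' @export
rmax_to_growth_rate <- function(R_max) {
  stopifnot(all(R_max >= 0))
  R_max / 2 - 1
}

#' Critical fecundity above which wild-types outrun the drive
#'
#' Solves `rmax_to_growth_rate(R) = intrinsic_fitness(0, c, system)` for R:
#' above this fecundity the wild-type wave speed `2 sqrt(D r)` exceeds the
#' drive's bound `2 sqrt(D m)` (the common factor D cancels). At c = 1 the
#' thresholds are 2.5 (W-shredder) and 4 (X-shredder).
#'
#' @param system drive system.
#' @param c shredding efficiency (> 0 for a finite threshold).
#' @return the critical maximum female fecundity.
#' @export
critical_fecundity <- function(system = c("X_SHREDDER", "W_SHREDDER"), c = 1) {
  system <- match.arg(system)
  stopifnot(c > 0, c <= 1)
  m0 <- intrinsic_fitness(0, c, system)
  uniroot(function(R) rmax_to_growth_rate(R) - m0,
          interval = c(2, 2 + 2 * (m0 + 1)), tol = 1e-12)$root
}

#' Iterate the coupled frequency/density recursions
#'
#' @param q0 initial drive frequency.
#' @param N0 initial density (per spatial unit).
#' @param R,N_star,c model parameters.
#' @param system drive system.
#' @param generations number of steps.
#' @return data frame with columns `generation`, `q`, `N`.
#' @export
iterate_recursion <- function(q0, N0, R, N_star, c,
                              system = c("X_SHREDDER", "W_SHREDDER"),
                              generations = 100) {
  system <- match.arg(system)
  check_qc(q0, c)
  q <- numeric(generations + 1)
  N <- numeric(generations + 1)
  q[1] <- q0
  N[1] <- N0
  for (t in seq_len(generations)) {
    N[t + 1] <- next_population_density(N[t], q[t], R, N_star, c)
    q[t + 1] <- next_drive_frequency(q[t], c, system)
  }
  data.frame(generation = 0:generations, q = q, N = N)
}

#' Predicted Fisher wave width
#'
#' For a standard Fisher wave the front width scales as `sqrt(D / m)`; used in
#' the width-scaling analyses as the naive (advection-free) expectation.
#'
#' @param D diffusion coefficient.
#' @param m growth/fitness coefficient (> 0).
#' @return predicted width, spatial units.
#' @export
predicted_wave_width <- function(D, m) {
  stopifnot(all(D >= 0), all(m > 0))
  sqrt(D / m)
}
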