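# The generation loop. A population is a plain list:
#   list(generation = <int>, x = <numeric>, genotype = <integer codes>)
# Generations are discrete and non-overlapping: the offspring of generation t
# are the adults of generation t + 1.

population <- function(x, genotype, generation = 0L) {
  stopifnot(length(x) == length(genotype))
  list(generation = as.integer(generation),
       x = as.numeric(x),
       genotype = as.integer(genotype))
}

#' Build the initial population of a scenario
#'
#' Wild-types are placed uniformly on `wt_init_range` at density `N_star`
#' (count `round(N_star * width)`), each independently female or male with
#' probability 1/2. Drive carriers (`round(intro_fraction * WT count)`
#' heterozygotes: XYd males for the X-shredder, ZdW females for the
#' W-shredder) are added at `intro_position`, or scattered over
#' `wt_init_range` when `intro_scatter` is set. Uses R's global RNG.
#'
#' @param config a [scenario_config()].
#' @return a population (list with `generation`, `x`, `genotype`).
#' @export
initialize_population <- function(config) {
  rng <- config$wt_init_range
  n_wt <- round(config$N_star * (rng[2] - rng[1]))
  x <- runif(n_wt, rng[1], rng[2])
  female <- runif(n_wt) < 0.5
  if (config$drive_system == "W_SHREDDER") {
    geno <- ifelse(female, 4L, 6L)  # ZW / ZZ
    carrier <- 5L                   # ZdW female
  } else {
    geno <- ifelse(female, 1L, 2L)  # XX / XY
    carrier <- 3L                   # XYd male
  }
  n_d <- if (config$drive_system == "NONE") 0L
         else round(config$intro_fraction * n_wt)
  if (n_d > 0) {
    xd <- if (config$intro_scatter) runif(n_d, rng[1], rng[2])
          else rep(config$intro_position, n_d)
    x <- c(x, xd)
    geno <- c(geno, rep(carrier, n_d))
  }
  population(x, geno, 0L)
}

#' Find a mate for one female
#'
#' Candidate males lie within `mate_radius` of the female; one is sampled with
#' probability proportional to the Gaussian kernel density he provides at her
#' location. With no candidate the female dies unmated (the spatial Allee
#' effect).
#'
#' @param female_x female's position (scalar).
#' @param male_x positions of all males.
#' @param mate_radius neighbourhood radius (spatial units).
#' @return the index of the chosen male in `male_x`, or `NA_integer_` when no
#'   male is in range.
#' @export
find_mate <- function(female_x, male_x, mate_radius = 3) {
  stopifnot(length(female_x) == 1L, mate_radius > 0)
  ord <- order(male_x)
  pick <- choose_mates_sorted(female_x, male_x[ord], mate_radius)
  if (pick == 0L) NA_integer_ else ord[pick]
}

# One round of mating and reproduction. Returns the offspring population
# (pre-dispersal: offspring sit at their mother's position) plus per-parent
# statistics for the generation record.
#' Mate and reproduce one generation
#'
#' For every female: her competition density is the kernel sum over all other
#' individuals (Equation-1 field minus her own term); a mate is drawn from
#' within `mate_radius` (kernel-weighted), unmated females leave no offspring;
#' brood size is Poisson with Beverton-Holt mean `R / (1 + a N_i)`; offspring
#' genotypes follow the gamete rules at shredding efficiency `c` and offspring
#' are born at their mother's position. All adults die.
#'
#' @param state a population.
#' @param config a [scenario_config()].
#' @return list with `offspring` (a population, generation incremented) and
#'   `stats` (mean brood over all females, and over mated pairs split into
#'   wild-type-only pairs vs pairs with a drive-carrying parent).
#' @export
reproduce_generation <- function(state, config) {
  a <- density_response_coefficient(config$R, config$N_star)
  female <- state$genotype %in% FEMALE_CODES
  f_idx <- which(female)
  m_idx <- which(!female)
  empty_stats <- list(mean_offspring_total = NA_real_,
                      mean_offspring_wt_parents = NA_real_,
                      mean_offspring_drive_parents = NA_real_)
  if (length(f_idx) == 0L || length(m_idx) == 0L) {
    off <- population(numeric(0), integer(0), state$generation + 1L)
    if (length(f_idx) > 0L) empty_stats$mean_offspring_total <- 0
    return(list(offspring = off, stats = empty_stats))
  }
  fx <- state$x[f_idx]
  # neighbours-only competition density: full field minus the self term
  n_f <- kernel_density_sorted(fx, sort(state$x)) - INV_SQRT_2PI
  n_f <- pmax(n_f, 0)
  mx <- state$x[m_idx]
  ord <- order(mx)
  mate_pick <- choose_mates_sorted(fx, mx[ord], config$mate_radius)
  mated <- mate_pick > 0L
  father_idx <- rep(NA_integer_, length(f_idx))
  father_idx[mated] <- m_idx[ord][mate_pick[mated]]

  brood <- integer(length(f_idx))
  if (any(mated)) {
    ew <- expected_offspring(n_f[mated], config$R, a)
    brood[mated] <- draw_offspring_count(ew)
  }
  mother_code <- rep(state$genotype[f_idx], brood)
  father_code <- rep(state$genotype[father_idx], brood)
  off_geno <- offspring_codes(mother_code, father_code, config$c)
  off_x <- rep(state$x[f_idx], brood)

  # NA father (unmated) indexes to NA genotype, and is_carrier(NA) is FALSE
  pair_drive <- is_carrier(state$genotype[f_idx]) |
    is_carrier(state$genotype[father_idx])
  stats <- list(
    mean_offspring_total = mean(brood),
    mean_offspring_wt_parents =
      if (any(mated & !pair_drive)) mean(brood[mated & !pair_drive]) else NA_real_,
    mean_offspring_drive_parents =
      if (any(mated & pair_drive)) mean(brood[mated & pair_drive]) else NA_real_
  )
  list(offspring = population(off_x, off_geno, state$generation + 1L),
       stats = stats)
}

#' Disperse offspring with absorbing boundaries
#'
#' Each position receives an independent Normal(0, sigma^2) displacement;
#' individuals landing outside `[0, landscape_length]` are removed.
#'
#' @param offspring a population.
#' @param sigma dispersal standard deviation (> 0).
#' @param landscape_length landscape extent.
#' @return the dispersed population.
#' @export
disperse <- function(offspring, sigma, landscape_length) {
  stopifnot(sigma > 0)
  n <- length(offspring$x)
  if (n == 0L) return(offspring)
  x <- offspring$x + rnorm(n, 0, sigma)
  keep <- x >= 0 & x <= landscape_length
  population(x[keep], offspring$genotype[keep], offspring$generation)
}

class_extent <- function(x, sel) {
  if (!any(sel)) c(NA_real_, NA_real_)
  else range(x[sel])
}

#' Run one full simulation
#'
#' Iterates record -> mate/reproduce -> disperse until the first of: the
#' generation cap, total extinction, or `post_loss_generations` generations
#' after the first generation with zero drive alleles. Penetration (a
#' wild-type at least sigma units behind the drive wave's trailing edge) and
#' chasing (drive carriers re-entering the recolonized region) are scored
#' per generation; wave velocities, heights and widths are measured within the
#' window that ends at the first penetration or at boundary contact (leading
#' individual within sigma of the landscape edge).
#'
#' @param config a [scenario_config()]. When `config$seed` is set the global
#'   RNG is seeded, making the run fully reproducible.
#' @return an object of class `drive_sim`: list with `config`,
#'   `per_generation` (data frame, one row per generation), `events`, `wave`
#'   ([wave metrics][measure_widths]) and `outcome` (see
#'   [classify_outcome()]).
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- initialize_population(config)
  sigma <- config$sigma
  L <- config$landscape_length

  rows <- vector("list", config$max_generations + 1L)
  first_pen <- NA_integer_
  chasing <- FALSE
  drive_loss_gen <- NA_integer_
  window_open <- TRUE
  prev_drive_min <- NA_real_
  gen1 <- NULL

  for (t in 0:config$max_generations) {
    g <- state$genotype
    n <- length(g)
    carrier <- is_carrier(g)
    n_drive <- sum(carrier)
    n_wt <- n - n_drive
    female <- g %in% FEMALE_CODES

    dens <- if (n > 0) {
      pmax(kernel_density_sorted(state$x, sort(state$x)) - INV_SQRT_2PI, 0)
    } else numeric(0)

    wt_ext <- class_extent(state$x, !carrier)
    dr_ext <- class_extent(state$x, carrier)

    # events -------------------------------------------------------------
    # a wild-type control run has no drive allele to lose, so the post-loss
    # stop rule only applies when a drive system is simulated
    if (config$drive_system != "NONE" &&
        is.na(drive_loss_gen) && n_drive == 0L) {
      drive_loss_gen <- t
    }
    if (is.na(first_pen) && n_drive > 0L && n_wt > 0L &&
        wt_ext[1] <= dr_ext[1] - sigma) {
      first_pen <- t
    }
    wt_behind_max <- NA_real_
    if (!is.na(first_pen) && n_drive > 0L && !is.na(prev_drive_min)) {
      behind <- !carrier & state$x < prev_drive_min
      if (any(behind)) {
        wt_behind_max <- max(state$x[behind])
        # reinvasion is only scored after the penetration generation
        if (t > first_pen && dr_ext[1] <= wt_behind_max) chasing <- TRUE
      }
    }

    # wave measurements ---------------------------------------------------
    if (window_open) {
      boundary_contact <- (!is.na(wt_ext[2]) && wt_ext[2] >= L - sigma) ||
        (!is.na(dr_ext[2]) && dr_ext[2] >= L - sigma)
      if (!is.na(first_pen) || boundary_contact ||
          n_wt == 0L || (config$drive_system != "NONE" && n_drive == 0L)) {
        window_open <- FALSE
      }
    }
    in_window <- window_open && t >= 1L
    wm <- if (in_window && n_wt > 0L && n_drive > 0L) {
      measure_widths(list(x = state$x, genotype = genotype_label(g)))
    } else NULL
    if (!is.null(wm) && t == 1L) gen1 <- wm

    rows[[t + 1L]] <- data.frame(
      generation = t,
      population_size = n,
      n_wt = n_wt,
      n_drive = n_drive,
      female_fraction = if (n > 0) mean(female) else NA_real_,
      mean_local_density = if (n > 0) mean(dens) else NA_real_,
      sd_local_density = if (n > 1) sd(dens) else NA_real_,
      drive_allele_frequency = drive_allele_frequency_codes(g, "chromosome"),
      drive_frequency_individual = drive_allele_frequency_codes(g, "individual"),
      wt_min_x = wt_ext[1], wt_max_x = wt_ext[2],
      drive_min_x = dr_ext[1], drive_max_x = dr_ext[2],
      wt_behind_max = wt_behind_max,
      in_window = in_window,
      wt_width = if (!is.null(wm)) wm$wt_width else NA_real_,
      wt_height = if (!is.null(wm)) wm$wt_height else NA_real_,
      drive_leading_half_width =
        if (!is.null(wm)) wm$drive_leading_half_width else NA_real_,
      drive_trailing_half_width =
        if (!is.null(wm)) wm$drive_trailing_half_width else NA_real_,
      drive_height = if (!is.null(wm)) wm$drive_height else NA_real_,
      mean_offspring_total = NA_real_,
      mean_offspring_wt_parents = NA_real_,
      mean_offspring_drive_parents = NA_real_
    )

    # stopping rules -------------------------------------------------------
    if (n == 0L) break
    if (t == config$max_generations) break
    if (!is.na(drive_loss_gen) &&
        t >= drive_loss_gen + config$post_loss_generations) break

    prev_drive_min <- dr_ext[1]
    rep_out <- reproduce_generation(state, config)
    rows[[t + 1L]]$mean_offspring_total <- rep_out$stats$mean_offspring_total
    rows[[t + 1L]]$mean_offspring_wt_parents <-
      rep_out$stats$mean_offspring_wt_parents
    rows[[t + 1L]]$mean_offspring_drive_parents <-
      rep_out$stats$mean_offspring_drive_parents
    state <- disperse(rep_out$offspring, sigma, L)
  }

  per_gen <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(per_gen) <- NULL
  events <- list(
    first_penetration_generation = first_pen,
    chasing_observed = chasing,
    drive_loss_generation = drive_loss_gen,
    penetration = !is.na(first_pen),
    drive_loss = !is.na(drive_loss_gen)
  )
  rec <- structure(
    list(config = config, per_generation = per_gen, events = events,
         wave = NULL, gen1_wave = gen1, outcome = NULL),
    class = "drive_sim"
  )
  rec$wave <- wave_metrics(rec)
  rec$outcome <- classify_outcome(rec)
  rec
}

# internal: frequency from integer codes without building a population object
drive_allele_frequency_codes <- function(code, weighting) {
  if (length(code) == 0L) return(NA_real_)
  drive_allele_frequency(structure(list(genotype = code)), weighting)
}

#' @export
print.drive_sim <- function(x, ...) {
  pg <- x$per_generation
  cat("<drive_sim> ", x$config$drive_system,
      sprintf(" R = %g, sigma = %g, c = %g\n",
              x$config$R, x$config$sigma, x$config$c))
  cat(sprintf("  %d generations simulated; final size %d (%d WT, %d drive)\n",
              max(pg$generation), pg$population_size[nrow(pg)],
              pg$n_wt[nrow(pg)], pg$n_drive[nrow(pg)]))
  cat(sprintf("  outcome: %s%s; penetration: %s, chasing: %s, drive loss: %s\n",
              x$outcome$outcome,
              if (x$outcome$failure_mode != "NONE")
                paste0(" (", x$outcome$failure_mode, ")") else "",
              x$events$penetration, x$events$chasing_observed,
              x$events$drive_loss))
  invisible(x)
}
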