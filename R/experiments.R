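# Scenario-grid machinery: run replicated simulations over an (R, sigma) grid,
# aggregate outcomes, fit the width-scaling and event regressions, and write
# results to plain files.

#' Specify a scenario grid
#'
#' The published design crosses 10 equidistant fecundities on `[2, 10]` with
#' 10 equidistant dispersal scales on `[2, 20]` (endpoints included) for each
#' drive system, 100 replicates per cell.
#'
#' @param drive_systems character vector of drive systems.
#' @param R_values,sigma_values grid axes.
#' @param replicates replicates per scenario (>= 1).
#' @param seed_base base seed; replicate seeds are
#'   `seed_base + (scenario_index - 1) * replicates + (replicate - 1)`, so any
#'   cell is reproducible in isolation.
#' @param ... further arguments passed to every [scenario_config()] (e.g.
#'   `max_generations` for scaled-down runs).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(drive_systems = c("W_SHREDDER", "X_SHREDDER"),
                      R_values = seq(2, 10, length.out = 10),
                      sigma_values = seq(2, 20, length.out = 10),
                      replicates = 100,
                      seed_base = 1L,
                      ...) {
  stopifnot(replicates >= 1, all(drive_systems %in% DRIVE_SYSTEMS))
  scen <- expand.grid(sigma = sigma_values, R = R_values,
                      drive_system = drive_systems,
                      stringsAsFactors = FALSE)
  scen <- scen[, c("drive_system", "R", "sigma")]
  scen$scenario <- seq_len(nrow(scen))
  structure(list(scenarios = scen, replicates = as.integer(replicates),
                 seed_base = as.integer(seed_base),
                 config_args = list(...)),
            class = "grid_spec")
}

replicate_seed <- function(spec, scenario_index, replicate) {
  spec$seed_base + (scenario_index - 1L) * spec$replicates + (replicate - 1L)
}

run_row <- function(record) {
  cfg <- record$config
  w <- record$wave
  ev <- record$events
  pg <- record$per_generation
  data.frame(
    drive_system = cfg$drive_system, R = cfg$R, sigma = cfg$sigma,
    c = cfg$c, seed = if (is.null(cfg$seed)) NA_integer_ else cfg$seed,
    generations = max(pg$generation),
    final_size = pg$population_size[nrow(pg)],
    outcome = record$outcome$outcome,
    failure_mode = record$outcome$failure_mode,
    penetration = ev$penetration,
    chasing = ev$chasing_observed,
    drive_loss = ev$drive_loss,
    first_penetration_generation = ev$first_penetration_generation,
    drive_loss_generation = ev$drive_loss_generation,
    wt_velocity = w$wt_velocity, drive_velocity = w$drive_velocity,
    wt_width = w$wt_width, drive_width = w$drive_width,
    drive_leading_half_width = w$drive_leading_half_width,
    drive_trailing_half_width = w$drive_trailing_half_width,
    wt_height = w$wt_height, drive_height = w$drive_height,
    measured_through_generation = w$measured_through_generation
  )
}

#' Run a scenario grid
#'
#' Runs every (scenario, replicate) pair with [run_simulation()] under its
#' derived seed. Replicates are independent, so results are identical whatever
#' the execution order. When `out_file` is given, rows are appended as they
#' complete (crash-safe) and, with `resume = TRUE`, already-present
#' (scenario, replicate) pairs are skipped.
#'
#' @param spec a [grid_spec()].
#' @param out_file optional CSV path for incremental writing.
#' @param resume skip rows already present in `out_file`.
#' @param quiet suppress progress messages.
#' @return data frame of one outcome row per replicate.
#' @export
run_scenario_grid <- function(spec, out_file = NULL, resume = FALSE,
                              quiet = TRUE) {
  stopifnot(inherits(spec, "grid_spec"))
  done <- NULL
  if (!is.null(out_file) && resume && file.exists(out_file)) {
    done <- read.csv(out_file)
  }
  rows <- list()
  for (i in seq_len(nrow(spec$scenarios))) {
    sc <- spec$scenarios[i, ]
    for (r in seq_len(spec$replicates)) {
      if (!is.null(done) &&
          any(done$scenario == sc$scenario & done$replicate == r)) next
      seed <- replicate_seed(spec, i, r)
      cfg <- do.call(scenario_config, c(
        list(drive_system = sc$drive_system, R = sc$R, sigma = sc$sigma,
             seed = seed),
        spec$config_args
      ))
      row <- run_row(run_simulation(cfg))
      row$scenario <- sc$scenario
      row$replicate <- r
      rows[[length(rows) + 1L]] <- row
      if (!is.null(out_file)) {
        write.table(row, out_file, sep = ",", row.names = FALSE,
                    col.names = !file.exists(out_file), append = file.exists(out_file))
      }
      if (!quiet) {
        message(sprintf("scenario %d/%d replicate %d/%d: %s",
                        i, nrow(spec$scenarios), r, spec$replicates,
                        row$outcome))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(done) && nrow(done) > 0) {
    out <- rbind(done[, names(out), drop = FALSE], out)
  }
  rownames(out) <- NULL
  out
}

#' Summarize grid outcomes
#'
#' @param rows outcome rows from [run_scenario_grid()].
#' @return list with overall and per-system failure proportions, failure-mode
#'   frequencies, the chasing-within-failure frequency, and the escape
#'   fraction among drive-loss runs.
#' @export
summarize_outcomes <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) stop("no outcome rows", call. = FALSE)
  n <- nrow(rows)
  fail <- rows$outcome == "FAILURE"
  per_system <- tapply(fail, rows$drive_system, mean)
  loss <- rows$drive_loss
  list(
    n = n,
    failure_proportion = mean(fail),
    failure_by_system = per_system,
    drift_loss_proportion = mean(rows$failure_mode == "DRIFT_LOSS"),
    wt_escape_proportion = mean(rows$failure_mode == "WT_ESCAPE"),
    coexistence_proportion = mean(rows$failure_mode == "COEXISTENCE"),
    drive_loss_proportion = mean(loss),
    chasing_in_failures =
      if (any(fail)) mean(rows$chasing[fail]) else NA_real_,
    escape_fraction_of_drive_loss =
      if (any(loss)) mean(rows$penetration[loss]) else NA_real_
  )
}

#' Log-log width-scaling regression
#'
#' Ordinary least squares of `ln(width)` on `ln(sigma)`; the slope is the
#' scaling exponent (1 = linear scaling). Rows with missing or non-positive
#' widths are dropped and counted.
#'
#' @param widths wave widths (positive).
#' @param sigmas matching dispersal parameters (positive).
#' @return list with `slope`, `se`, `intercept`, `n_used`, `n_dropped`.
#' @export
fit_width_scaling <- function(widths, sigmas) {
  stopifnot(length(widths) == length(sigmas), all(sigmas > 0, na.rm = TRUE))
  keep <- !is.na(widths) & !is.na(sigmas) & widths > 0
  n_dropped <- sum(!keep)
  if (sum(keep) < 3L) {
    stop("need at least 3 positive width observations", call. = FALSE)
  }
  fit <- lm(log(widths[keep]) ~ log(sigmas[keep]))
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]),
       intercept = unname(sm[1, 1]),
       n_used = sum(keep), n_dropped = n_dropped)
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counted one half — equivalent to exhaustive
#' concordant-pair counting.
#'
#' @param outcome binary (logical or 0/1) outcome.
#' @param score numeric predictor or fitted probability.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(outcome, score) {
  y <- as.logical(outcome)
  stopifnot(length(y) == length(score), !anyNA(y), !anyNA(score))
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both outcome classes must be represented", call. = FALSE)
  }
  r <- rank(score)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Univariate logistic event model with AUC
#'
#' Fits `P(event) ~ predictor` by maximum-likelihood logistic regression and
#' reports the ROC AUC of the predictor. Rows with missing values are dropped.
#' Perfect separation is flagged (the AUC is still returned).
#'
#' @param outcome binary event flags (e.g. penetration, escape).
#' @param predictor numeric wave characteristic (e.g. relative velocity
#'   `v_drive - v_WT`, relative width `width / sigma`, height, or sigma).
#' @return list with `coefficients` (intercept, slope), `auc`, `n`,
#'   `separation` flag and the fitted `glm` object.
#' @export
fit_event_model <- function(outcome, predictor) {
  keep <- !is.na(outcome) & !is.na(predictor)
  y <- as.integer(as.logical(outcome[keep]))
  x <- predictor[keep]
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be represented", call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  list(coefficients = coef(fit), auc = roc_auc(y == 1L, x),
       n = length(y), separation = separation, fit = fit)
}

#' Export grid results
#'
#' Writes the outcome rows, a per-scenario summary, a long-format
#' (system, R, sigma, failure probability) table ready for heat-mapping, and a
#' JSON manifest of the grid specification.
#'
#' @param rows outcome rows from [run_scenario_grid()].
#' @param spec the [grid_spec()] that produced them.
#' @param dir destination directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_results <- function(rows, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    outcomes = file.path(dir, "outcomes.csv"),
    scenario_summary = file.path(dir, "scenario_summary.csv"),
    failure_grid = file.path(dir, "failure_grid.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write.csv(rows, paths["outcomes"], row.names = FALSE)
  agg <- aggregate(cbind(failure = outcome == "FAILURE",
                         penetration = penetration,
                         chasing = chasing,
                         drive_loss = drive_loss) ~
                     drive_system + R + sigma, data = rows, FUN = mean)
  counts <- aggregate(list(n = rows$outcome),
                      by = rows[, c("drive_system", "R", "sigma")],
                      FUN = length)
  agg <- merge(agg, counts)
  write.csv(agg, paths["scenario_summary"], row.names = FALSE)
  write.csv(agg[, c("drive_system", "R", "sigma", "failure")],
            paths["failure_grid"], row.names = FALSE)
  manifest <- list(
    scenarios = spec$scenarios,
    replicates = spec$replicates,
    seed_base = spec$seed_base,
    config_args = spec$config_args,
    package_version = as.character(utils::packageVersion("drivewave"))
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Rebuild a grid spec from a manifest
#'
#' @param path path to a `manifest.json` written by [export_results()].
#' @return a [grid_spec()] equal to the exported one.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- m$scenarios
  do.call(grid_spec, c(
    list(drive_systems = unique(sc$drive_system),
         R_values = unique(sc$R),
         sigma_values = unique(sc$sigma),
         replicates = m$replicates,
         seed_base = m$seed_base),
    if (length(m$config_args)) m$config_args else list()
  ))
}

#' Width-scaling experiment
#'
#' Runs seeded replicates of the drive-introduction scenario at each dispersal
#' value, with the maximum fecundity cycling over the standard 10-point grid
#' on `[2, 10]` so replicates span the fecundity range, and collects the
#' window-averaged wave widths for the log-log scaling regressions.
#'
#' @param system drive system to simulate.
#' @param sigma_values dispersal values (default the standard 10-point grid).
#' @param replicates replicates per dispersal value.
#' @param seed_base base seed; run seeds are consecutive from it.
#' @param max_generations cap on each run (the measurement window usually
#'   closes earlier, at the first penetration or boundary contact).
#' @return data frame with one row per run: `sigma`, `R`, `seed`, the wave
#'   widths and the last measured generation.
#' @export
width_scaling_experiment <- function(system = "X_SHREDDER",
                                     sigma_values = seq(2, 20, length.out = 10),
                                     replicates = 30,
                                     seed_base = 1L,
                                     max_generations = 50L) {
  R_grid <- seq(2, 10, length.out = 10)
  rows <- vector("list", length(sigma_values) * replicates)
  k <- 0L
  seed <- seed_base
  for (s in sigma_values) {
    for (r in seq_len(replicates)) {
      cfg <- scenario_config(system, R = R_grid[(r - 1L) %% 10L + 1L],
                             sigma = s, max_generations = max_generations,
                             seed = seed)
      rec <- run_simulation(cfg)
      w <- rec$wave
      k <- k + 1L
      rows[[k]] <- data.frame(
        sigma = s, R = cfg$R, seed = seed,
        wt_width = w$wt_width,
        drive_leading_half_width = w$drive_leading_half_width,
        drive_trailing_half_width = w$drive_trailing_half_width,
        drive_width = w$drive_width,
        measured_through_generation = w$measured_through_generation
      )
      seed <- seed + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
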