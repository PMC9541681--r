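# Measurement of emergent invasion-wave properties and classification of run
# outcomes. A "snapshot" is a list with numeric `x` and character `genotype`
# (or a population with integer codes); the WT wave is all non-carriers, the
# drive wave all carriers.

snapshot_codes <- function(snapshot) {
  g <- snapshot$genotype
  if (is.character(g)) genotype_code(g) else as.integer(g)
}

# The crest level used to anchor the leading-edge peak of a flat-topped wave.
# Individual kernel densities fluctuate strongly (offspring are born at their
# mother's position, so sibling clumps produce local spikes well above the
# plateau mean); the class median is dominated by the plateau and insensitive
# to clumps, so the rightmost individual still attaining it tracks the
# shoulder of the front rather than a random clump.
crest_level <- function(dens) median(dens)

#' Wave peak and height
#'
#' The height of a wave is the maximum of the class-specific density field
#' (Gaussian kernel sum over that class only) across the class's individuals;
#' the peak is the position at which it is attained.
#'
#' @param snapshot list with `x` (positions) and `genotype` (strings or codes).
#' @param wave `"WT"` (non-carriers) or `"DRIVE"` (carriers).
#' @return list with `peak` (position) and `height` (density); both `NA` when
#'   the class is empty.
#' @export
wave_peak_and_height <- function(snapshot, wave = c("WT", "DRIVE")) {
  wave <- match.arg(wave)
  code <- snapshot_codes(snapshot)
  sel <- if (wave == "DRIVE") is_carrier(code) else !is_carrier(code)
  x <- snapshot$x[sel]
  if (length(x) == 0L) return(list(peak = NA_real_, height = NA_real_))
  x <- sort(x)
  d <- kernel_density_sorted(x, x)
  i <- which.max(d)
  list(peak = x[i], height = d[i])
}

# Leading-edge peak of a right-moving wave: the rightmost individual whose
# class density reaches the crest level. For a flat-topped wave the density
# argmax wanders over the whole plateau under sampling noise, whereas this
# threshold crossing tracks the shoulder of the front.
leading_edge_peak <- function(x_sorted, dens) {
  x_sorted[max(which(dens >= crest_level(dens)))]
}

#' Measure wave widths (and heights) on one snapshot
#'
#' Definitions for right-moving waves: the WT wave width is twice the distance
#' between the farthest (rightmost) wild-type and the peak of the wave at its
#' leading edge; the drive wave's leading half width is the distance from its
#' peak to the leading (rightmost) carrier and the trailing half width the
#' distance from the trailing (leftmost) carrier to the peak; the full drive
#' width is their sum. The WT leading-edge peak is the rightmost individual
#' whose class density still attains the wave's typical crest level (the
#' median of class-member densities, which is plateau-dominated and robust to
#' sibling-clump density spikes); the drive wave is pulse-shaped, so its peak
#' is the plain density argmax. Widths are clipped at zero.
#'
#' @param snapshot list with `x` and `genotype`.
#' @return list with `wt_width`, `wt_height`, `wt_peak`,
#'   `drive_leading_half_width`, `drive_trailing_half_width`, `drive_width`,
#'   `drive_height`, `drive_peak`; entries are `NA` for an empty class.
#' @export
measure_widths <- function(snapshot) {
  code <- snapshot_codes(snapshot)
  carrier <- is_carrier(code)
  out <- list(wt_width = NA_real_, wt_height = NA_real_, wt_peak = NA_real_,
              drive_leading_half_width = NA_real_,
              drive_trailing_half_width = NA_real_,
              drive_width = NA_real_, drive_height = NA_real_,
              drive_peak = NA_real_)
  wx <- sort(snapshot$x[!carrier])
  if (length(wx) > 0L) {
    wd <- kernel_density_sorted(wx, wx)
    out$wt_height <- max(wd)
    out$wt_peak <- leading_edge_peak(wx, wd)
    out$wt_width <- max(0, 2 * (wx[length(wx)] - out$wt_peak))
  }
  dx <- sort(snapshot$x[carrier])
  if (length(dx) > 0L) {
    dd <- kernel_density_sorted(dx, dx)
    # exact ties (e.g. several isolated carriers all at the self-term density)
    # resolve to the rightmost tied individual, the leading-edge side
    i <- max(which(dd == max(dd)))
    out$drive_height <- dd[i]
    out$drive_peak <- dx[i]
    out$drive_leading_half_width <- max(0, dx[length(dx)] - out$drive_peak)
    out$drive_trailing_half_width <- max(0, out$drive_peak - dx[1])
    out$drive_width <- out$drive_leading_half_width +
      out$drive_trailing_half_width
  }
  out
}

#' Wave velocity from a leading-edge series
#'
#' The mean of successive differences of the leading individual's position,
#' which telescopes to `(last - first) / (n - 1)`.
#'
#' @param leading_edge_series numeric vector of leading-edge positions at
#'   consecutive generations (already truncated to the measurement window).
#' @return velocity in spatial units per generation; `NA` when fewer than two
#'   positions are supplied.
#' @export
wave_velocity <- function(leading_edge_series) {
  s <- leading_edge_series[!is.na(leading_edge_series)]
  n <- length(s)
  if (n < 2L) return(NA_real_)
  (s[n] - s[1]) / (n - 1)
}

#' Detect wild-type penetration of the drive wave
#'
#' Penetration occurs when at least one wild-type sits at least `sigma` units
#' beyond (left of) the drive wave's trailing edge, the drive carrier with the
#' lowest position. Only the first penetration event of a run is reliably
#' scored, because the procedure assumes a single wild-type wave.
#'
#' @param snapshot list with `x` and `genotype`.
#' @param sigma the scenario's dispersal parameter.
#' @return `TRUE`/`FALSE`, or `NA` when no drive carriers remain.
#' @export
detect_penetration <- function(snapshot, sigma) {
  code <- snapshot_codes(snapshot)
  carrier <- is_carrier(code)
  if (!any(carrier)) return(NA)
  if (!any(!carrier)) return(FALSE)
  min(snapshot$x[!carrier]) <= min(snapshot$x[carrier]) - sigma
}

#' Detect chasing from a simulation record
#'
#' Chasing is the drive's reinvasion of wild-types that recolonized space
#' behind the drive wave. Operationally: at some generation after the first
#' penetration, a drive carrier sits at or left of the rightmost wild-type
#' that was behind the previous generation's drive trailing edge (the
#' `wt_behind_max` column of the per-generation record). Returns `FALSE` when
#' no penetration occurred.
#'
#' @param record a `drive_sim` object from [run_simulation()], or its
#'   `per_generation` data frame together with `first_penetration` supplied.
#' @param first_penetration optional override of the first penetration
#'   generation (used when re-scoring).
#' @return logical flag.
#' @export
detect_chasing <- function(record, first_penetration = NULL) {
  pg <- if (inherits(record, "drive_sim")) record$per_generation else record
  fp <- if (!is.null(first_penetration)) first_penetration
        else if (inherits(record, "drive_sim"))
          record$events$first_penetration_generation
        else NA_integer_
  if (is.na(fp)) return(FALSE)
  after <- pg$generation > fp & !is.na(pg$wt_behind_max) &
    !is.na(pg$drive_min_x)
  any(pg$drive_min_x[after] <= pg$wt_behind_max[after])
}

# Window-averaged wave metrics of one completed run.
wave_metrics <- function(record) {
  pg <- record$per_generation
  win <- pg[pg$in_window, , drop = FALSE]
  mean_or_na <- function(v) if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
  list(
    wt_velocity = wave_velocity(win$wt_max_x),
    drive_velocity = wave_velocity(win$drive_max_x),
    wt_width = mean_or_na(win$wt_width),
    drive_leading_half_width = mean_or_na(win$drive_leading_half_width),
    drive_trailing_half_width = mean_or_na(win$drive_trailing_half_width),
    drive_width = mean_or_na(win$drive_leading_half_width +
                               win$drive_trailing_half_width),
    wt_height = mean_or_na(win$wt_height),
    drive_height = mean_or_na(win$drive_height),
    measured_through_generation =
      if (nrow(win) > 0) max(win$generation) else NA_integer_
  )
}

#' Classify the outcome of a completed run
#'
#' Success is the complete eradication of the wild-type population at or
#' before the generation cap. Failures are split into: drift loss (drive
#' alleles lost with no prior penetration), wild-type escape (drive lost after
#' penetration) and coexistence (both allele classes extant at the cap).
#'
#' @param record a `drive_sim` object.
#' @return list with `outcome` (`"SUCCESS"`/`"FAILURE"`), `failure_mode`
#'   (`"NONE"`, `"DRIFT_LOSS"`, `"WT_ESCAPE"`, `"COEXISTENCE"`) and the event
#'   flags.
#' @export
classify_outcome <- function(record) {
  pg <- record$per_generation
  ev <- record$events
  eradicated <- any(pg$n_wt == 0L)
  if (eradicated) {
    outcome <- "SUCCESS"
    mode <- "NONE"
  } else {
    outcome <- "FAILURE"
    mode <- if (ev$drive_loss) {
      if (ev$penetration) "WT_ESCAPE" else "DRIFT_LOSS"
    } else "COEXISTENCE"
  }
  list(outcome = outcome, failure_mode = mode,
       events = list(penetration = ev$penetration,
                     chasing = ev$chasing_observed,
                     drive_loss = ev$drive_loss))
}
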