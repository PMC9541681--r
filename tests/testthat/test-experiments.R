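test_that("grid specs cross systems with equidistant parameter axes", {
  spec <- grid_spec(replicates = 3, seed_base = 7)
  expect_equal(nrow(spec$scenarios), 2 * 10 * 10)
  expect_equal(sort(unique(spec$scenarios$R)), seq(2, 10, by = 8 / 9))
  expect_equal(sort(unique(spec$scenarios$sigma)), seq(2, 20, by = 2))
  # replicate seeds make every cell reproducible in isolation
  expect_equal(drivewave:::replicate_seed(spec, 1L, 1L), 7L)
  expect_equal(drivewave:::replicate_seed(spec, 2L, 1L), 10L)
  expect_equal(drivewave:::replicate_seed(spec, 2L, 3L), 12L)
})

test_that("a tiny grid runs, repeats identically, and exports round-trip", {
  spec <- grid_spec("X_SHREDDER", R_values = 6, sigma_values = 8,
                    replicates = 3, seed_base = 100,
                    landscape_length = 600, wt_init_range = c(100, 350),
                    intro_position = 100, max_generations = 15)
  rows <- run_scenario_grid(spec)
  expect_equal(nrow(rows), 3)
  expect_true(all(rows$outcome %in% c("SUCCESS", "FAILURE")))
  rows2 <- run_scenario_grid(spec)
  expect_identical(rows, rows2)

  dir <- tempfile()
  paths <- export_results(rows, spec, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths["outcomes"])
  expect_equal(nrow(back), 3)
  expect_equal(back$seed, rows$seed)
  spec2 <- read_manifest(paths["manifest"])
  expect_equal(spec2$scenarios, spec$scenarios)
  expect_equal(spec2$replicates, spec$replicates)
  expect_equal(spec2$seed_base, spec$seed_base)
  expect_equal(spec2$config_args, spec$config_args)
})

test_that("outcome summaries reproduce hand-counted proportions", {
  toy <- data.frame(
    drive_system = rep(c("X_SHREDDER", "W_SHREDDER"), each = 4),
    outcome = c("FAILURE", "FAILURE", "SUCCESS", "FAILURE",
                "SUCCESS", "SUCCESS", "FAILURE", "SUCCESS"),
    failure_mode = c("DRIFT_LOSS", "WT_ESCAPE", "NONE", "COEXISTENCE",
                     "NONE", "NONE", "WT_ESCAPE", "NONE"),
    penetration = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    chasing = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    drive_loss = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  s <- summarize_outcomes(toy)
  expect_equal(s$failure_proportion, 0.5)
  expect_equal(unname(s$failure_by_system["X_SHREDDER"]), 0.75)
  expect_equal(unname(s$failure_by_system["W_SHREDDER"]), 0.25)
  expect_equal(s$drift_loss_proportion, 1 / 8)
  expect_equal(s$wt_escape_proportion, 2 / 8)
  expect_equal(s$coexistence_proportion, 1 / 8)
  expect_equal(s$chasing_in_failures, 0.5)
  expect_equal(s$escape_fraction_of_drive_loss, 2 / 3)
  # paper-scale arithmetic: 10132 failures of 20000 is 50.66%
  big <- data.frame(
    drive_system = "X_SHREDDER",
    outcome = rep(c("FAILURE", "SUCCESS"), c(10132, 9868)),
    failure_mode = rep(c("COEXISTENCE", "NONE"), c(10132, 9868)),
    penetration = FALSE, chasing = FALSE, drive_loss = FALSE
  )
  expect_equal(summarize_outcomes(big)$failure_proportion, 0.5066)
  expect_error(summarize_outcomes(toy[0, ]), "no outcome rows")
})

test_that("width-scaling regression recovers known exponents", {
  s <- rep(seq(2, 20, by = 2), each = 4)
  # suppressWarnings: lm flags the exact fits as "essentially perfect"
  f <- suppressWarnings(fit_width_scaling(s, s))
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_lt(f$se, 1e-12)
  f2 <- suppressWarnings(fit_width_scaling(s^2, s))
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  # parameter recovery under lognormal noise
  set.seed(11)
  s <- rep(seq(2, 20, by = 2), each = 100)
  w <- 3 * s^1.22 * exp(rnorm(length(s), 0, 0.1))
  f3 <- fit_width_scaling(w, s)
  expect_lt(abs(f3$slope - 1.22), 3 * f3$se)
  # zero/missing widths are dropped and counted, not log-transformed
  f4 <- suppressWarnings(fit_width_scaling(c(4, 9, 16, 25, 0, NA),
                                           c(2, 3, 4, 5, 6, 7)))
  expect_equal(f4$n_used, 4)
  expect_equal(f4$n_dropped, 2)
  expect_error(fit_width_scaling(c(1, 2), c(1, 2)), "at least 3")
})

test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  # perfectly separated predictor
  expect_equal(roc_auc(c(0, 0, 1, 1, 1), c(1, 2, 3, 4, 5)), 1)
  set.seed(12)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes present
    x <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(y, x), auc_by_pairs(y, x))
  }
  # an uninformative predictor sits near 1/2
  set.seed(13)
  y <- rbinom(4000, 1, 0.5)
  x <- runif(4000)
  expect_equal(roc_auc(y, x), 0.5, tolerance = 0.05)
  expect_error(roc_auc(rep(1, 5), 1:5), "both outcome classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- rbinom(300, 1, 0.4)
  x <- rnorm(300) + y
  ref <- suppressMessages(as.numeric(pROC::auc(y, x)))
  expect_equal(roc_auc(y, x), ref, tolerance = 1e-12)
})

test_that("logistic event models fit and flag separation", {
  set.seed(15)
  x <- rnorm(400)
  p <- plogis(-0.5 + 2 * x)
  y <- rbinom(400, 1, p)
  fit <- fit_event_model(y, x)
  expect_equal(unname(fit$coefficients[2]), 2, tolerance = 0.35)
  expect_gt(fit$auc, 0.8)
  expect_false(fit$separation)
  # perfect separation is flagged and the AUC is still 1
  sep <- fit_event_model(c(0, 0, 0, 1, 1, 1), c(1, 2, 3, 10, 11, 12))
  expect_true(sep$separation)
  expect_equal(sep$auc, 1)
  expect_error(fit_event_model(rep(0, 10), 1:10), "both outcome classes")
})
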