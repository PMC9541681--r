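test_that("initialization lays out wild-types and carriers as configured", {
  set.seed(1)
  cfg <- scenario_config("X_SHREDDER")
  pop <- initialize_population(cfg)
  geno <- drivewave:::genotype_label(pop$genotype)
  expect_equal(sum(geno %in% c("XX", "XY")), 5000)  # 5 x (1250 - 250)
  expect_equal(sum(geno == "XYd"), 50)              # 1% of 5000
  expect_true(all(pop$x[geno == "XYd"] == 250))
  wt_x <- pop$x[geno != "XYd"]
  expect_true(all(wt_x >= 250 & wt_x <= 1250))
  # sexes are balanced in expectation
  expect_equal(mean(geno == "XX"), 0.5, tolerance = 0.05)

  cfgw <- scenario_config("W_SHREDDER")
  popw <- initialize_population(cfgw)
  genow <- drivewave:::genotype_label(popw$genotype)
  expect_equal(sum(genow == "ZdW"), 50)  # W-shredder introduces ZdW females

  cfg0 <- scenario_config("X_SHREDDER", intro_fraction = 0)
  pop0 <- initialize_population(cfg0)
  expect_false(any(drivewave:::is_carrier(pop0$genotype)))
})

test_that("mate finding is kernel-weighted within the mating radius", {
  # no male within 3 units: the female dies unmated (Allee effect)
  expect_true(is.na(find_mate(0, c(3.5, 10), mate_radius = 3)))
  # single co-located male is chosen with probability 1
  expect_identical(find_mate(5, 5), 1L)
  # males at distance 0 and 2 are chosen at odds 1 : exp(-2)
  set.seed(2)
  picks <- replicate(20000, find_mate(0, c(0, 2)))
  odds <- mean(picks == 2) / mean(picks == 1)
  expect_equal(odds, exp(-2), tolerance = 0.1)
})

test_that("reproduction composes density, mating and gamete rules", {
  cfg <- small_config()
  # all-male population produces no offspring
  all_male <- make_pop(runif(40, 0, 100), rep("XY", 40))
  out <- reproduce_generation(all_male, cfg)
  expect_length(out$offspring$x, 0)
  # a single isolated pair: brood ~ Poisson(R / (1 + a * N)) with the
  # partner's kernel term as the only neighbour density
  a <- density_response_coefficient(cfg$R, cfg$N_star)
  expectation <- expected_offspring(1 / sqrt(2 * pi), cfg$R, a)
  set.seed(3)
  broods <- replicate(3000, {
    pair <- make_pop(c(50, 50), c("XX", "XY"))
    length(reproduce_generation(pair, cfg)$offspring$x)
  })
  se <- sqrt(expectation / 3000)
  expect_lt(abs(mean(broods) - expectation), 4 * se)
  # offspring are born at the mother's position
  set.seed(4)
  pair <- make_pop(c(77, 79), c("XX", "XY"))
  off <- reproduce_generation(pair, cfg)$offspring
  expect_true(all(off$x == 77))
  expect_equal(off$generation, 1L)
})

test_that("reproduction is deterministic under a fixed seed", {
  cfg <- small_config()
  pop <- local({set.seed(10); initialize_population(cfg)})
  set.seed(20); o1 <- reproduce_generation(pop, cfg)
  set.seed(20); o2 <- reproduce_generation(pop, cfg)
  expect_identical(o1, o2)
})

test_that("dispersal is Gaussian with absorbing boundaries", {
  pop <- make_pop(rep(1250, 1e5), rep("XX", 1e5))
  # sigma -> 0 leaves positions unchanged
  still <- disperse(pop, 1e-9, 2500)
  expect_equal(still$x, pop$x, tolerance = 1e-6)
  # RMS displacement equals sigma within 1%
  set.seed(5)
  moved <- disperse(pop, 10, 2500)
  expect_equal(sqrt(mean((moved$x - 1250)^2)), 10, tolerance = 0.01)
  # survival at the left boundary follows the normal CDF
  set.seed(6)
  edge <- make_pop(rep(1, 4e4), rep("XX", 4e4))
  kept <- disperse(edge, 2, 2500)
  expect_equal(length(kept$x) / 4e4, 1 - pnorm(-0.5), tolerance = 0.02)
})

test_that("runs are reproducible and respect the stopping rules", {
  cfg <- small_config(seed = 31, max_generations = 25)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$per_generation, r2$per_generation)
  expect_identical(r1$outcome, r2$outcome)
  # zero carriers introduced: the post-loss rule stops the run at generation 10
  cfg0 <- small_config(intro_fraction = 0, seed = 32)
  r0 <- run_simulation(cfg0)
  expect_equal(max(r0$per_generation$generation), cfg0$post_loss_generations)
  expect_equal(r0$events$drive_loss_generation, 0L)
  # a wild-type control run has no drive to lose and runs to the cap
  cfgn <- small_config(drive_system = "NONE", intro_fraction = 0,
                       max_generations = 15, seed = 33)
  rn <- run_simulation(cfgn)
  expect_equal(max(rn$per_generation$generation), 15)
})

test_that("generations do not overlap: adults never persist", {
  cfg <- small_config(seed = 40, max_generations = 8)
  set.seed(40)
  state <- initialize_population(cfg)
  for (t in 1:3) {
    out <- reproduce_generation(state, cfg)
    nxt <- disperse(out$offspring, cfg$sigma, cfg$landscape_length)
    expect_equal(nxt$generation, state$generation + 1L)
    state <- nxt
  }
})

test_that("a neutral drive allele (c = 0) drifts without direction", {
  # carriers are scattered through the population: a stacked point release is
  # systematically disadvantaged by mate competition and local density, which
  # is a founder-configuration effect, not drift
  set.seed(50)
  dq <- replicate(40, {
    cfg <- small_config(c = 0, sigma = 8, max_generations = 6,
                        intro_fraction = 0.05, intro_scatter = TRUE,
                        seed = sample.int(1e6, 1))
    pg <- run_simulation(cfg)$per_generation
    q <- pg$drive_allele_frequency
    q[length(q)] - q[1]
  })
  se <- sd(dq) / sqrt(length(dq))
  expect_lt(abs(mean(dq)), 4 * se)
})
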