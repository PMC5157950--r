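test_that("growth conserves cells plus resource and empties it into cells", {
  p <- default_params()
  st <- population_state(make_grid(0.5, 0.15), vegetative = 1e3, R = 1e8)
  g <- integrate_growth(st, p)
  expect_equal(g$state$vegetative, 1.00001e8, tolerance = 1e-8)
  expect_identical(g$state$R, 0)
  expect_identical(g$state$phase, "starvation")
  expect_gt(g$elapsed, 0)
  # a zero pulse changes nothing
  st0 <- population_state(make_grid(0.5, 0.15), vegetative = 1e3, R = 0)
  g0 <- integrate_growth(st0, p)
  expect_identical(g0$elapsed, 0)
  expect_identical(g0$state$vegetative, st0$vegetative)
})

test_that("growth conservation holds across random mixed populations", {
  p <- default_params()
  with_rng_stream(42, "conservation", {
    for (i in 1:8) {
      n <- sample(2:10, 1)
      X0 <- runif(n, 10, 1e8)
      grid <- make_grid(runif(n), runif(n, 0.05, 0.45))
      R0 <- 10^runif(1, 6, 9)
      g <- integrate_growth(population_state(grid, vegetative = X0, R = R0),
                            p)
      expect_equal(sum(g$state$vegetative), sum(X0) + R0,
                   tolerance = 1e-8)
      expect_true(all(g$state$vegetative >= X0))
    }
  })
})

test_that("growth matches the full-system reference integrator", {
  p <- default_params()
  X0 <- c(5e5, 5e5)
  cvec <- c(0.1, 0.2)
  st <- population_state(make_grid(c(0.2, 0.8), cvec),
                         vegetative = X0, R = 1e8)
  g <- integrate_growth(st, p)
  ref <- oracle_growth(X0, cvec, 1e8, p)
  expect_equal(g$state$vegetative, ref$X, tolerance = 1e-6)
  expect_equal(g$elapsed, ref$elapsed, tolerance = 1e-5)
  # the faster divider ends strictly ahead
  expect_gt(g$state$vegetative[2], g$state$vegetative[1])
})

test_that("a time budget interrupts growth with the resource still present", {
  p <- default_params()
  st <- population_state(make_grid(0.5, 0.15), vegetative = 1e3, R = 1e8)
  g <- integrate_growth(st, p, t_limit = 4)
  expect_identical(g$state$phase, "growth")
  expect_identical(g$elapsed, 4)
  expect_gt(g$state$R, 0.99e8)
  # near-saturated uptake: X(4) ~ X0 exp(c * f(R0) * 4)
  expect_equal(g$state$vegetative,
               1e3 * exp(0.15 * (1e8 / (p$R_half + 1e8)) * 4),
               tolerance = 1e-4)
})

test_that("starvation-onset partitioning splits the population exactly", {
  p <- default_params()
  st <- population_state(make_grid(0.5, 0.15), vegetative = 1000, R = 0,
                         phase = "growth")
  st$phase <- "starvation"
  pd <- partition_discrete(st, p)
  expect_equal(pd$partition$spores, 400)
  expect_equal(pd$partition$solitary, 500)
  expect_equal(pd$partition$stalk, 100)
  # alpha = 0 and alpha = 1 degenerate splits
  st2 <- population_state(make_grid(c(0, 1), c(0.15, 0.15)),
                          vegetative = c(800, 800))
  st2$phase <- "starvation"
  pd2 <- partition_discrete(st2, p)
  expect_equal(pd2$partition$spores, c(0, 640))
  expect_equal(pd2$partition$solitary, c(800, 0))
  expect_equal(pd2$partition$stalk, c(0, 160))
  expect_equal(rowSums(pd2$partition), c(800, 800))
  # continuous-mechanism grids are refused
  stc <- population_state(structure(data.frame(gamma = 0.1, c = 0.15),
                                    mechanism = "continuous"),
                          vegetative = 10)
  stc$phase <- "starvation"
  expect_error(partition_discrete(stc, p), "continuous")
})

test_that("starvation mortality follows the closed forms", {
  p <- default_params()
  st <- population_state(make_grid(0.5, 0.15), R = 0)
  st$phase <- "starvation"
  st$spores <- 1e6
  st$solitary <- 500
  st$solitary_onset <- 500
  s0 <- starve_discrete(st, 0, p)
  expect_identical(s0$spores, st$spores)
  s100 <- starve_discrete(st, 100, p)
  expect_equal(s100$spores, 1e6 * exp(-0.01), tolerance = 1e-12)
  expect_equal(s100$solitary, 500 * survival_probability(0.15, 100, p),
               tolerance = 1e-12)
  sdead <- starve_discrete(st, p$T_sur + 10, p)
  expect_identical(sdead$solitary, 0)
  expect_error(starve_discrete(st, -1, p), "T must be")
})

test_that("closed-form starvation matches the hazard-ODE reference on random draws", {
  p <- default_params()
  with_rng_stream(42, "starve-oracle", {
    for (i in 1:10) {
      c <- runif(1, 0.05, 0.45)
      T <- runif(1, 5, 190)
      N0 <- 10^runif(1, 2, 8)
      expect_equal(N0 * survival_probability(c, T, p),
                   oracle_starve_solitary(N0, c, T, p),
                   tolerance = 1e-6,
                   label = sprintf("solitary decline c=%.3f T=%.1f", c, T))
    }
  })
})

test_that("continuous aggregation matches its reference ODE and limits", {
  p0 <- default_params(delta = 0)
  # gamma = 0 reduces to a never-aggregating strain
  cs0 <- continuous_starvation(1000, 0, 0.15, 50, p0)
  expect_equal(cs0$solitary, 1000 * survival_probability(0.15, 50, p0))
  expect_identical(cs0$aggregated, 0)
  # closed form at gamma = 0.1, t = 10, delta = 0
  cs1 <- continuous_starvation(1, 0.1, 0.15, 10, p0)
  expect_equal(cs1$solitary, exp(-1) * survival_probability(0.15, 10, p0),
               tolerance = 1e-10)
  expect_equal(cs1$solitary, 0.3676, tolerance = 1e-3)
  # against the two-pool reference ODE, with spore decay active
  p <- default_params()
  with_rng_stream(42, "continuous-oracle", {
    for (i in 1:6) {
      gamma <- runif(1, 0.01, 1)
      c <- runif(1, 0.05, 0.45)
      T <- runif(1, 5, 190)
      got <- continuous_starvation(1e6, gamma, c, T, p)
      ref <- oracle_continuous(1e6, gamma, c, T, p)
      expect_equal(got$solitary, ref$N, tolerance = 1e-6)
      expect_equal(got$aggregated, ref$A, tolerance = 1e-6)
    }
  })
  # very fast aggregation reproduces the all-aggregating discrete strain
  big <- continuous_starvation(1e6, 1e3, 0.15, p$T_sur, p)
  expect_equal(big$spores, p$s * 1e6 * exp(-p$delta * p$T_sur),
               tolerance = 1e-3)
  expect_lt(big$solitary, 1)
  expect_error(continuous_starvation(1, -0.1, 0.15, 10, p), "gamma")
})

test_that("aggregation time is bounded by the maximum lifetime and monotone in gamma", {
  p <- default_params()
  t0 <- aggregation_time(genotype("continuous", gamma = 0, c = 0.15), p)
  expect_equal(t0, p$T_sur, tolerance = 1e-3)
  tg <- vapply(c(0.05, 0.1, 0.5, 2),
               function(g) aggregation_time(
                 genotype("continuous", gamma = g, c = 0.15), p), 0)
  expect_true(all(diff(tg) < 0))
  expect_true(all(tg <= p$T_sur))
  # coarser thresholds are reached sooner
  gg <- genotype("continuous", gamma = 0.1, c = 0.15)
  expect_lte(aggregation_time(gg, p, epsilon = 0.5),
             aggregation_time(gg, p, epsilon = 1e-6))
  expect_error(aggregation_time(gg, p, epsilon = 2), "epsilon")
})

test_that("germination recruits the viable fraction when food is present", {
  p <- default_params()
  g1 <- germinate(1e4, 0.05, p)
  expect_equal(g1$recruits, 1e4)   # full viability for the slowest divider
  expect_equal(g1$died, 0)
  g2 <- germinate(1e5, 0.45, p)
  expect_equal(g2$recruits, 2e4)
  expect_equal(g2$died, 8e4)
  expect_identical(g2$spores, 0)
  g3 <- germinate(0, 0.45, p)
  expect_identical(g3$recruits, 0)
  # without food the pool stays dormant
  g4 <- germinate(1e5, 0.45, p, resources_available = FALSE)
  expect_identical(g4$spores, 1e5)
  expect_identical(g4$recruits, 0)
})

test_that("one full cycle composes growth, partitioning and starvation correctly", {
  p <- default_params()
  X0 <- 1e3; R0 <- 1e8
  # all-aggregating clone: spores decay from s * (X0 + R0)
  st <- apply_pulse(population_state(make_grid(1, 0.15), vegetative = X0),
                    R0)
  rc <- run_cycle(st, 150, p)
  expect_equal(sum(rc$state$spores),
               p$s * (X0 + R0) * exp(-p$delta * 150), tolerance = 1e-8)
  expect_identical(sum(rc$state$solitary), 0)
  expect_equal(rc$record$stalk_at_onset, (1 - p$s) * (X0 + R0),
               tolerance = 1e-8)
  # never-aggregating clone outlasted by the starvation period
  st <- apply_pulse(population_state(make_grid(0, 0.15), vegetative = X0),
                    R0)
  rc <- run_cycle(st, p$T_sur + 1, p)
  expect_identical(sum(total_cells(rc$state)), 0)
  # mixed strategy, instantaneous pulse return: 1 - alpha + s*alpha survive
  st <- apply_pulse(population_state(make_grid(0.5, 0.15),
                                     vegetative = X0), R0)
  rc <- run_cycle(st, 0, p)
  expect_equal(sum(rc$state$solitary) + sum(rc$state$spores),
               0.9 * (X0 + R0), tolerance = 1e-8)
})

test_that("spores carried into a cycle germinate after the lag and rejoin growth", {
  p <- default_params()
  grid <- make_grid(1, 0.05)   # full viability: no germination loss
  st <- population_state(grid, spores = 1e6)
  st <- apply_pulse(st, 1e8)
  rc <- run_cycle(st, 0, p)
  # all spores germinate, eat everything, and re-sporulate
  expect_equal(sum(rc$state$spores), p$s * (1e6 + 1e8), tolerance = 1e-8)
  expect_gt(rc$record$growth_duration, p$tau)
})
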