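test_that("clonal growth reaches the same carrying capacity for every genotype", {
  p <- default_params()
  grid <- reduced_grid()
  X0 <- 1e3; R0 <- 1e8
  for (i in seq(1, nrow(grid), by = 7)) {
    g <- genotype("discrete", alpha = grid$alpha[i], c = grid$c[i])
    res <- clonal_growth_assay(g, X0, R0, p)
    expect_equal(res$P, X0 + R0, tolerance = 1e-8)
    expect_equal(res$aggregators + res$non_aggregators, res$P)
    expect_equal(res$spores, p$s * res$aggregators)
  }
  a1 <- clonal_growth_assay(genotype("discrete", alpha = 1, c = 0.2),
                            X0, R0, p)
  expect_equal(a1$non_aggregators, 0)
  a3 <- clonal_growth_assay(genotype("discrete", alpha = 0.3, c = 0.2),
                            X0, R0, p)
  expect_equal(a3$aggregators / a3$non_aggregators, 3 / 7)
})

test_that("exponential growth plus abrupt starvation favours fast dividers", {
  p <- default_params()
  g <- genotype("discrete", alpha = 0.5, c = 0.2)
  e0 <- exponential_starve_assay(g, 1e3, 0, p)
  expect_equal(e0$spores, p$s * 0.5 * 1e3)
  e1 <- exponential_starve_assay(g, 1e3, 20, p)
  expect_equal(e1$population, 1e3 * exp(4), tolerance = 1e-12)
  expect_error(exponential_starve_assay(g, 1e3, 1e5, p), "overflow")
  # across an all-aggregating strain set, spores rank with division rate
  cs <- seq(0.05, 0.45, by = 0.1)
  sp <- vapply(cs, function(cc) exponential_starve_assay(
    genotype("discrete", alpha = 1, c = cc), 1e3, 20, p)$spores, 0)
  expect_gt(cor(sp, cs, method = "spearman"), 0)
  expect_true(all(diff(sp) > 0))
})

test_that("starvation-mix chimeric success has the alpha-ratio closed form", {
  p <- default_params()
  gA <- genotype("discrete", alpha = 0.8, c = 0.2)
  gB <- genotype("discrete", alpha = 0.4, c = 0.3)
  cs <- chimeric_success_starvation(gA, gB, 1e8, p)
  expect_equal(cs$cs[1], 0.8 / (0.8 + 0.4), tolerance = 1e-12)
  expect_equal(sum(cs$cs), 1, tolerance = 1e-15)
  expect_false(cs$tie)
  # identical genotypes split evenly
  same <- chimeric_success_starvation(gA, gA, 1e8, p)
  expect_identical(same$cs, c(0.5, 0.5))
  # two all-loner strains produce no spores: tie by convention
  z <- chimeric_success_starvation(genotype("discrete", alpha = 0, c = 0.1),
                                   genotype("discrete", alpha = 0, c = 0.2),
                                   1e8, p)
  expect_true(z$tie)
  expect_identical(z$cs, c(0.5, 0.5))
  # closed form holds across random pairs to 1e-12
  with_rng_stream(5, "cs-closed-form", {
    for (i in 1:10) {
      a <- runif(2); cc <- runif(2, 0.05, 0.45)
      r <- chimeric_success_starvation(
        genotype("discrete", alpha = a[1], c = cc[1]),
        genotype("discrete", alpha = a[2], c = cc[2]), 1e7, p)
      if (sum(a) > 0)
        expect_equal(r$cs[1], a[1] / (a[1] + a[2]), tolerance = 1e-12)
    }
  })
  expect_error(chimeric_success_starvation(
    gA, genotype("continuous", gamma = 1, c = 0.2), 1e8, p), "mechanism")
})

test_that("growth-starvation chimeric success reduces to the starvation measure at high density", {
  p <- default_params()
  gA <- genotype("discrete", alpha = 0.8, c = 0.2)
  gB <- genotype("discrete", alpha = 0.4, c = 0.3)
  s <- chimeric_success_starvation(gA, gB, 1e10, p)
  gs <- chimeric_success_growth_starvation(gA, gB, 1e10, 1e8, p)
  expect_equal(gs$cs[1], s$cs[1], tolerance = 0.01)
  expect_equal(sum(gs$cs), 1, tolerance = 1e-15)
  # at low density the faster divider dominates equal-alpha mixes
  g1 <- genotype("discrete", alpha = 0.5, c = 0.2)
  g2 <- genotype("discrete", alpha = 0.5, c = 0.1)
  low <- chimeric_success_growth_starvation(g1, g2, 1e3, 1e8, p)
  expect_gt(low$cs[1], 0.5)
  same <- chimeric_success_growth_starvation(g1, g1, 1e3, 1e8, p)
  expect_identical(same$cs, c(0.5, 0.5))
})

test_that("average chimeric success is the mean over partners", {
  p <- default_params()
  gl <- list(genotype("discrete", alpha = 0.2, c = 0.1),
             genotype("discrete", alpha = 0.5, c = 0.1),
             genotype("discrete", alpha = 0.9, c = 0.1))
  # same c: growth cancels and pairwise cs is the alpha ratio
  avg <- average_chimeric_success(gl, mode = "S", X0 = 1e6, params = p)
  exp_a <- c(mean(c(0.2 / 0.7, 0.2 / 1.1)),
             mean(c(0.5 / 0.7, 0.5 / 1.4)),
             mean(c(0.9 / 1.1, 0.9 / 1.4)))
  expect_equal(avg, exp_a, tolerance = 1e-12)
  expect_true(all(avg >= 0 & avg <= 1))
  # two genotypes: the average IS the pairwise value
  expect_equal(average_chimeric_success(gl[1:2], mode = "S", X0 = 1e6,
                                        params = p),
               c(0.2 / 0.7, 0.5 / 0.7), tolerance = 1e-12)
  # identical strains all sit at one half
  gsame <- list(gl[[2]], gl[[2]], gl[[2]])
  expect_equal(average_chimeric_success(gsame, mode = "S", X0 = 1e6,
                                        params = p), rep(0.5, 3))
  expect_error(average_chimeric_success(gl[1], mode = "S", params = p),
               "at least 2")
})

test_that("dominance matrices are antisymmetric with complete win/loss/tie accounting", {
  p <- default_params()
  set <- winnerlike_set()
  dm <- dominance_matrix(set, mode = "GS", X0 = 1e7, R0 = 1e8, params = p)
  n <- nrow(set)
  expect_true(all(diag(dm$outcome) == "tie"))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    expect_identical(dm$outcome[i, j] == "win", dm$outcome[j, i] == "loss")
    expect_equal(dm$cs[i, j] + dm$cs[j, i], 1, tolerance = 1e-12)
  }
  expect_equal(unname(dm$wins + dm$losses + dm$ties), rep(n - 1, n))
})

test_that("tournament ranking detects transitive orders and cyclic triples", {
  trans <- matrix("tie", 3, 3)
  trans[1, 2] <- trans[1, 3] <- trans[2, 3] <- "win"
  trans[2, 1] <- trans[3, 1] <- trans[3, 2] <- "loss"
  r <- rank_and_check_linearity(trans)
  expect_identical(r$ranking, c(1L, 2L, 3L))
  expect_true(r$is_transitive)
  expect_equal(nrow(r$violations), 0)
  rps <- matrix("tie", 3, 3)   # rock-paper-scissors
  rps[1, 2] <- rps[2, 3] <- rps[3, 1] <- "win"
  rps[2, 1] <- rps[3, 2] <- rps[1, 3] <- "loss"
  r2 <- rank_and_check_linearity(rps)
  expect_false(r2$is_transitive)
  expect_equal(nrow(r2$violations), 1)
})

test_that("density shifts re-order the middle of the hierarchy but not its ends", {
  p <- default_params()
  set <- winnerlike_set()
  lo <- dominance_matrix(set, mode = "GS", X0 = 1e3, R0 = 1e8, params = p)
  hi <- dominance_matrix(set, mode = "GS", X0 = 1e10, R0 = 1e8, params = p)
  expect_true(lo$is_transitive)
  expect_true(hi$is_transitive)
  # at high density the ranking is ordered by spore investment
  expect_true(all(diff(set$alpha[hi$ranking]) <= 0))
  # the intermediate-environment block (alpha rising as c falls)
  # interchanges under residual-growth vs long-growth conditions
  mid <- which(set$alpha > 0 & set$alpha < 1)
  expect_false(identical(match(mid, lo$ranking), match(mid, hi$ranking)))
  # a slow-environment winner stays on top and the fast-environment
  # (sporeless) winners stay at the bottom, at every density
  for (dm in list(lo, hi)) {
    expect_equal(set$alpha[dm$ranking[1]], 1)
    expect_true(all(set$alpha[dm$ranking[(nrow(set) - 1):nrow(set)]] == 0))
  }
})

test_that("continuous mechanism: spore output anti-correlates with aggregation time", {
  p <- default_params()
  gammas <- c(0.02, 0.05, 0.1, 0.3, 1)
  spores <- vapply(gammas, function(g)
    continuous_starvation(1e6, g, 0.15, p$T_sur, p)$spores, 0)
  tagg <- vapply(gammas, function(g)
    aggregation_time(genotype("continuous", gamma = g, c = 0.15), p), 0)
  expect_lt(cor(spores, tagg, method = "spearman"), 0)
})
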