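test_that("synthetic panels have the requested dimensions after QC refill", {
  g <- generate_genotypes(96, 2000, Fst = 0.1, seed = 71)
  expect_equal(dim(g$dosages), c(2000L, 96L))
  expect_true(all(pmin(g$allele_freq, 1 - g$allele_freq) > 0.05))
  expect_true(all(g$dosages %in% 0:2))
  # map sorted within chromosome
  sp <- split(g$position_cM, g$chromosome)
  expect_true(all(vapply(sp, function(v) !is.unsorted(v), logical(1))))
  expect_error(generate_genotypes(96, 100, Fst = 1), "Fst")
  expect_error(generate_genotypes(1, 100), "degenerate")
})

test_that("Fst = 0 panels show only binomial sampling noise between groups", {
  g <- generate_genotypes(200, 400, n_subpops = 2, Fst = 0, seed = 72)
  sp <- attr(g, "subpop")
  pvals <- apply(g$dosages, 1, function(x) {
    counts <- rbind(c(sum(x[sp == 1]), 2 * sum(sp == 1) - sum(x[sp == 1])),
                    c(sum(x[sp == 2]), 2 * sum(sp == 2) - sum(x[sp == 2])))
    suppressWarnings(stats::chisq.test(counts)$p.value)
  })
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)
})

test_that("structured panels separate on the first principal component", {
  g <- generate_genotypes(80, 400, n_subpops = 2, Fst = 0.2, seed = 73)
  sc <- compute_structure_covariates(g, 1)
  sp <- attr(g, "subpop")
  expect_true(abs(mean(sc$scores[sp == 1, 1] > 0) -
                    mean(sc$scores[sp == 2, 1] > 0)) > 0.9)
})

test_that("simulation spec validates its targets and fills defaults", {
  expect_error(simulation_spec("persistence", pve_qtl_target = 0.2,
                               h2_target = 0.5), "infeasible")
  expect_error(simulation_spec("persistence", h2_target = 1.2), "\\(0, 1\\)")
  s <- simulation_spec("crossover")
  expect_equal(unname(s$effect_by_env), c(-1, 1))
  expect_equal(unname(simulation_spec("divergence")$effect_by_env),
               c(0.5, 1))
})

test_that("calibration hits the PVE and heritability targets exactly", {
  r <- small_replicate(seed = 74, m = 60, I = 300)
  sim <- r$sim
  expect_equal(unname(sim$realized_pve), rep(0.1, 3), tolerance = 1e-5)
  expect_equal(sim$realized_h2, 0.5, tolerance = 1e-5)
  # realized quantities recomputable from the stored components
  y <- sim$values
  gen <- rowSums(sim$components$qtl_parts) + sim$components$u / sim$omega
  expect_equal(stats::var(gen) / stats::var(y), sim$realized_h2,
               tolerance = 1e-10)
  expect_equal(apply(sim$components$qtl_parts, 2, stats::var) / stats::var(y),
               unname(sim$realized_pve), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("per-trial QTL effects are identical within an environment", {
  r <- small_replicate(seed = 75, condition = "divergence", m = 40, I = 120)
  eff <- r$sim$truth$effect_by_trial
  d <- r$design
  for (e in d$environment_ids) {
    cols <- which(d$trial_env == e)
    expect_true(all(eff[, cols] == eff[, cols[1]]))
  }
})

test_that("the same seed reproduces y; new seeds keep calibration", {
  g <- generate_genotypes(40, 150, seed = 76)
  d <- complete_design(g)
  s1 <- simulate_phenotype(g, d, simulation_spec("persistence", seed = 10))
  s2 <- simulate_phenotype(g, d, simulation_spec("persistence", seed = 10))
  s3 <- simulate_phenotype(g, d, simulation_spec("persistence", seed = 11))
  expect_identical(s1$values, s2$values)
  expect_false(identical(s1$values, s3$values))
  expect_equal(s3$realized_h2, 0.5, tolerance = 1e-5)
  expect_equal(mean(s3$realized_pve), 0.1, tolerance = 1e-5)
})

test_that("convergence QTLs explain exactly zero variance in the null
           environment", {
  r <- small_replicate(seed = 77, condition = "convergence", m = 40, I = 120)
  pve_tr <- r$sim$realized_pve_per_trial
  a_trials <- which(r$design$trial_env == "A")
  b_trials <- which(r$design$trial_env == "B")
  expect_equal(unname(pve_tr[, a_trials]),
               matrix(0, 3, length(a_trials)), ignore_attr = TRUE)
  expect_true(all(pve_tr[, b_trials] > 0))
})

test_that("crossover effects cancel in the pooled dosage-phenotype
           correlation", {
  r <- small_replicate(seed = 78, condition = "crossover", m = 60, I = 200)
  d <- r$design
  qtl_total <- rowSums(r$sim$components$qtl_parts)
  for (i in r$sim$truth$qtl_index) {
    x <- drop(d$Z_G %*% r$geno$dosages[i, ])
    # the QTL contribution cancels exactly by the +-1 antisymmetry with
    # balanced trials; what remains of cor(x, y) is background sampling
    # noise of order 1/sqrt(m)
    expect_lt(abs(stats::cov(x, qtl_total)), 1e-10)
    expect_lt(abs(stats::cor(x, r$sim$values)), 0.2)
  }
})

test_that("calibration is invariant to rescaling the component draws", {
  r <- small_replicate(seed = 79, m = 40, I = 120)
  comp <- r$sim$components
  comp2 <- list(qtl_parts = comp$qtl_parts, u = 2 * comp$u,
                eps = 2 * comp$eps)
  cal2 <- calibrate_scalars(comp2, list(pve_qtl = 0.1, h2 = 0.5))
  expect_equal(mean(cal2$pve), 0.1, tolerance = 1e-6)
  expect_equal(cal2$h2, 0.5, tolerance = 1e-6)
  expect_equal(cal2$omega, 2 * r$sim$omega, tolerance = 1e-4)
  expect_equal(cal2$phi, 2 * r$sim$phi, tolerance = 1e-4)
})

test_that("with no background, omega is irrelevant and phi sets h2", {
  set.seed(80)
  qtl <- matrix(rnorm(300), 100, 3)
  comp <- list(qtl_parts = qtl, u = rep(0, 100), eps = rnorm(100))
  cal <- calibrate_scalars(comp, list(pve_qtl = 0.1, h2 = 0.5))
  expect_equal(cal$omega, 1)
  expect_equal(cal$h2, 0.5, tolerance = 1e-6)
  expect_error(calibrate_scalars(comp, list(pve_qtl = 0.2, h2 = 0.5)),
               "infeasible")
})

test_that("QTL selection respects the MAF floor and map spacing", {
  g <- generate_genotypes(60, 200, seed = 81)
  d <- complete_design(g)
  spec <- simulation_spec("persistence", seed = 82)
  sim <- simulate_phenotype(g, d, spec)
  tr <- sim$truth
  maf <- pmin(g$allele_freq, 1 - g$allele_freq)
  expect_true(all(maf[tr$qtl_index] >= 0.2))
  for (a in 1:2) for (b in (a + 1):3)
    expect_true(tr$chromosome[a] != tr$chromosome[b] ||
                  abs(tr$position_cM[a] - tr$position_cM[b]) >= 5)
  expect_error(simulate_phenotype(g, d, spec, min_qtl_maf = 0.51),
               "MAF")
})

test_that("genotype-by-trial draws are uncorrelated between trials", {
  g <- generate_genotypes(500, 1000, Fst = 0, seed = 83)
  G <- compute_grm(g)
  eg <- eigen(G, symmetric = TRUE)
  set.seed(84)
  draws <- replicate(4, drop(eg$vectors %*%
                               (sqrt(pmax(eg$values, 0)) * rnorm(500))))
  cc <- stats::cor(draws)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.1)
})
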