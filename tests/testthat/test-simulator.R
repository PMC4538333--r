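test_that("genotypes follow Hardy-Weinberg proportions and are reproducible", {
  g <- simulate_genotypes(6000, 4, maf = 0.2, seed = 1)
  freq <- tabulate(g + 1L, 3L) / length(g)
  expect_equal(freq, c(0.64, 0.32, 0.04), tolerance = 0.02)
  g5 <- simulate_genotypes(6000, 2, maf = 0.5, seed = 2)
  expect_equal(tabulate(g5 + 1L, 3L) / length(g5), c(0.25, 0.5, 0.25),
               tolerance = 0.02)
  expect_identical(simulate_genotypes(50, 3, 0.2, seed = 9),
                   simulate_genotypes(50, 3, 0.2, seed = 9))
  expect_error(simulate_genotypes(10, 2, 0.7), "maf")
  expect_error(simulate_genotypes(10, 2, 0), "maf")
})

test_that("gamma parameters solve the mean/variance relations exactly", {
  p <- gamma_params(2.0, 0.8)
  expect_equal(p$shape, 5.0)
  expect_equal(p$scale, 0.4)
  p <- gamma_params(1.0, 1.0) # exponential
  expect_equal(p$shape, 1.0)
  expect_equal(p$scale, 1.0)
  p <- gamma_params(0.5, 1.2)
  expect_equal(p$shape, 0.5^2 / 1.2, tolerance = 1e-12)
  expect_equal(p$scale, 2.4)
  # identities k*theta = f, k*theta^2 = sigma for arbitrary inputs
  for (f in c(0.3, 1.7)) for (s in c(0.8, 1.2)) {
    q <- gamma_params(f, s)
    expect_equal(q$shape * q$scale, f)
    expect_equal(q$shape * q$scale^2, s)
  }
  expect_error(gamma_params(-1, 1), "positive")
  expect_error(gamma_params(1, 0), "positive")
})

test_that("generated penetrance models hit the target heritability", {
  # the full MAF x heritability design grid is achievable
  for (maf in c(0.2, 0.4)) {
    for (h2 in c(0.01, 0.025, 0.05, 0.1, 0.2, 0.3, 0.4)) {
      m <- generate_penetrance(maf, h2, seed = round(1000 * (maf + h2)))
      expect_lt(abs(m$heritability - h2), 1e-3)
      expect_true(all(m$f > 0))
      # risk rule: high iff cell mean >= HWE-weighted mean
      w <- outer(c((1 - maf)^2, 2 * maf * (1 - maf), maf^2),
                 c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
      expect_identical(m$risk_class, m$f >= sum(w * m$f))
    }
  }
  # flat table has zero genetic variance
  flat <- matrix(2, 3, 3)
  w <- outer(c(0.64, 0.32, 0.04), c(0.64, 0.32, 0.04))
  vg <- sum(w * (flat - sum(w * flat))^2)
  expect_equal(vg, 0)
  expect_error(generate_penetrance(0.2, 0), "heritability")
  expect_error(generate_penetrance(0.2, 1), "heritability")
})

test_that("penetrance tables round-trip through the TSV format", {
  m <- generate_penetrance(0.2, 0.3, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_penetrance(m, path)
  m2 <- load_penetrance(path)
  expect_equal(m2$f, m$f)
  expect_equal(m2$maf, m$maf)
  expect_equal(m2$heritability, m$heritability)
  expect_identical(m2$risk_class, m$risk_class)
  # malformed inputs
  bad <- tempfile()
  writeLines(c("# maf\t0.2", "# heritability\t0.1",
               "1\t2\t3", "4\t5\t6"), bad)
  expect_error(load_penetrance(bad), "3 rows")
  writeLines(c("# maf\t0.2", "# heritability\t0.1",
               "1\t2\t3", "4\tx\t6", "7\t8\t9"), bad)
  expect_error(load_penetrance(bad), "non-numeric")
  writeLines(c("# maf\t0.2",
               "1\t2\t3", "4\t5\t6", "7\t8\t9"), bad)
  expect_error(load_penetrance(bad), "metadata")
  writeLines(c("# maf\t0.2", "# heritability\t0.1",
               "1\t2\t3", "4\t-5\t6", "7\t8\t9"), bad)
  expect_error(load_penetrance(bad, family = "gamma"), "positive")
})

test_that("emitted phenotypes satisfy the risk-group mean constraint", {
  for (fam in c("normal", "gamma", "mixed")) {
    cfg <- sim_config(family = fam, heritability = 0.2, seed = 17,
                      n_samples = 300)
    ds <- simulate_dataset(cfg)
    cells <- cbind(ds$genotypes[, 1] + 1L, ds$genotypes[, 2] + 1L)
    high <- ds$model$risk_class[cells]
    y <- as.numeric(ds$phenotype)
    expect_gte(mean(y[high]), mean(y))
    expect_lt(mean(y[!high]), mean(y))
  }
})

test_that("gamma emission reproduces per-cell moments", {
  cfg <- sim_config(family = "gamma", heritability = 0.3, sigma_high = 1.2,
                    sigma_low = 0.8, n_samples = 40000, n_snps = 2,
                    maf = 0.4, seed = 23)
  ds <- simulate_dataset(cfg)
  cells <- paste(ds$genotypes[, 1], ds$genotypes[, 2])
  y <- as.numeric(ds$phenotype)
  for (i in 0:2) for (j in 0:2) {
    sel <- cells == paste(i, j)
    if (sum(sel) < 500) next
    f <- ds$model$f[i + 1, j + 1]
    sig <- if (ds$model$risk_class[i + 1, j + 1]) 1.2 else 0.8
    expect_lt(abs(mean(y[sel]) - f), 6 * sqrt(sig / sum(sel)) + 0.02)
    expect_lt(abs(var(y[sel]) - sig), 0.2)
  }
})

test_that("datasets are reproducible and a flat-sigma degenerate model is null-like", {
  cfg <- sim_config(seed = 33)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$phenotype, d2$phenotype)
  # null dataset: no causal pair, phenotype independent of genotypes
  dn <- simulate_dataset(sim_config(causal = NULL, seed = 34))
  expect_length(dn$phenotype, 400)
  expect_null(dn$config$causal)
})

test_that("a large causal dataset recovers the model heritability", {
  cfg <- sim_config(family = "normal", heritability = 0.3, n_samples = 20000,
                    n_snps = 2, maf = 0.3, seed = 29)
  ds <- simulate_dataset(cfg)
  cell <- interaction(ds$genotypes[, 1], ds$genotypes[, 2])
  y <- as.numeric(ds$phenotype)
  fit <- stats::lm(y ~ cell)
  expect_equal(summary(fit)$r.squared, ds$model$heritability,
               tolerance = 0.05)
})

test_that("the full condition grid enumerates 1890 settings", {
  grid <- simulation_grid()
  expect_equal(nrow(grid), 3 * 70 * 9)
  # 70 penetrance models per family: 2 MAFs x 7 heritabilities x 5 reps
  one_family <- grid[grid$family == "normal" &
                       grid$sigma_high == 0.8 & grid$sigma_low == 0.8, ]
  expect_equal(nrow(one_family), 70)
  # alternative heritability grid is accepted
  g2 <- simulation_grid(heritabilities = c(0.01, 0.025, 0.05, 0.1,
                                           0.2, 0.3, 0.4))
  expect_equal(nrow(g2), 1890)
})
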