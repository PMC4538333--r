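make_dataset <- function(n = 90, p = 5, maf = 0.3, seed = 1,
                         heritability = 0.4) {
  simulate_dataset(sim_config(n_samples = n, n_snps = p, maf = maf,
                              heritability = heritability, seed = seed))
}

test_that("combo_index follows base-3 coding, first SNP most significant", {
  # full 9-category pair enumeration
  k <- 0L
  for (i in 0:2) for (j in 0:2) {
    expect_identical(combo_index(c(i, j)), k)
    k <- k + 1L
  }
  expect_identical(combo_index(c(0L)), 0L)
  expect_identical(combo_index(2L), 2L)
  expect_identical(combo_index(c(1L, 0L)), 3L)
  expect_identical(combo_index(c(2L, 2L, 2L)), 26L)
  expect_identical(combo_index(rbind(c(0, 1), c(2, 2))), c(1L, 8L))
  expect_error(combo_index(c(3L, 0L)), "0, 1, 2")
  expect_error(combo_index(c(0L, 1L, 2L, 0L)), "1 to 3")
})

test_that("conditional entropy is the class-weighted m-averaged entropy", {
  # two classes of sizes (2, 1): closed form for the pair, zero for the
  # singleton
  y <- c(0, 1, 5)
  g <- matrix(c(0L, 0L, 1L), ncol = 1)
  expect_equal(conditional_entropy(y, g, 1),
               (2 / 3) * (log(2) + euler_gamma), tolerance = 1e-12)
  # all samples in one category: equals the marginal entropy
  set.seed(3)
  y2 <- rnorm(30)
  g2 <- matrix(1L, nrow = 30, ncol = 1)
  expect_equal(conditional_entropy(y2, g2, 1), as.numeric(entropy_avg(y2)),
               tolerance = 1e-12)
  expect_equal(information_gain(y2, g2, 1), 0)
  # agreement with the naive per-class oracle on a real split
  ds <- make_dataset()
  lab <- ds$genotypes[, 1] * 3L + ds$genotypes[, 2]
  expect_equal(conditional_entropy(ds$phenotype, ds$genotypes, c(1, 2)),
               oracle_cond_entropy(as.numeric(ds$phenotype), lab),
               tolerance = 1e-10)
})

test_that("information gain is exactly scale-invariant and shifts with ln c", {
  # exact invariance requires every non-empty class to carry >= 2 samples
  # (classes of one sample contribute zero regardless of scale); use a
  # common-allele dataset where all 9 pair cells are populated
  ds <- make_dataset(n = 200, maf = 0.5, seed = 11)
  lab <- ds$genotypes[, 1] * 3L + ds$genotypes[, 2]
  expect_true(all(tabulate(lab + 1L, 9L) >= 2L)) # precondition of the identity
  y <- as.numeric(ds$phenotype)
  ig <- information_gain(y, ds$genotypes, c(1, 2))
  for (cc in c(0.01, 3.7, 250)) {
    expect_equal(information_gain(cc * y, ds$genotypes, c(1, 2)), ig,
                 tolerance = 1e-9)
    expect_equal(conditional_entropy(cc * y, ds$genotypes, c(1, 2)),
                 conditional_entropy(y, ds$genotypes, c(1, 2)) + log(cc),
                 tolerance = 1e-9)
  }
  # with singleton classes the deviation is exactly the uncovered weight
  ds2 <- make_dataset(seed = 11)
  lab2 <- ds2$genotypes[, 1] * 3L + ds2$genotypes[, 2]
  n1 <- sum(tabulate(lab2 + 1L, 9L) == 1L)
  expect_gt(n1, 0L) # this fixture does carry singleton cells
  y2 <- as.numeric(ds2$phenotype)
  dev <- conditional_entropy(3.7 * y2, ds2$genotypes, c(1, 2)) -
    conditional_entropy(y2, ds2$genotypes, c(1, 2))
  expect_equal(dev, (1 - n1 / length(y2)) * log(3.7), tolerance = 1e-9)
})

test_that("marginal entropy is invariant under phenotype permutation", {
  ds <- make_dataset(seed = 21)
  y <- as.numeric(ds$phenotype)
  h <- as.numeric(entropy_avg(y))
  for (i in 1:5) expect_identical(as.numeric(entropy_avg(sample(y))), h)
})

test_that("null summary statistics follow the n-1 definition", {
  nu <- null_summary(c(1, 3), order_d = 2)
  expect_equal(nu$ig_bar_p, 2)
  expect_equal(nu$s_p, sqrt(2))
  nu4 <- null_summary(c(2, 2, 2, 2), order_d = 1)
  expect_equal(nu4$s_p, 0)
  expect_error(igs_score(5, nu4), "degenerate")
})

test_that("igs_score standardizes against the null", {
  nu <- null_summary(c(0, 4), order_d = 2) # mean 2, sd sqrt(8)
  nu$s_p <- 2; nu$ig_bar_p <- 2 # direct Eq-style arithmetic check
  expect_equal(igs_score(10, nu), 4)
  expect_equal(igs_score(2, nu), 0)
  nu$s_p <- 0.5
  expect_equal(igs_score(1, nu), -2)
})

test_that("permutation p-values count exceeding maxima with a 1/n floor", {
  nu <- null_summary(seq_len(1000) / 1000, order_d = 2)
  expect_equal(permutation_pvalue(2, nu), 1 / 1000)  # above all maxima
  expect_equal(permutation_pvalue(-1, nu), 1.0)      # below all maxima
  expect_equal(permutation_pvalue(0.5005, nu), 0.5)  # at the median
  nu3 <- null_summary(c(1, 2, 3), order_d = 1)
  expect_equal(permutation_pvalue(2, nu3), 2 / 3)    # ties count as >=
})

test_that("permutation null is deterministic given a seed and order-matched", {
  ds <- make_dataset(seed = 31)
  combos <- list(c(1, 2), c(1, 3), c(2, 3))
  n1 <- permutation_null(ds$phenotype, ds$genotypes, combos, 25, seed = 5)
  n2 <- permutation_null(ds$phenotype, ds$genotypes, combos, 25, seed = 5)
  expect_identical(n1$max_igs, n2$max_igs)
  expect_identical(n1$order_d, 2L)
  expect_equal(n1$n_perm, 25L)
  # maxima dominate any single combo's null
  n_single <- permutation_null(ds$phenotype, ds$genotypes, list(c(1, 2)),
                               25, seed = 5)
  expect_true(all(n1$max_igs >= n_single$max_igs - 1e-12))
  expect_error(permutation_null(ds$phenotype, ds$genotypes,
                                list(c(1, 2), c(3)), 25, seed = 1),
               "share one interaction order")
  expect_error(permutation_null(ds$phenotype, ds$genotypes, combos, 1,
                                seed = 1), "at least 2")
})

test_that("scan enumerates all combinations and ranks reproducibly", {
  ds <- make_dataset(n = 120, p = 6, seed = 41)
  res <- scan_interactions(ds$phenotype, ds$genotypes, max_order = 2,
                           n_perm = 20, seed = 8)
  expect_equal(sum(res$order == 1), 6)
  expect_equal(sum(res$order == 2), choose(6, 2))
  expect_false(is.unsorted(rev(res$igs)))
  # class counts conserve the sample count for every combo
  counts <- lapply(strsplit(res$class_counts, "/"), as.integer)
  expect_true(all(vapply(counts, sum, 0L) == 120L))
  expect_true(all(vapply(counts[res$order == 1], length, 0L) == 3L))
  expect_true(all(vapply(counts[res$order == 2], length, 0L) == 9L))
  # determinism
  res2 <- scan_interactions(ds$phenotype, ds$genotypes, max_order = 2,
                            n_perm = 20, seed = 8)
  expect_identical(res$igs, res2$igs)
  expect_identical(res$p_value, res2$p_value)
  # nulls attached per order
  nulls <- attr(res, "nulls")
  expect_length(nulls, 2)
  expect_identical(vapply(nulls, `[[`, 0L, "order_d"), 1:2)
})

test_that("higher interaction order inflates raw IG on the same data", {
  mean_ig <- function(res, d) mean(res$ig[res$order == d])
  up <- 0L
  for (s in 1:3) {
    ds <- make_dataset(n = 100, p = 5, seed = 50 + s, heritability = 0.1)
    res <- scan_interactions(ds$phenotype, ds$genotypes, max_order = 3,
                             n_perm = 10, seed = s)
    if (mean_ig(res, 2) > mean_ig(res, 1) &&
        mean_ig(res, 3) > mean_ig(res, 2)) up <- up + 1L
  }
  expect_gte(up, 2L)
})

test_that("genotype validation rejects missing or out-of-range entries", {
  ds <- make_dataset()
  g <- ds$genotypes
  g[1, 1] <- NA
  expect_error(conditional_entropy(ds$phenotype, g, c(1, 2)), "missing")
  g[1, 1] <- 3L
  expect_error(conditional_entropy(ds$phenotype, g, c(1, 2)), "\\{0, 1, 2\\}")
  expect_error(conditional_entropy(ds$phenotype, ds$genotypes, c(1, 1)),
               "distinct")
  expect_error(conditional_entropy(ds$phenotype, ds$genotypes, c(1, 99)),
               "range")
})
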