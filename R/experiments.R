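#' Type-I error experiment on null datasets
#'
#' For each (family, heritability) condition, simulates datasets whose
#' phenotype is independent of every genotype ("no causal pair intended"),
#' computes the permutation p-value of a designated SNP pair in each
#' dataset (its observed IG against its own permutation null of `n_perm`
#' phenotype shuffles), and reports the fraction of datasets with
#' `p <= alpha`.  A well-calibrated method keeps this fraction near the
#' nominal level.
#'
#' Note the intrinsic discreteness of permutation p-values with the
#' `r / n_perm` floor convention: the exact per-pair rejection probability
#' at level alpha is `(floor(alpha * n_perm) + 1) / (n_perm + 1)` (5.09\%
#' at `n_perm = 1000`, 5.47\% at `n_perm = 200`, for alpha 0.05).
#'
#' @param families trait families to cover.
#' @param heritabilities heritability levels of the generating penetrance
#'   models (the null phenotype is the model's marginal mixture, so the
#'   level shapes the trait distribution but carries no association).
#' @param maf minor allele frequency.
#' @param n_datasets null datasets per condition.
#' @param n_perm permutations per dataset.
#' @param alpha significance level.
#' @param n_samples,n_snps dataset dimensions.
#' @param pair designated SNP pair whose p-value is tracked.
#' @param sigma_high,sigma_low risk-group dispersions.
#' @param seed optional integer seed for the whole experiment.
#' @return data frame with one row per condition: `family`, `heritability`,
#'   `n_datasets`, `rejections`, `rate`.
#' @export
type1_experiment <- function(families = c("normal", "gamma", "mixed"),
                             heritabilities = c(0.01, 0.02, 0.05, 0.1,
                                                0.2, 0.3, 0.4),
                             maf = 0.2, n_datasets = 100L, n_perm = 200L,
                             alpha = 0.05, n_samples = 400L, n_snps = 20L,
                             pair = c(1L, 2L),
                             sigma_high = 1.0, sigma_low = 1.0,
                             seed = NULL) {
  if (n_perm < 20L) stop("'n_perm' below 20 cannot resolve alpha = 0.05")
  if (n_datasets < 1L) stop("'n_datasets' must be positive")
  with_seed(seed, {
    grid <- expand.grid(family = families, heritability = heritabilities,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$n_datasets <- as.integer(n_datasets)
    grid$rejections <- 0L
    for (r in seq_len(nrow(grid))) {
      cfg <- sim_config(family = grid$family[r], maf = maf,
                        heritability = grid$heritability[r],
                        sigma_high = sigma_high, sigma_low = sigma_low,
                        n_samples = n_samples, n_snps = n_snps,
                        causal = NULL)
      rej <- 0L
      for (b in seq_len(n_datasets)) {
        ds <- simulate_dataset(cfg)
        ig <- information_gain(ds$phenotype, ds$genotypes, pair)
        null <- permutation_null(ds$phenotype, ds$genotypes, list(pair),
                                 n_perm = n_perm)
        if (permutation_pvalue(ig, null) <= alpha) rej <- rej + 1L
      }
      grid$rejections[r] <- rej
    }
    grid$rate <- grid$rejections / grid$n_datasets
    grid
  })
}

#' Detection-power (hit ratio) experiment
#'
#' For each (family, heritability) condition, simulates datasets with a
#' single causal SNP pair and counts a "hit" when that pair attains the top
#' IGS among all second-order combinations.  Within one interaction order
#' IGS is a fixed monotone transform of IG, so the top-IGS pair is found by
#' ranking raw IG — no permutations are needed for the hit ratio itself.
#'
#' @inheritParams type1_experiment
#' @param n_datasets causal datasets per condition.
#' @return data frame with one row per condition: `family`, `heritability`,
#'   `n_datasets`, `hits`, `hit_ratio`.
#' @export
power_experiment <- function(families = "normal",
                             heritabilities = c(0.01, 0.02, 0.05, 0.1,
                                                0.2, 0.3, 0.4),
                             maf = 0.2, n_datasets = 100L,
                             n_samples = 400L, n_snps = 20L,
                             sigma_high = 1.0, sigma_low = 1.0,
                             seed = NULL) {
  with_seed(seed, {
    pairs <- combn(n_snps, 2L)
    grid <- expand.grid(family = families, heritability = heritabilities,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$n_datasets <- as.integer(n_datasets)
    grid$hits <- 0L
    for (r in seq_len(nrow(grid))) {
      hits <- 0L
      for (b in seq_len(n_datasets)) {
        causal <- sort(sample.int(n_snps, 2L))
        cfg <- sim_config(family = grid$family[r], maf = maf,
                          heritability = grid$heritability[r],
                          sigma_high = sigma_high, sigma_low = sigma_low,
                          n_samples = n_samples, n_snps = n_snps,
                          causal = causal)
        ds <- simulate_dataset(cfg)
        y <- as.numeric(ds$phenotype)
        labels <- vapply(seq_len(ncol(pairs)), function(j)
          genotype_labels(ds$genotypes, pairs[, j]),
          integer(cfg$n_samples))
        hc <- cond_entropy_multi_cpp(y, labels, 9L)
        top <- which.min(hc) # max IG = min conditional entropy
        if (all(pairs[, top] == causal)) hits <- hits + 1L
      }
      grid$hits[r] <- hits
    }
    grid$hit_ratio <- grid$hits / grid$n_datasets
    grid
  })
}
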