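#' Simulation configuration
#'
#' Bundles the settings of one simulated dataset.  Defaults reproduce the
#' reference study conditions: 400 samples, 20 independent SNPs, a single
#' causal pair, and unit variance in both risk groups.
#'
#' The `sigma_high`/`sigma_low` dispersion parameters (conventionally drawn
#' from \{0.8, 1.0, 1.2\}) are interpreted per trait family as printed in
#' the emission laws: for the normal family sigma is the *standard
#' deviation* of \eqn{N(f_{ij}, \sigma^2)}; for the gamma family sigma is
#' the *variance*, via \eqn{f_{ij} = k\theta}, \eqn{\sigma = k\theta^2}.
#' Both interpretations are switchable through `normal_sigma` and
#' `gamma_sigma`.
#'
#' @param family trait emission family: `"normal"`, `"gamma"` or `"mixed"`
#'   (each genotype cell independently assigned normal or gamma with
#'   probability 1/2).
#' @param maf minor allele frequency in (0, 0.5].
#' @param heritability target fraction of trait variance explained by the
#'   causal pair, in (0, 1).
#' @param sigma_high,sigma_low dispersion of the high- and low-risk groups.
#' @param n_samples,n_snps dataset dimensions.
#' @param causal pair of causal SNP column indices, or `NULL` for a null
#'   dataset (phenotype independent of every genotype).
#' @param seed optional integer seed making the dataset reproducible.
#' @param normal_sigma,gamma_sigma `"sd"` or `"variance"`: how sigma is read
#'   for each family.
#' @return a `sim_config` list.
#' @export
sim_config <- function(family = c("normal", "gamma", "mixed"),
                       maf = 0.2, heritability = 0.1,
                       sigma_high = 1.0, sigma_low = 1.0,
                       n_samples = 400L, n_snps = 20L,
                       causal = c(1L, 2L), seed = NULL,
                       normal_sigma = c("sd", "variance"),
                       gamma_sigma = c("variance", "sd")) {
  family <- match.arg(family)
  normal_sigma <- match.arg(normal_sigma)
  gamma_sigma <- match.arg(gamma_sigma)
  if (!(maf > 0 && maf <= 0.5)) stop("'maf' must be in (0, 0.5]")
  if (!(heritability > 0 && heritability < 1))
    stop("'heritability' must be in (0, 1)")
  if (sigma_high <= 0 || sigma_low <= 0) stop("sigma values must be positive")
  if (!is.null(causal)) {
    causal <- sort(as.integer(causal))
    if (length(causal) != 2L || anyDuplicated(causal) ||
        any(causal < 1L) || any(causal > n_snps))
      stop("'causal' must be two distinct SNP indices within 1..n_snps")
  }
  structure(list(family = family, maf = maf, heritability = heritability,
                 sigma_high = sigma_high, sigma_low = sigma_low,
                 n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 causal = causal, seed = seed,
                 normal_sigma = normal_sigma, gamma_sigma = gamma_sigma),
            class = "sim_config")
}

#' Hardy-Weinberg genotype simulation
#'
#' Draws each SNP independently with genotype (minor-allele count)
#' frequencies \eqn{(1-q)^2, 2q(1-q), q^2} for counts 0/1/2 at minor allele
#' frequency q.
#'
#' @param n_samples,n_snps dimensions of the genotype matrix.
#' @param maf minor allele frequency in (0, 0.5].
#' @param seed optional integer seed.
#' @return integer matrix with rownames `S0001..` and colnames `SNP1..`.
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf, seed = NULL) {
  if (!(maf > 0 && maf <= 0.5)) stop("'maf' must be in (0, 0.5]")
  probs <- hwe_freqs(maf)
  g <- with_seed(seed,
    matrix(sample(0:2, n_samples * n_snps, replace = TRUE, prob = probs),
           nrow = n_samples, ncol = n_snps))
  storage.mode(g) <- "integer"
  dimnames(g) <- list(sprintf("S%04d", seq_len(n_samples)),
                      paste0("SNP", seq_len(n_snps)))
  g
}

hwe_freqs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

# 3x3 HWE cell weights for a two-locus table, rows = SNP1 genotype 0/1/2.
hwe_cell_weights <- function(maf) {
  w <- hwe_freqs(maf)
  outer(w, w)
}

#' Gamma emission parameters from a cell mean and dispersion
#'
#' Solves \eqn{f_{ij} = k\theta} and \eqn{\sigma = k\theta^2} for the shape
#' `k` and scale `theta` of the gamma emission in a genotype cell:
#' `k = f^2/sigma`, `theta = sigma/f`.
#'
#' @param f cell mean (penetrance value), positive.
#' @param sigma cell variance, positive.
#' @return named list with `shape` and `scale`.
#' @export
gamma_params <- function(f, sigma) {
  if (any(f <= 0) || any(sigma <= 0))
    stop("gamma emission needs positive mean and dispersion")
  list(shape = f^2 / sigma, scale = sigma / f)
}

# Per-cell emission variance implied by the risk classification and the
# family's reading of sigma; used by the heritability bookkeeping.
cell_variances <- function(risk_class, sigma_high, sigma_low, family,
                           normal_sigma = "sd", gamma_sigma = "variance") {
  sig <- ifelse(risk_class, sigma_high, sigma_low)
  norm_var <- if (normal_sigma == "sd") sig^2 else sig
  gamm_var <- if (gamma_sigma == "variance") sig else sig^2
  switch(family,
         normal = norm_var,
         gamma = gamm_var,
         mixed = (norm_var + gamm_var) / 2)
}

# Broad-sense heritability of a penetrance table under HWE cell weights:
# h2 = Var_G(f) / (Var_G(f) + E_G[cell variance]).
penetrance_h2 <- function(f, w, cell_var) {
  mu <- sum(w * f)
  vg <- sum(w * (f - mu)^2)
  vg / (vg + sum(w * cell_var))
}

#' Generate a two-locus penetrance model with target heritability
#'
#' Draws a random 3x3 table of genotype-cell trait means \eqn{f_{ij}} and
#' rescales its deviations about the HWE-weighted mean so that the
#' broad-sense heritability \eqn{h^2 = Var_G(f) / (Var_G(f) + E_G[\sigma^2])}
#' (cells weighted by HWE genotype frequencies at the given MAF) equals the
#' target.  A cell is classified high-risk iff its mean is at least the
#' weighted mean; the classification is invariant under the rescaling, and
#' the overall level is shifted so every cell mean stays positive (required
#' by gamma emission).
#'
#' This is a reproducible stand-in for externally published penetrance
#' tables; exact tables can be supplied through [load_penetrance()] instead.
#'
#' @inheritParams sim_config
#' @param family used only to translate sigma into per-cell variances for
#'   the heritability bookkeeping.
#' @return a `penetrance_model`: list with `f` (3x3 means), `maf`,
#'   `heritability` (achieved), `risk_class` (3x3 logical), `sigma_high`,
#'   `sigma_low`, `family`.
#' @export
generate_penetrance <- function(maf, heritability,
                                sigma_high = 1.0, sigma_low = 1.0,
                                family = c("normal", "gamma", "mixed"),
                                seed = NULL,
                                normal_sigma = "sd",
                                gamma_sigma = "variance") {
  family <- match.arg(family)
  if (!(heritability > 0 && heritability < 1))
    stop("'heritability' must be in (0, 1)")
  if (!(maf > 0 && maf <= 0.5)) stop("'maf' must be in (0, 0.5]")
  w <- hwe_cell_weights(maf)
  with_seed(seed, {
    for (attempt in 1:100) {
      f0 <- matrix(runif(9, 0.5, 1.5), 3, 3)
      mu0 <- sum(w * f0)
      vg0 <- sum(w * (f0 - mu0)^2)
      if (vg0 > 1e-8) break
    }
    if (vg0 <= 1e-8) stop("could not draw a table with genetic variance")
    risk <- f0 >= mu0
    ve <- sum(w * cell_variances(risk, sigma_high, sigma_low, family,
                                 normal_sigma, gamma_sigma))
    s <- sqrt(heritability / (1 - heritability) * ve / vg0)
    dev <- s * (f0 - mu0)
    level <- max(2, 0.25 - min(dev)) # keep all cell means positive
    f <- level + dev
    dimnames(f) <- list(paste0("SNP1_", 0:2), paste0("SNP2_", 0:2))
    achieved <- penetrance_h2(
      f, w, cell_variances(risk, sigma_high, sigma_low, family,
                           normal_sigma, gamma_sigma))
    structure(list(f = f, maf = maf, heritability = achieved,
                   risk_class = f >= sum(w * f),
                   sigma_high = sigma_high, sigma_low = sigma_low,
                   family = family),
              class = "penetrance_model")
  })
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf(
    "penetrance model: MAF = %.3f, heritability = %.4f, family = %s\n",
    x$maf, x$heritability, x$family))
  print(round(x$f, 4))
  invisible(x)
}

# Draw trait values for given per-sample cell means / dispersions / families.
emit_values <- function(f_vec, sig_vec, fam_vec, normal_sigma, gamma_sigma) {
  n <- length(f_vec)
  y <- numeric(n)
  is_norm <- fam_vec == "normal"
  if (any(is_norm)) {
    sdv <- if (normal_sigma == "sd") sig_vec[is_norm] else sqrt(sig_vec[is_norm])
    y[is_norm] <- rnorm(sum(is_norm), mean = f_vec[is_norm], sd = sdv)
  }
  if (any(!is_norm)) {
    varv <- if (gamma_sigma == "variance") sig_vec[!is_norm] else sig_vec[!is_norm]^2
    gp <- gamma_params(f_vec[!is_norm], varv)
    y[!is_norm] <- rgamma(sum(!is_norm), shape = gp$shape, scale = gp$scale)
  }
  y
}

#' Emit a phenotype from a penetrance model
#'
#' For each sample, looks up the genotype cell (i, j) at the causal pair and
#' draws the trait from \eqn{N(f_{ij}, \sigma^2_{cell})} or
#' \eqn{\Gamma(k, \theta)} according to the configured family, with the
#' cell dispersion chosen by its risk class.  For the mixed family each of
#' the 9 cells is assigned normal or gamma emission with probability 1/2
#' once per dataset.  The draw is repeated (up to 1000 times) until the
#' grouping constraint holds: the high-risk group mean is at least the
#' overall mean and the low-risk group mean is below it.
#'
#' @param genotypes genotype matrix containing the causal columns.
#' @param model a `penetrance_model`.
#' @param config a [sim_config()] with a non-`NULL` `causal` pair.
#' @return numeric phenotype vector, one value per sample.
#' @export
emit_phenotype <- function(genotypes, model, config) {
  stopifnot(inherits(model, "penetrance_model"),
            inherits(config, "sim_config"))
  if (is.null(config$causal))
    stop("emit_phenotype needs a causal pair; use a null config with simulate_dataset")
  check_genotypes(genotypes)
  i <- genotypes[, config$causal[1L]] + 1L
  j <- genotypes[, config$causal[2L]] + 1L
  cells <- cbind(i, j)
  f_vec <- model$f[cells]
  high <- model$risk_class[cells]
  sig_vec <- ifelse(high, config$sigma_high, config$sigma_low)
  fam_cell <- cell_families(config$family)
  fam_vec <- fam_cell[cells]
  for (attempt in seq_len(1000L)) {
    y <- emit_values(f_vec, sig_vec, fam_vec,
                     config$normal_sigma, config$gamma_sigma)
    if (grouping_ok(y, high)) return(y)
  }
  mo <- mean(y)
  stop(sprintf(paste0(
    "grouping constraint unsatisfied after 1000 redraws ",
    "(mean high = %.4f, mean low = %.4f, overall = %.4f)"),
    mean(y[high]), mean(y[!high]), mo))
}

# 3x3 table of per-cell emission families.
cell_families <- function(family) {
  if (family == "mixed")
    matrix(sample(c("normal", "gamma"), 9, replace = TRUE), 3, 3)
  else
    matrix(family, 3, 3)
}

grouping_ok <- function(y, high) {
  mo <- mean(y)
  (!any(high) || mean(y[high]) >= mo) && (!any(!high) || mean(y[!high]) < mo)
}

#' Simulate a genotype/phenotype dataset
#'
#' Generates Hardy-Weinberg genotypes and a quantitative trait under a
#' two-locus penetrance model.  With `config$causal` set, the phenotype
#' depends on the causal pair through the model; with `causal = NULL` a null
#' dataset is produced whose phenotype is drawn from the model's HWE-weighted
#' marginal mixture (a latent genotype cell is sampled from the HWE cell
#' frequencies, independent of every actual genotype), i.e. the same
#' generating scheme with no causal pair intended.
#'
#' @param config a [sim_config()].
#' @param model optional `penetrance_model` to reuse; generated from the
#'   config when absent.
#' @return an `mspacing_dataset`: list with `genotypes`, `phenotype` (named
#'   by sample), `config`, `model`.
#' @export
simulate_dataset <- function(config, model = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    if (is.null(model))
      model <- generate_penetrance(config$maf, config$heritability,
                                   config$sigma_high, config$sigma_low,
                                   family = config$family,
                                   normal_sigma = config$normal_sigma,
                                   gamma_sigma = config$gamma_sigma)
    geno <- simulate_genotypes(config$n_samples, config$n_snps, config$maf)
    y <- if (is.null(config$causal)) {
      # latent cells from HWE frequencies, independent of all genotypes
      li <- sample(1:3, config$n_samples, replace = TRUE,
                   prob = hwe_freqs(config$maf))
      lj <- sample(1:3, config$n_samples, replace = TRUE,
                   prob = hwe_freqs(config$maf))
      cells <- cbind(li, lj)
      fam_cell <- cell_families(config$family)
      emit_values(model$f[cells],
                  ifelse(model$risk_class[cells],
                         config$sigma_high, config$sigma_low),
                  fam_cell[cells], config$normal_sigma, config$gamma_sigma)
    } else {
      emit_phenotype(geno, model, config)
    }
    names(y) <- rownames(geno)
    structure(list(genotypes = geno, phenotype = y,
                   config = config, model = model),
              class = "mspacing_dataset")
  })
}

#' @export
print.mspacing_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated dataset: %d samples x %d SNPs, family = %s, causal = %s\n",
    nrow(x$genotypes), ncol(x$genotypes), x$config$family,
    if (is.null(x$config$causal)) "none"
    else paste(x$config$causal, collapse = ",")))
  invisible(x)
}

#' Full simulation condition grid
#'
#' Enumerates the complete study design: 3 trait families x 70 penetrance
#' models (5 model replicates x 7 heritabilities x 2 MAFs) x 9 high/low-risk
#' dispersion combinations = 1890 conditions.
#'
#' @param families trait families.
#' @param mafs minor allele frequencies.
#' @param heritabilities heritability levels (an alternative published grid
#'   swaps 0.02 for 0.025).
#' @param models_per_cell penetrance-model replicates per (MAF,
#'   heritability) combination.
#' @param sigmas dispersion levels used independently for the high- and
#'   low-risk groups.
#' @return data frame with one row per condition.
#' @export
simulation_grid <- function(families = c("normal", "gamma", "mixed"),
                            mafs = c(0.2, 0.4),
                            heritabilities = c(0.01, 0.02, 0.05, 0.1,
                                               0.2, 0.3, 0.4),
                            models_per_cell = 5L,
                            sigmas = c(0.8, 1.0, 1.2)) {
  grid <- expand.grid(family = families, maf = mafs,
                      heritability = heritabilities,
                      model_rep = seq_len(models_per_cell),
                      sigma_high = sigmas, sigma_low = sigmas,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid[order(grid$family, grid$maf, grid$heritability, grid$model_rep,
             grid$sigma_high, grid$sigma_low), , drop = FALSE]
}
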