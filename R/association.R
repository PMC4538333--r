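#' Genotype category index for a SNP combination
#'
#' Maps the genotype values (minor-allele counts 0/1/2) of d SNPs to a single
#' category in `0:(3^d - 1)` by base-3 positional encoding with the first SNP
#' most significant: for a pair, `(SNP_i = 0, SNP_j = 1)` is category 1 and
#' `(SNP_i = 2, SNP_j = 2)` is category 8.
#'
#' @param genotypes integer vector of length d (one genotype per SNP in the
#'   combination), or an n-by-d matrix of such rows; values in `{0, 1, 2}`,
#'   `1 <= d <= 3`.
#' @return integer category (or vector of categories for a matrix input).
#' @export
combo_index <- function(genotypes) {
  g <- if (is.matrix(genotypes)) genotypes else matrix(genotypes, nrow = 1L)
  d <- ncol(g)
  if (d < 1L || d > 3L) stop("a combination holds 1 to 3 SNPs")
  if (anyNA(g) || !all(g %in% 0:2))
    stop("genotype values must be minor-allele counts in {0, 1, 2}")
  idx <- integer(nrow(g))
  for (t in seq_len(d)) idx <- idx * 3L + as.integer(g[, t])
  if (is.matrix(genotypes)) idx else idx[1L]
}

# Per-sample category labels for one combination of genotype columns.
genotype_labels <- function(genotypes, snps) {
  lab <- integer(nrow(genotypes))
  for (t in seq_along(snps)) lab <- lab * 3L + as.integer(genotypes[, snps[t]])
  lab
}

check_genotypes <- function(genotypes) {
  if (!is.matrix(genotypes)) stop("'genotypes' must be a matrix")
  if (anyNA(genotypes))
    stop("missing genotypes are not accepted; impute or filter upstream")
  if (!all(genotypes %in% 0:2))
    stop("genotype entries must be minor-allele counts in {0, 1, 2}")
  invisible(genotypes)
}

check_combo <- function(snps, n_snps) {
  snps <- as.integer(snps)
  if (length(snps) < 1L || length(snps) > 3L)
    stop("a combination holds 1 to 3 SNP indices")
  if (anyNA(snps) || any(snps < 1L) || any(snps > n_snps))
    stop("SNP indices out of range")
  if (anyDuplicated(snps)) stop("SNP indices in a combination must be distinct")
  sort(snps)
}

#' Genotype-conditional entropy and information gain
#'
#' `conditional_entropy()` estimates \eqn{H(P \mid G) = \sum_g (n_g/n)
#' H(P \mid G = g)} where G is the 3^d-category coding of a d-SNP
#' combination and each class entropy uses the m-averaged spacing estimator
#' on that class's phenotype values (with its own spacing range
#' \eqn{m_g = 1, \dots, n_g - 1}).  Classes with at most one sample
#' contribute zero; their weight \eqn{n_g/n} suppresses them naturally.
#'
#' `information_gain()` returns \eqn{IG = H(P) - H(P \mid G)}, the
#' association strength of the combination with the trait.  IG is invariant
#' to rescaling of the phenotype (both entropies shift by \eqn{\ln c}) and
#' may be slightly negative on null data, which is legitimate for an
#' estimator of a non-negative quantity.
#'
#' @param phenotype numeric vector of trait values, one per sample.
#' @param genotypes n-by-p integer matrix of minor-allele counts in
#'   `{0, 1, 2}`.
#' @param snps integer vector of 1-3 distinct column indices (the
#'   combination; order does not matter).
#' @return a single number in nats.
#' @export
conditional_entropy <- function(phenotype, genotypes, snps) {
  check_sample(phenotype)
  check_genotypes(genotypes)
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length must match the genotype row count")
  snps <- check_combo(snps, ncol(genotypes))
  lab <- genotype_labels(genotypes, snps)
  h <- cond_entropy_cpp(as.numeric(phenotype), lab, 3L^length(snps))
  if (is.na(h))
    stop("degenerate (tied) phenotype values within a genotype class")
  h
}

#' @rdname conditional_entropy
#' @export
information_gain <- function(phenotype, genotypes, snps) {
  as.numeric(entropy_avg(phenotype)) -
    conditional_entropy(phenotype, genotypes, snps)
}

#' Permutation null of maximum information gain
#'
#' Shuffles the phenotype `n_perm` times while keeping all genotypes fixed,
#' and for each permuted dataset records the maximum IG over the candidate
#' combinations.  The mean \eqn{\overline{IG}_p} and standard deviation
#' \eqn{S_p} (n-1 denominator) of these maxima define the null used by
#' [igs_score()] and [permutation_pvalue()].  The marginal entropy
#' \eqn{H(P)} is permutation-invariant and computed once.
#'
#' All candidate combinations must share one interaction order d; a separate
#' null is built per order, which is what makes IGS comparable across
#' orders.  Passing a single combination yields that combination's own
#' (per-pair) permutation null, as used for type-I error calibration.
#'
#' @inheritParams conditional_entropy
#' @param combos list of SNP-index vectors, all of one length d (or a single
#'   index vector for one combination).
#' @param n_perm number of permutations, at least 2.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return a `null_summary` with fields `order_d`, `ig_bar_p`, `s_p`,
#'   `n_perm`, `max_igs`.
#' @export
permutation_null <- function(phenotype, genotypes, combos, n_perm,
                             seed = NULL) {
  check_sample(phenotype)
  check_genotypes(genotypes)
  if (!is.list(combos)) combos <- list(combos)
  if (length(combos) < 1L) stop("need at least one candidate combination")
  combos <- lapply(combos, check_combo, n_snps = ncol(genotypes))
  d <- length(combos[[1L]])
  if (!all(lengths(combos) == d))
    stop("all candidate combinations must share one interaction order")
  if (n_perm < 2L) stop("'n_perm' must be at least 2 (SD undefined below)")
  n <- length(phenotype)
  labels <- vapply(combos, genotype_labels, integer(n), genotypes = genotypes)
  hp <- as.numeric(entropy_avg(phenotype))
  maxima <- with_seed(seed,
    perm_max_ig_cpp(as.numeric(phenotype), labels, 3L^d, as.integer(n_perm),
                    hp))
  null_summary(maxima, d)
}

#' @rdname permutation_null
#' @param max_igs numeric vector of per-permutation maximum IGs.
#' @param order_d interaction order the maxima were taken over.
#' @export
null_summary <- function(max_igs, order_d) {
  if (length(max_igs) < 2L) stop("a null needs at least 2 permutation maxima")
  structure(
    list(order_d = as.integer(order_d),
         ig_bar_p = mean(max_igs),
         s_p = sd(max_igs),
         n_perm = length(max_igs),
         max_igs = as.numeric(max_igs)),
    class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "permutation null (order %d): mean max IG = %.6f, SD = %.6f, %d perms\n",
    x$order_d, x$ig_bar_p, x$s_p, x$n_perm))
  invisible(x)
}

#' Standardized information gain and permutation p-value
#'
#' `igs_score()` standardizes an observed IG against a permutation null:
#' \eqn{IGS = (IG - \overline{IG}_p) / S_p}.  Unlike raw IG, whose
#' distribution shifts upward with the interaction order, IGS is comparable
#' across orders.  `permutation_pvalue()` is the fraction of permutation
#' maxima at least as large as the observed IG, floored at `1/n_perm` (a
#' permutation p-value is never exactly zero).
#'
#' @param ig observed information gain.
#' @param null a `null_summary` of the same interaction order.
#' @return a single number.
#' @export
igs_score <- function(ig, null) {
  stopifnot(inherits(null, "null_summary"))
  if (!(null$s_p > 0))
    stop("degenerate permutation null: zero spread in maximum IG")
  (ig - null$ig_bar_p) / null$s_p
}

#' @rdname igs_score
#' @export
permutation_pvalue <- function(ig, null) {
  stopifnot(inherits(null, "null_summary"))
  r <- sum(null$max_igs >= ig)
  max(r, 1L) / null$n_perm
}

#' Exhaustive association scan over SNP combinations
#'
#' Enumerates every combination of `1:max_order` SNPs, computes its
#' information gain, builds one permutation null per interaction order
#' (maximum IG over all combinations of that order, per permutation), and
#' returns IGS scores and family-wise permutation p-values for every
#' combination, sorted by IGS (descending; ties broken by SNP index order).
#'
#' @inheritParams permutation_null
#' @param max_order largest interaction order to scan, 1 to 3.
#' @param snp_ids optional SNP identifiers (defaults to genotype column
#'   names, or `SNP1..SNPp`).
#' @return a data frame with one row per combination: `order`, `snps`,
#'   `class_counts` (3^d per-category sample counts joined by "/"), `ig`,
#'   `igs`, `p_value`.  Per-order `null_summary` objects are attached as
#'   `attr(, "nulls")`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_samples = 120, n_snps = 5,
#'                                   heritability = 0.4, seed = 1))
#' res <- scan_interactions(ds$phenotype, ds$genotypes, max_order = 2,
#'                          n_perm = 50, seed = 1)
#' head(res)
#' @export
scan_interactions <- function(phenotype, genotypes, max_order = 2L,
                              n_perm = 1000L, seed = NULL, snp_ids = NULL) {
  check_sample(phenotype)
  check_genotypes(genotypes)
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length must match the genotype row count")
  max_order <- as.integer(max_order)
  if (max_order < 1L || max_order > 3L) stop("'max_order' must be 1, 2 or 3")
  p <- ncol(genotypes)
  if (p < max_order) stop("need at least 'max_order' SNPs")
  snp_ids <- snp_ids %||% colnames(genotypes) %||% paste0("SNP", seq_len(p))
  n <- length(phenotype)
  y <- as.numeric(phenotype)
  hp <- as.numeric(entropy_avg(y))

  with_seed(seed, {
    nulls <- vector("list", max_order)
    pieces <- vector("list", max_order)
    for (d in seq_len(max_order)) {
      combos <- combn(p, d)
      ncat <- 3L^d
      labels <- vapply(seq_len(ncol(combos)), function(j)
        genotype_labels(genotypes, combos[, j]), integer(n))
      ig <- hp - cond_entropy_multi_cpp(y, labels, ncat)
      if (anyNA(ig))
        stop("degenerate (tied) phenotype values within a genotype class")
      maxima <- perm_max_ig_cpp(y, labels, ncat, as.integer(n_perm), hp)
      nulls[[d]] <- null_summary(maxima, d)
      counts <- vapply(seq_len(ncol(labels)), function(j)
        paste(tabulate(labels[, j] + 1L, nbins = ncat), collapse = "/"),
        character(1L))
      pieces[[d]] <- data.frame(
        order = d,
        snps = vapply(seq_len(ncol(combos)), function(j)
          paste(snp_ids[combos[, j]], collapse = ","), character(1L)),
        class_counts = counts,
        ig = ig,
        igs = vapply(ig, igs_score, 0.0, null = nulls[[d]]),
        p_value = vapply(ig, permutation_pvalue, 0.0, null = nulls[[d]]),
        key = vapply(seq_len(ncol(combos)), function(j)
          paste(sprintf("%06d", combos[, j]), collapse = ","), character(1L)),
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, pieces)
    res <- res[order(-res$igs, res$order, res$key), ]
    res$key <- NULL
    rownames(res) <- NULL
    attr(res, "nulls") <- nulls
    res
  })
}
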