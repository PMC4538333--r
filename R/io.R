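#' Read a genotype matrix from TSV or PLINK .raw text
#'
#' The TSV dialect is a header line plus one row per sample; a leading
#' `sample_id` (or `IID`/`ID`) column supplies sample identifiers and every
#' remaining column is one SNP of minor-allele counts in `{0, 1, 2}`.  The
#' PLINK `.raw` dialect is whitespace-separated with the six leading columns
#' `FID IID PAT MAT SEX PHENOTYPE` (skipped, `IID` kept as the sample id)
#' followed by SNP dosage columns.  Any entry outside `{0, 1, 2}` or missing
#' is an error naming the offending sample and SNP.
#'
#' @param path file to read.
#' @param dialect `"auto"` (detected from the header), `"tsv"` or
#'   `"plink_raw"`.
#' @return integer genotype matrix with sample ids as rownames.
#' @export
read_genotypes <- function(path, dialect = c("auto", "tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    header <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
    dialect <- if (length(header) >= 6L &&
                   identical(toupper(header[1:2]), c("FID", "IID")))
      "plink_raw" else "tsv"
  }
  if (dialect == "plink_raw") {
    tab <- read.table(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 7L) stop("PLINK .raw file has no SNP columns")
    ids <- as.character(tab[[2L]])
    geno <- tab[, -(1:6), drop = FALSE]
  } else {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    idcol <- which(tolower(names(tab)) %in% c("sample_id", "iid", "id"))[1]
    if (!is.na(idcol)) {
      ids <- as.character(tab[[idcol]])
      geno <- tab[, -idcol, drop = FALSE]
    } else {
      ids <- sprintf("S%04d", seq_len(nrow(tab)))
      geno <- tab
    }
  }
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(geno)
  suppressWarnings(storage.mode(m) <- "integer")
  bad <- which(is.na(m) | m < 0L | m > 2L, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "genotype entry outside {0,1,2} at sample '%s', SNP '%s'",
      ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  rownames(m) <- ids
  m
}

#' Read a phenotype vector from a two-column TSV
#'
#' Columns are sample id and trait value; a header line is detected and
#' skipped.  Duplicate ids and non-finite or non-numeric values are errors
#' (no imputation).
#'
#' @param path file to read.
#' @return named numeric vector of trait values.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2L])))
  tab <- read.delim(path, header = has_header, stringsAsFactors = FALSE,
                    colClasses = c("character", "character"))
  if (ncol(tab) != 2L) stop("phenotype file must have exactly 2 columns")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample ids in phenotype file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- suppressWarnings(as.numeric(tab[[2L]]))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad) > 0L)
    stop("non-numeric or non-finite phenotype value for sample '",
         ids[bad[1L]], "'")
  setNames(vals, ids)
}

#' Load / write a penetrance model as annotated TSV
#'
#' The format is comment metadata lines `# key<TAB>value` (at least `maf`
#' and `heritability`; optionally `sigma_high`, `sigma_low`, `family`)
#' followed by the 3x3 table of genotype-cell trait means, tab-separated.
#' Lets externally published penetrance tables be used in place of
#' [generate_penetrance()].
#'
#' @param path file to read or write.
#' @param family trait family the model will be used with; gamma emission
#'   requires strictly positive cell means.
#' @return `load_penetrance()` returns a `penetrance_model`;
#'   `write_penetrance()` returns the path invisibly.
#' @export
load_penetrance <- function(path, family = c("normal", "gamma", "mixed")) {
  family <- match.arg(family)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "\t")[[1]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
  }
  if (is.null(meta$maf) || is.null(meta$heritability))
    stop("penetrance file must carry '# maf' and '# heritability' metadata")
  if (length(body) != 3L)
    stop("penetrance table must have exactly 3 rows, found ", length(body))
  rows <- strsplit(body, "\t")
  if (any(lengths(rows) != 3L))
    stop("penetrance table must have exactly 3 columns per row")
  f <- suppressWarnings(matrix(as.numeric(unlist(rows)), nrow = 3L,
                               byrow = TRUE))
  if (anyNA(f)) stop("non-numeric cell in penetrance table")
  if (family == "gamma" && any(f <= 0))
    stop("gamma emission requires strictly positive penetrance values")
  maf <- as.numeric(meta$maf)
  sigma_high <- as.numeric(meta$sigma_high %||% 1.0)
  sigma_low <- as.numeric(meta$sigma_low %||% 1.0)
  w <- hwe_cell_weights(maf)
  dimnames(f) <- list(paste0("SNP1_", 0:2), paste0("SNP2_", 0:2))
  structure(list(f = f, maf = maf,
                 heritability = as.numeric(meta$heritability),
                 risk_class = f >= sum(w * f),
                 sigma_high = sigma_high, sigma_low = sigma_low,
                 family = meta$family %||% family),
            class = "penetrance_model")
}

#' @rdname load_penetrance
#' @param model a `penetrance_model`.
#' @export
write_penetrance <- function(model, path) {
  stopifnot(inherits(model, "penetrance_model"))
  meta <- c(sprintf("# maf\t%.17g", model$maf),
            sprintf("# heritability\t%.17g", model$heritability),
            sprintf("# sigma_high\t%.17g", model$sigma_high),
            sprintf("# sigma_low\t%.17g", model$sigma_low),
            sprintf("# family\t%s", model$family))
  body <- apply(model$f, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `genotypes.tsv` (sample_id + one column per SNP; or PLINK `.raw`
#' dialect as `genotypes.raw`), `phenotype.tsv` (sample_id, value) and
#' `metadata.json` (config, causal pair, achieved heritability, penetrance
#' table) into `dir`.
#'
#' @param dataset an `mspacing_dataset` from [simulate_dataset()].
#' @param dir output directory, created if needed.
#' @param geno_format `"tsv"` or `"plink_raw"`.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir, geno_format = c("tsv", "plink_raw")) {
  stopifnot(inherits(dataset, "mspacing_dataset"))
  geno_format <- match.arg(geno_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- dataset$genotypes
  if (geno_format == "tsv") {
    tab <- data.frame(sample_id = rownames(g), g, check.names = FALSE)
    write.table(tab, file.path(dir, "genotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(FID = rownames(g), IID = rownames(g), PAT = 0L,
                      MAT = 0L, SEX = 0L, PHENOTYPE = -9,
                      g, check.names = FALSE)
    write.table(tab, file.path(dir, "genotypes.raw"), sep = " ",
                quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(sample_id = names(dataset$phenotype),
                         value = sprintf("%.17g", dataset$phenotype)),
              file.path(dir, "phenotype.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  meta <- list(config = cfg[setdiff(names(cfg), "causal")],
               causal = cfg$causal,
               model = list(f = dataset$model$f,
                            maf = dataset$model$maf,
                            heritability = dataset$model$heritability,
                            risk_class = dataset$model$risk_class))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  invisible(dir)
}

#' Run a full association scan from genotype and phenotype files
#'
#' Loads and validates the inputs, aligns samples by id (erroring with the
#' offending ids on any mismatch), runs [scan_interactions()], and writes
#' `results.tsv` (ranked by IGS, 6 decimal places) plus `nulls.tsv` (the
#' per-order permutation null mean/SD) into `out_dir`.  Output files are
#' only written after the whole computation succeeds.
#'
#' @param geno_path,pheno_path input files for [read_genotypes()] /
#'   [read_phenotype()].
#' @param out_dir output directory, created if needed.
#' @inheritParams scan_interactions
#' @param dialect genotype file dialect, see [read_genotypes()].
#' @return the results data frame, invisibly.
#' @export
run_scan <- function(geno_path, pheno_path, out_dir, max_order = 2L,
                     n_perm = 1000L, seed = NULL, dialect = "auto") {
  geno <- read_genotypes(geno_path, dialect)
  pheno <- read_phenotype(pheno_path)
  only_g <- setdiff(rownames(geno), names(pheno))
  only_p <- setdiff(names(pheno), rownames(geno))
  if (length(only_g) || length(only_p))
    stop("sample id mismatch between genotype and phenotype files; ",
         "genotypes only: [", paste(only_g, collapse = ", "),
         "], phenotype only: [", paste(only_p, collapse = ", "), "]")
  pheno <- pheno[rownames(geno)]
  message(sprintf("scan: %d samples, %d SNPs, max_order = %d, n_perm = %d, seed = %s",
                  nrow(geno), ncol(geno), max_order, n_perm,
                  if (is.null(seed)) "NULL" else seed))
  res <- scan_interactions(pheno, geno, max_order = max_order,
                           n_perm = n_perm, seed = seed)
  nulls <- attr(res, "nulls")
  for (nu in nulls)
    message(sprintf("order %d null: mean max IG = %.6f, SD = %.6f",
                    nu$order_d, nu$ig_bar_p, nu$s_p))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- res
  out$ig <- sprintf("%.6f", out$ig)
  out$igs <- sprintf("%.6f", out$igs)
  out$p_value <- sprintf("%.6g", out$p_value)
  write.table(out, file.path(out_dir, "results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ntab <- data.frame(order = vapply(nulls, `[[`, 0L, "order_d"),
                     ig_bar_p = sprintf("%.6f",
                       vapply(nulls, `[[`, 0.0, "ig_bar_p")),
                     s_p = sprintf("%.6f", vapply(nulls, `[[`, 0.0, "s_p")),
                     n_perm = vapply(nulls, `[[`, 0L, "n_perm"))
  write.table(ntab, file.path(out_dir, "nulls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(res)
}
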