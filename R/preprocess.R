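# Count filtering, TMM/log-CPM normalization and batch-effect handling
# upstream of network construction.

#' Filter lowly expressed genes
#'
#' Retains exactly the genes with count strictly greater than `min_reads`
#' in at least `min_samples` samples. The rule is read in raw read units
#' ("more than 3 reads" means >= 4).
#'
#' @param counts a [count_matrix()].
#' @param min_reads count that must be exceeded (default 3).
#' @param min_samples minimum number of samples exceeding it (default 20).
#' @return the filtered `count_matrix`; the sample set is unchanged.
#' @export
filter_low_expression <- function(counts, min_reads = 3, min_samples = 20) {
  stopifnot(min_reads >= 0, min_samples >= 1)
  if (min_samples > ncol(counts))
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         ncol(counts), ")")
  keep <- rowSums(counts > min_reads) >= min_samples
  out <- counts[keep, , drop = FALSE]
  class(out) <- class(counts)
  out
}

#' Normalize counts to log2 counts-per-million
#'
#' Library-composition scaling factors are computed by trimmed mean of
#' M-values (TMM: reference sample with upper quartile closest to the mean
#' upper quartile; 30%/5% trimming of M/A values; factors normalized to
#' geometric mean 1), then expression is log2(CPM + 1) on the effective
#' library sizes (library size x scaling factor).
#'
#' @param counts a filtered [count_matrix()] with >= 2 samples.
#' @param method currently only "tmm_log_cpm".
#' @return an `expression_matrix`: numeric matrix (genes x samples) with
#'   attribute `norm_factors`.
#' @export
normalize_counts <- function(counts, method = "tmm_log_cpm") {
  method <- match.arg(method, "tmm_log_cpm")
  if (ncol(counts) < 2) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero sample(s): ", paste(colnames(counts)[lib == 0], collapse = ", "))
  nf <- edgeR::calcNormFactors(unclass(counts), method = "TMM")
  cpm <- sweep(unclass(counts), 2, lib * nf, "/") * 1e6
  expr <- log2(cpm + 1)
  attr(expr, "norm_factors") <- setNames(nf, colnames(counts))
  class(expr) <- c("expression_matrix", "matrix", "array")
  expr
}

#' Estimate and remove batch effects
#'
#' Fits, per gene, an ordinary least squares model of expression on the
#' named nuisance factors coded with sum-to-zero contrasts, and subtracts
#' the fitted batch terms. Biological factors are deliberately left
#' unmodeled, matching the contract of removing only the named nuisance
#' factors. The global magnitude of a factor is the root mean square of
#' its level coefficients over genes.
#'
#' @param expr an `expression_matrix`.
#' @param samples a [sample_table()] covering the expression columns.
#' @param factors character vector of sample-table column names to remove.
#' @return list with `estimates` (per factor: a genes x levels coefficient
#'   matrix plus `magnitude`) and `adjusted` (the corrected matrix).
#' @export
estimate_batch_effects <- function(expr, samples,
                                   factors = c("year", "block")) {
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  fl <- lapply(factors, function(f) {
    v <- factor(samples[[f]])
    if (nlevels(v) < 2) stop("factor '", f, "' has fewer than 2 levels")
    for (bio in c("stage")) {
      tab <- table(v, samples[[bio]])
      if (all(rowSums(tab > 0) == 1))
        warning("factor '", f, "' is confounded with ", bio,
                "; estimation proceeds")
    }
    v
  })
  names(fl) <- factors
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  design <- model.matrix(~ ., data = as.data.frame(fl))
  fit <- lm.fit(design, t(unclass(expr)))
  coefs <- t(fit$coefficients)              # genes x model columns
  batch_cols <- setdiff(colnames(design), "(Intercept)")
  fitted_batch <- coefs[, batch_cols, drop = FALSE] %*%
    t(design[, batch_cols, drop = FALSE])
  adjusted <- unclass(expr) - fitted_batch
  class(adjusted) <- c("expression_matrix", "matrix", "array")

  estimates <- lapply(factors, function(f) {
    v <- fl[[f]]
    cols <- grep(paste0("^", f), batch_cols, value = TRUE)
    b <- coefs[, cols, drop = FALSE]        # first L-1 sum-to-zero coefs
    last <- -rowSums(b)
    lev <- matrix(cbind(b, last), nrow(b),
                  dimnames = list(rownames(coefs), levels(v)))
    list(factor = f, coefficients = lev,
         magnitude = sqrt(mean(lev^2)))
  })
  names(estimates) <- factors
  list(estimates = estimates, adjusted = adjusted)
}
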