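# Signed weighted co-expression network: correlation, soft-thresholded
# adjacency, scale-free topology scan, topological overlap, module
# detection with eigengene merging, strong-correlation refinement,
# module meta-clustering, intramodular connectivity and hub ranking.

#' Pearson correlation between gene expression profiles
#'
#' @param expr `expression_matrix`, genes x samples, >= 3 samples.
#' @return symmetric correlation matrix with unit diagonal. Zero-variance
#'   genes are dropped with a warning.
#' @export
pearson_correlation <- function(expr) {
  if (ncol(expr) < 3) stop("need at least 3 samples for correlations")
  v <- apply(expr, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped")
    expr <- expr[v > 0, , drop = FALSE]
  }
  r <- cor(t(unclass(expr)))
  diag(r) <- 1
  r
}

#' Soft-thresholded adjacency
#'
#' Raises correlations to the power `beta` to amplify the disparity
#' between strong and weak co-expression:
#' * `unsigned`: |r|^beta
#' * `signed`: ((1 + r)/2)^beta
#' * `signed_hybrid`: r^beta for r > 0, else 0 (default: preserves the
#'   direction of co-variation while keeping adjacency = correlation^beta,
#'   so an adjacency cutoff of 0.1 at beta = 12 corresponds to r ~ 0.82).
#'
#' @param correlation symmetric correlation matrix.
#' @param beta soft-threshold power (integer >= 1).
#' @param variant adjacency functional form.
#' @return adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
adjacency <- function(correlation, beta = 12,
                      variant = c("signed_hybrid", "signed", "unsigned")) {
  variant <- match.arg(variant)
  if (beta < 1) stop("beta must be >= 1")
  a <- switch(variant,
              unsigned = abs(correlation)^beta,
              signed = ((1 + correlation) / 2)^beta,
              signed_hybrid = ifelse(correlation > 0, correlation^beta, 0))
  diag(a) <- 0
  a
}

#' Scale-free topology scan over candidate powers
#'
#' For each power, computes the connectivity distribution and the signed
#' scale-free fit index: R^2 of the regression of log10 frequency on
#' log10 mean connectivity over equal-count bins, signed by minus the
#' slope sign (positive when the degree distribution decays).
#'
#' @param correlation symmetric correlation matrix (>= 50 genes advised).
#' @param powers candidate powers.
#' @param variant adjacency variant, as in [adjacency()].
#' @param n_bins connectivity bins for the fit.
#' @return data.frame with columns power, fit_r2, mean_connectivity,
#'   median_connectivity, max_connectivity.
#' @export
soft_threshold_scan <- function(correlation, powers = 1:20,
                                variant = "signed_hybrid", n_bins = 10) {
  res <- lapply(powers, function(p) {
    a <- adjacency(correlation, beta = p, variant = variant)
    k <- rowSums(a)
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = p, fit_r2 = fit, mean_connectivity = mean(k),
               median_connectivity = median(k), max_connectivity = max(k))
  })
  do.call(rbind, res)
}

# Signed R^2 of the log-log degree-density regression over equal-count
# connectivity bins: density (frequency per unit connectivity) rather than
# raw frequency, which is constant by construction under quantile binning.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(NA_real_)
  brk <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 4) return(NA_real_)
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  dens <- (tapply(k, bin, length) / length(k)) / diff(brk)
  ok <- !is.na(dk) & dens > 0
  if (sum(ok) < 3) return(NA_real_)
  x <- log10(dk[ok]); y <- log10(dens[ok])
  f <- stats::lm(y ~ x)
  r2 <- summary(f)$r.squared
  unname(-sign(coef(f)[2]) * r2)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for
#' i != j, with unit diagonal: pairwise similarity combining direct
#' adjacency with shared-neighbor weight.
#'
#' @param adj symmetric adjacency matrix, zero diagonal, entries in \[0,1\].
#' @return TOM matrix in \[0, 1\].
#' @export
topological_overlap <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(adj)
  shared <- crossprod(adj)              # sum_u a_iu a_uj (diag irrelevant)
  minK <- outer(k, k, pmin)
  tom <- (shared + adj) / (minK + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# Fixed color palette for deterministic module naming, ordered so that
# larger modules receive the familiar early colors.
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta",
    "sienna", "lightsteelblue", "yellowgreen", "ivory", "floralwhite",
    "plum", "thistle", "salmon4", "palevioletred", "navajowhite",
    "brown4", "bisque", "darkslateblue", "coral", "honeydew", "orangered")
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on dissTOM = 1 - TOM, static
#' tree cut at `cut_height`, removal of clusters below `min_module_size`
#' (members labelled "unassigned"), then iterative merging of modules
#' whose eigengenes correlate above `merge_correlation` (requires `expr`;
#' skipped otherwise). Surviving modules are named with a fixed color
#' palette in order of decreasing size.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param expr optional `expression_matrix` (needed for eigengene merging).
#' @param min_module_size smallest retained cluster.
#' @param cut_height static cut height on the dissTOM dendrogram.
#' @param merge_correlation eigengene correlation above which modules merge.
#' @return a `module_set`: list with `labels` (named character, "unassigned"
#'   for background genes), `sizes`, `dendrogram`, and `eigengenes`
#'   (samples x modules, when `expr` given).
#' @export
detect_modules <- function(tom, expr = NULL, min_module_size = 30,
                           cut_height = 0.99, merge_correlation = 0.75) {
  if (nrow(tom) < 2) stop("need at least 2 genes")
  genes <- rownames(tom)
  diss <- 1 - tom
  h <- hclust(as.dist(diss), method = "average")
  cl <- cutree(h, h = cut_height)
  labels <- ifelse(tabulate(cl)[cl] >= min_module_size, paste0("m", cl),
                   "unassigned")
  names(labels) <- genes

  if (!is.null(expr) && length(setdiff(unique(labels), "unassigned")) >= 2) {
    repeat {
      mods <- setdiff(unique(labels), "unassigned")
      if (length(mods) < 2) break
      me <- eigengene_matrix(expr, labels, mods)
      rc <- cor(me)
      diag(rc) <- 0
      mx <- which(rc == max(rc), arr.ind = TRUE)[1, ]
      if (rc[mx[1], mx[2]] <= merge_correlation) break
      a <- mods[mx[1]]; b <- mods[mx[2]]
      labels[labels == b] <- a
    }
  }

  mods <- setdiff(unique(labels), "unassigned")
  sizes <- sort(table(factor(labels[labels != "unassigned"], levels = mods)),
                decreasing = TRUE)
  # deterministic tie-break: size desc, then first gene ID in the module
  first_gene <- vapply(names(sizes), function(m) min(genes[labels == m]), "")
  ord <- order(-as.integer(sizes), first_gene)
  pal <- module_palette()
  if (length(sizes) > length(pal))
    pal <- c(pal, sprintf("module%03d", seq_len(length(sizes) - length(pal))))
  rename <- setNames(pal[seq_along(sizes)], names(sizes)[ord])
  labels[labels != "unassigned"] <- rename[labels[labels != "unassigned"]]
  sizes <- table(factor(labels[labels != "unassigned"],
                        levels = unname(rename)))
  eg <- if (!is.null(expr) && length(rename))
    eigengene_matrix(expr, labels, unname(rename)) else NULL
  structure(list(labels = labels, sizes = sizes, dendrogram = h,
                 eigengenes = eg, retained = NULL),
            class = "module_set")
}

eigengene_matrix <- function(expr, labels, modules) {
  me <- vapply(modules, function(m) {
    module_eigengene(expr[names(labels)[labels == m], , drop = FALSE])
  }, numeric(ncol(expr)))
  rownames(me) <- colnames(expr)
  me
}

#' Module eigengene
#'
#' First principal component of the standardized within-module expression,
#' sign-oriented to correlate positively with the module's mean expression
#' profile, scaled to unit norm.
#'
#' @param expr_module expression submatrix (module genes x samples,
#'   >= 2 genes).
#' @return numeric vector over samples, unit Euclidean norm.
#' @export
module_eigengene <- function(expr_module) {
  if (nrow(expr_module) < 2) stop("module must have >= 2 genes")
  z <- t(scale(t(unclass(expr_module))))
  if (anyNA(z)) stop("constant gene expression in module; eigengene undefined")
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  m <- colMeans(z)
  if (sum(e * m) < 0) e <- -e
  e / sqrt(sum(e^2))
}

#' Module eigengenes for every module in a module set
#'
#' @param expr `expression_matrix`.
#' @param module_set result of [detect_modules()].
#' @return samples x modules matrix of unit-norm eigengenes.
#' @export
module_eigengenes <- function(expr, module_set) {
  mods <- setdiff(unique(module_set$labels), "unassigned")
  eigengene_matrix(expr, module_set$labels, mods)
}

#' Strong-correlation refinement of modules
#'
#' A gene is retained in its module iff its maximum within-module
#' adjacency to another member reaches `adjacency_threshold` (at the
#' default signed-hybrid power of 12, adjacency 0.1 corresponds to a
#' correlation of about 0.82). Modules with fewer than `min_retained`
#' retained genes are dropped from the retained map.
#'
#' @param adj adjacency matrix.
#' @param module_set a `module_set`.
#' @param adjacency_threshold minimum within-module adjacency (default 0.1).
#' @param min_retained minimum retained genes for a module to be kept.
#' @return the `module_set` with `retained` populated (module -> gene IDs).
#' @export
apply_strong_correlation_filter <- function(adj, module_set,
                                            adjacency_threshold = 0.1,
                                            min_retained = 3) {
  labels <- module_set$labels
  mods <- setdiff(unique(labels), "unassigned")
  retained <- list()
  for (m in mods) {
    g <- names(labels)[labels == m]
    if (length(g) < 2) next
    sub <- adj[g, g, drop = FALSE]
    diag(sub) <- 0
    keep <- g[apply(sub, 1, max) >= adjacency_threshold]
    if (length(keep) >= min_retained) retained[[m]] <- sort(keep)
  }
  module_set$retained <- retained
  module_set$adjacency_threshold <- adjacency_threshold
  module_set
}

#' Cluster module expression profiles into meta-clusters
#'
#' Correlates the modules' mean normalized expression profiles, clusters
#' 1 - r by average linkage, and cuts into `n_clusters` groups; also
#' returns the module x module correlation matrix for heatmap rendering.
#'
#' @param profiles samples x modules matrix (eigengenes or module mean
#'   standardized expression).
#' @param n_clusters number of meta-clusters.
#' @return list with `clusters` (named integer vector), `correlation`,
#'   `dendrogram`.
#' @export
cluster_module_profiles <- function(profiles, n_clusters = 7) {
  if (ncol(profiles) < n_clusters)
    stop("n_clusters exceeds the number of modules")
  rc <- cor(profiles)
  h <- hclust(as.dist(1 - rc), method = "average")
  cl <- cutree(h, k = n_clusters)
  list(clusters = cl, correlation = rc, dendrogram = h)
}

#' Intramodular connectivity
#'
#' Per gene: kTotal (whole-network connectivity), kWithin (connectivity to
#' same-module genes), kOut = kTotal - kWithin, kDiff = kWithin - kOut.
#' Unassigned genes have kWithin 0 by convention.
#'
#' @param adj adjacency matrix (zero diagonal).
#' @param module_set a `module_set` whose labels cover the adjacency genes.
#' @return data.frame: gene_id, module, kTotal, kWithin, kOut, kDiff.
#' @export
intramodular_connectivity <- function(adj, module_set) {
  genes <- rownames(adj)
  labels <- module_set$labels[genes]
  kTotal <- rowSums(adj)
  kWithin <- numeric(length(genes))
  for (m in setdiff(unique(labels), "unassigned")) {
    idx <- which(labels == m)
    kWithin[idx] <- rowSums(adj[idx, idx, drop = FALSE])
  }
  data.frame(gene_id = genes, module = unname(labels),
             kTotal = kTotal, kWithin = kWithin,
             kOut = kTotal - kWithin, kDiff = 2 * kWithin - kTotal,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank hub genes by intramodular connectivity
#'
#' Within each module, genes are sorted by kWithin descending (ties by
#' gene ID ascending); the top `top_n` and the top
#' `ceiling(top_fraction x module size)` are reported, either over all
#' members or over the strong-correlation retained subset, together with
#' the overlap between the two list lengths.
#'
#' @param connectivity output of [intramodular_connectivity()].
#' @param module_set a `module_set` (with `retained` populated when
#'   `use_retained = TRUE`).
#' @param top_n fixed-size hub list length (default 10).
#' @param top_fraction fractional hub list (default 0.10).
#' @param use_retained rank only the retained genes of each module.
#' @return named list per module: `ranked`, `top_n`, `top_fraction`,
#'   `overlap` (genes common to the two lists).
#' @export
rank_hub_genes <- function(connectivity, module_set, top_n = 10,
                           top_fraction = 0.10, use_retained = FALSE) {
  mods <- if (use_retained) names(module_set$retained)
          else setdiff(unique(module_set$labels), "unassigned")
  out <- lapply(mods, function(m) {
    g <- if (use_retained) module_set$retained[[m]]
         else names(module_set$labels)[module_set$labels == m]
    sub <- connectivity[connectivity$gene_id %in% g, , drop = FALSE]
    sub <- sub[order(-sub$kWithin, sub$gene_id), , drop = FALSE]
    n_frac <- ceiling(top_fraction * nrow(sub))
    t10 <- head(sub$gene_id, top_n)
    tfr <- head(sub$gene_id, n_frac)
    list(module = m, ranked = sub$gene_id, top_n = t10,
         top_fraction = tfr, overlap = intersect(t10, tfr))
  })
  setNames(out, mods)
}
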