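# Bait-gene neighborhood extraction: two-layer top-k correlated-gene
# subnetworks around MYB/NAC transcription factors, cell-wall enrichment
# counting and category classification.

#' Top-k correlated neighbors of a gene
#'
#' Ranks by raw signed correlation (matching the signed-network
#' convention: strong negative correlations do not qualify), self
#' excluded, ties broken by ascending gene ID.
#'
#' @param gene gene ID present in the correlation matrix.
#' @param correlation symmetric correlation matrix with gene dimnames.
#' @param k neighbors to return (default 15).
#' @return character vector of up to `k` gene IDs (with a warning when
#'   fewer than `k` candidates exist).
#' @export
top_neighbors <- function(gene, correlation, k = 15) {
  if (!gene %in% rownames(correlation)) stop("gene not in correlation matrix: ", gene)
  r <- correlation[gene, ]
  r <- r[names(r) != gene]
  if (length(r) < k) {
    warning("only ", length(r), " candidate neighbors for ", gene,
            " (k = ", k, ")")
    k <- length(r)
  }
  ord <- order(-r, names(r))
  names(r)[ord][seq_len(k)]
}

#' Two-layer top-k subnetwork around a bait gene
#'
#' Layer 1 is the bait's top-k correlated genes; layer 2 gathers the
#' top-k neighbors of every layer-1 gene (over the full gene pool). The
#' union list includes the bait, so its size is at most 1 + k + k^2
#' (241 for k = 15).
#'
#' @param bait bait gene ID.
#' @param correlation correlation matrix.
#' @param k per-gene neighbor count (default 15).
#' @return a `subnetwork`: list with `bait`, `k`, `layer1` (ordered),
#'   `layer2`, `union_list`, `size`.
#' @export
two_layer_subnetwork <- function(bait, correlation, k = 15) {
  l1 <- top_neighbors(bait, correlation, k)
  l2 <- unique(unlist(lapply(l1, top_neighbors, correlation = correlation,
                             k = k), use.names = FALSE))
  union_list <- sort(unique(c(bait, l1, l2)))
  structure(list(bait = bait, k = k, layer1 = l1,
                 layer2 = sort(setdiff(l2, c(bait, l1))),
                 union_list = union_list, size = length(union_list)),
            class = "subnetwork")
}

#' Classify a subnetwork's cell-wall enrichment level
#'
#' Number of significant cell-wall GO terms mapped to an ordinal
#' category: fewer than 3 -> "none", 3-5 -> "light", 6-11 -> "medium",
#' 12 or more -> "high" (the printed category bounds overlap at their
#' endpoints; the half-open reading keeps the classification total and
#' monotone).
#'
#' @param cw_term_count non-negative integer count of significant
#'   cell-wall terms.
#' @return factor level among none < light < medium < high.
#' @export
classify_cw_enrichment <- function(cw_term_count) {
  if (any(cw_term_count < 0)) stop("cell-wall term count must be >= 0")
  cut(cw_term_count, breaks = c(-Inf, 3, 6, 12, Inf), right = FALSE,
      labels = c("none", "light", "medium", "high"), ordered_result = TRUE)
}

#' Screen all bait transcription factors
#'
#' For every bait MYB/NAC gene: baits absent from the filtered expression
#' set are reported with status `excluded_low_expression`; baits whose
#' gene failed the strong-correlation retention get
#' `excluded_weak_correlation`; the remainder get their module label, the
#' two-layer subnetwork, the count of significant cell-wall GO terms in
#' the union list (BP + CC), and the enrichment category.
#'
#' @param bait_table data.frame with columns gene_id, tf_family, and
#'   optionally clade.
#' @param correlation correlation matrix over the filtered gene universe.
#' @param module_set a `module_set` with `retained` populated.
#' @param annotation an [annotation_table()] covering the baits.
#' @param keywords a [keyword_map()] of cell-wall keywords.
#' @param k subnetwork neighbor count.
#' @param alpha enrichment significance level.
#' @return data.frame, one row per bait, sorted by gene ID: gene_id,
#'   tf_family, clade, status, module, subnetwork_size, n_bp_cw_terms,
#'   n_cc_cw_terms, cw_term_count, category.
#' @export
screen_baits <- function(bait_table, correlation, module_set, annotation,
                         keywords, k = 15, alpha = 0.05) {
  missing_ann <- setdiff(bait_table$gene_id, annotation$genes$gene_id)
  if (length(missing_ann))
    stop("bait gene(s) absent from annotation: ",
         paste(missing_ann, collapse = ", "))
  universe <- rownames(correlation)
  retained_all <- unlist(module_set$retained, use.names = FALSE)
  bait_table <- bait_table[order(bait_table$gene_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(bait_table)), function(i) {
    g <- bait_table$gene_id[i]
    base <- data.frame(gene_id = g, tf_family = bait_table$tf_family[i],
                       clade = if ("clade" %in% names(bait_table))
                         bait_table$clade[i] else NA_character_,
                       status = "ok", module = NA_character_,
                       subnetwork_size = NA_integer_,
                       n_bp_cw_terms = NA_integer_,
                       n_cc_cw_terms = NA_integer_,
                       cw_term_count = NA_integer_,
                       category = NA_character_, stringsAsFactors = FALSE)
    if (!g %in% universe) {
      base$status <- "excluded_low_expression"
      return(base)
    }
    if (!g %in% retained_all) {
      base$status <- "excluded_weak_correlation"
      base$module <- unname(module_set$labels[g])
      return(base)
    }
    sn <- two_layer_subnetwork(g, correlation, k)
    enr <- term_enrichment(sn$union_list, annotation, universe, alpha = alpha)
    cwc <- count_cw_terms(enr, keywords)
    n_cw <- cwc$n_bp_cw_terms + cwc$n_cc_cw_terms
    base$module <- unname(module_set$labels[g])
    base$subnetwork_size <- sn$size
    base$n_bp_cw_terms <- cwc$n_bp_cw_terms
    base$n_cc_cw_terms <- cwc$n_cc_cw_terms
    base$cw_term_count <- n_cw
    base$category <- as.character(classify_cw_enrichment(n_cw))
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a subnetwork as a weighted edge list
#'
#' Generic `source TAB target TAB weight` rows for graph tools: all pairs
#' within the union list with correlation at or above `min_correlation`.
#'
#' @param subnetwork a `subnetwork`.
#' @param correlation correlation matrix.
#' @param min_correlation reporting threshold (default 0).
#' @return data.frame with columns source, target, weight.
#' @export
subnetwork_edges <- function(subnetwork, correlation, min_correlation = 0) {
  g <- intersect(subnetwork$union_list, rownames(correlation))
  sub <- correlation[g, g, drop = FALSE]
  el <- edge_list(sub, sub, threshold = min_correlation)
  data.frame(source = el$gene_a, target = el$gene_b,
             weight = el$correlation, stringsAsFactors = FALSE)
}
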