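# Over-representation statistics: GO terms (one-sided hypergeometric),
# the custom cell-wall gene list (one-sided Fisher), keyword grouping and
# cell-wall term counting.

#' GO term over-representation in a gene set
#'
#' Classic one-sided hypergeometric test per term: the upper-tail
#' probability P\[X >= set_count\] of drawing at least the observed number
#' of annotated genes when sampling `set_size` genes from the universe
#' without replacement. Terms with no annotated gene in the universe are
#' skipped.
#'
#' @param gene_set character vector, subset of `universe`.
#' @param annotation an [annotation_table()].
#' @param universe character vector of all genes entering the analysis
#'   (typically the genes surviving the expression filter).
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param adjust optionally "BH" for Benjamini-Hochberg adjusted
#'   significance calls instead of raw p-values.
#' @return data.frame with term, namespace, set_count, set_size,
#'   universe_count, universe_size, p_value, significant; sorted by
#'   p-value then term ID.
#' @export
term_enrichment <- function(gene_set, annotation, universe, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!length(universe)) stop("empty universe")
  extra <- setdiff(gene_set, universe)
  if (length(extra))
    stop("gene set not contained in universe: ", paste(head(extra, 5), collapse = ", "))
  empty <- data.frame(term = character(), namespace = character(),
                      set_count = integer(), set_size = integer(),
                      universe_count = integer(), universe_size = integer(),
                      p_value = numeric(), significant = logical())
  if (!length(gene_set)) return(empty)
  tr <- annotation$terms[annotation$terms$gene_id %in% universe, ]
  if (!nrow(tr)) return(empty)
  key <- paste(tr$term, tr$namespace)
  uni_count <- table(key)
  in_set <- tr$gene_id %in% gene_set
  set_count <- table(factor(key[in_set], levels = names(uni_count)))
  ns <- vapply(strsplit(names(uni_count), " ", fixed = TRUE), `[`, "", 2)
  trm <- vapply(strsplit(names(uni_count), " ", fixed = TRUE), `[`, "", 1)
  N <- length(universe); n <- length(gene_set)
  K <- as.integer(uni_count); x <- as.integer(set_count)
  p <- phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term = trm, namespace = ns, set_count = x, set_size = n,
                    universe_count = K, universe_size = N, p_value = p,
                    stringsAsFactors = FALSE)
  res$significant <- if (adjust == "BH")
    p.adjust(res$p_value, "BH") < alpha else res$p_value < alpha
  res <- res[order(res$p_value, res$term), ]
  rownames(res) <- NULL
  res
}

#' Enrichment of a module in the custom cell-wall gene list
#'
#' One-sided Fisher exact test on the 2x2 table (in module x in list)
#' over the analysis universe.
#'
#' @param module_genes character vector, subset of `universe`.
#' @param cw_list character vector of custom cell-wall genes (intersected
#'   with the universe).
#' @param universe all genes entering the analysis.
#' @param alpha significance level.
#' @return one-row data.frame: set_count, set_size, universe_count,
#'   universe_size, odds_ratio, p_value, significant.
#' @export
custom_list_enrichment <- function(module_genes, cw_list, universe,
                                   alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  extra <- setdiff(module_genes, universe)
  if (length(extra))
    stop("module genes not in universe: ", paste(head(extra, 5), collapse = ", "))
  cw <- intersect(cw_list, universe)
  a <- length(intersect(module_genes, cw))
  b <- length(module_genes) - a
  c_ <- length(cw) - a
  d <- length(universe) - a - b - c_
  ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                    alternative = "greater")
  data.frame(set_count = a, set_size = length(module_genes),
             universe_count = length(cw), universe_size = length(universe),
             odds_ratio = unname(ft$estimate), p_value = ft$p.value,
             significant = ft$p.value < alpha)
}

#' Group significant enriched terms by keyword
#'
#' @param enrichment result of [term_enrichment()].
#' @param keywords a [keyword_map()].
#' @return named list: keyword -> character vector of significant enriched
#'   member terms (a term may appear under several keywords).
#' @export
group_terms_by_keyword <- function(enrichment, keywords) {
  sig <- enrichment$term[enrichment$significant]
  lapply(keywords, function(members) sort(intersect(sig, members)))
}

#' Count significant cell-wall terms by namespace
#'
#' Distinct significant terms belonging to any of the cell-wall keyword
#' groups, split into Biological Process and Cellular Component counts.
#'
#' @param enrichment result of [term_enrichment()].
#' @param keywords a [keyword_map()].
#' @param cw_keywords keyword names considered cell-wall related
#'   (default: all keywords in the map).
#' @return list with `n_bp_cw_terms`, `n_cc_cw_terms`, `terms`.
#' @export
count_cw_terms <- function(enrichment, keywords,
                           cw_keywords = names(keywords)) {
  cw_terms <- unique(unlist(keywords[intersect(cw_keywords, names(keywords))]))
  sig <- enrichment[enrichment$significant & enrichment$term %in% cw_terms, ]
  sig <- sig[!duplicated(paste(sig$term, sig$namespace)), ]
  list(n_bp_cw_terms = length(unique(sig$term[sig$namespace == "BP"])),
       n_cc_cw_terms = length(unique(sig$term[sig$namespace == "CC"])),
       terms = sort(unique(sig$term)))
}
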