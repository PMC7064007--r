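# Shared data model + readers/writers for every on-disk artifact.
# All tabular I/O is plain TSV (UTF-8, '.' decimal); counts may alternatively
# be MatrixMarket. Gene/sample order is never semantic: deterministic outputs
# are sorted by ID.

#' Construct a validated count matrix
#'
#' A count matrix is a plain integer matrix (genes in rows, samples in
#' columns) with unique, non-empty dimnames and non-negative entries.
#'
#' @param counts numeric matrix of non-negative integers with rownames
#'   (gene IDs) and colnames (sample IDs).
#' @return the matrix, validated, with class `count_matrix` prepended.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' Construct a validated sample design table
#'
#' @param df data.frame with columns `sample_id`, `year`, `block`, `regime`
#'   (levels WW/WD), `internode_rank`, `stage`, `replicate`. `stage` must be
#'   an ordered factor or will be coerced to one using `stage_levels`.
#' @param stage_levels optional character vector giving the stage order.
#' @return a `sample_table` data.frame.
#' @export
sample_table <- function(df, stage_levels = NULL) {
  need <- c("sample_id", "year", "block", "regime", "internode_rank",
            "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in sample table")
  bad <- setdiff(unique(as.character(df$regime)), c("WW", "WD"))
  if (length(bad)) stop("unknown regime level(s): ", paste(bad, collapse = ", "))
  if (!is.ordered(df$stage)) {
    lv <- if (is.null(stage_levels)) sort(unique(as.character(df$stage))) else stage_levels
    df$stage <- factor(as.character(df$stage), levels = lv, ordered = TRUE)
  }
  if (anyNA(df$stage)) stop("stage values outside declared levels")
  df$year <- factor(df$year)
  df$block <- factor(df$block)
  df$regime <- factor(df$regime, levels = c("WW", "WD"))
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Construct a gene annotation table
#'
#' Bundles per-gene GO term sets (with BP/CC namespace), the custom
#' cell-wall list flag, transcription-factor family and clade, and the bait
#' flag used for subnetwork screening.
#'
#' @param genes data.frame with columns `gene_id`, `cw_custom` (logical),
#'   `tf_family` (one of "MYB", "NAC", "none"), `clade` (character, NA
#'   allowed), `is_bait` (logical).
#' @param terms data.frame of gene-term pairs with columns `gene_id`,
#'   `term`, `namespace` (one of "BP", "CC").
#' @return an `annotation_table` (list with elements `genes` and `terms`).
#' @export
annotation_table <- function(genes, terms) {
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene IDs in annotation")
  genes$tf_family <- as.character(genes$tf_family)
  bad <- setdiff(unique(genes$tf_family), c("MYB", "NAC", "none"))
  if (length(bad)) stop("unknown tf_family: ", paste(bad, collapse = ", "))
  if (any(genes$is_bait & genes$tf_family == "none"))
    stop("bait genes must have a TF family")
  bad_ns <- setdiff(unique(terms$namespace), c("BP", "CC"))
  if (length(bad_ns)) stop("unknown GO namespace: ", paste(bad_ns, collapse = ", "))
  terms <- unique(terms[, c("gene_id", "term", "namespace")])
  rownames(genes) <- rownames(terms) <- NULL
  structure(list(genes = genes, terms = terms), class = "annotation_table")
}

#' GO term sets of one or more genes
#'
#' @param annotation an `annotation_table`.
#' @param gene_ids character vector of gene IDs.
#' @return named list mapping each gene to its character vector of term IDs.
#' @export
go_terms <- function(annotation, gene_ids) {
  tr <- annotation$terms[annotation$terms$gene_id %in% gene_ids, ]
  out <- split(tr$term, factor(tr$gene_id, levels = gene_ids))
  lapply(out, unique)
}

#' Construct a keyword -> GO term grouping map
#'
#' Keyword groups gather related ontology terms (e.g. an "SCW" keyword
#' bundling the secondary-cell-wall biogenesis terms) so enrichment results
#' can be read off at the process level. A term may belong to several
#' keywords.
#'
#' @param df data.frame with columns `keyword`, `term`.
#' @return a `keyword_map`: named list of character term vectors.
#' @export
keyword_map <- function(df) {
  if (!all(c("keyword", "term") %in% names(df)))
    stop("keyword map needs columns keyword, term")
  if (!all(grepl("^\\S+$", df$term))) stop("malformed GO term IDs")
  km <- lapply(split(df$term, df$keyword), function(x) sort(unique(x)))
  structure(km, class = "keyword_map")
}

#' Construct a validated fiber biochemistry table
#'
#' Van Soest fractions in percent of dry matter: NDF (total fiber), ADF
#' (lignocellulose), ADL (lignin), satisfying 0 <= ADL <= ADF <= NDF <= 100.
#'
#' @param df data.frame with columns `sample_id`, `NDF`, `ADF`, `ADL`.
#' @return a `biochem_table` data.frame.
#' @export
biochem_table <- function(df) {
  need <- c("sample_id", "NDF", "ADF", "ADL")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("biochem table missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(df$ADL >= 0 & df$ADF >= df$ADL & df$NDF >= df$ADF & df$NDF <= 100))
  if (length(bad))
    stop("fiber ordering 0 <= ADL <= ADF <= NDF <= 100 violated for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("biochem_table", "data.frame")
  df
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, quote = "")
}

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV layout: header row of sample IDs, first column of gene IDs. A
#' MatrixMarket (.mtx) file is accepted for sparse counts, with gene and
#' sample IDs in sibling `<stem>.genes.txt` / `<stem>.samples.txt` files
#' (one ID per line).
#'
#' @param path file path (.tsv or .mtx).
#' @return a `count_matrix`.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".genes.txt"))
    colnames(m) <- readLines(paste0(stem, ".samples.txt"))
    return(count_matrix(m))
  }
  df <- read_tsv_strict(path)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric count cell at row ", bad[1, 1] + 1L, ", column ",
         colnames(df)[-1][bad[1, 2]])
  }
  rownames(m) <- genes
  count_matrix(m)
}

#' Load and cross-reference a full input dataset
#'
#' Reads counts, sample design, gene-GO annotation pairs, the custom
#' cell-wall gene list, the bait TF table, and the keyword map, validating
#' cross-references: every count-matrix sample must appear in the sample
#' table; custom-list genes absent from the counts are kept (with a
#' warning giving their number) since annotation sources routinely exceed
#' the expressed gene set.
#'
#' @param counts_path counts TSV/MTX.
#' @param samples_path sample table TSV.
#' @param annotations_path 3-column TSV `gene_id`, `term`, `namespace`
#'   (namespace defaulting to BP when the column is missing).
#' @param cw_list_path plain text, one gene ID per line.
#' @param keyword_path 2-column TSV `keyword`, `term`.
#' @param baits_path optional TSV `gene_id`, `tf_family`, `clade`.
#' @return list with `counts`, `samples`, `annotation`, `keywords`.
#' @export
load_dataset <- function(counts_path, samples_path, annotations_path,
                         cw_list_path, keyword_path, baits_path = NULL) {
  counts <- read_counts(counts_path)
  samples <- sample_table(read_tsv_strict(samples_path))
  missing_samples <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_samples))
    stop("samples present in counts but absent from sample table: ",
         paste(missing_samples, collapse = ", "))
  pairs <- read_tsv_strict(annotations_path)
  if (!"namespace" %in% names(pairs)) pairs$namespace <- "BP"
  names(pairs)[1:2] <- c("gene_id", "term")
  cw <- readLines(cw_list_path)
  cw <- cw[nzchar(cw)]
  n_absent <- sum(!cw %in% rownames(counts))
  if (n_absent)
    warning(n_absent, " custom cell-wall list gene(s) absent from the count matrix")
  baits <- if (is.null(baits_path)) NULL else read_tsv_strict(baits_path)
  all_genes <- sort(unique(c(rownames(counts), pairs$gene_id, cw,
                             if (!is.null(baits)) baits$gene_id)))
  genes <- data.frame(gene_id = all_genes,
                      cw_custom = all_genes %in% cw,
                      tf_family = "none", clade = NA_character_,
                      is_bait = FALSE, stringsAsFactors = FALSE)
  if (!is.null(baits)) {
    idx <- match(baits$gene_id, genes$gene_id)
    genes$tf_family[idx] <- baits$tf_family
    if ("clade" %in% names(baits)) genes$clade[idx] <- baits$clade
    genes$is_bait[idx] <- TRUE
  }
  annotation <- annotation_table(genes, pairs)
  keywords <- keyword_map(read_tsv_strict(keyword_path))
  list(counts = counts, samples = samples, annotation = annotation,
       keywords = keywords)
}

#' Write a pipeline artifact deterministically
#'
#' Tables are written as TSV with rows sorted by their first (ID) column;
#' edge lists as `gene_a TAB gene_b TAB correlation TAB adjacency` with
#' `gene_a < gene_b` lexicographically; module assignments as
#' `gene_id TAB module`. Round-trips through [read_artifact()] are exact
#' for tables.
#'
#' @param object the object to save (matrix or data.frame; for
#'   `edge_list`, a list with `correlation` and `adjacency` matrices and
#'   a reporting `threshold` on adjacency).
#' @param path output file path.
#' @param kind one of "table", "counts", "edge_list", "module_assignment",
#'   "report".
#' @export
save_artifact <- function(object, path,
                          kind = c("table", "counts", "edge_list",
                                   "module_assignment", "report")) {
  kind <- match.arg(kind)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (kind == "counts") {
    m <- object[order(rownames(object)), order(colnames(object)), drop = FALSE]
    df <- data.frame(gene_id = rownames(m), as.data.frame(unclass(m)),
                     check.names = FALSE)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (kind == "edge_list") {
    el <- edge_list(object$correlation, object$adjacency,
                    threshold = object$threshold %||% 0)
    write.table(el, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (kind == "module_assignment") {
    df <- data.frame(gene_id = names(object) %||% character(),
                     module = as.character(unname(object)))
    df <- df[order(df$gene_id), , drop = FALSE]
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- as.data.frame(object)
    if (nrow(df)) df <- df[order(df[[1]]), , drop = FALSE]
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a saved artifact
#'
#' @param path file written by [save_artifact()].
#' @param kind artifact kind used when saving.
#' @return a `count_matrix` for kind "counts", a named character vector for
#'   "module_assignment", otherwise a data.frame.
#' @export
read_artifact <- function(path, kind = c("table", "counts", "edge_list",
                                         "module_assignment", "report")) {
  kind <- match.arg(kind)
  if (kind == "counts") return(read_counts(path))
  df <- read_tsv_strict(path)
  if (kind == "module_assignment") return(setNames(df$module, df$gene_id))
  df
}

#' Turn symmetric correlation/adjacency matrices into a sorted edge list
#'
#' One row per unordered gene pair with adjacency >= `threshold`; no
#' self-pairs; `gene_a < gene_b` lexicographically; rows sorted by
#' (gene_a, gene_b).
#'
#' @param correlation symmetric correlation matrix with gene dimnames.
#' @param adjacency matching adjacency matrix.
#' @param threshold minimum adjacency for a pair to be reported.
#' @return data.frame with columns gene_a, gene_b, correlation, adjacency.
#' @export
edge_list <- function(correlation, adjacency, threshold = 0) {
  g <- rownames(correlation)
  ut <- upper.tri(correlation)
  keep <- ut & adjacency >= threshold
  idx <- which(keep, arr.ind = TRUE)
  a <- g[idx[, 1]]; b <- g[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(gene_a = a, gene_b = b,
                   correlation = correlation[idx],
                   adjacency = adjacency[idx], stringsAsFactors = FALSE)
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
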