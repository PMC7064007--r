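# Evidence integration, clade composition summaries and end-to-end
# pipeline orchestration.

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-clade lineage composition
#'
#' Counts genes per clade and the share belonging to a focal lineage,
#' with nearest-integer (half away from zero) percentages.
#'
#' @param membership data.frame with columns gene_id, clade, lineage.
#' @param lineage focal lineage label (default "monocot").
#' @return data.frame: clade, n_total, n_lineage, pct_lineage; sorted by
#'   clade.
#' @export
clade_composition <- function(membership, lineage = "monocot") {
  need <- c("gene_id", "clade", "lineage")
  miss <- setdiff(need, names(membership))
  if (length(miss)) stop("membership table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(membership$lineage))
    stop("gene(s) missing lineage: ",
         paste(membership$gene_id[is.na(membership$lineage)], collapse = ", "))
  sp <- split(membership$lineage, membership$clade)
  out <- data.frame(clade = names(sp),
                    n_total = vapply(sp, length, 0L),
                    n_lineage = vapply(sp, function(v) sum(v == lineage), 0L),
                    stringsAsFactors = FALSE)
  out$pct_lineage <- as.integer(round_half_up(100 * out$n_lineage / out$n_total))
  out <- out[order(out$clade), ]
  rownames(out) <- NULL
  out
}

#' Modules with convergent cell-wall evidence
#'
#' A module is flagged cell-wall related when it is enriched both in the
#' custom cell-wall gene list (Fisher p < alpha) and in at least one
#' cell-wall GO term — the dual criterion used to shortlist modules for
#' regulator screening.
#'
#' @param module_set a `module_set` with retained sets populated.
#' @param annotation an [annotation_table()].
#' @param keywords a [keyword_map()].
#' @param universe analysis gene universe.
#' @param alpha significance level.
#' @return data.frame per retained module: module, n_genes, n_retained,
#'   cw_list_p, n_cw_go_terms, cw_related.
#' @export
flag_cw_modules <- function(module_set, annotation, keywords, universe,
                            alpha = 0.05) {
  cw_list <- annotation$genes$gene_id[annotation$genes$cw_custom]
  mods <- names(module_set$retained)
  rows <- lapply(mods, function(m) {
    members <- intersect(names(module_set$labels)[module_set$labels == m],
                         universe)
    fis <- custom_list_enrichment(members, cw_list, universe, alpha)
    enr <- term_enrichment(members, annotation, universe, alpha)
    cwc <- count_cw_terms(enr, keywords)
    n_cw <- cwc$n_bp_cw_terms + cwc$n_cc_cw_terms
    data.frame(module = m, n_genes = length(members),
               n_retained = length(module_set$retained[[m]]),
               cw_list_p = fis$p_value, n_cw_go_terms = n_cw,
               cw_related = fis$p_value < alpha & n_cw >= 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Integrated evidence table for bait transcription factors
#'
#' One row per bait combining module membership, hub status (top-10 /
#' top-10% by intramodular connectivity within the bait's module),
#' subnetwork size and cell-wall enrichment category, sorted by category
#' (high first), then cell-wall term count descending, then gene ID —
#' a total order.
#'
#' @param module_set a `module_set` with retained sets.
#' @param connectivity output of [intramodular_connectivity()].
#' @param bait_screen output of [screen_baits()].
#' @param annotation an [annotation_table()].
#' @return data.frame of evidence rows.
#' @export
build_evidence_table <- function(module_set, connectivity, bait_screen,
                                 annotation) {
  bad <- setdiff(bait_screen$gene_id, annotation$genes$gene_id)
  if (length(bad))
    stop("bait(s) outside the annotation universe: ", paste(bad, collapse = ", "))
  hubs <- rank_hub_genes(connectivity, module_set, use_retained = TRUE)
  df <- bait_screen
  df$is_hub_top10 <- FALSE
  df$is_hub_top10pct <- FALSE
  for (i in seq_len(nrow(df))) {
    m <- df$module[i]
    if (df$status[i] == "ok" && !is.na(m) && m %in% names(hubs)) {
      df$is_hub_top10[i] <- df$gene_id[i] %in% hubs[[m]]$top_n
      df$is_hub_top10pct[i] <- df$gene_id[i] %in% hubs[[m]]$top_fraction
    }
  }
  cat_rank <- match(df$category, c("high", "medium", "light", "none"))
  cat_rank[is.na(cat_rank)] <- 5L
  cwc <- ifelse(is.na(df$cw_term_count), -1L, df$cw_term_count)
  df <- df[order(cat_rank, -cwc, df$gene_id), ]
  rownames(df) <- NULL
  df[, c("gene_id", "tf_family", "clade", "module", "is_hub_top10",
         "is_hub_top10pct", "subnetwork_size", "cw_term_count", "category",
         "status")]
}

#' Run the full pipeline from a configuration
#'
#' Stages: simulate (optional) -> preprocess -> network -> enrichment ->
#' subnetworks -> biochem (optional) -> report. Artifacts and a JSON run
#' manifest (parameters, seed, per-stage row counts) are written to
#' `output_dir`. Any stage error aborts with the stage name.
#'
#' @param config path to a YAML configuration file, or an equivalent
#'   named list. Recognized sections: `seed`, `output_dir`, `simulate`
#'   (logical or list of [sim_config()] arguments), `input` (paths for
#'   [load_dataset()] when not simulating), `preprocess` (min_reads,
#'   min_samples, batch_factors), `network` (power, variant,
#'   adj_threshold, min_module_size, cut_height, merge_correlation,
#'   min_retained), `subnet` (k), `enrich` (alpha), `biochem` (logical).
#' @return invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir %||% "stemnet_output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[stemnet] ", ...)
  stage <- function(name, fun) {
    log_stage("stage: ", name)
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dat <- if (isTRUE(config$simulate) || is.list(config$simulate)) {
    stage("simulate", function() {
      args <- if (is.list(config$simulate)) config$simulate else list()
      args$seed <- seed
      generate_dataset(do.call(sim_config, args))
    })
  } else {
    inp <- config$input
    if (is.null(inp)) stop("config error: no input section and simulate disabled")
    stage("load", function()
      c(load_dataset(inp$counts, inp$samples, inp$annotations, inp$cw_list,
                     inp$keywords, inp$baits), list(biochem = NULL, truth = NULL)))
  }

  pp <- config$preprocess %||% list()
  net_cfg <- config$network %||% list()
  res <- stage("preprocess", function() {
    filt <- filter_low_expression(dat$counts,
                                  min_reads = pp$min_reads %||% 3,
                                  min_samples = pp$min_samples %||% 20)
    expr <- normalize_counts(filt)
    be <- estimate_batch_effects(expr, dat$samples,
                                 factors = pp$batch_factors %||% c("year", "block"))
    list(filtered = filt, expr = be$adjusted, batch = be$estimates)
  })

  net <- stage("network", function() {
    r <- pearson_correlation(res$expr)
    a <- adjacency(r, beta = net_cfg$power %||% 12,
                   variant = net_cfg$variant %||% "signed_hybrid")
    tom <- topological_overlap(a)
    ms <- detect_modules(tom, expr = res$expr,
                         min_module_size = net_cfg$min_module_size %||% 30,
                         cut_height = net_cfg$cut_height %||% 0.99,
                         merge_correlation = net_cfg$merge_correlation %||% 0.75)
    ms <- apply_strong_correlation_filter(a, ms,
            adjacency_threshold = net_cfg$adj_threshold %||% 0.1,
            min_retained = net_cfg$min_retained %||% 3)
    conn <- intramodular_connectivity(a, ms)
    list(correlation = r, adjacency = a, modules = ms, connectivity = conn)
  })

  alpha <- (config$enrich %||% list())$alpha %||% 0.05
  universe <- rownames(res$expr)
  cw_flags <- stage("enrichment", function()
    flag_cw_modules(net$modules, dat$annotation, dat$keywords, universe,
                    alpha = alpha))

  baits <- dat$annotation$genes[dat$annotation$genes$is_bait,
                                c("gene_id", "tf_family", "clade")]
  screen <- stage("subnetworks", function()
    screen_baits(baits, net$correlation, net$modules, dat$annotation,
                 dat$keywords, k = (config$subnet %||% list())$k %||% 15,
                 alpha = alpha))
  evidence <- stage("report", function()
    build_evidence_table(net$modules, net$connectivity, screen,
                         dat$annotation))

  bc_summary <- NULL
  if (!is.null(dat$biochem) && !isFALSE(config$biochem)) {
    bc_summary <- stage("biochem", function() {
      fr <- derive_wall_fractions(dat$biochem)
      do.call(rbind, lapply(c("hemicellulose", "cellulose", "lignin"),
                            function(tr) compare_stages(fr, dat$samples, tr)))
    })
  }

  stage("write", function() {
    save_artifact(dat$samples, file.path(out_dir, "samples.tsv"), "table")
    save_artifact(net$modules$labels, file.path(out_dir, "modules.tsv"),
                  "module_assignment")
    retained <- unlist(lapply(names(net$modules$retained), function(m)
      setNames(rep(m, length(net$modules$retained[[m]])),
               net$modules$retained[[m]])))
    save_artifact(retained %||% character(),
                  file.path(out_dir, "retained_genes.tsv"), "module_assignment")
    save_artifact(net$connectivity, file.path(out_dir, "connectivity.tsv"),
                  "table")
    save_artifact(cw_flags, file.path(out_dir, "module_cw_enrichment.tsv"),
                  "table")
    save_artifact(screen, file.path(out_dir, "bait_screen.tsv"), "table")
    save_artifact(evidence, file.path(out_dir, "evidence.tsv"), "table")
    if (!is.null(bc_summary))
      save_artifact(bc_summary, file.path(out_dir, "biochem_stages.tsv"),
                    "table")
    manifest <- list(
      seed = seed,
      package_version = as.character(utils::packageVersion("stemnet")),
      config = config,
      stages = list(
        n_samples = nrow(dat$samples),
        n_genes_input = nrow(dat$counts),
        n_genes_filtered = nrow(res$filtered),
        n_modules = length(setdiff(unique(net$modules$labels), "unassigned")),
        n_modules_retained = length(net$modules$retained),
        n_baits = nrow(baits),
        n_baits_ok = sum(screen$status == "ok")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  log_stage("done: ", out_dir)
  invisible(list(data = dat, preprocess = res, network = net,
                 cw_modules = cw_flags, bait_screen = screen,
                 evidence = evidence, biochem = bc_summary))
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same genes;
#' 1 for identical partitions (up to label names), about 0 for unrelated
#' ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_i * sum_j / n2
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
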