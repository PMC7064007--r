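# Synthetic developing-internode datasets with planted co-expression
# structure: a multi-year unbalanced field design, negative-binomial counts
# driven by unimodal stage profiles, GO/cell-wall annotations concentrated
# in chosen modules, and Van Soest fiber trajectories.

#' Specification of one planted co-expression module
#'
#' @param module_id label for the planted module.
#' @param n_genes number of member genes (>= 1).
#' @param peak_stage stage label at which the latent profile peaks.
#' @param amplitude loading of the latent profile on log2 expression.
#' @param within_correlation target mean pairwise Pearson correlation of
#'   member log-CPM profiles, in (0, 1).
#' @param cw_annotation_rate probability that a member gene carries
#'   cell-wall GO terms and the custom-list flag.
#' @param n_bait_tfs number of member genes designated MYB/NAC baits.
#' @return a `module_spec` list.
#' @export
module_spec <- function(module_id, n_genes, peak_stage, amplitude = 2,
                        within_correlation = 0.9, cw_annotation_rate = 0,
                        n_bait_tfs = 0) {
  stopifnot(n_genes >= 1, amplitude >= 0,
            within_correlation > 0, within_correlation < 1,
            cw_annotation_rate >= 0, cw_annotation_rate <= 1,
            n_bait_tfs >= 0, n_bait_tfs <= n_genes)
  structure(list(module_id = module_id, n_genes = n_genes,
                 peak_stage = peak_stage, amplitude = amplitude,
                 within_correlation = within_correlation,
                 cw_annotation_rate = cw_annotation_rate,
                 n_bait_tfs = n_bait_tfs), class = "module_spec")
}

#' Default planted-module set
#'
#' Five modules of 60 genes peaking at successive developmental stages.
#' The two late-peaking modules mimic SCW modules: saturated cell-wall
#' annotation and several planted bait TFs; the early modules mimic
#' elongation/primary-wall modules with no CW annotation.
#' @return list of `module_spec`.
#' @export
default_module_specs <- function() {
  list(
    module_spec("M1", 60, "D1", amplitude = 2, within_correlation = 0.9,
                cw_annotation_rate = 0,   n_bait_tfs = 2),
    module_spec("M2", 60, "D2", amplitude = 2, within_correlation = 0.9,
                cw_annotation_rate = 0,   n_bait_tfs = 2),
    module_spec("M3", 60, "D3", amplitude = 2, within_correlation = 0.9,
                cw_annotation_rate = 1,   n_bait_tfs = 3),
    module_spec("M4", 60, "D4", amplitude = 2, within_correlation = 0.9,
                cw_annotation_rate = 1,   n_bait_tfs = 3),
    module_spec("M5", 60, "D5", amplitude = 2, within_correlation = 0.9,
                cw_annotation_rate = 0,   n_bait_tfs = 2)
  )
}

#' Simulation configuration
#'
#' @param n_genes_total total genes (planted + background).
#' @param module_specs list of [module_spec()] objects.
#' @param design design configuration from [default_design_config()].
#' @param library_size_range range of per-sample library sizes (log-uniform).
#' @param dispersion negative-binomial dispersion (> 0).
#' @param seed integer seed fixing all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes_total = 2000,
                       module_specs = default_module_specs(),
                       design = default_design_config(),
                       library_size_range = c(5e5, 2e6),
                       dispersion = 0.05,
                       seed = 1L) {
  n_mod <- sum(vapply(module_specs, function(s) s$n_genes, 0))
  if (n_mod > n_genes_total)
    stop("module genes (", n_mod, ") exceed n_genes_total (", n_genes_total, ")")
  if (dispersion <= 0) stop("dispersion must be > 0")
  structure(list(n_genes_total = n_genes_total, module_specs = module_specs,
                 n_background_genes = n_genes_total - n_mod,
                 design = design, library_size_range = library_size_range,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default field design configuration (191 internode samples)
#'
#' Emulates a three-year unbalanced internode sampling design:
#' * 2013 — internodes 12 and 16, five stages (D1–D5), two water regimes,
#'   four replicates; internode 16 absent at D1 (not yet emerged) and one
#'   replicate lost, giving 71 samples;
#' * 2014 — six internode levels over three stages (13/15 at all three,
#'   14/16 at the first only, 17/19 at the last two), two regimes, three
#'   replicates: 72 samples;
#' * 2015 — four internode levels at two stages, two regimes, three
#'   replicates: 48 samples.
#' Total 191.
#'
#' @return a `design_config` list; each cell block declares year, ranks,
#'   stages, regimes and replicates, with an optional `drop` mask of
#'   sample keys.
#' @export
default_design_config <- function() {
  structure(list(
    stage_levels = paste0("D", 1:5),
    blocks = list(
      list(year = "2013", ranks = 12, stages = paste0("D", 1:5),
           regimes = c("WW", "WD"), replicates = 4),
      list(year = "2013", ranks = 16, stages = paste0("D", 2:5),
           regimes = c("WW", "WD"), replicates = 4,
           drop = "2013_I16_D5_WD_r4"),
      list(year = "2014", ranks = c(13, 15), stages = c("D1", "D3", "D5"),
           regimes = c("WW", "WD"), replicates = 3),
      list(year = "2014", ranks = c(14, 16), stages = "D1",
           regimes = c("WW", "WD"), replicates = 3),
      list(year = "2014", ranks = c(17, 19), stages = c("D3", "D5"),
           regimes = c("WW", "WD"), replicates = 3),
      list(year = "2015", ranks = c(11, 12, 13, 14), stages = c("D3", "D5"),
           regimes = c("WW", "WD"), replicates = 3)
    )), class = "design_config")
}

#' Generate the sample design table
#'
#' Expands the design configuration into one row per internode sample.
#' Blocks are field replicates (the replicate index doubles as block).
#'
#' @param design a `design_config` (default reproduces the 191-sample
#'   three-year design).
#' @return a [sample_table()].
#' @export
generate_design <- function(design = default_design_config()) {
  if (!length(design$blocks)) stop("design has no blocks")
  rows <- lapply(design$blocks, function(b) {
    for (f in c("ranks", "stages", "regimes"))
      if (!length(b[[f]])) stop("empty factor level list: ", f)
    if (anyDuplicated(b$stages)) stop("duplicated stage label in design block")
    g <- expand.grid(internode_rank = b$ranks, stage = b$stages,
                     regime = b$regimes, replicate = seq_len(b$replicates),
                     stringsAsFactors = FALSE)
    g$year <- b$year
    key <- sprintf("%s_I%d_%s_%s_r%d", g$year, g$internode_rank, g$stage,
                   g$regime, g$replicate)
    g$sample_id <- key
    if (!is.null(b$drop)) g <- g[!key %in% b$drop, , drop = FALSE]
    g
  })
  df <- do.call(rbind, rows)
  df$block <- paste0("B", df$replicate)
  df <- df[, c("sample_id", "year", "block", "regime", "internode_rank",
               "stage", "replicate")]
  df <- df[order(df$sample_id), ]
  sample_table(df, stage_levels = design$stage_levels)
}

planted_gene_ids <- function(config) {
  sprintf("G%05d", seq_len(config$n_genes_total))
}

#' Planted truth labels for a simulation configuration
#'
#' Gene-to-module assignment is deterministic given the configuration:
#' module genes occupy the leading gene IDs in spec order, the remainder
#' are background. The first gene of every module is its planted hub
#' (largest latent loading).
#'
#' @param config a [sim_config()].
#' @return list with `labels` (named character vector; background genes
#'   labelled "background") and `hubs` (named character vector, module ->
#'   hub gene).
#' @export
planted_truth <- function(config) {
  ids <- planted_gene_ids(config)
  labels <- rep("background", config$n_genes_total)
  hubs <- character(0)
  at <- 1L
  for (s in config$module_specs) {
    idx <- at:(at + s$n_genes - 1L)
    labels[idx] <- s$module_id
    hubs[s$module_id] <- ids[at]
    at <- at + s$n_genes
  }
  list(labels = setNames(labels, ids), hubs = hubs)
}

# Unimodal latent stage profile: Gaussian bump over the ordered stage index,
# standardized over the realized sample set.
latent_profile <- function(samples, peak_stage, width = 1.0) {
  stage_idx <- as.integer(samples$stage)
  peak <- match(peak_stage, levels(samples$stage))
  if (is.na(peak)) stop("peak_stage not a design stage: ", peak_stage)
  f <- exp(-((stage_idx - peak)^2) / (2 * width^2))
  (f - mean(f)) / sd(f)
}

#' Generate annotations and the keyword map for a simulated dataset
#'
#' Genes in modules with a positive `cw_annotation_rate` are tagged (at
#' that rate) with cell-wall GO terms in both namespaces and the custom
#' cell-wall list flag; designated bait genes get MYB/NAC families with
#' clade labels. Every gene also receives background GO terms. The keyword
#' map groups the CW terms, including an "SCW" keyword of four member
#' terms.
#'
#' @param config a [sim_config()].
#' @param go_vocab_size total GO vocabulary size (>= 40).
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `annotation` ([annotation_table()]) and `keywords`
#'   ([keyword_map()]).
#' @export
generate_annotations <- function(config, go_vocab_size = 200,
                                 seed = config$seed) {
  n_cw_bp <- 20; n_cw_cc <- 8
  if (go_vocab_size < n_cw_bp + n_cw_cc + 10)
    stop("GO vocabulary too small for the required distinct terms")
  set.seed(seed)
  vocab <- sprintf("GO:%07d", seq_len(go_vocab_size))
  cw_bp <- vocab[seq_len(n_cw_bp)]
  cw_cc <- vocab[n_cw_bp + seq_len(n_cw_cc)]
  bg <- vocab[(n_cw_bp + n_cw_cc + 1L):go_vocab_size]
  ids <- planted_gene_ids(config)
  truth <- planted_truth(config)

  genes <- data.frame(gene_id = ids, cw_custom = FALSE, tf_family = "none",
                      clade = NA_character_, is_bait = FALSE,
                      stringsAsFactors = FALSE)
  pairs <- vector("list", length(ids))
  at <- 1L
  for (s in config$module_specs) {
    idx <- at:(at + s$n_genes - 1L)
    cw_hit <- runif(s$n_genes) < s$cw_annotation_rate
    genes$cw_custom[idx] <- cw_hit
    if (s$n_bait_tfs > 0) {
      bait_idx <- idx[seq_len(s$n_bait_tfs)]
      genes$is_bait[bait_idx] <- TRUE
      fam <- rep(c("NAC", "MYB"), length.out = s$n_bait_tfs)
      genes$tf_family[bait_idx] <- fam
      genes$clade[bait_idx] <- ifelse(fam == "NAC", "C", "4")
    }
    for (j in seq_along(idx)) {
      g <- ids[idx[j]]
      trm <- sample(bg, 3)
      ns <- rep("BP", 3)
      if (cw_hit[j]) {
        trm <- c(trm, sample(cw_bp, 4), sample(cw_cc, 2))
        ns <- c(ns, rep("BP", 4), rep("CC", 2))
      }
      pairs[[idx[j]]] <- data.frame(gene_id = g, term = trm, namespace = ns,
                                    stringsAsFactors = FALSE)
    }
    at <- at + s$n_genes
  }
  if (config$n_background_genes > 0) {
    for (i in at:(at + config$n_background_genes - 1L)) {
      trm <- sample(bg, 3)
      pairs[[i]] <- data.frame(gene_id = ids[i], term = trm, namespace = "BP",
                               stringsAsFactors = FALSE)
    }
  }
  terms <- do.call(rbind, pairs)

  kw <- rbind(
    data.frame(keyword = "SCW", term = cw_bp[1:4]),
    data.frame(keyword = "cellulose", term = cw_bp[5:9]),
    data.frame(keyword = "xylan", term = cw_bp[10:14]),
    data.frame(keyword = "lignin", term = cw_bp[15:20]),
    data.frame(keyword = "cell wall organization", term = cw_cc)
  )
  list(annotation = annotation_table(genes, terms),
       keywords = keyword_map(kw), truth = truth)
}

#' Generate a negative-binomial count matrix with planted modules
#'
#' Each planted module draws a unimodal latent stage profile; a member
#' gene's log2 mean is baseline + loading x latent + gene-sample noise,
#' exponentiated and scaled to the sample's library size, then sampled
#' negative-binomial. The per-gene noise standard deviation is calibrated
#' so that the realized mean pairwise within-module Pearson correlation of
#' log-CPM approximates the spec's `within_correlation` (counting noise
#' included in the calibration). Background genes carry no latent signal.
#'
#' @param design a [sample_table()] (default: [generate_design()]).
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return a [count_matrix()], genes x samples.
#' @export
generate_counts <- function(design = generate_design(config$design),
                            config = sim_config(), seed = config$seed) {
  if (config$dispersion <= 0) stop("dispersion must be > 0")
  set.seed(seed)
  ids <- planted_gene_ids(config)
  n_s <- nrow(design)
  n_g <- config$n_genes_total
  log2mu <- matrix(0, n_g, n_s, dimnames = list(ids, design$sample_id))
  baseline <- rnorm(n_g, mean = 6, sd = 1.5)
  disp <- config$dispersion

  at <- 1L
  for (s in config$module_specs) {
    idx <- at:(at + s$n_genes - 1L)
    lat <- latent_profile(design, s$peak_stage)
    u <- runif(s$n_genes, 0.85, 1.0)
    u[1] <- 1.3                       # planted hub: strongest loading
    load <- s$amplitude * u
    # decompose target correlation: shared variance over total; subtract the
    # approximate log2-scale counting variance of the NB draw
    sig2 <- (s$amplitude * mean(u))^2          # signal variance (unit latent)
    count_var <- (log2(exp(1)))^2 * (disp + 2^(-6))
    eps2 <- max(sig2 * (1 - s$within_correlation) / s$within_correlation -
                  count_var, 0.01)
    noise <- matrix(rnorm(s$n_genes * n_s, sd = sqrt(eps2)), s$n_genes, n_s)
    log2mu[idx, ] <- baseline[idx] + outer(load, lat) + noise
    at <- at + s$n_genes
  }
  if (config$n_background_genes > 0) {
    idx <- at:n_g
    noise <- matrix(rnorm(length(idx) * n_s, sd = 1), length(idx), n_s)
    log2mu[idx, ] <- baseline[idx] + noise
  }

  rel <- 2^log2mu
  lsr <- log(config$library_size_range)
  lib <- exp(runif(n_s, lsr[1], lsr[2]))
  mu <- sweep(rel, 2, colSums(rel), "/")
  mu <- sweep(mu, 2, lib, "*")
  counts <- matrix(rnbinom(n_g * n_s, mu = mu, size = 1 / disp), n_g, n_s,
                   dimnames = dimnames(mu))
  count_matrix(counts)
}

#' Generate Van Soest fiber trajectories over internode development
#'
#' Each wall component (hemicellulose, cellulose, lignin) follows a
#' logistic accumulation curve over the ordered stage index; lignin's
#' inflection must not precede the polysaccharides', reflecting its later
#' deposition. NDF/ADF/ADL are reassembled from the components, so
#' 0 <= ADL <= ADF <= NDF holds by construction.
#'
#' @param design a [sample_table()].
#' @param profile_params list of per-component logistic parameters
#'   (`base`, `amplitude`, `inflection` in stage-index units, `scale`) for
#'   `hemicellulose`, `cellulose`, `lignin`, plus `noise_sd`.
#' @param seed integer seed.
#' @return a [biochem_table()].
#' @export
generate_biochem <- function(design,
                             profile_params = default_biochem_params(),
                             seed = 1L) {
  p <- profile_params
  if (p$lignin$inflection < p$cellulose$inflection ||
      p$lignin$inflection < p$hemicellulose$inflection)
    stop("lignin inflection must not precede the polysaccharide inflections")
  set.seed(seed)
  s <- as.integer(design$stage)
  logi <- function(par) par$base + par$amplitude / (1 + exp(-(s - par$inflection) / par$scale))
  comp <- cbind(hemicellulose = logi(p$hemicellulose),
                cellulose = logi(p$cellulose),
                lignin = logi(p$lignin))
  if (p$noise_sd > 0) {
    comp <- pmax(comp + matrix(rnorm(length(comp), sd = p$noise_sd),
                               nrow(comp)), 0)
    # quantize to 1/128 %DM (below measurement resolution) so that the
    # NDF/ADF/ADL sums and differences are exact in floating point
    comp <- round(comp * 128) / 128
  }
  ADL <- comp[, "lignin"]
  ADF <- ADL + comp[, "cellulose"]
  NDF <- ADF + comp[, "hemicellulose"]
  if (any(NDF > 100)) stop("parameterization drives NDF above 100 %DM")
  biochem_table(data.frame(sample_id = design$sample_id,
                           NDF = NDF, ADF = ADF, ADL = ADL,
                           stringsAsFactors = FALSE))
}

#' Default fiber accumulation parameters
#'
#' Plateaus near 30/25/6 %DM for hemicellulose/cellulose/lignin on top of
#' pre-elongation bases, polysaccharides inflecting around stage D2-D3 and
#' lignin about one stage later, with 1 %DM replicate noise.
#' @return parameter list for [generate_biochem()].
#' @export
default_biochem_params <- function() {
  list(hemicellulose = list(base = 12, amplitude = 18, inflection = 2.2, scale = 0.6),
       cellulose     = list(base = 10, amplitude = 15, inflection = 2.4, scale = 0.6),
       lignin        = list(base = 1.5, amplitude = 4.5, inflection = 3.4, scale = 0.6),
       noise_sd = 1)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper bundling design, annotations, counts, biochemistry
#' and the planted truth, all driven by one seed.
#'
#' @param config a [sim_config()].
#' @return list with `counts`, `samples`, `annotation`, `keywords`,
#'   `biochem`, `truth`.
#' @export
generate_dataset <- function(config = sim_config()) {
  design <- generate_design(config$design)
  ann <- generate_annotations(config, seed = config$seed + 1L)
  counts <- generate_counts(design, config, seed = config$seed)
  bc <- generate_biochem(design, seed = config$seed + 2L)
  list(counts = counts, samples = design, annotation = ann$annotation,
       keywords = ann$keywords, biochem = bc, truth = ann$truth)
}
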