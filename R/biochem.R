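# Van Soest fiber fraction arithmetic and stage-wise comparison of
# cell-wall component accumulation.

#' Derive wall components from Van Soest fiber fractions
#'
#' hemicellulose = NDF - ADF, cellulose = ADF - ADL, lignin = ADL
#' (all %DM), so hemicellulose + cellulose + lignin = NDF exactly.
#'
#' @param biochem a [biochem_table()].
#' @return data.frame: sample_id, hemicellulose, cellulose, lignin.
#' @export
derive_wall_fractions <- function(biochem) {
  bad <- which(biochem$NDF < biochem$ADF | biochem$ADF < biochem$ADL)
  if (length(bad))
    stop("fiber ordering violated for sample(s): ",
         paste(biochem$sample_id[bad], collapse = ", "))
  data.frame(sample_id = biochem$sample_id,
             hemicellulose = biochem$NDF - biochem$ADF,
             cellulose = biochem$ADF - biochem$ADL,
             lignin = biochem$ADL, stringsAsFactors = FALSE)
}

#' Stage-wise comparison of a wall component
#'
#' Per-stage mean and standard error (sd / sqrt(n)), all pairwise Welch
#' t-tests with Holm correction, and a compact letter display (stages
#' sharing a letter are not significantly different at `alpha`), built by
#' the greedy insert-and-absorb algorithm over stages sorted by
#' descending mean.
#'
#' @param derived table from [derive_wall_fractions()] (or any per-sample
#'   table with the trait column).
#' @param samples a [sample_table()] giving each sample's stage.
#' @param trait column of `derived` to compare.
#' @param alpha significance level (default 0.05).
#' @return data.frame: stage, n, mean, standard_error (NA with a flag for
#'   single-replicate stages), letter_group; stage order follows the
#'   design's stage ordering.
#' @export
compare_stages <- function(derived, samples, trait, alpha = 0.05) {
  stopifnot(trait %in% names(derived))
  st <- samples$stage[match(derived$sample_id, samples$sample_id)]
  if (anyNA(st)) stop("samples missing from the sample table")
  x <- derived[[trait]]
  stages <- levels(droplevels(st))
  if (length(stages) < 2) stop("need at least 2 stages")
  vals <- split(x, droplevels(st))
  n <- vapply(vals, length, 0L)
  mu <- vapply(vals, mean, 0)
  se <- ifelse(n >= 2, vapply(vals, sd, 0) / sqrt(n), NA_real_)

  pairs <- utils::combn(stages, 2)
  pv <- apply(pairs, 2, function(p) {
    a <- vals[[p[1]]]; b <- vals[[p[2]]]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (sd(a) == 0 && sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    t.test(a, b)$p.value
  })
  pv <- p.adjust(pv, method = "holm")
  differ <- matrix(FALSE, length(stages), length(stages),
                   dimnames = list(stages, stages))
  for (j in seq_len(ncol(pairs))) {
    if (!is.na(pv[j]) && pv[j] < alpha) {
      differ[pairs[1, j], pairs[2, j]] <- TRUE
      differ[pairs[2, j], pairs[1, j]] <- TRUE
    }
  }
  letters_by_stage <- compact_letter_display(differ, order(-mu))

  data.frame(trait = trait, stage = stages, n = as.integer(n),
             mean = unname(mu), standard_error = unname(se),
             single_replicate = n < 2,
             letter_group = unname(letters_by_stage[stages]),
             stringsAsFactors = FALSE)
}

# Greedy insert-and-absorb compact letter display. `differ` is a logical
# significance matrix; `ord` visits groups by descending mean.
compact_letter_display <- function(differ, ord) {
  groups <- rownames(differ)
  sets <- list()                      # each: character vector of groups
  for (g in groups[ord]) {
    placed <- FALSE
    for (i in seq_along(sets)) {
      if (!any(differ[g, sets[[i]]])) {
        sets[[i]] <- c(sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  # absorb sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets))
    if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
        length(sets[[i]]) < length(sets[[j]])) keep[i] <- FALSE
  sets <- sets[keep]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}
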