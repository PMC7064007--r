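test_that("top_neighbors ranks by signed correlation with ID tie-breaks", {
  r <- matrix(c(1, 0.9, 0.5,
                0.9, 1, 0.2,
                0.5, 0.2, 1), 3, dimnames = list(c("g", "a", "b"),
                                                 c("g", "a", "b")))
  expect_equal(top_neighbors("g", r, k = 1), "a")
  expect_equal(top_neighbors("g", r, k = 2), c("a", "b"))
  # a perfect duplicate ranks first
  rd <- random_correlation(10, seed = 60)
  rd["g01", "g02"] <- rd["g02", "g01"] <- 1
  expect_equal(top_neighbors("g01", rd, k = 1), "g02")
  # ties resolved by ascending gene ID
  rt <- matrix(0.5, 4, 4, dimnames = list(c("g", "c", "a", "b"),
                                          c("g", "c", "a", "b")))
  diag(rt) <- 1
  expect_equal(top_neighbors("g", rt, k = 2), c("a", "b"))
  expect_warning(out <- top_neighbors("g", rt, k = 10), "only 3")
  expect_length(out, 3)
  expect_error(top_neighbors("zz", rt), "not in correlation")
  # random instance vs full sort oracle
  r30 <- random_correlation(30, seed = 61)
  got <- top_neighbors("g05", r30, k = 15)
  v <- r30["g05", setdiff(rownames(r30), "g05")]
  oracle <- names(sort(v, decreasing = TRUE))[1:15]
  expect_setequal(got, oracle)
  expect_equal(got, oracle[order(match(oracle, got))])
})

test_that("two-layer subnetworks hit the 241 bound only when fully disjoint", {
  # construction: bait -> 15 distinct neighbors, each with 15 fresh genes
  n <- 1 + 15 + 15 * 15
  ids <- sprintf("n%03d", seq_len(n))
  r <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(r) <- 1
  bait <- ids[1]
  l1 <- ids[2:16]
  # bait-layer1 links weaker than layer1-layer2 links, so the bait does not
  # occupy a top-k slot of its own neighbors
  r[bait, l1] <- r[l1, bait] <- seq(0.50, 0.40, length.out = 15)
  at <- 17
  for (i in seq_along(l1)) {
    l2 <- ids[at:(at + 14)]
    r[l1[i], l2] <- r[l2, l1[i]] <- seq(0.99, 0.90, length.out = 15)
    at <- at + 15
  }
  sn <- two_layer_subnetwork(bait, r, k = 15)
  expect_equal(sn$size, 241)
  expect_equal(sn$layer1, l1)
  expect_true(bait %in% sn$union_list)
  # mutual chain at k = 1 closes on itself
  rc <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.2, 0.1, 0.2, 1), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  snc <- two_layer_subnetwork("a", rc, k = 1)
  expect_setequal(snc$union_list, c("a", "b"))
  expect_equal(snc$size, 2)
  # a fully mutual 16-clique stays inside itself
  cl <- matrix(0.9, 16, 16, dimnames = list(sprintf("c%02d", 1:16),
                                            sprintf("c%02d", 1:16)))
  diag(cl) <- 1
  sncl <- two_layer_subnetwork("c01", cl, k = 15)
  expect_equal(sncl$size, 16)
})

test_that("subnetwork size respects the 1 + k + k^2 bound and grows with k", {
  for (seed in 1:20) {
    r <- random_correlation(40, seed = 100 + seed)
    k <- sample(2:6, 1)
    sn <- two_layer_subnetwork("g01", r, k = k)
    expect_lte(sn$size, 1 + k + k^2)
    expect_true(all(sn$layer1 %in% sn$union_list))
    sn_bigger <- two_layer_subnetwork("g01", r, k = k + 2)
    expect_true(all(sn$union_list %in% sn_bigger$union_list))
  }
})

test_that("cell-wall enrichment categories follow the half-open bounds", {
  expect_equal(as.character(classify_cw_enrichment(c(0, 2, 3, 5, 6, 11, 12, 18, 25))),
               c("none", "none", "light", "light", "medium", "medium",
                 "high", "high", "high"))
  expect_true(is.ordered(classify_cw_enrichment(4)))
  expect_error(classify_cw_enrichment(-1), ">= 0")
  # monotone step function of the count
  lv <- as.integer(classify_cw_enrichment(0:30))
  expect_true(all(diff(lv) >= 0))
})

test_that("bait screening reports exclusions and enrichment categories", {
  dat <- generate_dataset(sim_config(n_genes_total = 400, seed = 33))
  filt <- filter_low_expression(dat$counts)
  expr <- normalize_counts(filt)
  r <- pearson_correlation(expr)
  a <- adjacency(r)
  ms <- detect_modules(topological_overlap(a), expr = expr)
  ms <- apply_strong_correlation_filter(a, ms)
  baits <- dat$annotation$genes[dat$annotation$genes$is_bait,
                                c("gene_id", "tf_family", "clade")]
  # add one bait absent from the filtered matrix and one weakly correlated
  extra <- data.frame(gene_id = c("GX_lowexp", tail(rownames(r), 1)),
                      tf_family = "MYB", clade = "4")
  ann2 <- dat$annotation
  ann2$genes <- rbind(ann2$genes,
                      data.frame(gene_id = "GX_lowexp", cw_custom = FALSE,
                                 tf_family = "MYB", clade = "4", is_bait = TRUE))
  out <- screen_baits(rbind(baits, extra), r, ms, ann2, dat$keywords)
  expect_equal(out$status[out$gene_id == "GX_lowexp"], "excluded_low_expression")
  bg <- tail(rownames(r), 1)         # background gene: not retained anywhere
  expect_equal(out$status[out$gene_id == bg], "excluded_weak_correlation")
  ok <- out[out$status == "ok", ]
  expect_true(all(ok$subnetwork_size <= 241))
  # baits planted in saturated CW modules classify at least medium
  truth <- dat$truth$labels
  cw_baits <- ok$gene_id[truth[ok$gene_id] %in% c("M3", "M4")]
  expect_true(all(out$category[out$gene_id %in% cw_baits] %in%
                    c("medium", "high")))
  # row-order invariance
  shuf <- rbind(baits, extra)[c(3, 1, 2, 4:nrow(rbind(baits, extra))), ]
  out2 <- screen_baits(shuf, r, ms, ann2, dat$keywords)
  expect_identical(out, out2)
  expect_error(screen_baits(data.frame(gene_id = "ghost", tf_family = "NAC"),
                            r, ms, dat$annotation, dat$keywords), "ghost")
})

test_that("subnetwork edge export lists weighted in-network pairs", {
  r <- random_correlation(20, seed = 70)
  sn <- two_layer_subnetwork("g01", r, k = 3)
  ed <- subnetwork_edges(sn, r, min_correlation = -1)
  expect_equal(nrow(ed), choose(sn$size, 2))
  expect_true(all(ed$source < ed$target))
})
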