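test_that("pearson correlation matches the hand formula and handles edge cases", {
  e <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5),
             dup = c(1, 2, 3, 4), neg = c(-1, -2, -3, -4))
  colnames(e) <- paste0("s", 1:4)
  r <- pearson_correlation(e)
  expect_equal(r["a", "b"], 0.9827076298, tolerance = 1e-9)
  expect_equal(r["a", "dup"], 1)
  expect_equal(r["a", "neg"], -1)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_error(pearson_correlation(e[, 1:2]), "3 samples")
  e2 <- rbind(e, flat = c(2, 2, 2, 2))
  expect_warning(r2 <- pearson_correlation(e2), "zero-variance")
  expect_false("flat" %in% rownames(r2))
})

test_that("adjacency variants implement their functional forms", {
  r <- matrix(c(1, 0.82, -0.5, 0.82, 1, 0.3, -0.5, 0.3, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  ah <- adjacency(r, beta = 12, variant = "signed_hybrid")
  expect_equal(ah["a", "b"], 0.82^12)
  expect_equal(round(ah["a", "b"], 1), 0.1)   # the 0.1 <-> 0.82 mapping
  expect_equal(ah["a", "c"], 0)               # negative r zeroed
  au <- adjacency(r, beta = 12, variant = "unsigned")
  expect_equal(au["a", "c"], 0.5^12)
  as_ <- adjacency(r, beta = 12, variant = "signed")
  expect_equal(as_["a", "c"], 0.25^12)
  # r = 1 maps to 1 for every variant (off-diagonal)
  r1 <- matrix(1, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  for (v in c("unsigned", "signed", "signed_hybrid"))
    expect_equal(adjacency(r1, beta = 7, variant = v)["x", "y"], 1)
  expect_error(adjacency(r, variant = "nope"))
  # bounds, symmetry, monotonicity in r for r > 0
  rr <- random_correlation(20, seed = 3)
  a <- adjacency(rr, beta = 12)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(isSymmetric(unname(a)))
  pos <- rr[upper.tri(rr)] > 0
  expect_true(all(diff(a[upper.tri(a)][pos][order(rr[upper.tri(rr)][pos])]) >= 0))
})

test_that("soft-threshold scan tracks connectivity decay and scale-freeness", {
  idm <- diag(60)
  dimnames(idm) <- list(sprintf("g%02d", 1:60), sprintf("g%02d", 1:60))
  scan0 <- soft_threshold_scan(idm, powers = c(1, 6, 12))
  expect_equal(scan0$mean_connectivity, rep(0, 3))
  rr <- abs(random_correlation(80, seed = 4))
  scan <- soft_threshold_scan(rr, powers = c(6, 12), variant = "unsigned")
  expect_lt(scan$mean_connectivity[scan$power == 12],
            scan$mean_connectivity[scan$power == 6])
  # power-law connectivities give a high signed fit
  set.seed(5)
  k <- 1 / runif(5000)^(1 / 1.5)            # Pareto(alpha = 2.5) degrees
  expect_gte(stemnet:::scale_free_fit(k), 0.8)
})

test_that("topological overlap matches hand values and the triple-loop oracle", {
  # 3-node path: a12 = a23 = 0.5, a13 = 0
  a <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  a["a", "b"] <- a["b", "a"] <- 0.5
  a["b", "c"] <- a["c", "b"] <- 0.5
  tom <- topological_overlap(a)
  expect_equal(tom["a", "c"], 1 / 6)
  expect_equal(unname(diag(tom)), rep(1, 3))
  # complete graph with unit weights
  cg <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(cg) <- 0
  expect_true(all(topological_overlap(cg) == 1))
  # no edge, no shared neighbor
  z <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(topological_overlap(z)["x", "y"], 0)
  # random instances against the brute-force oracle
  for (seed in 1:5) {
    ra <- random_adjacency(8, seed)
    expect_equal(topological_overlap(ra), tom_bruteforce(ra), tolerance = 1e-12)
  }
  expect_error(topological_overlap(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  tomr <- topological_overlap(random_adjacency(10, 99) / 2)
  expect_true(all(tomr >= 0 & tomr <= 1))
})

test_that("module detection recovers planted blocks and stays silent on noise", {
  e <- block_expression(n_block = 50, n_noise = 20, seed = 42)
  r <- pearson_correlation(e)
  a <- adjacency(r, beta = 12)
  tom <- topological_overlap(a)
  ms <- detect_modules(tom, expr = e, min_module_size = 30)
  truth <- c(rep("b1", 50), rep("b2", 50), rep("unassigned", 20))
  expect_equal(length(setdiff(unique(ms$labels), "unassigned")), 2)
  planted <- truth != "unassigned"
  expect_equal(adjusted_rand_index(ms$labels[planted], truth[planted]), 1)
  # pure noise: nearly everything unassigned
  set.seed(10)
  noise <- matrix(rnorm(200 * 60), 200,
                  dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:60)))
  rn <- pearson_correlation(noise)
  msn <- detect_modules(topological_overlap(adjacency(rn)), expr = noise)
  expect_gte(mean(msn$labels == "unassigned"), 0.9)
  expect_error(detect_modules(tom[1, 1, drop = FALSE]), "2 genes")
})

test_that("modules with duplicated profiles merge via their eigengenes", {
  set.seed(13)
  f <- rnorm(60)
  g1 <- t(sapply(1:40, function(i) f + rnorm(60, sd = 0.1)))
  g2 <- t(sapply(1:40, function(i) f + rnorm(60, sd = 0.1)))
  other <- t(sapply(1:40, function(i) rnorm(60)))
  e <- rbind(g1, g2, other)
  dimnames(e) <- list(sprintf("g%03d", 1:120), sprintf("s%02d", 1:60))
  r <- pearson_correlation(e)
  tom <- topological_overlap(adjacency(r))
  ms <- detect_modules(tom, expr = e, min_module_size = 30,
                       merge_correlation = 0.75)
  # the two identical blocks end up in one module
  lab <- ms$labels[1:80]
  expect_equal(length(unique(lab)), 1)
})

test_that("module naming is deterministic and ordered by size", {
  e <- block_expression(n_block = 50, n_noise = 0, seed = 17)
  e <- rbind(e, block_expression(n_block = 15, n_noise = 0, seed = 18)[1:30, ] )
  rownames(e) <- sprintf("g%03d", seq_len(nrow(e)))
  r <- pearson_correlation(e)
  ms <- detect_modules(topological_overlap(adjacency(r)), expr = e,
                       min_module_size = 10)
  sizes <- as.integer(ms$sizes)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(names(ms$sizes)[1], "turquoise")
  ms2 <- detect_modules(topological_overlap(adjacency(r)), expr = e,
                        min_module_size = 10)
  expect_identical(ms$labels, ms2$labels)
})

test_that("eigengenes are oriented, unit norm and PCA-optimal", {
  set.seed(20)
  f <- rnorm(40)
  dup <- rbind(a = f, b = f)
  colnames(dup) <- sprintf("s%02d", 1:40)
  e1 <- module_eigengene(dup)
  zs <- as.numeric(scale(f))
  expect_equal(abs(cor(e1, zs)), 1, tolerance = 1e-10)
  expect_gt(cor(e1, zs), 0)                       # oriented with the mean
  expect_equal(sum(e1^2), 1, tolerance = 1e-12)
  # orientation follows the module mean: flipped data give the flipped
  # eigengene, still positively tracking its own module mean profile
  e_flip <- module_eigengene(-dup)
  expect_equal(e_flip, -e1, tolerance = 1e-10)
  expect_gt(cor(e_flip, colMeans(t(scale(t(-dup))))), 0)
  # flipping a minority of genes leaves the orientation unchanged
  five <- rbind(f, f, f, f, f) + matrix(rnorm(200, sd = 0.3), 5)
  rownames(five) <- letters[1:5]; colnames(five) <- sprintf("s%02d", 1:40)
  flip_one <- five; flip_one[1, ] <- -flip_one[1, ]
  expect_gt(cor(module_eigengene(five), module_eigengene(flip_one)), 0.99)
  # variance explained beats any single gene in a 2-gene module
  two <- rbind(a = f + rnorm(40, sd = 0.5), b = f + rnorm(40, sd = 0.5))
  colnames(two) <- sprintf("s%02d", 1:40)
  z <- t(scale(t(two)))
  e <- module_eigengene(two)
  var_expl <- sum((z %*% e)^2) / sum(z^2)
  share_best_gene <- max(apply(z, 1, function(g)
    sum((z %*% (g / sqrt(sum(g^2))))^2))) / sum(z^2)
  expect_gte(var_expl + 1e-12, share_best_gene)
  expect_error(module_eigengene(dup[1, , drop = FALSE]), ">= 2 genes")
})

test_that("strong-correlation filter keeps genes at the adjacency threshold", {
  mk_pair <- function(r) {
    m <- matrix(c(1, r, r, 1), 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
    adjacency(m, beta = 12)
  }
  ms <- structure(list(labels = c(g1 = "blue", g2 = "blue"), retained = NULL),
                  class = "module_set")
  keep <- apply_strong_correlation_filter(mk_pair(0.83), ms, min_retained = 2)
  expect_equal(keep$retained$blue, c("g1", "g2"))   # 0.83^12 ~ 0.107 >= 0.1
  drop <- apply_strong_correlation_filter(mk_pair(0.80), ms, min_retained = 2)
  expect_null(drop$retained$blue)                   # 0.80^12 ~ 0.069 < 0.1
  # monotone: raising the threshold never adds a retained gene
  e <- block_expression(50, 20, seed = 30)
  r <- pearson_correlation(e)
  a <- adjacency(r)
  msd <- detect_modules(topological_overlap(a), expr = e)
  lo <- apply_strong_correlation_filter(a, msd, adjacency_threshold = 0.05)
  hi <- apply_strong_correlation_filter(a, msd, adjacency_threshold = 0.2)
  for (m in names(hi$retained))
    expect_true(all(hi$retained[[m]] %in% lo$retained[[m]]))
})

test_that("module profile meta-clustering groups planted archetypes", {
  set.seed(31)
  arch <- matrix(rnorm(3 * 50), ncol = 3)
  profiles <- sapply(rep(1:3, each = 3), function(i) arch[, i] + rnorm(50, sd = 0.1))
  colnames(profiles) <- paste0("mod", 1:9)
  cl <- cluster_module_profiles(profiles, n_clusters = 3)
  expect_equal(length(unique(cl$clusters)), 3)
  expect_equal(adjusted_rand_index(cl$clusters, rep(1:3, each = 3)), 1)
  expect_equal(dim(cl$correlation), c(9, 9))
  # identical profiles always share a cluster
  expect_equal(cl$clusters[["mod1"]], cl$clusters[["mod2"]])
  expect_error(cluster_module_profiles(profiles, n_clusters = 10), "exceeds")
})

test_that("intramodular connectivity matches closed forms and brute force", {
  # complete module with constant adjacency c
  cfit <- 0.4
  m <- 5
  a <- matrix(cfit, m, m, dimnames = list(letters[1:m], letters[1:m]))
  diag(a) <- 0
  ms <- structure(list(labels = setNames(rep("blue", m), letters[1:m])),
                  class = "module_set")
  ct <- intramodular_connectivity(a, ms)
  expect_equal(ct$kWithin, rep((m - 1) * cfit, m))
  expect_equal(ct$kOut, rep(0, m))
  # isolated gene
  a2 <- rbind(cbind(a, iso = 0), iso = 0)
  dimnames(a2) <- list(c(letters[1:m], "iso"), c(letters[1:m], "iso"))
  ms2 <- structure(list(labels = c(ms$labels, iso = "unassigned")),
                   class = "module_set")
  ct2 <- intramodular_connectivity(a2, ms2)
  expect_equal(unlist(ct2[ct2$gene_id == "iso", c("kTotal", "kWithin", "kOut", "kDiff")]),
               c(kTotal = 0, kWithin = 0, kOut = 0, kDiff = 0))
  # random instance vs a double loop
  ra <- random_adjacency(6, seed = 44)
  lab <- setNames(c("m1", "m1", "m1", "m2", "m2", "unassigned"), rownames(ra))
  msr <- structure(list(labels = lab), class = "module_set")
  ctr <- intramodular_connectivity(ra, msr)
  for (i in seq_len(6)) {
    kt <- kw <- 0
    for (j in seq_len(6)) {
      if (i == j) next
      kt <- kt + ra[i, j]
      if (lab[i] != "unassigned" && lab[i] == lab[j]) kw <- kw + ra[i, j]
    }
    expect_equal(ctr$kTotal[i], kt)
    expect_equal(ctr$kWithin[i], kw)
  }
  # conservation: sums balance exactly
  expect_equal(sum(ctr$kWithin) + sum(ctr$kOut), sum(ctr$kTotal))
  expect_equal(ctr$kDiff, ctr$kWithin - ctr$kOut)
})

test_that("hub ranking uses kWithin with deterministic tie-breaks", {
  genes <- sprintf("g%02d", 1:29)
  conn <- data.frame(gene_id = genes, module = "blue",
                     kTotal = 30 - seq_along(genes),
                     kWithin = 30 - seq_along(genes))
  conn$kOut <- 0; conn$kDiff <- conn$kWithin
  ms <- structure(list(labels = setNames(rep("blue", 29), genes),
                       retained = list(blue = genes)), class = "module_set")
  h <- rank_hub_genes(conn, ms)
  expect_length(h$blue$top_n, 10)
  expect_length(h$blue$top_fraction, 3)           # ceiling(0.1 * 29)
  expect_equal(h$blue$top_n[1], "g01")
  # identical connectivities break ties by gene ID
  conn2 <- conn; conn2$kWithin <- 1
  h2 <- rank_hub_genes(conn2, ms)
  expect_equal(h2$blue$top_n, genes[1:10])
  # retained-only ranking restricts the candidate pool
  ms$retained <- list(blue = genes[15:29])
  h3 <- rank_hub_genes(conn, ms, use_retained = TRUE)
  expect_equal(h3$blue$top_n[1], "g15")
  expect_equal(h3$blue$overlap, intersect(h3$blue$top_n, h3$blue$top_fraction))
})
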