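# In-code fixtures shared across test files.

tiny_counts <- function() {
  m <- matrix(c(10, 20, 30, 40,
                 0,  5,  1,  2,
                 7,  7,  7,  7), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  count_matrix(m)
}

# correlated expression with two planted blocks and noise genes
block_expression <- function(n_block = 50, n_noise = 20, n_samples = 60,
                             within_sd = 0.2, seed = 42) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  g1 <- t(sapply(seq_len(n_block), function(i) f1 + rnorm(n_samples, sd = within_sd)))
  g2 <- t(sapply(seq_len(n_block), function(i) f2 + rnorm(n_samples, sd = within_sd)))
  gn <- matrix(rnorm(n_noise * n_samples), n_noise, n_samples)
  m <- rbind(g1, g2, gn)
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("s%03d", seq_len(n_samples)))
  class(m) <- c("expression_matrix", "matrix", "array")
  m
}

# small random symmetric adjacency with zero diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# random symmetric correlation-like matrix with unit diagonal
random_correlation <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * (n + 5)), n)
  r <- cor(t(x))
  dimnames(r) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  r
}

# brute-force TOM by triple loop
tom_bruteforce <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# brute-force hypergeometric upper tail by direct enumeration
hyper_upper_bruteforce <- function(x, K, N, n) {
  xs <- x:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

small_annotation <- function() {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    cw_custom = c(rep(TRUE, 4), rep(FALSE, 6)),
    tf_family = c("NAC", rep("none", 9)),
    clade = c("C", rep(NA, 9)),
    is_bait = c(TRUE, rep(FALSE, 9)), stringsAsFactors = FALSE)
  terms <- data.frame(
    gene_id = c("g01", "g02", "g03", "g04", "g05", "g06", "g07", "g08"),
    term = c("GO:1", "GO:1", "GO:1", "GO:1", "GO:2", "GO:2", "GO:3", "GO:3"),
    namespace = c("BP", "BP", "BP", "BP", "BP", "BP", "CC", "CC"),
    stringsAsFactors = FALSE)
  annotation_table(genes, terms)
}
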