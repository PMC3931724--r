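# Independent brute-force oracles used across the suite.  They deliberately
# avoid the package's own code paths.

oracle_chisq <- function(o, e) sum((o - e)^2 / e)

# pool tail bins (highest multiplicity first) until the pooled bin reaches 5
oracle_pool <- function(o, e) {
  while (length(e) > 1 && e[length(e)] < 5) {
    n <- length(e)
    e <- c(e[seq_len(n - 2)], e[n - 1] + e[n])
    o <- c(o[seq_len(n - 2)], o[n - 1] + o[n])
  }
  list(o = o, e = e)
}

# rank-then-Pearson Spearman with midranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  a <- rx - mean(rx); b <- ry - mean(ry)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Kruskal-Wallis H with tie correction, straight from the formula
oracle_kw <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(split(r, groups), function(z) sum(z)^2 / length(z), 0)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

oracle_centroid_distance <- function(emb, labels) {
  cls <- unique(labels)
  ca <- colMeans(emb[labels == cls[1], , drop = FALSE])
  cb <- colMeans(emb[labels == cls[2], , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

# exhaustive two-class permutation p of the centroid distance on a fixed
# embedding (all label splits that preserve class sizes)
oracle_exhaustive_perm_p <- function(emb, labels) {
  cls <- unique(labels)
  n <- length(labels)
  obs <- oracle_centroid_distance(emb, labels)
  idx <- utils::combn(n, sum(labels == cls[1]))
  null <- apply(idx, 2, function(a) {
    perm <- rep(cls[2], n)
    perm[a] <- cls[1]
    oracle_centroid_distance(emb, perm)
  })
  mean(null >= obs - 1e-12)
}

# brute-force multiplicity count: loop over signatures, count membership
oracle_multiplicity <- function(collection, gene) {
  sum(vapply(collection$signatures, function(s) gene %in% s$genes, logical(1)))
}

# all permutations of 1:n (n small)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

make_toy_collection <- function() {
  signature_collection(list(A = c("a", "b", "c"), B = c("b", "c"), C = "c"))
}
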