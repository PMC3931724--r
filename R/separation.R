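#' PCA of a signature submatrix
#'
#' Subsets the dataset to the signature genes, standardizes every gene to
#' mean 0 / variance 1 across samples (`scale = TRUE`; `scale = FALSE`
#' centers only, i.e. covariance PCA), and computes principal components of
#' the samples in gene space.  The first component is sign-oriented so that
#' its scores correlate non-negatively with the per-sample mean of the
#' standardized signature genes, which makes loadings comparable across
#' datasets.  Zero-variance genes are dropped with a warning; if fewer than
#' two signature genes are measured the call fails with
#' "signature too small in dataset".  If every gene is degenerate a
#' zero embedding is returned so that fully identical samples yield a
#' centroid distance of 0.
#'
#' @param ds an `expression_dataset` with >= 3 samples.
#' @param genes character vector of signature gene symbols.
#' @param n_components number of components to return (zero-padded when the
#'   data support fewer).
#' @param scale standardize genes before PCA?
#' @return object of class `signature_pca`: `scores` (samples x components),
#'   `loadings` (genes x components), `sdev`, `genes_used`, `genes_dropped`.
#' @export
signature_pca <- function(ds, genes, n_components = 2L, scale = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  genes <- normalize_symbols(genes)
  if (ncol(ds$matrix) < 3L) stop("need at least 3 samples")
  present <- match_features(genes, rownames(ds$matrix))
  if (length(present) < 2L) stop("signature too small in dataset")
  x <- ds$matrix[present, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  dropped <- rownames(x)[sds == 0]
  if (length(dropped))
    warning("dropping zero-variance gene(s): ", paste(dropped, collapse = ", "))
  x <- x[sds > 0, , drop = FALSE]
  ns <- ncol(ds$matrix)
  pcnames <- paste0("PC", seq_len(n_components))
  if (nrow(x) == 0L) {
    scores <- matrix(0, ns, n_components,
                     dimnames = list(colnames(ds$matrix), pcnames))
    return(structure(list(scores = scores,
                          loadings = matrix(0, 0, n_components,
                                            dimnames = list(NULL, pcnames)),
                          sdev = rep(0, n_components),
                          genes_used = character(0), genes_dropped = dropped,
                          scale = scale),
                     class = "signature_pca"))
  }
  z <- x - rowMeans(x)
  if (scale) z <- z / apply(x, 1, stats::sd)
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  sdev <- pc$sdev[seq_len(k)]
  if (k < n_components) {   # pad degenerate trailing components with zeros
    pad <- n_components - k
    scores <- cbind(scores, matrix(0, nrow(scores), pad))
    loadings <- cbind(loadings, matrix(0, nrow(loadings), pad))
    sdev <- c(sdev, rep(0, pad))
  }
  colnames(scores) <- colnames(loadings) <- pcnames
  orient <- suppressWarnings(stats::cor(scores[, 1], colMeans(z)))
  if (!is.na(orient) && orient < 0) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
  }
  structure(list(scores = scores, loadings = loadings, sdev = sdev,
                 genes_used = rownames(z), genes_dropped = dropped,
                 scale = scale),
            class = "signature_pca")
}

#' @export
print.signature_pca <- function(x, ...) {
  cat("<signature_pca> ", length(x$genes_used), " genes, ",
      nrow(x$scores), " samples, ", ncol(x$scores), " components\n", sep = "")
  invisible(x)
}

#' Euclidean distance between two class centroids in an embedding
#'
#' @param embedding numeric matrix of per-sample coordinates (samples in
#'   rows, e.g. the `scores` of [signature_pca()]), or a `signature_pca`.
#' @param labels two-class vector, named by sample id or in row order; both
#'   classes must be non-empty.
#' @return the Euclidean distance between the class mean points.
#' @export
centroid_distance <- function(embedding, labels) {
  if (inherits(embedding, "signature_pca")) embedding <- embedding$scores
  embedding <- as.matrix(embedding)
  labels <- align_labels(labels, rownames(embedding), nrow(embedding))
  cls <- unique(labels)
  if (length(cls) != 2L) stop("need exactly two classes")
  if (any(table(labels) == 0L)) stop("a class has no samples")
  ca <- colMeans(embedding[labels == cls[1], , drop = FALSE])
  cb <- colMeans(embedding[labels == cls[2], , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

align_labels <- function(labels, ids, n) {
  if (is.factor(labels)) labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels)) && !is.null(ids)) {
    if (!all(ids %in% names(labels))) stop("labels missing for some samples")
    labels <- unname(labels[ids])
  }
  if (length(labels) != n) stop("labels do not match the samples")
  labels
}

#' Class-label permutation test of centroid separation
#'
#' Embeds the samples with [signature_pca()], measures the centroid distance
#' between the two classes, and compares it with distances obtained after
#' shuffling the class labels (class sizes preserved) on the *fixed*
#' embedding.  Recomputing the PCA per permutation would change nothing:
#' the embedding is unsupervised and label shuffles leave the data matrix
#' untouched, so the fixed-embedding scheme is exactly equivalent (and much
#' cheaper).  The p-value uses the plus-one rule
#' `p = (1 + #[null >= observed]) / (1 + n_perm)` and can therefore never
#' be 0.
#'
#' @param ds an `expression_dataset`.
#' @param genes signature gene symbols.
#' @param labels two-class labels (defaults to `ds$labels`).
#' @param n_perm number of label permutations (>= 1).
#' @param seed optional integer seed.
#' @param n_components,scale passed to [signature_pca()].
#' @return object of class `separation_result`: `embedding`, `centroids`,
#'   `distance`, `permutation_null`, `permutation_p`, plus empty baseline
#'   slots filled by [random_geneset_baseline()] / [separation_analysis()].
#' @export
permutation_test <- function(ds, genes, labels = NULL, n_perm = 100L,
                             seed = NULL, n_components = 2L, scale = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  labels <- labels %||% ds$labels
  if (is.null(labels)) stop("labels required")
  labels <- align_labels(labels, colnames(ds$matrix), ncol(ds$matrix))
  if (!is.null(seed)) set.seed(seed)
  pca <- suppressWarnings(signature_pca(ds, genes, n_components, scale))
  obs <- centroid_distance(pca$scores, labels)
  null <- vapply(seq_len(n_perm), function(i) {
    centroid_distance(pca$scores, sample(labels))
  }, numeric(1))
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  cls <- unique(labels)
  structure(list(embedding = pca$scores,
                 genes_used = pca$genes_used,
                 labels = labels,
                 centroids = rbind(colMeans(pca$scores[labels == cls[1], , drop = FALSE]),
                                   colMeans(pca$scores[labels == cls[2], , drop = FALSE])),
                 classes = cls,
                 distance = obs,
                 permutation_null = null,
                 permutation_p = p,
                 n_perm = n_perm,
                 baseline_distances = NULL, baseline_p = NULL),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat("<separation_result> centroid distance =", format(x$distance, digits = 6),
      "\n  permutation p =", format(x$permutation_p, digits = 4),
      paste0("(", x$n_perm, " label permutations)"), "\n")
  if (!is.null(x$baseline_p))
    cat("  random-gene-set baseline p =", format(x$baseline_p, digits = 4),
        paste0("(", length(x$baseline_distances), " random sets)"), "\n")
  invisible(x)
}

#' Random-gene-set separation baseline
#'
#' Draws `n_sets` gene sets of the candidate signature's size uniformly
#' without replacement from the gene universe (restricted to genes measured
#' and non-degenerate in `ds`), runs the full [signature_pca()] +
#' [centroid_distance()] pipeline for each, and reports the resulting null
#' distances.  When an observed distance is supplied, the plus-one baseline
#' p-value `(1 + #[baseline >= observed]) / (1 + n_sets)` is attached.
#'
#' @param ds an `expression_dataset`.
#' @param signature_size size of the random sets.
#' @param universe character vector of candidate genes.
#' @param labels two-class labels (defaults to `ds$labels`).
#' @param n_sets number of random sets.
#' @param seed optional integer seed.
#' @param observed_distance distance to compare against, if any.
#' @param n_components,scale passed to [signature_pca()].
#' @return list with `baseline_distances` and `baseline_p` (NULL when no
#'   observed distance was given).
#' @export
random_geneset_baseline <- function(ds, signature_size, universe,
                                    labels = NULL, n_sets = 100L, seed = NULL,
                                    observed_distance = NULL,
                                    n_components = 2L, scale = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  labels <- labels %||% ds$labels
  if (is.null(labels)) stop("labels required")
  labels <- align_labels(labels, colnames(ds$matrix), ncol(ds$matrix))
  if (!is.null(seed)) set.seed(seed)
  pool <- match_features(normalize_symbols(universe), rownames(ds$matrix))
  pool <- pool[apply(ds$matrix[pool, , drop = FALSE], 1, stats::sd) > 0]
  if (length(pool) < signature_size) stop("universe too small")
  bd <- vapply(seq_len(n_sets), function(i) {
    g <- sample(pool, signature_size)
    centroid_distance(signature_pca(ds, g, n_components, scale)$scores, labels)
  }, numeric(1))
  p <- if (is.null(observed_distance)) NULL
       else (1 + sum(bd >= observed_distance)) / (1 + n_sets)
  list(baseline_distances = bd, baseline_p = p)
}

#' Full separation analysis of a candidate signature
#'
#' Convenience wrapper: class-label permutation test plus (when a gene
#' universe is supplied) the random-gene-set baseline, combined into one
#' `separation_result`.
#'
#' @inheritParams permutation_test
#' @param universe gene universe for the random baseline, or `NULL` to skip.
#' @param n_sets number of random gene sets.
#' @return a `separation_result` with baseline slots filled.
#' @export
separation_analysis <- function(ds, genes, universe = NULL, labels = NULL,
                                n_perm = 100L, n_sets = 100L, seed = NULL,
                                n_components = 2L, scale = TRUE) {
  res <- permutation_test(ds, genes, labels = labels, n_perm = n_perm,
                          seed = seed, n_components = n_components,
                          scale = scale)
  if (!is.null(universe)) {
    genes <- normalize_symbols(genes)
    base <- random_geneset_baseline(
      ds, signature_size = length(intersect(genes, rownames(ds$matrix))),
      universe = universe, labels = res$labels, n_sets = n_sets,
      observed_distance = res$distance,
      n_components = n_components, scale = scale)
    res$baseline_distances <- base$baseline_distances
    res$baseline_p <- base$baseline_p
  }
  res
}
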