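#' First-component loadings of a signature across datasets
#'
#' Runs [signature_pca()] per dataset and extracts the PC1 loading of every
#' signature gene measured there.  Genes absent from (or degenerate in) a
#' dataset are simply missing from that dataset's vector — absent, not zero.
#' The shared sign convention of [signature_pca()] makes loadings comparable
#' across datasets.
#'
#' @param dsets a (preferably named) list of `expression_dataset`s.
#' @param genes signature gene symbols.
#' @param scale standardize genes before PCA?
#' @return named list (one element per dataset) of named numeric loading
#'   vectors.
#' @export
fit_loadings <- function(dsets, genes, scale = TRUE) {
  stopifnot(length(dsets) >= 1L)
  if (is.null(names(dsets)))
    names(dsets) <- sprintf("dataset_%02d", seq_along(dsets))
  lapply(dsets, function(d) {
    pca <- suppressWarnings(signature_pca(d, genes, n_components = 1L,
                                          scale = scale))
    stats::setNames(pca$loadings[, 1], rownames(pca$loadings))
  })
}

#' Build a metagene model from per-dataset loadings
#'
#' Per gene, the median PC1 loading over the datasets in which it was
#' observed becomes its weight.  A gene is flagged *robust* when its loading
#' range does not straddle zero (all observed loadings share a sign); genes
#' observed in a single dataset are robust by convention but flagged
#' `single_source`.  Genes observed nowhere are excluded.
#'
#' @param loadings named list of named numeric vectors, as returned by
#'   [fit_loadings()].
#' @return object of class `metagene_model`: `table` (per-gene data frame
#'   with `median_loading`, `n_datasets`, `robust`, `single_source`),
#'   `loadings` (gene x dataset matrix, `NA` = absent), `datasets`,
#'   `orientation`.
#' @export
build_model <- function(loadings) {
  stopifnot(is.list(loadings), length(loadings) >= 1L)
  if (is.null(names(loadings)))
    names(loadings) <- sprintf("dataset_%02d", seq_along(loadings))
  genes <- sort(unique(unlist(lapply(loadings, names), use.names = FALSE)))
  if (!length(genes)) stop("no genes observed in any dataset")
  lmat <- sapply(loadings, function(l) l[genes])
  lmat <- matrix(lmat, nrow = length(genes),
                 dimnames = list(genes, names(loadings)))
  med <- apply(lmat, 1, stats::median, na.rm = TRUE)
  lo <- apply(lmat, 1, min, na.rm = TRUE)
  hi <- apply(lmat, 1, max, na.rm = TRUE)
  nobs <- as.integer(rowSums(!is.na(lmat)))
  tab <- data.frame(gene = genes,
                    median_loading = unname(med),
                    n_datasets = nobs,
                    robust = unname(!(lo < 0 & hi > 0)),
                    single_source = unname(nobs == 1L),
                    row.names = NULL)
  structure(list(table = tab, loadings = lmat, datasets = names(loadings),
                 orientation = "pc1_scores_positively_correlated_with_mean_signature_expression"),
            class = "metagene_model")
}

#' @export
print.metagene_model <- function(x, ...) {
  cat("<metagene_model> ", nrow(x$table), " genes over ",
      length(x$datasets), " training dataset(s); ",
      sum(x$table$robust), " robust\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Serialize / restore a metagene model (JSON)
#'
#' Full double precision is preserved so a model round-trips bit-identically.
#'
#' @param model a `metagene_model`.
#' @param path file path.
#' @return `path` (write) or the restored `metagene_model` (read).
#' @export
write_metagene_model <- function(model, path) {
  stopifnot(inherits(model, "metagene_model"))
  payload <- list(orientation = model$orientation,
                  datasets = model$datasets,
                  genes = model$table$gene,
                  median_loading = model$table$median_loading,
                  n_datasets = model$table$n_datasets,
                  robust = model$table$robust,
                  single_source = model$table$single_source,
                  loadings = stats::setNames(
                    lapply(seq_along(model$datasets), function(j) {
                      v <- model$loadings[, j]
                      as.list(v[!is.na(v)])   # named list -> JSON object
                    }),
                    model$datasets))
  # digits = I(17): 17 significant digits round-trip doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_metagene_model
#' @export
read_metagene_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  genes <- as.character(unlist(p$genes))
  datasets <- as.character(unlist(p$datasets))
  lmat <- matrix(NA_real_, length(genes), length(datasets),
                 dimnames = list(genes, datasets))
  for (d in datasets) {
    v <- unlist(p$loadings[[d]])   # nulls (absent genes) drop out here
    if (length(v)) lmat[names(v), d] <- as.numeric(v)
  }
  tab <- data.frame(gene = genes,
                    median_loading = as.numeric(unlist(p$median_loading)),
                    n_datasets = as.integer(unlist(p$n_datasets)),
                    robust = as.logical(unlist(p$robust)),
                    single_source = as.logical(unlist(p$single_source)),
                    row.names = NULL)
  structure(list(table = tab, loadings = lmat, datasets = datasets,
                 orientation = as.character(p$orientation)),
            class = "metagene_model")
}

#' Score samples with a metagene model
#'
#' The per-sample score is the weighted sum `sum_g w_g * z_g(sample)` where
#' `w_g` is the gene's median loading and `z_g` is its within-dataset
#' standardized expression (mean 0 / sd 1 across samples).  By default only
#' robust (sign-consistent) genes are used — the "informative genes only"
#' convention.  Model genes not measured (or constant) in the dataset are
#' dropped without weight renormalization and reported in `genes_missing`.
#'
#' @param model a `metagene_model`.
#' @param ds an `expression_dataset`.
#' @param robust_only use only robust genes?
#' @return object of class `score_vector`: `scores` (named numeric, one per
#'   sample), `genes_used`, `genes_missing`.
#' @export
score_samples <- function(model, ds, robust_only = TRUE) {
  stopifnot(inherits(model, "metagene_model"),
            inherits(ds, "expression_dataset"))
  tab <- model$table
  if (robust_only) tab <- tab[tab$robust, , drop = FALSE]
  wmap <- stats::setNames(tab$median_loading, toupper(trimws(tab$gene)))
  present <- match_features(names(wmap), rownames(ds$matrix))
  if (length(present)) {
    sds <- apply(ds$matrix[present, , drop = FALSE], 1, stats::sd)
    present <- present[sds > 0]
  }
  missing <- tab$gene[!toupper(trimws(tab$gene)) %in% toupper(trimws(present))]
  if (length(present) < 2L) stop("fewer than 2 usable model genes in dataset")
  x <- ds$matrix[present, , drop = FALSE]
  z <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  scores <- as.numeric(crossprod(z, wmap[toupper(trimws(present))]))
  structure(list(scores = stats::setNames(scores, colnames(x)),
                 genes_used = present, genes_missing = missing),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat("<score_vector> ", length(x$scores), " samples scored with ",
      length(x$genes_used), " genes",
      if (length(x$genes_missing)) paste0(" (", length(x$genes_missing),
                                          " model genes missing)"),
      "\n", sep = "")
  invisible(x)
}

as_scores <- function(scores) {
  if (inherits(scores, "score_vector")) scores$scores else scores
}

#' Rank-correlation trend test
#'
#' Spearman correlation (midranks for ties) between metagene scores and a
#' per-sample numeric covariate such as treatment/exposure time, with its
#' two-sided p-value (exact when there are no ties and few samples, the
#' usual t approximation otherwise).
#'
#' @param scores a `score_vector` or named/plain numeric vector.
#' @param covariate numeric covariate, matched by name when both are named.
#' @return list with `rho`, `p`, and `n`.
#' @export
trend_test <- function(scores, covariate) {
  s <- as_scores(scores)
  if (!is.null(names(s)) && !is.null(names(covariate))) {
    ids <- intersect(names(s), names(covariate))
    s <- s[ids]; covariate <- covariate[ids]
  }
  if (length(s) != length(covariate)) stop("scores and covariate differ in length")
  if (length(s) < 4L) stop("need at least 4 paired observations")
  if (stats::sd(s) == 0 || stats::sd(covariate) == 0)
    stop("constant scores or covariate: rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(s, covariate, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(s))
}

#' Kruskal-Wallis multi-group comparison with post-hoc tests
#'
#' Kruskal-Wallis H (with tie correction) and its chi-square p-value across
#' >= 2 groups, followed by pairwise post-hoc comparisons.  The default
#' post-hoc is rank-based pairwise Wilcoxon tests with Holm family-wise
#' adjustment; `posthoc = "tukey"` runs Tukey HSD on the raw values for
#' parity with parametric workflows.
#'
#' @param scores a `score_vector` or numeric vector.
#' @param labels group labels (>= 2 groups, each with >= 2 samples), named
#'   by sample id or in order.
#' @param posthoc `"wilcox_holm"` or `"tukey"`.
#' @return list with `H`, `df`, `p`, `pairwise` (data frame `group1`,
#'   `group2`, `p_adj`), `posthoc`.
#' @export
group_test <- function(scores, labels, posthoc = c("wilcox_holm", "tukey")) {
  posthoc <- match.arg(posthoc)
  s <- as_scores(scores)
  labels <- align_labels(labels, names(s), length(s))
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) < 2L)) stop("singleton class")
  kw <- stats::kruskal.test(s, g)
  if (posthoc == "wilcox_holm") {
    pw <- suppressWarnings(stats::pairwise.wilcox.test(s, g,
                                                       p.adjust.method = "holm"))
    m <- pw$p.value
    pairs <- which(!is.na(m), arr.ind = TRUE)
    tab <- data.frame(group1 = rownames(m)[pairs[, 1]],
                      group2 = colnames(m)[pairs[, 2]],
                      p_adj = m[pairs], row.names = NULL)
  } else {
    tk <- stats::TukeyHSD(stats::aov(s ~ g))$g
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    tab <- data.frame(group1 = vapply(nm, `[`, character(1), 1),
                      group2 = vapply(nm, `[`, character(1), 2),
                      p_adj = tk[, "p adj"], row.names = NULL)
  }
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = tab, posthoc = posthoc)
}
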