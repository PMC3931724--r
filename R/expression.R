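#' Construct an expression dataset
#'
#' A log2-scale feature-by-sample matrix with optional per-sample class
#' labels, an optional probe-to-gene map, and an optional per-sample numeric
#' covariate (e.g. exposure time for a time series).
#'
#' @param m numeric matrix, features in rows (unique rownames), samples in
#'   columns (unique colnames); all values finite.
#' @param labels optional character/factor vector of class labels, named by
#'   sample id or given in column order.
#' @param feature_map optional named character vector mapping feature
#'   (probe) ids to gene symbols.
#' @param time optional numeric per-sample covariate, named by sample id or
#'   in column order.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(m, labels = NULL, feature_map = NULL,
                               time = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  # a filtered-to-empty matrix is legal; R normalizes its rownames to NULL
  if ((is.null(rownames(m)) && nrow(m) > 0L) || is.null(colnames(m)))
    stop("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (anyDuplicated(rownames(m))) stop("duplicate feature ids")
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  align <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (is.factor(v)) v <- stats::setNames(as.character(v), names(v))
    if (is.null(names(v))) {
      if (length(v) != ncol(m))
        stop(what, " must be named by sample or match the sample count")
      names(v) <- colnames(m)
    } else {
      if (!all(names(v) %in% colnames(m)))
        stop(what, " refers to unknown samples")
    }
    v[colnames(m)[colnames(m) %in% names(v)]]
  }
  labels <- align(labels, "labels")
  time <- align(time, "time")
  if (!is.null(time)) time <- stats::setNames(as.numeric(time), names(time))
  if (!is.null(feature_map)) {
    if (is.null(names(feature_map))) stop("feature_map must be named by probe id")
    feature_map <- stats::setNames(toupper(trimws(as.character(feature_map))),
                                   names(feature_map))
  }
  structure(list(matrix = m, labels = labels, feature_map = feature_map,
                 time = time),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$matrix), " features x ",
      ncol(x$matrix), " samples", sep = "")
  if (!is.null(x$labels))
    cat("; labels: ", paste(names(table(x$labels)), table(x$labels),
                            sep = "=", collapse = ", "), sep = "")
  if (!is.null(x$time)) cat("; time covariate present")
  cat("\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

# replace the matrix, keeping the metadata aligned to surviving rows/columns
subset_features <- function(ds, features) {
  expression_dataset(ds$matrix[features, , drop = FALSE],
                     labels = ds$labels,
                     feature_map = ds$feature_map[intersect(names(ds$feature_map), features)],
                     time = ds$time)
}

subset_samples <- function(ds, samples) {
  expression_dataset(ds$matrix[, samples, drop = FALSE],
                     labels = ds$labels[intersect(names(ds$labels), samples)],
                     feature_map = ds$feature_map,
                     time = ds$time[intersect(names(ds$time), samples)])
}

#' Read / write expression datasets as TSV
#'
#' The expression TSV has feature ids in the first column and sample ids in
#' the header.  Phenotype tables are two-column TSVs (`sample_id`, `label`),
#' feature maps are (`probe_id`, `gene_symbol`).
#'
#' @param path expression TSV path.
#' @param labels_path,feature_map_path,time_path optional companion tables
#'   (`time_path`: columns `sample_id`, `time`).
#' @return an `expression_dataset`.
#' @export
read_expression_tsv <- function(path, labels_path = NULL,
                                feature_map_path = NULL, time_path = NULL) {
  for (p in c(path, labels_path, feature_map_path, time_path))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  two_col <- function(p) {
    if (is.null(p)) return(NULL)
    t2 <- utils::read.delim(p, stringsAsFactors = FALSE)
    stats::setNames(t2[[2]], as.character(t2[[1]]))
  }
  expression_dataset(m, labels = two_col(labels_path),
                     feature_map = two_col(feature_map_path),
                     time = two_col(time_path))
}

#' @rdname read_expression_tsv
#' @param ds an `expression_dataset` to write.
#' @export
write_expression_tsv <- function(ds, path) {
  df <- data.frame(feature_id = rownames(ds$matrix), ds$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fluorescence-intensity filter
#'
#' Keeps features whose log2 intensity exceeds `threshold_log2` in at least
#' `ceiling(min_fraction * n_samples)` samples — the "above log2(100) in at
#' least 10\% of the arrays" rule.  Feature order is preserved.  An empty
#' result triggers a warning, not an error.
#'
#' @param ds an `expression_dataset` (log2 scale).
#' @param threshold_log2 intensity threshold, default `log2(100)`.
#' @param min_fraction minimum fraction of samples above threshold.
#' @return the filtered `expression_dataset`.
#' @export
intensity_filter <- function(ds, threshold_log2 = log2(100),
                             min_fraction = 0.10) {
  stopifnot(inherits(ds, "expression_dataset"))
  need <- ceiling(min_fraction * ncol(ds$matrix))
  keep <- rowSums(ds$matrix > threshold_log2) >= need
  if (!any(keep)) {
    warning("intensity filter removed every feature")
    return(subset_features(ds, character(0)))
  }
  subset_features(ds, rownames(ds$matrix)[keep])
}

#' Collapse probes to genes
#'
#' One row per gene symbol.  By default the probe with the highest mean
#' intensity represents the gene (`method = "max_mean"`); alternatively the
#' per-sample median over a gene's probes is taken (`method = "median"`).
#' Probes without a mapping are dropped (a message reports how many).  The
#' representative-probe choice is recorded in the `"collapse_map"` attribute.
#'
#' @param ds an `expression_dataset` with a `feature_map`.
#' @param method `"max_mean"` or `"median"`.
#' @return an `expression_dataset` keyed by gene symbol.
#' @export
collapse_probes <- function(ds, method = c("max_mean", "median")) {
  stopifnot(inherits(ds, "expression_dataset"))
  method <- match.arg(method)
  if (is.null(ds$feature_map)) stop("collapse_probes needs a feature_map")
  probes <- rownames(ds$matrix)
  mapped <- probes[probes %in% names(ds$feature_map)]
  n_drop <- length(probes) - length(mapped)
  if (n_drop > 0)
    message(n_drop, " unmapped probe(s) dropped")
  if (!length(mapped)) stop("no mapped probes")
  gene <- unname(ds$feature_map[mapped])
  if (method == "max_mean") {
    mu <- rowMeans(ds$matrix[mapped, , drop = FALSE])
    ord <- order(gene, -mu)
    pick <- mapped[ord][!duplicated(gene[ord])]
    m <- ds$matrix[pick, , drop = FALSE]
    rownames(m) <- gene[match(pick, mapped)]
    cmap <- stats::setNames(pick, rownames(m))
  } else {
    genes <- sort(unique(gene))
    m <- do.call(rbind, lapply(genes, function(g) {
      apply(ds$matrix[mapped[gene == g], , drop = FALSE], 2, stats::median)
    }))
    rownames(m) <- genes
    cmap <- NULL
  }
  out <- expression_dataset(m[order(rownames(m)), , drop = FALSE],
                            labels = ds$labels, time = ds$time)
  attr(out, "collapse_map") <- cmap
  out
}

#' Align datasets on shared features (and samples)
#'
#' Restricts every dataset to the intersection of feature ids and, when
#' `samples = TRUE`, to the intersection of sample ids, with identical
#' row/column ordering across outputs.  Sample ids are matched
#' case-insensitively (ids are case-folded before intersecting; each output
#' keeps its own original spelling order).
#'
#' @param dsets a list of >= 2 `expression_dataset`s.
#' @param samples also intersect sample ids?
#' @return list of aligned `expression_dataset`s.
#' @export
align_common <- function(dsets, samples = TRUE) {
  if (length(dsets) < 2L) stop("need at least two datasets")
  stopifnot(all(vapply(dsets, inherits, logical(1), "expression_dataset")))
  feats <- Reduce(intersect, lapply(dsets, function(d) rownames(d$matrix)))
  if (!length(feats)) stop("empty feature intersection")
  if (samples) {
    keys <- Reduce(intersect, lapply(dsets, function(d) toupper(colnames(d$matrix))))
    if (!length(keys)) stop("empty sample intersection")
  }
  lapply(dsets, function(d) {
    out <- subset_features(d, feats)
    if (samples) {
      ids <- colnames(out$matrix)[match(keys, toupper(colnames(out$matrix)))]
      out <- subset_samples(out, ids)
    }
    out
  })
}

# row-wise Spearman correlation between two matrices over matching rows;
# constant rows give NA (callers decide what that means)
rowwise_spearman <- function(a, b) {
  ra <- t(apply(a, 1, rank))
  rb <- t(apply(b, 1, rank))
  ca <- ra - rowMeans(ra)
  cb <- rb - rowMeans(rb)
  den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
  num <- rowSums(ca * cb)
  out <- ifelse(den > 0, num / den, NA_real_)
  stats::setNames(out, rownames(a))
}

#' Cross-dataset consistency filter
#'
#' For every feature, computes the Spearman rank correlation (midranks for
#' ties) of its expression across shared samples for every pair of datasets
#' (`D * (D - 1) / 2` coefficients) and keeps the feature iff the median
#' coefficient is at least `threshold` (0.50 in the original procedure).
#' Correlations undefined because a feature is constant within a dataset
#' score 0 (conservative: degenerate probes cannot pass) and are flagged in
#' the report.
#'
#' @param dsets list of >= 2 `expression_dataset`s sharing samples.
#' @param threshold median-correlation cutoff.
#' @param align align the datasets first (see [align_common()])?
#' @return list with `kept` (character vector of feature ids) and `report`
#'   (data frame of per-pair coefficients, the median, undefined-pair count
#'   and keep flag) plus the `threshold` used.
#' @export
consistency_filter <- function(dsets, threshold = 0.50, align = TRUE) {
  if (length(dsets) < 2L) stop("need at least two datasets")
  if (align) dsets <- align_common(dsets, samples = TRUE)
  n <- ncol(dsets[[1]]$matrix)
  if (n < 3L) stop("need at least 3 shared samples")
  feats <- rownames(dsets[[1]]$matrix)
  pairs <- utils::combn(length(dsets), 2)
  cors <- matrix(NA_real_, length(feats), ncol(pairs),
                 dimnames = list(feats, apply(pairs, 2, paste, collapse = "_")))
  for (j in seq_len(ncol(pairs))) {
    cors[, j] <- rowwise_spearman(dsets[[pairs[1, j]]]$matrix,
                                  dsets[[pairs[2, j]]]$matrix)
  }
  n_undef <- rowSums(is.na(cors))
  cors0 <- cors
  cors0[is.na(cors0)] <- 0
  med <- apply(cors0, 1, stats::median)
  kept <- feats[med >= threshold]
  report <- data.frame(feature = feats, cors0,
                       median_cor = med, n_undefined = as.integer(n_undef),
                       kept = med >= threshold,
                       row.names = NULL, check.names = FALSE)
  list(kept = kept, report = report, threshold = threshold)
}
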