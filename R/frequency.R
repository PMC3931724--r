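#' Construct a repetition-frequency table
#'
#' Tabulates how many genes appear in exactly `k` signatures
#' (`exact`) and in at least `k` signatures (`cumulative`) of a collection.
#' Either representation may be supplied; the other is derived:
#' `cumulative(k) = sum_{j >= k} exact(j)` and, conversely,
#' `exact(k) = cumulative(k) - cumulative(k + 1)` with the last exact count
#' equal to the last cumulative count.  Expected tables (Monte-Carlo means
#' over random collections) may hold fractional counts.
#'
#' @param exact numeric vector of exact counts, aligned with `multiplicity`.
#' @param cumulative numeric vector of cumulative counts (non-increasing).
#' @param multiplicity integer vector of multiplicities the counts refer to;
#'   defaults to `seq_along()` of whichever count vector was given.
#' @param kind `"observed"` or `"expected"`.
#' @param replicates number of Monte-Carlo replicates behind an expected
#'   table (1 for observed tables).
#' @return object of class `frequency_table` with fields `multiplicity`,
#'   `exact`, `cumulative`, `kind`, `replicates`.
#' @export
frequency_table <- function(exact = NULL, cumulative = NULL,
                            multiplicity = NULL,
                            kind = c("observed", "expected"),
                            replicates = 1L) {
  kind <- match.arg(kind)
  if (is.null(exact) == is.null(cumulative))
    stop("supply exactly one of 'exact' or 'cumulative'")
  if (is.null(exact)) {
    cumulative <- as.numeric(cumulative)
    if (any(diff(cumulative) > 1e-9))
      stop("cumulative counts must be non-increasing in multiplicity")
    exact <- c(-diff(cumulative), cumulative[length(cumulative)])
  } else {
    exact <- as.numeric(exact)
    cumulative <- rev(cumsum(rev(exact)))
  }
  if (any(exact < -1e-9) || any(cumulative < -1e-9))
    stop("negative counts")
  multiplicity <- as.integer(multiplicity %||% seq_along(exact))
  if (length(multiplicity) != length(exact) || any(diff(multiplicity) != 1L))
    stop("'multiplicity' must be consecutive integers matching the counts")
  structure(list(multiplicity = multiplicity, exact = exact,
                 cumulative = cumulative, kind = kind,
                 replicates = as.integer(replicates)),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> kind =", x$kind,
      if (x$kind == "expected") paste0("(", x$replicates, " replicates)"),
      "\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.frequency_table <- function(x, ...) {
  data.frame(multiplicity = x$multiplicity, exact = x$exact,
             cumulative = x$cumulative)
}

#' Look up counts at a given multiplicity
#'
#' Multiplicities beyond the table's support count zero genes.
#'
#' @param ft a `frequency_table`.
#' @param k integer multiplicities.
#' @return numeric vector of counts.
#' @name frequency_counts
#' @export
cumulative_count <- function(ft, k) {
  stopifnot(inherits(ft, "frequency_table"))
  idx <- match(k, ft$multiplicity)
  out <- ifelse(is.na(idx), 0, ft$cumulative[idx])
  # a truncated table cannot answer below its support
  out[k < ft$multiplicity[1]] <- NA_real_
  out
}

#' @rdname frequency_counts
#' @export
exact_count <- function(ft, k) {
  stopifnot(inherits(ft, "frequency_table"))
  idx <- match(k, ft$multiplicity)
  ifelse(is.na(idx), 0, ft$exact[idx])
}

#' Observed repetition frequencies of a collection
#'
#' Counts, for every multiplicity `1..n_signatures`, how many universe genes
#' appear in exactly / at least that many signatures.
#'
#' @param collection a `signature_collection`.
#' @return a `frequency_table` of kind `"observed"`.
#' @export
observed_frequencies <- function(collection) {
  if (!inherits(collection, "signature_collection") ||
      length(collection$signatures) == 0L)
    stop("empty collection")
  k <- length(collection$signatures)
  mult <- gene_multiplicity(collection)
  frequency_table(exact = tabulate(mult, nbins = k), kind = "observed")
}

#' Draw a size-matched random signature collection
#'
#' The randomization null: one random gene list per original signature, of
#' the same size, drawn uniformly without replacement (within a list) from
#' the collection's gene universe; draws are independent across lists.
#'
#' @param collection a `signature_collection`.
#' @param seed optional integer seed for reproducibility.
#' @return a `signature_collection` of random lists over the same universe.
#' @export
sample_random_collection <- function(collection, seed = NULL) {
  stopifnot(inherits(collection, "signature_collection"))
  if (length(collection$signatures) == 0L) stop("empty collection")
  if (!is.null(seed)) set.seed(seed)
  universe <- collection$universe
  sizes <- signature_sizes(collection)
  if (any(sizes > length(universe)))
    stop("signature size exceeds universe size")
  sigs <- lapply(seq_along(sizes), function(i) {
    gene_signature(sprintf("random_%02d", i),
                   sample(universe, sizes[i]),
                   source = "randomized")
  })
  signature_collection(sigs)
}

#' Expected repetition frequencies under the randomization null
#'
#' Mean exact counts per multiplicity over `replicates` independent
#' size-matched random collections (see [sample_random_collection()]).
#' `replicates = 1` reproduces the single matched random draw of the original
#' procedure; larger values stabilize the null.
#'
#' @param collection a `signature_collection`.
#' @param replicates number of random collections to average (>= 1).
#' @param seed optional integer seed.
#' @return a `frequency_table` of kind `"expected"`.
#' @export
expected_frequencies <- function(collection, replicates = 1000L, seed = NULL) {
  stopifnot(inherits(collection, "signature_collection"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  k <- length(collection$signatures)
  nu <- length(collection$universe)
  sizes <- signature_sizes(collection)
  if (any(sizes > nu)) stop("signature size exceeds universe size")
  acc <- numeric(k)
  # index-based equivalent of averaging observed_frequencies() over
  # sample_random_collection() draws, avoiding object construction
  for (r in seq_len(replicates)) {
    idx <- unlist(lapply(sizes, function(s) sample.int(nu, s)),
                  use.names = FALSE)
    acc <- acc + tabulate(tabulate(idx, nbins = nu), nbins = k)
  }
  frequency_table(exact = acc / replicates, kind = "expected",
                  replicates = replicates)
}

#' Chi-square goodness-of-fit between observed and expected frequencies
#'
#' Pearson statistic `sum((O - E)^2 / E)` over exact-count bins with
#' multiplicity `>= min_multiplicity`.  When `pool_tail` is `TRUE`, tail bins
#' are merged (from the highest multiplicity downward) until the pooled tail
#' bin has expected count >= 5, the usual validity rule for the chi-square
#' approximation; the original procedure does not state its binning.
#' Degrees of freedom are the number of bins minus one.
#'
#' @param observed,expected `frequency_table`s over the same multiplicity
#'   support.
#' @param min_multiplicity smallest multiplicity entering the test
#'   (default 2: singletons carry no repetition information).
#' @param pool_tail pool sparse tail bins (expected < 5)?
#' @return list with `stat`, `df`, `p`, and the pooled `observed_bins` /
#'   `expected_bins`.
#' @export
chi_square_gof <- function(observed, expected, min_multiplicity = 2L,
                           pool_tail = TRUE) {
  stopifnot(inherits(observed, "frequency_table"),
            inherits(expected, "frequency_table"))
  ks <- intersect(observed$multiplicity, expected$multiplicity)
  ks <- ks[ks >= min_multiplicity]
  if (length(ks) < 2L) stop("need at least two shared multiplicity bins")
  o <- exact_count(observed, ks)
  e <- exact_count(expected, ks)
  if (pool_tail) {
    while (length(e) > 1L && e[length(e)] < 5) {
      n <- length(e)
      e <- c(e[seq_len(n - 2L)], e[n - 1L] + e[n])
      o <- c(o[seq_len(n - 2L)], o[n - 1L] + o[n])
    }
  }
  if (any(e <= 0)) stop("degenerate expected bin")
  if (length(e) < 2L) stop("fewer than two bins after pooling")
  stat <- sum((o - e)^2 / e)
  df <- length(e) - 1L
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       observed_bins = o, expected_bins = e)
}

#' Select the core signature
#'
#' Implements the core-selection rule: a multiplicity `k >= min_multiplicity`
#' qualifies when the observed cumulative count of genes represented at least
#' `k` times exceeds the expected cumulative count under the randomization
#' null.  The threshold `k*` is the qualifying multiplicity whose observed
#' cumulative gene set is largest (ties broken toward the smaller `k`; since
#' cumulative counts are non-increasing this is the smallest qualifying
#' multiplicity), and the core is every gene with multiplicity `>= k*`.  The
#' selection is gated on a significant chi-square test between the observed
#' and expected exact-count distributions: if `p >= alpha` an empty core is
#' returned with status `"not significant"`; if no multiplicity qualifies the
#' status is `"no overrepresentation"`.
#'
#' @param observed,expected `frequency_table`s over a shared support.
#' @param collection the `signature_collection` behind `observed`; optional.
#'   When supplied, the member genes of the core are reported, otherwise only
#'   the core size (taken from the observed cumulative count at `k*`).
#' @param alpha significance gate for the chi-square test.
#' @param min_multiplicity smallest multiplicity eligible for selection.
#' @return object of class `core_selection` with fields
#'   `threshold_multiplicity`, `core_genes` (or `NULL`), `core_size`,
#'   `chi_square_stat`, `df`, `p_value`, `qualifying_multiplicities`,
#'   `status`.
#' @export
select_core_signature <- function(observed, expected, collection = NULL,
                                  alpha = 0.05, min_multiplicity = 2L) {
  chi <- chi_square_gof(observed, expected,
                        min_multiplicity = min_multiplicity)
  ks <- intersect(observed$multiplicity, expected$multiplicity)
  ks <- sort(ks[ks >= min_multiplicity])
  ocum <- cumulative_count(observed, ks)
  ecum <- cumulative_count(expected, ks)
  qual <- ks[ocum > ecum]
  empty <- function(status) {
    structure(list(threshold_multiplicity = NA_integer_,
                   core_genes = if (is.null(collection)) NULL else character(0),
                   core_size = 0L,
                   chi_square_stat = chi$stat, df = chi$df,
                   p_value = chi$p,
                   qualifying_multiplicities = qual,
                   status = status),
              class = "core_selection")
  }
  if (chi$p >= alpha) return(empty("not significant"))
  if (length(qual) == 0L) return(empty("no overrepresentation"))
  qcum <- cumulative_count(observed, qual)
  kstar <- qual[which.max(qcum)]   # first max = smallest k on ties
  core_genes <- NULL
  if (!is.null(collection)) {
    mult <- gene_multiplicity(collection)
    core_genes <- sort(names(mult)[mult >= kstar])
  }
  structure(list(threshold_multiplicity = as.integer(kstar),
                 core_genes = core_genes,
                 core_size = as.integer(round(cumulative_count(observed, kstar))),
                 chi_square_stat = chi$stat, df = chi$df, p_value = chi$p,
                 qualifying_multiplicities = qual,
                 status = "ok"),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat("<core_selection> status:", x$status, "\n")
  cat("  chi-square:", format(x$chi_square_stat, digits = 6),
      "on", x$df, "df, p =", format(x$p_value, digits = 3), "\n")
  if (x$status == "ok") {
    cat("  threshold multiplicity k* =", x$threshold_multiplicity,
        "-> core of", x$core_size, "genes\n")
    if (!is.null(x$core_genes))
      cat("  core:", paste(x$core_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export observed and expected frequency tables as TSV
#'
#' Columns: multiplicity, observed_exact, observed_cumulative,
#' expected_exact, expected_cumulative.
#'
#' @param observed,expected `frequency_table`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(observed, expected, path) {
  ks <- sort(union(observed$multiplicity, expected$multiplicity))
  df <- data.frame(multiplicity = ks,
                   observed_exact = exact_count(observed, ks),
                   observed_cumulative = cumulative_count(observed, ks),
                   expected_exact = exact_count(expected, ks),
                   expected_cumulative = cumulative_count(expected, ks))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
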