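config_error <- function(...) {
  stop(structure(class = c("coresig_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

write_manifest <- function(out_dir, step, seed, params) {
  manifest <- list(tool = "coresig",
                   version = as.character(utils::packageVersion("coresig")),
                   step = step,
                   date = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
                   seed = seed,
                   parameters = params)
  jsonlite::write_json(manifest, file.path(out_dir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a pipeline configuration (JSON)
#'
#' Configuration files are JSON objects whose fields mirror the arguments of
#' [run_discover()], [run_validate()] and [run_score()]; every threshold
#' defaults to the published procedure's value (intensity `log2(100)` in
#' `>= 10\%` of arrays, consistency 0.50, alpha 0.05, 100 label permutations,
#' 100 random gene sets).
#'
#' @param path JSON file path.
#' @return a named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

as_collection <- function(x, what = "signature collection") {
  if (inherits(x, "signature_collection")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) config_error(what, " file not found: ", x)
    return(read_gmt(x))
  }
  signature_collection(x)
}

as_dataset <- function(x, labels = NULL, feature_map = NULL, time = NULL) {
  if (inherits(x, "expression_dataset")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) config_error("expression file not found: ", x)
    return(read_expression_tsv(x, labels_path = labels,
                               feature_map_path = feature_map,
                               time_path = time))
  }
  expression_dataset(x, labels = labels, feature_map = feature_map, time = time)
}

#' Discover a core signature from a collection
#'
#' End-to-end overrepresentation step: observed repetition frequencies,
#' Monte-Carlo expected frequencies under the size-matched randomization
#' null, chi-square gate, and core selection.  When `out_dir` is given, the
#' frequency tables (TSV), the core signature (GMT) and a run manifest
#' (JSON, recording seed and all parameters) are written.
#'
#' @param collection a `signature_collection`, a GMT path, or a list of
#'   gene vectors.
#' @param replicates random collections averaged for the expected table.
#' @param alpha chi-square significance gate.
#' @param min_multiplicity smallest multiplicity eligible for selection.
#' @param seed optional integer seed.
#' @param out_dir optional output directory.
#' @return a `core_selection` (with `observed` / `expected` tables attached
#'   as attributes).
#' @export
run_discover <- function(collection, replicates = 1000L, alpha = 0.05,
                         min_multiplicity = 2L, seed = NULL, out_dir = NULL) {
  collection <- as_collection(collection)
  obs <- observed_frequencies(collection)
  exp <- expected_frequencies(collection, replicates = replicates, seed = seed)
  sel <- select_core_signature(obs, exp, collection = collection,
                               alpha = alpha,
                               min_multiplicity = min_multiplicity)
  attr(sel, "observed") <- obs
  attr(sel, "expected") <- exp
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_frequency_table(obs, exp, file.path(out_dir, "frequencies.tsv"))
    if (sel$status == "ok" && length(sel$core_genes))
      write_gmt(gene_signature("core_signature", sel$core_genes,
                               source = "coresig::run_discover"),
                file.path(out_dir, "core_signature.gmt"))
    write_manifest(out_dir, "discover", seed,
                   list(n_signatures = length(collection),
                        universe_size = length(collection$universe),
                        replicates = replicates, alpha = alpha,
                        min_multiplicity = min_multiplicity))
  }
  sel
}

#' Validate a signature on labeled expression datasets
#'
#' Per dataset: intensity filter, optional cross-dataset consistency filter
#' (applied when several datasets share samples), then PCA centroid
#' separation with class-label permutation and random-gene-set baselines.
#'
#' @param datasets an `expression_dataset`, or a (named) list of datasets /
#'   expression TSV paths.
#' @param signature candidate gene symbols (or a `gene_signature`).
#' @param universe gene universe for the random baseline (character vector,
#'   `signature_collection` or `NULL` to skip the baseline).
#' @param labels optional labels TSV path(s) or vectors, parallel to
#'   `datasets`, for datasets that do not carry labels.
#' @param intensity_threshold,min_fraction see [intensity_filter()].
#' @param consistency_threshold see [consistency_filter()]; used when >= 2
#'   datasets are given and `consistency = TRUE`.
#' @param consistency apply the cross-dataset consistency filter?
#' @param n_perm,n_sets permutation and baseline replicate counts.
#' @param seed optional integer seed.
#' @param out_dir optional output directory (JSON results, embedding TSVs,
#'   manifest).
#' @return named list of `separation_result`s, one per dataset.
#' @export
run_validate <- function(datasets, signature, universe = NULL, labels = NULL,
                         intensity_threshold = log2(100), min_fraction = 0.10,
                         consistency_threshold = 0.50, consistency = TRUE,
                         n_perm = 100L, n_sets = 100L, seed = NULL,
                         out_dir = NULL) {
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  if (!is.list(labels)) labels <- list(labels)
  dsets <- lapply(seq_along(datasets), function(i) {
    as_dataset(datasets[[i]],
               labels = if (i <= length(labels)) labels[[i]] else NULL)
  })
  names(dsets) <- names(datasets) %||% sprintf("dataset_%02d", seq_along(dsets))
  for (nm in names(dsets))
    if (is.null(dsets[[nm]]$labels))
      config_error("dataset '", nm, "' has no class labels")
  if (inherits(signature, "gene_signature")) signature <- signature$genes
  if (inherits(universe, "signature_collection")) universe <- universe$universe
  if (!is.null(seed)) set.seed(seed)
  dsets <- lapply(dsets, intensity_filter,
                  threshold_log2 = intensity_threshold,
                  min_fraction = min_fraction)
  n_before <- vapply(dsets, nrow, integer(1))
  kept <- NULL
  if (length(dsets) >= 2L && isTRUE(consistency)) {
    cons <- consistency_filter(dsets, threshold = consistency_threshold)
    kept <- cons$kept
    if (length(kept) == 0L) stop("consistency filter removed every feature")
    dsets <- lapply(dsets, function(d)
      subset_features(d, intersect(rownames(d$matrix), kept)))
    message("consistency filter: ", nrow(cons$report) - length(kept),
            " of ", nrow(cons$report), " shared features removed")
  }
  results <- lapply(names(dsets), function(nm) {
    separation_analysis(dsets[[nm]], signature, universe = universe,
                        n_perm = n_perm, n_sets = n_sets)
  })
  names(results) <- names(dsets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      r <- results[[nm]]
      jsonlite::write_json(
        list(dataset = nm, distance = r$distance,
             permutation_p = r$permutation_p,
             permutation_null = r$permutation_null,
             baseline_p = r$baseline_p,
             baseline_distances = r$baseline_distances,
             genes_used = r$genes_used),
        file.path(out_dir, paste0("validate_", nm, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.table(
        data.frame(sample_id = rownames(r$embedding), r$embedding,
                   label = r$labels, check.names = FALSE),
        file.path(out_dir, paste0("embedding_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(out_dir, "validate", seed,
                   list(intensity_threshold = intensity_threshold,
                        min_fraction = min_fraction,
                        consistency_threshold = consistency_threshold,
                        consistency = consistency,
                        n_perm = n_perm, n_sets = n_sets,
                        features_after_intensity = as.list(n_before),
                        features_after_consistency =
                          if (is.null(kept)) NA else length(kept)))
  }
  results
}

#' Score datasets with a metagene model
#'
#' Applies [score_samples()] and, when the dataset carries the relevant
#' metadata, the Spearman trend test against the time covariate and the
#' Kruskal-Wallis group comparison against the class labels.
#'
#' @param model a `metagene_model` or a model JSON path.
#' @param datasets an `expression_dataset` or (named) list of datasets /
#'   TSV paths.
#' @param robust_only score with robust genes only?
#' @param out_dir optional output directory (scores TSV + test reports).
#' @return named list per dataset: `scores` (a `score_vector`), `trend`
#'   (or NULL), `groups` (or NULL).
#' @export
run_score <- function(model, datasets, robust_only = TRUE, out_dir = NULL) {
  if (is.character(model)) {
    if (!file.exists(model)) config_error("model file not found: ", model)
    model <- read_metagene_model(model)
  }
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  dsets <- lapply(datasets, as_dataset)
  names(dsets) <- names(datasets) %||% sprintf("dataset_%02d", seq_along(dsets))
  results <- lapply(names(dsets), function(nm) {
    d <- dsets[[nm]]
    sv <- score_samples(model, d, robust_only = robust_only)
    trend <- if (!is.null(d$time)) trend_test(sv, d$time) else NULL
    groups <- if (!is.null(d$labels) && length(unique(d$labels)) >= 2 &&
                  all(table(d$labels) >= 2))
      group_test(sv, d$labels) else NULL
    list(scores = sv, trend = trend, groups = groups)
  })
  names(results) <- names(dsets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      r <- results[[nm]]
      utils::write.table(
        data.frame(sample_id = names(r$scores$scores),
                   score = unname(r$scores$scores)),
        file.path(out_dir, paste0("scores_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      report <- list(dataset = nm, genes_used = r$scores$genes_used,
                     genes_missing = r$scores$genes_missing)
      if (!is.null(r$trend)) report$trend <- r$trend
      if (!is.null(r$groups))
        report$groups <- list(H = r$groups$H, df = r$groups$df,
                              p = r$groups$p, posthoc = r$groups$posthoc,
                              pairwise = r$groups$pairwise)
      jsonlite::write_json(report,
                           file.path(out_dir, paste0("score_", nm, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  results
}
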