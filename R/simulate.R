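#' Published signature-collection metadata
#'
#' The 21 signature descriptions and sizes of the motility/invasion
#' collection this package's defaults emulate (3209 membership slots over a
#' 2636-gene universe).  Shipped as a plain TSV under `extdata`.
#'
#' @return data frame with columns `description` and `n_genes`.
#' @export
collection_metadata <- function() {
  utils::read.delim(system.file("extdata", "signature_collection_sizes.tsv",
                                package = "coresig"),
                    stringsAsFactors = FALSE)
}

#' The 16-gene core invasiveness signature
#'
#' The published consensus list of genes overrepresented across the
#' signature collection, shipped as a GMT fixture.
#'
#' @return a `gene_signature` of 16 genes.
#' @export
cig_signature <- function() {
  read_gmt(system.file("extdata", "cig_signature.gmt",
                       package = "coresig"))$signatures[[1]]
}

#' Published repetition-frequency tables
#'
#' The printed observed and expected gene-repetition counts for
#' multiplicities 2..7 (read as cumulative, "represented at least k times"),
#' usable as a worked-example input to [select_core_signature()].
#'
#' @return list of two `frequency_table`s, `observed` and `expected`.
#' @export
reported_repetition_frequencies <- function() {
  tab <- utils::read.delim(system.file("extdata", "repetition_frequencies.tsv",
                                       package = "coresig"),
                           stringsAsFactors = FALSE)
  list(observed = frequency_table(cumulative = tab$observed_cumulative,
                                  multiplicity = tab$multiplicity,
                                  kind = "observed"),
       expected = frequency_table(cumulative = tab$expected_cumulative,
                                  multiplicity = tab$multiplicity,
                                  kind = "expected"))
}

#' Simulate a signature collection with a planted core
#'
#' Generates `n_signatures` gene lists over a universe of `universe_size`
#' symbols.  Each of the `n_core` planted core genes is included in every
#' signature independently with probability `core_multiplicity_fraction`;
#' the remaining slots of each signature are filled uniformly without
#' replacement from the rest of the universe.  With
#' `core_multiplicity_fraction = 0` (or `n_core = 0`) the collection is a
#' pure random draw, i.e. the null model.  Signature sizes default to the
#' published collection's 21 sizes (resampled when `n_signatures != 21`).
#'
#' @param n_signatures number of gene lists.
#' @param universe_size number of distinct gene symbols.
#' @param signature_sizes integer vector of list sizes (recycled/sampled as
#'   needed); default: the published sizes.
#' @param n_core number of planted core genes.
#' @param core_multiplicity_fraction per-signature inclusion probability of
#'   each core gene.
#' @param seed optional integer seed.
#' @return list with `collection` (a `signature_collection`) and `truth`
#'   (the planted core gene symbols).
#' @export
simulate_signature_collection <- function(n_signatures = 21L,
                                          universe_size = 2636L,
                                          signature_sizes = NULL,
                                          n_core = 16L,
                                          core_multiplicity_fraction = 0.8,
                                          seed = NULL) {
  stopifnot(n_signatures >= 1L, universe_size >= 1L, n_core >= 0L,
            core_multiplicity_fraction >= 0, core_multiplicity_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(signature_sizes)) {
    pub <- collection_metadata()$n_genes
    signature_sizes <- if (n_signatures == length(pub)) pub
                       else sample(pub, n_signatures, replace = TRUE)
  } else {
    signature_sizes <- rep_len(as.integer(signature_sizes), n_signatures)
  }
  if (any(signature_sizes > universe_size))
    stop("signature size exceeds universe size")
  universe <- sprintf("G%05d", seq_len(universe_size))
  core <- if (n_core > 0) sample(universe, n_core) else character(0)
  sigs <- lapply(seq_len(n_signatures), function(i) {
    hits <- core[stats::runif(length(core)) < core_multiplicity_fraction]
    if (length(hits) > signature_sizes[i])
      stop("infeasible sizes: ", length(hits), " planted genes for a ",
           "signature of size ", signature_sizes[i])
    fill <- sample(setdiff(universe, hits),
                   signature_sizes[i] - length(hits))
    gene_signature(sprintf("sim_sig_%02d", i), c(hits, fill),
                   source = "simulated")
  })
  list(collection = signature_collection(sigs), truth = sort(core))
}

#' Simulate a labeled two-class expression dataset
#'
#' Log2-scale values are `baseline` plus Gaussian noise; signature genes get
#' an additional `effect_size` shift (in noise-SD units when `noise_sd = 1`)
#' in the second class ("invasive").  Optionally, some decoy features are
#' generated around a low baseline so they fail the intensity filter by
#' construction.
#'
#' @param signature character vector of signal gene symbols (rows are
#'   created for them; may be empty).
#' @param n_genes total number of features (>= signature size).
#' @param n_per_class integer vector of length 2: samples per class.
#' @param effect_size planted between-class shift for signature genes.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param baseline mean log2 intensity of expressed features.
#' @param low_intensity_features optional character vector naming features
#'   (created as extra rows) centered at `low_baseline`.
#' @param low_baseline mean log2 intensity of the decoy features.
#' @param class_names the two class labels.
#' @param seed optional integer seed.
#' @return an `expression_dataset` with labels attached.
#' @export
simulate_expression <- function(signature = character(0), n_genes = 500L,
                                n_per_class = c(15L, 15L), effect_size = 0,
                                noise_sd = 1, baseline = 8,
                                low_intensity_features = NULL,
                                low_baseline = 4,
                                class_names = c("non_invasive", "invasive"),
                                seed = NULL) {
  stopifnot(length(n_per_class) == 2L, all(n_per_class >= 1L))
  if (!is.null(seed)) set.seed(seed)
  signature <- normalize_symbols(signature)
  if (n_genes < length(signature)) stop("n_genes smaller than the signature")
  fillers <- sprintf("F%05d", seq_len(n_genes - length(signature)))
  feats <- c(signature, fillers, normalize_symbols(low_intensity_features))
  n <- sum(n_per_class)
  samples <- sprintf("S%03d", seq_len(n))
  labels <- stats::setNames(rep(class_names, n_per_class), samples)
  m <- matrix(stats::rnorm(length(feats) * n, mean = baseline, sd = noise_sd),
              nrow = length(feats), dimnames = list(feats, samples))
  if (!is.null(low_intensity_features))
    m[normalize_symbols(low_intensity_features), ] <-
      m[normalize_symbols(low_intensity_features), ] - (baseline - low_baseline)
  if (length(signature) && effect_size != 0)
    m[signature, labels == class_names[2]] <-
      m[signature, labels == class_names[2]] + effect_size
  expression_dataset(m, labels = labels)
}

#' Simulate a family of datasets sharing samples
#'
#' One latent truth matrix (built like [simulate_expression()]) is observed
#' `n_datasets` times with independent per-dataset measurement noise, the
#' same sample ids and labels throughout — emulating the same cell lines
#' profiled on several platforms.  A configurable fraction of non-signature
#' features is "scrambled": regenerated independently per dataset, so they
#' carry no cross-dataset signal and are the targets of
#' [consistency_filter()].
#'
#' @inheritParams simulate_expression
#' @param n_datasets number of datasets (>= 2).
#' @param dataset_noise_sd SD of the per-dataset measurement noise.
#' @param scrambled_fraction fraction of features regenerated independently
#'   per dataset.
#' @return list with `datasets` (named list of `expression_dataset`s) and
#'   `truth` (`signature`, `scrambled_features`, `consistent_features`).
#' @export
simulate_dataset_family <- function(signature = character(0),
                                    n_datasets = 3L, n_genes = 400L,
                                    n_per_class = c(11L, 10L),
                                    effect_size = 2, noise_sd = 1,
                                    dataset_noise_sd = 0.5,
                                    scrambled_fraction = 0,
                                    baseline = 8, seed = NULL) {
  stopifnot(n_datasets >= 2L, scrambled_fraction >= 0, scrambled_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  truth <- simulate_expression(signature = signature, n_genes = n_genes,
                               n_per_class = n_per_class,
                               effect_size = effect_size,
                               noise_sd = noise_sd, baseline = baseline)
  feats <- rownames(truth$matrix)
  signature <- normalize_symbols(signature)
  pool <- setdiff(feats, signature)
  scrambled <- sort(sample(pool, round(scrambled_fraction * n_genes)))
  dsets <- lapply(seq_len(n_datasets), function(d) {
    m <- truth$matrix +
      matrix(stats::rnorm(length(truth$matrix), sd = dataset_noise_sd),
             nrow = nrow(truth$matrix))
    if (length(scrambled))
      m[scrambled, ] <- baseline +
        stats::rnorm(length(scrambled) * ncol(m), sd = noise_sd)
    dimnames(m) <- dimnames(truth$matrix)
    expression_dataset(m, labels = truth$labels)
  })
  names(dsets) <- sprintf("dataset_%02d", seq_len(n_datasets))
  list(datasets = dsets,
       truth = list(signature = signature,
                    scrambled_features = scrambled,
                    consistent_features = setdiff(feats, scrambled)))
}

#' Simulate a forced-transition time series
#'
#' Emulates tumour cells driven through a phenotype transition over an
#' exposure time course: signature-gene means increase linearly with time at
#' `slope` log2-units per time unit on top of Gaussian noise.  The per-sample
#' time covariate is attached to the dataset.
#'
#' @inheritParams simulate_expression
#' @param timepoints numeric vector of >= 4 distinct exposure times
#'   (default: an 8-point 0-72 h course).
#' @param n_per_timepoint replicates per timepoint.
#' @param slope planted log2 change of signature genes per time unit.
#' @return an `expression_dataset` with `time` covariate attached.
#' @export
simulate_timeseries <- function(signature, timepoints = c(0, 2, 4, 8, 16, 24, 48, 72),
                                n_per_timepoint = 2L, slope = 0.02,
                                noise_sd = 1, n_genes = 300L, baseline = 8,
                                seed = NULL) {
  if (length(unique(timepoints)) < 4L) stop("need at least 4 timepoints")
  if (!is.null(seed)) set.seed(seed)
  signature <- normalize_symbols(signature)
  if (n_genes < length(signature)) stop("n_genes smaller than the signature")
  time <- rep(sort(timepoints), each = n_per_timepoint)
  n <- length(time)
  samples <- sprintf("T%03d", seq_len(n))
  feats <- c(signature, sprintf("F%05d", seq_len(n_genes - length(signature))))
  m <- matrix(stats::rnorm(length(feats) * n, mean = baseline, sd = noise_sd),
              nrow = length(feats), dimnames = list(feats, samples))
  if (length(signature))
    m[signature, ] <- m[signature, ] + rep(slope * time, each = length(signature))
  expression_dataset(m, time = stats::setNames(time, samples))
}
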