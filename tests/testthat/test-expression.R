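make_ds <- function(m, ...) expression_dataset(m, ...)

rand_matrix <- function(nr, nc, seed = 1, mean = 8) {
  set.seed(seed)
  matrix(rnorm(nr * nc, mean = mean), nr, nc,
         dimnames = list(sprintf("g%03d", seq_len(nr)),
                         sprintf("s%02d", seq_len(nc))))
}

test_that("dataset construction enforces its invariants", {
  m <- rand_matrix(4, 3)
  expect_s3_class(make_ds(m), "expression_dataset")
  bad <- m; rownames(bad)[2] <- "g001"
  expect_error(make_ds(bad), "duplicate feature")
  inf <- m; inf[1, 1] <- Inf
  expect_error(make_ds(inf), "non-finite")
  expect_error(make_ds(m, labels = c(x = "a")), "unknown samples")
  ds <- make_ds(m, labels = c(s02 = "inv", s01 = "non", s03 = "inv"))
  expect_identical(ds$labels, c(s01 = "non", s02 = "inv", s03 = "inv"))
})

test_that("intensity filter keeps features above log2(100) in >=10% of arrays", {
  m <- rand_matrix(5, 4, mean = 10)
  expect_identical(rownames(intensity_filter(make_ds(m))$matrix), rownames(m))

  m["g003", ] <- 5.0   # below log2(100) ~ 6.644 everywhere
  kept <- intensity_filter(make_ds(m))
  expect_false("g003" %in% rownames(kept$matrix))

  # planted fixture: exactly 30 of 100 features fail the filter
  ds <- simulate_expression(n_genes = 70, n_per_class = c(10, 10),
                            low_intensity_features = sprintf("LOW%02d", 1:30),
                            low_baseline = 4, seed = 5)
  filt <- intensity_filter(ds)
  expect_identical(nrow(filt$matrix), 70L)
  expect_false(any(grepl("^LOW", rownames(filt$matrix))))

  # idempotent
  expect_identical(intensity_filter(filt)$matrix, filt$matrix)

  all_low <- make_ds(matrix(2, 2, 4, dimnames = list(c("a", "b"), sprintf("s%d", 1:4))))
  expect_warning(intensity_filter(all_low), "every feature")
})

test_that("probe collapse picks the max-mean probe per gene", {
  m <- rand_matrix(4, 5)
  fmap <- c(g001 = "GENEA", g002 = "GENEA", g003 = "GENEB", g004 = "GENEC")
  m["g001", ] <- m["g001", ] + 2   # clearly the brighter GENEA probe
  ds <- make_ds(m, feature_map = fmap)
  coll <- collapse_probes(ds)
  expect_setequal(rownames(coll$matrix), c("GENEA", "GENEB", "GENEC"))
  expect_identical(unname(coll$matrix["GENEA", ]), unname(m["g001", ]))

  # one probe per gene: values unchanged up to renaming
  ds1 <- make_ds(m, feature_map = c(g001 = "W", g002 = "X", g003 = "Y", g004 = "Z"))
  c1 <- collapse_probes(ds1)
  expect_identical(unname(c1$matrix[c("W", "X", "Y", "Z"), ]), unname(m))

  # random fixture against a brute-force per-gene oracle
  set.seed(8)
  big <- rand_matrix(30, 6, seed = 8)
  genes <- sample(sprintf("G%02d", 1:10), 30, replace = TRUE)
  names(genes) <- rownames(big)
  cc <- collapse_probes(make_ds(big, feature_map = genes))
  for (g in unique(genes)) {
    probes <- names(genes)[genes == g]
    best <- probes[which.max(rowMeans(big[probes, , drop = FALSE]))]
    expect_identical(unname(cc$matrix[g, ]), unname(big[best, ]))
  }

  # unmapped probes dropped with a message
  expect_message(collapse_probes(make_ds(big, feature_map = genes[1:20])),
                 "unmapped")
  expect_error(collapse_probes(make_ds(big)), "feature_map")
})

test_that("alignment restricts to shared features and samples", {
  m <- rand_matrix(3, 4)
  ds <- make_ds(m)
  out <- align_common(list(ds, ds))
  expect_identical(out[[1]]$matrix, m)
  expect_identical(out[[2]]$matrix, m)

  m2 <- rand_matrix(3, 4, seed = 2)
  rownames(m) <- c("A", "B", "C"); rownames(m2) <- c("B", "C", "D")
  ab <- align_common(list(make_ds(m), make_ds(m2)))
  expect_identical(rownames(ab[[1]]$matrix), c("B", "C"))
  expect_identical(rownames(ab[[2]]$matrix), c("B", "C"))

  # three datasets sharing 21 of 40 cell lines
  shared <- sprintf("CELL%02d", 1:21)
  mk <- function(extra, seed) {
    ids <- c(shared, sprintf("ONLY%s%02d", extra, 1:19))
    m <- rand_matrix(10, 40, seed = seed)
    colnames(m) <- ids
    make_ds(m)
  }
  fam <- align_common(list(mk("A", 1), mk("B", 2), mk("C", 3)))
  expect_true(all(vapply(fam, function(d) ncol(d$matrix), 0L) == 21L))

  rownames(m2) <- c("X", "Y", "Z")
  expect_error(align_common(list(make_ds(m), make_ds(m2))), "feature intersection")
})

test_that("consistency filter keeps cross-dataset reproducible features", {
  ds <- make_ds(rand_matrix(50, 10))
  res <- consistency_filter(list(ds, ds, ds))
  expect_identical(res$kept, rownames(ds$matrix))
  expect_true(all(abs(res$report$median_cor - 1) < 1e-12))

  # independent noise: median pair correlation ~ 0, nearly everything drops
  noise <- lapply(1:3, function(i) make_ds(rand_matrix(200, 15, seed = 10 + i)))
  rn <- consistency_filter(noise)
  expect_lt(length(rn$kept) / 200, 0.05)

  # planted family: half the features scrambled per dataset
  fam <- simulate_dataset_family(signature = sprintf("SIG%02d", 1:10),
                                 n_genes = 400, scrambled_fraction = 0.5,
                                 dataset_noise_sd = 0.5, seed = 21)
  rf <- consistency_filter(fam$datasets)
  tp <- length(intersect(rf$kept, fam$truth$consistent_features))
  precision <- tp / length(rf$kept)
  recall <- tp / length(fam$truth$consistent_features)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)

  # symmetric in dataset order and idempotent
  rf2 <- consistency_filter(rev(fam$datasets))
  expect_setequal(rf2$kept, rf$kept)
  sub <- lapply(fam$datasets, function(d)
    expression_dataset(d$matrix[rf$kept, , drop = FALSE], labels = d$labels))
  expect_setequal(consistency_filter(sub)$kept, rf$kept)

  # constant features cannot pass: undefined correlations score 0
  cm <- rand_matrix(5, 8)
  cm["g001", ] <- 7
  cds <- make_ds(cm)
  rc <- consistency_filter(list(cds, cds))
  expect_false("g001" %in% rc$kept)
  expect_identical(rc$report$n_undefined[rc$report$feature == "g001"], 1L)
})

test_that("per-feature rank correlations match the rank-then-Pearson oracle", {
  a <- make_ds(rand_matrix(20, 9, seed = 31))
  b <- make_ds(rand_matrix(20, 9, seed = 32))
  res <- consistency_filter(list(a, b))
  for (f in rownames(a$matrix)[1:10]) {
    expect_equal(res$report[res$report$feature == f, "1_2"],
                 oracle_spearman(a$matrix[f, ], b$matrix[f, ]),
                 tolerance = 1e-12)
  }
})

test_that("expression TSVs round-trip with labels, maps and time", {
  ds <- simulate_expression(signature = c("FN1", "SPP1"), n_genes = 10,
                            n_per_class = c(3, 3), effect_size = 1, seed = 2)
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  write_expression_tsv(ds, ep)
  write.table(data.frame(sample_id = names(ds$labels), label = unname(ds$labels)),
              lp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_expression_tsv(ep, labels_path = lp)
  expect_equal(back$matrix, ds$matrix, tolerance = 1e-12)
  expect_identical(back$labels, ds$labels)
  expect_error(read_expression_tsv(file.path(dir, "nope.tsv")), "not found")
})
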