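test_that("gene signatures normalize, deduplicate and reject empty sets", {
  s <- gene_signature("toy", c(" a ", "A", "b"))
  expect_identical(s$genes, c("A", "B"))
  expect_error(gene_signature("bad", c("", NA)), "empty")
  aliased <- gene_signature("al", c("c-Fos", "JUN"), alias = c("C-FOS" = "FOS"))
  expect_setequal(aliased$genes, c("FOS", "JUN"))

  coll <- make_toy_collection()
  expect_identical(coll$universe, c("A", "B", "C"))
  expect_error(signature_collection(list()), "empty collection")
})

test_that("observed frequencies count repetition once per signature", {
  coll <- make_toy_collection()
  ft <- observed_frequencies(coll)
  expect_identical(ft$exact, c(1, 1, 1))
  expect_identical(ft$cumulative, c(3, 2, 1))
  expect_identical(cumulative_count(ft, 2), 2)

  # a single signature cannot produce repetition
  one <- signature_collection(list(letters[1:10]))
  f1 <- observed_frequencies(one)
  expect_identical(f1$exact, 10)
  expect_identical(cumulative_count(f1, 2), 0)

  # every planted gene present in all 21 signatures counts at multiplicity 21
  sim <- simulate_signature_collection(n_signatures = 21, universe_size = 400,
                                       signature_sizes = 40, n_core = 5,
                                       core_multiplicity_fraction = 1,
                                       seed = 7)
  f21 <- observed_frequencies(sim$collection)
  brute <- sum(vapply(sim$collection$universe,
                      function(g) oracle_multiplicity(sim$collection, g) == 21,
                      logical(1)))
  expect_identical(cumulative_count(f21, 21), as.numeric(brute))
  expect_gte(brute, 5)
})

test_that("conservation and monotonicity hold for observed and random tables", {
  base <- simulate_signature_collection(n_signatures = 8, universe_size = 150,
                                        signature_sizes = c(10, 25, 40), n_core = 5,
                                        core_multiplicity_fraction = 0.7, seed = 1)
  slots <- sum(signature_sizes(base$collection))
  for (s in 1:8) {
    rand <- sample_random_collection(base$collection, seed = s)
    ft <- observed_frequencies(rand)
    expect_equal(sum(ft$multiplicity * ft$exact), slots)
    expect_true(all(diff(ft$cumulative) <= 0))
  }
  ft <- observed_frequencies(base$collection)
  expect_equal(sum(ft$multiplicity * ft$exact), slots)
  expect_true(all(diff(ft$cumulative) <= 0))
})

test_that("random collections are size-matched, uniform and reproducible", {
  base <- make_toy_collection()
  r1 <- sample_random_collection(base, seed = 11)
  r2 <- sample_random_collection(base, seed = 11)
  r3 <- sample_random_collection(base, seed = 12)
  expect_identical(signature_sizes(r1), signature_sizes(base))
  expect_identical(lapply(r1$signatures, `[[`, "genes"),
                   lapply(r2$signatures, `[[`, "genes"))
  expect_false(identical(lapply(r1$signatures, `[[`, "genes"),
                         lapply(r3$signatures, `[[`, "genes")))

  # sampling without replacement forces a full-size list to equal the universe
  full <- signature_collection(list(letters[1:10]))
  expect_setequal(sample_random_collection(full, seed = 1)$signatures[[1]]$genes,
                  full$universe)

  # all 6 unordered pairs from a 4-gene universe are equally likely
  pairbase <- signature_collection(list(p = c("A", "B"), q = c("A", "B", "C", "D")))
  pairbase$signatures <- pairbase$signatures[1]   # one size-2 list, 4-gene universe
  set.seed(42)
  draws <- replicate(10000, paste(sort(sample_random_collection(pairbase)$signatures[[1]]$genes),
                                  collapse = ""))
  freq <- table(draws) / 10000
  expect_length(freq, 6)
  se <- sqrt((1 / 6) * (5 / 6) / 10000)
  expect_true(all(abs(freq - 1 / 6) < 3 * se + 1e-9))
})

test_that("expected frequencies average the randomization null", {
  expect_error(expected_frequencies(make_toy_collection(), replicates = 0),
               "replicates")

  # one full-size list: no randomness left
  full <- signature_collection(list(letters[1:10]))
  ft <- expected_frequencies(full, replicates = 5, seed = 1)
  expect_identical(ft$exact, 10)
  expect_identical(cumulative_count(ft, 2), 0)
  expect_identical(ft$kind, "expected")
  expect_identical(ft$replicates, 5L)

  # two independent size-1 draws from a 2-gene universe collide half the time
  two <- signature_collection(list(s1 = "A", s2 = "B"))
  ft2 <- expected_frequencies(two, replicates = 2000, seed = 2)
  expect_lt(abs(cumulative_count(ft2, 2) - 0.5), 3 * sqrt(0.25 / 2000))

  # Monte-Carlo convergence: 1000 vs 4000 replicates agree within MC error
  base <- simulate_signature_collection(n_signatures = 5, universe_size = 100,
                                        signature_sizes = 20, n_core = 0, seed = 3)
  a <- expected_frequencies(base$collection, replicates = 1000, seed = 4)
  b <- expected_frequencies(base$collection, replicates = 4000, seed = 5)
  expect_lt(abs(cumulative_count(a, 2) - cumulative_count(b, 2)), 0.6)
})

test_that("chi-square matches the pooled textbook formula", {
  o <- frequency_table(exact = c(20, 30, 50), multiplicity = 1:3)
  e <- frequency_table(exact = c(20, 30, 50), multiplicity = 1:3,
                       kind = "expected")
  res <- chi_square_gof(o, e, min_multiplicity = 1)
  expect_equal(res$stat, 0)
  expect_equal(res$p, 1)

  # printed frequency vectors, treated as the test's exact bins
  obs <- frequency_table(exact = c(646, 202, 62, 16, 6, 3), multiplicity = 2:7)
  exp <- frequency_table(exact = c(1065, 376, 87, 14, 1, 1), multiplicity = 2:7,
                         kind = "expected")
  res <- chi_square_gof(obs, exp)
  pooled <- oracle_pool(c(646, 202, 62, 16, 6, 3), c(1065, 376, 87, 14, 1, 1))
  expect_equal(res$stat, oracle_chisq(pooled$o, pooled$e), tolerance = 1e-12)
  expect_identical(res$df, length(pooled$e) - 1L)
  expect_lt(res$p, 0.001)

  # homogeneity: doubling all counts doubles the statistic exactly
  o2 <- frequency_table(exact = 2 * c(20, 30, 50), multiplicity = 1:3)
  e2 <- frequency_table(exact = 2 * c(18, 35, 47), multiplicity = 1:3,
                        kind = "expected")
  o1 <- frequency_table(exact = c(20, 30, 50), multiplicity = 1:3)
  e1 <- frequency_table(exact = c(18, 35, 47), multiplicity = 1:3,
                        kind = "expected")
  s1 <- chi_square_gof(o1, e1, min_multiplicity = 1, pool_tail = FALSE)$stat
  s2 <- chi_square_gof(o2, e2, min_multiplicity = 1, pool_tail = FALSE)$stat
  expect_equal(s2, 2 * s1, tolerance = 1e-12)

  ez <- frequency_table(exact = c(10, 0, 10), multiplicity = 1:3,
                        kind = "expected")
  expect_error(chi_square_gof(o1, ez, min_multiplicity = 1, pool_tail = FALSE),
               "degenerate expected bin")
})

test_that("core selection reproduces the published worked example", {
  rep <- reported_repetition_frequencies()
  sel <- select_core_signature(rep$observed, rep$expected)
  expect_identical(sel$status, "ok")
  expect_identical(sel$threshold_multiplicity, 5L)
  expect_identical(sel$core_size, 16L)
  expect_identical(sel$qualifying_multiplicities, c(5L, 6L, 7L))
})

test_that("core selection gates on significance and qualification", {
  # significant chi-square but observed never exceeds expected
  obs <- frequency_table(exact = c(30, 5), multiplicity = 2:3)
  exp <- frequency_table(exact = c(100, 20), multiplicity = 2:3,
                         kind = "expected")
  sel <- select_core_signature(obs, exp)
  expect_identical(sel$status, "no overrepresentation")
  expect_identical(sel$core_size, 0L)

  # no signal at all: chi-square p = 1 >= alpha
  same <- frequency_table(exact = c(30, 20), multiplicity = 2:3)
  same_e <- frequency_table(exact = c(30, 20), multiplicity = 2:3,
                            kind = "expected")
  sel2 <- select_core_signature(same, same_e)
  expect_identical(sel2$status, "not significant")

  # tie in observed cumulative counts resolves to the smaller multiplicity
  obs3 <- frequency_table(exact = c(0, 10, 6), multiplicity = 2:4)
  exp3 <- frequency_table(exact = c(5, 5, 5), multiplicity = 2:4,
                          kind = "expected")
  sel3 <- select_core_signature(obs3, exp3)
  expect_identical(sel3$status, "ok")
  expect_identical(sel3$qualifying_multiplicities, c(2L, 3L, 4L))
  expect_identical(sel3$threshold_multiplicity, 2L)
  expect_identical(sel3$core_size, 16L)
})

test_that("planted core genes are always contained in the selected core", {
  for (s in 1:5) {
    sim <- simulate_signature_collection(n_signatures = 20,
                                         universe_size = 2000,
                                         n_core = 10,
                                         core_multiplicity_fraction = 0.8,
                                         seed = s)
    obs <- observed_frequencies(sim$collection)
    exp <- expected_frequencies(sim$collection, replicates = 100,
                                seed = 100 + s)
    sel <- select_core_signature(obs, exp, collection = sim$collection)
    expect_identical(sel$status, "ok")
    expect_true(all(sim$truth %in% sel$core_genes))
    expect_identical(length(sel$core_genes), sel$core_size |> as.integer())
  }
})

test_that("GMT files round-trip and frequency tables export as TSV", {
  coll <- signature_collection(list(alpha = c("TP53", "MYC"),
                                    beta = c("MYC", "FN1", "SPP1")))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, gmt)
  back <- read_gmt(gmt)
  expect_identical(lapply(back$signatures, `[[`, "genes"),
                   lapply(coll$signatures, `[[`, "genes"))
  expect_identical(back$universe, coll$universe)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  rep <- reported_repetition_frequencies()
  write_frequency_table(rep$observed, rep$expected, tsv)
  tab <- read.delim(tsv)
  expect_identical(tab$observed_cumulative, c(646L, 202L, 62L, 16L, 6L, 3L))
  expect_identical(tab$expected_cumulative, c(1065L, 376L, 87L, 14L, 1L, 1L))

  # the shipped 16-gene fixture matches its own metadata
  cig <- cig_signature()
  expect_length(cig$genes, 16)
  expect_true(all(c("CDH1", "FN1", "SPP1", "TNFAIP3") %in% cig$genes))
  expect_equal(sum(collection_metadata()$n_genes), 3209)
})
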