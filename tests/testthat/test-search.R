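make_search_inputs <- function(sim_seed = 3, effect = 1, n_genes = 12,
                               n_informative = 3, n_per_class = 15) {
  sim <- simulate_expression(sim_config(n_genes = n_genes,
                                        n_informative = n_informative,
                                        n_per_class = n_per_class,
                                        effect = effect, seed = sim_seed))
  ds <- zscore_normalize(sim$dataset)
  list(ds = ds, ranking = kwrst_pvalues(ds), truth = sim$truth$gene_id)
}

test_that("first expansion reproduces exhaustive pair scoring", {
  inp <- make_search_inputs(n_genes = 5)
  spec <- classifier_spec("knn", seed = 7)
  cfg <- search_config(p = 5, w = 10, acc_max = 1, depth = 2)
  opt <- hbsa(inp$ds, inp$ranking, cfg, spec)

  fold <- make_folds(inp$ds$labels, spec$cv_folds, spec$seed)
  pair_accs <- oracle_exhaustive(inp$ds, preselect(inp$ranking, 5), 2,
                                 spec, fold)
  got <- sort(vapply(opt$subsets, `[[`, numeric(1), "acc"), decreasing = TRUE)
  expect_equal(got, sort(pair_accs, decreasing = TRUE))
  expect_true(all(vapply(opt$subsets, function(s) length(s$genes), 0L) == 2))
  # all C(5,2) pairs scored once plus 5 singletons
  expect_equal(opt$evaluations, 5 + choose(5, 2))
})

test_that("depth 1 returns singletons ranked by single-gene accuracy", {
  inp <- make_search_inputs()
  spec <- classifier_spec("knn", seed = 2)
  opt <- hbsa(inp$ds, inp$ranking, search_config(p = 8, w = 4, depth = 1), spec)
  expect_true(all(vapply(opt$subsets, function(s) length(s$genes), 0L) == 1))
  expect_equal(length(opt$subsets), 4)
  fold <- make_folds(inp$ds$labels, spec$cv_folds, spec$seed)
  singles <- vapply(preselect(inp$ranking, 8), function(g)
    cv_accuracy(inp$ds, g, spec, fold = fold), numeric(1))
  expect_equal(vapply(opt$subsets, `[[`, numeric(1), "acc"),
               unname(sort(singles, decreasing = TRUE)[1:4]))
})

test_that("a perfectly separable pair stops the search at size 2", {
  sep <- separable_dataset(m_per_class = 10, n = 6, gap = 8)
  ds <- zscore_normalize(sep)
  r <- kwrst_pvalues(ds)
  spec <- classifier_spec("knn", seed = 5)
  opt <- hbsa(ds, r, search_config(p = 6, w = 5, acc_max = 1, depth = 6), spec)
  sizes <- vapply(opt$subsets, function(s) length(s$genes), 0L)
  # every gene separates here, so even singletons may reach 100%
  expect_lte(max(sizes), 2)
  expect_equal(max(vapply(opt$subsets, `[[`, numeric(1), "acc")), 1)
  expect_equal(cv_accuracy(ds, opt$subsets[[1]]$genes, spec,
                           fold = make_folds(ds$labels, 10, 5)), 1)
})

test_that("subset growth, evaluation budget and no-reevaluation invariants", {
  inp <- make_search_inputs(effect = 0.6, n_genes = 15)
  spec <- classifier_spec("knn", seed = 11)
  cfg <- search_config(p = 10, w = 6, acc_max = 1, depth = 4)
  opt <- suppressMessages(hbsa(inp$ds, inp$ranking, cfg, spec))
  expect_lte(opt$evaluations, cfg$depth * max(cfg$w, cfg$p) * cfg$p)
  # one trace entry per layer, ending at the final subset size
  expect_equal(length(opt$trace),
               length(opt$subsets[[1]]$genes))
  # a dip in the layer maximum is possible (adding a gene can hurt CV
  # accuracy) and is reported as a message rather than hidden
  expect_message(hbsa(inp$ds, inp$ranking, cfg, spec),
                 "accuracy decreased")
  # final subsets all have the final-layer size and are distinct
  sizes <- vapply(opt$subsets, function(s) length(s$genes), 0L)
  expect_equal(length(unique(sizes)), 1)
  keys <- vapply(opt$subsets, function(s) paste(s$genes, collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("same seed reproduces the run; distinct seeds give <= w subsets each", {
  inp <- make_search_inputs(effect = 1.2)
  spec <- classifier_spec("knn", seed = 1)
  cfg <- search_config(p = 8, w = 5, depth = 3)
  runs <- multi_run_hbsa(inp$ds, inp$ranking, cfg, spec, seeds = c(4, 4)) |>
    suppressWarnings()
  expect_identical(runs[[1]]$subsets, runs[[2]]$subsets)
  expect_warning(multi_run_hbsa(inp$ds, inp$ranking, cfg, spec,
                                seeds = c(4, 4)), "duplicate")
  runs5 <- multi_run_hbsa(inp$ds, inp$ranking, cfg, spec, seeds = 1:5)
  expect_true(all(vapply(runs5, function(r) length(r$subsets), 0L) <= 5))
})

test_that("strong planted genes recur in the union across 5 seeded runs", {
  inp <- make_search_inputs(effect = 3, n_genes = 20, n_informative = 2)
  cfg <- search_config(p = 10, w = 8, depth = 2)
  runs <- multi_run_hbsa(inp$ds, inp$ranking, cfg,
                         classifier_spec("knn"), seeds = 11:15)
  hits <- vapply(inp$truth, function(g)
    sum(vapply(runs, function(r) g %in% r$union_genes, TRUE)), 0L)
  expect_true(all(hits >= 4))
})

test_that("filter_subsets applies conjunctive clauses lazily", {
  subs <- list(list(genes = c("a", "b"), acc = 1.0, fullfold = NULL),
               list(genes = c("a", "c"), acc = 0.95, fullfold = NULL),
               list(genes = c("b", "c"), acc = 1.0, fullfold = NULL))
  opt <- structure(list(subsets = subs, union_genes = c("a", "b", "c"),
                        run_id = 1), class = "optimal_subsets")
  expect_equal(length(filter_subsets(opt, top_n = 300)$subsets), 3)
  kept <- filter_subsets(opt, tenfold_eq = 1.0)
  expect_equal(vapply(kept$subsets, function(s) paste(s$genes, collapse = ""),
                      ""), c("ab", "bc"))
  expect_warning(filter_subsets(opt, tenfold_min = 1.1), "no subsets")

  sep <- separable_dataset(m_per_class = 5, n = 3)
  spec <- classifier_spec("knn", knn_k = 3, cv_folds = 5)
  opt2 <- hbsa(zscore_normalize(sep), kwrst_pvalues(sep),
               search_config(p = 3, w = 3, depth = 2), spec)
  both <- filter_subsets(opt2, tenfold_eq = 1, fullfold_min = 0.99,
                         ds = zscore_normalize(sep), spec = spec)
  # conjunction equals intersecting the two one-clause filters
  a <- filter_subsets(opt2, tenfold_eq = 1)
  b <- filter_subsets(opt2, fullfold_min = 0.99, ds = zscore_normalize(sep),
                      spec = spec)
  key <- function(o) vapply(o$subsets, function(s)
    paste(s$genes, collapse = ","), "")
  expect_equal(key(both), intersect(key(a), key(b)))
})
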