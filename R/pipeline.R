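# Pipeline driver: wires simulate -> prefilter -> search -> ensemble/rank
# from one structured (YAML) configuration, with seeded reproducibility and
# sidecar metadata per artifact. A thin command-line wrapper lives at
# inst/cli/genebeam.

#' Run the analysis pipeline
#'
#' Executes the requested stages in flowchart order: `simulate` (or load
#' expression/labels TSVs), `prefilter`, `search`, `rank`, and optionally
#' `ensemble` when a test dataset is available. Every artifact written to
#' the output directory gets a sidecar `<file>.meta.json` recording the
#' seed and a hash of the configuration.
#'
#' The search stage sees only the training data: the test dataset (when
#' configured) is loaded for the ensemble stage after the search has
#' finished and is never passed to [hbsa()]. Supplying a test path inside
#' the `search` config block is refused.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure. Recognized top-level keys: `seed`, `out_dir`, `stages`
#'   (character vector), `data` (`expression`/`labels`/`test_expression`/
#'   `test_labels` paths), `simulate` ([sim_config()] arguments),
#'   `prefilter` (`p`), `classifier` ([classifier_spec()] arguments),
#'   `search` ([search_config()] arguments), `ensemble` (`mode`), `rank`
#'   (`ks`).
#' @return Invisibly, a list of the computed stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!is.null(config$search$test_expression) ||
      !is.null(config$search$test_labels))
    stop("test data must not enter the search stage; put test paths under 'data'")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("prefilter", "search", "rank")
  known <- c("simulate", "prefilter", "search", "ensemble", "rank")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  cfg_hash <- config_hash(config)
  emit <- function(path) {
    jsonlite::write_json(list(seed = seed, config_hash = cfg_hash,
                              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
    path
  }
  res <- list()

  if ("simulate" %in% stages) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    sim <- simulate_expression(do.call(sim_config, sim_args))
    res$simulate <- sim
    ds <- sim$dataset
    write_expression(ds, emit(file.path(out_dir, "expression.tsv")),
                     emit(file.path(out_dir, "labels.tsv")))
    utils::write.table(sim$truth, emit(file.path(out_dir, "truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ds <- read_expression(config$data$expression, config$data$labels)
  }
  ds <- zscore_normalize(ds)

  spec_args <- config$classifier %||% list()
  spec_args$seed <- spec_args$seed %||% seed
  spec <- do.call(classifier_spec, spec_args)

  ranking <- NULL
  if ("prefilter" %in% stages || "search" %in% stages) {
    ranking <- kwrst_pvalues(ds)
    res$prefilter <- ranking
    write_ranking(ranking, emit(file.path(out_dir, "ranking.tsv")),
                  top = config$prefilter$p %||% NULL)
  }

  opt <- NULL
  if ("search" %in% stages) {
    search_args <- config$search %||% list()
    search_args$p <- min(as.integer(search_args$p %||% 300L), ds$n)
    opt <- hbsa(ds, ranking, do.call(search_config, search_args), spec)
    res$search <- opt
    write_subsets(opt, emit(file.path(out_dir, "subsets.jsonl")))
  }

  if ("rank" %in% stages && !is.null(opt)) {
    ft <- gene_frequency(opt, ranking)
    res$rank <- ft
    write_frequency(ft, emit(file.path(out_dir, "frequency.tsv")))
  }

  if ("ensemble" %in% stages && !is.null(opt)) {
    if (is.null(config$data$test_expression))
      stop("ensemble stage needs data$test_expression / data$test_labels")
    test <- zscore_normalize(read_expression(config$data$test_expression,
                                             config$data$test_labels))
    kept <- shared_subsets(opt, test)
    ens <- ensemble_predict(train = ds, test = test, opt = kept, spec = spec,
                            mode = config$ensemble$mode %||% "unbiased")
    res$ensemble <- ens
    write_ensemble_report(ens, emit(file.path(out_dir, "ensemble.tsv")))
  }

  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}
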