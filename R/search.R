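# Beam search over gene subsets (heuristic breadth-first search).
#
# Layer i holds subsets of size i. Each layer scores the classification
# matrix CM with a_ij = Acc(Row[i] union Column[j]) over the p candidate
# genes, keeps the w best open nodes, and closes duplicates so no subset is
# ever evaluated twice. Closed/invalid cells carry a negative sentinel
# (never a literal 0, which could collide with a genuinely 0-accuracy open
# subset).

SENTINEL <- -1

#' Search configuration
#'
#' @param p Prefilter size: number of top-ranked candidate genes (default
#'   300).
#' @param w Beam width: number of top-ranked subsets kept per layer (at
#'   layer 1 the beam always holds all p singletons, whatever `w`).
#' @param acc_max Stopping accuracy threshold in (0, 1] (default 1: stop on
#'   a perfectly classifying subset).
#' @param depth Maximal subset size; the search stops at this layer if
#'   `acc_max` is never reached (default 15).
#' @param delta Optional plateau tolerance: stop when the layer-to-layer
#'   change in maximal accuracy is below `delta` (off by default).
#' @param tau Optional accuracy tolerance for the returned subsets: keep
#'   only final-layer subsets within `tau` of the best. `NULL` (default)
#'   keeps all final-layer top-w subsets.
#' @return A `search_config` list.
#' @export
search_config <- function(p = 300, w = 300, acc_max = 1, depth = 15,
                          delta = NULL, tau = NULL) {
  if (w < 1) stop("w must be >= 1")
  if (depth < 1) stop("depth must be >= 1")
  if (acc_max <= 0 || acc_max > 1) stop("acc_max must be in (0, 1]")
  if (!is.null(delta) && delta < 0) stop("delta must be >= 0")
  structure(list(p = as.integer(p), w = as.integer(w), acc_max = acc_max,
                 depth = as.integer(depth), delta = delta, tau = tau),
            class = "search_config")
}

# Accuracy-evaluation context: fixed fold partition per run; for knn, cached
# per-gene squared-distance matrices so a subset's distance matrix is a sum.
make_acc_context <- function(ds, cols, spec) {
  fold <- make_folds(ds$labels, spec$cv_folds, spec$seed)
  ctx <- list(ds = ds, cols = cols, spec = spec, fold = fold)
  if (spec$kind == "knn" && spec$normalize == "none") {
    ctx$gene_d2 <- lapply(cols, function(g) {
      x <- ds$values[, g]
      outer(x, x, "-")^2
    })
  }
  ctx
}

# Evaluate Acc for a subset given by indices into ctx$cols. d2 is the cached
# summed distance matrix for knn (NULL to compute from gene_d2).
acc_eval <- function(ctx, idx, d2 = NULL) {
  if (!is.null(ctx$gene_d2)) {
    if (is.null(d2)) d2 <- Reduce(`+`, ctx$gene_d2[idx])
    list(acc = knn_cv_from_d2(d2, ctx$ds$labels, ctx$fold, ctx$spec$knn_k),
         d2 = d2)
  } else {
    list(acc = cv_accuracy(ctx$ds, ctx$cols[idx], ctx$spec, fold = ctx$fold),
         d2 = NULL)
  }
}

subset_key <- function(idx) paste(idx, collapse = ",")

# Order candidates: accuracy descending, then sum of members' prefilter
# ranks ascending (a bias toward stronger marginal genes; candidate gene
# order in `cols` is the prefilter rank), then lexicographic gene tuple.
order_candidates <- function(accs, idx_list, cols) {
  ranksum <- vapply(idx_list, sum, numeric(1))
  lex <- vapply(idx_list, function(i) paste(cols[i], collapse = "\r"),
                character(1))
  order(-accs, ranksum, lex)
}

#' Expand the beam by one layer
#'
#' Computes the classification matrix over the current beam rows and the p
#' candidate genes: cell (i, j) scores Row\[i\] union Column\[j\] unless the
#' column gene is already in the row subset (no growth) or the union was
#' evaluated on another path (closed node); both get a negative sentinel and
#' are never expanded. The top `w` open cells become the next beam. On the
#' symmetric first layer the closed-node registry makes each unordered pair
#' score once, so only the matrix's lower triangle costs evaluations.
#'
#' @param state A `search_state` as built by [hbsa()].
#' @return The updated `search_state`; `state$exhausted` is `TRUE` when no
#'   open cell remained.
#' @export
hbsa_expand <- function(state) {
  ctx <- state$ctx
  w <- state$config$w
  p <- length(ctx$cols)
  cand_idx <- vector("list", length(state$rows) * p)
  cand_acc <- numeric(length(cand_idx))
  cand_d2 <- vector("list", length(cand_idx))
  nc <- 0L
  for (i in seq_along(state$rows)) {
    row <- state$rows[[i]]
    row_d2 <- state$row_d2[[i]]
    for (j in seq_len(p)) {
      if (j %in% row) next                       # no growth
      u <- sort(c(row, j))
      key <- subset_key(u)
      if (!is.null(state$seen[[key]])) next      # closed node
      state$seen[[key]] <- TRUE
      d2 <- if (!is.null(row_d2)) row_d2 + ctx$gene_d2[[j]] else NULL
      ev <- acc_eval(ctx, u, d2)
      state$evaluations <- state$evaluations + 1L
      nc <- nc + 1L
      cand_idx[[nc]] <- u
      cand_acc[nc] <- ev$acc
      cand_d2[[nc]] <- ev$d2
    }
  }
  if (nc == 0L) {
    state$exhausted <- TRUE
    return(state)
  }
  keep <- order_candidates(cand_acc[seq_len(nc)], cand_idx[seq_len(nc)],
                           ctx$cols)[seq_len(min(w, nc))]
  state$rows <- cand_idx[keep]
  state$row_accs <- cand_acc[seq_len(nc)][keep]
  state$row_d2 <- cand_d2[keep]
  layer_max <- max(cand_acc[seq_len(nc)])
  if (layer_max < state$trace[length(state$trace)])
    message(sprintf(
      "beam max accuracy decreased at layer %d: %.4f -> %.4f",
      length(state$trace) + 1L, state$trace[length(state$trace)], layer_max))
  state$trace <- c(state$trace, layer_max)
  state$exhausted <- FALSE
  state
}

#' Beam search for minimal high-accuracy gene subsets
#'
#' Seeds layer 1 with all p prefiltered candidate genes as singletons, then
#' repeatedly grows the beam one gene per layer via [hbsa_expand()]. The
#' search stops as soon as the layer's maximal cross-validated accuracy
#' reaches `config$acc_max`, when the layer index reaches `config$depth`,
#' when (if `config$delta` is set) the maximal accuracy plateaus, or when
#' the beam is exhausted. All final-layer top-w subsets are returned as the
#' optimal collection.
#'
#' The dataset is expected to be normalized (e.g. [zscore_normalize()])
#' before the search; because column z-scoring commutes with column
#' subsetting this equals z-scoring each restricted gene block at
#' evaluation time. Test data must never be passed to this function.
#'
#' @param ds Training [expression_dataset()].
#' @param ranking A `gene_ranking` from [kwrst_pvalues()] on `ds`.
#' @param config A [search_config()].
#' @param spec A [classifier_spec()]; `spec$seed` fixes the single CV
#'   partition used for every evaluation of the run.
#' @return An `optimal_subsets` object: list with `subsets` (each a list
#'   with `genes`, `acc`, `fullfold`), `union_genes`, `run_id` (the seed),
#'   `trace` (per-layer maximal accuracy), `evaluations`, `config`.
#' @export
hbsa <- function(ds, ranking, config, spec) {
  if (config$p > ds$n) stop("config$p exceeds the number of genes")
  cols <- preselect(ranking, config$p)
  ctx <- make_acc_context(ds, cols, spec)
  p <- length(cols)

  seen <- new.env(parent = emptyenv(), hash = TRUE)
  evals <- 0L
  sing_acc <- numeric(p)
  sing_d2 <- vector("list", p)
  for (j in seq_len(p)) {
    seen[[subset_key(j)]] <- TRUE
    ev <- acc_eval(ctx, j)
    evals <- evals + 1L
    sing_acc[j] <- ev$acc
    sing_d2[[j]] <- ev$d2
  }
  ord <- order_candidates(sing_acc, as.list(seq_len(p)), cols)
  # layer 1 keeps all p singletons in the beam, whatever w is
  state <- list(ctx = ctx, config = config, seen = seen,
                rows = as.list(ord), row_accs = sing_acc[ord],
                row_d2 = sing_d2[ord],
                trace = max(sing_acc), evaluations = evals,
                exhausted = FALSE)
  class(state) <- "search_state"

  layer <- 1L
  while (layer < config$depth &&
         state$trace[layer] < config$acc_max) {
    if (!is.null(config$delta) && layer >= 2L &&
        abs(state$trace[layer] - state$trace[layer - 1L]) < config$delta)
      break
    state <- hbsa_expand(state)
    if (state$exhausted) break
    layer <- layer + 1L
  }

  top <- seq_len(min(config$w, length(state$rows)))
  subs <- lapply(top, function(i) {
    list(genes = sort(cols[state$rows[[i]]]), acc = state$row_accs[i],
         fullfold = NULL)
  })
  if (!is.null(config$tau)) {
    best <- max(vapply(subs, `[[`, numeric(1), "acc"))
    subs <- Filter(function(s) s$acc >= best - config$tau, subs)
  }
  structure(list(subsets = subs,
                 union_genes = sort(unique(unlist(lapply(subs, `[[`, "genes")))),
                 run_id = spec$seed, trace = state$trace,
                 evaluations = state$evaluations, config = config),
            class = "optimal_subsets")
}

#' @export
print.optimal_subsets <- function(x, ...) {
  sizes <- vapply(x$subsets, function(s) length(s$genes), integer(1))
  cat("optimal_subsets: ", length(x$subsets), " subsets (sizes ",
      paste(unique(sizes), collapse = "/"), "), best acc ",
      format(max(vapply(x$subsets, `[[`, numeric(1), "acc")), digits = 4),
      ", ", x$evaluations, " evaluations\n", sep = "")
  invisible(x)
}

#' Repeated beam search over CV partitions
#'
#' Runs [hbsa()] once per seed, each run with an independent stratified CV
#' partition. Averaging the k-NN objective over partitions removes the
#' dependence on any single random fold division; five runs is the
#' conventional choice.
#'
#' @inheritParams hbsa
#' @param seeds Integer vector of run seeds (duplicates trigger a warning,
#'   not an error).
#' @return List of `optimal_subsets`, one per seed.
#' @export
multi_run_hbsa <- function(ds, ranking, config, spec, seeds) {
  if (anyDuplicated(seeds)) warning("duplicate seeds: runs will be identical")
  lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- as.integer(s)
    hbsa(ds, ranking, config, sp)
  })
}

#' Filter an optimal-subset collection
#'
#' Keeps the subsets satisfying a conjunction of accuracy clauses, in the
#' original order. Full-fold clauses trigger lazy [full_fold_cv()]
#' computation (which requires `ds` and `spec`).
#'
#' @param opt An `optimal_subsets` object.
#' @param tenfold_min,tenfold_eq Keep subsets with stored CV accuracy >= /
#'   == the given fraction.
#' @param fullfold_min,fullfold_eq Keep subsets with Full-fold mean >= / ==
#'   the given fraction.
#' @param top_n Keep at most the first `top_n` subsets (applied last).
#' @param ds,spec Dataset and classifier spec, required for the Full-fold
#'   clauses.
#' @return The filtered `optimal_subsets` (with `fullfold` fields populated
#'   where computed); empty results are returned with a warning.
#' @export
filter_subsets <- function(opt, tenfold_min = NULL, tenfold_eq = NULL,
                           fullfold_min = NULL, fullfold_eq = NULL,
                           top_n = NULL, ds = NULL, spec = NULL) {
  subs <- opt$subsets
  keep_acc <- function(s) {
    (is.null(tenfold_min) || s$acc >= tenfold_min) &&
      (is.null(tenfold_eq) || isTRUE(all.equal(s$acc, tenfold_eq)))
  }
  subs <- Filter(keep_acc, subs)
  if (!is.null(fullfold_min) || !is.null(fullfold_eq)) {
    if (is.null(ds) || is.null(spec))
      stop("Full-fold clauses need ds and spec")
    subs <- lapply(subs, function(s) {
      if (is.null(s$fullfold)) s$fullfold <- full_fold_cv(ds, s$genes, spec)
      s
    })
    subs <- Filter(function(s) {
      (is.null(fullfold_min) || s$fullfold$mean >= fullfold_min) &&
        (is.null(fullfold_eq) ||
           isTRUE(all.equal(s$fullfold$mean, fullfold_eq)))
    }, subs)
  }
  if (!is.null(top_n)) subs <- subs[seq_len(min(top_n, length(subs)))]
  if (!length(subs)) warning("no subsets satisfy the filter")
  out <- opt
  out$subsets <- subs
  out$union_genes <- sort(unique(unlist(lapply(subs, `[[`, "genes"))))
  out
}

#' Write optimal subsets as JSON lines
#'
#' One record per subset: `genes`, `size`, `tenfold_acc`, `fullfold_mean`,
#' `fullfold_std`, `run_id`.
#'
#' @param opt An `optimal_subsets` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_subsets <- function(opt, path) {
  lines <- vapply(opt$subsets, function(s) {
    jsonlite::toJSON(list(
      genes = s$genes, size = length(s$genes), tenfold_acc = s$acc,
      fullfold_mean = if (is.null(s$fullfold)) NA else s$fullfold$mean,
      fullfold_std = if (is.null(s$fullfold)) NA else s$fullfold$std,
      run_id = opt$run_id), auto_unbox = TRUE, na = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
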