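#' Greedy acquisition of the most promising molecules
#'
#' Returns the `batch` ids with the most negative predicted binding free
#' energy, excluding `exclude`; ties are broken lexicographically by id. If
#' fewer than `batch` candidates remain, all are returned with a warning.
#'
#' @param predictions named numeric vector (id -> predicted dG, kcal/mol).
#' @param batch number of molecules to acquire (>= 1).
#' @param exclude ids never to acquire (e.g. already computed).
#' @return character vector of acquired ids, most negative first.
#' @export
greedy_acquire <- function(predictions, batch, exclude = character(0)) {
  if (!.is_count(batch) || batch < 1) .stopf("batch must be a positive integer")
  stopifnot(!is.null(names(predictions)))
  avail <- predictions[!(names(predictions) %in% exclude)]
  if (length(avail) < batch) {
    .warnf("batch (%d) exceeds available candidates (%d); returning all",
           batch, length(avail))
    batch <- length(avail)
  }
  if (batch == 0) return(character(0))
  ord <- order(avail, names(avail))
  names(avail)[ord[seq_len(batch)]]
}

#' Active-learning configuration
#'
#' @param batch_schedule integer vector, molecules to acquire per iteration.
#' @param representations fingerprint kinds to consider in the AutoML grid.
#' @param algorithms model zoo (see [fit_model()]).
#' @param scope_values group label(s) eligible during restricted iterations
#'   (matched against the `groups` argument of [run_al_loop()]).
#' @param scope_until last restricted iteration (later iterations see the
#'   whole pool); default `length(batch_schedule) - 1`, mirroring a campaign
#'   that opens the second analog series only at the final iteration.
#' @param seed root RNG seed.
#' @return a list of class `al_config`.
#' @export
al_config <- function(batch_schedule,
                      representations = c("ecfp6_2048", "path7_2048"),
                      algorithms = c("linear_regression", "gp_tanimoto"),
                      scope_values = NULL,
                      scope_until = length(batch_schedule) - 1L,
                      seed = 1L) {
  stopifnot(length(batch_schedule) >= 1, all(batch_schedule >= 1))
  structure(list(batch_schedule = as.integer(batch_schedule),
                 representations = representations,
                 algorithms = algorithms,
                 scope_values = scope_values,
                 scope_until = as.integer(scope_until),
                 seed = as.integer(seed)),
            class = "al_config")
}

#' Run the AutoML active-learning loop
#'
#' Per iteration: select the best (representation, algorithm) cell by inner
#' 5-fold tuning + LOOCV R-squared, refit on all labels, predict the
#' not-yet-labeled pool, acquire the batch with the most negative predictions,
#' query the oracle and append the new labels. When a scope column is
#' configured, training and screening are restricted to the scoped subset
#' until `scope_until`, after which the whole pool participates. The loop
#' never queries the oracle twice for one id; oracle failures (NA) are logged
#' and not retried.
#'
#' @param pool a `mol_library` (or data.frame with `id`, `smiles`).
#' @param oracle function taking a character vector of ids and returning a
#'   named numeric vector of absolute binding free energies (kcal/mol); NA
#'   marks a failed computation.
#' @param init_train named numeric vector of pre-AL labels (id -> dG).
#' @param config an [al_config()].
#' @param features optional precomputed named list of fingerprint matrices
#'   covering the pool and the pre-AL molecules (computed on demand from the
#'   pool otherwise; pre-AL ids absent from a matrix are then dropped from
#'   training for that representation).
#' @param groups optional named character vector (id -> group label) covering
#'   pool and training ids, used with the config's scope settings; ids without
#'   a group are always in scope.
#' @return an object of class `al_state`: list with `train` (data.frame id,
#'   dg_abs, iteration_added), `history` (per-iteration model spec, acquired
#'   ids, labels), `failed_ids`.
#' @export
run_al_loop <- function(pool, oracle, init_train, config, features = NULL,
                        groups = NULL) {
  stopifnot(inherits(config, "al_config"), length(init_train) > 0,
            !is.null(names(init_train)))
  if (is.null(features)) {
    features <- lapply(stats::setNames(nm = config$representations),
                       function(kind) featurize(pool, kind, seed = config$seed))
  }
  in_scope <- function(ids, it) {
    if (is.null(groups) || is.null(config$scope_values) ||
        it > config$scope_until) return(rep(TRUE, length(ids)))
    g <- groups[ids]
    is.na(g) | g %in% config$scope_values
  }
  train <- data.frame(id = names(init_train), dg_abs = unname(init_train),
                      iteration_added = "pre_AL", stringsAsFactors = FALSE)
  failed <- character(0)
  history <- list()
  for (it in seq_along(config$batch_schedule)) {
    scoped_pool <- pool$id[in_scope(pool$id, it)]
    train_it <- train[in_scope(train$id, it), , drop = FALSE]
    if (nrow(train_it) < 3) train_it <- train
    ## training ids must be featurized in every considered representation
    have <- Reduce(intersect, lapply(features, rownames))
    train_it <- train_it[train_it$id %in% have, , drop = FALSE]
    labels <- stats::setNames(train_it$dg_abs, train_it$id)
    spec <- automl_select(features, labels, algorithms = config$algorithms,
                          seed = config$seed + it)
    Xp <- features[[spec$representation]]
    cand_ids <- setdiff(intersect(scoped_pool, rownames(Xp)),
                        c(train$id, failed))
    preds <- stats::setNames(
      stats::predict(spec$model, Xp[cand_ids, , drop = FALSE]), cand_ids)
    acquired <- greedy_acquire(preds, min(config$batch_schedule[it], length(preds)))
    new_labels <- oracle(acquired)
    if (is.null(names(new_labels))) names(new_labels) <- acquired
    ok <- !is.na(new_labels)
    if (any(!ok)) failed <- c(failed, names(new_labels)[!ok])
    iter_tag <- paste0("AL_", it)
    if (any(ok)) {
      stopifnot(!any(names(new_labels)[ok] %in% train$id))  # never re-query
      train <- rbind(train, data.frame(id = names(new_labels)[ok],
                                       dg_abs = unname(new_labels)[ok],
                                       iteration_added = iter_tag,
                                       stringsAsFactors = FALSE))
    }
    history[[iter_tag]] <- list(
      iteration = it,
      model = list(representation = spec$representation,
                   algorithm = spec$algorithm,
                   hyperparameters = spec$hyperparameters,
                   cv_r2 = spec$cv_r2),
      acquired = acquired,
      labels = new_labels,
      n_train = length(labels),
      scope = if (length(scoped_pool) < nrow(pool)) "restricted" else "full"
    )
  }
  structure(list(train = train, history = history, failed_ids = failed,
                 config = config),
            class = "al_state")
}

#' @export
print.al_state <- function(x, ...) {
  cat(sprintf("<al_state> %d iterations, %d labeled molecules (%d failed)\n",
              length(x$history), nrow(x$train), length(x$failed_ids)))
  invisible(x)
}

#' Budgeted selection of experimental candidates
#'
#' Picks `greedy_n` molecules with the most negative scores, then `diverse_n`
#' additional molecules from those passing `diverse_filter` (by default:
#' negative score, not already chosen) via max-min Tanimoto diversity picking
#' seeded with the most negative eligible molecule. If too few eligible
#' diverse candidates exist the remainder is filled greedily, with a warning.
#'
#' @param scores named numeric vector (id -> computed dG, kcal/mol).
#' @param features fingerprint matrix covering at least the eligible ids.
#' @param budget_total total selection budget (default 75).
#' @param greedy_n purely greedy picks (default 70).
#' @param diverse_n diversity-biased picks (default 5).
#' @param diverse_filter predicate `function(ids, scores)` returning the
#'   eligible subset of ids for the diversity stage.
#' @return character vector of `budget_total` ids.
#' @export
select_candidates <- function(scores, features, budget_total = 75L,
                              greedy_n = 70L, diverse_n = 5L,
                              diverse_filter = NULL) {
  if (greedy_n + diverse_n != budget_total)
    .stopf("greedy_n + diverse_n must equal budget_total")
  stopifnot(!is.null(names(scores)))
  greedy <- if (greedy_n > 0) greedy_acquire(scores, min(greedy_n, length(scores)))
            else character(0)
  if (is.null(diverse_filter))
    diverse_filter <- function(ids, sc) ids[sc[ids] < 0]
  eligible <- setdiff(diverse_filter(names(scores), scores), greedy)
  chosen <- character(0)
  if (length(eligible) > 0 && diverse_n > 0) {
    elig_feat <- features[intersect(eligible, rownames(features)), , drop = FALSE]
    eligible <- rownames(elig_feat)
    ## seed with the most negative eligible molecule
    seed_id <- greedy_acquire(scores[eligible], 1)
    chosen <- seed_id
    while (length(chosen) < diverse_n && length(setdiff(eligible, chosen)) > 0) {
      rest <- setdiff(eligible, chosen)
      d <- .tanimoto_matrix(elig_feat[rest, , drop = FALSE],
                            elig_feat[chosen, , drop = FALSE])
      min_d <- apply(d, 1, min)
      ord <- order(-min_d, rest)
      chosen <- c(chosen, rest[ord[1]])
    }
  }
  if (length(chosen) < diverse_n) {
    .warnf("only %d eligible diverse candidates; filling greedily",
           length(chosen))
    filler <- greedy_acquire(scores, budget_total, exclude = c(greedy, chosen))
    chosen <- c(chosen, filler[seq_len(min(diverse_n - length(chosen),
                                           length(filler)))])
  }
  c(greedy, chosen)
}

#' 2D chemical-space projection (t-SNE)
#'
#' Exact (O(n^2)) t-SNE embedding of a fingerprint matrix using Tanimoto
#' dissimilarities, deterministic for a fixed seed. Used for reporting only.
#'
#' @param features binary fingerprint matrix (rows = molecules).
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity; requires `nrow(features) > 3 * perplexity`.
#' @param n_iter gradient-descent iterations.
#' @return `n x 2` coordinate matrix with the input rownames.
#' @export
project_chemical_space <- function(features, seed = 1L, perplexity = 30,
                                   n_iter = 400L) {
  n <- nrow(features)
  if (n <= 3 * perplexity)
    .stopf("perplexity %.0f too large for %d molecules (need n > 3*perplexity)",
           perplexity, n)
  D <- .tanimoto_matrix(features, features)
  Y <- .tsne(D, perplexity = perplexity, seed = seed, n_iter = n_iter)
  rownames(Y) <- rownames(features)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}
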