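## Small deterministic fingerprint-like matrices keep these tests independent
## of the chemistry layer.
fake_fp <- function(n, p = 32, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n * p, 1, 0.4), n, p)
  m[rowSums(m) == 0, 1] <- 1L
  rownames(m) <- sprintf("f%03d", seq_len(n))
  storage.mode(m) <- "integer"
  m
}

test_that("LOOCV closed form equals an explicit refit loop for kernel models", {
  X <- fake_fp(9)
  set.seed(2)
  y <- stats::setNames(rnorm(9, -7), rownames(X))
  for (alg in c("gp_tanimoto", "linear_regression")) {
    spec <- list(algorithm = alg, hyperparameters = alfe:::.hyper_grid(alg)[[1]])
    fast <- alfe:::.loocv_predictions(spec, X, unname(y))
    slow <- vapply(1:9, function(i) {
      fit <- fit_model(alg, X[-i, , drop = FALSE], unname(y)[-i],
                       spec$hyperparameters)
      predict(fit, X[i, , drop = FALSE])
    }, numeric(1))
    expect_equal(fast, slow, tolerance = 1e-7)
  }
})

test_that("LOOCV R-squared grades models as expected", {
  # fewer features than training points: the small-ridge linear model recovers
  # the exact coefficients, so held-out predictions are (numerically) perfect
  X <- fake_fp(20, p = 8)
  y_lin <- -5 - 0.3 * rowSums(X)
  r2 <- loocv_r2(list(algorithm = "linear_regression",
                      hyperparameters = list(lambda = 1e-8)), X, y_lin)
  expect_gt(r2, 0.999)
  # heavy shrinkage makes a near-constant predictor: R^2 <= ~0
  r2_const <- loocv_r2(list(algorithm = "linear_regression",
                            hyperparameters = list(lambda = 1e8)), X, y_lin)
  expect_lte(r2_const, 0.05)
  # zero label variance: -Inf sentinel and a warning
  expect_warning(
    r2_flat <- loocv_r2(list(algorithm = "linear_regression",
                             hyperparameters = list(lambda = 1)),
                        X, rep(-6, 20)), "variance")
  expect_identical(r2_flat, -Inf)
  expect_error(loocv_r2(list(algorithm = "gp_tanimoto",
                             hyperparameters = list(noise = 1e-2)),
                        X[1:2, ], y_lin[1:2]), "at least 3")
})

test_that("random forest LOOCV equals the manual leave-one-out loop", {
  X <- fake_fp(5, p = 8, seed = 3)
  set.seed(4)
  y <- rnorm(5, -6)
  spec <- list(algorithm = "random_forest",
               hyperparameters = list(ntree = 100, nodesize = 1))
  fast <- alfe:::.loocv_predictions(spec, X, y, seed = 10)
  manual <- vapply(1:5, function(i) {
    fit <- fit_model("random_forest", X[-i, , drop = FALSE], y[-i],
                     spec$hyperparameters, seed = 10 + i)
    unname(predict(fit$model, X[i, , drop = FALSE]))
  }, numeric(1))
  expect_equal(fast, manual)
})

test_that("automl picks the right model family for constructed labels", {
  X <- fake_fp(30, p = 8, seed = 5)
  feats <- list(fp = X)
  # a single-cell grid returns that cell
  y <- stats::setNames(-5 - 0.3 * rowSums(X), rownames(X))
  one <- automl_select(feats, y, algorithms = "gp_tanimoto", seed = 1)
  expect_equal(one$algorithm, "gp_tanimoto")
  expect_equal(one$representation, "fp")
  # labels linear in the bit count: the linear cell wins with high R^2
  lin <- automl_select(feats, y,
                       algorithms = c("linear_regression", "gp_tanimoto"),
                       seed = 1)
  expect_gte(lin$cv_r2, 0.9)
  # determinism
  lin2 <- automl_select(feats, y,
                        algorithms = c("linear_regression", "gp_tanimoto"),
                        seed = 1)
  expect_equal(lin$algorithm, lin2$algorithm)
  expect_equal(lin$cv_r2, lin2$cv_r2)
  expect_equal(predict(lin$model, X), predict(lin2$model, X))
})

test_that("labels drawn from a Tanimoto-kernel GP favor the GP cell", {
  X <- fake_fp(36, seed = 6)
  K <- alfe:::.tanimoto_kernel(X) + diag(1e-6, 36)
  L <- t(chol(K))
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    y <- stats::setNames(as.numeric(L %*% rnorm(36)) - 6, rownames(X))
    best <- automl_select(list(fp = X), y,
                          algorithms = c("linear_regression", "gp_tanimoto"),
                          seed = s)
    wins <- wins + (best$algorithm == "gp_tanimoto")
  }
  expect_gte(wins, 16)  # >= 80% of seeds
})

test_that("greedy acquisition ranks by predicted affinity with stable ties", {
  preds <- c(a = -3, b = -5, c = -1)
  expect_equal(greedy_acquire(preds, 2), c("b", "a"))
  expect_equal(greedy_acquire(preds, 2, exclude = "b"), c("a", "c"))
  expect_warning(all3 <- greedy_acquire(preds, 5), "exceeds")
  expect_equal(all3, c("b", "a", "c"))
  # ties break lexicographically by id
  expect_equal(greedy_acquire(c(z = -2, y = -2, x = -2), 2), c("x", "y"))
  # brute-force full sort oracle on random predictions
  set.seed(7)
  p <- stats::setNames(rnorm(100), sprintf("m%03d", sample(100)))
  expect_equal(greedy_acquire(p, 10), names(sort(p))[1:10])
  expect_error(greedy_acquire(p, 0), "positive")
})

test_that("the AL loop respects budgets, scope, and never re-queries", {
  camp <- small_campaign(noise_sd = 0)
  lib <- camp$library
  truth <- affinity_oracle(lib, camp$spec, noiseless = TRUE)
  feats <- list(ecfp6_2048 = featurize(lib, "ecfp6_2048"))
  init <- truth[lib$id[1:4]]
  pool <- lib[-(1:4), , drop = FALSE]
  # constant oracle: pure tie-break order, loop completes
  cfgc <- al_config(c(2L, 2L), representations = "ecfp6_2048",
                    algorithms = "linear_regression", seed = 3)
  st_const <- run_al_loop(pool, function(ids) stats::setNames(rep(-5, length(ids)), ids),
                          init, cfgc, features = feats)
  expect_equal(nrow(st_const$train), 4 + 4)
  # batch schedule summing to pool size: every molecule labeled exactly once
  n_pool <- nrow(pool)
  cfg_all <- al_config(c(3L, n_pool - 3L), representations = "ecfp6_2048",
                       algorithms = "linear_regression", seed = 3)
  st_all <- run_al_loop(pool, function(ids) truth[ids], init, cfg_all,
                        features = feats)
  expect_setequal(st_all$train$id, c(names(init), pool$id))
  expect_false(anyDuplicated(st_all$train$id) > 0)
  # acquired ids never repeat across iterations
  acq <- unlist(lapply(st_all$history, `[[`, "acquired"))
  expect_false(anyDuplicated(acq) > 0)
  # oracle failures are logged, not retried
  failing <- function(ids) {
    out <- truth[ids]
    out[1] <- NA
    out
  }
  st_fail <- run_al_loop(pool, failing, init,
                         al_config(c(2L, 2L), representations = "ecfp6_2048",
                                   algorithms = "linear_regression", seed = 3),
                         features = feats)
  expect_length(st_fail$failed_ids, 2)
  expect_false(any(st_fail$failed_ids %in% st_fail$train$id))
})

test_that("scope restriction keeps early iterations inside one series", {
  camp <- small_campaign(noise_sd = 0)
  lib <- camp$library
  truth <- affinity_oracle(lib, camp$spec, noiseless = TRUE)
  feats <- list(ecfp6_2048 = featurize(lib, "ecfp6_2048"))
  groups <- stats::setNames(rep(c("hit1", "hit2"), length.out = nrow(lib)), lib$id)
  init <- truth[lib$id[1:6]]
  pool <- lib[-(1:6), , drop = FALSE]
  cfg <- al_config(c(4L, 4L), representations = "ecfp6_2048",
                   algorithms = "linear_regression",
                   scope_values = "hit1", scope_until = 1L, seed = 5)
  st <- run_al_loop(pool, function(ids) truth[ids], init, cfg,
                    features = feats, groups = groups)
  it1 <- st$history[[1]]$acquired
  expect_true(all(groups[it1] == "hit1"))
  expect_equal(st$history[[1]]$scope, "restricted")
  expect_equal(st$history[[2]]$scope, "full")
})

test_that("candidate selection combines greedy and diversity picks", {
  n <- 80
  X <- fake_fp(n, seed = 8)
  set.seed(9)
  scores <- stats::setNames(runif(n, -9, -1), rownames(X))
  sel <- select_candidates(scores, X, budget_total = 75L, greedy_n = 70L,
                           diverse_n = 5L)
  expect_length(sel, 75)
  expect_false(anyDuplicated(sel) > 0)
  expect_equal(sel[1:70], names(sort(scores))[1:70])
  expect_error(select_candidates(scores, X, 75L, 60L, 5L), "must equal")

  # two well-separated clusters: diversity alternates between them
  Xc <- rbind(matrix(rep(c(rep(1L, 16), rep(0L, 16)), 10), 10, byrow = TRUE),
              matrix(rep(c(rep(0L, 16), rep(1L, 16)), 10), 10, byrow = TRUE))
  # small within-cluster variation so ids are distinguishable
  set.seed(10)
  flip <- matrix(rbinom(20 * 32, 1, 0.05), 20, 32)
  Xc <- (Xc + flip) %% 2L
  storage.mode(Xc) <- "integer"
  rownames(Xc) <- sprintf("c%02d", 1:20)
  sc <- stats::setNames(seq(-5, -3, length.out = 20), rownames(Xc))
  pick <- select_candidates(sc, Xc, budget_total = 4L, greedy_n = 0L,
                            diverse_n = 4L,
                            diverse_filter = function(ids, s) ids)
  cluster_of <- rep(1:2, each = 10)
  expect_equal(cluster_of[match(pick[1:2], rownames(Xc))], c(1, 2))

  # all-identical fingerprints: diversity reduces to greedy order
  Xs <- matrix(1L, 10, 8, dimnames = list(sprintf("s%02d", 1:10), NULL))
  ss <- stats::setNames(seq(-9, -1, length.out = 10), rownames(Xs))
  pick2 <- select_candidates(ss, Xs, budget_total = 4L, greedy_n = 2L,
                             diverse_n = 2L,
                             diverse_filter = function(ids, s) ids)
  expect_equal(pick2[1:2], names(sort(ss))[1:2])
  expect_equal(pick2[3], names(sort(ss))[3])  # max-min seeds with most negative
})

test_that("chemical-space projection is deterministic and separates clusters", {
  n <- 120
  half <- n / 2
  set.seed(11)
  A <- cbind(matrix(rbinom(half * 20, 1, 0.8), half), matrix(0L, half, 20))
  B <- cbind(matrix(0L, half, 20), matrix(rbinom(half * 20, 1, 0.8), half))
  X <- rbind(A, B)
  storage.mode(X) <- "integer"
  rownames(X) <- sprintf("m%03d", 1:n)
  emb <- project_chemical_space(X, seed = 3, perplexity = 15)
  expect_equal(dim(emb), c(n, 2))
  expect_identical(emb, project_chemical_space(X, seed = 3, perplexity = 15))
  # mean silhouette of the true cluster labels on the embedding
  lab <- rep(1:2, each = half)
  D <- as.matrix(dist(emb))
  sil <- vapply(1:n, function(i) {
    same <- which(lab == lab[i] & seq_len(n) != i)
    a <- mean(D[i, same])
    b <- mean(D[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(project_chemical_space(X, perplexity = 50), "perplexity")
})
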