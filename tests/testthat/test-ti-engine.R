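test_that("the Gauss-Legendre schedule is exact for its polynomial degree", {
  for (n in c(3, 5, 9)) {
    sched <- gauss_legendre_schedule(n)
    expect_equal(sum(sched$weights), 1, tolerance = 1e-12)
    expect_true(all(diff(sched$nodes) > 0))
    # symmetry about 0.5
    expect_equal(sched$nodes + rev(sched$nodes), rep(1, n), tolerance = 1e-12)
    # exact for monomials of degree <= 2n - 1
    for (d in c(0, 1, n, 2 * n - 1)) {
      expect_equal(sum(sched$weights * sched$nodes^d), 1 / (d + 1),
                   tolerance = 1e-12)
    }
    # one degree above breaks exactness
    expect_gt(abs(sum(sched$weights * sched$nodes^(2 * n)) - 1 / (2 * n + 1)),
              1e-13)
  }
  expect_equal(gauss_legendre_schedule(9)$nodes[5], 0.5)
  expect_error(gauss_legendre_schedule(0), "positive")
})

test_that("statistical inefficiency tracks AR(1) theory", {
  # g ~ (1 + phi) / (1 - phi) ~ 2 tau + 1
  set.seed(1)
  tau <- 20
  phi <- exp(-1 / tau)
  x <- as.numeric(stats::filter(rnorm(10000, 0, sqrt(1 - phi^2)), phi,
                                method = "recursive"))
  g <- statistical_inefficiency(x)
  expect_gt(g, 25); expect_lt(g, 60)  # theory ~ 41
  expect_equal(statistical_inefficiency(rep(3, 100)), 1)
})

test_that("equilibration detection maximizes effective sample size", {
  # iid noise: no transient, g near 1
  set.seed(2)
  eq <- detect_equilibration(rnorm(5000))
  expect_lte(eq$t0, 5000 / 49)  # within grid resolution of zero
  expect_lt(eq$g, 1.5)
  # constant series: defined degenerate behavior
  expect_equal(detect_equilibration(rep(2, 100)), list(t0 = 0L, g = 1, n_eff = 100))
  expect_error(detect_equilibration(rnorm(5)), "at least 10")
})

test_that("equilibration detection matches an exhaustive oracle over all t0", {
  # independent oracle: stats::acf-based inefficiency, full scan of every t0
  oracle_g <- function(x) {
    n <- length(x)
    if (stats::var(x) == 0) return(1)
    rho <- stats::acf(x, lag.max = n - 1, plot = FALSE)$acf[-1]
    neg <- which(rho <= 0)
    stop_at <- if (length(neg)) neg[1] - 1 else length(rho)
    if (stop_at == 0) return(1)
    max(1, 1 + 2 * sum((1 - seq_len(stop_at) / n) * rho[seq_len(stop_at)]))
  }
  set.seed(3)
  for (trial in 1:5) {
    n <- 200
    x <- 5 * exp(-(1:n) / 15) + rnorm(n)
    eq <- detect_equilibration(x, n_grid = n)  # full grid
    neff <- sapply(0:(n - 10), function(t0) (n - t0) / oracle_g(x[(t0 + 1):n]))
    expect_equal(eq$t0, which.max(neff) - 1L)
    expect_equal(eq$n_eff, max(neff), tolerance = 1e-8)
  }
})

test_that("decorrelated subsampling thins by ceiling(g)", {
  expect_equal(subsample_decorrelated(1:50, 0, 1), 1:50)
  expect_equal(subsample_decorrelated(1:100, 0, 10), seq(1, 100, by = 10))
  # 23 post-t0 samples at g = 2.3: stride 3 -> 8 values
  expect_length(subsample_decorrelated(1:23, 0, 2.3), 8)
  expect_error(subsample_decorrelated(1:10, 10, 1), "smaller")
})

test_that("Jensen-Shannon distance matches the discrete definition", {
  # p = (1, 0) vs q = (1/2, 1/2): distance sqrt(0.311278) = 0.557922
  expect_equal(sqrt(js_divergence(c(1, 0), c(0.5, 0.5))), 0.557922,
               tolerance = 1e-5)
  # the histogram route reproduces it from raw samples
  expect_equal(js_distance(c(0, 0), c(0, 1), n_bins = 2), 0.557922,
               tolerance = 1e-5)
  expect_equal(js_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  # fully disjoint supports: distance 1 under the base-2 convention
  expect_equal(js_distance(rnorm(100), rnorm(100) + 100, n_bins = 10), 1)
  expect_error(js_distance(1:5, 1:5, n_bins = 1), "n_bins")
  # symmetry and boundedness on random inputs
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(200); b <- rnorm(200, mean = runif(1, 0, 3))
    expect_equal(js_distance(a, b), js_distance(b, a))
    d <- js_distance(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("stationary windows converge, drifting windows do not", {
  set.seed(5)
  conv <- sapply(1:20, function(s) {
    set.seed(s)
    isTRUE(as.logical(window_converged(rnorm(10000))))
  })
  expect_gte(sum(conv), 18)
  # steady drift separating the halves by ~5 sigma survives any truncation
  drift <- seq(0, 10, length.out = 2000) + rnorm(2000)
  expect_false(as.logical(window_converged(drift)))
  # criterion 1.0 accepts any nondegenerate input
  expect_true(as.logical(window_converged(drift, criterion = 1.0)))
})

test_that("replicate pooling shrinks the standard error", {
  mk <- function(seed) {
    set.seed(seed)
    gradient_series(rnorm(2000, -3, 1), leg = "complex", lambda_index = 1)
  }
  single <- combine_replicates(list(mk(1)))
  # single replicate equals the per-window estimate
  eq <- detect_equilibration(mk(1))
  dec <- subsample_decorrelated(mk(1), eq$t0, eq$g)
  expect_equal(single$mean, mean(dec))
  expect_equal(single$stderr, sd(dec) / sqrt(length(dec)))
  # two statistically identical replicates: stderr ratio near 1/sqrt(2)
  ratios <- sapply(1:50, function(s) {
    one <- combine_replicates(list(mk(s)))
    two <- combine_replicates(list(mk(s), mk(s + 1000)))
    two$stderr / one$stderr
  })
  expect_gt(median(ratios), 0.6)
  expect_lt(median(ratios), 0.85)
  # pooling two near-noiseless replicates with means 0 and 2 gives ~1
  a <- gradient_series(rnorm(1000, 0, 1e-6), lambda_index = 2)
  b <- gradient_series(rnorm(1000, 2, 1e-6), lambda_index = 2)
  expect_equal(combine_replicates(list(a, b))$mean, 1, tolerance = 1e-3)
  expect_error(combine_replicates(list()), "nonempty")
  expect_error(combine_replicates(list(mk(1),
    gradient_series(1:20, leg = "solvent", lambda_index = 1))), "share")
})

test_that("the extension policy accepts, extends, then gives up at the cap", {
  sched <- gauss_legendre_schedule(9)
  quiet <- gradient_series(rnorm(2500, -2, 1e-8), dt = 0.001)
  w_ok <- combine_replicates(list(quiet))
  expect_equal(extend_policy(w_ok, quiet, max_total = 5)$decision, "accept")
  drift <- gradient_series(seq(0, 10, length.out = 1250) + rnorm(1250),
                           dt = 0.002)  # 2.5 ns total
  w_bad <- combine_replicates(list(drift))
  d <- extend_policy(w_bad, drift, max_total = 5.0)
  expect_equal(d$decision, "extend")
  expect_equal(d$requested_ns, 0.5)
  expect_equal(extend_policy(w_bad, drift, max_total = 2.5)$decision, "give_up")
})

test_that("the window protocol never exceeds the budget and accepts only converged", {
  set.seed(6)
  phi <- exp(-1 / 3)
  mk_sampler <- function(drifting) {
    total <- 0
    function(n) {
      total <<- total + n
      base <- as.numeric(stats::filter(rnorm(n, 0, 1.5 * sqrt(1 - phi^2)), phi,
                                       method = "recursive"))
      if (drifting) base + seq(total - n + 1, total) * 0.005 else base - 2
    }
  }
  for (drifting in c(FALSE, TRUE)) {
    est <- run_window_protocol(mk_sampler(drifting), dt = 0.001, max_total = 4.0)
    expect_lte(est$total_time, 4.0)
    trace <- attr(est, "decision_trace")
    if (trace[length(trace)] == "accept") expect_true(est$converged)
    if (drifting) expect_gte(attr(est, "n_extensions"), 1)
  }
})

test_that("leg integration reproduces analytic integrals", {
  sched <- gauss_legendre_schedule(9)
  expect_equal(integrate_leg(rep(-4.2, 9), sched)$dg, -4.2, tolerance = 1e-12)
  expect_equal(integrate_leg(sched$nodes, sched)$dg, 0.5, tolerance = 1e-12)
  f <- 3 * sched$nodes^2 - 1  # integral over [0,1] is zero
  expect_equal(integrate_leg(f, sched)$dg, 0, tolerance = 1e-12)
  se <- integrate_leg(rep(0, 9), sched, rep(1, 9))$stderr
  expect_equal(se, sqrt(sum(sched$weights^2)))
  expect_error(integrate_leg(1:5, sched), "match")
})

test_that("rbfe assembly subtracts legs and propagates convergence flags", {
  sched <- gauss_legendre_schedule(9)
  mk_leg <- function(level, seed) {
    set.seed(seed)
    lapply(1:9, function(i)
      gradient_series(rnorm(1000, level, 1e-6), lambda_index = i))
  }
  res0 <- compute_rbfe(mk_leg(-1, 1), mk_leg(-1, 1), sched)
  expect_equal(res0$ddg, 0, tolerance = 1e-7)
  res <- compute_rbfe(mk_leg(-3, 2), mk_leg(-1, 3), sched)
  expect_equal(res$ddg, -2, tolerance = 1e-6)
  expect_equal(res$ddg, res$dg_complex - res$dg_solvent, tolerance = 1e-12)
  expect_error(compute_rbfe(mk_leg(-3, 2)[1:8], mk_leg(-1, 3), sched), "windows")
})

test_that("a constructed transformation is recovered within its uncertainty", {
  sched <- gauss_legendre_schedule(9)
  spec <- gradient_profile_spec(c(complex = -3.0, solvent = -1.3),
                                transient_amplitude = 7.5, seed = 99)
  tr <- synth_transformation(spec, sched)
  expect_equal(tr$truth, -1.7)
  res <- compute_rbfe(tr$complex, tr$solvent, sched)
  expect_lt(abs(res$ddg - tr$truth), 3 * res$ddg_stderr)
})

test_that("gradient series round-trip through the long csv format", {
  sched <- gauss_legendre_schedule(3)
  spec <- gradient_profile_spec(c(complex = -2, solvent = -1), seed = 8)
  ser <- c(synth_gradient_series(spec, sched, "complex", n_samples = 50),
           synth_gradient_series(spec, sched, "solvent", n_samples = 50))
  path <- tempfile(fileext = ".csv")
  write_gradient_series(ser, path)
  back <- read_gradient_series(path)
  expect_length(back, 6)
  expect_equal(back[[1]]$samples, ser[[1]]$samples)
  expect_equal(back[[4]]$leg, "solvent")
})
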