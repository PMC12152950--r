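#' Gauss-Legendre lambda schedule on [0, 1]
#'
#' Nodes and weights of the n-point Gauss-Legendre quadrature mapped affinely
#' from `[-1, 1]` to the alchemical coupling interval `[0, 1]`. The 9-point
#' rule is the workflow default; it integrates polynomials up to degree 17
#' exactly, and its weights sum to 1.
#'
#' @param n number of lambda windows (default 9).
#' @return an object of class `lambda_schedule`: list with `nodes`, `weights`.
#' @export
gauss_legendre_schedule <- function(n = 9L) {
  if (!.is_count(n) || n < 1) .stopf("n must be a positive integer")
  gl <- pracma::gaussLegendre(as.integer(n), 0, 1)
  structure(list(nodes = gl$x, weights = gl$w), class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf("<lambda_schedule> %d-point Gauss-Legendre on [0,1]\n",
              length(x$nodes)))
  print(data.frame(lambda = x$nodes, weight = x$weights))
  invisible(x)
}

#' Gradient time series for one lambda window
#'
#' The atom of the TI engine: ordered dU/dlambda samples (kcal/mol) for one
#' lambda window of one leg (complex or solvent), with the sampling interval
#' in nanoseconds.
#'
#' @param samples numeric vector of dU/dlambda samples (kcal/mol).
#' @param leg `"complex"` or `"solvent"`.
#' @param lambda_index integer window index.
#' @param dt time per sample (ns).
#' @param replicate_id integer replicate label.
#' @return an object of class `gradient_series`.
#' @export
gradient_series <- function(samples, leg = c("complex", "solvent"),
                            lambda_index = 1L, dt = 0.001, replicate_id = 1L) {
  leg <- match.arg(leg)
  samples <- as.numeric(samples)
  if (length(samples) == 0) .stopf("samples must be nonempty")
  if (!(dt > 0)) .stopf("dt must be positive")
  structure(list(samples = samples, leg = leg,
                 lambda_index = as.integer(lambda_index),
                 dt = dt, replicate_id = as.integer(replicate_id)),
            class = "gradient_series")
}

.series_samples <- function(x) if (inherits(x, "gradient_series")) x$samples else as.numeric(x)

#' Statistical inefficiency of a time series
#'
#' `g = 1 + 2 * sum_t (1 - t/N) * acf(t)`, accumulated until the first
#' non-positive autocorrelation value. A constant series returns `g = 1`
#' (autocorrelation undefined, degenerate case).
#'
#' @param x numeric samples (or a [gradient_series()]).
#' @return statistical inefficiency `g >= 1` (correlated samples per
#'   effectively independent sample).
#' @export
statistical_inefficiency <- function(x) {
  x <- .series_samples(x)
  n <- length(x)
  v <- stats::var(x)
  if (n < 3 || !is.finite(v) || v == 0) return(1)
  rho <- .acf_fft(x)[-1]  # lags 1 .. n-1
  neg <- which(rho <= 0)
  stop_at <- if (length(neg) > 0) neg[1] - 1L else length(rho)
  g <- 1
  if (stop_at > 0) {
    tt <- seq_len(stop_at)
    g <- 1 + 2 * sum((1 - tt / n) * rho[tt])
  }
  max(1, g)
}

## Full autocorrelation function via FFT (biased normalization, lag 0 .. n-1).
.acf_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  np <- stats::nextn(2L * n, 2)
  f <- stats::fft(c(xc, rep(0, np - n)))
  ac <- Re(stats::fft(Conj(f) * f, inverse = TRUE))[seq_len(n)]
  ac / ac[1]
}

#' Automatic equilibration detection
#'
#' Scans candidate truncation points `t0` on a grid; for each, computes the
#' statistical inefficiency of the remaining samples and the effective sample
#' size `n_eff(t0) = (N - t0) / g(t0)`. Returns the truncation maximizing
#' `n_eff` (the iterative equilibration-detection scheme standard in free
#' energy post-processing). `t0` is the number of discarded leading samples.
#'
#' @param series a [gradient_series()] or numeric vector (>= 10 samples).
#' @param n_grid number of candidate truncation points (default 50; grids
#'   larger than the series scan every point).
#' @return list with `t0`, `g`, `n_eff`.
#' @export
detect_equilibration <- function(series, n_grid = 50L) {
  x <- .series_samples(series)
  n <- length(x)
  if (n < 10) .stopf("need at least 10 samples, got %d", n)
  if (stats::var(x) == 0) return(list(t0 = 0L, g = 1, n_eff = n))
  t_max <- n - 10L
  grid <- unique(as.integer(floor(seq(0, t_max, length.out = min(n_grid, t_max + 1L)))))
  best <- list(t0 = 0L, g = Inf, n_eff = -Inf)
  for (t0 in grid) {
    tail_x <- x[(t0 + 1):n]
    if (stats::var(tail_x) == 0) { g <- 1 } else { g <- statistical_inefficiency(tail_x) }
    n_eff <- (n - t0) / g
    if (n_eff > best$n_eff) best <- list(t0 = t0, g = g, n_eff = n_eff)
  }
  best
}

#' Thin an equilibrated series to decorrelated samples
#'
#' Drops the first `t0` samples and thins the remainder with stride
#' `ceiling(g)`.
#'
#' @param series a [gradient_series()] or numeric vector.
#' @param t0 number of discarded leading samples.
#' @param g statistical inefficiency (>= 1).
#' @return numeric vector of decorrelated samples (at least one).
#' @export
subsample_decorrelated <- function(series, t0, g) {
  x <- .series_samples(series)
  n <- length(x)
  if (t0 >= n) .stopf("t0 (%d) must be smaller than the series length (%d)", t0, n)
  if (g < 1) .stopf("g must be >= 1")
  tail_x <- x[(t0 + 1):n]
  tail_x[seq(1, length(tail_x), by = ceiling(g))]
}

#' Jensen-Shannon divergence and distance
#'
#' `js_divergence` takes two discrete probability vectors on a common support
#' and returns the base-2 Jensen-Shannon divergence (bounded by 1).
#' `js_distance` histograms two sample sets on shared equal-width bins
#' spanning the pooled range and returns the square root of the divergence
#' (the distance, in `[0, 1]`).
#'
#' @param p,q probability vectors of equal length (each summing to 1).
#' @return `js_divergence`: divergence in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) .stopf("p and q must have equal length")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    .stopf("p and q must each sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  max(0, (kl(p, m) + kl(q, m)) / 2)
}

#' @rdname js_divergence
#' @param a,b numeric sample vectors (nonempty).
#' @param n_bins number of shared histogram bins (>= 2); the default follows
#'   Sturges' rule on the pooled sample count (a finite-sample JS distance has
#'   positive bias of roughly `sqrt(B / (4 N ln 2))` for `B` bins, so bin
#'   counts growing faster than `log N` would swamp a 0.1 criterion at
#'   realistic window lengths).
#' @return `js_distance`: distance in `[0, 1]`.
#' @export
js_distance <- function(a, b, n_bins = NULL) {
  if (length(a) == 0 || length(b) == 0) .stopf("a and b must be nonempty")
  if (is.null(n_bins)) n_bins <- max(10L, ceiling(log2(length(a) + length(b))) + 1L)
  if (n_bins < 2) .stopf("n_bins must be >= 2")
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  pa <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins)
  pb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins)
  sqrt(js_divergence(pa / sum(pa), pb / sum(pb)))
}

#' Window convergence by chronological-halves Jensen-Shannon test
#'
#' Equilibrates and decorrelates the series, splits the decorrelated samples
#' into two chronological halves and declares the window converged when their
#' Jensen-Shannon distance does not exceed `criterion` (workflow default 0.1).
#' The default bin count grows with the cube root of the decorrelated sample
#' count (at least 4 bins), which keeps the finite-sample JS bias comfortably
#' under the criterion once a window holds a few hundred independent samples
#' while retaining power against distributional drift. Fewer than 4
#' equilibrated samples cannot be split meaningfully and return `FALSE` with
#' attribute `flagged = TRUE`.
#'
#' @param series a [gradient_series()] or numeric vector.
#' @param criterion convergence threshold on the JS distance (default 0.1).
#' @param n_bins histogram bins passed to [js_distance()].
#' @param eq optional precomputed [detect_equilibration()] result.
#' @return logical; attribute `js` carries the measured distance.
#' @export
window_converged <- function(series, criterion = 0.1, n_bins = NULL, eq = NULL) {
  x <- .series_samples(series)
  if (is.null(eq)) eq <- detect_equilibration(x)
  xe <- x[(eq$t0 + 1):length(x)]
  if (length(xe) < 4) {
    out <- FALSE
    attr(out, "flagged") <- TRUE
    return(out)
  }
  dec <- subsample_decorrelated(x, eq$t0, eq$g)
  if (length(dec) < 4) dec <- xe
  if (is.null(n_bins)) n_bins <- max(4L, ceiling(length(dec)^(1 / 3)))
  half <- floor(length(dec) / 2)
  d <- js_distance(dec[seq_len(half)], dec[(half + 1):length(dec)],
                   n_bins = n_bins)
  out <- d <= criterion
  attr(out, "js") <- d
  out
}

#' Per-window estimate from one or more replicates
#'
#' Each replicate is equilibrated and decorrelated independently; the pooled
#' decorrelated values give the window mean and its standard error
#' (`sd / sqrt(n_pooled)`). `converged` is the AND of the per-replicate
#' chronological-halves tests.
#'
#' @param series_list list of [gradient_series()] sharing one (leg, lambda).
#' @param criterion JS convergence threshold (default 0.1).
#' @param n_bins histogram bins for the convergence test.
#' @return an object of class `window_estimate`: list with `t0`, `g`, `n_eff`,
#'   `mean`, `stderr`, `converged`, `total_time` (and `replicates` detail).
#' @export
combine_replicates <- function(series_list, criterion = 0.1, n_bins = NULL) {
  if (inherits(series_list, "gradient_series")) series_list <- list(series_list)
  if (length(series_list) == 0) .stopf("series_list must be nonempty")
  legs <- unique(vapply(series_list, function(s) s$leg, character(1)))
  lams <- unique(vapply(series_list, function(s) s$lambda_index, integer(1)))
  if (length(legs) > 1 || length(lams) > 1)
    .stopf("all replicates must share one (leg, lambda_index)")
  pooled <- numeric(0)
  reps <- vector("list", length(series_list))
  conv <- TRUE
  total_time <- 0
  for (k in seq_along(series_list)) {
    s <- series_list[[k]]
    eq <- detect_equilibration(s)
    dec <- subsample_decorrelated(s, eq$t0, eq$g)
    wc <- window_converged(s, criterion = criterion, n_bins = n_bins, eq = eq)
    conv <- conv && isTRUE(as.logical(wc))
    pooled <- c(pooled, dec)
    total_time <- total_time + length(s$samples) * s$dt
    reps[[k]] <- list(t0 = eq$t0, g = eq$g, n_eff = eq$n_eff,
                      converged = isTRUE(as.logical(wc)))
  }
  n <- length(pooled)
  est <- list(
    t0 = reps[[1]]$t0,
    g = reps[[1]]$g,
    n_eff = n,
    mean = mean(pooled),
    stderr = if (n > 1) stats::sd(pooled) / sqrt(n) else NA_real_,
    converged = conv,
    total_time = total_time,
    replicates = reps
  )
  class(est) <- "window_estimate"
  est
}

#' Simulation extension policy for one lambda window
#'
#' Given the current window estimate, decide whether to accept the window,
#' request exactly one additional increment of simulation, or give up (the
#' unconverged flag is carried into the transformation result). The standard
#' protocol starts windows at 2.5 ns and extends in 0.5 ns increments; the
#' `fast` preset uses 1.0 ns / 0.25 ns.
#'
#' @param window a `window_estimate` (see [combine_replicates()]).
#' @param series the window's [gradient_series()].
#' @param init_len initial simulation length per window (ns).
#' @param increment extension length (ns).
#' @param criterion JS convergence threshold.
#' @param max_total maximum total simulation length per window (ns).
#' @return list with `decision` (`"accept"`, `"extend"` or `"give_up"`) and
#'   `requested_ns` (the increment, 0 unless extending).
#' @export
extend_policy <- function(window, series, init_len = 2.5, increment = 0.5,
                          criterion = 0.1, max_total = 10) {
  stopifnot(inherits(window, "window_estimate"))
  if (isTRUE(window$converged))
    return(list(decision = "accept", requested_ns = 0))
  if (window$total_time + increment <= max_total)
    return(list(decision = "extend", requested_ns = increment))
  list(decision = "give_up", requested_ns = 0)
}

#' @rdname extend_policy
#' @param sampler function(n) returning `n` further dU/dlambda samples,
#'   continuing the series (a closure over the simulation state).
#' @param dt time per sample (ns).
#' @param leg,lambda_index passed to [gradient_series()].
#' @param n_bins histogram bins for the convergence test.
#' @return `run_window_protocol`: the final `window_estimate`, with attributes
#'   `n_extensions` and `decision_trace`.
#' @export
run_window_protocol <- function(sampler, dt, init_len = 2.5, increment = 0.5,
                                criterion = 0.1, max_total = 10,
                                leg = "complex", lambda_index = 1L,
                                n_bins = NULL) {
  n_init <- max(10L, round(init_len / dt))
  x <- sampler(n_init)
  n_ext <- 0L
  trace <- character(0)
  repeat {
    ser <- gradient_series(x, leg = leg, lambda_index = lambda_index, dt = dt)
    est <- combine_replicates(list(ser), criterion = criterion, n_bins = n_bins)
    dec <- extend_policy(est, ser, init_len = init_len, increment = increment,
                         criterion = criterion, max_total = max_total)
    trace <- c(trace, dec$decision)
    if (dec$decision != "extend") break
    x <- c(x, sampler(max(1L, round(dec$requested_ns / dt))))
    n_ext <- n_ext + 1L
  }
  attr(est, "n_extensions") <- n_ext
  attr(est, "decision_trace") <- trace
  est
}

#' Integrate one leg over the lambda schedule
#'
#' The TI estimator: `dG = sum_i w_i * <dU/dlambda>_i`. When per-window
#' standard errors are supplied the leg standard error is propagated as
#' `sqrt(sum w_i^2 s_i^2)`.
#'
#' @param window_means per-window mean dU/dlambda (kcal/mol), one per node.
#' @param schedule a [gauss_legendre_schedule()].
#' @param window_stderrs optional per-window standard errors.
#' @return list with `dg` (kcal/mol) and `stderr` (NA when not supplied).
#' @export
integrate_leg <- function(window_means, schedule, window_stderrs = NULL) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  if (length(window_means) != length(schedule$nodes))
    .stopf("window_means length (%d) must match schedule (%d windows)",
           length(window_means), length(schedule$nodes))
  dg <- sum(schedule$weights * window_means)
  se <- if (is.null(window_stderrs)) NA_real_ else {
    if (length(window_stderrs) != length(schedule$nodes))
      .stopf("window_stderrs length must match schedule")
    sqrt(sum(schedule$weights^2 * window_stderrs^2))
  }
  list(dg = dg, stderr = se)
}

#' Relative binding free energy of one transformation
#'
#' Runs the per-window analysis (equilibration, decorrelation, replicate
#' pooling, convergence flags) over both legs and integrates:
#' `ddG = dG_complex - dG_solvent`, with standard errors combined in
#' quadrature.
#'
#' @param complex_windows,solvent_windows lists with one element per lambda
#'   node; each element is a [gradient_series()] or a list of replicate
#'   series.
#' @param schedule a [gauss_legendre_schedule()].
#' @param criterion JS convergence threshold.
#' @param n_bins histogram bins for the convergence test.
#' @return an object of class `ti_result`: list with `dg_complex`,
#'   `dg_solvent`, `ddg`, `ddg_stderr`, `all_converged` and the per-window
#'   estimates.
#' @export
compute_rbfe <- function(complex_windows, solvent_windows, schedule,
                         criterion = 0.1, n_bins = NULL) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  n <- length(schedule$nodes)
  if (length(complex_windows) != n || length(solvent_windows) != n)
    .stopf("each leg needs exactly %d windows", n)
  leg_est <- function(windows) {
    ests <- lapply(windows, function(w) {
      if (inherits(w, "gradient_series")) w <- list(w)
      combine_replicates(w, criterion = criterion, n_bins = n_bins)
    })
    means <- vapply(ests, `[[`, numeric(1), "mean")
    ses <- vapply(ests, `[[`, numeric(1), "stderr")
    list(int = integrate_leg(means, schedule, ses), ests = ests)
  }
  cx <- leg_est(complex_windows)
  sv <- leg_est(solvent_windows)
  all_conv <- all(vapply(c(cx$ests, sv$ests), `[[`, logical(1), "converged"))
  res <- list(
    dg_complex = cx$int$dg,
    dg_solvent = sv$int$dg,
    ddg = cx$int$dg - sv$int$dg,
    ddg_stderr = sqrt(cx$int$stderr^2 + sv$int$stderr^2),
    all_converged = all_conv,
    complex_windows = cx$ests,
    solvent_windows = sv$ests
  )
  class(res) <- "ti_result"
  res
}

#' @export
print.ti_result <- function(x, ...) {
  cat(sprintf(
    "<ti_result> ddG = %.2f +/- %.2f kcal/mol (complex %.2f, solvent %.2f)%s\n",
    x$ddg, x$ddg_stderr, x$dg_complex, x$dg_solvent,
    if (x$all_converged) "" else " [UNCONVERGED WINDOWS]"))
  invisible(x)
}

#' Read / write gradient series in long CSV format
#'
#' Columns: `leg, lambda_index, replicate, dt_ns, sample_kcal_per_mol_per_lambda`.
#'
#' @param path CSV path.
#' @return `read_gradient_series`: a list of [gradient_series()] grouped by
#'   `(leg, lambda_index, replicate)`, in file order.
#' @export
read_gradient_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("leg", "lambda_index", "replicate", "dt_ns",
            "sample_kcal_per_mol_per_lambda")
  if (!all(need %in% names(df)))
    .stopf("gradient CSV must have columns %s", paste(need, collapse = ","))
  key <- paste(df$leg, df$lambda_index, df$replicate, sep = "\r")
  lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))), function(idx) {
    gradient_series(df$sample_kcal_per_mol_per_lambda[idx],
                    leg = df$leg[idx[1]],
                    lambda_index = df$lambda_index[idx[1]],
                    dt = df$dt_ns[idx[1]],
                    replicate_id = df$replicate[idx[1]])
  })
}

#' @rdname read_gradient_series
#' @param series_list list of [gradient_series()].
#' @export
write_gradient_series <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(leg = s$leg, lambda_index = s$lambda_index,
               replicate = s$replicate_id, dt_ns = s$dt,
               sample_kcal_per_mol_per_lambda = s$samples)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
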