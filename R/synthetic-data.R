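#' Synthetic affinity oracle specification
#'
#' An additive group-contribution free-energy landscape standing in for MD TI
#' plus experiment: a molecule's absolute binding free energy is the scaffold
#' base value plus the contribution of each substituent, plus seeded Gaussian
#' noise (reproducible per molecule). Additive energetics give the surrogate
#' models learnable structure without making the task trivial; the default
#' noise (0.5 kcal/mol) is comparable to a TI standard error.
#'
#' @param base_dg scaffold binding free energy (kcal/mol).
#' @param group_contributions named numeric vector, one entry per substituent
#'   label of the form `"R1=CC"` (kcal/mol).
#' @param noise_sd Gaussian noise standard deviation (kcal/mol, >= 0).
#' @param seed integer seed for the per-molecule noise stream.
#' @return an object of class `synthetic_oracle_spec`.
#' @export
synthetic_oracle_spec <- function(base_dg = -6.0, group_contributions,
                                  noise_sd = 0.5, seed = 1L) {
  stopifnot(noise_sd >= 0, !is.null(names(group_contributions)))
  structure(list(base_dg = base_dg,
                 group_contributions = group_contributions,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_oracle_spec")
}

.subst_label <- function(site, frag) paste0(site, "=", ifelse(frag == "", "H", frag))

#' Enumerate an analog library around a scaffold
#'
#' The scaffold SMILES carries attachment placeholders `{R1}`, `{R2}`, ...
#' (write `({R1})` where the substituent is a branch; an empty fragment
#' removes the branch, i.e. hydrogen). All combinations of the substituent
#' sets are enumerated, or sampled without replacement (seeded) when the
#' product exceeds `n_max`. Every product is validated and canonicalized;
#' duplicate canonical SMILES are dropped.
#'
#' @param scaffold scaffold SMILES with `{Rk}` placeholders.
#' @param substituent_sets named list (`R1`, `R2`, ...) of fragment SMILES
#'   character vectors; `""` denotes hydrogen.
#' @param n_max maximum library size.
#' @param seed RNG seed for subsampling.
#' @param id_prefix prefix for generated ids.
#' @return a `mol_library` with a `substituents` column (labels like
#'   `"R1=CC;R2=H"`) consumed by [affinity_oracle()].
#' @export
generate_analog_library <- function(scaffold, substituent_sets, n_max = 1000L,
                                    seed = 1L, id_prefix = "syn") {
  stopifnot(is.list(substituent_sets), !is.null(names(substituent_sets)))
  sites <- names(substituent_sets)
  ## validate each fragment in isolation (others as hydrogen)
  for (site in sites) {
    for (frag in unique(substituent_sets[[site]])) {
      one <- stats::setNames(as.list(rep("", length(sites))), sites)
      one[[site]] <- frag
      smi <- .substitute_scaffold(scaffold, one)
      if (is.na(.ob_canonical(smi)))
        .stopf("invalid fragment '%s' at site %s (product '%s' does not parse)",
               frag, site, smi)
    }
  }
  combos <- expand.grid(substituent_sets, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) > n_max) {
    pick <- .with_seed(seed, sample(nrow(combos), n_max))
    combos <- combos[sort(pick), , drop = FALSE]
  }
  smis <- vapply(seq_len(nrow(combos)), function(k)
    .substitute_scaffold(scaffold, as.list(combos[k, , drop = FALSE])),
    character(1))
  labels <- vapply(seq_len(nrow(combos)), function(k)
    paste(vapply(sites, function(s) .subst_label(s, combos[k, s]), character(1)),
          collapse = ";"), character(1))
  can <- .ob_canonical(smis)
  if (anyNA(can))
    .stopf("substituent combination produced unparseable SMILES: '%s'",
           smis[which(is.na(can))[1]])
  keep <- !duplicated(can)
  lib <- molecule_library(
    id = sprintf("%s%04d", id_prefix, seq_len(sum(keep))),
    smiles = can[keep], source_tag = "synthetic",
    compute_scaffolds = FALSE, canonicalize = FALSE)
  lib$substituents <- labels[keep]
  lib
}

.substitute_scaffold <- function(scaffold, frags) {
  smi <- scaffold
  for (site in names(frags)) {
    frag <- frags[[site]]
    branch <- paste0("({", site, "})")
    if (grepl(branch, smi, fixed = TRUE)) {
      smi <- gsub(branch, if (frag == "") "" else paste0("(", frag, ")"),
                  smi, fixed = TRUE)
    }
    smi <- gsub(paste0("{", site, "}"), frag, smi, fixed = TRUE)
  }
  smi
}

#' Query the synthetic affinity oracle
#'
#' `dG = base + sum of group contributions + N(0, noise_sd)`, with the noise
#' drawn from a per-molecule seeded stream so repeated queries return the
#' identical value.
#'
#' @param records a `mol_library` carrying a `substituents` column (from
#'   [generate_analog_library()]), or a subset of one.
#' @param spec a [synthetic_oracle_spec()].
#' @param noiseless if `TRUE`, return the ground-truth additive value.
#' @return named numeric vector (id -> dG, kcal/mol).
#' @export
affinity_oracle <- function(records, spec, noiseless = FALSE) {
  stopifnot(inherits(spec, "synthetic_oracle_spec"))
  if (!"substituents" %in% names(records))
    .stopf("records lack the 'substituents' labels of a generated library")
  out <- vapply(seq_len(nrow(records)), function(k) {
    labs <- strsplit(records$substituents[k], ";", fixed = TRUE)[[1]]
    labs <- labs[!grepl("=H$", labs)]
    unknown <- setdiff(labs, names(spec$group_contributions))
    if (length(unknown) > 0)
      .stopf("unknown substituent label(s): %s", paste(unknown, collapse = ", "))
    dg <- spec$base_dg + sum(spec$group_contributions[labs])
    if (!noiseless && spec$noise_sd > 0) {
      dg <- dg + .with_seed(spec$seed + .str_hash(records$id[k]) %% 1e7,
                            stats::rnorm(1, 0, spec$noise_sd))
    }
    dg
  }, numeric(1))
  stats::setNames(out, records$id)
}

#' Mock docking-pose tables
#'
#' Emulates the score/RMSD columns consumed by the docking filter cascades:
#' three poses per molecule; the docking score tracks the true affinity
#' (`score = score_scale * dG + noise`); a seeded `pass_fraction` of molecules
#' receives best-pose geometry (indole RMSD, Murcko RMSD, clash) inside the
#' standard filter thresholds, the rest outside.
#'
#' @param records a `mol_library` with `substituents`.
#' @param oracle_spec a [synthetic_oracle_spec()] supplying true affinities.
#' @param seed RNG seed.
#' @param pass_fraction fraction of molecules given passing geometry.
#' @param score_scale multiplier mapping dG to docking score (> 0 preserves
#'   ranking).
#' @param score_noise_sd Gaussian noise on the score.
#' @return pose `data.frame` (3 rows per molecule) as in [read_pose_table()].
#' @export
mock_docking <- function(records, oracle_spec, seed = 1L, pass_fraction = 0.8,
                         score_scale = 1.0, score_noise_sd = 0) {
  dg <- affinity_oracle(records, oracle_spec, noiseless = TRUE)
  n <- nrow(records)
  .with_seed(seed, {
    passes <- stats::runif(n) < pass_fraction
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      base_score <- score_scale * dg[k] +
        if (score_noise_sd > 0) stats::rnorm(1, 0, score_noise_sd) else 0
      if (passes[k]) {
        ri <- stats::runif(1, 0, 5); rm <- stats::runif(1, 0, 4)
        cl <- stats::runif(1, 0, 0.5)
      } else {
        ## at least one geometry field out of range; each field fails
        ## independently so the two filter stages prune different subsets
        fail <- stats::runif(3) < 0.6
        if (!any(fail)) fail[sample.int(3, 1)] <- TRUE
        ri <- if (fail[1]) stats::runif(1, 5.5, 12) else stats::runif(1, 0, 5)
        rm <- if (fail[2]) stats::runif(1, 4.5, 10) else stats::runif(1, 0, 4)
        cl <- if (fail[3]) stats::runif(1, 0.6, 3) else stats::runif(1, 0, 0.5)
      }
      worse <- sort(stats::runif(2, 0.5, 6))
      rows[[k]] <- data.frame(
        molecule_id = records$id[k],
        pose_id = 1:3,
        docking_score = c(base_score, base_score + worse / 2),
        clash_component = c(cl, cl + worse / 4),
        rmsd_indole = c(ri, ri + worse),
        rmsd_murcko = c(rm, rm + worse),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
}

#' Gradient-profile specification for synthetic TI data
#'
#' Defines, per leg, a polynomial mean dU/dlambda curve whose Gauss-Legendre
#' quadrature equals the requested free energy by construction (the constant
#' coefficient is shifted accordingly), plus an AR(1) noise model and an
#' optional initial equilibration transient.
#'
#' @param target_dg_per_leg named numeric, e.g. `c(complex = -3, solvent = -1)`
#'   (kcal/mol).
#' @param base_shape ascending polynomial coefficients of the unshifted mean
#'   curve (default `c(0, 0, 3)`, i.e. `3 lambda^2`).
#' @param noise_sd stationary sd of the AR(1) noise (kcal/mol).
#' @param autocorrelation_time AR(1) correlation time in samples.
#' @param transient_amplitude initial transient amplitude (kcal/mol).
#' @param transient_length e-folding time of the transient as a fraction of
#'   the series length.
#' @param seed RNG seed.
#' @return an object of class `gradient_profile_spec`.
#' @export
gradient_profile_spec <- function(target_dg_per_leg = c(complex = -3, solvent = -1),
                                  base_shape = c(0, 0, 3),
                                  noise_sd = 1.5,
                                  autocorrelation_time = 3,
                                  transient_amplitude = 0,
                                  transient_length = 0.2,
                                  seed = 1L) {
  stopifnot(!is.null(names(target_dg_per_leg)))
  base_int <- sum(base_shape / seq_along(base_shape))  # integral on [0,1]
  coefs <- lapply(target_dg_per_leg, function(tgt) {
    cf <- base_shape
    cf[1] <- cf[1] + (tgt - base_int)
    cf
  })
  structure(list(target_dg_per_leg = target_dg_per_leg,
                 curve_shape = coefs, noise_sd = noise_sd,
                 autocorrelation_time = autocorrelation_time,
                 transient_amplitude = transient_amplitude,
                 transient_length = transient_length,
                 seed = as.integer(seed)),
            class = "gradient_profile_spec")
}

.polyval_asc <- function(coefs, x) {
  sum(coefs * x^(seq_along(coefs) - 1))
}

#' Synthesize gradient time series for one leg
#'
#' Per lambda node: `samples = mean_curve(lambda) + AR(1) noise + optional
#' decaying transient`, fully seeded (distinct streams per leg, window and
#' replicate).
#'
#' @param spec a [gradient_profile_spec()].
#' @param schedule a [gauss_legendre_schedule()].
#' @param leg which leg to synthesize (must name an entry of the spec's
#'   targets).
#' @param n_samples samples per window.
#' @param dt ns per sample.
#' @param replicate_id replicate label (also offsets the RNG stream).
#' @return list of [gradient_series()], one per lambda node.
#' @export
synth_gradient_series <- function(spec, schedule, leg = "complex",
                                  n_samples = 2500L, dt = 0.001,
                                  replicate_id = 1L) {
  stopifnot(inherits(spec, "gradient_profile_spec"),
            inherits(schedule, "lambda_schedule"),
            leg %in% names(spec$target_dg_per_leg))
  coefs <- spec$curve_shape[[leg]]
  phi <- exp(-1 / spec$autocorrelation_time)
  innov_sd <- spec$noise_sd * sqrt(1 - phi^2)
  lapply(seq_along(schedule$nodes), function(i) {
    mu <- .polyval_asc(coefs, schedule$nodes[i])
    stream <- spec$seed + 13 * i + 131 * .str_hash(leg) %% 1e6 +
      1013 * replicate_id
    x <- .with_seed(stream, {
      noise <- if (spec$noise_sd > 0) {
        e <- stats::rnorm(n_samples, 0, innov_sd)
        as.numeric(stats::filter(e, phi, method = "recursive")) +
          stats::rnorm(1, 0, spec$noise_sd) * phi^(seq_len(n_samples))
      } else rep(0, n_samples)
      tr <- if (spec$transient_amplitude != 0 && spec$transient_length > 0) {
        ## transient_length is the e-folding time as a fraction of the series
        len <- spec$transient_length * n_samples
        spec$transient_amplitude * exp(-(seq_len(n_samples) - 1) / len)
      } else 0
      mu + noise + tr
    })
    gradient_series(x, leg = leg, lambda_index = i, dt = dt,
                    replicate_id = replicate_id)
  })
}

#' @rdname synth_gradient_series
#' @param n_replicates replicates per window.
#' @return `synth_transformation`: list with `complex` and `solvent` (each a
#'   list over lambda of lists of replicate series) and `truth` (the
#'   constructed ddG, kcal/mol).
#' @export
synth_transformation <- function(spec, schedule, n_samples = 2500L, dt = 0.001,
                                 n_replicates = 1L) {
  legs <- lapply(stats::setNames(nm = c("complex", "solvent")), function(leg) {
    lapply(seq_along(schedule$nodes), function(i) NULL)
  })
  for (leg in c("complex", "solvent")) {
    for (r in seq_len(n_replicates)) {
      ser <- synth_gradient_series(spec, schedule, leg = leg,
                                   n_samples = n_samples, dt = dt,
                                   replicate_id = r)
      for (i in seq_along(ser)) legs[[leg]][[i]] <- c(legs[[leg]][[i]], list(ser[[i]]))
    }
  }
  list(complex = legs$complex, solvent = legs$solvent,
       truth = unname(spec$target_dg_per_leg["complex"] -
                        spec$target_dg_per_leg["solvent"]))
}
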