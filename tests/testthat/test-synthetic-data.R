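test_that("analog enumeration counts and seeding behave", {
  # one site, three substituents
  lib1 <- generate_analog_library("Cc1ccccc1{R1}", list(R1 = c("", "C", "F")),
                                  n_max = 10)
  expect_equal(nrow(lib1), 3)
  # two sites, 4 x 5 combinations, all unique
  lib2 <- generate_analog_library(
    "O=C(N{R1})c1ccc({R2})cc1",
    list(R1 = c("C", "CC", "CCC", "CCCC"),
         R2 = c("", "F", "Cl", "OC", "C")),
    n_max = 100)
  expect_equal(nrow(lib2), 20)
  expect_false(anyDuplicated(lib2$smiles) > 0)
  # seeded subsampling: same seed identical, different seed differs
  s1 <- generate_analog_library("Cc1ccccc1{R1}",
                                list(R1 = c("", "C", "F", "Cl", "CC", "OC",
                                            "N", "CO", "CCC", "CCO")),
                                n_max = 7, seed = 1)
  s1b <- generate_analog_library("Cc1ccccc1{R1}",
                                 list(R1 = c("", "C", "F", "Cl", "CC", "OC",
                                             "N", "CO", "CCC", "CCO")),
                                 n_max = 7, seed = 1)
  s2 <- generate_analog_library("Cc1ccccc1{R1}",
                                list(R1 = c("", "C", "F", "Cl", "CC", "OC",
                                            "N", "CO", "CCC", "CCO")),
                                n_max = 7, seed = 2)
  expect_identical(s1$smiles, s1b$smiles)
  expect_false(identical(s1$smiles, s2$smiles))
  expect_equal(nrow(s1), 7)
  expect_error(
    generate_analog_library("Cc1ccccc1{R1}", list(R1 = c("C", "C1C")), 10),
    "C1C")
})

test_that("the affinity oracle is additive and reproducible", {
  camp <- small_campaign(noise_sd = 0)
  spec0 <- synthetic_oracle_spec(base_dg = -4.0,
                                 group_contributions = c("R1=C" = -1.0,
                                                         "R2=OC" = +0.5),
                                 noise_sd = 0)
  rec <- data.frame(id = "x", substituents = "R1=C;R2=OC")
  expect_equal(unname(affinity_oracle(rec, spec0)), -4.5)
  # hydrogen sites contribute nothing
  recH <- data.frame(id = "h", substituents = "R1=H;R2=H")
  expect_equal(unname(affinity_oracle(recH, spec0)), -4.0)
  expect_error(affinity_oracle(data.frame(id = "u", substituents = "R9=Se"),
                               spec0), "unknown substituent")
  # same molecule queried twice gives the identical noisy value
  noisy <- synthetic_oracle_spec(-4, c("R1=C" = -1), noise_sd = 0.5, seed = 3)
  recN <- data.frame(id = "n1", substituents = "R1=C")
  expect_identical(affinity_oracle(recN, noisy), affinity_oracle(recN, noisy))
})

test_that("library-mean oracle values concentrate at the base value", {
  # symmetric contributions: full enumeration averages to base_dg exactly,
  # so the noisy library mean lands within 3 standard errors of base
  frags <- c("", "C", "CC", "CCC", "CCCC", "CCCCC", "OC", "OCC")
  contrib <- stats::setNames(c(-1.5, -1, -0.5, 0.5, 1, 1.5, 0),
                             paste0("R1=", frags[-1]))
  lib <- generate_analog_library("CCCC1CCN({R1})CC1", list(R1 = frags),
                                 n_max = 8, seed = 1)
  expect_equal(nrow(lib), 8)
  spec <- synthetic_oracle_spec(base_dg = -6, group_contributions = contrib,
                                noise_sd = 0.3, seed = 5)
  # replicate the enumeration to reach n = 1000 independent noise draws;
  # each fragment stays equally represented so the noiseless mean is -6 exactly
  big <- do.call(rbind, lapply(1:125, function(k) {
    d <- as.data.frame(lib)
    d$id <- paste0(d$id, "_", k)
    d
  }))
  vals <- affinity_oracle(alfe:::.as_mol_library(big), spec)
  se <- 0.3 / sqrt(length(vals))
  expect_lt(abs(mean(vals) - (-6)), 3 * se)
})

test_that("mock docking preserves affinity ranking and pass rates", {
  frags <- c("", "C", "CC", "F", "Cl", "OC", "CO", "N", "CCO", "COC")
  lib <- generate_analog_library("O=C(c1ccccc1)N1CCCC1({R1})",
                                 list(R1 = frags), n_max = 10, seed = 2)
  contrib <- stats::setNames(runif(9, -1, 1), paste0("R1=", frags[-1]))
  # labels comfortably below the -6 score threshold
  spec <- synthetic_oracle_spec(base_dg = -7.5, group_contributions = contrib,
                                noise_sd = 0, seed = 4)
  poses <- mock_docking(lib, spec, seed = 1, pass_fraction = 1,
                        score_scale = 1, score_noise_sd = 0)
  # exactly three poses per molecule
  expect_equal(as.integer(table(poses$molecule_id)), rep(3L, nrow(lib)))
  # noiseless scores rank like the true affinities
  best <- best_pose_per_molecule(poses, "murcko")
  truth <- affinity_oracle(lib, spec, noiseless = TRUE)
  expect_equal(order(best$docking_score), order(truth[best$molecule_id]))

  # a seeded pass fraction of one half puts ~50 of 100 through stage 2
  big <- do.call(rbind, lapply(1:10, function(k) {
    d <- as.data.frame(lib); d$id <- paste0(d$id, "_", k); d
  }))
  big <- alfe:::.as_mol_library(big)
  poses2 <- mock_docking(big, spec, seed = 9, pass_fraction = 0.5)
  surv <- stage2_filter(best_pose_per_molecule(poses2, "murcko"))
  expect_gte(length(surv), 40)
  expect_lte(length(surv), 60)
})

test_that("synthetic gradients integrate to their target by construction", {
  sched <- gauss_legendre_schedule(9)
  spec <- gradient_profile_spec(c(complex = -4.2, solvent = -1.1),
                                noise_sd = 0, transient_amplitude = 0)
  for (leg in c("complex", "solvent")) {
    ser <- synth_gradient_series(spec, sched, leg, n_samples = 50)
    means <- vapply(ser, function(s) mean(s$samples), numeric(1))
    expect_equal(integrate_leg(means, sched)$dg,
                 unname(spec$target_dg_per_leg[leg]), tolerance = 1e-10)
  }
  # bit-reproducibility under a fixed seed
  a <- synth_gradient_series(spec, sched, "complex", n_samples = 50)
  b <- synth_gradient_series(spec, sched, "complex", n_samples = 50)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
})

test_that("transients are detected and AR(1) inefficiency matches theory", {
  sched <- gauss_legendre_schedule(9)
  # 5-sigma transient over the first 20%: t0 should land past 15% of N
  hits <- 0
  for (s in 1:50) {
    spec <- gradient_profile_spec(c(complex = 0, solvent = 0), noise_sd = 1,
                                  autocorrelation_time = 2,
                                  transient_amplitude = 5,
                                  transient_length = 0.2, seed = s)
    ser <- synth_gradient_series(spec, sched, "complex", n_samples = 2000)[[1]]
    eq <- detect_equilibration(ser)
    hits <- hits + (eq$t0 >= 0.15 * 2000)
  }
  expect_gte(hits, 45)  # >= 90% of seeds

  # tau = 20 samples: measured g in [25, 60] at N = 10000 (theory ~ 41)
  spec_ar <- gradient_profile_spec(c(complex = 0, solvent = 0), noise_sd = 1,
                                   autocorrelation_time = 20,
                                   transient_amplitude = 0, seed = 77)
  ser <- synth_gradient_series(spec_ar, sched, "complex", n_samples = 10000)[[5]]
  g <- statistical_inefficiency(ser)
  expect_gt(g, 25); expect_lt(g, 60)
})
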