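#' Pipeline configuration
#'
#' Assembles every tunable of the synthetic end-to-end campaign: SMARTS
#' patterns, docking-filter thresholds, TI convergence settings, AL batch
#' schedule and scope switch, selection budget, and reference-ligand anchors.
#' All randomness flows from the single root `seed`.
#'
#' @param smarts_closest SMARTS selecting "closest analogs" (default: a
#'   secondary carboxamide retained on the variable substituent).
#' @param rmsd_indole_max,rmsd_murcko_max,score_max,clash_max docking filter
#'   thresholds (inclusive).
#' @param ti TI settings: `init_len`, `increment`, `criterion`, `max_total`
#'   (ns); the `fast` preset uses 1.0/0.25.
#' @param al_batches per-iteration acquisition sizes (default 7 x 20).
#' @param al_representations,al_algorithms AutoML grid of the AL loop.
#' @param budget_total,greedy_n,diverse_n experimental selection budget.
#' @param anchors named numeric: absolute binding free energy (kcal/mol)
#'   assigned to the reference ligands (`Hit1`, `Hit2`).
#' @param ti_noise_sd standard error emulated for each synthetic RBFE label.
#' @param n_hit1,n_hit2 library sizes enumerated per hit series.
#' @param pass_fraction fraction of molecules given passing mock-docking
#'   geometry.
#' @param nns_queries,nns_k nearest-neighbor stage: number of top-ranked
#'   query molecules and neighbors per query.
#' @param make_tsne write a 2D chemical-space projection of the computed set.
#' @param seed root RNG seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(smarts_closest = "C(=O)[NH1]",
                            rmsd_indole_max = 5.0, rmsd_murcko_max = 4.0,
                            score_max = -6.0, clash_max = 0.5,
                            ti = list(init_len = 2.5, increment = 0.5,
                                      criterion = 0.1, max_total = 10),
                            al_batches = rep(20L, 7L),
                            al_representations = c("ecfp6_2048", "path7_2048"),
                            al_algorithms = c("linear_regression", "gp_tanimoto"),
                            budget_total = 75L, greedy_n = 70L, diverse_n = 5L,
                            anchors = c(Hit1 = -6.5, Hit2 = -6.0),
                            ti_noise_sd = 0.4,
                            n_hit1 = 576L, n_hit2 = 432L,
                            pass_fraction = 0.8,
                            nns_queries = 9L, nns_k = 3L,
                            make_tsne = TRUE,
                            seed = 1L) {
  cfg <- list(smarts_closest = smarts_closest,
              rmsd_indole_max = rmsd_indole_max,
              rmsd_murcko_max = rmsd_murcko_max,
              score_max = score_max, clash_max = clash_max,
              ti = ti, al_batches = as.integer(al_batches),
              al_representations = al_representations,
              al_algorithms = al_algorithms,
              budget_total = as.integer(budget_total),
              greedy_n = as.integer(greedy_n),
              diverse_n = as.integer(diverse_n),
              anchors = anchors, ti_noise_sd = ti_noise_sd,
              n_hit1 = as.integer(n_hit1), n_hit2 = as.integer(n_hit2),
              pass_fraction = pass_fraction,
              nns_queries = as.integer(nns_queries), nns_k = as.integer(nns_k),
              make_tsne = isTRUE(make_tsne), seed = as.integer(seed))
  if (cfg$greedy_n + cfg$diverse_n != cfg$budget_total)
    .stopf("greedy_n + diverse_n must equal budget_total")
  if (!all(is.finite(c(cfg$rmsd_indole_max, cfg$rmsd_murcko_max,
                       cfg$score_max, cfg$clash_max))))
    .stopf("filter thresholds must be finite")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$anchors <- unlist(raw$anchors)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$anchors <- as.list(x$anchors)
  yaml::write_yaml(x, path)
  invisible(path)
}

## The two synthetic analog series used by the default campaign. Both cores
## carry a (tertiary, in-ring) amide so the "closest analog" SMARTS -- a
## secondary carboxamide, C(=O)[NH1] -- selects exactly the molecules whose
## variable substituent retains an amide, mirroring a pattern that preserves
## the pharmacophore groups of a hit.
.CAMPAIGN_SCAFFOLDS <- list(
  hit1 = list(
    scaffold = "O=C(c1cc2cc({R2})ccc2[nH]1)N1CCc2cc({R3})ccc2C1{R1}",
    substituents = list(
      R1 = c("", "C", "CC", "CO", "CC(=O)NC", "COC", "OC", "CCO"),
      R2 = c("", "C", "F", "Cl", "OC", "CC", "O", "CF"),
      R3 = c("", "C", "F", "Cl", "OC", "CC", "N", "O", "COC")
    )
  ),
  hit2 = list(
    scaffold = "O=C(c1ccc2cc({R2})ccc2n1)N1CCC({R1})CC1{R3}",
    substituents = list(
      R1 = c("", "C", "O", "CO", "C(=O)NC", "CC"),
      R2 = c("", "C", "F", "Cl", "OC", "CC", "O", "N"),
      R3 = c("", "C", "F", "CO", "OC", "CC", "N", "COC", "Cl")
    )
  )
)

#' Default synthetic campaign
#'
#' Enumerates two analog series around hit-like scaffolds (an indole-2-carbonyl
#' tetrahydroisoquinoline and a quinoline-2-carbonyl piperidine), assigns each
#' substituent a deterministic group contribution (seeded N(0, 0.7) kcal/mol)
#' and returns the libraries plus the affinity oracle.
#'
#' @param config a [pipeline_config()].
#' @return list with `library` (a `mol_library` with `hit_group` column),
#'   `oracle_spec` and `truth` (noiseless dG per molecule).
#' @export
default_campaign <- function(config = pipeline_config()) {
  libs <- list()
  labels_all <- character(0)
  for (grp in names(.CAMPAIGN_SCAFFOLDS)) {
    sc <- .CAMPAIGN_SCAFFOLDS[[grp]]
    n_max <- if (grp == "hit1") config$n_hit1 else config$n_hit2
    lib <- generate_analog_library(sc$scaffold, sc$substituents, n_max = n_max,
                                   seed = config$seed + .str_hash(grp) %% 1e6,
                                   id_prefix = grp)
    lib$hit_group <- grp
    libs[[grp]] <- lib
    labs <- unlist(lapply(strsplit(lib$substituents, ";", fixed = TRUE), identity))
    labels_all <- union(labels_all, paste0(grp, ":", labs))
  }
  labels_all <- sort(setdiff(labels_all, grep("=H$", labels_all, value = TRUE)))
  contrib <- .with_seed(config$seed + 77,
                        stats::setNames(stats::rnorm(length(labels_all), 0, 0.7),
                                        labels_all))
  lib <- .as_mol_library(rbind(as.data.frame(libs$hit1), as.data.frame(libs$hit2)))
  ## per-group label namespacing keeps the two series' contributions distinct
  lib$substituents <- vapply(seq_len(nrow(lib)), function(k) {
    labs <- strsplit(lib$substituents[k], ";", fixed = TRUE)[[1]]
    paste(paste0(lib$hit_group[k], ":", labs), collapse = ";")
  }, character(1))
  spec <- synthetic_oracle_spec(base_dg = -6.0, group_contributions = contrib,
                                noise_sd = config$ti_noise_sd,
                                seed = config$seed + 991)
  truth <- affinity_oracle(lib, spec, noiseless = TRUE)
  list(library = lib, oracle_spec = spec, truth = truth)
}

#' Run the full synthetic hit-optimization pipeline
#'
#' Executes library enumeration, closest-analog substructure selection, mock
#' docking with the two filter cascades, duplicate/charge hygiene, pre-AL
#' labeling (closest analogs + nearest-neighbor additions) on a hit-anchored
#' perturbation map, the AutoML active-learning loop over the AL set,
#' RBFE-to-ABFE conversion, budgeted candidate selection, and report files.
#' Deterministic for a fixed config seed.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory (created; default a tempdir subdirectory).
#' @return invisibly, the run directory; the `"summary"` attribute carries the
#'   in-memory results (counts, affinities, candidates, AL state).
#' @export
run_pipeline <- function(config = pipeline_config(), run_dir = NULL) {
  if (is.null(run_dir))
    run_dir <- file.path(tempdir(), sprintf("alfe_run_%d", config$seed))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(run_dir, "log.txt")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }

  stage <- "library"
  result <- tryCatch({
    camp <- default_campaign(config)
    lib <- camp$library
    write_molecule_library(lib, file.path(run_dir, "library.csv"))
    log_line("library: %d molecules (%d hit1, %d hit2)", nrow(lib),
             sum(lib$hit_group == "hit1"), sum(lib$hit_group == "hit2"))

    stage <- "closest_analogs"
    closest <- substructure_filter(lib, config$smarts_closest)
    log_line("closest analogs: %d", nrow(closest))

    stage <- "docking_filters"
    poses <- mock_docking(lib, camp$oracle_spec, seed = config$seed + 5,
                          pass_fraction = config$pass_fraction)
    best1 <- best_pose_per_molecule(poses, "indole")
    s1 <- stage1_filter(best1, rmsd_max = config$rmsd_indole_max,
                        score_max = config$score_max)
    best2 <- best_pose_per_molecule(poses[poses$molecule_id %in% s1, ], "murcko")
    s2 <- stage2_filter(best2, rmsd_max = config$rmsd_murcko_max,
                        score_max = config$score_max,
                        clash_max = config$clash_max)
    log_line("docking filters: stage1 %d, stage2 %d", length(s1), length(s2))

    stage <- "dedup"
    al_pool <- canonicalize_and_dedup(lib[lib$id %in% s2, , drop = FALSE])
    al_pool <- al_pool[!(al_pool$id %in% closest$id), , drop = FALSE]
    log_line("AL set after hygiene filters: %d", nrow(al_pool))

    stage <- "pre_al"
    label_store <- new.env(parent = emptyenv())
    edges <- list()
    ti_label <- function(ids, ref_id, ref_dg) {
      rows <- lib[match(ids, lib$id), , drop = FALSE]
      dg <- affinity_oracle(rows, camp$oracle_spec)  # truth + TI-scale noise
      for (k in seq_along(ids)) {
        edges[[length(edges) + 1]] <<- data.frame(
          reference_id = ref_id, target_id = ids[k],
          ddg = unname(dg[k]) - ref_dg, stderr = config$ti_noise_sd)
        assign(ids[k], unname(dg[k]), envir = label_store)
      }
      dg
    }
    pre_al_labels <- c(
      ti_label(closest$id[closest$hit_group == "hit1"], "Hit1",
               config$anchors[["Hit1"]]),
      ti_label(closest$id[closest$hit_group == "hit2"], "Hit2",
               config$anchors[["Hit2"]])
    )
    ## nearest-neighbor augmentation: top queries by computed label
    h1_labels <- pre_al_labels[names(pre_al_labels) %in%
                                 closest$id[closest$hit_group == "hit1"]]
    n_q <- min(config$nns_queries, length(h1_labels))
    nns_ids <- character(0)
    pool_h1 <- al_pool[al_pool$hit_group == "hit1", , drop = FALSE]
    if (n_q > 0 && nrow(pool_h1) >= config$nns_k) {
      queries <- lib[match(greedy_acquire(h1_labels, n_q), lib$id), , drop = FALSE]
      nn <- nearest_neighbors(queries, pool_h1, k = config$nns_k,
                              exclude = names(pre_al_labels))
      nns_ids <- nn$id
      pre_al_labels <- c(pre_al_labels,
                         ti_label(nns_ids, "Hit1", config$anchors[["Hit1"]]))
    }
    log_line("pre-AL set: %d labels (%d closest + %d NNS)",
             length(pre_al_labels), nrow(closest), length(nns_ids))

    stage <- "al_loop"
    al_pool_run <- al_pool[!(al_pool$id %in% names(pre_al_labels)), , drop = FALSE]
    feat_lib <- .as_mol_library(rbind(
      as.data.frame(al_pool_run),
      as.data.frame(lib[match(setdiff(names(pre_al_labels), al_pool_run$id),
                              lib$id), , drop = FALSE])))
    features <- lapply(stats::setNames(nm = config$al_representations),
                       function(kind) featurize(feat_lib, kind, seed = config$seed))
    ## ligand-A reference: the lowest pre-AL hit1 affinity anchors AL-era edges
    ligand_a <- greedy_acquire(h1_labels, 1)
    ligand_a_dg <- get(ligand_a, envir = label_store)
    groups <- stats::setNames(lib$hit_group[match(feat_lib$id, lib$id)], feat_lib$id)
    alcfg <- al_config(batch_schedule = config$al_batches,
                       representations = config$al_representations,
                       algorithms = config$al_algorithms,
                       scope_values = "hit1",
                       scope_until = length(config$al_batches) - 1L,
                       seed = config$seed)
    al_oracle <- function(ids) {
      grp <- lib$hit_group[match(ids, lib$id)]
      out <- numeric(0)
      if (any(grp == "hit1"))
        out <- c(out, ti_label(ids[grp == "hit1"], ligand_a, ligand_a_dg))
      if (any(grp == "hit2"))
        out <- c(out, ti_label(ids[grp == "hit2"], "Hit2", config$anchors[["Hit2"]]))
      out[ids]
    }
    al_state <- run_al_loop(al_pool_run, al_oracle, pre_al_labels, alcfg,
                            features = features, groups = groups)
    log_line("AL loop: %d iterations, %d molecules computed in total",
             length(al_state$history), nrow(al_state$train))

    stage <- "abfe_conversion"
    map <- perturbation_map(do.call(rbind, edges))
    ## Hit1 -> ligand A edge already exists (pre-AL); anchors are the two hits
    affin <- to_abfe(map, data.frame(ligand_id = names(config$anchors),
                                     dg_abs = unname(config$anchors)))
    affin <- affin[!(affin$ligand_id %in% names(config$anchors)), , drop = FALSE]
    affin$hit_group <- lib$hit_group[match(affin$ligand_id, lib$id)]
    affin$iteration <- al_state$train$iteration_added[
      match(affin$ligand_id, al_state$train$id)]
    utils::write.csv(affin, file.path(run_dir, "affinities.csv"), row.names = FALSE)
    write_perturbation_map(map, file.path(run_dir, "perturbation_map.csv"))

    stage <- "candidate_selection"
    scores <- stats::setNames(affin$dg_abs, affin$ligand_id)
    feats_sel <- features[[config$al_representations[1]]]
    hit2_ids <- affin$ligand_id[affin$hit_group == "hit2"]
    candidates <- select_candidates(
      scores, feats_sel,
      budget_total = config$budget_total, greedy_n = config$greedy_n,
      diverse_n = config$diverse_n,
      diverse_filter = function(ids, sc) intersect(ids[sc[ids] < 0], hit2_ids))
    utils::write.csv(data.frame(id = candidates,
                                dg_abs = unname(scores[candidates])),
                     file.path(run_dir, "candidates.csv"), row.names = FALSE)
    log_line("selected %d experimental candidates", length(candidates))

    stage <- "report"
    counts <- data.frame(
      stage = c("library", "closest_analogs", "stage1_filter", "stage2_filter",
                "al_set", "pre_AL", "computed", "candidates"),
      hit1 = c(sum(lib$hit_group == "hit1"),
               sum(closest$hit_group == "hit1"),
               sum(lib$hit_group[match(s1, lib$id)] == "hit1"),
               sum(lib$hit_group[match(s2, lib$id)] == "hit1"),
               sum(al_pool$hit_group == "hit1"),
               sum(lib$hit_group[match(names(pre_al_labels), lib$id)] == "hit1"),
               sum(affin$hit_group == "hit1"),
               sum(lib$hit_group[match(candidates, lib$id)] == "hit1")),
      hit2 = c(sum(lib$hit_group == "hit2"),
               sum(closest$hit_group == "hit2"),
               sum(lib$hit_group[match(s1, lib$id)] == "hit2"),
               sum(lib$hit_group[match(s2, lib$id)] == "hit2"),
               sum(al_pool$hit_group == "hit2"),
               sum(lib$hit_group[match(names(pre_al_labels), lib$id)] == "hit2"),
               sum(affin$hit_group == "hit2"),
               sum(lib$hit_group[match(candidates, lib$id)] == "hit2")))
    counts <- campaign_counts(counts)
    utils::write.csv(counts, file.path(run_dir, "stage_counts.csv"),
                     row.names = FALSE)
    hist_out <- lapply(al_state$history, function(h) {
      h$labels <- as.list(h$labels); h
    })
    jsonlite::write_json(hist_out, file.path(run_dir, "al_history.json"),
                         auto_unbox = TRUE, digits = NA)
    write_pipeline_config(config, file.path(run_dir, "config.yaml"))
    if (config$make_tsne && nrow(affin) > 95) {
      emb <- project_chemical_space(
        feats_sel[intersect(affin$ligand_id, rownames(feats_sel)), , drop = FALSE],
        seed = config$seed, perplexity = 30)
      utils::write.csv(data.frame(id = rownames(emb), emb),
                       file.path(run_dir, "tsne.csv"), row.names = FALSE)
    }
    list(counts = counts, affinities = affin, candidates = candidates,
         al_state = al_state, map = map, truth = camp$truth)
  }, error = function(e) {
    log_line("FAILED at stage '%s': %s", stage, conditionMessage(e))
    .stopf("pipeline failed at stage '%s': %s (partial outputs in %s)",
           stage, conditionMessage(e), run_dir)
  })
  out <- invisible(run_dir)
  attr(out, "summary") <- result
  out
}

#' Per-stage molecule counts of a completed run
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return data.frame with per-hit and total counts per pipeline stage.
#' @export
report_counts <- function(run_dir) {
  path <- file.path(run_dir, "stage_counts.csv")
  if (!file.exists(path)) .stopf("no stage_counts.csv in '%s'", run_dir)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
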