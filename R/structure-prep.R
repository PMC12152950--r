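#' Read a docked-pose table
#'
#' Pose tables are CSV with columns `molecule_id, pose_id, docking_score,
#' clash_component, rmsd_indole, rmsd_murcko` (the two RMSD columns may be
#' empty/NA where not computed). Scores are dimensionless (lower is better);
#' RMSD values are in Angstrom.
#'
#' @param path CSV path.
#' @return a `data.frame` of poses.
#' @export
read_pose_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "pose_id", "docking_score")
  if (!all(need %in% names(df)))
    .stopf("pose table must have columns %s", paste(need, collapse = ","))
  df
}

#' Best pose per molecule by minimal RMSD
#'
#' Selects, for each molecule, the pose minimizing the named RMSD field; ties
#' are broken by better (lower) docking score, then lower pose id. Molecules
#' whose RMSD is missing for every pose are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @param poses pose `data.frame` (see [read_pose_table()]).
#' @param rmsd_field `"indole"` or `"murcko"`, naming the `rmsd_*` column.
#' @return one-row-per-molecule pose `data.frame`.
#' @export
best_pose_per_molecule <- function(poses, rmsd_field = c("indole", "murcko")) {
  rmsd_field <- match.arg(rmsd_field)
  col <- paste0("rmsd_", rmsd_field)
  if (!col %in% names(poses)) .stopf("pose table lacks column '%s'", col)
  split_idx <- split(seq_len(nrow(poses)), poses$molecule_id)
  keep <- integer(0)
  excluded <- character(0)
  for (mol in names(split_idx)) {
    idx <- split_idx[[mol]]
    r <- poses[[col]][idx]
    if (all(is.na(r))) { excluded <- c(excluded, mol); next }
    idx <- idx[!is.na(r)]
    ord <- order(poses[[col]][idx], poses$docking_score[idx], poses$pose_id[idx])
    keep <- c(keep, idx[ord[1]])
  }
  if (length(excluded) > 0)
    .warnf("excluded %d molecule(s) with all-missing %s: %s", length(excluded),
           col, paste(utils::head(excluded, 5), collapse = ", "))
  out <- poses[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Docking filter cascades
#'
#' `stage1_filter` retains molecules from the template-free docking stage with
#' `rmsd_indole <= rmsd_max` and `docking_score <= score_max`.
#' `stage2_filter` retains molecules from the template docking stage passing
#' `rmsd_murcko <= rmsd_max`, `docking_score <= score_max` and
#' `clash_component <= clash_max`. All boundaries are inclusive.
#'
#' @param best_poses one pose per molecule (see [best_pose_per_molecule()]).
#' @param rmsd_max,score_max,clash_max inclusive thresholds; defaults are the
#'   workflow's standard cutoffs (5 A / 4 A, score -6, clash 0.5).
#' @return character vector of surviving molecule ids.
#' @export
stage1_filter <- function(best_poses, rmsd_max = 5.0, score_max = -6.0) {
  need <- c("rmsd_indole", "docking_score")
  if (!all(need %in% names(best_poses)))
    .stopf("stage1 filter needs columns %s", paste(need, collapse = ","))
  ok <- best_poses$rmsd_indole <= rmsd_max & best_poses$docking_score <= score_max
  best_poses$molecule_id[which(ok)]
}

#' @rdname stage1_filter
#' @export
stage2_filter <- function(best_poses, rmsd_max = 4.0, score_max = -6.0,
                          clash_max = 0.5) {
  need <- c("rmsd_murcko", "docking_score", "clash_component")
  if (!all(need %in% names(best_poses)))
    .stopf("stage2 filter needs columns %s", paste(need, collapse = ","))
  ok <- best_poses$rmsd_murcko <= rmsd_max &
    best_poses$docking_score <= score_max &
    best_poses$clash_component <= clash_max
  best_poses$molecule_id[which(ok)]
}

#' Toy trajectory container
#'
#' @param coords numeric array `frames x atoms x 3` (Angstrom), or a list of
#'   `atoms x 3` matrices with identical dimensions.
#' @param atom_roles per-atom role: `"ligand_heavy"`, `"protein_calpha"` or
#'   `"other"`. Only the first two enter RMSD computations.
#' @return an object of class `toy_trajectory`.
#' @export
toy_trajectory <- function(coords, atom_roles) {
  if (is.list(coords)) {
    n_atom <- nrow(coords[[1]])
    stopifnot(all(vapply(coords, nrow, 1L) == n_atom))
    arr <- array(0, c(length(coords), n_atom, 3))
    for (f in seq_along(coords)) arr[f, , ] <- as.matrix(coords[[f]])
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  atom_roles <- match.arg(atom_roles, c("ligand_heavy", "protein_calpha", "other"),
                          several.ok = TRUE)
  atom_roles <- rep_len(atom_roles, dim(coords)[2])
  structure(list(coords = coords, atom_roles = atom_roles),
            class = "toy_trajectory")
}

#' Representative frame of a trajectory
#'
#' Discards the leading `discard_fraction` of frames, averages the coordinates
#' of ligand heavy atoms and protein C-alpha atoms over the retained window,
#' and returns the retained frame with minimal (unweighted, unfitted) RMSD to
#' that average structure. Ties go to the earliest frame.
#'
#' @param traj a [toy_trajectory()].
#' @param discard_fraction fraction of leading frames to discard
#'   (default 0.1, mirroring discarding the first tenth of production MD).
#' @return the 1-based index of the representative frame, in original frame
#'   numbering.
#' @export
representative_frame <- function(traj, discard_fraction = 0.1) {
  stopifnot(inherits(traj, "toy_trajectory"))
  if (!(discard_fraction >= 0 && discard_fraction < 1))
    .stopf("discard_fraction must be in [0, 1)")
  n_frames <- dim(traj$coords)[1]
  first <- floor(discard_fraction * n_frames) + 1L
  if (first > n_frames) .stopf("no frames retained after discard")
  sel <- traj$atom_roles %in% c("ligand_heavy", "protein_calpha")
  if (!any(sel)) .stopf("trajectory has no ligand_heavy or protein_calpha atoms")
  sub <- traj$coords[first:n_frames, sel, , drop = FALSE]
  avg <- apply(sub, c(2, 3), mean)
  rmsd <- vapply(seq_len(dim(sub)[1]), function(f) {
    d <- sub[f, , , drop = TRUE] - avg
    sqrt(mean(rowSums(matrix(d, ncol = 3)^2)))
  }, numeric(1))
  first + which.min(rmsd) - 1L
}

#' Distance-constrained maximum common substructure atom mapping
#'
#' Finds the largest connected common substructure of two molecules (heavy
#' atoms, element- and bond-order-matched) restricted to atom pairs whose 3D
#' distance does not exceed `dmax`. An empty mapping is a valid result and
#' signals a fully decoupled transformation.
#'
#' @param ref_smiles,target_smiles SMILES of the two molecules.
#' @param ref_coords,target_coords numeric `heavy_atoms x 3` matrices in the
#'   molecules' SMILES atom order (Angstrom).
#' @param dmax maximum allowed distance between mapped atoms (default 1.1 A).
#' @param timeout search time budget in seconds (default 60).
#' @return list with `pairs` (data.frame `ref_atom`, `target_atom`, `distance`)
#'   and `max_pair_distance`.
#' @export
map_atoms <- function(ref_smiles, ref_coords, target_smiles, target_coords,
                      dmax = 1.1, timeout = 60) {
  g1 <- .mol_graphs(ref_smiles)[[1]]
  g2 <- .mol_graphs(target_smiles)[[1]]
  ref_coords <- as.matrix(ref_coords); target_coords <- as.matrix(target_coords)
  if (nrow(ref_coords) != length(g1$elem) || nrow(target_coords) != length(g2$elem))
    .stopf("coordinate rows must cover all heavy atoms")
  n1 <- length(g1$elem); n2 <- length(g2$elem)
  dxy <- matrix(0, n1, n2)
  for (i in seq_len(n1))
    dxy[i, ] <- sqrt(colSums((t(target_coords) - ref_coords[i, ])^2))
  cand <- which(outer(g1$elem, g2$elem, "==") & dxy <= dmax, arr.ind = TRUE)
  empty <- list(pairs = data.frame(ref_atom = integer(0), target_atom = integer(0),
                                   distance = numeric(0)),
                max_pair_distance = dmax)
  if (nrow(cand) == 0) return(empty)

  bond_order <- function(g, n) {
    m <- matrix(0L, n, n)
    if (nrow(g$bonds) > 0) {
      m[g$bonds[, c("a", "b"), drop = FALSE]] <- g$bonds[, "order"]
      m[g$bonds[, c("b", "a"), drop = FALSE]] <- g$bonds[, "order"]
    }
    m
  }
  B1 <- bond_order(g1, n1); B2 <- bond_order(g2, n2)

  n_cand <- nrow(cand)
  best <- integer(0)
  t_start <- Sys.time()

  ## pairwise compatibility of candidate pairs: equal bond order on both sides
  ## (0/0 counts as compatible but not adjacent); sharing an atom conflicts.
  compat <- matrix(FALSE, n_cand, n_cand)
  adjac <- matrix(FALSE, n_cand, n_cand)
  for (x in seq_len(n_cand)) for (y in seq_len(n_cand)) {
    if (x == y) next
    if (cand[x, 1] == cand[y, 1] || cand[x, 2] == cand[y, 2]) next
    o1 <- B1[cand[x, 1], cand[y, 1]]; o2 <- B2[cand[x, 2], cand[y, 2]]
    if (o1 == o2) { compat[x, y] <- TRUE; if (o1 > 0) adjac[x, y] <- TRUE }
  }

  ## branch and bound over candidate pairs: grow a connected consistent set;
  ## include/exclude branching so each subset is visited once.
  search <- function(sel, allowed) {
    if (length(sel) > length(best)) best <<- sel
    if (length(sel) + length(allowed) <= length(best)) return(invisible())
    if (as.numeric(Sys.time() - t_start, units = "secs") > timeout) return(invisible())
    frontier <- allowed[vapply(allowed, function(c2)
      all(compat[sel, c2]) && any(adjac[sel, c2]), logical(1))]
    if (length(frontier) == 0) return(invisible())
    c2 <- frontier[1]
    search(c(sel, c2), setdiff(allowed, c2))
    search(sel, setdiff(allowed, c2))
    invisible()
  }
  for (ci in seq_len(n_cand)) {
    if (n_cand - ci + 1 <= length(best)) break
    later <- if (ci < n_cand) seq(ci + 1, n_cand) else integer(0)
    search(ci, later)
  }
  if (length(best) == 0) return(empty)
  pairs <- data.frame(ref_atom = as.integer(cand[best, 1]),
                      target_atom = as.integer(cand[best, 2]))
  pairs$distance <- dxy[cbind(pairs$ref_atom, pairs$target_atom)]
  pairs <- pairs[order(pairs$ref_atom), , drop = FALSE]
  rownames(pairs) <- NULL
  stopifnot(all(pairs$distance <= dmax),
            !anyDuplicated(pairs$ref_atom), !anyDuplicated(pairs$target_atom))
  list(pairs = pairs, max_pair_distance = dmax)
}
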