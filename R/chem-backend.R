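## Low-level bridge to the OpenBabel toolkit (via ChemmineOB) and to the
## ChemmineR SDF container. Everything above this file works with plain R
## structures: character SMILES, atom/bond tables, 0/1 fingerprint matrices.

.smiles_block <- function(smiles, ids) {
  paste0(paste(smiles, ids), "\n", collapse = "")
}

## Canonical isomeric SMILES for a vector of inputs. OpenBabel aborts batch
## conversion at the first unparseable record, so conversion is resumed after
## each failure; failures come back as NA.
.ob_canonical <- function(smiles, ids = NULL) {
  n <- length(smiles)
  if (n == 0) return(character(0))
  tmp_ids <- paste0("r", seq_len(n))
  out <- rep(NA_character_, n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    block <- .smiles_block(smiles[todo], tmp_ids[todo])
    res <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", block)),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    got_ids <- sub("^.*[ \t]", "", lines)
    got_smi <- sub("[ \t][^ \t]*$", "", lines)
    ok <- match(got_ids, tmp_ids[todo])
    ok <- ok[!is.na(ok)]
    if (length(ok) > 0) out[todo[ok]] <- got_smi[seq_along(ok)]
    n_ok <- length(ok)
    if (n_ok == length(todo)) break
    ## the (n_ok+1)-th pending record is the offender: leave NA, resume after it
    todo <- todo[-seq_len(n_ok + 1)]
  }
  out
}

.smiles_parse_ok <- function(smiles) !is.na(.ob_canonical(smiles))

## ChemmineR SDFset from SMILES (2D coordinates).
.as_sdfset <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  ChemmineR::smiles2sdf(stats::setNames(smiles, ids))
}

## Per-molecule heavy-atom graph: elements, bond table (a, b, order),
## aromatic flags (ring perception), implicit hydrogen counts, input coords.
.DEFAULT_VALENCE <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1, B = 3, Si = 4
)
.MDL_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)

.mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  elem <- sub("_.*$", "", rownames(ab))
  coords <- matrix(0, n, 3)
  kc <- min(3L, ncol(ab))
  coords[, seq_len(kc)] <- ab[, seq_len(kc)]
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- unname(.MDL_CHARGE[as.character(charge_code)])
  charge[is.na(charge)] <- 0
  ## single-atom molecules parse with a degenerate bond block
  bonds <- if (nrow(bb) > 0 && ncol(bb) >= 3 && n > 1) {
    cbind(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]), order = as.integer(bb[, 3]))
  } else {
    cbind(a = integer(0), b = integer(0), order = integer(0))
  }
  valsum <- rep(0L, n)
  for (i in seq_len(nrow(bonds))) {
    o <- bonds[i, "order"]
    valsum[bonds[i, "a"]] <- valsum[bonds[i, "a"]] + o
    valsum[bonds[i, "b"]] <- valsum[bonds[i, "b"]] + o
  }
  defval <- .DEFAULT_VALENCE[elem]
  defval[is.na(defval)] <- valsum[is.na(defval)]
  n_h <- pmax(0L, as.integer(defval + charge - valsum))
  arom <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    rr <- tryCatch(
      ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = FALSE),
      error = function(e) NULL
    )
    if (!is.null(rr) && length(rr$RINGS) > 0) {
      for (k in seq_along(rr$RINGS)) {
        if (isTRUE(rr$AROMATIC[[k]])) {
          idx <- match(rr$RINGS[[k]], rownames(ab))
          arom[idx[!is.na(idx)]] <- TRUE
        }
      }
    }
  }
  list(elem = elem, bonds = bonds, coords = coords, charge = charge,
       n_h = n_h, aromatic = arom)
}

.mol_graphs <- function(smiles, ids = NULL) {
  sdfs <- .as_sdfset(smiles, ids)
  lapply(seq_along(smiles), function(i) {
    g <- .mol_graph(sdfs[[i]])
    ## single-atom molecules parse to a degenerate SDF whose atom label drops
    ## the element symbol; recover it from the SMILES itself
    if (length(g$elem) == 1 && !grepl("^[A-Z][a-z]?$", g$elem)) {
      g$elem <- sub("^\\[?([A-Z][a-z]?).*$", "\\1", smiles[i])
    }
    g
  })
}

## 3D coordinates from OpenBabel's deterministic structure generation.
## Returns a list of n x 3 matrices (NULL where generation failed).
.gen3d <- function(smiles, ids = NULL) {
  n <- length(smiles)
  if (is.null(ids)) ids <- paste0("m", seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sdftxt <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "SDF", .smiles_block(smiles[i], ids[i]),
        options = data.frame(names = "gen3D", args = "")
      )),
      error = function(e) NULL
    )
    if (is.null(sdftxt) || !nzchar(sdftxt)) next
    sdf <- tryCatch(
      ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(sdftxt)))[[1]],
      error = function(e) NULL
    )
    if (is.null(sdf)) next
    ab <- ChemmineR::atomblock(sdf)
    heavy <- sub("_.*$", "", rownames(ab)) != "H"
    out[[i]] <- ab[heavy, 1:3, drop = FALSE]
  }
  out
}

## Number of SMARTS matches per molecule.
.smarts_counts <- function(smiles, pattern) {
  if (length(smiles) == 0) return(integer(0))
  block <- .smiles_block(smiles, paste0("q", seq_along(smiles)))
  res <- ChemmineOB::forEachMol("SMILES", block, function(mol) {
    ChemmineOB::smartsSearch_OB(list(mol), pattern, uniqueMatches = TRUE)
  })
  unlist(res, use.names = FALSE)
}

.smarts_valid <- function(pattern) {
  ok <- tryCatch({
    .smarts_counts("C", pattern)
    TRUE
  }, error = function(e) FALSE)
  ok
}

## Native OpenBabel fingerprint bits. Fast path reads the packed words through
## ChemmineOB's low-level wrappers (bit order verified against the exported
## accessor); falls back to ChemmineOB::fingerprint_OB.
.ob_fingerprint <- function(smiles, name) {
  if (length(smiles) == 0) return(matrix(0L, 0, 0))
  block <- .smiles_block(smiles, paste0("m", seq_along(smiles)))
  fast <- tryCatch({
    find_fp <- get("OBFingerprint_FindFingerprint", envir = asNamespace("ChemmineOB"))
    get_fp <- get("OBFingerprint_GetFingerprint", envir = asNamespace("ChemmineOB"))
    fph <- find_fp(name)
    rows <- ChemmineOB::forEachMol("SMILES", block, function(mol) {
      words <- get_fp(fph, mol, numeric(1))[[2]]
      as.integer(intToBits(as.integer(words)))
    })
    do.call(rbind, rows)
  }, error = function(e) NULL)
  if (!is.null(fast)) return(fast)
  rows <- ChemmineOB::forEachMol("SMILES", block, function(mol) {
    ChemmineOB::fingerprint_OB(list(mol), name)
  })
  m <- do.call(rbind, rows)
  storage.mode(m) <- "integer"
  m
}

## Net formal charge from the InChI /q and /p layers (zwitterions are net 0).
.net_charge <- function(sdfset) {
  props <- ChemmineR::propOB(sdfset)
  vapply(props$InChI, function(inchi) {
    q <- 0
    for (layer in c("q", "p")) {
      m <- regmatches(inchi, regexec(sprintf("/%s([+-][0-9]+(?:;[+-][0-9]+)*)", layer), inchi))[[1]]
      if (length(m) == 2) q <- q + sum(as.numeric(strsplit(m[2], ";", fixed = TRUE)[[1]]))
    }
    q
  }, numeric(1), USE.NAMES = FALSE)
}

## Canonical SMILES of an atom subset of one molecule (used for scaffolds):
## rebuilds the SDF atom/bond blocks and round-trips through OpenBabel.
.subgraph_smiles <- function(sdf, keep_idx) {
  if (length(keep_idx) == 0) return("")
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  keep_idx <- sort(keep_idx)
  sub_ab <- ab[keep_idx, , drop = FALSE]
  sub_bb <- bb[bb[, 1] %in% keep_idx & bb[, 2] %in% keep_idx, , drop = FALSE]
  remap <- match(seq_len(nrow(ab)), keep_idx)
  sub_bb[, 1] <- remap[sub_bb[, 1]]
  sub_bb[, 2] <- remap[sub_bb[, 2]]
  s <- sdf
  s@atomblock <- sub_ab
  s@bondblock <- sub_bb
  h <- ChemmineR::header(s)
  h["Counts_Line"] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                              nrow(sub_ab), nrow(sub_bb))
  s@header <- h
  smi <- as.character(ChemmineR::sdf2smiles(ChemmineR::SDFset(list(s), "sub")))
  out <- .ob_canonical(smi)
  if (is.na(out)) "" else out
}
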