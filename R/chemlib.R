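#' Build a molecule library
#'
#' A molecule library is a plain `data.frame` with one row per compound and
#' columns `id`, `smiles`, `net_formal_charge`, `scaffold_smiles` and
#' `source_tag`. SMILES are canonicalized (isomeric) on construction;
#' unparseable records are dropped with a warning and recorded in the
#' `"rejected"` attribute.
#'
#' @param id character vector of unique identifiers.
#' @param smiles character vector of SMILES strings.
#' @param source_tag provenance tag per record: `"closest"`, `"general"` or
#'   `"synthetic"`.
#' @param compute_scaffolds if `TRUE` (default) the Murcko scaffold of every
#'   record is computed; set `FALSE` to defer (e.g. for large pools).
#' @param canonicalize if `TRUE` (default) store canonical isomeric SMILES.
#' @return a `data.frame` of class `mol_library`.
#' @seealso [canonicalize_and_dedup()], [murcko_scaffold()], [featurize()]
#' @export
molecule_library <- function(id, smiles,
                             source_tag = "synthetic",
                             compute_scaffolds = TRUE,
                             canonicalize = TRUE) {
  stopifnot(length(id) == length(smiles))
  id <- as.character(id)
  if (anyDuplicated(id)) .stopf("duplicate ids in library: %s",
                                paste(unique(id[duplicated(id)]), collapse = ", "))
  source_tag <- rep_len(match.arg(source_tag, c("closest", "general", "synthetic"),
                                  several.ok = FALSE), length(id))
  can <- .ob_canonical(smiles)
  bad <- is.na(can)
  rejected <- data.frame(id = id[bad], smiles = smiles[bad],
                         reason = rep("unparseable SMILES", sum(bad)),
                         stringsAsFactors = FALSE)
  if (any(bad)) {
    .warnf("%d record(s) dropped (unparseable SMILES): %s",
           sum(bad), paste(utils::head(id[bad], 5), collapse = ", "))
    id <- id[!bad]; smiles <- smiles[!bad]; can <- can[!bad]
    source_tag <- source_tag[!bad]
  }
  smi_out <- if (canonicalize) can else smiles
  lib <- data.frame(id = id, smiles = smi_out,
                    net_formal_charge = NA_real_,
                    scaffold_smiles = NA_character_,
                    source_tag = source_tag,
                    stringsAsFactors = FALSE)
  if (nrow(lib) > 0) {
    lib$net_formal_charge <- .net_charge(.as_sdfset(lib$smiles, lib$id))
    if (compute_scaffolds) lib$scaffold_smiles <- murcko_scaffold(lib$smiles)
  }
  attr(lib, "rejected") <- rejected
  class(lib) <- c("mol_library", "data.frame")
  lib
}

#' @export
print.mol_library <- function(x, ...) {
  cat(sprintf("<mol_library> %d molecules\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

.as_mol_library <- function(df) {
  class(df) <- c("mol_library", "data.frame")
  df
}

#' Read / write molecule libraries
#'
#' CSV files must carry a header with at least `id,smiles` (optional
#' `source_tag`); `.smi` files are whitespace-separated `smiles id` with no
#' header.
#'
#' @param path file path (`.csv` or `.smi`).
#' @param ... passed to [molecule_library()].
#' @return a `mol_library`.
#' @export
read_molecule_library <- function(path, ...) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 2) .stopf("'%s': .smi files need 'smiles id' columns", path)
    return(molecule_library(id = raw[[2]], smiles = raw[[1]], ...))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(raw)))
    .stopf("'%s' must have columns id,smiles", path)
  args <- list(id = raw$id, smiles = raw$smiles, ...)
  if ("source_tag" %in% names(raw) && is.null(args$source_tag))
    args$source_tag <- raw$source_tag[1]
  do.call(molecule_library, args)
}

#' @rdname read_molecule_library
#' @param lib a `mol_library`.
#' @export
write_molecule_library <- function(lib, path) {
  utils::write.csv(as.data.frame(lib), path, row.names = FALSE)
  invisible(path)
}

#' Canonicalize, deduplicate and drop charged molecules
#'
#' Library hygiene applied before free-energy calculations: one record per
#' canonical isomeric SMILES (the first id wins), records with nonzero net
#' formal charge removed. Unparseable SMILES are rejected into the report
#' rather than raising an error.
#'
#' @param records a `mol_library` or a data.frame with `id`, `smiles` columns.
#' @return the filtered `mol_library`; per-record removals are available via
#'   [dedup_report()].
#' @export
canonicalize_and_dedup <- function(records) {
  if (!all(c("id", "smiles") %in% names(records)))
    .stopf("records must have columns id,smiles")
  can <- .ob_canonical(records$smiles)
  report <- data.frame(id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  bad <- is.na(can)
  if (any(bad)) {
    report <- rbind(report, data.frame(id = records$id[bad],
                                       reason = "unparseable SMILES"))
    records <- records[!bad, , drop = FALSE]
    can <- can[!bad]
  }
  records$smiles <- can
  charge <- if ("net_formal_charge" %in% names(records) &&
                !anyNA(records$net_formal_charge)) {
    records$net_formal_charge
  } else if (nrow(records) > 0) {
    .net_charge(.as_sdfset(records$smiles, records$id))
  } else numeric(0)
  records$net_formal_charge <- charge
  charged <- charge != 0
  if (any(charged)) {
    report <- rbind(report, data.frame(id = records$id[charged],
                                       reason = "nonzero net formal charge"))
    records <- records[!charged, , drop = FALSE]
  }
  dup <- duplicated(records$smiles)
  if (any(dup)) {
    report <- rbind(report, data.frame(id = records$id[dup],
                                       reason = "duplicate canonical SMILES"))
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  out <- .as_mol_library(records)
  attr(out, "dedup_report") <- report
  out
}

#' @rdname canonicalize_and_dedup
#' @param x output of [canonicalize_and_dedup()].
#' @export
dedup_report <- function(x) attr(x, "dedup_report")

#' Filter a library by SMARTS substructure
#'
#' Keeps exactly the records whose molecule contains at least one match of the
#' pattern, preserving input order. The operation is idempotent.
#'
#' @param records a `mol_library`.
#' @param pattern a SMARTS string.
#' @return the matching subset of `records`.
#' @export
substructure_filter <- function(records, pattern) {
  if (!.smarts_valid(pattern))
    .stopf("invalid SMARTS pattern: '%s'", pattern)
  if (nrow(records) == 0) return(records)
  counts <- .smarts_counts(records$smiles, pattern)
  out <- records[counts >= 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Murcko scaffold of a molecule
#'
#' The ring systems plus the linkers connecting them, with acyclic side chains
#' pruned; atoms double-bonded to a retained atom (e.g. exocyclic carbonyl
#' oxygens) are retained, following the usual Bemis-Murcko convention. Acyclic
#' molecules return the empty string.
#'
#' @param smiles character vector of SMILES (vectorized).
#' @return character vector of canonical scaffold SMILES ("" if acyclic).
#' @export
murcko_scaffold <- function(smiles) {
  n <- length(smiles)
  if (n == 0) return(character(0))
  can <- .ob_canonical(smiles)
  if (anyNA(can)) .stopf("unparseable SMILES: '%s'", smiles[which(is.na(can))[1]])
  sdfs <- .as_sdfset(can)
  out <- character(n)
  for (i in seq_len(n)) {
    sdf <- sdfs[[i]]
    g <- .mol_graph(sdf)
    n_atoms <- length(g$elem)
    bonds <- g$bonds
    keep <- rep(TRUE, n_atoms)
    ## iterative leaf pruning leaves exactly rings + inter-ring linkers
    repeat {
      idx <- which(keep)
      if (length(idx) == 0) break
      sub <- bonds[keep[bonds[, "a"]] & keep[bonds[, "b"]], , drop = FALSE]
      deg <- tabulate(c(sub[, "a"], sub[, "b"]), nbins = n_atoms)
      leaves <- idx[deg[idx] <= 1]
      if (length(leaves) == 0) break
      keep[leaves] <- FALSE
    }
    if (!any(keep)) { out[i] <- ""; next }
    ## re-attach atoms multiply bonded to the scaffold (exocyclic =O, =N)
    repeat {
      add <- bonds[, "order"] >= 2 &
        xor(keep[bonds[, "a"]], keep[bonds[, "b"]])
      if (!any(add)) break
      keep[c(bonds[add, "a"], bonds[add, "b"])] <- TRUE
    }
    out[i] <- .subgraph_smiles(sdf, which(keep))
  }
  out
}

#' Molecular fingerprints
#'
#' Binary fingerprint matrix for a library. Kinds:
#' \describe{
#'   \item{`ecfp6_2048`}{extended-connectivity fingerprint, radius 3
#'     (OpenBabel ECFP6 folded to 2048 bits).}
#'   \item{`path7_2048`}{linear-path fingerprint, paths up to 7 bonds, hashed
#'     to 2048 bits.}
#'   \item{`ph4_2d_1024`}{pharmacophore pair fingerprint on topological
#'     distances, 1024 bits.}
#'   \item{`ph4_3d_1024`}{pharmacophore pair fingerprint on 3D distances from
#'     a deterministically generated conformer, 1024 bits.}
#'   \item{`e3fp_default`}{iterative 3D shell fingerprint on the generated
#'     conformer, 1024 bits.}
#' }
#' Featurization is deterministic for a fixed `(smiles, kind, seed)`. Records
#' whose conformer generation fails (3D kinds only) are skipped; their ids are
#' returned in the `"skipped"` attribute.
#'
#' @param records a `mol_library`, or a character vector of SMILES.
#' @param kind fingerprint kind (see above).
#' @param seed integer seed for conformer-dependent kinds.
#' @return integer 0/1 matrix, one row per molecule, rownames = ids,
#'   with attributes `kind` and `skipped`.
#' @export
featurize <- function(records, kind = c("ecfp6_2048", "path7_2048",
                                        "ph4_2d_1024", "ph4_3d_1024",
                                        "e3fp_default"),
                      seed = 1L) {
  kind <- match.arg(kind)
  if (is.character(records)) {
    records <- data.frame(id = if (is.null(names(records)))
      paste0("m", seq_along(records)) else names(records),
      smiles = unname(records), stringsAsFactors = FALSE)
  }
  smiles <- records$smiles
  ids <- records$id
  skipped <- character(0)
  m <- switch(kind,
    ecfp6_2048 = {
      raw <- .ob_fingerprint(smiles, "ECFP6")
      fold <- raw[, 1:2048, drop = FALSE] | raw[, 2049:4096, drop = FALSE]
      storage.mode(fold) <- "integer"
      fold
    },
    path7_2048 = .fp_path7(smiles),
    ph4_2d_1024 = .fp_ph4(smiles, mode = "2d"),
    ph4_3d_1024 = {
      r <- .fp_ph4(smiles, mode = "3d", seed = seed)
      skipped <- attr(r, "skipped") %||% character(0)
      r
    },
    e3fp_default = {
      r <- .fp_e3fp(smiles, seed = seed)
      skipped <- attr(r, "skipped") %||% character(0)
      r
    }
  )
  keep <- if (length(skipped)) !(seq_along(ids) %in% skipped) else rep(TRUE, length(ids))
  m <- m[keep, , drop = FALSE]
  rownames(m) <- ids[keep]
  attr(m, "kind") <- kind
  attr(m, "skipped") <- ids[!keep]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tanimoto distance between binary fingerprints
#'
#' `1 - |a AND b| / |a OR b|`. Two all-zero fingerprints have distance 0 by
#' convention (identical objects).
#'
#' @param a,b binary vectors of equal length (and equal `kind` when present).
#' @return a number in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  ka <- attr(a, "kind"); kb <- attr(b, "kind")
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb))
    .stopf("fingerprint kind mismatch: %s vs %s", ka, kb)
  if (length(a) != length(b)) .stopf("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(0)
  1 - sum(a & b) / un
}

## Pairwise Tanimoto distance matrix between fingerprint matrices (rows).
.tanimoto_matrix <- function(A, B) {
  A <- matrix(as.numeric(A), nrow = nrow(A), dimnames = dimnames(A))
  B <- matrix(as.numeric(B), nrow = nrow(B), dimnames = dimnames(B))
  inter <- A %*% t(B)
  un <- outer(rowSums(A), rowSums(B), "+") - inter
  d <- 1 - inter / un
  d[un == 0] <- 0
  d
}

#' Nearest-neighbor search by Tanimoto distance on ECFP6 fingerprints
#'
#' For each query, the `k` pool members with the smallest Tanimoto distance
#' (ties broken by pool order); the union of all neighbor sets, deduplicated by
#' id in order of first appearance.
#'
#' @param queries,pool `mol_library` objects.
#' @param k neighbors per query.
#' @param exclude character vector of pool ids to exclude (e.g. queries
#'   already computed).
#' @return a `mol_library` of unique neighbors.
#' @export
nearest_neighbors <- function(queries, pool, k = 3L, exclude = character(0)) {
  if (!.is_count(k) || k < 1) .stopf("k must be a positive integer")
  pool_use <- pool[!(pool$id %in% exclude), , drop = FALSE]
  if (k > nrow(pool_use)) .stopf("k (%d) exceeds pool size (%d)", k, nrow(pool_use))
  fq <- featurize(queries, "ecfp6_2048")
  fp <- featurize(pool_use, "ecfp6_2048")
  d <- .tanimoto_matrix(fq, fp)
  picked <- character(0)
  for (i in seq_len(nrow(d))) {
    ord <- order(d[i, ], seq_len(ncol(d)))[seq_len(k)]
    picked <- c(picked, pool_use$id[ord])
  }
  picked <- unique(picked)
  out <- pool_use[match(picked, pool_use$id), , drop = FALSE]
  rownames(out) <- NULL
  .as_mol_library(out)
}
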