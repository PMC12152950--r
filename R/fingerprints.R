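## In-package fingerprint engines operating on the heavy-atom graph.
## These cover the kinds whose declared lengths no installed R package
## provides; bit hashing is the package's own deterministic string hash,
## so bits are stable within and across runs on the same inputs.

## Linear-path fingerprint: all simple paths of 0..max_len bonds, encoded as
## element / bond-order strings (canonical direction = lexicographic min of
## forward and reverse), hashed to `nbits`.
.fp_path7 <- function(smiles, max_len = 7L, nbits = 2048L) {
  graphs <- .mol_graphs(smiles)
  m <- matrix(0L, length(smiles), nbits)
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    n <- length(g$elem)
    if (n == 0) next
    adj <- vector("list", n)
    if (nrow(g$bonds) > 0) {
      for (b in seq_len(nrow(g$bonds))) {
        i <- g$bonds[b, "a"]; j <- g$bonds[b, "b"]; o <- g$bonds[b, "order"]
        adj[[i]] <- rbind(adj[[i]], c(j, o))
        adj[[j]] <- rbind(adj[[j]], c(i, o))
      }
    }
    lab <- ifelse(g$aromatic, paste0(g$elem, "ar"), g$elem)
    keys <- new.env(hash = TRUE)
    walk <- function(path, key_fwd) {
      key_rev <- .path_key_rev(path, lab, adj)
      key <- if (key_fwd <= key_rev) key_fwd else key_rev
      assign(key, TRUE, envir = keys)
      if (length(path) > max_len) return(invisible())
      a <- path[length(path)]
      nb <- adj[[a]]
      if (is.null(nb)) return(invisible())
      for (r in seq_len(nrow(nb))) {
        nxt <- nb[r, 1]
        if (nxt %in% path) next
        walk(c(path, nxt), paste0(key_fwd, nb[r, 2], lab[nxt]))
      }
      invisible()
    }
    for (a in seq_len(n)) walk(a, lab[a])
    for (key in ls(keys)) {
      m[gi, (.str_hash(key) %% nbits) + 1] <- 1L
    }
  }
  m
}

.path_key_rev <- function(path, lab, adj) {
  k <- lab[path[length(path)]]
  if (length(path) == 1) return(k)
  for (i in seq(length(path) - 1, 1)) {
    nb <- adj[[path[i + 1]]]
    o <- nb[nb[, 1] == path[i], 2][1]
    k <- paste0(k, o, lab[path[i]])
  }
  k
}

## Pharmacophore feature typing on the heavy-atom graph.
.ph4_features <- function(g) {
  feats <- list()
  is_no <- g$elem %in% c("N", "O")
  donor <- is_no & g$n_h > 0
  acceptor <- is_no
  aromatic <- g$aromatic
  hetero_adj <- rep(FALSE, length(g$elem))
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, "a"]; j <- g$bonds[b, "b"]
      if (g$elem[j] %in% c("N", "O", "S")) hetero_adj[i] <- TRUE
      if (g$elem[i] %in% c("N", "O", "S")) hetero_adj[j] <- TRUE
    }
  }
  hydrophobe <- g$elem == "C" & !aromatic & !hetero_adj
  anion <- g$charge < 0
  cation <- g$charge > 0
  list(D = which(donor), A = which(acceptor), R = which(aromatic),
       H = which(hydrophobe), N = which(anion), P = which(cation))
}

## Pharmacophore-pair fingerprint: (type_i, type_j, distance bin) hashed to
## `nbits`. 2D mode uses topological (bond-count) distances capped at 7;
## 3D mode bins Euclidean distances from a generated conformer.
.fp_ph4 <- function(smiles, mode = c("2d", "3d"), nbits = 1024L, seed = 1L) {
  mode <- match.arg(mode)
  graphs <- .mol_graphs(smiles)
  coords <- NULL
  skipped <- integer(0)
  if (mode == "3d") {
    coords <- .gen3d(.ob_canonical(smiles))
    skipped <- which(vapply(coords, is.null, logical(1)))
  }
  m <- matrix(0L, length(smiles), nbits)
  breaks3d <- c(0, 2, 3, 4, 5, 6, 8, 10, Inf)
  for (gi in seq_along(graphs)) {
    if (gi %in% skipped) next
    g <- graphs[[gi]]
    n <- length(g$elem)
    fts <- .ph4_features(g)
    atom_types <- lapply(seq_len(n), function(a)
      names(fts)[vapply(fts, function(v) a %in% v, logical(1))])
    dm <- if (mode == "2d") {
      gr <- igraph::make_empty_graph(n, directed = FALSE)
      if (nrow(g$bonds) > 0)
        gr <- igraph::add_edges(gr, t(g$bonds[, c("a", "b"), drop = FALSE]))
      pmin(igraph::distances(gr), 7)
    } else {
      as.matrix(stats::dist(coords[[gi]]))
    }
    for (a in seq_len(n)) {
      ta <- atom_types[[a]]
      if (length(ta) == 0) next
      for (b in a:n) {
        tb <- atom_types[[b]]
        if (length(tb) == 0) next
        bin <- if (mode == "2d") dm[a, b] else findInterval(dm[a, b], breaks3d)
        if (!is.finite(bin)) next
        for (x in ta) for (y in tb) {
          pair <- if (x <= y) c(x, y) else c(y, x)
          key <- paste0(pair[1], "|", pair[2], "|", bin)
          m[gi, (.str_hash(key) %% nbits) + 1] <- 1L
        }
      }
    }
  }
  attr(m, "skipped") <- skipped
  m
}

## Iterative 3D shell fingerprint (E3FP-style): atom identifiers start from
## the element symbol and are re-hashed each level from the sorted identifiers
## of atoms within a growing radial shell. Default 5 levels, shell radius
## increment 1.718 A, 1024 bits.
.fp_e3fp <- function(smiles, nbits = 1024L, levels = 5L, shell = 1.718, seed = 1L) {
  coords <- .gen3d(.ob_canonical(smiles))
  graphs <- .mol_graphs(smiles)
  skipped <- which(vapply(coords, is.null, logical(1)))
  m <- matrix(0L, length(smiles), nbits)
  for (gi in seq_along(graphs)) {
    if (gi %in% skipped) next
    g <- graphs[[gi]]
    xyz <- coords[[gi]]
    n <- length(g$elem)
    dm <- as.matrix(stats::dist(xyz))
    ident <- vapply(g$elem, .str_hash, numeric(1))
    all_ids <- ident
    for (lev in seq_len(levels)) {
      r <- lev * shell
      new_ident <- numeric(n)
      for (a in seq_len(n)) {
        nb <- setdiff(which(dm[a, ] <= r), a)
        nb_ids <- sort(ident[nb])
        new_ident[a] <- .hash_ints(c(lev, ident[a], nb_ids))
      }
      ident <- new_ident
      all_ids <- c(all_ids, ident)
    }
    m[gi, (unique(all_ids) %% nbits) + 1] <- 1L
  }
  attr(m, "skipped") <- skipped
  m
}
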