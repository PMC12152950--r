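#' Perturbation map of RBFE transformations
#'
#' A directed graph whose edges carry computed relative binding free energies
#' (ddG, kcal/mol) from a reference ligand to a target ligand. Anchored path
#' sums convert the map to absolute binding free energies.
#'
#' @param edges data.frame with columns `reference_id`, `target_id`, `ddg`
#'   and optionally `stderr` (kcal/mol; missing stderr is treated as 0).
#' @return an object of class `perturbation_map`.
#' @export
perturbation_map <- function(edges) {
  need <- c("reference_id", "target_id", "ddg")
  if (!all(need %in% names(edges)))
    .stopf("edges must have columns %s", paste(need, collapse = ","))
  if (!"stderr" %in% names(edges)) edges$stderr <- 0
  edges$stderr[is.na(edges$stderr)] <- 0
  edges$reference_id <- as.character(edges$reference_id)
  edges$target_id <- as.character(edges$target_id)
  structure(list(edges = edges,
                 nodes = unique(c(edges$reference_id, edges$target_id))),
            class = "perturbation_map")
}

#' @export
print.perturbation_map <- function(x, ...) {
  cat(sprintf("<perturbation_map> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read / write perturbation maps and anchors
#'
#' Map CSV columns: `reference_id,target_id,ddg_kcal,stderr_kcal`; anchor CSV
#' columns: `ligand_id,dg_abs_kcal`.
#'
#' @param path CSV path.
#' @return a [perturbation_map()] (or an anchors data.frame).
#' @export
read_perturbation_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "ddg_kcal"] <- "ddg"
  names(df)[names(df) == "stderr_kcal"] <- "stderr"
  perturbation_map(df)
}

#' @rdname read_perturbation_map
#' @param map a [perturbation_map()].
#' @export
write_perturbation_map <- function(map, path) {
  df <- map$edges
  names(df)[names(df) == "ddg"] <- "ddg_kcal"
  names(df)[names(df) == "stderr"] <- "stderr_kcal"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_perturbation_map
#' @export
read_anchors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "dg_abs_kcal"] <- "dg_abs"
  if (!all(c("ligand_id", "dg_abs") %in% names(df)))
    .stopf("anchor CSV must have columns ligand_id,dg_abs_kcal")
  df
}

.map_igraph <- function(map) {
  igraph::graph_from_data_frame(
    map$edges[, c("reference_id", "target_id")],
    directed = FALSE,
    vertices = data.frame(name = map$nodes)
  )
}

#' Convert relative to absolute binding free energies
#'
#' For every ligand in the map: `dG(target) = dG(anchor) + sum of ddG` along
#' the path from its nearest anchor (edges traversed against their direction
#' contribute `-ddg`); standard errors propagate in quadrature. Every node
#' must be reachable from at least one anchor; in components holding several
#' anchors the nearest (fewest edges) is used and discrepancies beyond
#' 3 sigma between anchors raise a warning.
#'
#' @param map a [perturbation_map()].
#' @param anchors data.frame with `ligand_id`, `dg_abs` (kcal/mol), e.g.
#'   experimentally measured round-1 affinities of the reference hits.
#' @return data.frame (`affinity_table`) with `ligand_id`, `dg_abs`, `stderr`,
#'   `anchor_id`, `path_length`.
#' @export
to_abfe <- function(map, anchors) {
  stopifnot(inherits(map, "perturbation_map"))
  if (is.numeric(anchors) && !is.null(names(anchors)))
    anchors <- data.frame(ligand_id = names(anchors), dg_abs = unname(anchors))
  if (!all(c("ligand_id", "dg_abs") %in% names(anchors)))
    .stopf("anchors must have columns ligand_id,dg_abs")
  missing_anchor <- setdiff(anchors$ligand_id, map$nodes)
  if (length(missing_anchor) > 0)
    .stopf("anchor(s) not in map: %s", paste(missing_anchor, collapse = ", "))
  g <- .map_igraph(map)
  anchor_ids <- anchors$ligand_id
  hops <- igraph::distances(g, v = anchor_ids, to = igraph::V(g))
  reach <- apply(is.finite(hops), 2, any)
  if (!all(reach))
    .stopf("node(s) unreachable from any anchor: %s",
           paste(map$nodes[!reach], collapse = ", "))
  ## signed path sum from one anchor to one node
  edge_key <- paste(map$edges$reference_id, map$edges$target_id, sep = "\r")
  path_sum <- function(anchor, node) {
    vp <- igraph::shortest_paths(g, from = anchor, to = node, output = "vpath")$vpath[[1]]
    vs <- names(vp)
    ddg <- 0; var <- 0
    if (length(vs) > 1) {
      for (k in seq_len(length(vs) - 1)) {
        fwd <- match(paste(vs[k], vs[k + 1], sep = "\r"), edge_key)
        if (!is.na(fwd)) {
          ddg <- ddg + map$edges$ddg[fwd]
          var <- var + map$edges$stderr[fwd]^2
        } else {
          rev <- match(paste(vs[k + 1], vs[k], sep = "\r"), edge_key)
          ddg <- ddg - map$edges$ddg[rev]
          var <- var + map$edges$stderr[rev]^2
        }
      }
    }
    c(ddg = ddg, var = var, hops = length(vs) - 1)
  }
  out <- data.frame(ligand_id = map$nodes, dg_abs = NA_real_, stderr = NA_real_,
                    anchor_id = NA_character_, path_length = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(map$nodes)) {
    node <- map$nodes[i]
    reachable <- anchor_ids[is.finite(hops[, i])]
    vals <- vapply(reachable, function(a) {
      ps <- path_sum(a, node)
      c(anchors$dg_abs[anchors$ligand_id == a] + ps["ddg"], ps["var"], ps["hops"])
    }, numeric(3))
    if (length(reachable) > 1) {
      for (x in seq_len(ncol(vals) - 1)) for (y in seq(x + 1, ncol(vals))) {
        sig <- sqrt(vals[2, x] + vals[2, y])
        if (abs(vals[1, x] - vals[1, y]) > 3 * max(sig, 1e-12))
          .warnf("node '%s': anchors %s and %s disagree by %.2f kcal/mol (> 3 sigma)",
                 node, reachable[x], reachable[y], abs(vals[1, x] - vals[1, y]))
      }
    }
    pick <- which.min(vals[3, ])
    out$dg_abs[i] <- vals[1, pick]
    out$stderr[i] <- sqrt(vals[2, pick])
    out$anchor_id[i] <- reachable[pick]
    out$path_length[i] <- as.integer(vals[3, pick])
  }
  class(out) <- c("affinity_table", "data.frame")
  out
}

#' Cycle-closure errors of a perturbation map
#'
#' For each independent cycle (one per non-tree edge of a spanning forest),
#' the signed sum of edge ddG values around the cycle. A thermodynamically
#' consistent map closes every cycle to 0; tree maps return an empty result.
#'
#' @param map a [perturbation_map()].
#' @return data.frame with `cycle` (" -> "-joined node ids) and `closure`
#'   (kcal/mol); zero rows for a tree.
#' @export
cycle_closure <- function(map) {
  stopifnot(inherits(map, "perturbation_map"))
  out <- data.frame(cycle = character(0), closure = numeric(0),
                    stringsAsFactors = FALSE)
  g <- .map_igraph(map)
  if (igraph::ecount(g) == 0) return(out)
  mst <- igraph::mst(g)
  edge_key <- paste(map$edges$reference_id, map$edges$target_id, sep = "\r")
  signed <- function(u, v) {
    fwd <- match(paste(u, v, sep = "\r"), edge_key)
    if (!is.na(fwd)) return(map$edges$ddg[fwd])
    -map$edges$ddg[match(paste(v, u, sep = "\r"), edge_key)]
  }
  tree_keys <- apply(igraph::as_edgelist(mst), 1, function(e)
    paste(sort(e), collapse = "\r"))
  el <- igraph::as_edgelist(g)
  for (k in seq_len(nrow(el))) {
    u <- el[k, 1]; v <- el[k, 2]
    if (paste(sort(c(u, v)), collapse = "\r") %in% tree_keys) next
    vp <- igraph::shortest_paths(mst, from = v, to = u, output = "vpath")$vpath[[1]]
    vs <- names(vp)
    total <- signed(u, v)
    if (length(vs) > 1)
      for (m in seq_len(length(vs) - 1)) total <- total + signed(vs[m], vs[m + 1])
    out <- rbind(out, data.frame(
      cycle = paste(c(u, vs), collapse = " -> "),
      closure = total, stringsAsFactors = FALSE))
  }
  out
}

## Gas constant in kcal/(mol K).
.R_KCAL <- 1.987204e-3

#' Dissociation constant / binding free energy conversion
#'
#' `dG = R T ln(KD / 1 M)` with `R = 1.987204e-3 kcal/(mol K)`; the default
#' temperature 298 K matches a 25 C binding assay. `dg_to_kd` is the exact
#' inverse.
#'
#' @param kd dissociation constant in molar (> 0); vectorized.
#' @param temperature temperature in kelvin (default 298).
#' @return `kd_to_dg`: free energy in kcal/mol (negative for KD < 1 M).
#' @export
kd_to_dg <- function(kd, temperature = 298) {
  if (any(kd <= 0)) .stopf("kd must be positive")
  .R_KCAL * temperature * log(kd)
}

#' @rdname kd_to_dg
#' @param dg binding free energy in kcal/mol; vectorized.
#' @return `dg_to_kd`: dissociation constant in molar.
#' @export
dg_to_kd <- function(dg, temperature = 298) {
  exp(dg / (.R_KCAL * temperature))
}

#' Mean absolute error between computed and experimental values
#'
#' @param computed,experimental numeric vectors of equal nonzero length
#'   (kcal/mol).
#' @return mean of `|computed - experimental|`.
#' @export
mae <- function(computed, experimental) {
  if (length(computed) == 0 || length(computed) != length(experimental))
    .stopf("computed and experimental must have equal nonzero length")
  mean(abs(computed - experimental))
}

#' Campaign bookkeeping: hit rate and stage-count rollups
#'
#' `hit_rate` is the percentage of experimentally confirmed binders among
#' tested compounds. `campaign_counts` sums per-hit stage counts into a totals
#' column (the Figure-2C style table of a screening funnel).
#'
#' @param n_confirmed,n_tested counts of confirmed and tested compounds.
#' @return `hit_rate`: percentage in `[0, 100]`.
#' @export
hit_rate <- function(n_confirmed, n_tested) {
  if (n_tested <= 0) .stopf("n_tested must be positive")
  if (n_confirmed < 0 || n_confirmed > n_tested)
    .stopf("n_confirmed must be between 0 and n_tested")
  100 * n_confirmed / n_tested
}

#' @rdname hit_rate
#' @param counts data.frame with a `stage` column and one numeric column per
#'   hit series.
#' @return `campaign_counts`: the same data.frame with a `total` column.
#' @export
campaign_counts <- function(counts) {
  stopifnot("stage" %in% names(counts))
  num <- vapply(counts, is.numeric, logical(1))
  counts$total <- rowSums(counts[, num, drop = FALSE])
  counts
}
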