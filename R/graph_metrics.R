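#' All-pairs shortest paths with path counts
#'
#' Runs Floyd-Warshall on the weighted network, returning the shortest-path
#' distance matrix, the number of distinct shortest paths per pair
#' (path-length ties resolved under an absolute tolerance) and a
#' reachability mask. With strictly positive weights the counts are exact;
#' zero-weight edges (perfectly correlated pairs) can make "distinct
#' shortest path" ambiguous and the counts then depend on the tolerance.
#'
#' @param g An [igraph::igraph] with edge attribute `weight` (>= 0), or a
#'   symmetric numeric weight matrix with `NA`/`Inf` for missing edges.
#' @param tol Tie tolerance on path lengths (default 1e-9).
#' @return A `path_matrix`: list with `d` (distances, `Inf` when
#'   unreachable), `sigma` (shortest-path counts, 0 when unreachable),
#'   `reachable` (logical), `names` (node labels).
#' @export
shortest_paths_all <- function(g, tol = 1e-9) {
  if (inherits(g, "igraph")) {
    w <- .weight_matrix(g)
    nm <- igraph::V(g)$name
  } else {
    w <- as.matrix(g)
    nm <- rownames(w)
  }
  if (any(w[is.finite(w)] < 0)) stop("negative edge weight")
  res <- .fw_core(w, tol)
  d <- res$d
  sigma <- res$sigma
  if (!is.null(nm)) dimnames(d) <- dimnames(sigma) <- list(nm, nm)
  reach <- is.finite(d)
  structure(list(d = d, sigma = sigma, reachable = reach, names = nm),
            class = "path_matrix")
}

.weight_matrix <- function(g) {
  n <- igraph::vcount(g)
  w <- matrix(NA_real_, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) {
    wt <- igraph::E(g)$weight
    if (is.null(wt)) stop("network has no edge weights")
    w[el] <- wt
    w[el[, c(2L, 1L), drop = FALSE]] <- wt
  }
  w
}

#' Closeness centrality
#'
#' `C(x) = (n - 1) / sum_y d(x, y)`, with `n` and the sum restricted to the
#' connected component containing `x`, so that unreachable nodes do not
#' zero out the score. Isolated nodes get closeness 0 with a warning.
#'
#' @param p A `path_matrix` from [shortest_paths_all()].
#' @return Named numeric vector of per-node closeness values.
#' @export
closeness_centrality <- function(p) {
  n <- nrow(p$d)
  out <- numeric(n)
  for (i in seq_len(n)) {
    comp <- which(p$reachable[i, ] & seq_len(n) != i)
    if (!length(comp)) {
      out[i] <- 0
    } else {
      out[i] <- length(comp) / sum(p$d[i, comp])
    }
  }
  if (any(out == 0)) warning("isolated node(s): closeness set to 0")
  names(out) <- p$names
  out
}

#' Betweenness centrality (raw shortest-path counts)
#'
#' Counts, over all unordered node pairs `{s, t}` with `s != x != t`, the
#' number of distinct shortest s-t paths that pass through `x` as an
#' interior node. Raw counts are reported (not Brandes fractions); the
#' z-scoring used downstream removes the scale.
#'
#' @param p A `path_matrix`.
#' @param tol Tie tolerance on path lengths (default 1e-9).
#' @return Named numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(p, tol = 1e-9) {
  n <- nrow(p$d)
  d <- p$d; sigma <- p$sigma
  out <- numeric(n)
  for (x in seq_len(n)) {
    thru <- outer(d[, x], d[x, ], "+")        # d(s,x) + d(x,t)
    on_path <- is.finite(thru) & abs(thru - d) <= tol
    cnt <- sigma[, x] %o% sigma[x, ]
    cnt[!on_path] <- 0
    cnt[x, ] <- 0; cnt[, x] <- 0
    diag(cnt) <- 0
    out[x] <- sum(cnt[upper.tri(cnt)])
  }
  names(out) <- p$names
  out
}

#' Characteristic path length
#'
#' Mean shortest-path length over unordered reachable node pairs
#' (self-pairs excluded).
#'
#' @param p A `path_matrix`.
#' @return Scalar CPL.
#' @export
cpl <- function(p) {
  ut <- upper.tri(p$d)
  vals <- p$d[ut][p$reachable[ut]]
  if (!length(vals)) stop("no reachable pairs: network has no edges")
  mean(vals)
}

#' Delta path length on node removal
#'
#' For each node, `DPL(x) = CPL(G - x) - CPL(G)`: positive values mean
#' removing the node lengthens the remaining shortest paths. Node removal
#' deletes the node and its incident edges; pairs disconnected by the
#' removal are dropped from the post-removal average and flagged; if no
#' reachable pair remains at all, the DPL of that node is `NA`.
#'
#' @param g Weighted [igraph::igraph] network (or weight matrix) with at
#'   least 3 nodes.
#' @param tol Tie tolerance passed to the path solver.
#' @return Data frame with `node`, `dpl` and logical `disconnects`
#'   (whether removal makes some remaining pair unreachable).
#' @export
dpl <- function(g, tol = 1e-9) {
  w <- if (inherits(g, "igraph")) .weight_matrix(g) else as.matrix(g)
  n <- nrow(w)
  if (n < 3L) stop("node removal would leave fewer than 2 nodes")
  nm <- if (inherits(g, "igraph")) igraph::V(g)$name else rownames(w)
  base <- shortest_paths_all(w, tol)
  cpl0 <- cpl(base)
  out <- data.frame(node = if (is.null(nm)) as.character(seq_len(n)) else nm,
                    dpl = NA_real_, disconnects = NA,
                    stringsAsFactors = FALSE)
  for (x in seq_len(n)) {
    sub <- shortest_paths_all(w[-x, -x, drop = FALSE], tol)
    has_pair <- any(sub$reachable[upper.tri(sub$reachable)])
    out$dpl[x] <- if (has_pair) cpl(sub) - cpl0 else NA_real_
    pre_reach <- base$reachable[-x, -x, drop = FALSE]
    out$disconnects[x] <- any(pre_reach & !sub$reachable)
  }
  out
}

#' Z-scores with outlier flags
#'
#' Standardises a per-node metric over the node set and flags nodes whose
#' z-score exceeds `cutoff` (1.5 is used for betweenness, 1.0 for delta
#' path length when mirroring the reference analysis). The population
#' standard deviation is used: the node set is the whole population, not
#' a sample.
#'
#' @param values Named numeric vector (`NA`s are ignored when
#'   standardising and never flagged).
#' @param cutoff Flagging threshold on the z-score.
#' @return Data frame with `node`, `value`, `z`, `flagged`.
#' @export
zscore_flags <- function(values, cutoff = 1.5) {
  if (length(values) < 2L) stop("need at least 2 nodes to z-score")
  mu <- mean(values, na.rm = TRUE)
  s <- sqrt(mean((values - mu)^2, na.rm = TRUE))
  if (!is.finite(s) || s == 0) {
    warning("zero standard deviation: all z-scores set to 0, nothing flagged")
    z <- rep(0, length(values))
    z[is.na(values)] <- NA_real_
  } else {
    z <- (values - mu) / s
  }
  data.frame(node = if (is.null(names(values))) as.character(seq_along(values))
             else names(values),
             value = unname(values), z = unname(z),
             flagged = !is.na(z) & z > cutoff,
             stringsAsFactors = FALSE)
}

#' Closeness tiers
#'
#' Rank-percentile assignment of nodes into recognition-likelihood tiers:
#' `high` (top 20% closeness), `intermediate` (20-60%) and `low` (the rest).
#' Ties share the better tier.
#'
#' @param values Named numeric vector of closeness values (>= 5 nodes).
#' @return Character vector of tiers, named like `values`.
#' @export
closeness_tiers <- function(values) {
  n <- length(values)
  if (n < 5L) stop("need at least 5 nodes for tier assignment")
  # fraction of nodes strictly better; ties take the better tier
  frac_better <- (rank(-values, ties.method = "min") - 1) / n
  tier <- ifelse(frac_better < 0.20, "high",
          ifelse(frac_better < 0.60, "intermediate", "low"))
  if (all(tier == "high") && n > 1L && stats::sd(values) == 0) {
    warning("all closeness values equal: every node assigned the top tier")
  }
  names(tier) <- names(values)
  tier
}

#' Full node-metric table for a dynamical network
#'
#' Convenience wrapper running the path solver once and assembling
#' closeness, betweenness, delta path length, their z-scores, flags at the
#' conventional cutoffs and closeness tiers.
#'
#' @param g Weighted [igraph::igraph] network.
#' @param betweenness_z_cutoff,dpl_z_cutoff Flagging cutoffs (defaults 1.5
#'   and 1.0).
#' @return List with `nodes` (per-node data frame) and `summary` (CPL,
#'   node/edge counts, component count).
#' @export
network_metrics <- function(g, betweenness_z_cutoff = 1.5, dpl_z_cutoff = 1.0) {
  p <- shortest_paths_all(g)
  cl <- closeness_centrality(p)
  bw <- betweenness_centrality(p)
  dp <- dpl(g)
  zb <- zscore_flags(bw, betweenness_z_cutoff)
  zd <- zscore_flags(dp$dpl, dpl_z_cutoff)
  nodes <- data.frame(
    node = p$names %||% as.character(seq_along(cl)),
    closeness = unname(cl), betweenness = unname(bw), dpl = dp$dpl,
    z_betweenness = zb$z, z_dpl = zd$z,
    flag_betweenness = zb$flagged, flag_dpl = zd$flagged,
    dpl_disconnects = dp$disconnects,
    tier = unname(closeness_tiers(cl)),
    stringsAsFactors = FALSE
  )
  list(nodes = nodes,
       summary = list(cpl = cpl(p),
                      n_nodes = nrow(nodes),
                      n_edges = igraph::ecount(g),
                      n_components = igraph::count_components(g)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write network metrics
#'
#' @param metrics Output of [network_metrics()].
#' @param tsv Per-node metrics TSV path.
#' @param summary_json Optional network-level summary JSON path.
#' @return Invisible list of written paths.
#' @export
write_metrics <- function(metrics, tsv, summary_json = NULL) {
  utils::write.table(metrics$nodes, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_json)) {
    jsonlite::write_json(metrics$summary, summary_json, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(tsv = tsv, summary_json = summary_json))
}
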