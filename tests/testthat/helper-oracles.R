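# Independent oracles used across the test files. These deliberately use
# naive algorithms (exhaustive path enumeration, direct formula evaluation)
# so they share no code path with the package implementation.

# --- exhaustive shortest-path oracle ---------------------------------------

# Enumerates every simple path between every ordered pair by depth-first
# search and keeps the shortest ones (ties within `tol`). Returns distances,
# shortest-path counts and the paths themselves.
bf_all_paths <- function(w, tol = 1e-9) {
  n <- nrow(w)
  adj <- lapply(seq_len(n), function(i) {
    which(is.finite(w[i, ]) & seq_len(n) != i)
  })
  d <- matrix(Inf, n, n); diag(d) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  paths <- vector("list", n * n)  # index (s-1)*n + t
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    path <- s
    rec <- function(v, dist) {
      for (u in adj[[v]]) {
        if (visited[u]) next
        nd <- dist + w[v, u]
        key <- (s - 1L) * n + u
        if (nd < d[s, u] - tol) {
          d[s, u] <<- nd
          paths[[key]] <<- list(c(path, u))
        } else if (nd <= d[s, u] + tol) {
          paths[[key]] <<- c(paths[[key]], list(c(path, u)))
        }
        visited[u] <<- TRUE
        path <<- c(path, u)
        rec(u, nd)
        path <<- path[-length(path)]
        visited[u] <<- FALSE
      }
    }
    rec(s, 0)
  }
  # drop recorded paths longer than the final optimum (found before a
  # shorter route was discovered)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    key <- (s - 1L) * n + t
    ps <- paths[[key]]
    if (is.null(ps)) next
    lens <- vapply(ps, function(p) {
      sum(w[cbind(p[-length(p)], p[-1L])])
    }, numeric(1L))
    keep <- lens <= d[s, t] + tol
    ps <- ps[keep]
    # de-duplicate (same path can be re-found)
    ps <- ps[!duplicated(vapply(ps, paste, character(1L), collapse = "-"))]
    paths[[key]] <- ps
    sigma[s, t] <- length(ps)
  }
  list(d = d, sigma = sigma, paths = paths, n = n)
}

bf_closeness <- function(bf) {
  vapply(seq_len(bf$n), function(i) {
    comp <- which(is.finite(bf$d[i, ]) & seq_len(bf$n) != i)
    if (!length(comp)) 0 else length(comp) / sum(bf$d[i, comp])
  }, numeric(1L))
}

bf_betweenness <- function(bf) {
  out <- numeric(bf$n)
  for (s in seq_len(bf$n - 1L)) for (t in (s + 1L):bf$n) {
    for (p in bf$paths[[(s - 1L) * bf$n + t]]) {
      interior <- p[-c(1L, length(p))]
      out[interior] <- out[interior] + 1
    }
  }
  out
}

bf_cpl <- function(bf) {
  ut <- bf$d[upper.tri(bf$d)]
  mean(ut[is.finite(ut)])
}

bf_dpl <- function(w, tol = 1e-9) {
  n <- nrow(w)
  base <- bf_cpl(bf_all_paths(w, tol))
  out <- vapply(seq_len(n), function(x) {
    bf_cpl(bf_all_paths(w[-x, -x, drop = FALSE], tol)) - base
  }, numeric(1L))
  out[is.nan(out)] <- NA_real_   # removal left no reachable pair
  out
}

# random connected weighted graph as a weight matrix (NA = no edge)
random_graph <- function(n, p = 0.45, wmin = 0.2, wmax = 1.5) {
  repeat {
    w <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (stats::runif(1) < p) w[i, j] <- w[j, i] <- stats::runif(1, wmin, wmax)
    }
    adj <- !is.na(w)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::is_connected(g) && sum(adj) > 0) return(w)
  }
}

# --- analytic SASA oracle ---------------------------------------------------

# Exposed area of sphere 1 (radius R1 = r1 + probe) partially occluded by
# sphere 2 (radius R2) at centre distance `dist`: full sphere minus the
# spherical cap cut off by the intersection plane.
two_sphere_sasa <- function(r1, r2, probe, dist) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (dist >= R1 + R2) return(4 * pi * R1^2)
  if (dist + R1 <= R2) return(0)
  h1 <- R1 - (dist^2 + R1^2 - R2^2) / (2 * dist)
  4 * pi * R1^2 - 2 * pi * R1 * h1
}

# --- direct-formula motion correlation oracle -------------------------------

# Direct evaluation with explicit loops over frames and residue pairs.
direct_correlation <- function(ca_frames) {
  nf <- dim(ca_frames)[1L]; n <- dim(ca_frames)[2L]
  mean_pos <- apply(ca_frames, c(2L, 3L), mean)
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; vi <- 0; vj <- 0
    for (f in seq_len(nf)) {
      di <- ca_frames[f, i, ] - mean_pos[i, ]
      dj <- ca_frames[f, j, ] - mean_pos[j, ]
      num <- num + sum(di * dj)
      vi <- vi + sum(di * di)
      vj <- vj + sum(dj * dj)
    }
    C[i, j] <- (num / nf) / sqrt((vi / nf) * (vj / nf))
  }
  C
}

# --- direct-summation frequency oracle --------------------------------------

# Literal evaluation of the reweighted frequency definitions with loops.
direct_frequencies <- function(seq_mat, weights, M_eff, lambda, q = 21L) {
  M <- nrow(seq_mat); L <- ncol(seq_mat)
  fi <- array(0, c(L, q))
  for (i in seq_len(L)) for (A in seq_len(q)) {
    s <- sum(weights[seq_mat[, i] == A])
    fi[i, A] <- (lambda / q + s) / (lambda + M_eff)
  }
  fij <- array(0, c(L, L, q, q))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    for (a in seq_len(M)) {
      fij[i, j, seq_mat[a, i], seq_mat[a, j]] <-
        fij[i, j, seq_mat[a, i], seq_mat[a, j]] + weights[a]
    }
    fij[i, j, , ] <- (fij[i, j, , ] + lambda / q^2) / (lambda + M_eff)
  }
  list(fi = fi, fij = fij)
}

# --- misc -------------------------------------------------------------------

# one correctly column-aligned PDB ATOM/HETATM record
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM", element = "C") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, " ", resname, chain, resno, x, y, z, 1, 0,
          element)
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")
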