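#' Construct a trajectory object
#'
#' @param topology A `lectin_structure` giving the atom table (coordinates
#'   in the topology are those of the first frame unless stated otherwise).
#' @param coords Numeric array `n_frames x n_atoms x 3` of coordinates in
#'   Angstrom.
#' @param frame_interval Optional time between frames (ps), metadata only.
#' @return A `lectin_trajectory` object.
#' @export
new_trajectory <- function(topology, coords, frame_interval = NA_real_) {
  stopifnot(inherits(topology, "lectin_structure"),
            length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  if (dim(coords)[2L] != nrow(topology$atoms)) {
    stop("coordinate array does not match topology atom count")
  }
  if (dim(coords)[1L] < 2L) stop("a trajectory needs at least 2 frames")
  if (any(!is.finite(coords))) stop("non-finite coordinates in trajectory")
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval),
            class = "lectin_trajectory")
}

#' @export
print.lectin_trajectory <- function(x, ...) {
  cat("lectin_trajectory:", dim(x$coords)[1L], "frames,",
      dim(x$coords)[2L], "atoms\n")
  invisible(x)
}

#' Read a trajectory from a multi-model PDB file
#'
#' Each MODEL block becomes one frame; the shared topology comes from the
#' first model (hydrogens and waters dropped, as in [read_structure()]).
#'
#' @param path Multi-model PDB file.
#' @param frame_start,frame_end Optional 1-based frame window, e.g. to use
#'   only the equilibrated tail of a simulation.
#' @return A `lectin_trajectory`.
#' @export
read_trajectory <- function(path, frame_start = 1L, frame_end = NULL) {
  pdbobj <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- read_structure(path, model_index = 1L)
  nmod <- nrow(pdbobj$xyz)
  if (is.null(frame_end)) frame_end <- nmod
  if (frame_start < 1L || frame_end > nmod || frame_start >= frame_end) {
    stop("invalid frame window [", frame_start, ", ", frame_end, "] for ",
         nmod, " models")
  }
  # map retained heavy atoms back to columns of the xyz matrix
  elem <- .atom_elements(pdbobj$atom)
  keep <- which(elem != "H" & !(toupper(pdbobj$atom$resid) %in% .water_names))
  frames <- frame_start:frame_end
  coords <- array(NA_real_, c(length(frames), length(keep), 3L))
  for (f in seq_along(frames)) {
    m <- matrix(pdbobj$xyz[frames[f], ], ncol = 3L, byrow = TRUE)
    coords[f, , ] <- m[keep, , drop = FALSE]
  }
  new_trajectory(topo, coords)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A `lectin_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$topology$atoms
  nf <- dim(traj$coords)[1L]
  xyz <- matrix(NA_real_, nf, nrow(a) * 3L)
  for (f in seq_len(nf)) xyz[f, ] <- t(traj$coords[f, , ])
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   eleno = seq_len(nrow(a)), elety = a$elety)
  invisible(path)
}

# index of the C-alpha atom of every residue, in residue-table order
.calpha_index <- function(topology) {
  a <- topology$atoms
  res <- .residue_table(topology)
  ca <- which(a$elety == "CA" & !a$het)
  idx <- ca[match(paste(res$chain, res$resno), paste(a$chain[ca], a$resno[ca]))]
  if (anyNA(idx)) {
    bad <- res[which(is.na(idx))[1L], ]
    stop("residue without a CA atom: ", bad$resid, " ", bad$chain, bad$resno)
  }
  list(res = res, idx = idx)
}

#' Motion correlation matrix of C-alpha displacements
#'
#' For residues i and j the correlation is the time average of the dot
#' product of their C-alpha displacement vectors (deviations from the mean
#' position), normalised by the root of the product of the mean squared
#' displacements. Values lie in `[-1, 1]`; the diagonal is exactly 1.
#'
#' @param traj A `lectin_trajectory` whose residues all have a CA atom.
#' @return A `motion_correlation`: list with `residues` (data frame) and
#'   `C` (symmetric correlation matrix).
#' @export
motion_correlation <- function(traj) {
  ca <- .calpha_index(traj$topology)
  nf <- dim(traj$coords)[1L]
  # displacement matrices, frames x residues, per coordinate axis
  dx <- traj$coords[, ca$idx, 1L, drop = FALSE][, , 1L]
  dy <- traj$coords[, ca$idx, 2L, drop = FALSE][, , 1L]
  dz <- traj$coords[, ca$idx, 3L, drop = FALSE][, , 1L]
  dx <- sweep(dx, 2L, colMeans(dx)); dy <- sweep(dy, 2L, colMeans(dy))
  dz <- sweep(dz, 2L, colMeans(dz))
  cov <- (crossprod(dx) + crossprod(dy) + crossprod(dz)) / nf
  v <- diag(cov)
  if (any(v <= 0)) {
    bad <- ca$res[which(v <= 0)[1L], ]
    stop("zero displacement variance (frozen residue): ",
         bad$resid, " ", bad$chain, bad$resno)
  }
  C <- cov / sqrt(outer(v, v))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  structure(list(residues = ca$res, C = C), class = "motion_correlation")
}

#' Persistent residue-residue contacts over a trajectory
#'
#' A residue pair is persistent when the minimum heavy-atom distance
#' between the two residues is below `cutoff` in at least `min_fraction`
#' of the frames. Sequence-consecutive residues of the same chain are
#' never persistent (they are excluded from the dynamical network).
#'
#' @param traj A `lectin_trajectory`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param min_fraction Minimum fraction of frames in contact (default
#'   0.75; the boundary counts, i.e. "at least").
#' @return List with `residues` and logical symmetric matrix `persistent`.
#' @export
contact_persistence <- function(traj, cutoff = 4.5, min_fraction = 0.75) {
  if (dim(traj$coords)[1L] < 2L) stop("a trajectory needs at least 2 frames")
  a <- traj$topology$atoms
  res <- .residue_table(traj$topology)
  n <- nrow(res)
  ridx <- match(paste(a$chain, a$resno), paste(res$chain, res$resno))
  nf <- dim(traj$coords)[1L]
  cut2 <- cutoff^2

  count <- matrix(0L, n, n)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[f, , ]
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
    within <- d2 < cut2
    # residue pairs with any atom pair within cutoff
    tp <- which(within, arr.ind = TRUE)
    if (nrow(tp)) {
      rp <- unique(cbind(ridx[tp[, 1L]], ridx[tp[, 2L]]))
      rp <- rp[rp[, 1L] != rp[, 2L], , drop = FALSE]
      count[rp] <- count[rp] + 1L
    }
  }
  persistent <- count >= min_fraction * nf
  persistent <- persistent & t(persistent)  # counts are symmetric already
  diag(persistent) <- FALSE
  consec <- which(res$chain[-1L] == res$chain[-n] &
                  abs(res$resno[-1L] - res$resno[-n]) == 1L)
  for (k in consec) {
    persistent[k, k + 1L] <- FALSE
    persistent[k + 1L, k] <- FALSE
  }
  list(residues = res, persistent = persistent)
}

#' Build the weighted dynamical residue network
#'
#' Edges connect persistently contacting, non-consecutive residue pairs
#' whose motion correlation is positive; anticorrelated pairs (correlation
#' in `[-1, 0]`) are removed. The edge weight is `-log(C_ij)` (natural
#' log), so strongly correlated pairs are "close" in path-length terms.
#'
#' @param corr A `motion_correlation`.
#' @param persistence Output of [contact_persistence()] on the same
#'   trajectory (matching residue tables).
#' @return An [igraph::igraph] graph with vertex attributes `name`
#'   (`chain:resno`), `chain`, `resno`, `resid` and edge attributes
#'   `weight` (`-log C`) and `correlation`.
#' @export
build_network <- function(corr, persistence) {
  res <- corr$residues
  if (!identical(paste(res$chain, res$resno),
                 paste(persistence$residues$chain, persistence$residues$resno))) {
    stop("correlation and persistence residue tables do not match")
  }
  C <- corr$C
  keep <- persistence$persistent & C > 0
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  ij <- which(keep, arr.ind = TRUE)

  g <- igraph::make_empty_graph(n = nrow(res), directed = FALSE)
  igraph::V(g)$name <- paste0(res$chain, ":", res$resno)
  igraph::V(g)$chain <- res$chain
  igraph::V(g)$resno <- res$resno
  igraph::V(g)$resid <- res$resid
  if (nrow(ij)) {
    g <- igraph::add_edges(g, t(ij))
    igraph::E(g)$correlation <- C[ij]
    igraph::E(g)$weight <- -log(C[ij])
  }
  g
}

#' Export a dynamical network
#'
#' Writes the graph as GraphML and/or node-link JSON.
#'
#' @param g Network from [build_network()].
#' @param graphml,json Output paths (either may be `NULL` to skip).
#' @return Invisible list of written paths.
#' @export
write_network <- function(g, graphml = NULL, json = NULL) {
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(json)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    nodes <- data.frame(id = igraph::V(g)$name,
                        chain = igraph::V(g)$chain,
                        resno = igraph::V(g)$resno,
                        resid = igraph::V(g)$resid)
    links <- data.frame(source = el[, 1L] - 1L, target = el[, 2L] - 1L,
                        weight = igraph::E(g)$weight,
                        correlation = igraph::E(g)$correlation)
    jsonlite::write_json(list(nodes = nodes, links = links), json,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(list(graphml = graphml, json = json))
}

#' Write a motion-correlation matrix as TSV
#'
#' @param corr A `motion_correlation`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(corr, path) {
  m <- corr$C
  dimnames(m) <- list(paste0(corr$residues$chain, ":", corr$residues$resno),
                      paste0(corr$residues$chain, ":", corr$residues$resno))
  utils::write.table(m, path, sep = "\t", quote = FALSE)
  invisible(path)
}
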