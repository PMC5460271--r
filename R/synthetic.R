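# deterministic quasi-uniform points on a capsule (cylinder + end caps)
# around the x-axis segment [x0, x1], radius r, spacing ~ `spacing`
.capsule_points <- function(x0, x1, r, spacing = 1.5) {
  pts <- list()
  nring <- max(8L, ceiling(2 * pi * r / spacing))
  theta <- seq(0, 2 * pi, length.out = nring + 1L)[-1L]
  for (x in seq(x0, x1, by = spacing)) {
    pts[[length(pts) + 1L]] <- cbind(x, r * cos(theta), r * sin(theta))
  }
  # end caps: latitude rings shrinking to the poles
  for (sgn in c(-1, 1)) {
    xe <- if (sgn < 0) x0 else x1
    for (phi in seq(spacing / r, pi / 2, by = spacing / r)) {
      rc <- r * cos(phi)
      nr <- max(4L, ceiling(2 * pi * rc / spacing))
      th <- seq(0, 2 * pi, length.out = nr + 1L)[-1L]
      pts[[length(pts) + 1L]] <- cbind(xe + sgn * r * sin(phi),
                                       rc * cos(th), rc * sin(th))
    }
    pts[[length(pts) + 1L]] <- cbind(xe + sgn * r, 0, 0)
  }
  do.call(rbind, pts)
}

#' Generate a toy monomer/dimer pair with known interface
#'
#' Chain A is a linear peptide-like chain (C-alpha spacing 3.8 Angstrom,
#' one side-chain pseudo-atom per residue). A contiguous patch of its
#' residues is designated the interface: chain B is a tight shell of
#' pseudo-atoms wrapped around the patch so that, in the complex, every
#' patch residue is fully occluded from solvent while the remaining chain-A
#' residues stay exposed. The generator records the designed interface set
#' as machine-readable ground truth, together with the cross-chain residue
#' pairs within 4 Angstrom (computed directly from the geometry).
#'
#' The recorded buried set is the designed patch plus its two
#' bond-neighbours: the shell's end caps necessarily shadow the residues
#' directly bonded to the patch (a 3.8 Angstrom bond keeps them inside the
#' sealing halo), so they are buried by design as well; the next residues
#' out remain clearly exposed. This is a synthetic construct for
#' validating the SASA-based classifier; chain B is not a chemically
#' sensible protein.
#'
#' @param n_residues_per_chain Number of chain-A residues (>= 7).
#' @param seed Integer seed (patch placement and coordinate jitter).
#' @param patch_size Number of shell-wrapped residues (default
#'   `max(2, round(n/3))`; the recorded interface set has two more).
#' @return List with `monomer` (`lectin_structure`, chain A alone),
#'   `dimer` (chains A + B) and `truth` (list: `interface_resno`,
#'   `contact_pairs` data frame, `seed`, parameters).
#' @export
make_toy_dimer <- function(n_residues_per_chain, seed = 1L,
                           patch_size = NULL) {
  n <- as.integer(n_residues_per_chain)
  if (n < 7L) stop("need at least 7 residues per chain")
  if (is.null(patch_size)) patch_size <- max(2L, min(round(n / 3), n - 4L))
  set.seed(as.integer(seed))

  # shell patch kept two residues off the termini: its bond-neighbours are
  # buried with it, and the residues beyond them must remain exposed
  start_max <- n - patch_size - 1L
  if (start_max < 3L) stop("patch_size too large for chain length")
  patch_start <- if (start_max == 3L) 3L else sample(3:start_max, 1L)
  patch <- patch_start:(patch_start + patch_size - 1L)
  buried <- (min(patch) - 1L):(max(patch) + 1L)

  ca <- cbind(3.8 * (seq_len(n) - 1L), 0, 0) +
    matrix(stats::runif(3L * n, -0.05, 0.05), n, 3L)
  cb <- sweep(ca, 2L, c(0, 1.5, 0), "+")
  atoms_a <- data.frame(
    chain = "A",
    resno = rep(seq_len(n), each = 2L),
    resid = "ALA",
    elety = rep(c("CA", "CB"), n),
    element = "C",
    x = as.vector(rbind(ca[, 1L], cb[, 1L])),
    y = as.vector(rbind(ca[, 2L], cb[, 2L])),
    z = as.vector(rbind(ca[, 3L], cb[, 3L])),
    het = FALSE, stringsAsFactors = FALSE
  )

  # shell around the patch segment: radius 3.0 around the chain axis seals
  # the patch against a 1.4 probe while leaving flanking residues outside
  x0 <- 3.8 * (min(patch) - 1L)
  x1 <- 3.8 * (max(patch) - 1L)
  shell <- .capsule_points(x0, x1, r = 3.0, spacing = 1.5)
  shell[, 2L] <- shell[, 2L] + 0.75   # centre the shell on the CA-CB midline
  nshell <- nrow(shell)
  per_res <- 10L
  shell_resno <- (seq_len(nshell) - 1L) %/% per_res + 1L
  atoms_b <- data.frame(
    chain = "B",
    resno = shell_resno,
    resid = "GLY",
    elety = paste0("C", sprintf("%02d", (seq_len(nshell) - 1L) %% per_res + 1L)),
    element = "C",
    x = shell[, 1L], y = shell[, 2L], z = shell[, 3L],
    het = FALSE, stringsAsFactors = FALSE
  )

  monomer <- new_structure(atoms_a)
  dimer <- new_structure(rbind(atoms_a, atoms_b))

  # ground-truth contact pairs straight from the geometry
  xa <- as.matrix(atoms_a[, c("x", "y", "z")])
  xb <- as.matrix(atoms_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  hits <- which(sqrt(pmax(d2, 0)) < 4.0, arr.ind = TRUE)
  contact_pairs <- unique(data.frame(resno_a = atoms_a$resno[hits[, 1L]],
                                     resno_b = atoms_b$resno[hits[, 2L]]))
  rownames(contact_pairs) <- NULL

  list(monomer = monomer, dimer = dimer,
       truth = list(interface_resno = buried,
                    shell_patch_resno = patch,
                    contact_pairs = contact_pairs,
                    seed = seed, n_residues = n, patch_size = patch_size))
}

#' Specification for a synthetic correlated-motion trajectory
#'
#' @param topology A `lectin_structure` giving the reference (mean)
#'   geometry; every residue needs a CA atom.
#' @param correlation Planted residue-residue correlation matrix
#'   (symmetric positive semi-definite, unit diagonal), ordered like the
#'   topology's residue table.
#' @param amplitude Per-axis fluctuation amplitude in Angstrom
#'   (default 0.5, a typical C-alpha RMSF scale).
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @return A `trajectory_spec` list.
#' @export
trajectory_spec <- function(topology, correlation, amplitude = 0.5,
                            n_frames = 1000L, seed = 1L) {
  n <- nrow(.residue_table(topology))
  if (!is.matrix(correlation) || nrow(correlation) != n ||
      ncol(correlation) != n) {
    stop("correlation matrix must be ", n, " x ", n)
  }
  if (max(abs(correlation - t(correlation))) > 1e-10 ||
      max(abs(diag(correlation) - 1)) > 1e-10) {
    stop("correlation matrix must be symmetric with unit diagonal")
  }
  if (n_frames < 2L) stop("n_frames must be >= 2")
  structure(list(topology = topology, correlation = correlation,
                 amplitude = amplitude, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Simulate a trajectory with a planted correlation structure
#'
#' Frames are the reference coordinates plus correlated Gaussian
#' displacements: for each coordinate axis independently, the vector of
#' per-residue displacements is drawn from `N(0, amplitude^2 * R)` with
#' `R` the planted correlation matrix (via its symmetric matrix square
#' root), so the motion correlation of any residue pair converges to the
#' planted value. All heavy atoms of a residue translate rigidly with its
#' C-alpha, so contact persistence is controlled by the reference
#' geometry.
#'
#' @param spec A `trajectory_spec`.
#' @return A `lectin_trajectory` with attribute `truth` (planted matrix,
#'   amplitude, seed).
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  R <- spec$correlation
  eig <- eigen(R, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    stop("planted correlation matrix is not positive semi-definite (min ",
         "eigenvalue ", signif(min(eig$values), 3), ")")
  }
  S <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))

  a <- spec$topology$atoms
  res <- .residue_table(spec$topology)
  n <- nrow(res)
  ridx <- match(paste(a$chain, a$resno), paste(res$chain, res$resno))
  ref <- as.matrix(a[, c("x", "y", "z")])

  set.seed(spec$seed)
  nf <- spec$n_frames
  coords <- array(NA_real_, c(nf, nrow(a), 3L))
  for (ax in 1:3) {
    Z <- matrix(stats::rnorm(nf * n), n, nf)
    disp <- spec$amplitude * t(S %*% Z)          # frames x residues
    coords[, , ax] <- rep(ref[, ax], each = nf) + disp[, ridx]
  }
  traj <- new_trajectory(spec$topology, coords)
  attr(traj, "truth") <- list(correlation = R, amplitude = spec$amplitude,
                              n_frames = nf, seed = spec$seed)
  traj
}

#' Build a bottleneck network system (topology + planted correlations)
#'
#' Constructs a 16-residue synthetic system of two 5-residue clusters
#' joined by one bridge residue. Each cluster is a clique (a tetrahedron
#' of residues around a central one, all mutually in contact) so no
#' cluster node is a hub by itself; the bridge contacts one "gateway"
#' vertex of each cluster and is the only short route between them. A
#' long, weakly correlated 5-residue backup chain links a rear vertex of
#' each cluster, so removing the bridge forces long detours instead of
#' disconnecting the graph. Every residue is its own chain, keeping the
#' consecutive-residue edge exclusion out of play. By construction the
#' bridge carries every inter-cluster shortest path (top betweenness) and
#' its removal lengthens all of them (top delta path length).
#'
#' @return List with `topology` (`lectin_structure`), `correlation`
#'   (planted PSD matrix), `bridge` (name of the bottleneck node,
#'   `"F:1"`), `residue_names`, `labels`.
#' @export
make_bottleneck_system <- function() {
  # tetrahedral unit directions, one along +x
  dirs <- rbind(c(1, 0, 0),
                c(-1 / 3, 2 * sqrt(2) / 3, 0),
                c(-1 / 3, -sqrt(2) / 3, sqrt(2 / 3)),
                c(-1 / 3, -sqrt(2) / 3, -sqrt(2 / 3)))
  cluster <- function(centre, flip) {
    v <- dirs * 2.2
    if (flip) v[, 1L] <- -v[, 1L]
    rbind(sweep(v, 2L, centre, "+"), centre)  # 4 vertices + centre
  }
  c1 <- c(0, 0, 0); c2 <- c(11.2, 0, 0)
  p1 <- cluster(c1, flip = FALSE)   # vertex 1 = gateway G1 at (2.2, 0, 0)
  p2 <- cluster(c2, flip = TRUE)    # vertex 1 = gateway G2 at (9.0, 0, 0)
  bridge <- c(5.6, 0, 0)            # 3.4 from both gateways
  b1 <- p1[4L, ]; b2 <- p2[4L, ]    # rear vertices, z = -1.80
  relays <- rbind(b1 + c(0, 0, -3.3),
                  c(2.44, b1[2L], b1[3L] - 3.3),
                  c(5.60, b1[2L], b1[3L] - 3.3),
                  c(8.77, b1[2L], b1[3L] - 3.3),
                  b2 + c(0, 0, -3.3))
  pos <- rbind(p1, bridge, p2, relays)
  dimnames(pos) <- NULL
  n <- nrow(pos)
  labels <- c("G1", "V12", "V13", "B1", "C1", "H",
              "G2", "V22", "V23", "B2", "C2",
              "K1", "K2", "K3", "K4", "K5")
  chains <- LETTERS[seq_len(n)]
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = chains[i], resno = 1L, resid = "ALA",
               elety = c("CA", "CB", "CG"), element = "C",
               x = pos[i, 1L], y = pos[i, 2L],
               z = unname(pos[i, 3L] + c(0, 0.7, -0.7)),
               het = FALSE, stringsAsFactors = FALSE, row.names = NULL)
  }))
  topo <- new_structure(atoms)

  R <- matrix(0.10, n, n)
  clust1 <- 1:5; clust2 <- 7:11
  R[clust1, clust1] <- 0.75
  R[clust2, clust2] <- 0.75
  R[6, c(1, 7)] <- R[c(1, 7), 6] <- 0.85        # bridge links G1-H, H-G2
  backup <- rbind(c(4, 12), c(12, 13), c(13, 14), c(14, 15), c(15, 16),
                  c(16, 10))
  R[backup] <- R[backup[, 2:1]] <- 0.45
  diag(R) <- 1
  # shrink toward identity until positive semi-definite (design-time fix;
  # edge ordering is preserved because shrinkage is uniform)
  while (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-6) {
    R <- 0.95 * R
    diag(R) <- 1
  }
  list(topology = topo, correlation = R,
       bridge = "F:1", residue_names = paste0(chains, ":1"),
       labels = labels)
}

#' Specification for a Potts-model alignment sample
#'
#' @param L Alignment length (columns).
#' @param M Number of sequences to draw.
#' @param coupled_pairs Integer matrix (`k x 2`) of planted coupled column
#'   pairs; pairs must be distinct with sequence separation >= 2.
#' @param coupling_strength Scalar (recycled) coupling: pair `(i, j)` gets
#'   interaction `e_ij(A, B) = strength * [A == B]`, favouring matched
#'   states.
#' @param fields `L x 20` matrix of local fields (default 0).
#' @param gap_prob Per-cell gap probability applied after sampling
#'   (default 0.05).
#' @param burn_in Gibbs burn-in sweeps (default 100).
#' @param thin Sweeps between retained samples (default 10).
#' @param seed Integer seed.
#' @return A `potts_spec` list.
#' @export
potts_spec <- function(L, M, coupled_pairs, coupling_strength = 2.0,
                       fields = NULL, gap_prob = 0.05,
                       burn_in = 100L, thin = 10L, seed = 1L) {
  coupled_pairs <- matrix(as.integer(coupled_pairs), ncol = 2L)
  if (nrow(coupled_pairs)) {
    if (any(abs(coupled_pairs[, 1L] - coupled_pairs[, 2L]) < 2L)) {
      stop("planted pairs must have sequence separation >= 2")
    }
    key <- apply(t(apply(coupled_pairs, 1L, sort)), 1L, paste, collapse = "-")
    if (anyDuplicated(key)) stop("planted pairs must be distinct")
    if (any(coupled_pairs < 1L) || any(coupled_pairs > L)) {
      stop("planted pair index out of range")
    }
  }
  if (is.null(fields)) fields <- matrix(0, L, 20L)
  if (!all(is.finite(coupling_strength)) || !all(is.finite(fields))) {
    stop("couplings and fields must be finite")
  }
  if (burn_in < 0L || thin < 1L) stop("need burn_in >= 0 and thin >= 1 sweeps")
  structure(list(L = as.integer(L), M = as.integer(M),
                 coupled_pairs = coupled_pairs,
                 coupling_strength = rep_len(coupling_strength,
                                             nrow(coupled_pairs)),
                 fields = fields, gap_prob = gap_prob,
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "potts_spec")
}

#' Sample an alignment from a pairwise (Potts) sequence model
#'
#' Draws `M` sequences over the 20 amino-acid states by single-site Gibbs
#' sampling of the pairwise maximum-entropy model with the planted
#' couplings and fields (one chain; `burn_in` sweeps discarded, one sample
#' kept every `thin` sweeps). Gaps are then inserted independently per
#' cell with probability `gap_prob`. The planted pairs are recorded as
#' ground truth on the returned object.
#'
#' @param spec A `potts_spec`.
#' @return An `msa` with attribute `truth` (planted pairs, strengths,
#'   seed, spec parameters).
#' @export
sample_potts_msa <- function(spec) {
  stopifnot(inherits(spec, "potts_spec"))
  L <- spec$L; M <- spec$M; q <- 20L
  set.seed(spec$seed)

  partners <- vector("list", L)
  if (nrow(spec$coupled_pairs)) {
    for (k in seq_len(nrow(spec$coupled_pairs))) {
      i <- spec$coupled_pairs[k, 1L]; j <- spec$coupled_pairs[k, 2L]
      s <- spec$coupling_strength[k]
      partners[[i]] <- c(partners[[i]], list(list(j = j, s = s)))
      partners[[j]] <- c(partners[[j]], list(list(j = i, s = s)))
    }
  }
  # precompute stationary sampling for sites with no coupling partner
  free_cum <- apply(spec$fields, 1L, function(h) {
    p <- exp(h - max(h)); cumsum(p / sum(p))
  })  # q x L

  a <- sample.int(q, L, replace = TRUE)
  out <- matrix(NA_integer_, M, L)
  total_sweeps <- spec$burn_in + spec$thin * M
  m <- 0L
  for (sweep in seq_len(total_sweeps)) {
    for (i in seq_len(L)) {
      pp <- partners[[i]]
      if (is.null(pp)) {
        a[i] <- findInterval(stats::runif(1L), free_cum[, i]) + 1L
      } else {
        logw <- spec$fields[i, ]
        for (p in pp) logw[a[p$j]] <- logw[a[p$j]] + p$s
        w <- exp(logw - max(logw))
        a[i] <- findInterval(stats::runif(1L) * sum(w), cumsum(w)) + 1L
      }
    }
    if (sweep > spec$burn_in &&
        (sweep - spec$burn_in) %% spec$thin == 0L) {
      m <- m + 1L
      out[m, ] <- a
    }
  }

  chars <- matrix(.aa_states[out], M, L)
  if (spec$gap_prob > 0) {
    gap <- matrix(stats::runif(M * L) < spec$gap_prob, M, L)
    chars[gap] <- "-"
  }
  msa <- new_msa(chars, ids = sprintf("potts_%05d", seq_len(M)))
  attr(msa, "truth") <- list(coupled_pairs = spec$coupled_pairs,
                             coupling_strength = spec$coupling_strength,
                             gap_prob = spec$gap_prob, seed = spec$seed,
                             burn_in = spec$burn_in, thin = spec$thin)
  msa
}

#' Write an alignment as FASTA
#'
#' @param a An `msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path) {
  seqinr::write.fasta(lapply(seq_len(nrow(a$chars)),
                             function(i) a$chars[i, ]),
                      names = a$ids, file.out = path)
  invisible(path)
}

#' Write a structure as PDB
#'
#' @param s A `lectin_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   eleno = seq_len(nrow(a)), elety = a$elety)
  invisible(path)
}

#' Write a generator ground-truth manifest as JSON
#'
#' @param truth Ground-truth list (from a generator's `truth` element or
#'   attribute).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(path)
}
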