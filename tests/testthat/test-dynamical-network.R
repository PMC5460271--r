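# small helper: trajectory from explicit C-alpha frames (one atom/residue)
traj_from_ca <- function(frames) {
  n <- dim(frames)[2L]
  topo <- new_structure(data.frame(
    chain = LETTERS[seq_len(n)], resno = 1L, resid = "ALA", elety = "CA",
    element = "C", x = frames[1, , 1], y = frames[1, , 2], z = frames[1, , 3]
  ))
  new_trajectory(topo, frames)
}

test_that("uniform translation of all residues gives correlation 1", {
  set.seed(1)
  nf <- 50L; n <- 4L
  base <- array(rep(cbind(3.8 * (seq_len(n) - 1), 0, 0), each = nf),
                c(nf, n, 3L))
  shift <- matrix(rnorm(nf * 3), nf, 3L)
  frames <- base
  for (ax in 1:3) frames[, , ax] <- base[, , ax] + shift[, ax]
  C <- motion_correlation(traj_from_ca(frames))$C
  expect_equal(max(abs(C - 1)), 0, tolerance = 1e-12)
})

test_that("exactly opposite motion gives correlation -1", {
  nf <- 40L
  disp <- rnorm(nf)
  frames <- array(0, c(nf, 2L, 3L))
  frames[, 1, 1] <- disp
  frames[, 2, 1] <- 10 - disp
  C <- motion_correlation(traj_from_ca(frames))$C
  expect_equal(C[1, 2], -1, tolerance = 1e-12)
  expect_equal(diag(C), c(1, 1))
})

test_that("correlation matches direct evaluation of the definition", {
  set.seed(2)
  frames <- array(rnorm(4 * 3 * 3), c(4L, 3L, 3L))
  got <- motion_correlation(traj_from_ca(frames))$C
  oracle <- direct_correlation(frames)
  expect_equal(got[upper.tri(got)], oracle[upper.tri(oracle)],
               tolerance = 1e-12)
  expect_equal(diag(got), rep(1, 3))
  expect_true(all(abs(got) <= 1))
})

test_that("a frozen residue triggers an error naming it", {
  frames <- array(0, c(10L, 2L, 3L))
  frames[, 1, 1] <- rnorm(10)
  expect_error(motion_correlation(traj_from_ca(frames)), "frozen")
})

test_that("contact persistence honours cutoff, fraction and the boundary", {
  nf <- 20L
  frames <- array(0, c(nf, 2L, 3L))
  frames[, 2, 1] <- 4.0               # static pair at 4.0 A
  pers <- contact_persistence(traj_from_ca(frames))
  expect_true(pers$persistent[1, 2])

  in_contact <- function(k) {         # within cutoff in k of 20 frames
    fr <- array(0, c(nf, 2L, 3L))
    fr[, 2, 1] <- c(rep(4.0, k), rep(6.0, nf - k))
    contact_persistence(traj_from_ca(fr))$persistent[1, 2]
  }
  expect_false(in_contact(14L))       # 70% < 75%
  expect_true(in_contact(15L))        # exactly 75% counts ("at least")
  expect_true(in_contact(20L))
})

test_that("sequence-consecutive residues are never persistent", {
  nf <- 10L
  topo <- new_structure(data.frame(
    chain = "A", resno = 1:3, resid = "ALA", elety = "CA", element = "C",
    x = c(0, 3.8, 30), y = 0, z = 0
  ))
  frames <- array(0, c(nf, 3L, 3L))
  frames[, , 1] <- matrix(rep(c(0, 3.8, 30), each = nf), nf, 3L)
  pers <- contact_persistence(new_trajectory(topo, frames))
  expect_false(pers$persistent[1, 2])   # in contact every frame, but bonded
})

test_that("network edges implement the weight rule and correlation filter", {
  res <- data.frame(chain = c("A", "B", "C"), resno = 1L, resid = "ALA")
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 1       # perfectly correlated
  C[1, 3] <- C[3, 1] <- -0.5    # anticorrelated
  C[2, 3] <- C[3, 2] <- 0.5
  pers <- matrix(TRUE, 3, 3); diag(pers) <- FALSE
  g <- build_network(structure(list(residues = res, C = C),
                               class = "motion_correlation"),
                     list(residues = res, persistent = pers))
  ends <- igraph::as_edgelist(g)
  key <- apply(ends, 1, paste, collapse = "-")
  w <- igraph::E(g)$weight
  expect_setequal(key, c("A:1-B:1", "B:1-C:1"))   # negative C edge removed
  expect_equal(w[key == "A:1-B:1"], 0)            # -log(1) = 0
  expect_equal(w[key == "B:1-C:1"], log(2))       # -log(0.5), natural log
  # non-persistent pair with positive correlation gets no edge
  pers2 <- pers; pers2[2, 3] <- pers2[3, 2] <- FALSE
  g2 <- build_network(structure(list(residues = res, C = C),
                                class = "motion_correlation"),
                      list(residues = res, persistent = pers2))
  expect_equal(igraph::ecount(g2), 1L)
})

test_that("trajectories round-trip through multi-model PDB", {
  bs <- make_bottleneck_system()
  traj <- simulate_trajectory(trajectory_spec(bs$topology, bs$correlation,
                                              n_frames = 5L, seed = 3))
  tf <- tempfile(fileext = ".pdb")
  write_trajectory(traj, tf)
  back <- read_trajectory(tf)
  expect_equal(dim(back$coords), dim(traj$coords))
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)  # PDB has 3 decimals
  expect_equal(back$topology$atoms$chain, traj$topology$atoms$chain)
  # frame windowing
  win <- read_trajectory(tf, frame_start = 3L)
  expect_equal(dim(win$coords)[1L], 3L)
  expect_equal(win$coords[1, , ], traj$coords[3, , ], tolerance = 1e-3)
})
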