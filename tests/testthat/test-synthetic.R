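test_that("toy dimer: determinism, separation control and manifest
           completeness", {
  t1 <- make_toy_dimer(10, seed = 4)
  t2 <- make_toy_dimer(10, seed = 4)
  expect_identical(t1$dimer$atoms, t2$dimer$atoms)
  expect_identical(t1$truth$interface_resno, t2$truth$interface_resno)
  t3 <- make_toy_dimer(10, seed = 5)
  expect_false(identical(t1$dimer$atoms, t3$dimer$atoms))

  # translating the partner 50 A away leaves no interface pairs
  far <- t1$dimer$atoms
  far$x[far$chain == "B"] <- far$x[far$chain == "B"] + 50
  expect_equal(nrow(find_interface_pairs(new_structure(far), "A", "B")), 0L)
  # manifest records contacts that really are within 4 A
  expect_true(nrow(t1$truth$contact_pairs) > 0)
  expect_true(all(t1$truth$contact_pairs$resno_a %in%
                  t1$truth$interface_resno))
})

test_that("classifier recovers the generator's buried-residue set", {
  for (sd in 1:3) {
    td <- make_toy_dimer(10, seed = sd)
    sm <- compute_sasa(td$monomer)
    sc <- compute_sasa(td$dimer)
    cl <- classify_residues(sm, sc[sc$chain == "A", ])
    expect_equal(sort(cl$resno[cl$category == "interface"]),
                 sort(td$truth$interface_resno))
  }
})

test_that("simulated trajectories are deterministic and respect the
           planted correlation", {
  bs <- make_bottleneck_system()
  sp <- trajectory_spec(bs$topology, bs$correlation, n_frames = 200,
                        seed = 9)
  tr1 <- simulate_trajectory(sp)
  tr2 <- simulate_trajectory(sp)
  expect_identical(tr1$coords, tr2$coords)

  bad <- bs$correlation
  bad[1, 2] <- bad[2, 1] <- 5       # wildly non-PSD
  expect_error(simulate_trajectory(
    trajectory_spec(bs$topology, bad, n_frames = 10)), "positive semi")
})

test_that("planted identity correlation yields near-zero off-diagonals", {
  topo <- new_structure(data.frame(
    chain = LETTERS[1:6], resno = 1L, resid = "ALA", elety = "CA",
    element = "C", x = 10 * (0:5), y = 0, z = 0))
  sp <- trajectory_spec(topo, diag(6), n_frames = 5000, seed = 12)
  C <- motion_correlation(simulate_trajectory(sp))$C
  expect_equal(diag(C), rep(1, 6))
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
})

test_that("a planted perfect correlation is measured above 0.99", {
  topo <- new_structure(data.frame(
    chain = LETTERS[1:8], resno = 1L, resid = "ALA", elety = "CA",
    element = "C", x = 10 * (0:7), y = 0, z = 0))
  R <- diag(8)
  R[3, 7] <- R[7, 3] <- 1
  sp <- trajectory_spec(topo, R, n_frames = 5000, seed = 2)
  C <- motion_correlation(simulate_trajectory(sp))$C
  expect_gt(C[3, 7], 0.99)
})

test_that("Potts sampler: determinism, uniform null frequencies, and MI
           concentration on the coupled pair", {
  spec0 <- potts_spec(L = 8, M = 400, coupled_pairs = matrix(0L, 0, 2),
                      gap_prob = 0, seed = 3)
  m1 <- sample_potts_msa(spec0)
  m2 <- sample_potts_msa(spec0)
  expect_identical(m1$chars, m2$chars)

  # zero couplings, zero fields: per-column frequencies uniform (chi-square
  # goodness of fit, Bonferroni-wide bound), grand mean within 3 SE
  counts <- apply(m1$seq, 2, tabulate, nbins = 20)
  pvals <- apply(counts, 2, function(k) {
    stats::chisq.test(k, p = rep(1 / 20, 20))$p.value
  })
  expect_true(all(pvals > 1e-4))
  se <- sqrt(400 * (1 / 20) * (19 / 20))
  expect_lt(mean(abs(counts - 400 / 20)), 3 * se)

  # one strongly coupled pair attains the top empirical mutual information
  spec1 <- potts_spec(L = 8, M = 800, coupled_pairs = rbind(c(2L, 6L)),
                      coupling_strength = 2, gap_prob = 0, seed = 4)
  mc <- sample_potts_msa(spec1)
  mi <- function(x, y) {
    tab <- table(x, y) / length(x)
    px <- rowSums(tab); py <- colSums(tab)
    sum(tab * log(tab / outer(px, py)), na.rm = TRUE)
  }
  best <- c(NA, NA); best_mi <- -1
  for (i in 1:7) for (j in (i + 1):8) {
    v <- mi(mc$seq[, i], mc$seq[, j])
    if (v > best_mi) { best_mi <- v; best <- c(i, j) }
  }
  expect_equal(best, c(2, 6))

  expect_error(potts_spec(L = 8, M = 10, coupled_pairs = rbind(c(2L, 3L))),
               "separation")
  expect_error(potts_spec(L = 8, M = 10, coupled_pairs = rbind(c(2L, 6L)),
                          thin = 0L), "thin")
})

test_that("alignments round-trip through FASTA and manifests through
           JSON", {
  spec <- potts_spec(L = 6, M = 20, coupled_pairs = rbind(c(1L, 4L)),
                     gap_prob = 0.1, seed = 8)
  msa <- sample_potts_msa(spec)
  tf <- tempfile(fileext = ".fasta")
  write_alignment(msa, tf)
  back <- read_alignment(tf)
  expect_equal(back$chars, msa$chars, ignore_attr = TRUE)
  expect_equal(back$ids, msa$ids)

  mf <- tempfile(fileext = ".json")
  write_manifest(attr(msa, "truth"), mf)
  truth <- jsonlite::read_json(mf, simplifyVector = TRUE)
  expect_equal(matrix(truth$coupled_pairs, ncol = 2),
               matrix(spec$coupled_pairs, ncol = 2), ignore_attr = TRUE)
  expect_equal(truth$seed, 8)
})

test_that("structures round-trip through PDB", {
  td <- make_toy_dimer(8, seed = 6)
  tf <- tempfile(fileext = ".pdb")
  write_structure(td$dimer, tf)
  back <- read_structure(tf)
  expect_equal(nrow(back$atoms), nrow(td$dimer$atoms))
  expect_equal(back$atoms$x, td$dimer$atoms$x, tolerance = 1e-3)
  expect_equal(sort(unique(back$atoms$chain)), c("A", "B"))
})
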