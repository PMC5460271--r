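msa_from <- function(...) new_msa(do.call(rbind, strsplit(c(...), "")))

test_that("aligned FASTA parsing: dimensions, gap mapping, ragged error", {
  fa <- c(">s1", "ACD-", ">s2", "ac.w")
  a <- read_alignment(paste(fa, collapse = "\n"))
  expect_equal(dim(a$seq), c(2L, 4L))
  expect_equal(a$chars[2, ], c("A", "C", "-", "W"))   # uppercased, '.' -> gap
  expect_warning(ax <- read_alignment(">s1\nAXDW"), "nonstandard")
  expect_equal(ax$chars[1, 2], "-")
  expect_error(read_alignment(">s1\nACDE\n>s2\nAC"), "ragged")
})

test_that("gap-rich columns are removed with a strict >50% rule", {
  a <- msa_from("AC-E", "A--E", "AC-E", "ACWE", "A-W-", "ACW-",
                "ACWE", "ACWE", "ACWE", "ACWE")
  # gap fractions: 0, 0.2, 0.3, 0.3 -> nothing above 0.5
  expect_equal(filter_gap_columns(a)$colmap, 1:4)
  b <- msa_from("A-", "A-", "A-", "AC", "A-", "AC", "A-", "A-", "AC", "A-")
  # column 2 has 70% gaps -> dropped
  expect_equal(filter_gap_columns(b)$colmap, 1L)
  # exactly 50% gaps is retained
  d <- msa_from("A-", "AC", "A-", "AC")
  expect_equal(filter_gap_columns(d)$colmap, 1:2)
  allgap <- msa_from("--", "--")
  expect_error(filter_gap_columns(allgap), "all columns")
})

test_that("reweighting limits: redundant, distinct and the 3-sequence hand
           case", {
  ident <- msa_from("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKL")
  w <- sequence_weights(ident)
  expect_equal(w$m_a, rep(4, 4))
  expect_equal(w$M_eff, 1)

  set.seed(3)
  distinct <- new_msa(matrix(sample(c("A", "C", "D", "E", "F"), 8 * 20,
                                    replace = TRUE), 8, 20))
  wd <- sequence_weights(distinct)
  expect_equal(wd$M_eff, 8)   # all pairwise identities far below 0.8

  # two sequences 90% identical, third unrelated: m = (2, 2, 1), M_eff = 2
  hand <- msa_from("AAAAAAAAAA", "AAAAAAAAAC", "WWWWWWWWWW")
  wh <- sequence_weights(hand)
  expect_equal(wh$m_a, c(2, 2, 1))
  expect_equal(wh$M_eff, 2.0)

  # identity exactly at the threshold does not count as a neighbour
  border <- msa_from("AAAAAAAACC", "AAAAAAAAAA")  # identity = 0.8
  expect_equal(sequence_weights(border)$M_eff, 2)
  # gaps count as a state for identity
  gappy <- msa_from("AAAAAAAAA-", "AAAAAAAAA-")
  expect_equal(sequence_weights(gappy)$M_eff, 1)
})

test_that("frequency tables satisfy the analytic identities exactly", {
  set.seed(11)
  a <- new_msa(matrix(sample(c("A", "C", "D", "-", "W", "Y"), 12 * 6,
                             replace = TRUE), 12, 6))
  w <- sequence_weights(a)
  f <- frequencies(a, w, lambda = 0.5)
  expect_equal(rowSums(f$fi), rep(1, 6), tolerance = 1e-12)
  L <- 6L; q <- 21L
  for (i in 1:2) for (j in 3:4) {
    blk <- f$fij[(i - 1) * q + 1:q, (j - 1) * q + 1:q]
    expect_equal(rowSums(blk), f$fi[i, ], tolerance = 1e-12)
    expect_equal(colSums(blk), f$fi[j, ], tolerance = 1e-12)
    # f_ij(A,B) = f_ji(B,A)
    blk_t <- f$fij[(j - 1) * q + 1:q, (i - 1) * q + 1:q]
    expect_equal(blk, t(blk_t), tolerance = 1e-15)
  }
})

test_that("frequencies match a direct-summation oracle", {
  a <- msa_from("ACDW", "AC-W", "WCDA")
  w <- sequence_weights(a)
  f <- frequencies(a, w, lambda = 0.5)
  oracle <- direct_frequencies(a$seq, w$weight, w$M_eff, 0.5)
  expect_equal(matrix(f$fi, 4, 21), matrix(oracle$fi, 4, 21),
               tolerance = 1e-14)
  q <- 21L
  for (i in 1:4) for (j in 1:4) {
    expect_equal(f$fij[(i - 1) * q + 1:q, (j - 1) * q + 1:q],
                 oracle$fij[i, j, , ], tolerance = 1e-14)
  }
})

test_that("single sequence with lambda -> 0 concentrates all frequency", {
  a <- msa_from("AA")
  w <- sequence_weights(a)
  expect_warning(f <- frequencies(a, w, lambda = 0), "lambda = 0")
  expect_equal(f$fi[1, 1], 1)      # state 'A' is index 1
  expect_equal(sum(f$fi[1, -1]), 0)
})

test_that("couplings: symmetry, null-model spread, singularity guard", {
  set.seed(21)
  # independent columns over the 21-state alphabet (gaps populated so the
  # reference state of the reduced basis is observed): couplings are pure
  # noise. With the bare pseudocount the raw coupling spread is O(1), so
  # the bound is a sanity cap calibrated on the observed null spread; the
  # signal-bearing quantity (DI, tested below) stays two orders smaller
  # than for genuinely coupled pairs.
  a <- new_msa(matrix(sample(lectinet:::.aa_states, 5000 * 8,
                             replace = TRUE), 5000, 8))
  # i.i.d. rows are all far below the identity threshold: unit weights
  w <- list(weight = rep(1, 5000), M_eff = 5000)
  f <- frequencies(a, w, lambda = 0.5)
  cm <- couplings(f)
  qr <- 20L
  offdiag <- cm$e
  for (i in 1:8) offdiag[(i - 1) * qr + 1:qr, (i - 1) * qr + 1:qr] <- 0
  expect_lt(max(abs(offdiag)), 10)
  d_null <- direct_information(cm, f)
  expect_lt(max(d_null$DI), 0.15)
  # e_ij(A,B) = e_ji(B,A)
  expect_equal(cm$e, t(cm$e), tolerance = 1e-8)
  # degenerate data without pseudocount -> singular covariance
  degen <- msa_from("AAAA", "AAAA")
  wd <- sequence_weights(degen)
  fd <- suppressWarnings(frequencies(degen, wd, lambda = 0))
  expect_error(couplings(fd), "singular")
})

test_that("direct information: independence limit, nonnegativity,
           symmetry", {
  set.seed(31)
  a <- new_msa(matrix(sample(lectinet:::.aa_states,
                             2000 * 5, replace = TRUE), 2000, 5))
  w <- sequence_weights(a)
  f <- frequencies(a, w, lambda = 0.5)

  # zero couplings by construction: two-site model factorises, DI = 0
  cm0 <- structure(list(e = matrix(0, 5 * 20, 5 * 20), fi = f$fi, L = 5L,
                        q = 21L), class = "coupling_model")
  d0 <- direct_information(cm0, f)
  expect_equal(max(d0$DI), 0, tolerance = 1e-9)

  # fitted couplings on independent data: DI small but always >= 0
  d <- direct_information(couplings(f), f)
  expect_true(all(d$DI >= 0))
  expect_lt(max(d$DI), 0.3)
  expect_equal(d$DI, t(d$DI))
  expect_equal(diag(d$DI), rep(0, 5))
})

test_that("pair ranking flags by threshold and sequence separation", {
  DI <- matrix(0, 4, 4)
  DI[1, 3] <- DI[3, 1] <- 0.9
  DI[1, 2] <- DI[2, 1] <- 0.95   # adjacent columns: excluded from flags
  DI[2, 4] <- DI[4, 2] <- 0.5
  d <- structure(list(DI = DI), class = "direct_information")
  rp <- rank_pairs(d, threshold = 0.8, min_separation = 2L)
  expect_equal(rp$DI, sort(rp$DI, decreasing = TRUE))
  fl <- rp[rp$flagged, ]
  expect_equal(nrow(fl), 1L)
  expect_equal(c(fl$pos_i, fl$pos_j), c(1L, 3L))
  expect_equal(nrow(rank_pairs(d, threshold = 1.0)[rank_pairs(d,
               threshold = 1.0)$flagged, ]), 0L)
})

test_that("planted coupled pairs are recovered at the top of the DI
           ranking and the pipeline is deterministic", {
  pairs <- rbind(c(2, 7), c(4, 12))
  spec <- potts_spec(L = 14, M = 600, coupled_pairs = pairs,
                     coupling_strength = 2.0, gap_prob = 0.05, seed = 5)
  msa <- sample_potts_msa(spec)
  res1 <- run_dca(msa)
  res2 <- run_dca(msa)
  expect_identical(res1$di$DI, res2$di$DI)   # bit-identical rerun
  top <- res1$pairs[1:4, ]
  expect_true(all(pair_key(pairs[, 1], pairs[, 2]) %in%
                  pair_key(top$pos_i, top$pos_j)))
})

test_that("M_eff never increases when the identity threshold rises", {
  set.seed(41)
  chars <- matrix(sample(c("A", "C", "D"), 30 * 10, replace = TRUE), 30, 10)
  chars[2, ] <- chars[1, ]; chars[2, 1] <- "D"    # near-duplicate pair
  a <- new_msa(chars)
  m_eff <- vapply(c(0.5, 0.7, 0.8, 0.95),
                  function(th) sequence_weights(a, th)$M_eff, numeric(1))
  expect_true(all(diff(m_eff) >= -1e-12))
})
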