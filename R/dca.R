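# 21-letter alphabet: 20 amino acids + gap, gap last (reference state).
.aa_states <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
.n_states <- 21L
.gap_state <- 21L

#' Read an aligned FASTA file into an alignment object
#'
#' Sequences are uppercased; `'.'` and `'-'` both map to the gap state;
#' nonstandard residue letters (X, B, Z, ...) are mapped to gap with a
#' warning. All records must have equal length.
#'
#' @param fasta Path to an aligned FASTA file, or a character vector of
#'   FASTA lines.
#' @return An `msa` object: list with `ids`, integer matrix `seq`
#'   (`M x L`, states 1..21 with 21 = gap), character matrix `chars` and
#'   `colmap` (original column numbers, here `1:L`).
#' @export
read_alignment <- function(fasta) {
  if (length(fasta) == 1L && !grepl("\n", fasta) && file.exists(fasta)) {
    recs <- seqinr::read.fasta(fasta, seqtype = "AA", as.string = FALSE,
                               set.attributes = FALSE)
  } else {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    writeLines(unlist(strsplit(fasta, "\n", fixed = TRUE)), tf)
    recs <- seqinr::read.fasta(tf, seqtype = "AA", as.string = FALSE,
                               set.attributes = FALSE)
  }
  if (!length(recs)) stop("no FASTA records found")
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  chars <- toupper(do.call(rbind, recs))
  dimnames(chars) <- NULL
  chars[chars == "."] <- "-"
  new_msa(chars, ids = names(recs))
}

#' Construct an alignment object from a character matrix
#'
#' @param chars Character matrix (`M` sequences x `L` columns) of
#'   one-letter codes; `'-'`/`'.'` for gaps.
#' @param ids Sequence identifiers.
#' @param colmap Original column numbers (defaults to `1:L`).
#' @return An `msa` object.
#' @export
new_msa <- function(chars, ids = NULL, colmap = NULL) {
  chars <- toupper(chars)
  chars[chars == "."] <- "-"
  bad <- !(chars %in% .aa_states)
  if (any(bad)) {
    warning(sum(bad), " nonstandard residue letter(s) (",
            paste(unique(chars[bad]), collapse = ", "), ") mapped to gap")
    chars[bad] <- "-"
  }
  seq <- matrix(match(chars, .aa_states), nrow(chars), ncol(chars))
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(chars)))
  if (is.null(colmap)) colmap <- seq_len(ncol(chars))
  structure(list(ids = ids, seq = seq, chars = chars, colmap = colmap),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", nrow(x$seq), "sequences x", ncol(x$seq), "columns\n")
  invisible(x)
}

#' Drop gap-rich alignment columns
#'
#' Removes columns whose gap fraction is strictly above
#' `max_gap_fraction` (default 0.5, i.e. "more than 50% gaps"); a column
#' with exactly that fraction is retained. The `colmap` of the result
#' records the surviving original column numbers.
#'
#' @param a An `msa`.
#' @param max_gap_fraction Maximum tolerated gap fraction.
#' @return Filtered `msa`.
#' @export
filter_gap_columns <- function(a, max_gap_fraction = 0.5) {
  gapfrac <- colMeans(a$seq == .gap_state)
  keep <- gapfrac <= max_gap_fraction
  if (!any(keep)) stop("all columns exceed the gap-fraction limit")
  structure(list(ids = a$ids, seq = a$seq[, keep, drop = FALSE],
                 chars = a$chars[, keep, drop = FALSE],
                 colmap = a$colmap[keep]),
            class = "msa")
}

#' Sequence reweighting by identity clustering
#'
#' Each sequence `a` is down-weighted by `1/m_a`, where `m_a` counts the
#' sequences (including itself) with strictly more than
#' `identity_threshold` fractional identity to it; identity is computed
#' over all columns with the gap treated as a 21st state. The effective
#' sequence number is `M_eff = sum_a 1/m_a`.
#'
#' @param a An `msa`.
#' @param identity_threshold Fractional identity above which two sequences
#'   count as neighbours (default 0.8).
#' @return List with `m_a`, `weight` (`1/m_a`), `M_eff`,
#'   `identity_threshold`.
#' @export
sequence_weights <- function(a, identity_threshold = 0.8) {
  M <- nrow(a$seq); L <- ncol(a$seq)
  # one-hot encoding; matches between sequences = tcrossprod
  X <- Matrix::sparseMatrix(
    i = rep(seq_len(M), L),
    j = as.integer(a$seq) + rep((seq_len(L) - 1L) * .n_states, each = M),
    x = 1, dims = c(M, L * .n_states)
  )
  matches <- as.matrix(Matrix::tcrossprod(X))
  m_a <- rowSums(matches / L > identity_threshold)  # includes self (identity 1)
  list(m_a = m_a, weight = 1 / m_a, M_eff = sum(1 / m_a),
       identity_threshold = identity_threshold)
}

#' Reweighted, pseudocount-regularised frequency tables
#'
#' Single-column frequencies
#' `f_i(A) = (lambda/21 + sum_a w_a [A_i^a = A]) / (lambda + M_eff)` and
#' pair frequencies
#' `f_ij(A,B) = (lambda/21^2 + sum_a w_a [A_i^a = A][A_j^a = B]) /
#' (lambda + M_eff)` over the 21-state alphabet, with `w_a = 1/m_a`. The
#' marginal identity `sum_B f_ij(A,B) = f_i(A)` holds analytically.
#'
#' @param a An `msa`.
#' @param w Output of [sequence_weights()] on the same alignment.
#' @param lambda Pseudocount (default 0.5). `lambda = 0` is allowed with a
#'   warning; degenerate columns then make the downstream covariance
#'   singular.
#' @return A `freq_tables`: list with `fi` (`L x 21`), `fij`
#'   (`(L*21) x (L*21)`, block `(i,j)` holding `f_ij(A,B)`), `lambda`,
#'   `M_eff`, `L`.
#' @export
frequencies <- function(a, w, lambda = 0.5) {
  if (lambda == 0) warning("lambda = 0: zero frequencies possible, ",
                           "covariance may be singular")
  M <- nrow(a$seq); L <- ncol(a$seq); q <- .n_states
  X <- Matrix::sparseMatrix(
    i = rep(seq_len(M), L),
    j = as.integer(a$seq) + rep((seq_len(L) - 1L) * q, each = M),
    x = rep(w$weight, L), dims = c(M, L * q)
  )
  denom <- lambda + w$M_eff
  fi <- matrix(Matrix::colSums(X), L, q, byrow = TRUE)
  fi <- (fi + lambda / q) / denom
  # weighted pair counts: sum_a w_a one_hot_i one_hot_j; X carries w in both
  # factors, so divide the product by w once
  Xu <- Matrix::sparseMatrix(
    i = rep(seq_len(M), L),
    j = as.integer(a$seq) + rep((seq_len(L) - 1L) * q, each = M),
    x = 1, dims = c(M, L * q)
  )
  XtW <- Matrix::crossprod(Xu, X)   # sum_a w_a delta delta
  fij <- (as.matrix(XtW) + lambda / q^2) / denom
  structure(list(fi = fi, fij = fij, lambda = lambda, M_eff = w$M_eff, L = L),
            class = "freq_tables")
}

#' Mean-field couplings from the empirical covariance
#'
#' Builds the connected-correlation (covariance) matrix
#' `C_ij(A,B) = f_ij(A,B) - f_i(A) f_j(B)` on the reduced basis of the 20
#' amino-acid states (the gap is the reference state, whose couplings are
#' gauge-fixed to zero; the full 21-state matrix is singular by
#' construction), inverts it, and reads off the pair couplings
#' `e_ij(A,B) = -(C^{-1})_ij(A,B)`.
#'
#' @param f A `freq_tables`.
#' @return A `coupling_model`: list with `e` (`(L*20) x (L*20)`; block
#'   `(i,j)` holds `e_ij(A,B)` on the 20-state basis), `fi`, `L`, `q`.
#' @export
couplings <- function(f) {
  L <- f$L; q <- .n_states; qr <- q - 1L
  red <- as.vector(outer(seq_len(qr), (seq_len(L) - 1L) * q, "+"))
  C <- f$fij[red, red, drop = FALSE] -
    tcrossprod(as.vector(t(f$fi[, seq_len(qr), drop = FALSE])))
  # diagonal blocks: single-site multinomial covariance
  # f_i(A) delta_AB - f_i(A) f_i(B). The printed pair-frequency formula,
  # applied at i = j, gives identical rows for states unseen in a column
  # and an exactly singular matrix; the multinomial form is the standard
  # mean-field construction and is full-rank whenever lambda > 0.
  for (i in seq_len(L)) {
    b <- (i - 1L) * qr + seq_len(qr)
    fi <- f$fi[i, seq_len(qr)]
    C[b, b] <- diag(fi, qr) - tcrossprod(fi)
  }
  e <- tryCatch(-solve(C), error = function(err) {
    stop("covariance matrix is singular; use a pseudocount lambda > 0 (",
         conditionMessage(err), ")")
  })
  structure(list(e = e, fi = f$fi, L = L, q = q), class = "coupling_model")
}

# 21x21 coupling block of pair (i, j), gap row/column gauge-fixed to 0
.e_block <- function(c_model, i, j) {
  qr <- c_model$q - 1L
  bi <- (i - 1L) * qr + seq_len(qr)
  bj <- (j - 1L) * qr + seq_len(qr)
  e <- matrix(0, c_model$q, c_model$q)
  e[seq_len(qr), seq_len(qr)] <- c_model$e[bi, bj]
  e
}

#' Direct information of all column pairs
#'
#' For every column pair an isolated two-site model
#' `P_ij(A,B) = exp(e_ij(A,B) + h_i(A) + h_j(B)) / Z_ij` is fitted so that
#' its marginals reproduce the empirical single-column frequencies, by
#' alternating multiplicative field updates. The direct information is the
#' Kullback-Leibler divergence (natural log) of the fitted two-site
#' distribution from the factorised product of the single-column
#' frequencies; it is nonnegative and zero exactly when the pair decouples.
#'
#' @param c_model A `coupling_model`.
#' @param f The `freq_tables` the couplings were built from.
#' @param tol Convergence tolerance on the maximum marginal error
#'   (default 1e-6).
#' @param max_iter Iteration cap per pair (default 1000).
#' @return A `direct_information`: list with symmetric matrix `DI`
#'   (`L x L`, zero diagonal), `colmap` untouched (attach externally),
#'   `iterations` per pair.
#' @export
direct_information <- function(c_model, f, tol = 1e-6, max_iter = 1000L) {
  L <- c_model$L; q <- c_model$q
  DI <- matrix(0, L, L)
  iters <- matrix(0L, L, L)
  for (i in seq_len(L - 1L)) {
    fi <- f$fi[i, ]
    for (j in (i + 1L):L) {
      fj <- f$fi[j, ]
      e <- .e_block(c_model, i, j)
      # a constant shift of the couplings is absorbed by Z_ij; centring
      # keeps exp() in range for strongly coupled (or noisy) pairs
      W <- exp(pmax(e - max(e), -700))
      fit <- .fit_two_site(W, fi, fj, tol, max_iter)
      if (!fit$converged) {
        stop("two-site field fitting did not converge for pair (", i, ", ",
             j, ") after ", max_iter, " iterations")
      }
      P <- fit$P
      pos <- P > 0
      di <- sum(P[pos] * log(P[pos] / (fi %o% fj)[pos]))
      DI[i, j] <- DI[j, i] <- max(di, 0)
      iters[i, j] <- iters[j, i] <- fit$iter
    }
  }
  structure(list(DI = DI, iterations = iters), class = "direct_information")
}

# alternating fixed point on the two-site model marginals
.fit_two_site <- function(W, fi, fj, tol, max_iter) {
  mu_i <- rep(1 / length(fi), length(fi))
  mu_j <- rep(1 / length(fj), length(fj))
  for (it in seq_len(max_iter)) {
    mu_i <- fi / pmax(as.vector(W %*% mu_j), 1e-300)
    mu_i <- mu_i / sum(mu_i)
    mu_j <- fj / pmax(as.vector(crossprod(W, mu_i)), 1e-300)
    mu_j <- mu_j / sum(mu_j)
    P <- (mu_i %o% mu_j) * W
    P <- P / sum(P)
    err <- max(abs(rowSums(P) - fi), abs(colSums(P) - fj))
    if (err < tol) {
      return(list(P = P, iter = it, converged = TRUE))
    }
  }
  list(P = P, iter = max_iter, converged = FALSE)
}

#' Rank column pairs by direct information
#'
#' Sorts all column pairs by DI (descending) and flags coevolution
#' candidates: pairs with DI above `threshold` whose original positions
#' are at least `min_separation` columns apart (trivially coupled
#' neighbours are excluded from the flagged set, not from the table).
#'
#' @param d A `direct_information`.
#' @param threshold DI flagging threshold (default 0.8, the conventional
#'   significance level when the sequence number is comparable to the
#'   protein length).
#' @param min_separation Minimum sequence separation of flagged pairs
#'   (default 2).
#' @param colmap Original column numbers (default `1:L`).
#' @return Data frame with `i`, `j` (current columns), `pos_i`, `pos_j`
#'   (original positions), `DI`, `flagged`, sorted by DI descending.
#' @export
rank_pairs <- function(d, threshold = 0.8, min_separation = 2L,
                       colmap = NULL) {
  L <- nrow(d$DI)
  if (is.null(colmap)) colmap <- seq_len(L)
  ij <- which(upper.tri(d$DI), arr.ind = TRUE)
  out <- data.frame(i = ij[, 1L], j = ij[, 2L],
                    pos_i = colmap[ij[, 1L]], pos_j = colmap[ij[, 2L]],
                    DI = d$DI[ij], stringsAsFactors = FALSE)
  out$flagged <- out$DI > threshold &
    abs(out$pos_j - out$pos_i) >= min_separation
  out <- out[order(-out$DI, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full mean-field DCA pipeline on an alignment
#'
#' Gap-column filtering, identity reweighting, frequency estimation,
#' covariance inversion, two-site direct information and pair ranking in
#' one call.
#'
#' @param a An `msa` (or path to an aligned FASTA file).
#' @param lambda Pseudocount (default 0.5).
#' @param identity_threshold Reweighting identity threshold (default 0.8).
#' @param di_threshold DI flagging threshold (default 0.8).
#' @param max_gap_fraction Column gap-fraction filter (default 0.5).
#' @param min_separation Minimum separation for flagged pairs (default 2).
#' @param columns Optional integer vector restricting the analysis to a
#'   subset of (original) columns after gap filtering, e.g. the interface
#'   positions.
#' @return List with `pairs` (ranked table), `di`, `weights`, `freqs`,
#'   `manifest` (run parameters, M, L, M_eff).
#' @export
run_dca <- function(a, lambda = 0.5, identity_threshold = 0.8,
                    di_threshold = 0.8, max_gap_fraction = 0.5,
                    min_separation = 2L, columns = NULL) {
  if (is.character(a)) a <- read_alignment(a)
  filt <- filter_gap_columns(a, max_gap_fraction)
  if (!is.null(columns)) {
    keep <- which(filt$colmap %in% columns)
    if (length(keep) < 2L) stop("fewer than 2 requested columns survive filtering")
    filt <- structure(list(ids = filt$ids,
                           seq = filt$seq[, keep, drop = FALSE],
                           chars = filt$chars[, keep, drop = FALSE],
                           colmap = filt$colmap[keep]), class = "msa")
  }
  w <- sequence_weights(filt, identity_threshold)
  f <- frequencies(filt, w, lambda)
  cm <- couplings(f)
  di <- direct_information(cm, f)
  pairs <- rank_pairs(di, threshold = di_threshold,
                      min_separation = min_separation, colmap = filt$colmap)
  list(pairs = pairs, di = di, weights = w, freqs = f,
       manifest = list(M = nrow(filt$seq), L = ncol(filt$seq),
                       M_eff = w$M_eff, lambda = lambda,
                       identity_threshold = identity_threshold,
                       di_threshold = di_threshold,
                       max_gap_fraction = max_gap_fraction,
                       min_separation = min_separation))
}

#' Write a DI pair table and run manifest
#'
#' @param dca_result Output of [run_dca()].
#' @param tsv DI table TSV path.
#' @param manifest_json Optional manifest JSON path.
#' @return Invisible list of written paths.
#' @export
write_dca <- function(dca_result, tsv, manifest_json = NULL) {
  utils::write.table(dca_result$pairs, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(manifest_json)) {
    jsonlite::write_json(dca_result$manifest, manifest_json,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tsv = tsv, manifest_json = manifest_json))
}
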