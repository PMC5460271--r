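# Default hydrophobic set (Kyte-Doolittle-like 8-residue convention).
.hydrophobic_default <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' Per-column conservation scores and 9-grade scale
#'
#' Information-based conservation: the score of a column is one minus its
#' normalised Shannon entropy over the 20 amino-acid states (gaps are
#' excluded from the column distribution), so an invariant column scores 1
#' and a uniformly variable column scores 0. Scores are binned into 9
#' equal-width grades over `[0, 1]`, grade 9 the most conserved, mirroring
#' the familiar 9-grade conservation scale. This is an entropy stand-in,
#' not a phylogenetic rate model: no tree is inferred, and grade values are
#' not comparable to rate-based conservation services.
#'
#' @param a An `msa`.
#' @param gap_flag_fraction Columns with a gap fraction above this value
#'   are flagged (default 0.5); all-gap columns get `NA` score and grade.
#' @return Data frame with `column`, `position` (original numbering),
#'   `score`, `grade`, `gap_fraction`, `gap_flagged`.
#' @export
conservation_grades <- function(a, gap_flag_fraction = 0.5) {
  M <- nrow(a$seq); L <- ncol(a$seq)
  if (M < 5L) warning("fewer than 5 sequences: conservation scores are noisy")
  score <- rep(NA_real_, L)
  gapfrac <- colMeans(a$seq == .gap_state)
  for (i in seq_len(L)) {
    states <- a$seq[, i]
    states <- states[states != .gap_state]
    if (!length(states)) next
    pr <- tabulate(states, nbins = 20L)
    pr <- pr[pr > 0] / length(states)
    H <- -sum(pr * log(pr))
    score[i] <- 1 - H / log(20)
  }
  grade <- ifelse(is.na(score), NA_integer_,
                  pmin(9L, 1L + as.integer(floor(score * 9))))
  data.frame(column = seq_len(L), position = a$colmap, score = score,
             grade = grade, gap_fraction = gapfrac,
             gap_flagged = gapfrac > gap_flag_fraction | is.na(score))
}

#' Classify a residue as polar or hydrophobic
#'
#' @param residue One-letter amino-acid code(s).
#' @param hydrophobic_set Letters counted as hydrophobic (default
#'   `A, V, L, I, M, F, W, C`; everything else is polar). The set is
#'   configurable because polarity conventions differ at the margins
#'   (notably methionine).
#' @return Character vector of `"hydrophobic"`/`"polar"`.
#' @export
classify_hp <- function(residue, hydrophobic_set = .hydrophobic_default) {
  residue <- toupper(residue)
  bad <- !(residue %in% setdiff(.aa_states, "-"))
  if (any(bad)) {
    stop("cannot classify non-amino-acid letter(s): ",
         paste(unique(residue[bad]), collapse = ", "))
  }
  ifelse(residue %in% toupper(hydrophobic_set), "hydrophobic", "polar")
}

#' Hydrophobic-polar interaction-pattern resampling
#'
#' Compares the residue-pair character at two alignment positions between
#' single-domain and double-domain lectin alignments by repeated random
#' subsampling: per replicate, `n_single` of the single-domain and
#' `n_double` of the double-domain sequences are drawn without
#' replacement and the pair of each drawn sequence is classified as
#' polar-polar, polar-hydrophobic or hydrophobic-hydrophobic. Defaults
#' mirror the study conditions: 31 of 46 single-domain and 11 of 16
#' double-domain sequences, five replicates. Sequences with a gap at
#' either position are counted separately (`gapped`) rather than forced
#' into a class.
#'
#' @param single,double `msa` objects for the two domain classes.
#' @param pos_pair Length-2 integer vector: the two positions (original
#'   column numbering via `colmap`).
#' @param n_single,n_double Subsample sizes (defaults 31 and 11).
#' @param reps Number of replicates (default 5).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param hydrophobic_set Passed to [classify_hp()].
#' @return An `hp_pattern_result`: data frame with one row per replicate
#'   and domain class, columns `replicate`, `domain`, `n`, `polar_polar`,
#'   `polar_hydrophobic`, `hydrophobic_hydrophobic`, `gapped`, plus
#'   fraction columns; attributes record positions and seed.
#' @export
hp_pattern_analysis <- function(single, double, pos_pair,
                                n_single = 31L, n_double = 11L,
                                reps = 5L, seed = 1L,
                                hydrophobic_set = .hydrophobic_default) {
  stopifnot(length(pos_pair) == 2L)
  sets <- list(single = single, double = double)
  ns <- c(single = n_single, double = n_double)
  cols <- lapply(sets, function(a) {
    ix <- match(pos_pair, a$colmap)
    if (anyNA(ix)) stop("position(s) ", paste(pos_pair[is.na(ix)], collapse = ", "),
                        " not present in alignment")
    ix
  })
  for (d in names(sets)) {
    if (ns[[d]] > nrow(sets[[d]]$seq)) {
      stop("subsample size ", ns[[d]], " exceeds ", d, "-domain alignment size ",
           nrow(sets[[d]]$seq))
    }
    gf <- colMeans(sets[[d]]$chars[, cols[[d]], drop = FALSE] == "-")
    if (any(gf > 0.5)) {
      warning("position with >50% gaps in ", d, "-domain alignment")
    }
  }

  set.seed(as.integer(seed))
  rows <- list()
  for (r in seq_len(reps)) {
    for (d in names(sets)) {
      a <- sets[[d]]
      pick <- sample.int(nrow(a$seq), ns[[d]])
      r1 <- a$chars[pick, cols[[d]][1L]]
      r2 <- a$chars[pick, cols[[d]][2L]]
      gapped <- r1 == "-" | r2 == "-"
      cls <- rep(NA_character_, length(pick))
      if (any(!gapped)) {
        c1 <- classify_hp(r1[!gapped], hydrophobic_set)
        c2 <- classify_hp(r2[!gapped], hydrophobic_set)
        nh <- (c1 == "hydrophobic") + (c2 == "hydrophobic")
        cls[!gapped] <- c("polar_polar", "polar_hydrophobic",
                          "hydrophobic_hydrophobic")[nh + 1L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, domain = d, n = ns[[d]],
        polar_polar = sum(cls == "polar_polar", na.rm = TRUE),
        polar_hydrophobic = sum(cls == "polar_hydrophobic", na.rm = TRUE),
        hydrophobic_hydrophobic = sum(cls == "hydrophobic_hydrophobic",
                                      na.rm = TRUE),
        gapped = sum(gapped),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  for (cl in c("polar_polar", "polar_hydrophobic", "hydrophobic_hydrophobic")) {
    out[[paste0("frac_", cl)]] <- out[[cl]] / out$n
  }
  attr(out, "pos_pair") <- pos_pair
  attr(out, "seed") <- seed
  class(out) <- c("hp_pattern_result", "data.frame")
  out
}

#' Write conservation and HP-pattern tables
#'
#' @param x Data frame (conservation profile or `hp_pattern_result`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
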