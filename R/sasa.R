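# Van der Waals radii (Angstrom), NACCESS-style element defaults.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  FE = 1.47, ZN = 1.39, MG = 1.73, CA = 2.00, MN = 1.61, "NA" = 2.27, K = 2.75
)

# Theoretical per-residue maximum SASA (Angstrom^2), Tien et al. 2013.
.max_sasa <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# deterministic quasi-uniform sphere points (golden-spiral lattice)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by Shrake-Rupley sampling
#'
#' Rolls a probe sphere over the structure by testing quasi-uniform sample
#' points on each atom's solvent-accessible sphere (radius = van der Waals
#' radius + probe) against all neighbouring spheres. Per-atom areas are
#' summed per residue; relative SASA divides by the residue type's
#' theoretical maximum accessibility.
#'
#' @param s A `lectin_structure`.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Sample points per atom (default 960).
#' @param radii Named vector of van der Waals radii by element, overriding
#'   the bundled NACCESS-style table.
#' @param max_sasa Named vector of per-residue-type reference maxima
#'   (Angstrom^2) for relative SASA, overriding the bundled theoretical
#'   values.
#' @param include_het Include heteroatom residues in the calculation and
#'   the profile (they occlude protein atoms either way when present in
#'   `s`). Default `TRUE`.
#' @return A `sasa_profile`: data frame with columns `chain`, `resno`,
#'   `resid`, `sasa_abs`, `sasa_rel` (NA when the residue type has no
#'   reference maximum) and attributes `probe`, `n_points`.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960L, radii = NULL,
                         max_sasa = NULL, include_het = TRUE) {
  rt <- .vdw_radii
  if (!is.null(radii)) rt[names(radii)] <- radii
  mt <- .max_sasa
  if (!is.null(max_sasa)) mt[names(max_sasa)] <- max_sasa

  a <- s$atoms
  if (!include_het) a <- a[!a$het, , drop = FALSE]
  r <- rt[a$element]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1L]
    stop("no van der Waals radius for element '", a$element[bad],
         "' (atom ", a$elety[bad], " of ", a$resid[bad], " ",
         a$chain[bad], a$resno[bad], ")")
  }
  xyz <- cbind(a$x, a$y, a$z)
  rs <- unname(r) + probe                     # accessible-sphere radii
  pts <- .sphere_points(n_points)

  n <- nrow(a)
  area <- numeric(n)
  maxr <- max(rs)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums((xyz - matrix(xyz[i, ], n, 3L, byrow = TRUE))^2))
    nb <- which(di < rs[i] + maxr & seq_len(n) != i)
    nb <- nb[di[nb] < rs[i] + rs[nb]]
    if (!length(nb)) {
      area[i] <- 4 * pi * rs[i]^2
      next
    }
    p <- pts * rs[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    # a point is accessible if outside every neighbour's accessible sphere
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[acc, 1L] - xyz[j, 1L])^2 + (p[acc, 2L] - xyz[j, 2L])^2 +
             (p[acc, 3L] - xyz[j, 3L])^2
      acc[acc] <- dj2 > rs[j]^2
    }
    area[i] <- 4 * pi * rs[i]^2 * sum(acc) / n_points
  }

  key <- paste(a$chain, a$resno)
  res <- unique(a[, c("chain", "resno", "resid")])
  idx <- match(key, paste(res$chain, res$resno))
  abs_sasa <- as.numeric(rowsum(area, idx)[as.character(seq_len(nrow(res))), 1L])
  rel <- abs_sasa / unname(mt[res$resid])

  out <- data.frame(chain = res$chain, resno = res$resno, resid = res$resid,
                    sasa_abs = abs_sasa, sasa_rel = rel,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "probe") <- probe
  attr(out, "n_points") <- n_points
  class(out) <- c("sasa_profile", "data.frame")
  out
}

#' Classify residues by burial on complex formation
#'
#' Implements the interface definition for dimer formation: a residue is
#' *interface* when it is solvent exposed in the isolated monomer but not in
#' the complex; *surface* when exposed in both; *interior* when buried in
#' the monomer. "Exposed" means relative SASA above `exposed_threshold`.
#' Ligand-binding residues (supplied via `ligand_contacts`) take precedence
#' in the `category` column and are additionally reported as an independent
#' flag so the site sets may overlap.
#'
#' @param monomer_sasa `sasa_profile` of the isolated chain.
#' @param complex_sasa `sasa_profile` of the same chain computed within the
#'   complex (may cover more residues; it is matched on chain/resno).
#' @param exposed_threshold Relative-SASA exposure threshold (default 0.20).
#' @param ligand_contacts Optional data frame with `chain` and `resno`
#'   columns (e.g. from [find_ligand_contacts()]) naming ligand-binding
#'   residues.
#' @return Data frame with per-residue `rel_monomer`, `rel_complex`,
#'   `category` (one of `"ligand-binding"`, `"interface"`, `"surface"`,
#'   `"interior"`) and logical `ligand_binding`.
#' @export
classify_residues <- function(monomer_sasa, complex_sasa,
                              exposed_threshold = 0.20,
                              ligand_contacts = NULL) {
  mkey <- paste(monomer_sasa$chain, monomer_sasa$resno)
  ckey <- paste(complex_sasa$chain, complex_sasa$resno)
  miss <- setdiff(mkey, ckey)
  if (length(miss)) {
    stop("residue present in monomer profile only: ", miss[1L])
  }
  idx <- match(mkey, ckey)

  relm <- monomer_sasa$sasa_rel
  relc <- complex_sasa$sasa_rel[idx]
  if (anyNA(relm) || anyNA(relc)) {
    stop("relative SASA undefined (no reference maximum) for residue ",
         mkey[which(is.na(relm) | is.na(relc))[1L]])
  }

  lig <- rep(FALSE, length(mkey))
  if (!is.null(ligand_contacts) && nrow(ligand_contacts)) {
    lig <- mkey %in% paste(ligand_contacts$chain, ligand_contacts$resno)
  }

  category <- ifelse(relm <= exposed_threshold, "interior",
              ifelse(relc <= exposed_threshold, "interface", "surface"))
  category[lig] <- "ligand-binding"

  out <- data.frame(
    chain = monomer_sasa$chain, resno = monomer_sasa$resno,
    resid = monomer_sasa$resid,
    abs_monomer = monomer_sasa$sasa_abs, rel_monomer = relm,
    abs_complex = complex_sasa$sasa_abs[idx], rel_complex = relc,
    category = category, ligand_binding = lig,
    stringsAsFactors = FALSE
  )
  attr(out, "exposed_threshold") <- exposed_threshold
  class(out) <- c("residue_classification", "data.frame")
  out
}

#' Write a per-residue classification table
#'
#' @param classification Output of [classify_residues()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  utils::write.table(as.data.frame(classification), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
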