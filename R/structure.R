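#' @useDynLib lectinet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Residue names treated as solvent and dropped on read.
.water_names <- c("HOH", "WAT", "H2O", "DOD", "TIP", "TIP3", "SOL")

#' Read a protein structure from PDB text or file
#'
#' Parses ATOM/HETATM records into a heavy-atom structure. Hydrogens and
#' water molecules are dropped; non-water heteroatoms (e.g. a mannose
#' ligand) are retained and flagged with `het = TRUE`. When the file holds
#' several MODEL blocks, `model_index` selects the coordinate set.
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer of each atom.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB-format lines
#'   (anything containing a newline or an ATOM/HETATM record is treated as
#'   literal text).
#' @param model_index 1-based model number to extract (default 1).
#' @return An object of class `lectin_structure`: a list with element
#'   `atoms`, a data frame with columns `chain`, `resno`, `resid`, `elety`
#'   (atom name), `element`, `x`, `y`, `z` (Angstrom) and `het`.
#' @export
read_structure <- function(pdb, model_index = 1L) {
  lines <- .as_pdb_lines(pdb)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records found")

  # validate coordinate fields up front so the error can name the line
  coord_txt <- substr(lines[is_atom], 31L, 54L)
  bad <- which(is.na(suppressWarnings(as.numeric(substr(coord_txt, 1L, 8L)))) |
               is.na(suppressWarnings(as.numeric(substr(coord_txt, 9L, 16L)))) |
               is.na(suppressWarnings(as.numeric(substr(coord_txt, 17L, 24L)))))
  if (length(bad)) {
    stop("malformed coordinate field in PDB line: ",
         trimws(lines[is_atom][bad[1L]]))
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  multi <- sum(grepl("^MODEL", lines)) > 1L
  pdbobj <- bio3d::read.pdb(tf, multi = multi, verbose = FALSE)

  a <- pdbobj$atom
  if (multi) {
    nmod <- nrow(pdbobj$xyz)
    if (model_index < 1L || model_index > nmod) {
      stop("model_index ", model_index, " out of range (", nmod, " models)")
    }
    xyz <- matrix(pdbobj$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  } else if (model_index != 1L) {
    stop("model_index ", model_index, " out of range (1 model)")
  }

  elem <- .atom_elements(a)
  keep <- elem != "H" & !(toupper(a$resid) %in% .water_names)
  a <- a[keep, , drop = FALSE]
  elem <- elem[keep]
  if (!nrow(a)) stop("empty selection: no heavy protein or ligand atoms")

  atoms <- data.frame(
    chain = as.character(a$chain),
    resno = as.integer(a$resno),
    resid = toupper(as.character(a$resid)),
    elety = as.character(a$elety),
    element = elem,
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- " "

  # altloc: keep the highest-occupancy conformer per (chain, resno, elety)
  alt <- as.character(a$alt)
  if (any(!is.na(alt) & alt != "")) {
    occ <- a$o
    occ[is.na(occ)] <- 1
    key <- paste(atoms$chain, atoms$resno, atoms$elety)
    ord <- order(key, -occ)
    atoms <- atoms[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(match(paste(atoms$chain, atoms$resno, atoms$elety),
                               unique(key))), , drop = FALSE]
  }
  if (anyNA(atoms$x) || any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates after parsing")
  }
  rownames(atoms) <- NULL
  new_structure(atoms)
}

#' Construct a structure object from an atom table
#'
#' Low-level constructor used by the readers and the synthetic generators.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z` and optionally `het` (defaults to `FALSE`).
#' @return A `lectin_structure` object.
#' @export
new_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resid", "elety", "element",
                  "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) stop("duplicate (chain, resno, atom name): ",
                               key[anyDuplicated(key)])
  structure(list(atoms = atoms), class = "lectin_structure")
}

#' @export
print.lectin_structure <- function(x, ...) {
  a <- x$atoms
  cat("lectin_structure:", nrow(a), "heavy atoms,",
      nrow(unique(a[, c("chain", "resno")])), "residues, chains:",
      paste(sort(unique(a$chain)), collapse = " "), "\n")
  invisible(x)
}

#' Extract one or more chains as a new structure
#'
#' @param s A `lectin_structure`.
#' @param chains Character vector of chain identifiers.
#' @param keep_het Keep heteroatom (ligand) records of those chains.
#' @return A `lectin_structure` restricted to `chains`.
#' @export
extract_chains <- function(s, chains, keep_het = TRUE) {
  a <- s$atoms
  keep <- a$chain %in% chains & (keep_het | !a$het)
  if (!any(keep)) stop("chain(s) not found: ", paste(chains, collapse = ", "))
  new_structure(a[keep, , drop = FALSE])
}

.as_pdb_lines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    return(readLines(pdb, warn = FALSE))
  }
  unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
}

.atom_elements <- function(atom_df) {
  elem <- toupper(trimws(as.character(atom_df$elesy)))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) {
    # fall back on the atom-name convention: first alphabetic character
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", atom_df$elety[miss]))
    two <- toupper(substr(nm, 1L, 2L)) %in% c("CL", "BR", "FE", "ZN", "MG",
                                              "MN", "NA", "SE")
    elem[miss] <- toupper(ifelse(two, substr(nm, 1L, 2L), substr(nm, 1L, 1L)))
  }
  elem
}

.residue_table <- function(s, het = FALSE) {
  a <- s$atoms[s$atoms$het == het | het, , drop = FALSE]
  unique(a[, c("chain", "resno", "resid")])
}

#' Interacting residue pairs across a dimer interface
#'
#' Finds all cross-chain residue pairs whose minimum heavy-atom distance is
#' below `cutoff` (default 4 Angstrom, the standard interacting-pair rule
#' for protein-protein interfaces). The reported distance is the minimum
#' over all heavy-atom pairs, one atom from each residue.
#'
#' @param complex A `lectin_structure` holding both chains.
#' @param chain_a,chain_b Chain identifiers of the two partners.
#' @param cutoff Distance cutoff in Angstrom; pairs with minimum distance
#'   strictly below it are reported.
#' @param include_het Include heteroatom residues (default `FALSE`:
#'   protein residues only).
#' @return Data frame with columns `chain_a`, `resno_a`, `resid_a`,
#'   `chain_b`, `resno_b`, `resid_b`, `distance`, sorted by chain-A residue
#'   number. Zero rows if no pair lies within the cutoff.
#' @export
find_interface_pairs <- function(complex, chain_a, chain_b, cutoff = 4.0,
                                 include_het = FALSE) {
  a <- complex$atoms
  if (!include_het) a <- a[!a$het, , drop = FALSE]
  aa <- a[a$chain == chain_a, , drop = FALSE]
  ab <- a[a$chain == chain_b, , drop = FALSE]
  if (!nrow(aa)) stop("chain missing: ", chain_a)
  if (!nrow(ab)) stop("chain missing: ", chain_b)

  dmin <- .min_residue_distances(aa, ab)
  hits <- which(dmin$d < cutoff, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    chain_a = chain_a,
    resno_a = dmin$res_a$resno[hits[, 1L]],
    resid_a = dmin$res_a$resid[hits[, 1L]],
    chain_b = chain_b,
    resno_b = dmin$res_b$resno[hits[, 2L]],
    resid_b = dmin$res_b$resid[hits[, 2L]],
    distance = dmin$d[hits],
    stringsAsFactors = FALSE
  )
  out[order(out$resno_a, out$resno_b), , drop = FALSE]
}

# minimum heavy-atom distance between every residue of `aa` and of `ab`
.min_residue_distances <- function(aa, ab) {
  res_a <- unique(aa[, c("chain", "resno", "resid")])
  res_b <- unique(ab[, c("chain", "resno", "resid")])
  ia <- match(paste(aa$chain, aa$resno), paste(res_a$chain, res_a$resno))
  ib <- match(paste(ab$chain, ab$resno), paste(res_b$chain, res_b$resno))
  xa <- cbind(aa$x, aa$y, aa$z)
  xb <- cbind(ab$x, ab$y, ab$z)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  cols_by_res <- split(seq_len(nrow(ab)), ib)
  d <- matrix(Inf, nrow(res_a), nrow(res_b))
  for (k in seq_len(nrow(aa))) {
    row_min <- vapply(cols_by_res, function(ix) min(d2[k, ix]), numeric(1L))
    j <- as.integer(names(cols_by_res))
    d[ia[k], j] <- pmin(d[ia[k], j], row_min)
  }
  list(d = sqrt(d), res_a = res_a, res_b = res_b)
}

#' Protein residues in contact with a bound ligand
#'
#' Distance-based ligand-contact detection: a protein residue is a binding
#' residue when any of its heavy atoms lies within `cutoff` of any heavy
#' atom of a ligand residue named in `ligand_names`.
#'
#' @param s A `lectin_structure` containing ligand heteroatoms.
#' @param ligand_names Residue names identifying the ligand (e.g. `"MAN"`
#'   for mannose).
#' @param cutoff Contact cutoff in Angstrom (default 3.9).
#' @return Data frame of contacting protein residues (`chain`, `resno`,
#'   `resid`, `min_distance`).
#' @export
find_ligand_contacts <- function(s, ligand_names, cutoff = 3.9) {
  a <- s$atoms
  lig <- a[a$resid %in% toupper(ligand_names), , drop = FALSE]
  if (!nrow(lig)) stop("no ligand residue matching: ",
                       paste(ligand_names, collapse = ", "))
  prot <- a[!a$het & !(a$resid %in% toupper(ligand_names)), , drop = FALSE]
  if (!nrow(prot)) stop("no protein atoms in structure")
  dmin <- .min_residue_distances(prot, lig)
  mind <- apply(dmin$d, 1L, min)
  sel <- mind < cutoff
  out <- cbind(dmin$res_a[sel, , drop = FALSE],
               min_distance = mind[sel])
  rownames(out) <- NULL
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Write an interface contact-pair table
#'
#' Distances are formatted to two decimals in the file; the in-memory table
#' keeps full precision.
#'
#' @param pairs Output of [find_interface_pairs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_pairs <- function(pairs, path) {
  tab <- pairs
  tab$distance <- sprintf("%.2f", tab$distance)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
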