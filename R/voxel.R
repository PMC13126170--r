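# Structure-based featurisation: atoms of superposed A-domain models are
# binned into a cubic voxel grid centred on the substrate-binding pocket
# (the beta-carbon of the reference-bound phenylalanine), with per-voxel
# counts kept separately for 7 atom-type channels.

#' Atom-type channels for voxelisation
#'
#' Channel order of the voxel feature vector.
#' @return Character vector of the 7 channel names.
#' @export
voxel_channels <- function() {
  c("aromatic", "hydrophobic", "charged_oxygen", "noncharged_oxygen",
    "charged_nitrogen", "noncharged_nitrogen", "sulphur")
}

# (residue, atom-name) pairs classified ahead of the element defaults
AROMATIC_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "CD2", "CE1"))
CHARGED_O_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
CHARGED_N_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

#' Classify atoms into voxel channels
#'
#' Deterministic table-driven rules assigning each atom to exactly one of
#' the 7 channels, or `NA` (unclassified, e.g. hydrogens, metals,
#' phosphorus): side-chain ring carbons of Phe/Tyr/Trp/His are `aromatic`;
#' every other carbon is `hydrophobic`; Asp/Glu carboxylate oxygens and the
#' `OXT` terminus are `charged_oxygen`, other oxygens `noncharged_oxygen`;
#' the Lys amine and Arg guanidinium nitrogens are `charged_nitrogen`,
#' other nitrogens `noncharged_nitrogen`; sulphur atoms are `sulphur`.
#'
#' @param atoms Data.frame with columns `elety` (PDB atom name), `resid`
#'   (3-letter residue name) and `elesy` (element symbol).
#' @return Character vector of channel names (`NA` for unclassified atoms).
#' @export
classify_atoms <- function(atoms) {
  elety <- toupper(trimws(as.character(atoms$elety)))
  resid <- toupper(trimws(as.character(atoms$resid)))
  elesy <- toupper(trimws(as.character(atoms$elesy)))
  # fall back to the leading letter of the atom name when element is absent
  elesy[!nzchar(elesy) | is.na(elesy)] <-
    substr(gsub("[0-9]", "", elety[!nzchar(elesy) | is.na(elesy)]), 1, 1)
  n <- length(elety)
  ch <- rep(NA_character_, n)
  pick <- function(tab, res, atom)
    res %in% names(tab) & mapply(function(r, a) a %in% tab[[r]], res, atom)
  ch[elesy == "C"] <- "hydrophobic"
  aro <- pick(AROMATIC_ATOMS, resid, elety) & elesy == "C"
  ch[aro] <- "aromatic"
  ch[elesy == "O"] <- "noncharged_oxygen"
  ch[(pick(CHARGED_O_ATOMS, resid, elety) | elety == "OXT") & elesy == "O"] <-
    "charged_oxygen"
  ch[elesy == "N"] <- "noncharged_nitrogen"
  ch[pick(CHARGED_N_ATOMS, resid, elety) & elesy == "N"] <- "charged_nitrogen"
  ch[elesy == "S"] <- "sulphur"
  ch
}

#' Define a voxel grid
#'
#' A cube of `n^3` voxels centred at `center`. Voxel intervals are
#' half-open (`[lo, hi)`), so an atom exactly on a shared boundary belongs
#' deterministically to the voxel whose lower edge it sits on; atoms
#' outside the cube are dropped.
#'
#' @param center Numeric xyz of the grid centre, in Angstrom. The reference
#'   frame is that of the superposed structures (pocket-centred).
#' @param edge Cube edge length in Angstrom (default 16, i.e. 0.8 A voxels
#'   with the default resolution).
#' @param n Voxels per axis (default 20).
#' @return Object of class `voxel_grid`.
#' @export
voxel_grid <- function(center = c(0, 0, 0), edge = 16, n = 20L) {
  stopifnot(length(center) == 3L, edge > 0, n >= 1L)
  structure(list(center = as.numeric(center), edge = as.numeric(edge),
                 n = as.integer(n)),
            class = "voxel_grid")
}

#' Voxelise a superposed structure
#'
#' Counts atoms per voxel and channel, returning the counts flattened
#' voxel-major: for voxel (x fastest, then y, then z), the 7 channel counts
#' in [voxel_channels()] order. With the default 20-voxel grid the result
#' has length 56,000, and its sum equals the number of classified atoms
#' inside the grid.
#'
#' @param atoms Data.frame with columns `x`, `y`, `z`, `elety`, `resid`,
#'   `elesy` (as produced by [read_structure()]), or a `bio3d` `pdb`
#'   object.
#' @param grid A [voxel_grid()].
#' @return Integer vector of length `grid$n^3 * 7`.
#' @export
voxelise_structure <- function(atoms, grid = voxel_grid()) {
  if (inherits(atoms, "pdb")) atoms <- atoms$atom
  if (is.null(atoms) || nrow(atoms) == 0L)
    return(integer(grid$n^3 * 7L))
  need <- c("x", "y", "z", "elety", "resid")
  if (!all(need %in% names(atoms)))
    stop("malformed atom records: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"elesy" %in% names(atoms)) atoms$elesy <- ""
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!is.numeric(xyz) || anyNA(xyz))
    stop("malformed atom records: non-numeric coordinates", call. = FALSE)
  ch <- match(classify_atoms(atoms), voxel_channels())
  half <- grid$edge / 2
  vox <- floor(sweep(xyz, 2L, grid$center - half) / (grid$edge / grid$n))
  inside <- rowSums(vox >= 0 & vox <= grid$n - 1L) == 3L & !is.na(ch)
  counts <- integer(grid$n^3 * 7L)
  if (any(inside)) {
    v <- vox[inside, , drop = FALSE]
    flat_voxel <- v[, 1] + grid$n * v[, 2] + grid$n^2 * v[, 3]
    idx <- as.integer(flat_voxel * 7L + (ch[inside] - 1L) + 1L)
    tab <- table(idx)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records via `bio3d::read.pdb` and returns the atom
#' table used by [voxelise_structure()].
#'
#' @param path PDB file.
#' @return Data.frame of atoms with coordinates and annotations.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("malformed PDB file: ",
                                           conditionMessage(e), call. = FALSE))
  pdb$atom
}
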