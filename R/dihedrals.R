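## Backbone (phi/psi) and side-chain (chi) dihedral time series.

#' Construct a DihedralSeries
#'
#' One object holds a single torsion kind (phi, psi, chi1, ...) for a set of
#' residues over all frames.
#'
#' @param kind one of "phi", "psi", "chi1", "chi2", "chi3".
#' @param resno integer residue numbers (columns of `values`).
#' @param values n_frames x n_residues matrix, degrees in (-180, 180];
#'   NA marks an absent angle.
#' @param chain chain id.
#' @param flags named character vector of reasons for residues whose whole
#'   series is absent (name = residue number).
#' @return object of class `DihedralSeries`.
#' @export
dihedral_series <- function(kind, resno, values, chain = "A",
                            flags = character()) {
  kind <- match.arg(kind, c("phi", "psi", "chi1", "chi2", "chi3"))
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(resno))
  fin <- values[is.finite(values)]
  if (length(fin) > 0L && (any(fin <= -180) || any(fin > 180))) {
    stop("dihedral values outside (-180, 180]")
  }
  colnames(values) <- as.character(resno)
  structure(list(kind = kind, resno = as.integer(resno), chain = chain,
                 values = values, flags = flags),
            class = "DihedralSeries")
}

#' @export
print.DihedralSeries <- function(x, ...) {
  cat("DihedralSeries <", x$kind, ">: ", ncol(x$values), " residues x ",
      nrow(x$values), " frames, chain ", x$chain, "\n", sep = "")
  if (length(x$flags) > 0L) {
    cat("  absent:", paste(names(x$flags), x$flags, sep = ": ",
                           collapse = "; "), "\n")
  }
  invisible(x)
}

## Index atoms of one (chain, resno, elety); NA when missing or no residue.
.atom_index <- function(atoms, chain, resno, elety) {
  i <- which(atoms$chain == chain & atoms$resno == resno &
               atoms$elety == elety)
  if (length(i) == 0L) NA_integer_ else i[1]
}

#' Backbone phi/psi dihedral series
#'
#' Computes phi (C- N CA C) and psi (N CA C N+) for every residue of a
#' chain, per frame, in the IUPAC sign convention. Torsions spanning a
#' chain break (consecutive CA-CA distance > `break_cutoff` in a frame) or
#' a missing backbone atom are NA.
#'
#' @param traj a `Trajectory`.
#' @param chain chain id (default first chain present).
#' @param break_cutoff CA-CA distance (Angstrom) beyond which consecutive
#'   residues are treated as disconnected. Default 4.5.
#' @return list with elements `phi` and `psi`, each a `DihedralSeries`.
#' @export
backbone_dihedrals <- function(traj, chain = NULL, break_cutoff = 4.5) {
  validate_trajectory(traj)
  at <- traj$atoms
  if (is.null(chain)) chain <- at$chain[1]
  resno <- unique(at$resno[at$chain == chain])
  nres <- length(resno)
  if (nres < 2L) stop("chain ", chain, " has fewer than 2 residues")
  nf <- n_frames(traj)

  iN <- vapply(resno, function(r) .atom_index(at, chain, r, "N"), 1L)
  iCA <- vapply(resno, function(r) .atom_index(at, chain, r, "CA"), 1L)
  iC <- vapply(resno, function(r) .atom_index(at, chain, r, "C"), 1L)

  ## per-frame connectivity between residue i and i+1
  connected <- matrix(FALSE, nf, nres - 1L)
  for (i in seq_len(nres - 1L)) {
    if (!is.na(iCA[i]) && !is.na(iCA[i + 1L]) &&
        resno[i + 1L] == resno[i] + 1L) {
      d <- .vnorm(atom_xyz(traj, iCA[i + 1L]) - atom_xyz(traj, iCA[i]))
      connected[, i] <- d <= break_cutoff
    }
  }

  phi <- matrix(NA_real_, nf, nres)
  psi <- matrix(NA_real_, nf, nres)
  phi_flags <- character(); psi_flags <- character()
  for (i in seq_len(nres)) {
    ## phi_i: C(i-1) N(i) CA(i) C(i)
    if (i > 1L) {
      ok <- !is.na(iC[i - 1L]) && !is.na(iN[i]) && !is.na(iCA[i]) &&
        !is.na(iC[i])
      if (ok) {
        v <- torsion_angle(atom_xyz(traj, iC[i - 1L]), atom_xyz(traj, iN[i]),
                           atom_xyz(traj, iCA[i]), atom_xyz(traj, iC[i]))
        v[!connected[, i - 1L]] <- NA_real_
        phi[, i] <- v
      } else {
        phi_flags[as.character(resno[i])] <- "missing backbone atom"
      }
    } else {
      phi_flags[as.character(resno[i])] <- "no preceding residue"
    }
    ## psi_i: N(i) CA(i) C(i) N(i+1)
    if (i < nres) {
      ok <- !is.na(iN[i]) && !is.na(iCA[i]) && !is.na(iC[i]) &&
        !is.na(iN[i + 1L])
      if (ok) {
        v <- torsion_angle(atom_xyz(traj, iN[i]), atom_xyz(traj, iCA[i]),
                           atom_xyz(traj, iC[i]), atom_xyz(traj, iN[i + 1L]))
        v[!connected[, i]] <- NA_real_
        psi[, i] <- v
      } else {
        psi_flags[as.character(resno[i])] <- "missing backbone atom"
      }
    } else {
      psi_flags[as.character(resno[i])] <- "no following residue"
    }
  }
  list(phi = dihedral_series("phi", resno, phi, chain, phi_flags),
       psi = dihedral_series("psi", resno, psi, chain, psi_flags))
}

## Standard chi-defining atom quadruplets. Each entry: list of atom-name
## vectors, chi1 = (N, CA, CB, X), chi2 = (CA, CB, X, Y), chi3 where defined.
.chi_atoms <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","NE")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","CE")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"), c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

#' Side-chain chi dihedral series
#'
#' Computes chi torsions for selected residues using the standard atom-name
#' quadruplets per residue type. Residue types lacking a requested chi
#' (e.g. Ala for chi1, Ser for chi2) yield an all-NA series with an
#' explicit flag, as do residues with missing side-chain atoms.
#'
#' @param traj a `Trajectory`.
#' @param residues integer vector of residue numbers.
#' @param chain chain id (default first chain).
#' @param kinds which torsions to compute, subset of
#'   `c("chi1","chi2","chi3")`.
#' @return named list of `DihedralSeries`, one per requested kind.
#' @export
sidechain_chi <- function(traj, residues, chain = NULL,
                          kinds = c("chi1", "chi2")) {
  validate_trajectory(traj)
  at <- traj$atoms
  if (is.null(chain)) chain <- at$chain[1]
  kinds <- match.arg(kinds, c("chi1", "chi2", "chi3"), several.ok = TRUE)
  nf <- n_frames(traj)
  out <- list()
  for (k in kinds) {
    ik <- as.integer(sub("chi", "", k))
    vals <- matrix(NA_real_, nf, length(residues))
    flags <- character()
    for (j in seq_along(residues)) {
      r <- residues[j]
      rtype <- at$resid[at$chain == chain & at$resno == r][1]
      if (is.na(rtype)) {
        flags[as.character(r)] <- "residue not found"
        next
      }
      quads <- .chi_atoms[[rtype]]
      if (is.null(quads) || length(quads) < ik) {
        flags[as.character(r)] <- paste0("no such torsion for ", rtype)
        next
      }
      idx <- vapply(quads[[ik]], function(a) .atom_index(at, chain, r, a), 1L)
      if (anyNA(idx)) {
        flags[as.character(r)] <- paste0("missing atom ",
                                         quads[[ik]][which(is.na(idx))[1]])
        next
      }
      vals[, j] <- torsion_angle(atom_xyz(traj, idx[1]),
                                 atom_xyz(traj, idx[2]),
                                 atom_xyz(traj, idx[3]),
                                 atom_xyz(traj, idx[4]))
    }
    out[[k]] <- dihedral_series(k, residues, vals, chain, flags)
  }
  out
}
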