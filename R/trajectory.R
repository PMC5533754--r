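## Trajectory container and structure-file I/O.
##
## Coordinates are stored as a 3D array [frame, atom, xyz] in Angstrom, with
## an atom table carrying PDB-style labels. Multi-MODEL PDB is the canonical
## interchange dialect; DCD (+ PDB topology) is a read-only adapter.

#' Construct a Trajectory
#'
#' @param xyz numeric array \[n_frames, n_atoms, 3\] (Angstrom), or an
#'   n_atoms x 3 matrix for a single frame.
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (residue name), `resno` (residue number), `chain`, `elesy` (element).
#' @param frame_times optional numeric vector of frame times (ps).
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(xyz, atoms, frame_times = NULL) {
  if (length(dim(xyz)) == 2L) {
    xyz <- array(xyz, dim = c(1L, nrow(xyz), 3L))
  }
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[3] == 3L)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("elety", "resid", "resno", "chain", "elesy")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  obj <- structure(list(xyz = xyz, atoms = atoms, frame_times = frame_times),
                   class = "Trajectory")
  validate_trajectory(obj)
  obj
}

#' Validate Trajectory invariants
#'
#' Checks frame/atom consistency, finite coordinates and monotone residue
#' numbering within each chain.
#'
#' @param traj a `Trajectory`.
#' @return the object, invisibly; errors on violation.
#' @export
validate_trajectory <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  d <- dim(traj$xyz)
  if (d[2] != nrow(traj$atoms)) {
    stop("coordinate array has ", d[2], " atoms but atom table has ",
         nrow(traj$atoms))
  }
  if (!all(is.finite(traj$xyz))) stop("non-finite coordinates in trajectory")
  if (!is.null(traj$frame_times) && length(traj$frame_times) != d[1]) {
    stop("frame_times length does not match frame count")
  }
  for (ch in unique(traj$atoms$chain)) {
    rn <- traj$atoms$resno[traj$atoms$chain == ch]
    if (any(diff(rn) < 0)) {
      stop("residue numbers not monotone within chain ", ch)
    }
    ## strictly increasing at the residue level: no residue revisited
    r <- rle(rn)$values
    if (anyDuplicated(r)) stop("residue ", r[duplicated(r)][1],
                               " appears in disjoint blocks in chain ", ch)
  }
  invisible(traj)
}

#' @export
print.Trajectory <- function(x, ...) {
  d <- dim(x$xyz)
  cat("Trajectory:", d[1], "frame(s),", d[2], "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      "chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' Number of atoms in a trajectory
#' @param traj a `Trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(traj) dim(traj$xyz)[2]

#' Coordinates of one frame
#' @param traj a `Trajectory`.
#' @param i frame index.
#' @return n_atoms x 3 matrix.
#' @export
frame_xyz <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$xyz[i, , ], ncol = 3L)
}

## Coordinates of one atom across frames: n_frames x 3 matrix.
atom_xyz <- function(traj, j) matrix(traj$xyz[, j, ], ncol = 3L)

#' Load a structure trajectory
#'
#' Reads a multi-MODEL (or single-model) PDB file, or a binary DCD
#' trajectory with a separate PDB topology. Only the first alternate
#' location is kept; insertion codes are rejected.
#'
#' @param path path to a `.pdb` or `.dcd` file.
#' @param topology PDB topology path, required for DCD input.
#' @return a `Trajectory`.
#' @export
load_trajectory <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    if (is.null(topology)) stop("DCD input requires a PDB topology file")
    top <- load_trajectory(topology)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (ncol(xyz) != 3L * n_atoms(top)) {
      stop("DCD atom count (", ncol(xyz) / 3, ") does not match topology (",
           n_atoms(top), ")")
    }
    return(trajectory(.xyz_to_array(xyz), top$atoms))
  }
  .check_pdb_records(path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("could not parse PDB ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if ("alt" %in% names(at)) {
    ## keep first altloc per atom site
    alt <- at$alt
    site <- paste(at$chain, at$resno, at$elety)
    first_alt <- !duplicated(site)
    keep <- is.na(alt) | alt == "" | first_alt
  }
  idx <- which(keep)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- as.vector(rbind(3L * (idx - 1L) + 1L, 3L * (idx - 1L) + 2L,
                          3L * idx))
  xyz <- xyz[, cols, drop = FALSE]
  at <- at[idx, , drop = FALSE]
  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(elety = at$elety, resid = at$resid, resno = at$resno,
                      chain = chain, elesy = .element_of(at),
                      stringsAsFactors = FALSE)
  trajectory(.xyz_to_array(xyz), atoms)
}

## Pre-parse sanity pass over raw PDB lines: consistent MODEL atom counts,
## insertion-code rejection, line numbers in error messages.
.check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  icode <- substr(lines[is_atom], 27, 27)
  bad <- which(icode != " " & icode != "")
  if (length(bad) > 0L) {
    stop("insertion codes are not supported (line ",
         which(is_atom)[bad[1]], " of ", path, ")")
  }
  short <- which(nchar(lines[is_atom]) < 54)
  if (length(short) > 0L) {
    stop("unreadable ATOM record: line ", which(is_atom)[short[1]],
         " of ", path, " is too short for coordinates")
  }
  model_starts <- grepl("^MODEL", lines)
  if (sum(model_starts) > 1L) {
    mdl <- cumsum(model_starts)[is_atom]
    counts <- table(mdl[mdl > 0])
    if (length(unique(as.integer(counts))) > 1L) {
      stop("inconsistent atom counts across MODELs in ", path, ": ",
           paste(as.integer(counts), collapse = ", "))
    }
  }
  invisible(TRUE)
}

.element_of <- function(at) {
  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  guess <- toupper(substr(trimws(gsub("[0-9']", "", at$elety)), 1, 1))
  ifelse(is.na(el) | el == "", guess, trimws(el))
}

.xyz_to_array <- function(xyz) {
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  a <- array(NA_real_, dim = c(nf, na, 3L))
  a[, , 1] <- xyz[, seq(1L, by = 3L, length.out = na)]
  a[, , 2] <- xyz[, seq(2L, by = 3L, length.out = na)]
  a[, , 3] <- xyz[, seq(3L, by = 3L, length.out = na)]
  a
}

.array_to_xyz <- function(a) {
  nf <- dim(a)[1]; na <- dim(a)[2]
  xyz <- matrix(NA_real_, nf, 3L * na)
  xyz[, seq(1L, by = 3L, length.out = na)] <- a[, , 1]
  xyz[, seq(2L, by = 3L, length.out = na)] <- a[, , 2]
  xyz[, seq(3L, by = 3L, length.out = na)] <- a[, , 3]
  xyz
}

#' Write a trajectory as multi-MODEL PDB
#'
#' @param traj a `Trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  validate_trajectory(traj)
  at <- traj$atoms
  bio3d::write.pdb(file = path,
                   xyz = .array_to_xyz(traj$xyz),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = ifelse(at$chain == " ", "", at$chain),
                   elesy = at$elesy)
  invisible(path)
}

#' Subset a trajectory by frame stride
#'
#' @param traj a `Trajectory`.
#' @param stride keep every `stride`-th frame (default 1 = all).
#' @param burn_in number of initial frames to drop (default 0).
#' @return a `Trajectory`.
#' @export
thin_frames <- function(traj, stride = 1L, burn_in = 0L) {
  stopifnot(stride >= 1L, burn_in >= 0L)
  idx <- seq.int(burn_in + 1L, n_frames(traj), by = stride)
  trajectory(traj$xyz[idx, , , drop = FALSE], traj$atoms,
             traj$frame_times[idx])
}

## Resolve an atom selection against the atom table.
## sel: list with optional fields resno, chain, elety, elesy, resid.
resolve_selection <- function(traj, sel, what = "selection") {
  at <- traj$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$resno)) keep <- keep & at$resno %in% sel$resno
  if (!is.null(sel$chain)) keep <- keep & at$chain %in% sel$chain
  if (!is.null(sel$elety)) keep <- keep & at$elety %in% sel$elety
  if (!is.null(sel$elesy)) keep <- keep & at$elesy %in% sel$elesy
  if (!is.null(sel$resid)) keep <- keep & at$resid %in% sel$resid
  idx <- which(keep)
  if (length(idx) == 0L) stop("selection '", what, "' resolves to no atoms")
  idx
}
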