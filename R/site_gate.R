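## Metal coordination-shell geometry and intracellular-gate metrics.

#' Metal coordination shell per frame
#'
#' Ligands are donor-element atoms within `cutoff` of the metal; for each
#' frame the metal-ligand distances and all pairwise ligand-metal-ligand
#' angles are reported.
#'
#' @param traj a `Trajectory`.
#' @param metal atom selection resolving to exactly one atom: either an
#'   atom index or a list understood by the selection resolver (fields
#'   `elesy`, `elety`, `resno`, `chain`, `resid`).
#' @param cutoff donor distance cutoff (Angstrom), default 3.0 (typical
#'   Cd2+-O/N bonds of 2.2-2.6 A plus thermal slack).
#' @param donors donor element symbols, default O, N, S.
#' @return list of per-frame `CoordinationShell` objects; each holds
#'   `ligands` (atom table rows + distance), `angles` (degrees, one per
#'   ligand pair), `count`.
#' @export
coordination_shell <- function(traj, metal, cutoff = 3.0,
                               donors = c("O", "N", "S")) {
  validate_trajectory(traj)
  mi <- if (is.numeric(metal)) as.integer(metal) else
    resolve_selection(traj, metal, "metal")
  if (length(mi) != 1L) {
    stop("metal selection must resolve to exactly 1 atom, got ", length(mi))
  }
  don <- which(toupper(traj$atoms$elesy) %in% toupper(donors))
  don <- setdiff(don, mi)
  lapply(seq_len(n_frames(traj)), function(t) {
    xyz <- frame_xyz(traj, t)
    m <- xyz[mi, ]
    d <- .vnorm(sweep(xyz[don, , drop = FALSE], 2, m))
    lig <- don[d <= cutoff]
    dl <- d[d <= cutoff]
    k <- length(lig)
    angles <- numeric(0)
    if (k >= 2L) {
      pr <- utils::combn(k, 2L)
      angles <- bond_angle(xyz[lig[pr[1, ]], , drop = FALSE],
                           matrix(m, nrow = ncol(pr), ncol = 3,
                                  byrow = TRUE),
                           xyz[lig[pr[2, ]], , drop = FALSE])
    }
    structure(list(metal = mi, frame = t,
                   ligands = cbind(traj$atoms[lig, , drop = FALSE],
                                   distance = dl),
                   angles = angles, count = k, cutoff = cutoff),
              class = "CoordinationShell")
  })
}

#' @export
print.CoordinationShell <- function(x, ...) {
  cat("CoordinationShell (frame ", x$frame, "): ", x$count,
      " ligand(s) within ", x$cutoff, " A\n", sep = "")
  invisible(x)
}

#' Octahedricity score of a coordination shell
#'
#' score = (6 - penalty) / 6, clamped to \[0, 1\], where
#' penalty = (6 - count) + mean over observed ligand-metal-ligand angles of
#' min(|theta - 90|, |theta - 180|) / 45. A complete, exact octahedron
#' scores 1; shells with fewer than 2 ligands are undefined (NA).
#'
#' @param shell a `CoordinationShell` (or a list of them, scored
#'   element-wise).
#' @return numeric score(s) in \[0, 1\], NA when undefined.
#' @export
octahedral_score <- function(shell) {
  if (is.list(shell) && !inherits(shell, "CoordinationShell")) {
    return(vapply(shell, octahedral_score, 0))
  }
  stopifnot(inherits(shell, "CoordinationShell"))
  if (shell$count < 2L) return(NA_real_)
  ang_pen <- mean(pmin(abs(shell$angles - 90), abs(shell$angles - 180)) / 45)
  penalty <- (6 - shell$count) + ang_pen
  min(max((6 - penalty) / 6, 0), 1)
}

#' Default gate residue selections (ScaDMT numbering)
#'
#' The gate tyrosine (Y47) ring is measured against a pocket defined by
#' L265/Q82/N229 side chains; the gate methionine (M48) tip against the
#' hydrophobic pocket V271/L275/W53/F183/L180/I176; both overridable for
#' other numbering schemes.
#'
#' @return named list of selections accepted by [gate_metrics()].
#' @export
default_gate_selections <- function() {
  list(
    tyr = list(resno = 47,
               elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    tyr_pocket = list(resno = c(265, 82, 229)),
    met = list(resno = 48, elety = "CE"),
    met_pocket = list(resno = c(271, 275, 53, 183, 180, 176)),
    stub = list(resno = NULL)  # NULL = first modeled residue
  )
}

.sidechain_only <- function(traj, idx) {
  idx[!(traj$atoms$elety[idx] %in% c("N", "CA", "C", "O", "OXT"))]
}

.centroid_series <- function(traj, idx) {
  ## n_frames x 3 centroid of an atom set
  if (length(idx) == 1L) return(atom_xyz(traj, idx))
  x <- traj$xyz[, idx, , drop = FALSE]
  matrix(apply(x, c(1, 3), mean), ncol = 3L)
}

#' Intracellular gate geometry metrics
#'
#' Per-frame distances: `tyr_pocket` (gate-tyrosine aromatic-ring centroid
#' to the centroid of pocket-lining side chains), `met_pocket` (gate
#' methionine side-chain tip to the hydrophobic-pocket centroid) and
#' `stub_extension` (first modeled C-alpha to the C-alpha `k` residues
#' downstream). A frame is called open iff tyr_pocket exceeds its
#' threshold AND met_pocket is below its threshold.
#'
#' @param traj a `Trajectory`.
#' @param selections named selections as in [default_gate_selections()].
#' @param k stub length in residues, default 8.
#' @param open_thresholds named numeric, `tyr_pocket` (default 8 A, open
#'   above) and `met_pocket` (default 7 A, open below).
#' @return data.frame of class `GateMetrics`: frame, tyr_pocket,
#'   met_pocket, stub_extension (Angstrom), gate_state ("open"/"closed").
#' @export
gate_metrics <- function(traj, selections = default_gate_selections(),
                         k = 8L,
                         open_thresholds = c(tyr_pocket = 8, met_pocket = 7)) {
  validate_trajectory(traj)
  sel_at <- function(name, sidechain = FALSE) {
    idx <- tryCatch(resolve_selection(traj, selections[[name]], name),
                    error = function(e) stop(conditionMessage(e),
                                             call. = FALSE))
    if (sidechain) {
      idx2 <- .sidechain_only(traj, idx)
      if (length(idx2) > 0L) idx <- idx2
    }
    idx
  }
  tyr_c <- .centroid_series(traj, sel_at("tyr"))
  tyr_pocket_c <- .centroid_series(traj, sel_at("tyr_pocket",
                                                sidechain = TRUE))
  met_c <- .centroid_series(traj, sel_at("met"))
  met_pocket_c <- .centroid_series(traj, sel_at("met_pocket",
                                                sidechain = TRUE))
  ## stub: first modeled CA to the CA k residues downstream
  at <- traj$atoms
  first_res <- selections$stub$resno
  ch <- selections$stub$chain
  if (is.null(ch)) ch <- at$chain[1]
  if (is.null(first_res)) first_res <- min(at$resno[at$chain == ch])
  ca1 <- .atom_index(at, ch, first_res, "CA")
  ca2 <- .atom_index(at, ch, first_res + k, "CA")
  if (is.na(ca1) || is.na(ca2)) {
    stop("stub C-alpha atoms not found (residues ", first_res, " and ",
         first_res + k, ")")
  }
  tyr_pocket <- .vnorm(tyr_c - tyr_pocket_c)
  met_pocket <- .vnorm(met_c - met_pocket_c)
  stub_extension <- .vnorm(atom_xyz(traj, ca1) - atom_xyz(traj, ca2))
  open <- tyr_pocket > open_thresholds[["tyr_pocket"]] &
    met_pocket < open_thresholds[["met_pocket"]]
  out <- data.frame(frame = seq_len(n_frames(traj)),
                    tyr_pocket = tyr_pocket, met_pocket = met_pocket,
                    stub_extension = stub_extension,
                    gate_state = ifelse(open, "open", "closed"))
  attr(out, "open_thresholds") <- open_thresholds
  class(out) <- c("GateMetrics", "data.frame")
  out
}

#' Per-frame site/gate summary table
#'
#' Convenience joiner writing the TSV surface of the module.
#'
#' @param shells list of `CoordinationShell` per frame (or NULL).
#' @param gates `GateMetrics` (or NULL).
#' @param path output TSV path (or NULL to just return the table).
#' @return the combined data.frame, invisibly if written.
#' @export
write_site_gate_table <- function(shells = NULL, gates = NULL, path = NULL) {
  tabs <- list()
  if (!is.null(shells)) {
    tabs$shell <- data.frame(frame = vapply(shells, `[[`, 1L, "frame"),
                             coordination_number =
                               vapply(shells, `[[`, 1L, "count"),
                             octahedral_score = octahedral_score(shells))
  }
  if (!is.null(gates)) tabs$gate <- as.data.frame(gates)
  out <- if (length(tabs) == 2L) merge(tabs$shell, tabs$gate, by = "frame")
  else tabs[[1]]
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
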