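## Dihedral-sum profiling, peptide-bond flip detection and helicity.
##
## The statistic s_i(t) = psi_i(t) + phi_{i+1}(t) sits near -105 deg in an
## alpha-helix and near +200 deg when the peptide bond between residues i
## and i+1 has flipped; values are reported on the canonical interval
## [-135, 225) so both regimes appear un-wrapped.

#' Per-residue dihedral-sum profile psi(i) + phi(i+1)
#'
#' Sums are formed in circular arithmetic, mapped to \[-135, 225), and
#' time-averaged with the circular (unit-vector) mean.
#'
#' @param phi,psi `DihedralSeries` from [backbone_dihedrals()] of the same
#'   chain/trajectory.
#' @param burn_in initial frames to drop before averaging (default 0).
#' @return object of class `DihedralSumProfile`: residue ids (`resno`, the
#'   residue i of each psi_i + phi_(i+1) pair), per-frame `sums` matrix on
#'   \[-135, 225), circular `mean` and `circ_sd` per residue.
#' @export
dihedral_sum_profile <- function(phi, psi, burn_in = 0L) {
  stopifnot(inherits(phi, "DihedralSeries"), inherits(psi, "DihedralSeries"),
            phi$kind == "phi", psi$kind == "psi")
  if (nrow(phi$values) != nrow(psi$values)) {
    stop("phi and psi have different frame counts")
  }
  ## pair psi_i with phi_{i+1}
  res_i <- intersect(psi$resno, phi$resno - 1L)
  if (length(res_i) < 1L) {
    warning("no valid residue pairs for dihedral sums")
    return(structure(list(resno = integer(), sums = matrix(numeric(), 0, 0),
                          mean = numeric(), circ_sd = numeric()),
                     class = "DihedralSumProfile"))
  }
  s <- psi$values[, as.character(res_i), drop = FALSE] +
    phi$values[, as.character(res_i + 1L), drop = FALSE]
  s <- wrap_sum(s)
  if (burn_in > 0L) {
    if (burn_in >= nrow(s)) stop("burn_in removes all frames")
    savg <- s[-seq_len(burn_in), , drop = FALSE]
  } else {
    savg <- s
  }
  m <- apply(savg, 2, circ_mean)
  structure(list(resno = res_i, sums = s,
                 mean = wrap_sum(m),
                 circ_sd = apply(savg, 2, circ_sd)),
            class = "DihedralSumProfile")
}

#' @export
print.DihedralSumProfile <- function(x, ...) {
  cat("DihedralSumProfile:", length(x$resno), "residue pairs x",
      nrow(x$sums), "frames\n")
  invisible(x)
}

## Per-frame state classification on the canonical interval.
.flip_states <- function(s, helical_center, flipped_center, tolerance) {
  hc <- wrap_sum(helical_center)
  fc <- wrap_sum(flipped_center)
  st <- matrix(NA_character_, nrow(s), ncol(s))
  st[abs(s - hc) < tolerance] <- "helical"
  st[abs(s - fc) < tolerance] <- "flipped"
  st[is.na(st) & is.finite(s)] <- "other"
  st
}

#' Detect peptide-bond flip events
#'
#' Classifies each residue/frame as helical, flipped or other by distance
#' to the two landmark centers on the canonical interval, then emits an
#' event at every state change that persists for at least `min_dwell`
#' frames (shorter excursions are debounced away).
#'
#' @param profile a `DihedralSumProfile`.
#' @param helical_center,flipped_center landmark sums (degrees); defaults
#'   -105 and 200.
#' @param tolerance half-width of each state band (degrees), default 60.
#' @param min_dwell minimum persistence (frames) for a state change to
#'   count, default 5.
#' @return data.frame of class `FlipEvents` with columns `resno`, `frame`
#'   (first frame of the new state), `from`, `to`.
#' @export
detect_flips <- function(profile, helical_center = -105, flipped_center = 200,
                         tolerance = 60, min_dwell = 5L) {
  stopifnot(inherits(profile, "DihedralSumProfile"), min_dwell >= 1L)
  hc <- wrap_sum(helical_center); fc <- wrap_sum(flipped_center)
  if (abs(hc - fc) < 2 * tolerance) {
    stop("state bands overlap on [-135, 225): |", hc, " - ", fc, "| < 2 x ",
         tolerance)
  }
  if (length(profile$resno) == 0L) {
    return(structure(data.frame(resno = integer(), frame = integer(),
                                from = character(), to = character()),
                     class = c("FlipEvents", "data.frame")))
  }
  st <- .flip_states(profile$sums, hc, fc, tolerance)
  ev <- list()
  for (j in seq_along(profile$resno)) {
    sj <- st[, j]
    ok <- which(!is.na(sj))
    if (length(ok) < 2L) next
    r <- rle(sj[ok])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    current <- r$values[1]
    for (k in seq_along(r$values)[-1]) {
      if (r$lengths[k] >= min_dwell && r$values[k] != current) {
        ev[[length(ev) + 1L]] <- data.frame(
          resno = profile$resno[j],
          frame = ok[starts[k]],
          from = current, to = r$values[k],
          stringsAsFactors = FALSE)
        current <- r$values[k]
      }
    }
  }
  out <- if (length(ev) > 0L) do.call(rbind, ev) else
    data.frame(resno = integer(), frame = integer(),
               from = character(), to = character())
  structure(out, class = c("FlipEvents", "data.frame"))
}

#' Per-residue helicity profile from a phi/psi window criterion
#'
#' A residue is alpha-helical in a frame iff phi is in \[-100, -30\], psi
#' is in \[-80, -5\], and it belongs to a run of at least `min_run`
#' consecutive residues satisfying the window in that frame. The returned
#' fraction is the per-residue mean over frames. Residues lacking both
#' torsions (chain termini) are NA, not 0.
#'
#' @param phi,psi `DihedralSeries` from [backbone_dihedrals()].
#' @param min_run minimum helical run length in residues, default 4.
#' @param phi_window,psi_window inclusive windows (degrees).
#' @return object of class `HelicityProfile`: `resno`, `fraction` (0..1 or
#'   NA), and the per-frame logical matrix `helical`.
#' @export
helicity_profile <- function(phi, psi, min_run = 4L,
                             phi_window = c(-100, -30),
                             psi_window = c(-80, -5)) {
  stopifnot(inherits(phi, "DihedralSeries"), inherits(psi, "DihedralSeries"))
  resno <- union(phi$resno, psi$resno)
  resno <- sort(resno)
  nf <- nrow(phi$values)
  pv <- matrix(NA_real_, nf, length(resno),
               dimnames = list(NULL, as.character(resno)))
  sv <- pv
  pv[, as.character(phi$resno)] <- phi$values
  sv[, as.character(psi$resno)] <- psi$values
  in_window <- !is.na(pv) & !is.na(sv) &
    pv >= phi_window[1] & pv <= phi_window[2] &
    sv >= psi_window[1] & sv <= psi_window[2]
  ## run-length filter along residues, per frame; only consecutive resno count
  helical <- matrix(FALSE, nf, length(resno))
  for (t in seq_len(nf)) {
    w <- in_window[t, ]
    ## break runs where residue numbering jumps
    grp <- cumsum(c(TRUE, diff(resno) != 1L))
    for (g in unique(grp)) {
      jj <- which(grp == g)
      r <- rle(w[jj])
      keep <- rep(r$lengths >= min_run & r$values, r$lengths)
      helical[t, jj] <- keep
    }
  }
  absent <- colSums(!is.na(pv)) == 0L & colSums(!is.na(sv)) == 0L
  frac <- colMeans(helical)
  frac[absent] <- NA_real_
  structure(list(resno = resno, fraction = unname(frac), helical = helical),
            class = "HelicityProfile")
}

#' @export
print.HelicityProfile <- function(x, ...) {
  cat("HelicityProfile:", length(x$resno), "residues; mean fraction",
      round(mean(x$fraction, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Parse an external per-residue secondary-structure table
#'
#' Adapter for assignments produced by external tools (e.g. STRIDE dumps):
#' a whitespace/tab-delimited table with columns residue id, frame, and a
#' one-letter state. Returns the per-residue fraction of state "H".
#'
#' @param path path to the table; lines starting with `#` are ignored.
#' @return a `HelicityProfile` (without the per-frame matrix).
#' @export
parse_secondary_structure_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    warning("empty secondary-structure table: ", path)
    return(structure(list(resno = integer(), fraction = numeric(),
                          helical = NULL), class = "HelicityProfile"))
  }
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stop("malformed row at line ", keep[bad[1]], " of ", path,
         ": expected 3 fields, got ", lengths(parts)[bad[1]])
  }
  m <- do.call(rbind, parts)
  resno <- suppressWarnings(as.integer(m[, 1]))
  frame <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(resno) || anyNA(frame)) {
    i <- which(is.na(resno) | is.na(frame))[1]
    stop("malformed row at line ", keep[i], " of ", path,
         ": non-integer residue/frame field")
  }
  state <- m[, 3]
  res <- sort(unique(resno))
  frac <- vapply(res, function(r) mean(state[resno == r] == "H"), 0)
  structure(list(resno = res, fraction = frac, helical = NULL),
            class = "HelicityProfile")
}

#' Write profile and flip-event tables
#'
#' @param profile a `DihedralSumProfile`.
#' @param helicity optional `HelicityProfile` aligned on residue id.
#' @param events optional `FlipEvents`.
#' @param dir output directory (created if needed).
#' @return paths of written TSV files, invisibly.
#' @export
write_profile_tables <- function(profile, helicity = NULL, events = NULL,
                                 dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ptab <- data.frame(residue = profile$resno,
                     mean_sum_deg = profile$mean,
                     circ_sd_deg = profile$circ_sd)
  if (!is.null(helicity)) {
    ptab$helicity_fraction <-
      helicity$fraction[match(ptab$residue, helicity$resno)]
  }
  p1 <- file.path(dir, "residue_profile.tsv")
  utils::write.table(ptab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- p1
  if (!is.null(events)) {
    p2 <- file.path(dir, "flip_events.tsv")
    utils::write.table(as.data.frame(events), p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
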