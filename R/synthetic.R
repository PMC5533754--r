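## Synthetic-data generators with serialized ground truth.
##
## Every generator takes an explicit seed, uses a local RNG stream (the
## global .Random.seed is saved and restored), and returns a GroundTruth
## record sufficient to regenerate the dataset bit-identically.

#' Evaluate code with a local, seeded RNG stream
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`; the global RNG state is left untouched.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Construct a GroundTruth record
#'
#' @param generator generator name.
#' @param params full parameter record (all rates, amplitudes, schedules,
#'   noise levels).
#' @param seed the RNG seed used.
#' @return object of class `GroundTruth`.
#' @export
ground_truth <- function(generator, params, seed) {
  structure(list(generator = generator, params = params, seed = seed),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth <", x$generator, ">, seed ", x$seed, "\n", sep = "")
  utils::str(x$params, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Serialize a GroundTruth record next to a dataset
#'
#' @param gt a `GroundTruth`.
#' @param dir dataset directory (created if needed).
#' @return the written path, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(unclass(gt), p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(p)
}

#' Read a serialized GroundTruth record
#'
#' @param dir dataset directory containing `ground_truth.json`.
#' @return a `GroundTruth`.
#' @export
read_ground_truth <- function(dir) {
  x <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                           simplifyVector = TRUE)
  ground_truth(x$generator, x$params, x$seed)
}

#' Regenerate a dataset from its ground truth
#'
#' Dispatches on the generator name; output is bit-identical to the
#' original because every generator draws from a local stream seeded from
#' the recorded seed.
#'
#' @param gt a `GroundTruth`.
#' @return the regenerated dataset.
#' @export
regenerate <- function(gt) {
  stopifnot(inherits(gt, "GroundTruth"))
  p <- gt$params
  switch(gt$generator,
    make_ideal_helix = make_ideal_helix(p$n_residues, p$n_frames, p$phi,
                                        p$psi, p$thermal_sd, gt$seed),
    simulate_rotamer_markov = simulate_rotamer_markov(
      matrix(unlist(p$states), ncol = 2, byrow = is.null(dim(p$states))),
      matrix(unlist(p$rates), ncol = sqrt(length(unlist(p$rates)))),
      p$n_frames, p$within_state_sd, gt$seed),
    make_metal_site = make_metal_site(p$n_ligands, p$distance,
                                      p$angular_jitter_sd, p$n_frames,
                                      gt$seed),
    make_gate_states = make_gate_states(unlist(p$schedule), gt$seed),
    simulate_tevc = simulate_tevc(p$protocol, p$params, gt$seed),
    simulate_uptake = simulate_uptake(p, gt$seed),
    stop("unknown generator: ", gt$generator))
}

## ---- backbone construction --------------------------------------------
## Standard internal coordinates (Angstrom / degrees): N-CA 1.458,
## CA-C 1.525, C-N 1.329; angles N-CA-C 111.0, CA-C-N 116.2, C-N-CA 121.7;
## omega fixed at 180.
.bb_geom <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                 a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7)

## phi, psi: n_frames x n_res matrices (phi[,1] and psi[,n] are unused).
## Returns Trajectory of a polyalanine backbone (N, CA, C per residue).
build_backbone <- function(phi, psi, omega = 180) {
  nf <- nrow(phi); nres <- ncol(phi)
  stopifnot(nrow(psi) == nf, ncol(psi) == nres, nres >= 2L)
  g <- .bb_geom
  xyz <- array(NA_real_, dim = c(nf, 3L * nres, 3L))
  one <- function(v) matrix(v, nf, 3L, byrow = TRUE)
  N <- one(c(0, 0, 0))
  CA <- one(c(g$b_n_ca, 0, 0))
  th <- (180 - g$a_n_ca_c) * pi / 180  # direction of CA->C vs +x
  C <- CA + one(g$b_ca_c * c(cos(th), sin(th), 0))
  xyz[, 1, ] <- N; xyz[, 2, ] <- CA; xyz[, 3, ] <- C
  for (i in seq_len(nres - 1L)) {
    N2 <- place_atom(N, CA, C, g$b_c_n, g$a_ca_c_n, psi[, i])
    CA2 <- place_atom(CA, C, N2, g$b_n_ca, g$a_c_n_ca, omega)
    C2 <- place_atom(C, N2, CA2, g$b_ca_c, g$a_n_ca_c, phi[, i + 1L])
    xyz[, 3L * i + 1L, ] <- N2
    xyz[, 3L * i + 2L, ] <- CA2
    xyz[, 3L * i + 3L, ] <- C2
    N <- N2; CA <- CA2; C <- C2
  }
  atoms <- data.frame(
    elety = rep(c("N", "CA", "C"), nres),
    resid = "ALA",
    resno = rep(seq_len(nres), each = 3L),
    chain = "A",
    elesy = rep(c("N", "C", "C"), nres),
    stringsAsFactors = FALSE)
  trajectory(xyz, atoms)
}

#' Generate an ideal alpha-helix trajectory
#'
#' Polyalanine backbone built from internal coordinates with the requested
#' phi/psi, optionally with Gaussian torsion jitter per frame (thermal
#' noise stand-in).
#'
#' @param n_residues number of residues (>= 4).
#' @param n_frames number of frames, default 1.
#' @param phi,psi backbone torsions (degrees), defaults -57 / -47.
#' @param thermal_sd per-frame Gaussian jitter SD on every torsion
#'   (degrees), default 0.
#' @param seed RNG seed (used only when `thermal_sd > 0`).
#' @return list: `trajectory` (a `Trajectory`), `ground_truth`.
#' @export
make_ideal_helix <- function(n_residues, n_frames = 1L, phi = -57,
                             psi = -47, thermal_sd = 0, seed = 1L) {
  stopifnot(n_residues >= 4L, n_frames >= 1L)
  gt <- ground_truth("make_ideal_helix",
                     list(n_residues = n_residues, n_frames = n_frames,
                          phi = phi, psi = psi, thermal_sd = thermal_sd),
                     seed)
  pm <- matrix(phi, n_frames, n_residues)
  sm <- matrix(psi, n_frames, n_residues)
  if (thermal_sd > 0) {
    with_seed(seed, {
      pm <- pm + matrix(stats::rnorm(length(pm), 0, thermal_sd),
                        n_frames, n_residues)
      sm <- sm + matrix(stats::rnorm(length(sm), 0, thermal_sd),
                        n_frames, n_residues)
    })
  }
  list(trajectory = build_backbone(pm, sm), ground_truth = gt,
       phi_matrix = pm, psi_matrix = sm)
}

#' Inject peptide-bond flips into a backbone trajectory
#'
#' During each event the torsions (psi_i, phi_(i+1)) are set so their sum
#' maps to 200 deg on the canonical interval (default split 100/100, an
#' arbitrary but recorded choice), and the downstream coordinates are
#' rebuilt with standard internal-coordinate geometry. Intended for
#' backbone trajectories produced by [make_ideal_helix()].
#'
#' @param helix result of [make_ideal_helix()] (or any list with
#'   `phi_matrix`/`psi_matrix`).
#' @param events data.frame with columns `resno`, `start` (frame),
#'   `duration` (frames); events must not overlap per residue.
#' @param split c(psi_i, phi_(i+1)) during the event, summing to 200
#'   modulo 360; default c(100, 100).
#' @return list: `trajectory`, `ground_truth`.
#' @export
inject_flips <- function(helix, events, split = c(100, 100)) {
  pm <- helix$phi_matrix; sm <- helix$psi_matrix
  if (is.null(pm) || is.null(sm)) {
    stop("inject_flips needs the torsion matrices of a generated backbone")
  }
  nf <- nrow(pm); nres <- ncol(pm)
  stopifnot(all(c("resno", "start", "duration") %in% names(events)))
  for (r in unique(events$resno)) {
    ev <- events[events$resno == r, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    if (any(ev$start < 1 | ev$start + ev$duration - 1 > nf)) {
      stop("event out of frame bounds for residue ", r)
    }
    if (r < 1 || r + 1 > nres) stop("event residue ", r, " out of range")
    if (nrow(ev) > 1L &&
        any(ev$start[-1] <= (ev$start + ev$duration - 1)[-nrow(ev)])) {
      stop("overlapping events for residue ", r)
    }
  }
  for (k in seq_len(nrow(events))) {
    fr <- seq.int(events$start[k], length.out = events$duration[k])
    sm[fr, events$resno[k]] <- split[1]
    pm[fr, events$resno[k] + 1L] <- split[2]
  }
  gt <- ground_truth("inject_flips",
                     list(base = helix$ground_truth$params,
                          base_seed = helix$ground_truth$seed,
                          events = events, split = split),
                     helix$ground_truth$seed)
  list(trajectory = build_backbone(pm, sm), ground_truth = gt,
       phi_matrix = pm, psi_matrix = sm)
}

#' Build a single-residue side-chain conformer trajectory
#'
#' One residue (default Glu) with backbone N/CA/C and a side chain built
#' at the requested chi torsions; useful as a construction-identity
#' fixture for [sidechain_chi()].
#'
#' @param resid residue type, "GLU" (default) or "ALA".
#' @param chi1,chi2 torsions (degrees), scalars or length-n_frames.
#' @param n_frames number of frames.
#' @return a `Trajectory`.
#' @export
make_sidechain_residue <- function(resid = "GLU", chi1 = -60, chi2 = 180,
                                   n_frames = 1L) {
  g <- .bb_geom
  one <- function(v) matrix(v, n_frames, 3L, byrow = TRUE)
  N <- one(c(0, 0, 0))
  CA <- one(c(g$b_n_ca, 0, 0))
  th <- (180 - g$a_n_ca_c) * pi / 180
  C <- CA + one(g$b_ca_c * c(cos(th), sin(th), 0))
  names_ <- c("N", "CA", "C")
  coords <- list(N, CA, C)
  eles <- c("N", "C", "C")
  if (resid == "GLU") {
    CB <- place_atom(C, N, CA, 1.530, 110.5, -122)
    CG <- place_atom(N, CA, CB, 1.520, 114.0, chi1)
    CD <- place_atom(CA, CB, CG, 1.520, 114.0, chi2)
    OE1 <- place_atom(CB, CG, CD, 1.250, 118.0, 0)
    OE2 <- place_atom(CB, CG, CD, 1.250, 118.0, 180)
    coords <- c(coords, list(CB, CG, CD, OE1, OE2))
    names_ <- c(names_, "CB", "CG", "CD", "OE1", "OE2")
    eles <- c(eles, "C", "C", "C", "O", "O")
  }
  xyz <- array(NA_real_, dim = c(n_frames, length(coords), 3L))
  for (j in seq_along(coords)) xyz[, j, ] <- coords[[j]]
  trajectory(xyz, data.frame(elety = names_, resid = resid, resno = 1L,
                             chain = "A", elesy = eles,
                             stringsAsFactors = FALSE))
}

## ---- rotamer Markov chains --------------------------------------------

#' Five-state rotamer preset
#'
#' Centers are canonical (chi1, chi2) wells at least 120 deg apart on the
#' torus; the per-frame jump probability to each other state is 0.005
#' (mean dwell 50 frames).
#'
#' @return list(states = 5 x 2 matrix, rates = 5 x 5 matrix).
#' @export
rotamer_preset_5state <- function() {
  states <- rbind(c(-60, -60), c(-60, 60), c(180, 60), c(180, -60),
                  c(60, 180))
  k <- nrow(states)
  rates <- matrix(0.005, k, k); diag(rates) <- 0
  list(states = states, rates = rates)
}

#' Simulate a Markov chain of rotamer states
#'
#' Discrete-state chain sampled per frame (initial state drawn from the
#' stationary distribution); emitted angles are the state centers plus
#' wrapped Gaussian noise.
#'
#' @param states k x 2 matrix of (chi1, chi2) centers (degrees).
#' @param rates k x k matrix of per-frame jump probabilities (diagonal
#'   ignored); off-diagonal row sums must be < 1.
#' @param n_frames chain length.
#' @param within_state_sd angular emission noise SD (degrees), default 8.
#' @param seed RNG seed (mandatory).
#' @return list: `chi1`, `chi2` (degrees, wrapped), `states` (integer
#'   path), `ground_truth`.
#' @export
simulate_rotamer_markov <- function(states, rates, n_frames,
                                    within_state_sd = 8, seed) {
  if (missing(seed)) stop("seed is mandatory")
  states <- as.matrix(states)
  k <- nrow(states)
  rates <- as.matrix(rates)
  stopifnot(nrow(rates) == k, ncol(rates) == k)
  P <- rates; diag(P) <- 0
  if (any(P < 0) || any(rowSums(P) >= 1)) {
    stop("invalid jump probabilities: need 0 <= p, off-diagonal row sums < 1")
  }
  diag(P) <- 1 - rowSums(P)
  if (any(1 - diag(P) > 0.5)) {
    warning("jump probability > 0.5/frame: dwell < 2 frames, clusters may merge")
  }
  gt <- ground_truth("simulate_rotamer_markov",
                     list(states = states, rates = rates,
                          n_frames = n_frames,
                          within_state_sd = within_state_sd), seed)
  ## stationary distribution of the chain
  ev <- eigen(t(P))
  i1 <- which.min(abs(ev$values - 1))
  pi0 <- abs(Re(ev$vectors[, i1])); pi0 <- pi0 / sum(pi0)
  s <- integer(n_frames)
  out <- with_seed(seed, {
    s[1] <- sample.int(k, 1L, prob = pi0)
    u <- stats::runif(n_frames - 1L)
    for (t in seq_len(n_frames - 1L)) {
      s[t + 1L] <- findInterval(u[t], cumsum(P[s[t], ]),
                                rightmost.closed = TRUE) + 1L
      if (s[t + 1L] > k) s[t + 1L] <- k
    }
    noise <- matrix(stats::rnorm(2L * n_frames, 0, within_state_sd),
                    n_frames, 2L)
    list(s = s, noise = noise)
  })
  chi <- states[out$s, , drop = FALSE] + out$noise
  list(chi1 = wrap180(chi[, 1]), chi2 = wrap180(chi[, 2]),
       states = out$s, ground_truth = gt)
}

## ---- metal site and gate fixtures -------------------------------------

## Octahedral vertex directions in a fixed order: the first four are the
## equatorial positions, so n_ligands = 4 is the trans-vacant geometry.
.octa_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))

#' Generate a metal coordination-site trajectory
#'
#' A metal ion at the origin with `n_ligands` oxygen ligands on octahedral
#' vertices (the first four are equatorial, so n = 4 is trans-vacant),
#' optionally with per-frame angular jitter: each ligand direction is
#' rotated by an angle drawn from N(0, sd) about a random perpendicular
#' axis.
#'
#' @param n_ligands 2..6.
#' @param distance metal-ligand distance (Angstrom), default 2.3.
#' @param angular_jitter_sd jitter SD (degrees), default 0.
#' @param n_frames number of frames, default 1.
#' @param seed RNG seed.
#' @return list: `trajectory`, `ground_truth`.
#' @export
make_metal_site <- function(n_ligands = 6L, distance = 2.3,
                            angular_jitter_sd = 0, n_frames = 1L,
                            seed = 1L) {
  stopifnot(n_ligands >= 2L, n_ligands <= 6L)
  gt <- ground_truth("make_metal_site",
                     list(n_ligands = n_ligands, distance = distance,
                          angular_jitter_sd = angular_jitter_sd,
                          n_frames = n_frames), seed)
  dirs <- .octa_dirs[seq_len(n_ligands), , drop = FALSE]
  xyz <- array(0, dim = c(n_frames, n_ligands + 1L, 3L))
  coords <- with_seed(seed, {
    a <- array(NA_real_, dim = c(n_frames, n_ligands, 3L))
    for (t in seq_len(n_frames)) {
      for (j in seq_len(n_ligands)) {
        v <- dirs[j, ]
        if (angular_jitter_sd > 0) {
          th <- stats::rnorm(1, 0, angular_jitter_sd) * pi / 180
          r <- stats::rnorm(3)
          ax <- c(v[2] * r[3] - v[3] * r[2], v[3] * r[1] - v[1] * r[3],
                  v[1] * r[2] - v[2] * r[1])
          ax <- ax / sqrt(sum(ax^2))
          ## Rodrigues rotation of v about ax by th
          v <- v * cos(th) + c(ax[2] * v[3] - ax[3] * v[2],
                               ax[3] * v[1] - ax[1] * v[3],
                               ax[1] * v[2] - ax[2] * v[1]) * sin(th) +
            ax * sum(ax * v) * (1 - cos(th))
        }
        a[t, j, ] <- v * distance
      }
    }
    a
  })
  xyz[, 2:(n_ligands + 1L), ] <- coords
  atoms <- data.frame(
    elety = c("CD", rep("O", n_ligands)),
    resid = c("CD", rep("HOH", n_ligands)),
    resno = seq_len(n_ligands + 1L),
    chain = "A",
    elesy = c("CD", rep("O", n_ligands)),
    stringsAsFactors = FALSE)
  list(trajectory = trajectory(xyz, atoms), ground_truth = gt)
}

#' Generate an intracellular-gate fixture trajectory
#'
#' A minimal residue set (gate tyrosine ring, gate methionine tip, pocket
#' side chains and a C-alpha stub) placed so that the default
#' [gate_metrics()] thresholds classify each frame according to the
#' requested schedule: closed frames have the tyrosine in its pocket
#' (4 A) and the methionine out (12 A); open frames the reverse.
#'
#' @param schedule character vector of "open"/"closed", one per frame.
#' @param seed RNG seed (recorded; the fixture itself is deterministic).
#' @return list: `trajectory`, `ground_truth`.
#' @export
make_gate_states <- function(schedule, seed = 1L) {
  stopifnot(all(schedule %in% c("open", "closed")), length(schedule) >= 1L)
  nf <- length(schedule)
  open <- schedule == "open"
  d_tyr <- ifelse(open, 12, 4)
  d_met <- ifelse(open, 4, 12)
  ext <- ifelse(open, 16, 10)
  hex <- function(radius, center) {
    a <- seq(0, 300, by = 60) * pi / 180
    cbind(center[1] + radius * cos(a), center[2] + radius * sin(a),
          center[3])
  }
  tri <- function(radius, center) {
    a <- c(90, 210, 330) * pi / 180
    cbind(center[1] + radius * cos(a), center[2] + radius * sin(a),
          center[3])
  }
  P1 <- c(0, 0, 0)     # tyrosine pocket centroid
  P2 <- c(30, 0, 0)    # methionine pocket centroid
  S0 <- c(60, 0, 0)    # stub anchor
  atoms <- list(); coords <- list()
  add <- function(elety, resid, resno, elesy, xyz_frames) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      elety = elety, resid = resid, resno = resno, chain = "A",
      elesy = elesy, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz_frames  # nf x 3
  }
  fixed <- function(p) matrix(p, nf, 3L, byrow = TRUE)
  ## residue 47: TYR with CA + ring centered at P1 + (0,0,d_tyr)
  add("CA", "TYR", 47L, "C", fixed(S0))
  ring <- hex(1.39, c(0, 0, 0))
  for (j in seq_len(6)) {
    nm <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")[j]
    add(nm, "TYR", 47L, "C",
        cbind(P1[1] + ring[j, 1], P1[2] + ring[j, 2], P1[3] + d_tyr))
  }
  ## residue 48: MET tip at P2 + (0,0,d_met)
  add("CA", "MET", 48L, "C", fixed(S0 + c(3.8, 0, 0)))
  add("CE", "MET", 48L, "C", cbind(P2[1], P2[2], P2[3] + d_met))
  ## stub CAs 49..55; residue 55 moves to set the extension distance
  for (r in 49:54) {
    add("CA", "GLY", r, "C", fixed(S0 + c(3.8 * (r - 47L), 0, 0)))
  }
  add("CA", "GLY", 55L, "C", cbind(S0[1] + ext, S0[2], S0[3]))
  ## tyrosine pocket residues (side-chain CB), centroid exactly P1
  t3 <- tri(1.0, P1)
  add("CB", "GLN", 82L, "C", fixed(t3[1, ]))
  add("CB", "ASN", 229L, "C", fixed(t3[2, ]))
  add("CB", "LEU", 265L, "C", fixed(t3[3, ]))
  ## methionine pocket residues, centroid exactly P2
  h6 <- hex(1.0, P2)
  pk <- data.frame(resno = c(271L, 275L, 53L, 183L, 180L, 176L),
                   resid = c("VAL", "LEU", "TRP", "PHE", "LEU", "ILE"))
  pk <- pk[order(pk$resno), ]
  for (j in seq_len(6)) {
    add("CB", pk$resid[j], pk$resno[j], "C", fixed(h6[j, ]))
  }
  at <- do.call(rbind, atoms)
  ord <- order(at$resno)
  at <- at[ord, , drop = FALSE]
  coords <- coords[ord]
  xyz <- array(NA_real_, dim = c(nf, nrow(at), 3L))
  for (j in seq_along(coords)) xyz[, j, ] <- coords[[j]]
  gt <- ground_truth("make_gate_states", list(schedule = schedule), seed)
  list(trajectory = trajectory(xyz, at), ground_truth = gt)
}

## ---- electrophysiology and uptake simulators ---------------------------

#' Default TEVC step protocol
#'
#' Holding -50 mV; test potentials +90 to -110 mV in -20 mV increments,
#' 200 ms per step with 50 ms pre- and 200 ms post-segments at Vh;
#' 5 kHz sampling, 500 Hz filter tag.
#'
#' @return protocol list for [simulate_tevc()].
#' @export
tevc_protocol_default <- function() {
  list(Vh = -50, Vt = seq(90, -110, by = -20), pre_ms = 50, step_ms = 200,
       post_ms = 200, sampling_Hz = 5000, filter_Hz = 500)
}

#' Default TEVC simulator parameters
#'
#' Boltzmann charge movement Qmax 80 nC, V0.5 +60 mV, z -2 with tau_p
#' 10 ms; membrane capacitance 200 nF with tau_c 0.5 ms; linear leak;
#' no transport current; noise SD as a fraction of the largest
#' transporter-relaxation amplitude.
#'
#' @return parameter list for [simulate_tevc()].
#' @export
tevc_params_default <- function() {
  list(C_m_nF = 200, tau_c_ms = 0.5, Qmax_nC = 80, V05_mV = 60, z = -2,
       tau_p_ms = 10, T_K = 295.15, g_leak_nA_mV = 0.5, E_rev_mV = 0,
       hill = list(iU = 0, Imax = 0, K05 = 1, nH = 1), S_uM = 0,
       noise_frac = 0)
}

## Boltzmann steady-state charge at potential V (mV), relative scale.
.q_inf <- function(V, Qmax, V05, z, T_K) {
  kT <- FARADAY / (GAS_R * T_K * 1000)
  Qmax / (1 + exp(z * (V - V05) * kT))
}

.hill_current <- function(S, h) {
  if (S <= 0) return(h$iU)
  h$iU + h$Imax * S^h$nH / (h$K05^h$nH + S^h$nH)
}

#' Simulate a two-electrode voltage-clamp step family
#'
#' Per test potential, the ON-step current is
#' A_c exp(-t/tau_c) + (dQ/tau_p) exp(-t/tau_p) + I_ss(Vt) + noise, where
#' A_c = C_m (Vt - Vh)/tau_c, dQ(Vt) = Qinf(Vt) - Qinf(Vh) under the
#' Boltzmann charge law, and I_ss combines a linear leak with a
#' Hill-activated transport current; the OFF step mirrors with opposite
#' capacitive and transporter amplitudes. Noise is Gaussian with SD =
#' `noise_frac` x the largest |dQ|/tau_p across steps.
#'
#' @param protocol see [tevc_protocol_default()].
#' @param params see [tevc_params_default()].
#' @param seed RNG seed.
#' @return list: `traces` (list of `VoltageStepTrace`), `ground_truth`,
#'   `true_dQ` (data.frame Vt, dQ_nC).
#' @export
simulate_tevc <- function(protocol = tevc_protocol_default(),
                          params = tevc_params_default(), seed = 1L) {
  pr <- utils::modifyList(tevc_protocol_default(), protocol)
  pa <- utils::modifyList(tevc_params_default(), params)
  if (pa$tau_c_ms >= pa$tau_p_ms) {
    warning("tau_c >= tau_p: capacitive and transporter components overlap")
  }
  gt <- ground_truth("simulate_tevc", list(protocol = pr, params = pa),
                     seed)
  dt <- 1000 / pr$sampling_Hz
  total <- pr$pre_ms + pr$step_ms + pr$post_ms
  tgrid <- seq(0, total - dt, by = dt)
  on0 <- pr$pre_ms; off0 <- pr$pre_ms + pr$step_ms
  qh <- .q_inf(pr$Vh, pa$Qmax_nC, pa$V05_mV, pa$z, pa$T_K)
  dQ <- vapply(pr$Vt, function(v)
    .q_inf(v, pa$Qmax_nC, pa$V05_mV, pa$z, pa$T_K) - qh, 0)
  Ap <- dQ * 1000 / pa$tau_p_ms                 # nA at the step edge
  noise_sd <- pa$noise_frac * max(abs(Ap))
  iss_h <- pa$g_leak_nA_mV * (pr$Vh - pa$E_rev_mV) +
    .hill_current(pa$S_uM, pa$hill)
  traces <- with_seed(seed, lapply(seq_along(pr$Vt), function(i) {
    vt <- pr$Vt[i]
    Ac <- pa$C_m_nF * (vt - pr$Vh) / pa$tau_c_ms   # nF mV / ms = nA
    iss_t <- pa$g_leak_nA_mV * (vt - pa$E_rev_mV) +
      .hill_current(pa$S_uM, pa$hill)
    I <- numeric(length(tgrid))
    pre <- tgrid < on0
    on <- tgrid >= on0 & tgrid < off0
    post <- tgrid >= off0
    I[pre] <- iss_h
    ton <- tgrid[on] - on0
    I[on] <- Ac * exp(-ton / pa$tau_c_ms) + Ap[i] * exp(-ton / pa$tau_p_ms) +
      iss_t
    toff <- tgrid[post] - off0
    I[post] <- -Ac * exp(-toff / pa$tau_c_ms) -
      Ap[i] * exp(-toff / pa$tau_p_ms) + iss_h
    if (noise_sd > 0) I <- I + stats::rnorm(length(I), 0, noise_sd)
    voltage_step_trace(tgrid, I, pr$Vh, vt, on0, off0,
                       meta = list(pH = pa$pH, substrate_uM = pa$S_uM,
                                   T_K = pa$T_K,
                                   sampling_Hz = pr$sampling_Hz,
                                   filter_Hz = pr$filter_Hz))
  }))
  list(traces = traces, ground_truth = gt,
       true_dQ = data.frame(Vt = pr$Vt, dQ_nC = dQ))
}

#' Write TEVC traces as CSV + JSON sidecars
#'
#' One `step_<Vt>.csv` (time_ms, current_nA) and `step_<Vt>.json`
#' (protocol metadata) per step, plus `ground_truth.json` when supplied.
#'
#' @param sim result of [simulate_tevc()], or a bare list of traces.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_tevc_traces <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traces <- if (!is.null(sim$traces)) sim$traces else sim
  for (tr in traces) {
    tag <- sprintf("step_%+04d", as.integer(round(tr$Vt)))
    utils::write.csv(data.frame(time_ms = tr$time_ms,
                                current_nA = tr$current_nA),
                     file.path(dir, paste0(tag, ".csv")), row.names = FALSE)
    jsonlite::write_json(c(list(Vh = tr$Vh, Vt = tr$Vt,
                                onset_ms = tr$onset_ms,
                                offset_ms = tr$offset_ms), tr$meta),
                         file.path(dir, paste0(tag, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(sim$ground_truth)) write_ground_truth(sim$ground_truth, dir)
  invisible(dir)
}

#' Read TEVC traces written by [write_tevc_traces()]
#'
#' @param dir directory of `step_*.csv` / `step_*.json` pairs.
#' @return list of `VoltageStepTrace`, ordered by file name.
#' @export
read_tevc_traces <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "^step_.*\\.csv$",
                          full.names = TRUE))
  if (length(csvs) == 0L) stop("no step_*.csv traces in ", dir)
  lapply(csvs, function(p) {
    d <- utils::read.csv(p)
    m <- jsonlite::read_json(sub("\\.csv$", ".json", p),
                             simplifyVector = TRUE)
    voltage_step_trace(d$time_ms, d$current_nA, m$Vh, m$Vt, m$onset_ms,
                       m$offset_ms,
                       meta = m[setdiff(names(m),
                                        c("Vh", "Vt", "onset_ms",
                                          "offset_ms"))])
  })
}

#' Simulate substrate-activation currents for the Hill-with-leak model
#'
#' Steady-state currents I = iU + Imax S^nH / (K0.5^nH + S^nH) over a
#' proton-concentration design (pH grid mapped to uM), with proportional
#' Gaussian noise (SD = `noise_frac` x |I|).
#'
#' @param params list: `iU`, `Imax` (nA), `K05` (uM), `nH`, `pH` (grid,
#'   default 5.5-7.5 by 0.25), `noise_frac` (default 0.02).
#' @param seed RNG seed.
#' @return list: `data` (data.frame S_uM, I_nA), `ground_truth`.
#' @export
simulate_hill_currents <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(list(iU = -20, Imax = -200, K05 = 1, nH = 1.5,
                              pH = seq(5.5, 7.5, by = 0.25),
                              noise_frac = 0.02), params)
  gt <- ground_truth("simulate_hill_currents", p, seed)
  S <- ph_to_uM(p$pH)
  I0 <- p$iU + p$Imax * S^p$nH / (p$K05^p$nH + S^p$nH)
  I <- if (p$noise_frac > 0) {
    with_seed(seed, I0 * (1 + stats::rnorm(length(I0), 0, p$noise_frac)))
  } else I0
  list(data = data.frame(S_uM = S, I_nA = I), ground_truth = gt)
}

#' Default uptake-plate simulator parameters
#'
#' Michaelis-Menten uptake with Km 2 uM sampled over the 0.1-20 uM
#' concentration design, 15 min uptake, triplicate wells plus matched
#' background wells, 5% Gaussian noise on counts.
#'
#' @return parameter list for [simulate_uptake()].
#' @export
uptake_params_default <- function() {
  list(Km_uM = 2, vmax = 10, background_rate = 0.2,
       S_uM = c(0.1, 0.2, 0.5, 1, 2, 5, 10, 20),
       total_cpm_per_L = 1e9, time_min = 15, replicates = 3,
       noise = "gaussian", noise_sd_frac = 0.05)
}

#' Simulate a radiotracer uptake plate
#'
#' Per-well counts are obtained by inverting the influx-rate equation from
#' Michaelis-Menten rates (plus a background rate emulating unspecific
#' uptake by untransfected cells), then perturbed by Gaussian
#' (SD = `noise_sd_frac` x mean) or Poisson noise.
#'
#' @param params see [uptake_params_default()].
#' @param seed RNG seed.
#' @return list: `plate` (data.frame well, condition, S_uM, counts_cpm,
#'   total_cpm_per_L, time_min, is_background), `ground_truth`.
#' @export
simulate_uptake <- function(params = uptake_params_default(), seed = 1L) {
  p <- utils::modifyList(uptake_params_default(), params)
  gt <- ground_truth("simulate_uptake", p, seed)
  grid <- expand.grid(rep_i = seq_len(p$replicates), S_uM = p$S_uM,
                      is_background = c(FALSE, TRUE))
  rate <- ifelse(grid$is_background, p$background_rate,
                 p$vmax * grid$S_uM / (p$Km_uM + grid$S_uM) +
                   p$background_rate)
  counts <- rate * p$total_cpm_per_L * p$time_min / (grid$S_uM * 1e6)
  counts <- with_seed(seed, {
    if (p$noise == "gaussian") {
      pmax(counts * (1 + stats::rnorm(length(counts), 0, p$noise_sd_frac)),
           0)
    } else if (p$noise == "poisson") {
      stats::rpois(length(counts), counts)
    } else counts
  })
  plate <- data.frame(well = seq_len(nrow(grid)),
                      condition = ifelse(grid$is_background, "background",
                                         "transporter"),
                      S_uM = grid$S_uM, counts_cpm = counts,
                      total_cpm_per_L = p$total_cpm_per_L,
                      time_min = p$time_min,
                      is_background = grid$is_background)
  list(plate = plate, ground_truth = gt)
}

#' Uptake plate to Michaelis-Menten fit
#'
#' Full chain: counts -> influx rates -> per-concentration background
#' subtraction and expression normalization -> [fit_mm()].
#'
#' @param plate plate data.frame as produced by [simulate_uptake()].
#' @param expression_factor surface-expression factor (> 0), default 1.
#' @return list: `fit` (a `SaturationFit`), `points` (data.frame S_uM,
#'   rate).
#' @export
analyze_uptake <- function(plate, expression_factor = 1) {
  rate <- influx_rate(plate$counts_cpm, plate$S_uM * 1e6,
                      plate$total_cpm_per_L, plate$time_min)
  cond <- as.character(plate$S_uM)
  corr <- subtract_background_and_normalize(
    data.frame(condition = cond[!plate$is_background],
               rate = rate[!plate$is_background]),
    data.frame(condition = cond[plate$is_background],
               rate = rate[plate$is_background]),
    expression_factor)
  pts <- data.frame(S_uM = as.numeric(corr$condition),
                    rate = corr$corrected)
  list(fit = fit_mm(pts$S_uM, pts$rate), points = pts)
}
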