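## Config-driven pipeline orchestration.
##
## A run config is a JSON-serializable list:
##   list(seed = 1, out = "runs/demo",
##        stages = list(list(stage = "simulate_helix", n_residues = 20), ...))
## Stage parameters are validated against the formals of the mapped
## function before anything executes; the effective config is always
## written next to the outputs. Identical config + seed gives
## byte-identical numerical outputs.

.pipeline_stages <- function() {
  list(
    simulate_helix = list(
      fn = "make_ideal_helix",
      args = c("n_residues", "n_frames", "phi", "psi", "thermal_sd")),
    simulate_flips = list(
      fn = "inject_flips",
      args = c("n_residues", "n_frames", "phi", "psi", "thermal_sd",
               "events", "split")),
    simulate_rotamers = list(
      fn = "simulate_rotamer_markov",
      args = c("n_frames", "within_state_sd")),
    simulate_site = list(
      fn = "make_metal_site",
      args = c("n_ligands", "distance", "angular_jitter_sd", "n_frames")),
    simulate_gate = list(fn = "make_gate_states", args = c("schedule")),
    simulate_tevc = list(fn = "simulate_tevc",
                         args = c("protocol", "params")),
    simulate_uptake = list(fn = "simulate_uptake", args = c("params")),
    analyze_traj = list(
      fn = NULL,
      args = c("input", "chain", "stride", "burn_in", "helical_center",
               "flipped_center", "tolerance", "min_dwell", "min_run")),
    analyze_rotamers = list(
      fn = NULL, args = c("input", "eps", "min_members")),
    analyze_site_gate = list(
      fn = NULL, args = c("input", "metal", "cutoff", "k")),
    fit_uptake = list(fn = NULL, args = c("input", "expression_factor")),
    fit_qv = list(fn = NULL, args = c("input", "exclude", "edge", "T_K"))
  )
}

#' Validate a pipeline run configuration
#'
#' Checks top-level keys, stage names and per-stage parameter names
#' against the published stage schema; fails before any computation.
#'
#' @param config run configuration list (or path to a JSON config).
#' @return the normalized config list, invisibly; errors name the
#'   offending key.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = TRUE)
  }
  allowed_top <- c("seed", "out", "stages", "permissive")
  extra <- setdiff(names(config), allowed_top)
  if (length(extra) > 0L) stop("unknown config key: ", extra[1])
  if (is.null(config$seed)) stop("config key 'seed' is required")
  if (is.null(config$out)) stop("config key 'out' is required")
  if (is.null(config$stages) || length(config$stages) == 0L) {
    stop("config key 'stages' must list at least one stage")
  }
  schema <- .pipeline_stages()
  if (is.data.frame(config$stages)) {
    ## JSON round-trip: rows gain NA cells for keys of other stages
    config$stages <- lapply(split(config$stages,
                                  seq_len(nrow(config$stages))),
                            function(r) {
      l <- as.list(r)
      l[!vapply(l, function(x) is.atomic(x) && all(is.na(x)), FALSE)]
    })
  }
  for (st in config$stages) {
    if (is.null(st$stage)) stop("a stage entry lacks the 'stage' key")
    if (!st$stage %in% names(schema)) {
      stop("unknown stage: ", st$stage)
    }
    extra <- setdiff(names(st), c("stage", schema[[st$stage]]$args))
    if (length(extra) > 0L) {
      stop("unknown key '", extra[1], "' in stage ", st$stage)
    }
  }
  invisible(config)
}

.stage_params <- function(st) st[setdiff(names(st), "stage")]

#' Execute a pipeline run
#'
#' Runs the configured stages in order, writing every stage's outputs,
#' the effective config and a log under the output directory.
#'
#' @param config run configuration (list or JSON path); see
#'   [validate_config()].
#' @return list of per-stage results, invisibly; also written to disk.
#'   With `permissive = FALSE` (default) any flagged non-convergence
#'   raises an error.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  permissive <- isTRUE(config$permissive)
  jsonlite::write_json(config, file.path(out, "effective_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    log[length(log) + 1L] <<- msg
    message(msg)
  }
  seed <- as.integer(config$seed)
  results <- list()
  state <- new.env(parent = emptyenv())
  for (si in seq_along(config$stages)) {
    st <- config$stages[[si]]
    p <- .stage_params(st)
    say("stage ", si, ": ", st$stage)
    res <- switch(st$stage,
      simulate_helix = {
        h <- do.call(make_ideal_helix, c(p, list(seed = seed)))
        write_trajectory(h$trajectory, file.path(out, "helix.pdb"))
        write_ground_truth(h$ground_truth, out)
        state$helix <- h
        list(pdb = "helix.pdb", frames = n_frames(h$trajectory))
      },
      simulate_flips = {
        hp <- p[setdiff(names(p), c("events", "split"))]
        h <- do.call(make_ideal_helix, c(hp, list(seed = seed)))
        ev <- as.data.frame(p$events)
        fl <- if (is.null(p$split)) inject_flips(h, ev) else
          inject_flips(h, ev, unlist(p$split))
        write_trajectory(fl$trajectory, file.path(out, "flips.pdb"))
        write_ground_truth(fl$ground_truth, out)
        state$helix <- fl
        list(pdb = "flips.pdb", n_events = nrow(ev))
      },
      simulate_rotamers = {
        pre <- rotamer_preset_5state()
        r <- do.call(simulate_rotamer_markov,
                     c(list(states = pre$states, rates = pre$rates),
                       p, list(seed = seed)))
        utils::write.csv(data.frame(frame = seq_along(r$chi1),
                                    chi1 = r$chi1, chi2 = r$chi2,
                                    state = r$states),
                         file.path(out, "rotamers.csv"), row.names = FALSE)
        write_ground_truth(r$ground_truth, out)
        state$rotamers <- r
        list(csv = "rotamers.csv", n_frames = length(r$chi1))
      },
      simulate_site = {
        s <- do.call(make_metal_site, c(p, list(seed = seed)))
        write_trajectory(s$trajectory, file.path(out, "site.pdb"))
        write_ground_truth(s$ground_truth, out)
        state$site <- s
        list(pdb = "site.pdb")
      },
      simulate_gate = {
        g <- make_gate_states(unlist(p$schedule), seed = seed)
        write_trajectory(g$trajectory, file.path(out, "gate.pdb"))
        write_ground_truth(g$ground_truth, out)
        state$gate <- g
        list(pdb = "gate.pdb")
      },
      simulate_tevc = {
        s <- do.call(simulate_tevc, c(p, list(seed = seed)))
        write_tevc_traces(s, file.path(out, "tevc"))
        state$tevc <- s
        list(dir = "tevc", n_steps = length(s$traces))
      },
      simulate_uptake = {
        u <- do.call(simulate_uptake, c(p, list(seed = seed)))
        utils::write.csv(u$plate, file.path(out, "uptake.csv"),
                         row.names = FALSE)
        write_ground_truth(u$ground_truth, out)
        state$uptake <- u
        list(csv = "uptake.csv", n_wells = nrow(u$plate))
      },
      analyze_traj = {
        traj <- if (!is.null(p$input)) load_trajectory(p$input) else
          state$helix$trajectory
        if (is.null(traj)) stop("analyze_traj: no input trajectory")
        if (!is.null(p$stride) || !is.null(p$burn_in)) {
          traj <- thin_frames(traj,
                              if (is.null(p$stride)) 1L else p$stride,
                              if (is.null(p$burn_in)) 0L else p$burn_in)
        }
        bb <- backbone_dihedrals(traj, chain = p$chain)
        prof <- dihedral_sum_profile(bb$phi, bb$psi)
        det_args <- p[names(p) %in% c("helical_center", "flipped_center",
                                      "tolerance", "min_dwell")]
        ev <- do.call(detect_flips, c(list(prof), det_args))
        hel <- if (is.null(p$min_run)) helicity_profile(bb$phi, bb$psi)
        else helicity_profile(bb$phi, bb$psi, min_run = p$min_run)
        write_profile_tables(prof, hel, ev, out)
        list(mean_sum_deg = stats::setNames(prof$mean,
                                            prof$resno),
             interior_mean_deg = circ_mean(
               prof$mean[prof$resno > min(prof$resno) &
                           prof$resno < max(prof$resno)]),
             n_flip_events = nrow(ev))
      },
      analyze_rotamers = {
        r <- if (!is.null(p$input)) utils::read.csv(p$input) else
          data.frame(chi1 = state$rotamers$chi1,
                     chi2 = state$rotamers$chi2)
        cl_args <- p[names(p) %in% c("eps", "min_members")]
        cl <- do.call(cluster_rotamers,
                      c(list(r$chi1, r$chi2), cl_args))
        tc <- transition_counts(cl$labels)
        write_rotamer_tables(cl, tc, out)
        list(n_clusters = nrow(cl$clusters),
             noise_fraction = cl$noise_fraction)
      },
      analyze_site_gate = {
        traj_s <- if (!is.null(p$input)) load_trajectory(p$input) else
          state$site$trajectory
        shells <- NULL
        if (!is.null(traj_s)) {
          metal <- if (is.null(p$metal)) list(elesy = "CD") else p$metal
          sh_args <- p[names(p) %in% "cutoff"]
          shells <- do.call(coordination_shell,
                            c(list(traj_s, metal), sh_args))
        }
        gates <- if (!is.null(state$gate))
          gate_metrics(state$gate$trajectory,
                       k = if (is.null(p$k)) 8L else p$k) else NULL
        tab <- write_site_gate_table(shells, gates,
                                     file.path(out, "site_gate.tsv"))
        list(n_frames = nrow(tab))
      },
      fit_uptake = {
        plate <- if (!is.null(p$input)) utils::read.csv(p$input) else
          state$uptake$plate
        if (is.null(plate)) stop("fit_uptake: no plate input")
        ef <- if (is.null(p$expression_factor)) 1 else p$expression_factor
        an <- analyze_uptake(plate, ef)
        if (!an$fit$converged && !permissive) {
          stop("fit_uptake: Michaelis-Menten fit did not converge")
        }
        write_fit_report(an$fit, file.path(out, "uptake_fit"))
        as.list(an$fit$parameters)
      },
      fit_qv = {
        traces <- if (!is.null(p$input)) read_tevc_traces(p$input) else
          state$tevc$traces
        if (is.null(traces)) stop("fit_qv: no traces input")
        qa <- charge_movement_analysis(
          traces,
          exclude = if (is.null(p$exclude)) 0.4 else p$exclude,
          edge = if (is.null(p$edge)) "on" else p$edge,
          T_K = if (is.null(p$T_K)) 295.15 else p$T_K)
        if (!qa$fit$converged && !permissive) {
          stop("fit_qv: Boltzmann fit did not converge")
        }
        utils::write.table(qa$qv, file.path(out, "qv.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(Qmax = qa$fit$Qmax, Qhyp = qa$fit$Qhyp,
                                  V05 = qa$fit$V05, z = qa$fit$z,
                                  r2 = qa$fit$r2,
                                  converged = qa$fit$converged),
                             file.path(out, "qv_fit.json"),
                             auto_unbox = TRUE, digits = NA)
        list(Qmax = qa$fit$Qmax, V05 = qa$fit$V05, z = qa$fit$z)
      })
    results[[st$stage]] <- res
  }
  writeLines(log, file.path(out, "run.log"))
  jsonlite::write_json(results, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
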