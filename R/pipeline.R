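#' Average a property over trajectories with the exclusion rule
#'
#' Unweighted mean and sample standard deviation across trajectories.
#' Extensive or concentration-dependent properties can exclude flagged
#' trajectories (e.g. those simulated at a different protein
#' concentration) before averaging.
#'
#' @param values numeric vector, one value per trajectory
#' @param property_class `"intensive"` (all trajectories used) or
#'   `"extensive"` (flagged trajectories dropped)
#' @param excluded logical vector marking trajectories to drop for
#'   extensive/concentration-dependent properties
#' @return list with `mean`, `sd` (NA for a single trajectory), `n`
#' @export
average_over_trajectories <- function(values,
                                      property_class = c("intensive",
                                                         "extensive"),
                                      excluded = rep(FALSE,
                                                     length(values))) {
  property_class <- match.arg(property_class)
  if (length(excluded) != length(values)) {
    stop("'excluded' must have one flag per value")
  }
  use <- if (property_class == "extensive") !excluded else
    rep(TRUE, length(values))
  v <- values[use]
  if (length(v) == 0L) stop("no trajectories left after exclusion")
  list(mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
       n = length(v))
}

pipeline_known_keys <- c(
  "trajectories", "topologies", "format", "contact_cutoff",
  "min_lifetime_ns", "sasa_probe_radius", "sasa_n_points",
  "energy_cutoff", "electrostatics", "eps_rf", "stages", "output_dir",
  "reference", "phe_positions", "excluded_extensive", "min_snapshots"
)

pipeline_all_stages <- c("contacts", "oligomers", "kinetics", "propensity",
                         "foldedness", "energy")

#' Run the full aggregation-analysis pipeline
#'
#' Orchestrates contacts, oligomer classification, kinetics, propensity,
#' foldedness and energy decomposition over one or more trajectories and
#' writes tidy TSV outputs plus a summary. The configuration is validated
#' before any computation; unknown keys are rejected. Re-running with
#' identical inputs reproduces identical outputs.
#'
#' @param config a named list (or path to a YAML file) with keys:
#'   `trajectories` (paths, or in-memory trajectory objects),
#'   `topologies` (paths, one per trajectory, for path input), `format`,
#'   `contact_cutoff` (nm, default 0.4), `min_lifetime_ns` (default 1),
#'   `sasa_probe_radius` (default 0.14), `sasa_n_points` (default 960),
#'   `energy_cutoff` (default 1.4), `electrostatics`, `eps_rf`, `stages`
#'   (subset of contacts/oligomers/kinetics/propensity/foldedness/energy),
#'   `output_dir`, `reference` (path or frame, for foldedness),
#'   `phe_positions`, `excluded_extensive` (logical per trajectory),
#'   `min_snapshots` (default 20)
#' @return invisible list of per-stage results (`contacts`, `oligomers`,
#'   `species`, `kinetics`, `propensity`, `foldedness`, `energy`,
#'   `delta_E`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$trajectories)) stop("config needs 'trajectories'")
  stages <- if (is.null(config$stages)) pipeline_all_stages else
    config$stages
  bad <- setdiff(stages, pipeline_all_stages)
  if (length(bad) > 0L) stop("unknown stage(s): ",
                             paste(bad, collapse = ", "))
  cutoff <- config$contact_cutoff %||% 0.4
  min_life <- config$min_lifetime_ns %||% 1
  outdir <- config$output_dir
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  }
  log_msg <- function(...) message(sprintf(...))

  trajs <- config$trajectories
  if (is.character(trajs)) {
    fmt <- config$format %||% "internal"
    tops <- config$topologies
    if (is.null(tops)) stop("path input requires 'topologies'")
    trajs <- mapply(function(tr, tp) {
      top <- read_topology(tp, format = if (fmt == "internal") "internal"
                           else fmt)
      read_trajectory(tr, top, format = fmt)
    }, trajs, tops, SIMPLIFY = FALSE)
  }
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  n_traj <- length(trajs)
  excluded <- config$excluded_extensive %||% rep(FALSE, n_traj)

  out <- list()
  need_residue_map <- "propensity" %in% stages
  t_stage <- system.time({
    series <- lapply(trajs, contact_timeseries, cutoff = cutoff,
                     residue_map = need_residue_map)
  })
  log_msg("stage contacts: %d trajectories, cutoff %.2f nm (%.1f s)",
          n_traj, cutoff, t_stage[["elapsed"]])
  out$contacts <- series
  write_tsv <- function(df, name) {
    if (!is.null(outdir)) {
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  if ("contacts" %in% stages) {
    for (k in seq_len(n_traj)) {
      s <- series[[k]]
      live <- which(s$counts > 0L, arr.ind = TRUE)
      df <- data.frame(
        frame = live[, 1L], time_ps = s$times[live[, 1L]],
        mol_i = s$pairs[live[, 2L], 1L], mol_j = s$pairs[live[, 2L], 2L],
        n_contacts = s$counts[live]
      )
      df <- df[order(df$frame, df$mol_i, df$mol_j), , drop = FALSE]
      write_tsv(df, sprintf("contacts_%02d.tsv", k))
    }
  }

  states <- lapply(series, oligomer_timeseries)
  if ("oligomers" %in% stages) {
    out$oligomers <- states
    sp <- species_fraction_timeseries(states)
    out$species <- sp
    write_tsv(sp, "species_fractions.tsv")
    log_msg("stage oligomers: free-monomer fraction %.2f -> %.2f",
            sp$monomer[1L], sp$monomer[nrow(sp)])
  }

  if ("kinetics" %in% stages) {
    events <- lapply(series, detect_complexes, min_lifetime_ns = min_life)
    all_ev <- do.call(rbind, events)
    write_tsv(all_ev, "complex_events.tsv")
    ks <- lapply(seq_len(n_traj), function(k) {
      kinetics_summary(events[[k]], series[[k]]$times[1L],
                       series[[k]]$times[length(series[[k]]$times)],
                       molecules = series[[k]]$molecules)
    })
    out$kinetics <- ks
    log_msg("stage kinetics: %d events over %d trajectories",
            sum(vapply(events, nrow, integer(1))), n_traj)
  }

  if ("propensity" %in% stages) {
    sg <- lapply(trajs, function(tr) {
      t(vapply(tr$frames, function(f) {
        sasa_by_residue_group(f, tr$topology,
                              probe_radius = config$sasa_probe_radius %||%
                                0.14,
                              n_points = config$sasa_n_points %||% 960L)
      }, numeric(length(residue_group_labels(tr$topology)))))
    })
    prof <- interaction_propensity(lapply(series, `[[`, "group_counts"),
                                   sg)
    out$propensity <- prof
    write_tsv(prof, "propensity.tsv")
    log_msg("stage propensity: top group %s",
            prof$group[which.max(prof$propensity)])
  }

  if ("foldedness" %in% stages) {
    ref <- config$reference
    if (is.character(ref)) {
      rt <- read_topology(ref, format = "pdb")
      ref <- read_trajectory(ref, rt, format = "pdb")$frames[[1L]]
    }
    if (is.null(ref)) stop("foldedness stage requires 'reference'")
    fold <- lapply(seq_len(n_traj), function(k) {
      do.call(rbind, lapply(molecules_of_group(trajs[[k]]$topology),
                            function(m) {
        cbind(trajectory = k, molecule = m,
              foldedness_timeseries(trajs[[k]], ref, m,
                                    config$phe_positions %||% c(7, 11, 18)))
      }))
    })
    out$foldedness <- do.call(rbind, fold)
    write_tsv(out$foldedness, "foldedness.tsv")
  }

  if ("energy" %in% stages) {
    np <- nonbonded_params(
      cutoff = config$energy_cutoff %||% 1.4,
      electrostatics = config$electrostatics %||% "reaction_field",
      eps_rf = config$eps_rf %||% 65
    )
    en <- lapply(trajs, energy_decomposition_series, params = np)
    for (k in seq_len(n_traj)) write_tsv(en[[k]],
                                         sprintf("energy_%02d.tsv", k))
    out$energy <- en
    # nonbonded terms only; the persistence-rule states come from the
    # instantaneous contact graph
    keep <- !excluded
    de <- delta_E_aggregation(states[keep], en[keep],
                              min_snapshots = config$min_snapshots %||% 20)
    out$delta_E <- de
    if (de$n_trajectories > 0L) {
      write_tsv(data.frame(component = names(de$delta),
                           delta_kJmol = as.numeric(de$delta),
                           sd = as.numeric(de$sd)),
                "delta_E.tsv")
      log_msg("stage energy: delta E_total %.1f kJ/mol over %d trajectories",
              de$delta[["E_total"]], de$n_trajectories)
    }
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
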