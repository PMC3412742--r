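# Reproducible pipeline commands over a YAML run configuration.
#
# Every command writes plain CSV/text artifacts plus a provenance log
# (serialized config and the parameters each design decision left
# configurable), so identical configs and seeds give identical outputs.

#' Load a run configuration
#'
#' A nested YAML file (or an equivalent named list) describing inputs,
#' selections, model parameters and the output directory.  Recognized
#' top-level keys: `structure`, `structure_b`, `ss_labels`, `trajectory`,
#' `trajectory_format` (`pdb`/`xyz`), `selection`, `exclusions`,
#' `partition`, `enm` (fields of [enm_params()]), `hbond` (fields of
#' [hbond_criteria()]), `sasa` (fields of [sasa_config()]), `apolar`
#' (fields of [apolar_model()]), `n_modes_overlap`, `n_modes_correlation`,
#' `energy_tables`, `polar_table`, `stoich_step`, `window`, `seed`,
#' `outdir`.
#'
#' @param config path to a YAML file, or a named list
#' @return object of class `RunConfig`
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$outdir)) stop("config needs an 'outdir'")
  for (key in c("structure", "structure_b", "trajectory", "ss_labels",
                "polar_table")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config references missing file: ", cfg[[key]])
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.cfg_obj <- function(cfg, key, ctor) {
  if (is.null(cfg[[key]])) ctor() else do.call(ctor, cfg[[key]])
}

.pipeline_log <- function(cfg, outdir, extra = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(unclass(cfg), extra)
  yaml::write_yaml(prov, file.path(outdir, "run-config.yml"))
}

.load_structure <- function(cfg, key = "structure") {
  s <- read_pdb(cfg[[key]])
  if (!is.null(cfg$ss_labels)) s <- load_ss_labels(s, cfg$ss_labels)
  detect_disulfides(s, attach = TRUE)
}

.load_trajectory <- function(cfg) {
  fmt <- if (is.null(cfg$trajectory_format)) "pdb" else cfg$trajectory_format
  if (fmt == "pdb") read_trajectory_pdb(cfg$trajectory)
  else read_trajectory_xyz(cfg$trajectory, .load_structure(cfg))
}

#' Network-model command: modes, fluctuations, overlap, correlation
#'
#' Builds the extended network model for `structure`, writes an NMD-style
#' mode file, per-node mean-square fluctuations and B-factors, and the
#' low-mode correlation matrix; when `structure_b` is given, also the
#' 10-mode overlap matrix between the two models over their common node
#' count.
#'
#' @param config a [run_config()] (or path / list)
#' @return invisibly, the list of files written
#' @export
cmd_enm <- function(config) {
  cfg <- run_config(config)
  outdir <- cfg$outdir
  params <- .cfg_obj(cfg, "enm", enm_params)
  s <- .load_structure(cfg)
  net <- build_enm(s, params)
  modes <- eigenmodes(build_hessian(net), net = net)
  files <- character(0)
  f <- file.path(outdir, "modes.nmd")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  n_write <- min(20, length(modes$values) - modes$n_rigid)
  write_nmd(modes, f, n = n_write); files <- c(files, f)
  fl <- predicted_fluctuations(modes)
  f <- file.path(outdir, "fluctuations.csv")
  utils::write.csv(fl, f, row.names = FALSE); files <- c(files, f)
  n_corr <- if (is.null(cfg$n_modes_correlation)) 25 else cfg$n_modes_correlation
  n_corr <- min(n_corr, length(modes$values) - modes$n_rigid)
  C <- nma_correlation(modes, n_modes = n_corr)
  f <- file.path(outdir, "mode-correlation.csv")
  utils::write.csv(C, f, row.names = FALSE); files <- c(files, f)
  extra <- list(n_rigid = modes$n_rigid, n_modes_correlation_used = n_corr,
                connected = net$connected)
  if (!is.null(cfg$structure_b)) {
    sb <- .load_structure(cfg, "structure_b")
    netb <- build_enm(sb, params)
    modesb <- eigenmodes(build_hessian(netb), net = netb)
    n_ov <- if (is.null(cfg$n_modes_overlap)) 10 else cfg$n_modes_overlap
    O <- mode_overlap(modes, modesb, n = n_ov)
    f <- file.path(outdir, "mode-overlap.csv")
    utils::write.csv(O, f, row.names = FALSE); files <- c(files, f)
    extra$n_modes_overlap_used <- n_ov
  }
  .pipeline_log(cfg, outdir, extra)
  invisible(files)
}

#' Trajectory-metrics command: RMSD, RMSF, DCCM, H-bonds, buried area,
#' distance monitors
#'
#' Writes one tidy CSV per requested metric.  The RMSD fit excludes the
#' `exclusions` selections (e.g. flexible terminal receptor residues);
#' interface hydrogen bonds and buried area need a two-partner
#' `partition`; `distance_groups` (list of two selections) adds a
#' center-to-center monitor.
#'
#' @param config a [run_config()] (or path / list)
#' @return invisibly, the list of files written
#' @export
cmd_traj <- function(config) {
  cfg <- run_config(config)
  outdir <- cfg$outdir
  t <- .load_trajectory(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  sel <- cfg$selection
  rms <- rmsd_series(t, selection = sel, exclusions = cfg$exclusions)
  f <- file.path(outdir, "rmsd.csv")
  utils::write.csv(rms, f, row.names = FALSE); files <- c(files, f)
  degenerate <- NULL
  if (n_frames(t) >= 2) {
    f <- file.path(outdir, "rmsf.csv")
    utils::write.csv(rmsf(t, selection = sel), f, row.names = FALSE)
    files <- c(files, f)
    # a motionless trajectory has no correlation matrix; note it and move on
    C <- tryCatch(dccm(t, selection = sel), error = function(e) e)
    if (inherits(C, "error")) {
      degenerate <- conditionMessage(C)
    } else {
      f <- file.path(outdir, "dccm.csv")
      utils::write.csv(C, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  if (!is.null(cfg$partition)) {
    crit <- .cfg_obj(cfg, "hbond", hbond_criteria)
    hb <- interface_hbonds(t, cfg$partition[[1]], cfg$partition[[2]], crit)
    f <- file.path(outdir, "interface-hbonds.csv")
    utils::write.csv(hb, f, row.names = FALSE); files <- c(files, f)
    ba <- buried_area(t, cfg$partition, .cfg_obj(cfg, "sasa", sasa_config))
    f <- file.path(outdir, "buried-area.csv")
    utils::write.csv(ba, f, row.names = FALSE); files <- c(files, f)
  }
  if (!is.null(cfg$distance_groups)) {
    gd <- group_distance(t, cfg$distance_groups[[1]], cfg$distance_groups[[2]])
    f <- file.path(outdir, "group-distance.csv")
    utils::write.csv(gd, f, row.names = FALSE); files <- c(files, f)
  }
  .pipeline_log(cfg, outdir, list(exclusions_applied = cfg$exclusions,
                                  degenerate = degenerate))
  invisible(files)
}

#' MM/PBSA command: assemble a free-energy ledger
#'
#' In SITA mode the complex trajectory and a two-partner partition are
#' required; in SETA mode three per-species energy-component tables
#' (`energy_tables`: paths named `complex`, `protein`, `ligand`) are
#' combined under the step's stoichiometric coefficients.  The ledger CSV
#' mirrors the component rows (internal, van der Waals, electrostatic,
#' polar, apolar, solvation, total); the provenance log records the
#' entropy neglect and the Poisson-Boltzmann input metadata.
#'
#' @param config a [run_config()] (or path / list)
#' @param mode `"SITA"` or `"SETA"`
#' @return invisibly, the ledger
#' @export
cmd_mmpbsa <- function(config, mode = c("SITA", "SETA")) {
  mode <- match.arg(mode)
  cfg <- run_config(config)
  outdir <- cfg$outdir
  apolar <- .cfg_obj(cfg, "apolar", apolar_model)
  if (mode == "SITA") {
    t <- .load_trajectory(cfg)
    if (is.null(cfg$ff_table)) stop("SITA needs an 'ff_table' entry")
    ff <- read_ff_table(cfg$ff_table)
    polar <- if (is.null(cfg$polar_table)) NULL else read_energy_table(cfg$polar_table)
    led <- sita_ledger(t, cfg$partition, ff, polar_table = polar,
                       apolar = apolar, window = cfg$window,
                       sasa_cfg = .cfg_obj(cfg, "sasa", sasa_config))
  } else {
    if (is.null(cfg$energy_tables)) stop("SETA needs 'energy_tables' paths")
    tabs <- lapply(cfg$energy_tables, read_energy_table)
    st <- stoich_step(if (is.null(cfg$stoich_step)) 1 else cfg$stoich_step)
    led <- seta_ledger(tabs$complex, tabs$protein, tabs$ligand, stoich = st,
                       apolar = apolar)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- as.data.frame(led)
  if (mode == "SITA") out <- out[out$component != "H_int", , drop = FALSE]
  utils::write.csv(out, file.path(outdir, sprintf("ledger-%s.csv", tolower(mode))),
                   row.names = FALSE)
  .pipeline_log(cfg, outdir, list(
    mode = mode, entropy = attr(led, "entropy"),
    polar_input = unclass(attr(led, "polar_spec")),
    stoich_coefficients = if (mode == "SETA") as.list(attr(led, "stoich")$coef) else NULL))
  invisible(led)
}
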