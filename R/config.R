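# Configuration schema and command-level workflow: build -> run/remd ->
# analyze, driven by a versioned YAML config whose defaults are the
# protocol's printed parameters, so any deviation is a visible diff.

#' Default run configuration
#'
#' All protocol parameters appear as named defaults: 300 Angstrom periodic
#' cubic box, 10 fs time step, 1,000 fs Langevin damping, neighbor rebuild
#' every 1,000 steps, 28-rung 180-540 K replica ladder with swaps every 100
#' steps, 10 Angstrom dRMS interface cutoff, 0.5 Angstrom and 0.1 kcal/mol
#' histogram bin widths.
#'
#' @return Nested configuration list (schema version 1).
#' @export
default_config <- function() {
  list(
    schema_version = 1,
    seed = 1,
    structure = list(pdb = NULL, fixture = NULL),
    rigid = list(),
    flexible = list(),
    box = list(side = 300, periodic = TRUE),
    forcefield = list(lambda_scale = 0.159, e0 = -1.36, dielectric = 80,
                      debye_length = 10, elec_cutoff = 35,
                      lj_cutoff_factor = 3, bond_r0 = 3.81, bond_k = 189),
    integrator = list(dt = 10, damping = 1000, temperature = 300,
                      nsteps = 100000, output_every = 1000,
                      rebuild_every = 1000, skin = 4),
    remd = list(tmin = 180, tmax = 540, n = 28, exchange_interval = 100,
                nsweeps = 1000),
    analysis = list(components = c("A", "B"), drms_cutoff = 10,
                    hist_width_drms = 0.5, hist_width_energy = 0.1,
                    drms_every = 1))
}

#' Read / write a configuration
#'
#' Unspecified fields fall back to [default_config()]; overridden fields are
#' reported via message so deviations from the protocol defaults are visible
#' in logs.
#'
#' @param file YAML path.
#' @return The configuration list.
#' @export
read_config <- function(file) {
  user <- yaml::read_yaml(file)
  cfg <- utils::modifyList(default_config(), user, keep.null = TRUE)
  defs <- default_config()
  for (k in names(user))
    if (!identical(cfg[[k]], defs[[k]]))
      message("config override: ", k)
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

.config_params <- function(config) {
  f <- config$forcefield
  kh_params(lambda_scale = f$lambda_scale, e0 = f$e0,
            dielectric = f$dielectric, debye_length = f$debye_length,
            elec_cutoff = f$elec_cutoff, lj_cutoff_factor = f$lj_cutoff_factor,
            bond_r0 = f$bond_r0, bond_k = f$bond_k)
}

.config_integrator <- function(config) {
  i <- config$integrator
  integrator_params(dt = i$dt, damping = i$damping,
                    temperature = i$temperature, seed = config$seed,
                    skin = i$skin, rebuild_every = i$rebuild_every)
}

.provenance <- function(config, extra = list()) {
  c(list(package = "khmd",
         version = as.character(utils::packageVersion("khmd")),
         date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
         config = config), extra)
}

.as_config <- function(config) {
  if (is.character(config)) read_config(config) else
    utils::modifyList(default_config(), config, keep.null = TRUE)
}

#' Build a topology from a configuration
#'
#' Reads the structure (PDB path or fixture spec), applies the rigid and
#' flexible assignments, and writes the serialized topology plus a
#' human-readable summary.
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory.
#' @return The `kh_topology`, invisibly.
#' @export
cmd_build <- function(config, out_dir = ".") {
  config <- .as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$structure$fixture)) {
    fx <- config$structure$fixture
    topo <- switch(fx$kind,
      binding_pair = do.call(make_binding_pair,
                             fx[setdiff(names(fx), "kind")])$topology,
      tailed_domain = do.call(make_tailed_domain,
                              fx[setdiff(names(fx), "kind")]),
      filament_stub = do.call(make_filament_stub,
                              fx[setdiff(names(fx), "kind")]),
      stop("unknown fixture kind: ", fx$kind))
  } else if (!is.null(config$structure$pdb)) {
    st <- read_calpha_structure(config$structure$pdb)
    if (nrow(st$missing))
      message(nrow(st$missing), " residue(s) lack a C-alpha atom")
    topo <- build_system(st, rigid_spec = config$rigid,
                         flexible_spec = unlist(config$flexible),
                         box_side = config$box$side,
                         periodic = config$box$periodic,
                         params = .config_params(config))
  } else stop("config must give structure$pdb or structure$fixture")
  saveRDS(topo, file.path(out_dir, "topology.rds"))
  summ <- c(sprintf("beads: %d", nrow(topo$beads)),
            sprintf("rigid groups: %d", length(topo$groups)),
            sprintf("flexible beads: %d",
                    sum(is.na(topo$beads$group) & !topo$beads$fixed)),
            sprintf("bonds: %d", nrow(topo$bonds)),
            sprintf("box: %g A (%s)", topo$box$side,
                    if (topo$box$periodic) "periodic" else "open"))
  writeLines(summ, file.path(out_dir, "topology_summary.txt"))
  invisible(topo)
}

#' Run serial Langevin dynamics from a configuration
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory (expects `topology.rds` from
#'   [cmd_build()], or builds it).
#' @return The `kh_trajectory`, invisibly.
#' @export
cmd_run <- function(config, out_dir = ".") {
  config <- .as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tf <- file.path(out_dir, "topology.rds")
  topo <- if (file.exists(tf)) readRDS(tf) else cmd_build(config, out_dir)
  ff <- kh_forcefield(.config_params(config))
  st <- init_state(topo, temperature = config$integrator$temperature,
                   seed = config$seed)
  tr <- run_dynamics(topo, st, config$integrator$nsteps,
                     .config_integrator(config), ff,
                     output_every = config$integrator$output_every)
  utils::write.csv(tr$energy, file.path(out_dir, "energy.csv"),
                   row.names = FALSE)
  if (tr$nframes > 0) write_xyz(tr, file.path(out_dir, "trajectory.xyz"))
  saveRDS(tr, file.path(out_dir, "trajectory.rds"))
  yaml::write_yaml(.provenance(config), file.path(out_dir, "provenance.yaml"))
  invisible(tr)
}

#' Run replica-exchange MD from a configuration
#'
#' Writes per-rung energy logs named by temperature, the swap-record CSV and
#' the replica-trace CSV.
#'
#' @inheritParams cmd_run
#' @return The `kh_remd`, invisibly.
#' @export
cmd_remd <- function(config, out_dir = ".") {
  config <- .as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tf <- file.path(out_dir, "topology.rds")
  topo <- if (file.exists(tf)) readRDS(tf) else cmd_build(config, out_dir)
  ff <- kh_forcefield(.config_params(config))
  ladder <- geometric_ladder(config$remd$tmin, config$remd$tmax,
                             config$remd$n)
  rx <- run_remd(topo, nsweeps = config$remd$nsweeps, ladder = ladder,
                 exchange_interval = config$remd$exchange_interval,
                 integrator = .config_integrator(config), forcefield = ff,
                 seed = config$seed)
  for (k in seq_along(ladder)) {
    ce <- cold_ensemble(rx, k)
    utils::write.csv(ce$provenance,
                     file.path(out_dir, sprintf("rung_%.1fK.csv", ladder[k])),
                     row.names = FALSE)
  }
  utils::write.csv(rx$swaps, file.path(out_dir, "swap_records.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(rx$trace),
                   file.path(out_dir, "replica_trace.csv"), row.names = FALSE)
  saveRDS(rx, file.path(out_dir, "remd.rds"))
  yaml::write_yaml(.provenance(config), file.path(out_dir, "provenance.yaml"))
  invisible(rx)
}

#' Analyse a trajectory or REMD run against a reference
#'
#' Computes the interface-pair dRMS series, the dRMS occupancy histogram and
#' the hotspot summary, writing CSV/plain-text outputs.
#'
#' @param config Configuration list or YAML path.
#' @param reference A `kh_reference` for the bound complex.
#' @param out_dir Directory containing `trajectory.rds` or `remd.rds`.
#' @return List with `drms` tibble, `histogram` and `hotspots`, invisibly.
#' @export
cmd_analyze <- function(config, reference, out_dir = ".") {
  config <- .as_config(config)
  if (missing(reference) || is.null(reference))
    stop("a reference conformation is required for analysis")
  an <- config$analysis
  pairs <- select_interface_pairs(reference, an$components[1],
                                  an$components[2], an$drms_cutoff)
  rf <- file.path(out_dir, "remd.rds")
  tf <- file.path(out_dir, "trajectory.rds")
  frames <- if (file.exists(rf)) cold_ensemble(readRDS(rf))$frames
            else if (file.exists(tf)) readRDS(tf)$frames
            else stop("no trajectory.rds or remd.rds in ", out_dir)
  ds <- drms_series(frames, pairs, every = an$drms_every,
                    box = if (isTRUE(config$box$periodic)) config$box$side)
  h <- hist2d(ds$drms, ds$drms,
              widths = c(an$hist_width_drms, an$hist_width_drms))
  hs <- hotspot_summary(h)
  utils::write.csv(ds, file.path(out_dir, "drms_series.csv"),
                   row.names = FALSE)
  write_hist2d(h, file.path(out_dir, "drms_hist.txt"))
  utils::write.csv(hs, file.path(out_dir, "hotspots.csv"), row.names = FALSE)
  invisible(list(drms = ds, histogram = h, hotspots = hs))
}
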