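# Declarative end-to-end runs: a single structured config selects stages,
# every output is listed in a JSON manifest with its config snapshot and
# input checksums, and identical config + seed reproduce identical files.

default_run_config <- function() {
  list(
    output_dir = "cryspec_out",
    seed = 1,
    stages = character(0),
    synth = list(n_molecules = 4, intra = 20, inter = 2,
                 temperature = 300, dt = 0.5, n_steps = 20000,
                 friction = 0.01),
    static_spectrum = list(gamma = 5, volume_fraction = 0.10, host_eps = 2.0,
                           grid = c(5, 300, 0.5)),
    md_spectrum = list(window = list(family = "hann", width = 2000),
                       max_lag = NULL, quantum_correction = FALSE,
                       grid = c(5, 300, 0.5)),
    structures = list(input = NULL, dialect = "auto", supercell = c(1, 1, 1),
                      disorder = NULL, motif_report = FALSE,
                      motif_cutoff = 3.0),
    torsions = list(input = NULL, specs = NULL, basins = NULL, dwell = 0.5,
                    bin_width = 5)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate and normalize a pipeline run configuration
#'
#' @param config a list, or path to a YAML file; missing entries take the
#'   documented defaults.
#' @return normalized config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config)
  # YAML sequences arrive as lists; flatten the leaf vectors
  cfg$stages <- as.character(unlist(cfg$stages))
  cfg$static_spectrum$grid <- as.numeric(unlist(cfg$static_spectrum$grid))
  cfg$md_spectrum$grid <- as.numeric(unlist(cfg$md_spectrum$grid))
  cfg$structures$supercell <- as.integer(unlist(cfg$structures$supercell))
  problems <- character(0)
  known <- c("synth", "static_spectrum", "md_spectrum", "structures", "torsions")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0) problems <- c(problems, paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if ("static_spectrum" %in% cfg$stages && !"synth" %in% cfg$stages) {
    problems <- c(problems, "static_spectrum requires the synth stage")
  }
  if ("md_spectrum" %in% cfg$stages && !"synth" %in% cfg$stages) {
    problems <- c(problems, "md_spectrum requires the synth stage")
  }
  if ("structures" %in% cfg$stages && is.null(cfg$structures$input)) {
    problems <- c(problems, "structures stage needs structures$input")
  }
  if ("structures" %in% cfg$stages && !is.null(cfg$structures$input) &&
      !file.exists(cfg$structures$input)) {
    problems <- c(problems, paste("structures input not found:", cfg$structures$input))
  }
  if ("torsions" %in% cfg$stages &&
      (is.null(cfg$torsions$input) || !file.exists(cfg$torsions$input))) {
    problems <- c(problems, "torsions stage needs an existing torsions$input")
  }
  if (length(problems) > 0) {
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  cfg
}

# grids are given as (min, max, step) triples in configs
grid_from_spec <- function(g) {
  if (length(g) == 3) seq(g[1], g[2], by = g[3]) else g
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (synth before the
#' spectrum stages) and writes every artifact plus a \code{manifest.json}
#' listing each output file with its md5 checksum and the full config
#' snapshot. Reruns with identical config and seed reproduce the
#' deterministic outputs byte-identically.
#'
#' @param config list or YAML path, see \code{\link{validate_run_config}}.
#' @return the manifest, invisibly (list with \code{outputs},
#'   \code{stages}, \code{config}).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  stage_status <- list()
  add_output <- function(stage, path) {
    outputs[[length(outputs) + 1]] <<- list(
      stage = stage, path = path,
      md5 = as.character(tools::md5sum(path)))
  }
  state <- new.env(parent = emptyenv())
  order_known <- c("synth", "structures", "static_spectrum", "md_spectrum",
                   "torsions")
  stages <- order_known[order_known %in% cfg$stages]
  failed_deps <- character(0)
  for (stage in stages) {
    deps <- switch(stage, static_spectrum = "synth", md_spectrum = "synth",
                   character(0))
    if (any(deps %in% failed_deps)) {
      stage_status[[stage]] <- "skipped (failed dependency)"
      next
    }
    res <- tryCatch({
      run_stage(stage, cfg, state, add_output)
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    stage_status[[stage]] <- res
    if (res != "ok") failed_deps <- c(failed_deps, stage)
  }
  manifest <- list(stages = stage_status, outputs = outputs, config = cfg)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

run_stage <- function(stage, cfg, state, add_output) {
  od <- cfg$output_dir
  switch(stage,
    synth = {
      p <- cfg$synth
      sys <- make_toy_molecular_crystal(
        n_molecules = p$n_molecules, springs = c(p$intra, p$inter),
        seed = cfg$seed)
      state$system <- sys
      f1 <- file.path(od, "toy_structure.cif")
      write_structure(sys$crystal, f1, "cif"); add_output("synth", f1)
      f2 <- file.path(od, "toy_force_constants.txt")
      write_force_constants(sys$force_constants, f2); add_output("synth", f2)
      f3 <- file.path(od, "toy_born_charges.txt")
      write_born_charges(sys$born, f3); add_output("synth", f3)
      md <- simulate_harmonic_md(sys, temperature = p$temperature, dt = p$dt,
                                 n_steps = p$n_steps, friction = p$friction,
                                 seed = cfg$seed)
      state$dipole <- md$dipole
      f4 <- file.path(od, "toy_dipole.csv")
      utils::write.csv(data.frame(t_fs = md$dipole$times,
                                  Mx = md$dipole$dipoles[, 1],
                                  My = md$dipole$dipoles[, 2],
                                  Mz = md$dipole$dipoles[, 3]),
                       f4, row.names = FALSE)
      add_output("synth", f4)
    },
    static_spectrum = {
      p <- cfg$static_spectrum
      sys <- state$system
      modes <- toy_phonons(sys)
      conf <- spectrum_config(gamma = p$gamma,
                              volume_fraction = p$volume_fraction,
                              host_eps = p$host_eps,
                              grid = grid_from_spec(p$grid))
      sp <- static_spectrum(modes, cell_volume(sys$crystal$cell), conf)
      f1 <- file.path(od, "mode_table.csv")
      write_mode_table(modes, f1, crystal = sys$crystal); add_output("static_spectrum", f1)
      f2 <- file.path(od, "static_spectrum.csv")
      f3 <- file.path(od, "static_spectrum.json")
      write_spectrum(sp, f2, f3)
      add_output("static_spectrum", f2); add_output("static_spectrum", f3)
      state$static <- sp
    },
    md_spectrum = {
      p <- cfg$md_spectrum
      acf <- dipole_acf(state$dipole,
                        max_lag = if (is.null(p$max_lag)) NULL else p$max_lag)
      acf <- apply_window(acf, window_spec(p$window$family, p$window$width))
      sp <- absorption_from_acf(acf, grid_from_spec(p$grid),
                                quantum_correction = isTRUE(p$quantum_correction))
      f1 <- file.path(od, "md_spectrum.csv")
      f2 <- file.path(od, "md_spectrum.json")
      write_spectrum(sp, f1, f2)
      add_output("md_spectrum", f1); add_output("md_spectrum", f2)
      state$dynamic <- sp
    },
    structures = {
      p <- cfg$structures
      cr <- read_structure(p$input, p$dialect)
      cr <- build_supercell(cr, p$supercell)
      if (!is.null(p$disorder)) {
        d <- p$disorder
        specs <- lapply(d$torsions, function(t) as_torsion_spec(unlist(t)))
        res <- generate_disorder_model(cr, specs,
                                       angles = unlist(d$angles),
                                       fraction = d$fraction,
                                       seed = cfg$seed)
        cr <- res$crystal
        f0 <- file.path(od, "disorder_plan.csv")
        utils::write.csv(res$plan, f0, row.names = FALSE)
        add_output("structures", f0)
      }
      f1 <- file.path(od, "structure_out.cif")
      write_structure(cr, f1, "cif"); add_output("structures", f1)
      if (isTRUE(p$motif_report)) {
        hs <- which(cr$elements == "H")
        bonds <- bond_list(cr)
        rows <- list()
        for (h in hs) {
          partners <- c(bonds[bonds[, 1] == h, 2], bonds[bonds[, 2] == h, 1])
          if (!any(cr$elements[partners] == "S")) next
          m <- classify_sh_motif(cr, h, cutoff = p$motif_cutoff)
          rows[[length(rows) + 1]] <- data.frame(
            site = h, motif = m$motif,
            acceptor = if (is.na(m$acceptor)) NA_integer_ else m$acceptor,
            distance = if (is.na(m$distance)) NA_real_ else m$distance)
        }
        f2 <- file.path(od, "motif_report.csv")
        utils::write.csv(do.call(rbind, rows), f2, row.names = FALSE)
        add_output("structures", f2)
      }
      state$structure <- cr
    },
    torsions = {
      p <- cfg$torsions
      frames <- read_xyz_frames(p$input)
      specs <- lapply(p$specs, function(t) as_torsion_spec(unlist(t)))
      tt <- torsion_timeseries(frames, specs)
      basins <- if (is.null(p$basins)) default_basins()
                else lapply(p$basins, unlist)
      flips <- detect_flips(tt, basins = basins, dwell = p$dwell)
      f1 <- file.path(od, "flips.csv")
      utils::write.csv(flips, f1, row.names = FALSE); add_output("torsions", f1)
      dist <- torsion_distribution(as.vector(tt$wrapped), p$bin_width)
      f2 <- file.path(od, "torsion_distribution.csv")
      utils::write.csv(dist, f2, row.names = FALSE); add_output("torsions", f2)
      f3 <- file.path(od, "cell_stats.csv")
      utils::write.csv(average_cell(frames), f3, row.names = FALSE)
      add_output("torsions", f3)
    })
  invisible(NULL)
}
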