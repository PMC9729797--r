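# Configuration, end-to-end pipeline and the subcommand CLI.

#' Default pipeline configuration
#'
#' A fully serializable nested list with every tunable of the pipeline.
#' Missing fields in a user config are filled from these defaults.
#'
#' @param seed master seed recorded in all artifacts (the pipeline itself
#'   is deterministic; the seed feeds the fixture and the run log).
#' @return a `scaffem_config` list.
#' @export
pipeline_config <- function(seed = 42) {
  structure(list(
    seed = as.integer(seed),
    geometry = list(kind = "fixture", span_mm = 40, height_mm = 20,
                    width_mm = 10, curvature = 0.15, stump_mm = 10,
                    fillet_mm = 1.5, stl_path = NULL),
    cell = list(cell_kind = "rhombic_dodecahedron", pore_diameter_mm = 5,
                orientation = c(0, 0, 1)),
    strut = list(d_min_mm = 0.2, d_max_mm = 0.8,
                 gradient_axis = c(0, 0, -1)),
    fixation = list(retainer_thickness_mm = 2, screw_length_mm = 8,
                    screws_per_side = 5),
    voxel_mm = 1.25,
    load = list(bite_force_N = 800),
    bins = frequency_bins(),
    criteria = list(yield_strength_MPa = 897, strain_window_ue = 3000,
                    max_iterations = 20, improvement_tolerance = 0.5,
                    hotspot_quantile = 0.9),
    stages = c("G-T", "IM-B", "M-B"),
    export = list(stl = TRUE, segments_per_circle = 8, vtk = TRUE)
  ), class = "scaffem_config")
}

# deep-merge user values over defaults; NULLs in the user config (JSON
# nulls) keep the default rather than deleting the field
.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.null(user[[k]])) next
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]])))
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Read / write a pipeline configuration (JSON)
#'
#' `write_config()` serializes; `read_config()` parses and fills missing
#' fields from [pipeline_config()] defaults, so
#' `read_config(write_config(cfg)) == cfg`.
#'
#' @param config a `scaffem_config`.
#' @param path JSON file path.
#' @return `read_config()`: a `scaffem_config`; `write_config()`: `path`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- .merge_config(unclass(pipeline_config()), user)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "scaffem_config")
}

#' Hash of a configuration
#'
#' md5 of the canonical JSON serialization; changes iff any field changes.
#'
#' @param config a `scaffem_config`.
#' @return character md5 string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

# lattice graph <-> JSON (0-based node indices in the file)
write_lattice_json <- function(lattice, path) {
  obj <- list(
    nodes = unname(apply(lattice$nodes, 1, function(r) r, simplify = FALSE)),
    struts = list(a = lattice$struts$a - 1L, b = lattice$struts$b - 1L,
                  diameter = lattice$struts$diameter,
                  tag = lattice$struts$tag))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

read_lattice_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(obj$nodes)) obj$nodes <- do.call(rbind, obj$nodes)
  lattice_model(obj$nodes,
                data.frame(a = obj$struts$a + 1L, b = obj$struts$b + 1L,
                           diameter = obj$struts$diameter,
                           tag = obj$struts$tag, stringsAsFactors = FALSE))
}

# stage reports -> one tidy CSV (one row per stage per bin)
reports_to_csv <- function(reports, bins, path) {
  rows <- NULL
  slab <- c(paste0("<", bins$stress_edges[1]),
            paste(head(bins$stress_edges, -1), tail(bins$stress_edges, -1),
                  sep = "-"),
            paste0(">", tail(bins$stress_edges, 1)))
  tlab <- c(paste0("0-", bins$strain_edges[1]),
            paste(head(bins$strain_edges, -1), tail(bins$strain_edges, -1),
                  sep = "-"),
            paste0(">", tail(bins$strain_edges, 1)))
  for (r in reports) {
    rows <- rbind(rows,
                  data.frame(stage = r$stage, field = "implant_stress_MPa",
                             bin = slab, percent = r$stress_percentages,
                             max_value = r$max_stress),
                  data.frame(stage = r$stage, field = "graft_strain_ue",
                             bin = tlab, percent = r$strain_percentages,
                             max_value = r$max_strain))
  }
  write.csv(format(rows, digits = 10, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Run the full design pipeline
#'
#' Fixture -> lattice generation (trabecular core + grid shell + gradient +
#' fixation) -> Boolean graft voxelization -> three-stage healing sweep ->
#' strut-diameter optimization -> artifact export. All randomness flows
#' from `config$seed`; a second run with the same config reproduces every
#' numeric artifact byte for byte.
#'
#' Artifacts written to `out_dir`: `config.json`, `fixture_outer.stl`,
#' `fixture_defect.stl`, `fixture_sets.json` (0-based node-set indices),
#' `lattice_initial.json`/`.stl`, `lattice_final.json`/`.stl`,
#' `reports_initial.csv`, `reports_final.csv`, `trace.csv`,
#' `summary.json`, `field_final_GT.vtk`, `run.log`.
#'
#' @param config a `scaffem_config` (see [pipeline_config()]).
#' @param out_dir output directory (created if missing).
#' @param steps which stages of the pipeline to run (prefix of the default
#'   order); `"all"` means everything.
#' @param verbose log progress to stderr.
#' @return (invisibly) a list with the optimizer result and artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "scaffem_out",
                         steps = "all", verbose = FALSE) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    writeLines(msg, logcon)
    flush(logcon)
    if (verbose) message(msg)
  }
  say("config hash: ", config_hash(config), "; seed: ", config$seed)
  write_config(config, file.path(out_dir, "config.json"))

  do_all <- identical(steps, "all")
  want <- function(s) do_all || s %in% steps

  geom <- config$geometry
  if (identical(geom$kind, "stl")) {
    region <- read_stl(geom$stl_path)
    fixture <- NULL
    say("geometry: STL ", geom$stl_path, " (lattice generation only; ",
        "healing sweep and optimization need the fixture geometry)")
  } else {
    fixture <- make_defect_fixture(geom$span_mm, geom$height_mm, geom$width_mm,
                                   geom$curvature, config$seed,
                                   geom$stump_mm, geom$fillet_mm)
    region <- fixture$defect_region
    say("fixture: span ", geom$span_mm, " mm, defect volume ",
        sprintf("%.1f", mesh_volume(region)), " mm^3")
  }
  if (want("fixture") && !is.null(fixture)) {
    write_stl(fixture$outer_surface, file.path(out_dir, "fixture_outer.stl"))
    write_stl(fixture$defect_region, file.path(out_dir, "fixture_defect.stl"))
    jsonlite::write_json(
      list(stump_faces = lapply(fixture$stump_faces, function(i) i - 1L),
           occlusal_nodes = fixture$occlusal_nodes - 1L,
           condyle_nodes = fixture$condyle_nodes - 1L,
           seed = fixture$seed),
      file.path(out_dir, "fixture_sets.json"), digits = NA)
  }
  if (!any(vapply(c("generate", "solve", "analyze", "optimize", "export"),
                  want, logical(1))))
    return(invisible(list(fixture = fixture)))

  cell <- unit_cell_spec(config$cell$cell_kind, config$cell$pore_diameter_mm,
                         config$cell$orientation)
  sspec <- strut_spec(config$strut$d_min_mm, config$strut$d_max_mm,
                      config$strut$gradient_axis)
  insf <- if (!is.null(fixture))
    function(p) fixture_inside(fixture, p, "defect") else NULL
  trab <- tessellate_trabecular(region, cell, inside_fn = insf)
  shell <- build_grid_shell(region, cell, inside_fn = insf)
  lat <- merge_lattices(trab, shell, snap_tol = cell$pore_diameter / 10)
  lat <- assign_gradient_diameters(lat, sspec)
  if (!is.null(fixture)) {
    fspec <- fixation_spec(config$fixation$retainer_thickness_mm,
                           config$fixation$screw_length_mm,
                           config$fixation$screws_per_side)
    lat <- place_fixation(lat, fixture, fspec)
  }
  say("lattice: ", nrow(lat$nodes), " nodes, ", nrow(lat$struts), " struts")
  write_lattice_json(lat, file.path(out_dir, "lattice_initial.json"))
  if (isTRUE(config$export$stl))
    write_stl(lattice_to_surface(lat, config$export$segments_per_circle),
              file.path(out_dir, "lattice_initial.stl"))
  if (is.null(fixture) ||
      !any(vapply(c("solve", "analyze", "optimize"), want, logical(1)))) {
    say("done (generation only)")
    return(invisible(list(fixture = fixture, lattice = lat)))
  }

  design <- defect_model(fixture, lat, voxel_mm = config$voxel_mm,
                         load = load_case(config$load$bite_force_N))
  say("design: ", nrow(design$vox$elems), " voxels (", design$counts$graft,
      " graft), Boolean partition ",
      design$counts$graft + design$counts$strut, " = ",
      design$counts$region)
  stages <- healing_stages(config$stages)
  bins <- list(stress_edges = config$bins$stress_edges,
               strain_edges = config$bins$strain_edges)
  crit <- criteria_config(config$criteria$yield_strength_MPa,
                          config$criteria$strain_window_ue,
                          config$criteria$max_iterations,
                          config$criteria$improvement_tolerance)

  if (!want("optimize")) {
    reports <- run_stage_sweep(design, stages, bins)
    reports_to_csv(reports, bins, file.path(out_dir, "reports_initial.csv"))
    status <- evaluate_criteria(reports, crit)
    jsonlite::write_json(list(
      config_hash = config_hash(config), seed = config$seed,
      initial = list(max_stress = as.list(status$max_stress_by_stage),
                     adaptation = as.list(status$adaptation_by_stage),
                     stress_pass = status$stress_pass)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    say("done (analysis only)")
    return(invisible(list(fixture = fixture, lattice = lat, design = design,
                          reports = reports, status = status)))
  }

  opt <- optimize_lattice(design, crit,
                          quantile = config$criteria$hotspot_quantile,
                          stages = stages, verbose = verbose)
  reports_to_csv(opt$initial_reports, bins,
                 file.path(out_dir, "reports_initial.csv"))
  reports_to_csv(opt$final_reports, bins,
                 file.path(out_dir, "reports_final.csv"))
  write.csv(format(opt$trace, digits = 10, trim = TRUE),
            file.path(out_dir, "trace.csv"), row.names = FALSE, quote = FALSE)
  write_lattice_json(opt$design$lattice, file.path(out_dir, "lattice_final.json"))
  if (isTRUE(config$export$stl))
    write_stl(lattice_to_surface(opt$design$lattice,
                                 config$export$segments_per_circle),
              file.path(out_dir, "lattice_final.stl"))
  if (isTRUE(config$export$vtk)) {
    gt_stage <- healing_stages("G-T")[[1]]
    fin <- solve_stage(opt$design, gt_stage)
    write_vtk(fin$asm, fin$result, file.path(out_dir, "field_final_GT.vtk"))
  }
  init_status <- evaluate_criteria(opt$initial_reports, crit)
  jsonlite::write_json(list(
    config_hash = config_hash(config), seed = config$seed,
    converged = opt$converged, reason = opt$reason,
    iterations = nrow(opt$trace),
    initial = list(max_stress = as.list(init_status$max_stress_by_stage),
                   adaptation = as.list(init_status$adaptation_by_stage),
                   stress_pass = init_status$stress_pass),
    final = list(max_stress = as.list(opt$status$max_stress_by_stage),
                 adaptation = as.list(opt$status$adaptation_by_stage),
                 stress_pass = opt$status$stress_pass)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  say(sprintf("optimize: %s after %d iterations (%s); G-T max stress %.2f -> %.2f MPa, adaptation %.2f%% -> %.2f%%",
              if (opt$converged) "converged" else "NOT converged",
              nrow(opt$trace), opt$reason,
              init_status$max_stress_by_stage["G-T"],
              opt$status$max_stress_by_stage["G-T"],
              init_status$adaptation_by_stage["G-T"],
              opt$status$adaptation_by_stage["G-T"]))
  say("total ", sprintf("%.1f", as.numeric(Sys.time() - t0, units = "secs")),
      " s")
  invisible(list(fixture = fixture, lattice = lat, design = design,
                 opt = opt))
}

#' Command-line interface
#'
#' Subcommands: `fixture`, `generate`, `solve`, `analyze`, `optimize`,
#' `export`, `all`. Flags: `--config <json>`, `--seed <int>`,
#' `--out <dir>`, `--verbose`.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return exit status 0 invisibly; stops with a message on bad usage.
#' @export
scaffem_cli <- function(args = commandArgs(TRUE)) {
  usage <- paste(
    "usage: scaffem <fixture|generate|solve|analyze|optimize|export|all>",
    "[--config file.json] [--seed N] [--out dir] [--verbose]")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  args <- args[-1]
  opt <- list(config = NULL, seed = NULL, out = "scaffem_out", verbose = FALSE)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--verbose") { opt$verbose <- TRUE; i <- i + 1 }
    else if (a %in% c("--config", "--seed", "--out")) {
      if (i == length(args)) stop("missing value for ", a, call. = FALSE)
      opt[[sub("^--", "", a)]] <- args[i + 1]
      i <- i + 2
    } else stop("unknown argument ", a, "\n", usage, call. = FALSE)
  }
  cfg <- if (!is.null(opt$config)) read_config(opt$config) else pipeline_config()
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  steps <- switch(cmd,
                  fixture = "fixture",
                  generate = c("fixture", "generate"),
                  solve = c("fixture", "generate", "solve"),
                  analyze = c("fixture", "generate", "solve", "analyze"),
                  optimize = c("fixture", "generate", "solve", "analyze",
                               "optimize"),
                  export = "export_only",
                  all = "all",
                  stop("unknown subcommand ", cmd, "\n", usage, call. = FALSE))
  if (identical(steps, "export_only")) {
    lj <- file.path(opt$out, "lattice_final.json")
    if (!file.exists(lj)) lj <- file.path(opt$out, "lattice_initial.json")
    if (!file.exists(lj)) stop("no lattice JSON in ", opt$out, call. = FALSE)
    lat <- read_lattice_json(lj)
    write_stl(lattice_to_surface(lat, cfg$export$segments_per_circle),
              file.path(opt$out, sub("json$", "stl", basename(lj))))
  } else {
    run_pipeline(cfg, opt$out, steps = steps, verbose = opt$verbose)
  }
  invisible(0L)
}
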