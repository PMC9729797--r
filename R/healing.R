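# Healing-stage sweep and binned frequency statistics: the mechanobiological
# readout of the pipeline.

#' Default frequency bins
#'
#' Eight stress intervals (<50, 50-100, ..., 300-350, >350 MPa) and four
#' strain intervals (0-3000, 3000-6000, 6000-10000, >10000 microstrain).
#' Bins are encoded by their interior cut points.
#'
#' @return list with `stress_edges` (7 values, MPa) and `strain_edges`
#'   (3 values, microstrain).
#' @export
frequency_bins <- function() {
  list(stress_edges = seq(50, 350, by = 50),
       strain_edges = c(3000, 6000, 10000))
}

#' Binned frequency analysis of a field
#'
#' Percentages of values per bin. Membership is half-open `[lo, hi)`; the
#' first bin is open below, the last open above. Percentages sum to 100.
#'
#' @param field non-empty numeric vector (node values).
#' @param edges strictly increasing interior cut points.
#' @return numeric vector of length `length(edges) + 1`, percentages.
#' @export
frequency_analysis <- function(field, edges) {
  if (!length(field)) stop_invalid("empty field")
  if (is.unsorted(edges, strictly = TRUE)) stop_invalid("edges must be strictly increasing")
  counts <- tabulate(findInterval(field, edges) + 1L, nbins = length(edges) + 1L)
  100 * counts / length(field)
}

#' Frequency report for one healing stage
#'
#' @param stage_label `"G-T"`, `"IM-B"` or `"M-B"`.
#' @param implant_stress per-node implant equivalent stresses (MPa).
#' @param graft_strain per-node graft equivalent strains (microstrain).
#' @param bins a [frequency_bins()] list.
#' @return a `scaffem_report` list with `stress_percentages` (8),
#'   `strain_percentages` (4), `max_stress`, `max_strain` and
#'   `adaptation_fraction` (% of graft nodes inside the 0-3000 microstrain
#'   remodeling window = first strain bin).
#' @export
frequency_report <- function(stage_label, implant_stress, graft_strain,
                             bins = frequency_bins()) {
  sp <- frequency_analysis(implant_stress, bins$stress_edges)
  tp <- frequency_analysis(graft_strain, bins$strain_edges)
  structure(list(stage = stage_label,
                 stress_percentages = sp, strain_percentages = tp,
                 max_stress = max(implant_stress),
                 max_strain = max(graft_strain),
                 adaptation_fraction = tp[1]),
            class = "scaffem_report")
}

#' @export
print.scaffem_report <- function(x, ...) {
  cat(sprintf("<%s: max stress %.2f MPa, max strain %.0f ue, %% in 0-3000 ue: %.2f>\n",
              x$stage, x$max_stress, x$max_strain, x$adaptation_fraction))
  invisible(x)
}

#' Run the healing-stage sweep
#'
#' One independent linear solve per stage; only the graft material changes
#' between stages (granulation tissue 0.2 MPa, immature bone 1000 MPa,
#' mature bone 5000 MPa). Implant statistics are taken over strut end nodes,
#' graft statistics over graft voxel nodes.
#'
#' @param design a [defect_model()].
#' @param stages a [healing_stages()] list.
#' @param bins a [frequency_bins()] list.
#' @return list of [frequency_report()]s, one per stage, with the raw
#'   fields attached as attribute `fields`.
#' @export
run_stage_sweep <- function(design, stages = healing_stages(),
                            bins = frequency_bins()) {
  if (!length(stages)) stop_invalid("stages must be non-empty")
  out <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    res <- tryCatch(solve_stage(design, st),
                    error = function(e)
                      stop("stage ", st$label, " solve failed: ",
                           conditionMessage(e)))
    rep <- frequency_report(st$label, res$implant_stress, res$graft_strain, bins)
    attr(rep, "fields") <- res
    out[[i]] <- rep
  }
  out
}

#' Solve one healing stage of a defect design
#'
#' @param design a [defect_model()].
#' @param stage one element of [healing_stages()].
#' @return list: `implant_stress` (per strut-end, MPa), `graft_strain`
#'   (per graft voxel node, microstrain), `result` ([fe_solve()] output),
#'   `asm` (the assembly).
#' @export
solve_stage <- function(design, stage) {
  mats <- design$materials
  mats$graft <- stage$graft_material
  fem <- fe_model(vox = design$vox, beam_nodes = design$lattice$nodes,
                  beam_elems = design$beam_elems, materials = mats,
                  springs = design$springs, loads = design$loads,
                  bcs = design$bcs, tie_tol = design$tie_tol)
  asm <- fe_assemble(fem)
  res <- fe_solve(asm)
  list(implant_stress = as.vector(res$beams$end_stress),
       graft_strain = nodal_field(res, asm, "eq_strain", materials = "graft"),
       result = res, asm = asm)
}

#' Criteria configuration
#'
#' @param yield_strength implant yield strength (MPa), default 897 (Ti6Al4V).
#' @param strain_window_upper upper bound of the bone-remodeling strain
#'   adaptation window (microstrain), default 3000.
#' @param max_iterations optimizer iteration cap, default 20.
#' @param improvement_tolerance stop when the G-T adaptation fraction
#'   improves by less than this many percentage points, default 0.5.
#' @return a `scaffem_criteria` list.
#' @export
criteria_config <- function(yield_strength = 897, strain_window_upper = 3000,
                            max_iterations = 20, improvement_tolerance = 0.5) {
  if (any(c(yield_strength, strain_window_upper, max_iterations,
            improvement_tolerance) <= 0))
    stop_invalid("criteria values must be positive")
  structure(list(yield_strength = yield_strength,
                 strain_window_upper = strain_window_upper,
                 max_iterations = as.integer(max_iterations),
                 improvement_tolerance = improvement_tolerance),
            class = "scaffem_criteria")
}

#' Evaluate the design criteria on a set of stage reports
#'
#' The stress criterion passes when the maximum implant stress is at most
#' the yield strength (inclusive) at every stage. The adaptation fraction
#' (share of graft nodes in the 0-3000 microstrain window) is recorded per
#' stage; the optimizer maximizes it at the G-T stage subject to the stress
#' criterion.
#'
#' @param reports list of [frequency_report()]s.
#' @param criteria a [criteria_config()].
#' @return a `scaffem_criteria_status` list: `stress_pass` (overall),
#'   `stress_pass_by_stage`, `max_stress_by_stage`,
#'   `adaptation_by_stage` (named numeric).
#' @export
evaluate_criteria <- function(reports, criteria = criteria_config()) {
  lbl <- vapply(reports, function(r) r$stage, character(1))
  mx <- setNames(vapply(reports, function(r) r$max_stress, numeric(1)), lbl)
  ad <- setNames(vapply(reports, function(r) r$adaptation_fraction, numeric(1)), lbl)
  by_stage <- mx <= criteria$yield_strength
  structure(list(stress_pass = all(by_stage),
                 stress_pass_by_stage = by_stage,
                 max_stress_by_stage = mx,
                 adaptation_by_stage = ad),
            class = "scaffem_criteria_status")
}
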