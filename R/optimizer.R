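# Iterative strut-diameter optimization: fully-stressed-design resizing of
# stress-concentration struts until the yield criterion holds at every
# healing stage and the graft strain-adaptation fraction stops improving.

#' Identify stress-concentration struts
#'
#' Struts whose equivalent stress exceeds `max(quantile(stress, q),
#' yield/2)`. Evaluated on the worst (softest-graft, G-T) stage, where the
#' implant carries the most load. Deterministic: result ordered by strut id.
#'
#' @param stress per-strut equivalent stress (MPa, max over both ends).
#' @param quantile percentile cutoff in (0, 1), default 0.9.
#' @param yield yield strength (MPa), default 897.
#' @return sorted integer vector of strut ids (possibly empty).
#' @export
identify_hotspots <- function(stress, quantile = 0.9, yield = 897) {
  cutoff <- max(stats::quantile(stress, quantile, names = FALSE), yield / 2)
  sort(which(stress > cutoff))
}

#' Resize strut diameters toward the stress target and the strain window
#'
#' Stress side (fully-stressed design with per-step clamps): hotspot struts
#' get `d <- clip(d * sqrt(stress/target), 0.9 d, 1.25 d)`, then clip to
#' `[d_min, d_max]`, with `target = yield/1.5`.
#'
#' Mechanobiological side (active only when `local_strain` is supplied):
#' non-hotspot struts whose neighbouring graft strain exceeds the
#' remodeling window thicken by 15% per step (the graft needs a stiffer
#' cage to come back into the 0--3000 microstrain range); the 5%
#' stress-shielding shrink of struts loaded below `target/4` is restricted
#' to places where the local graft strain is also below half the window,
#' so material is removed only where neither strength nor stimulus needs
#' it. Without `local_strain` the shrink applies to all struts below
#' `target/4`. Only `trabecular` and `grid` struts are resized; fixation
#' geometry is fixed.
#'
#' @param lattice a [lattice_model()].
#' @param hotspots strut ids from [identify_hotspots()].
#' @param stress per-strut equivalent stress (MPa), same order as
#'   `lattice$struts`.
#' @param spec a [strut_spec()] (diameter bounds).
#' @param yield yield strength (MPa).
#' @param local_strain optional per-strut neighbouring graft equivalent
#'   strain (microstrain), `NA` where no graft is nearby.
#' @param strain_window upper bound of the adaptation window (microstrain).
#' @return the lattice with updated diameters.
#' @export
update_diameters <- function(lattice, hotspots, stress, spec = strut_spec(),
                             yield = 897, local_strain = NULL,
                             strain_window = 3000) {
  if (length(hotspots) && any(!hotspots %in% seq_len(nrow(lattice$struts))))
    stop_invalid("hotspot id outside lattice")
  target <- yield / 1.5
  d <- lattice$struts$diameter
  resizable <- lattice$struts$tag %in% c("trabecular", "grid")
  hs <- intersect(hotspots, which(resizable))
  if (length(hs)) {
    dn <- d[hs] * sqrt(stress[hs] / target)
    dn <- pmin(pmax(dn, 0.9 * d[hs]), 1.25 * d[hs])
    d[hs] <- pmin(pmax(dn, spec$d_min), spec$d_max)
  }
  overstrained <- rep(FALSE, length(d))
  calm <- rep(TRUE, length(d))
  if (!is.null(local_strain)) {
    overstrained <- !is.na(local_strain) & local_strain > strain_window
    calm <- is.na(local_strain) | local_strain < strain_window / 2
  }
  grow <- setdiff(which(resizable & overstrained), hs)
  d[grow] <- pmin(d[grow] * 1.15, spec$d_max)
  # load spreading around saturated hotspots: a hotspot already at d_max
  # cannot be strengthened further, so its incident struts thicken instead
  saturated <- hs[d[hs] >= spec$d_max - 1e-12]
  if (length(saturated)) {
    ends <- c(lattice$struts$a[saturated], lattice$struts$b[saturated])
    nb <- which(resizable &
                  (lattice$struts$a %in% ends | lattice$struts$b %in% ends))
    nb <- setdiff(nb, c(hs, grow))
    d[nb] <- pmin(d[nb] * 1.15, spec$d_max)
  } else nb <- integer(0)
  shielded <- setdiff(which(resizable & stress < target / 4 & calm),
                      c(hs, grow, nb))
  d[shielded] <- pmax(d[shielded] * 0.95, spec$d_min)
  lattice$struts$diameter <- d
  lattice
}

#' Neighbourhood graft strain per strut
#'
#' Mean equivalent strain of graft voxel nodes within `radius` of each strut
#' midpoint; `NA` for struts with no graft nearby (screws in bone).
#'
#' @param design a [defect_model()].
#' @param asm assembly from [solve_stage()].
#' @param graft_strain per-graft-node strains (microstrain) matching
#'   [nodal_field()] with `materials = "graft"`.
#' @param radius neighbourhood radius (mm); default half the pore diameter.
#' @return numeric vector, one value per strut.
#' @export
strut_local_strain <- function(design, asm, graft_strain, radius = NULL) {
  vox <- asm$fem$vox
  rows <- which(vox$mat == "graft")
  nn <- nrow(vox$nodes)
  cnt <- numeric(nn)
  for (a in 1:8) cnt <- cnt + .accum(vox$elems[rows, a], rep(1, length(rows)), nn)
  gid <- which(cnt > 0)
  gpos <- vox$nodes[gid, , drop = FALSE]
  if (is.null(radius)) {
    pore <- if (!is.null(design$lattice$provenance$cell))
      design$lattice$provenance$cell$pore_diameter else 5
    radius <- pore / 2
  }
  st <- design$lattice$struts
  mid <- (design$lattice$nodes[st$a, , drop = FALSE] +
            design$lattice$nodes[st$b, , drop = FALSE]) / 2
  out <- rep(NA_real_, nrow(st))
  r2 <- radius^2
  for (s in seq_len(nrow(st))) {
    d2 <- (gpos[, 1] - mid[s, 1])^2 + (gpos[, 2] - mid[s, 2])^2 +
      (gpos[, 3] - mid[s, 3])^2
    sel <- d2 <= r2
    if (any(sel)) out[s] <- mean(graft_strain[sel])
  }
  out
}

#' Optimize the lattice implant
#'
#' Two-phase deterministic loop. Each iteration solves all healing stages,
#' scores the design and re-voxelizes the graft on the same grid after any
#' diameter change.
#'
#' * Global phase: uniform 1.1x scaling of all resizable (trabecular/grid)
#'   diameters per step, as long as the G-T adaptation fraction keeps
#'   improving by at least `improvement_tolerance` percentage points. A
#'   stiffer cage is the dominant lever that pulls the soft early graft
#'   back into the 0--3000 microstrain window.
#' * Local phase: fully-stressed-design resizing of stress hotspots plus
#'   the mechanobiological growth/shrink rules of [update_diameters()],
#'   until the stress criterion passes at every stage and the adaptation
#'   improvement falls below the tolerance (or nothing changes, or
#'   `max_iterations` is reached).
#'
#' A design that already meets the criteria -- stress pass, no hotspots and
#' no over-window graft neighbourhood -- is returned unchanged after one
#' evaluation. Returns the best design seen, by the lexicographic key
#' (stress feasibility, then G-T adaptation fraction); `converged = FALSE`
#' flags that no feasible design was found within the budget. There is no
#' randomness in the loop; hotspot ties are broken by ascending strut id.
#'
#' @param design a [defect_model()].
#' @param criteria a [criteria_config()].
#' @param quantile hotspot percentile (see [identify_hotspots()]).
#' @param stages healing stages to score (default all three).
#' @param verbose print one line per iteration.
#' @return list: `design` (best), `trace` (data.frame, one row per
#'   iteration), `converged`, `reason`, `initial_reports`, `final_reports`,
#'   `status` (criteria status of the best design).
#' @export
optimize_lattice <- function(design, criteria = criteria_config(),
                             quantile = 0.9, stages = healing_stages(),
                             verbose = FALSE) {
  spec <- design$lattice$provenance$strut
  if (is.null(spec)) spec <- strut_spec()
  gt <- which(vapply(stages, function(s) s$label, character(1)) == "G-T")
  if (!length(gt)) gt <- 1L
  trace <- NULL
  best <- NULL
  prev_adapt <- NULL
  phase <- "global"
  reason <- "max_iterations"
  initial_reports <- NULL
  cur <- design
  for (iter in seq_len(criteria$max_iterations)) {
    reports <- run_stage_sweep(cur, stages)
    if (is.null(initial_reports)) initial_reports <- reports
    status <- evaluate_criteria(reports, criteria)
    adapt <- reports[[gt]]$adaptation_fraction
    fields <- attr(reports[[gt]], "fields")
    es <- matrix(fields$implant_stress, ncol = 2)
    strut_stress <- pmax(es[, 1], es[, 2])
    stopifnot(all(cur$lattice$struts$diameter[
      cur$lattice$struts$tag %in% c("trabecular", "grid")] >=
        spec$d_min - 1e-12))
    hotspots <- identify_hotspots(strut_stress, quantile,
                                  criteria$yield_strength)
    loc <- strut_local_strain(cur, fields$asm, fields$graft_strain)
    key <- c(as.numeric(status$stress_pass), adapt)
    if (is.null(best) || key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2])) {
      best <- list(design = cur, key = key, reports = reports,
                   status = status, iteration = iter)
    }
    n_mod <- 0L
    stop_now <- FALSE
    criteria_met <- status$stress_pass && !length(hotspots) &&
      !any(loc > criteria$strain_window_upper, na.rm = TRUE)
    if (criteria_met) {
      reason <- "criteria_met"; stop_now <- TRUE
    } else if (!is.null(prev_adapt) &&
               (adapt - prev_adapt) < criteria$improvement_tolerance) {
      if (phase == "global") {
        phase <- "local"        # global scaling exhausted; fine-tune locally
        prev_adapt <- NULL
      } else if (status$stress_pass) {
        reason <- "converged"; stop_now <- TRUE
      }
    }
    if (!stop_now && iter < criteria$max_iterations) {
      if (phase == "global") {
        newlat <- cur$lattice
        sel <- newlat$struts$tag %in% c("trabecular", "grid")
        newlat$struts$diameter[sel] <-
          pmin(newlat$struts$diameter[sel] * 1.1, spec$d_max)
        n_mod <- sum(abs(newlat$struts$diameter -
                           cur$lattice$struts$diameter) > 1e-12)
        if (n_mod == 0L) phase <- "local"  # bounds saturated
      }
      if (phase == "local") {
        newlat <- update_diameters(cur$lattice, hotspots, strut_stress, spec,
                                   criteria$yield_strength,
                                   local_strain = loc,
                                   strain_window = criteria$strain_window_upper)
        n_mod <- sum(abs(newlat$struts$diameter -
                           cur$lattice$struts$diameter) > 1e-12)
        if (n_mod == 0L) { reason <- "stalled"; stop_now <- TRUE }
      }
    }
    trace <- rbind(trace, data.frame(
      iteration = iter, phase = phase,
      t(setNames(status$max_stress_by_stage,
                 paste0("max_stress_", names(status$max_stress_by_stage)))),
      t(setNames(status$adaptation_by_stage,
                 paste0("adaptation_", names(status$adaptation_by_stage)))),
      n_modified = n_mod, feasible = status$stress_pass,
      check.names = FALSE))
    if (verbose)
      message(sprintf("iter %d [%s]: max G-T stress %.1f MPa, adaptation %.2f%%, %d struts modified",
                      iter, phase, status$max_stress_by_stage[gt], adapt, n_mod))
    if (stop_now || iter == criteria$max_iterations) break
    cur <- design_with_lattice(cur, newlat)
    prev_adapt <- adapt
  }
  trace$reason <- c(rep("", nrow(trace) - 1), reason)
  converged <- isTRUE(best$status$stress_pass)
  list(design = best$design, trace = trace, converged = converged,
       reason = reason, initial_reports = initial_reports,
       final_reports = best$reports, status = best$status)
}
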