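#' Isotropic linear-elastic material
#'
#' @param name material label.
#' @param E Young's modulus (MPa), > 0.
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param yield_strength yield strength (MPa) or `NA` when not applicable.
#' @return a `scaffem_material` list.
#' @export
material <- function(name, E, nu, yield_strength = NA_real_) {
  if (!is.numeric(E) || E <= 0) stop_invalid("E must be > 0 (got ", E, ")")
  if (!is.numeric(nu) || nu <= 0 || nu >= 0.5)
    stop_invalid("nu must be in (0, 0.5) (got ", nu, ")")
  structure(list(name = name, E = as.numeric(E), nu = as.numeric(nu),
                 yield_strength = as.numeric(yield_strength)),
            class = "scaffem_material")
}

#' Default material table
#'
#' Literature values used throughout the pipeline: cortical and cancellous
#' bone, articular disc, tooth, the Ti6Al4V implant alloy (with its 897 MPa
#' yield strength) and the three graft healing stages (granulation tissue,
#' immature bone, mature bone).
#'
#' @return named list of [material()] objects.
#' @export
default_materials <- function() {
  list(
    cortical    = material("cortical",    15000,  0.3),
    cancellous  = material("cancellous",   1500,  0.3),
    disc        = material("disc",           44.1, 0.4),
    tooth       = material("tooth",       20000,  0.3),
    ti6al4v     = material("ti6al4v",    110000,  0.3, yield_strength = 897),
    granulation = material("granulation",     0.2, 0.167),
    immature    = material("immature",     1000,  0.3),
    mature      = material("mature",       5000,  0.3)
  )
}

#' Healing stages for the graft-material sweep
#'
#' Three regeneration periods: `G-T` (granulation tissue, early), `IM-B`
#' (immature bone, middle), `M-B` (mature bone, final). Each stage assigns
#' the corresponding material to the bone-graft continuum.
#'
#' @param labels subset of `c("G-T", "IM-B", "M-B")`.
#' @return list of stages, each `list(label, graft_material)`.
#' @export
healing_stages <- function(labels = c("G-T", "IM-B", "M-B")) {
  mats <- default_materials()
  map <- list(`G-T` = mats$granulation, `IM-B` = mats$immature,
              `M-B` = mats$mature)
  bad <- setdiff(labels, names(map))
  if (length(bad)) stop_invalid("unknown healing stage: ", paste(bad, collapse = ", "))
  lapply(labels, function(l) list(label = l, graft_material = map[[l]]))
}

# muscle group -> spring stiffness N/mm
.muscle_stiffness <- c(temporalis = 14, masseter = 16.35,
                       lateral_pterygoid = 12, medial_pterygoid = 15)

#' Masticatory muscle force table (maximum 800 N bite)
#'
#' Eight muscle groups per side with their forces under a maximum-force bite
#' and the spring stiffness of the group they belong to (temporalis 14,
#' masseter 16.35, lateral pterygoid 12, medial pterygoid 15 N/mm). Muscles
#' act simultaneously as a point force along their direction vector and as a
#' grounded spring at the attachment node.
#'
#' @return data.frame with columns `name`, `side`, `force` (N), `stiffness`
#'   (N/mm).
#' @export
default_muscle_forces <- function() {
  nm <- c("anterior_temporalis", "posterior_temporalis",
          "superior_lateral_pterygoid", "inferior_lateral_pterygoid",
          "medial_pterygoid", "superficial_masseter",
          "deep_anterior_masseter", "deep_posterior_masseter")
  grp <- c("temporalis", "temporalis", "lateral_pterygoid", "lateral_pterygoid",
           "medial_pterygoid", "masseter", "masseter", "masseter")
  left  <- c(222.3, 158.6, 5.1, 65.5, 170.8, 196.3, 37.9, 44.9)
  right <- c(221.5, 156.5, 5.3, 76.1, 170.7, 196.3, 37.9, 44.2)
  data.frame(
    name = rep(nm, 2),
    side = rep(c("left", "right"), each = 8),
    force = c(left, right),
    stiffness = rep(unname(.muscle_stiffness[grp]), 2),
    stringsAsFactors = FALSE
  )
}

# Placeholder unit direction vectors per muscle, canonical (left) side;
# the right side mirrors the lateral (y) component. Published anatomical
# direction cosines are not part of the packaged data; override via config.
.muscle_directions <- rbind(
  anterior_temporalis        = c(-0.10, -0.20, 0.97),
  posterior_temporalis       = c(-0.45, -0.15, 0.88),
  superior_lateral_pterygoid = c(-0.60,  0.75, 0.28),
  inferior_lateral_pterygoid = c(-0.65,  0.72, -0.24),
  medial_pterygoid           = c(-0.10,  0.49, 0.87),
  superficial_masseter       = c( 0.20, -0.22, 0.95),
  deep_anterior_masseter     = c( 0.05, -0.30, 0.95),
  deep_posterior_masseter    = c(-0.20, -0.33, 0.92)
)

#' Placeholder muscle direction vectors
#'
#' Unit action lines for each muscle on each side. These are plausible
#' stand-ins (superior-medial pulls for elevators, anterior-medial for
#' pterygoids), not published anatomical direction cosines; override them in
#' the pipeline config when real directions are available.
#'
#' @return data.frame `name`, `side`, `dx`, `dy`, `dz` (unit vectors).
#' @export
default_muscle_directions <- function() {
  d <- .muscle_directions / sqrt(rowSums(.muscle_directions^2))
  out <- rbind(
    data.frame(name = rownames(d), side = "left",
               dx = d[, 1], dy = d[, 2], dz = d[, 3]),
    data.frame(name = rownames(d), side = "right",
               dx = d[, 1], dy = -d[, 2], dz = d[, 3])
  )
  rownames(out) <- NULL
  out
}
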