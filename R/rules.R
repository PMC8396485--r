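#' Geometric interaction rules
#'
#' Distance and angle criteria used to call protein-ligand interactions from
#' 3D geometry. Defaults follow common interaction-geometry surveys: hydrogen
#' bonds at 3.5 A donor-acceptor heavy-atom distance (D-H...A angle >= 130
#' degrees when hydrogens are present), hydrophobic contacts at 4.5 A,
#' aromatic stacking at 5.5 A centroid distance with parallel (<= 30 degrees)
#' or T-shaped (>= 60 degrees) interplanar angles, cation-pi at 6.0 A,
#' halogen bonds at 3.8 A with a near-linear C-X...A angle (>= 140 degrees),
#' and ionic contacts at 5.5 A. Parallel-displaced pi-stacking at ~5 A in a
#' channel pore falls inside the aromatic bound.
#'
#' @param hbond_dist_max maximum donor-acceptor heavy atom distance, A.
#' @param hbond_angle_min minimum D-H...A angle, degrees (only applied when an
#'   explicit hydrogen position is available; otherwise distance-only).
#' @param hydrophobic_dist_max maximum hydrophobic-feature-centroid to apolar
#'   protein atom distance, A.
#' @param aromatic_centroid_max maximum ring-centroid distance, A.
#' @param parallel_angle_max maximum interplanar angle for parallel /
#'   parallel-displaced stacking, degrees.
#' @param tshape_angle_min minimum interplanar angle for T-shaped stacking,
#'   degrees.
#' @param cation_pi_max maximum charged-center to ring-centroid distance, A.
#' @param halogen_dist_max maximum X...acceptor distance, A.
#' @param halogen_angle_min minimum C-X...A angle, degrees.
#' @param ionic_dist_max maximum distance between opposite charges, A.
#' @return an object of class `dynopharm_rules` (a named list).
#' @export
geometric_rules <- function(hbond_dist_max = 3.5,
                            hbond_angle_min = 130,
                            hydrophobic_dist_max = 4.5,
                            aromatic_centroid_max = 5.5,
                            parallel_angle_max = 30,
                            tshape_angle_min = 60,
                            cation_pi_max = 6.0,
                            halogen_dist_max = 3.8,
                            halogen_angle_min = 140,
                            ionic_dist_max = 5.5) {
  rules <- list(
    hbond_dist_max = hbond_dist_max,
    hbond_angle_min = hbond_angle_min,
    hydrophobic_dist_max = hydrophobic_dist_max,
    aromatic_centroid_max = aromatic_centroid_max,
    parallel_angle_max = parallel_angle_max,
    tshape_angle_min = tshape_angle_min,
    cation_pi_max = cation_pi_max,
    halogen_dist_max = halogen_dist_max,
    halogen_angle_min = halogen_angle_min,
    ionic_dist_max = ionic_dist_max
  )
  bad <- vapply(rules, function(v) !is.numeric(v) || length(v) != 1 || v <= 0,
                logical(1))
  if (any(bad)) {
    dyn_abort("bad-rules", paste("non-positive rule value:",
                                 paste(names(rules)[bad], collapse = ", ")))
  }
  ang <- c(hbond_angle_min, parallel_angle_max, tshape_angle_min,
           halogen_angle_min)
  if (any(ang < 0 | ang > 180)) {
    dyn_abort("bad-rules", "angle bounds must lie in [0, 180] degrees")
  }
  structure(rules, class = "dynopharm_rules")
}

#' Default pharmacophore feature radii
#'
#' Tolerance radii (A) assigned to perceived features: 1.5 A for point-like
#' features (hydrophobic, donor, acceptor, positive ionizable, halogen-bond
#' donor) and 1.1 A for aromatic ring features, mirroring common
#' pharmacophore-tool defaults.
#'
#' @param point radius for H/HBD/HBA/PI/XBD features, A.
#' @param aromatic radius for AR features, A.
#' @return named numeric vector keyed by feature type.
#' @export
feature_radii <- function(point = 1.5, aromatic = 1.1) {
  c(H = point, AR = aromatic, PI = point, HBD = point, HBA = point,
    XBD = point)
}

#' Feature type legend
#'
#' The closed set of feature / interaction types with display colours:
#' aromatic (blue), hydrophobic (yellow), hydrogen-bond acceptor (red),
#' hydrogen-bond donor (green), positive ionizable (cyan; cation-pi contacts
#' are reported under this type), halogen-bond donor (pink).
#'
#' @return tibble with columns `type`, `label`, `color`.
#' @export
feature_types <- function() {
  tibble(
    type = c("AR", "H", "HBA", "HBD", "PI", "XBD"),
    label = c("aromatic", "hydrophobic", "H-bond acceptor", "H-bond donor",
              "positive ionizable", "halogen-bond donor"),
    color = c("#3B6FB6", "#E8C84C", "#C0392B", "#2E8B57", "#2AB6C9",
              "#E377C2")
  )
}
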