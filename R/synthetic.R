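# Synthetic study system: a C4-symmetric channel-pore-like binding pocket
# (four chains, each contributing an inward-facing tyrosine ring, a serine
# hydroxyl, an alanine hydrophobic site and a stacking phenylalanine) and a
# quaternary-ammonium pore-blocker ligand with four independently togglable
# interaction arms. Trajectories realize prescribed per-frame interaction
# occupancies with Gaussian coordinate jitter; ground truth is computed by
# an evaluator that shares only the geometric rule *values* with the
# detection pipeline, not its code.

#' Synthetic pocket specification
#'
#' Geometry template of the C4-symmetric pocket: chain A carries SER436
#' (hydroxyl pointing into the pore), TYR464 (inward-facing aromatic ring
#' above the cavity, hydroxyl towards the pore axis), ALA465 (hydrophobic
#' CB lining the lower cavity) and PHE468 (ring poised for parallel
#' stacking); chains B, C, D are 90/180/270-degree rotations about the pore
#' axis.
#'
#' @param n_chains number of symmetric chains (fixed at 4).
#' @return a `dynopharm_pocket` list with the chain-A atom template.
#' @export
pocket_spec <- function(n_chains = 4) {
  if (n_chains != 4) {
    dyn_abort("infeasible-schedule", "the pocket template is C4-symmetric")
  }
  structure(list(n_chains = 4L, template = pocket_chain_template()),
            class = "dynopharm_pocket")
}

# chain A atoms; other chains by rotation about z
pocket_chain_template <- function() {
  hexagon <- function(center, attach_angle = 0) {
    ang <- (attach_angle + c(0, 60, 120, 180, 240, 300)) * pi / 180
    tibble(x = center[1] + 1.39 * cos(ang),
           y = center[2] + 1.39 * sin(ang),
           z = center[3])
  }
  ser <- tibble(
    resname = "SER", resid = 436L,
    name = c("N", "CA", "CB", "OG", "C", "O"),
    element = c("N", "C", "C", "O", "C", "O"),
    x = c(10.5, 9.5, 8.4, 7.0, 10.3, 11.5),
    y = c(0, 0, 0, 0, 1.2, 1.3),
    z = c(3.0, 2.0, 1.0, 0.7, 1.5, 1.7))
  tyr_ring <- hexagon(c(3.66, 0, 4.1))
  tyr <- bind_rows(
    tibble(resname = "TYR", resid = 464L,
           name = c("N", "CA", "CB", "C", "O", "OH"),
           element = c("N", "C", "C", "C", "O", "O"),
           x = c(8.6, 7.6, 6.44, 8.3, 9.5, 0.92),
           y = c(0, 0, 0, 1.2, 1.4, 0),
           z = c(6.0, 5.1, 4.3, 4.5, 4.4, 4.3)),
    tibble(resname = "TYR", resid = 464L,
           name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
           element = "C",
           x = tyr_ring$x, y = tyr_ring$y, z = tyr_ring$z))
  ala <- tibble(
    resname = "ALA", resid = 465L,
    name = c("N", "CA", "CB", "C", "O"),
    element = c("N", "C", "C", "C", "O"),
    x = c(9.6, 8.9, 7.5, 9.5, 10.7),
    y = c(0, 0, 0, 1.1, 1.2),
    z = c(0.3, -0.9, -0.5, -1.6, -1.8))
  phe_ring <- hexagon(c(4.4, 0, 5.0))
  phe <- bind_rows(
    tibble(resname = "PHE", resid = 468L,
           name = c("N", "CA", "CB", "C", "O"),
           element = c("N", "C", "C", "C", "O"),
           x = c(9.1, 8.1, 7.0, 8.8, 10.0),
           y = c(0, 0, 0, 1.2, 1.3),
           z = c(7.2, 6.2, 5.4, 5.6, 5.5)),
    tibble(resname = "PHE", resid = 468L,
           name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
           element = "C",
           x = phe_ring$x, y = phe_ring$y, z = phe_ring$z))
  bind_rows(ser, tyr, ala, phe)
}

# ring atoms named in the perception tables' cyclic order; fix TYR order
# (hexagon() emits CG at angle 0 = the outward attachment vertex)
pocket_protein_atoms <- function(pocket = pocket_spec()) {
  tpl <- pocket$template
  chains <- c("A", "B", "C", "D")
  angles <- c(0, 90, 180, 270)
  out <- purrr::map2_dfr(chains, angles, function(ch, ang) {
    th <- ang * pi / 180
    tibble(chain = ch, resname = tpl$resname, resid = tpl$resid,
           name = tpl$name, element = tpl$element,
           x = tpl$x * cos(th) - tpl$y * sin(th),
           y = tpl$x * sin(th) + tpl$y * cos(th),
           z = tpl$z)
  })
  out
}

#' Synthetic pore-blocker ligand
#'
#' A quaternary ammonium core with up to four interaction arms: an aromatic
#' arm (benzene, pi-stacks on PHE468 of chain A and TYR464), a hydroxyl arm
#' (hydrogen bonds to SER436 of chain B), a hydrophobic tail (contacts
#' ALA465 of chain C) and a chloroalkyl arm (halogen-bonds to SER436 of
#' chain D). Omitted arms are replaced by methyl stubs so the nitrogen stays
#' quaternary (+1). Each arm has an engaged pose (interaction geometry
#' satisfied with >= 0.4 A margin) and a disengaged pose (rotated away,
#' all criteria violated by >= 0.1 A / several degrees).
#'
#' @param arms character subset of `c("ar", "hb", "h", "x")`.
#' @param arm_shift named list of 3-vectors (per arm, A) applied to the
#'   arm's atoms in both poses; keep below ~0.12 A per coordinate so the
#'   engineered interaction margins survive.
#' @param tail_extra add one carbon to the hydrophobic tail.
#' @param id molecule id / residue name.
#' @return a `dynopharm_synth_ligand` list: `mol` (the engaged-pose
#'   `dynopharm_mol`), the atom table with per-arm pose coordinates, and the
#'   planted feature definitions used by the ground-truth evaluator.
#' @export
synthetic_ligand <- function(arms = c("ar", "hb", "h", "x"),
                             arm_shift = list(), tail_extra = FALSE,
                             id = "LIG") {
  arms <- match.arg(arms, c("ar", "hb", "h", "x"), several.ok = TRUE)
  at <- list()
  bd <- list()
  add_atom <- function(name, element, arm, moving, ex, ey, ez,
                       dx = NA, dy = NA, dz = NA) {
    at[[length(at) + 1]] <<- tibble(
      name = name, element = element, arm = arm, moving = moving,
      ex = ex, ey = ey, ez = ez,
      dxx = ifelse(is.na(dx), ex, dx), dyy = ifelse(is.na(dy), ey, dy),
      dzz = ifelse(is.na(dz), ez, dz))
    length(at)
  }
  add_bond <- function(i, j, order = 1L, aromatic = FALSE) {
    bd[[length(bd) + 1]] <<- tibble(i = i, j = j, order = order,
                                    aromatic = aromatic)
  }
  n1 <- add_atom("N1", "N", "core", FALSE, 0, 0, 0)

  rot_about <- function(pts, pivot, axis, angle) {
    r <- rotation_about_axis(axis, angle)
    sweep(t(r %*% t(sweep(pts, 2, pivot))), 2, pivot, "+")
  }

  # aromatic arm: pivot C2, ring centered (4.35, 0, 0.5); disengaged by
  # +65 degree rotation about y through C2 (swings the ring down/out)
  if ("ar" %in% arms) {
    c2 <- add_atom("C2", "C", "ar", FALSE, 1.45, 0, 0.5)
    ring_ctr <- c(4.35, 0, 0.5)
    ang <- (180 + c(0, 60, 120, 180, 240, 300)) * pi / 180
    ring_e <- cbind(ring_ctr[1] + 1.39 * cos(ang),
                    ring_ctr[2] + 1.39 * sin(ang),
                    ring_ctr[3])
    ring_d <- rot_about(ring_e, c(1.45, 0, 0.5), c(0, 1, 0), 65)
    ring_idx <- integer(6)
    for (k in 1:6) {
      ring_idx[k] <- add_atom(paste0("C", 2 + k), "C", "ar", TRUE,
                              ring_e[k, 1], ring_e[k, 2], ring_e[k, 3],
                              ring_d[k, 1], ring_d[k, 2], ring_d[k, 3])
    }
    add_bond(n1, c2)
    add_bond(c2, ring_idx[1])
    for (k in 1:6) {
      add_bond(ring_idx[k], ring_idx[(k %% 6) + 1],
               order = ifelse(k %% 2 == 1, 2L, 1L), aromatic = TRUE)
    }
  } else {
    add_bond(n1, add_atom("C2", "C", "ar_stub", FALSE, 1.45, 0, 0.5))
  }

  # hydroxyl arm: pivot C9; disengaged by -80 degrees about x through C9
  if ("hb" %in% arms) {
    c9 <- add_atom("C9", "C", "hb", FALSE, 0, 1.45, -0.5)
    hb_e <- rbind(c(0, 2.70, 0.45), c(0, 4.10, 0.70))
    hb_d <- rot_about(hb_e, c(0, 1.45, -0.5), c(1, 0, 0), -80)
    c10 <- add_atom("C10", "C", "hb", TRUE, hb_e[1, 1], hb_e[1, 2],
                    hb_e[1, 3], hb_d[1, 1], hb_d[1, 2], hb_d[1, 3])
    o11 <- add_atom("O11", "O", "hb", TRUE, hb_e[2, 1], hb_e[2, 2],
                    hb_e[2, 3], hb_d[2, 1], hb_d[2, 2], hb_d[2, 3])
    add_bond(n1, c9); add_bond(c9, c10); add_bond(c10, o11)
  } else {
    add_bond(n1, add_atom("C9", "C", "hb_stub", FALSE, 0, 1.45, -0.5))
  }

  # hydrophobic tail: pivot C12; disengaged by -40 degrees about y
  if ("h" %in% arms) {
    c12 <- add_atom("C12", "C", "h", FALSE, -1.45, 0, 0.5)
    tail_e <- rbind(c(-2.75, 0, -0.25), c(-4.20, 0, -0.55))
    if (tail_extra) tail_e <- rbind(tail_e, c(-5.65, 0, -0.85))
    tail_d <- rot_about(tail_e, c(-1.45, 0, 0.5), c(0, 1, 0), -40)
    prev <- c12
    for (k in seq_len(nrow(tail_e))) {
      ci <- add_atom(paste0("C", 12 + k), "C", "h", TRUE,
                     tail_e[k, 1], tail_e[k, 2], tail_e[k, 3],
                     tail_d[k, 1], tail_d[k, 2], tail_d[k, 3])
      add_bond(prev, ci); prev <- ci
    }
    add_bond(n1, c12)
  } else {
    add_bond(n1, add_atom("C12", "C", "h_stub", FALSE, -1.45, 0, 0.5))
  }

  # chloroalkyl arm: pivot C15; disengaged by +60 degrees about x
  if ("x" %in% arms) {
    c15 <- add_atom("C15", "C", "x", FALSE, 0, -1.45, -0.5)
    x_e <- rbind(c(0, -2.90, -0.55), c(0, -4.60, -0.55))
    x_d <- rot_about(x_e, c(0, -1.45, -0.5), c(1, 0, 0), 60)
    c16 <- add_atom("C16", "C", "x", TRUE, x_e[1, 1], x_e[1, 2],
                    x_e[1, 3], x_d[1, 1], x_d[1, 2], x_d[1, 3])
    cl17 <- add_atom("CL1", "Cl", "x", TRUE, x_e[2, 1], x_e[2, 2],
                     x_e[2, 3], x_d[2, 1], x_d[2, 2], x_d[2, 3])
    add_bond(n1, c15); add_bond(c15, c16); add_bond(c16, cl17)
  } else {
    add_bond(n1, add_atom("C15", "C", "x_stub", FALSE, 0, -1.45, -0.5))
  }

  atoms <- bind_rows(at)
  bonds <- bind_rows(bd)
  for (arm in names(arm_shift)) {
    sel <- atoms$arm == arm
    atoms$ex[sel] <- atoms$ex[sel] + arm_shift[[arm]][1]
    atoms$ey[sel] <- atoms$ey[sel] + arm_shift[[arm]][2]
    atoms$ez[sel] <- atoms$ez[sel] + arm_shift[[arm]][3]
    atoms$dxx[sel] <- atoms$dxx[sel] + arm_shift[[arm]][1]
    atoms$dyy[sel] <- atoms$dyy[sel] + arm_shift[[arm]][2]
    atoms$dzz[sel] <- atoms$dzz[sel] + arm_shift[[arm]][3]
  }
  mol <- molecule(
    id = id,
    atoms = tibble(element = atoms$element,
                   charge = ifelse(atoms$name == "N1", 1L, 0L)),
    bonds = bonds,
    conformers = list(cbind(atoms$ex, atoms$ey, atoms$ez)))
  structure(list(mol = mol, atoms = atoms, arms = arms, id = id),
            class = "dynopharm_synth_ligand")
}

ARM_SITES <- tibble(
  arm = c("ar", "hb", "h", "x"),
  resname = c("PHE", "SER", "ALA", "SER"),
  resid = c(468L, 436L, 465L, 436L),
  chain = c("A", "B", "C", "D"),
  type = c("AR", "HBD", "H", "XBD")
)

#' Occupancy schedule for the synthetic trajectory
#'
#' Target Bernoulli probabilities for each togglable interaction: the
#' aromatic stack on PHE468/A, the hydrogen bond to SER436/B, the
#' hydrophobic contact with ALA465/C and the halogen bond to SER436/D.
#'
#' @param p named numeric vector over a subset of `c("ar","hb","h","x")`,
#'   values in `[0, 1]`.
#' @param n_frames number of frames.
#' @param sigma isotropic per-atom Gaussian jitter, A. The default (0.05) is
#'   small enough that no planted interaction flips its state.
#' @param seed integer seed.
#' @return a `dynopharm_schedule` list.
#' @export
occupancy_schedule <- function(p = c(ar = 0.9, hb = 0.95, h = 0.9, x = 0.6),
                               n_frames = 500, sigma = 0.05, seed = 1) {
  if (is.null(names(p)) || !all(names(p) %in% ARM_SITES$arm)) {
    dyn_abort("infeasible-schedule",
              paste("schedule sites must be among:",
                    paste(ARM_SITES$arm, collapse = ", ")))
  }
  if (any(p < 0 | p > 1)) {
    dyn_abort("infeasible-schedule", "probabilities must lie in [0, 1]")
  }
  stopifnot(sigma >= 0, n_frames >= 1)
  structure(list(p = p, n_frames = as.integer(n_frames), sigma = sigma,
                 seed = as.integer(seed)),
            class = "dynopharm_schedule")
}

#' Generate a synthetic pocket-ligand trajectory with planted interactions
#'
#' For each frame, each scheduled arm is independently engaged with its
#' target probability (seeded); engaged/disengaged arm poses realize or
#' violate the corresponding geometric criterion with an engineered margin.
#' Isotropic Gaussian jitter is added to every atom; frames where jitter
#' pushed any interaction criterion within 0.05 A (2 degrees) of its
#' decision boundary, flipped a scheduled interaction, or perturbed
#' first-frame ring planarity / bond-inference distances are resampled (at
#' most 100 attempts).
#'
#' @param ligand a [synthetic_ligand()].
#' @param schedule an [occupancy_schedule()].
#' @param pocket a [pocket_spec()].
#' @return list with `trajectory` (a `dynopharm_traj`), `ground_truth`
#'   (tibble `frame`, `chain`, `resid`, `resname`, `type` of every realized
#'   interaction, computed by the independent evaluator), `states` (tibble
#'   `frame`, `arm`, `engaged`), and `ligand` (the engaged-pose molecule).
#' @export
generate_complex_trajectory <- function(ligand = synthetic_ligand(),
                                        schedule = occupancy_schedule(),
                                        pocket = pocket_spec()) {
  missing_arm <- setdiff(names(schedule$p), ligand$arms)
  if (length(missing_arm) > 0) {
    dyn_abort("infeasible-schedule",
              paste("ligand lacks scheduled arm(s):",
                    paste(missing_arm, collapse = ", ")))
  }
  prot <- pocket_protein_atoms(pocket)
  lat <- ligand$atoms
  nfr <- schedule$n_frames
  np <- nrow(prot); nl <- nrow(lat)
  withr::local_seed(schedule$seed)

  arms <- names(schedule$p)
  states <- matrix(0L, nrow = nfr, ncol = length(arms),
                   dimnames = list(NULL, arms))
  for (a in arms) {
    states[, a] <- stats::rbinom(nfr, 1L, schedule$p[[a]])
  }

  # ideal (jitter-free) coordinates per frame
  ideal_lig <- function(state_row) {
    xyz <- cbind(lat$ex, lat$ey, lat$ez)
    for (a in arms) {
      if (state_row[[a]] == 0L) {
        sel <- lat$arm == a & lat$moving
        xyz[sel, ] <- cbind(lat$dxx, lat$dyy, lat$dzz)[sel, , drop = FALSE]
      }
    }
    xyz
  }
  prot_xyz <- cbind(prot$x, prot$y, prot$z)
  gt_defs <- ground_truth_definitions(ligand, prot)

  lig_frames <- array(0, dim = c(nl, 3, nfr))
  prot_frames <- array(0, dim = c(np, 3, nfr))
  need <- rep(TRUE, nfr)
  attempt <- 0
  base_lig <- lapply(seq_len(nfr), function(fi) ideal_lig(states[fi, ]))
  while (any(need) && attempt < 100) {
    attempt <- attempt + 1
    idx <- which(need)
    for (fi in idx) {
      lig_frames[, , fi] <- base_lig[[fi]] +
        matrix(stats::rnorm(3 * nl, 0, schedule$sigma), nl, 3)
      prot_frames[, , fi] <- prot_xyz +
        matrix(stats::rnorm(3 * np, 0, schedule$sigma), np, 3)
    }
    ev <- evaluate_gt_frames(lig_frames[, , idx, drop = FALSE],
                             prot_frames[, , idx, drop = FALSE], gt_defs)
    ok <- ev$margin >= 0.05
    for (a in arms) {
      site <- ARM_SITES[ARM_SITES$arm == a, ]
      sel <- ev$hits$chain == site$chain & ev$hits$resid == site$resid &
        ev$hits$type == site$type
      pres <- logical(length(idx))
      pres[unique(ev$hits$frame[sel])] <- TRUE
      ok <- ok & (pres == (states[idx, a] == 1L))
    }
    if (1L %in% idx && ok[match(1L, idx)]) {
      ok[match(1L, idx)] <- frame1_topology_ok(
        lig_frames[, , 1], prot_frames[, , 1], gt_defs)
    }
    need[idx] <- !ok
  }
  if (any(need)) {
    dyn_abort("jitter-instability",
              "jitter kept flipping interactions; reduce sigma")
  }

  ev <- evaluate_gt_frames(lig_frames, prot_frames, gt_defs)
  gt <- ev$hits

  traj_atoms <- bind_rows(
    tibble(frame = rep(seq_len(nfr), each = np),
           serial = rep(seq_len(np), times = nfr),
           name = rep(prot$name, times = nfr),
           element = rep(prot$element, times = nfr),
           resname = rep(prot$resname, times = nfr),
           resid = rep(prot$resid, times = nfr),
           chain = rep(prot$chain, times = nfr),
           x = as.vector(prot_frames[, 1, ]),
           y = as.vector(prot_frames[, 2, ]),
           z = as.vector(prot_frames[, 3, ])),
    tibble(frame = rep(seq_len(nfr), each = nl),
           serial = rep(np + seq_len(nl), times = nfr),
           name = rep(lat$name, times = nfr),
           element = rep(lat$element, times = nfr),
           resname = ligand$id, resid = 1L, chain = "L",
           x = as.vector(lig_frames[, 1, ]),
           y = as.vector(lig_frames[, 2, ]),
           z = as.vector(lig_frames[, 3, ])))
  list(
    trajectory = as_trajectory(traj_atoms, ligand$id),
    ground_truth = gt,
    states = tibble(frame = rep(seq_len(nfr), times = length(arms)),
                    arm = rep(arms, each = nfr),
                    engaged = as.vector(states == 1L)),
    ligand = ligand$mol
  )
}

# ---- independent ground-truth evaluator ------------------------------------
# Enumerates the planted ligand features and protein groups directly from
# the templates (no perception) and applies the rule thresholds with plain
# matrix arithmetic.

ground_truth_definitions <- function(ligand, prot,
                                     rules = geometric_rules()) {
  lat <- ligand$atoms
  idx <- function(names) match(names, lat$name)
  feats <- list()
  if ("ar" %in% ligand$arms) {
    ring <- idx(paste0("C", 3:8))
    feats$AR_ring <- list(type = "AR", atoms = ring)
    feats$H_ring <- list(type = "H", atoms = ring)
  }
  if ("hb" %in% ligand$arms) {
    feats$HBD_o <- list(type = "HBD", atoms = idx("O11"))
    feats$HBA_o <- list(type = "HBA", atoms = idx("O11"))
  }
  if ("h" %in% ligand$arms) {
    tail <- idx(c("C13", "C14", "C15"))
    tail <- tail[!is.na(tail)]
    tail <- tail[lat$arm[tail] == "h"]
    feats$H_tail <- list(type = "H", atoms = tail)
  }
  if ("x" %in% ligand$arms) {
    feats$H_x <- list(type = "H", atoms = idx(c("C16", "CL1")))
    feats$XBD_cl <- list(type = "XBD", atoms = idx("CL1"),
                         carbon = idx("C16"))
  }
  feats$PI_n <- list(type = "PI", atoms = idx("N1"))

  groups <- list()
  res_key <- paste(prot$chain, prot$resid)
  for (key in unique(res_key)) {
    rows <- which(res_key == key)
    rn <- prot$resname[rows[1]]; ch <- prot$chain[rows[1]]
    rid <- prot$resid[rows[1]]
    gadd <- function(kind, atom_rows) {
      groups[[length(groups) + 1]] <<- list(
        kind = kind, chain = ch, resid = rid, resname = rn,
        rows = atom_rows)
    }
    nm <- prot$name[rows]
    if (rn %in% c("TYR", "PHE")) {
      ring_rows <- rows[match(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                              nm)]
      gadd("aromatic", ring_rows)
    }
    if (rn == "SER") { gadd("donor", rows[nm == "OG"])
                       gadd("acceptor", rows[nm == "OG"]) }
    if (rn == "TYR") { gadd("donor", rows[nm == "OH"])
                       gadd("acceptor", rows[nm == "OH"]) }
    gadd("donor", rows[nm == "N"])
    gadd("acceptor", rows[nm == "O"])
    hyd <- switch(rn,
                  ALA = "CB",
                  SER = character(0),
                  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
                  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
    for (h in hyd) gadd("hydrophobic", rows[nm == h])
  }
  list(features = feats, groups = groups, rules = rules,
       lig_bonds = ligand$mol$bonds, lig_elements = lat$element)
}

# mean position of an atom set across frames: 3 x nf matrix
gt_centers <- function(arr, rows) {
  nf <- dim(arr)[3]
  if (length(rows) == 1) {
    return(matrix(arr[rows, , ], nrow = 3, ncol = nf))
  }
  m <- matrix(arr[rows, , , drop = FALSE], nrow = length(rows))
  matrix(colSums(m) / length(rows), nrow = 3, ncol = nf)
}

# Newell polygon normals across frames (unit columns), written on arrays
gt_ring_normals <- function(arr, rows) {
  p <- arr[rows, , , drop = FALSE]
  q <- p[c(2:length(rows), 1), , , drop = FALSE]
  nr <- length(rows)
  px <- matrix(p[, 1, , drop = FALSE], nrow = nr)
  py <- matrix(p[, 2, , drop = FALSE], nrow = nr)
  pz <- matrix(p[, 3, , drop = FALSE], nrow = nr)
  qx <- matrix(q[, 1, , drop = FALSE], nrow = nr)
  qy <- matrix(q[, 2, , drop = FALSE], nrow = nr)
  qz <- matrix(q[, 3, , drop = FALSE], nrow = nr)
  nx <- colSums(py * qz - pz * qy)
  ny <- colSums(pz * qx - px * qz)
  nz <- colSums(px * qy - py * qx)
  nl <- sqrt(nx^2 + ny^2 + nz^2)
  rbind(nx / nl, ny / nl, nz / nl)
}

# Evaluates every planted feature x protein group criterion for all frames
# at once; returns residue-level hits (frame, chain, resid, resname, type)
# and the per-frame minimum decision margin (A; angle margins expressed in
# units of 10 degrees) used by the jitter guard. `frame` indexes into the
# supplied arrays.
evaluate_gt_frames <- function(lig_arr, prot_arr, defs) {
  rules <- defs$rules
  nf <- dim(lig_arr)[3]
  margin <- rep(Inf, nf)
  hits <- list()
  fgeo <- lapply(defs$features, function(f) {
    out <- list(center = gt_centers(lig_arr, f$atoms))
    if (f$type == "AR") out$normal <- gt_ring_normals(lig_arr, f$atoms)
    if (f$type == "XBD") {
      v <- matrix(lig_arr[f$atoms, , ] - lig_arr[f$carbon, , ], nrow = 3)
      nl <- sqrt(colSums(v^2))
      out$normal <- sweep(v, 2, nl, "/")
    }
    out
  })
  ggeo <- lapply(defs$groups, function(g) {
    out <- list(center = gt_centers(prot_arr, g$rows))
    if (g$kind == "aromatic") {
      out$normal <- gt_ring_normals(prot_arr, g$rows)
    }
    out
  })
  for (fi in seq_along(defs$features)) {
    f <- defs$features[[fi]]
    fc <- fgeo[[fi]]$center
    for (gi in seq_along(defs$groups)) {
      g <- defs$groups[[gi]]
      pair_kind <- paste(f$type, g$kind)
      dmax <- switch(pair_kind,
                     "HBD acceptor" = rules$hbond_dist_max,
                     "HBA donor" = rules$hbond_dist_max,
                     "H hydrophobic" = rules$hydrophobic_dist_max,
                     "PI aromatic" = rules$cation_pi_max,
                     "AR aromatic" = rules$aromatic_centroid_max,
                     "XBD acceptor" = rules$halogen_dist_max,
                     NULL)
      if (is.null(dmax)) next
      gc <- ggeo[[gi]]$center
      d <- sqrt(colSums((fc - gc)^2))
      hit <- d <= dmax
      m <- abs(d - dmax)
      if (pair_kind == "AR aromatic") {
        cosab <- abs(colSums(fgeo[[fi]]$normal * ggeo[[gi]]$normal))
        ang <- acos(pmin(1, cosab)) * 180 / pi
        ang_ok <- ang <= rules$parallel_angle_max |
          ang >= rules$tshape_angle_min
        hit <- hit & ang_ok
        am <- pmin(abs(ang - rules$parallel_angle_max),
                   abs(ang - rules$tshape_angle_min)) / 10
        m <- pmin(m, ifelse(d <= dmax + 0.3, am, Inf))
      }
      if (pair_kind == "XBD acceptor") {
        v <- gc - fc
        nl <- sqrt(colSums(v^2))
        cosa <- colSums(fgeo[[fi]]$normal * v) / nl
        ang <- 180 - acos(pmin(1, pmax(-1, cosa))) * 180 / pi
        hit <- hit & ang >= rules$halogen_angle_min
        m <- pmin(m, ifelse(d <= dmax + 0.3,
                            abs(ang - rules$halogen_angle_min) / 10, Inf))
      }
      margin <- pmin(margin, m)
      if (any(hit)) {
        hits[[length(hits) + 1]] <- tibble(
          frame = which(hit), chain = g$chain, resid = g$resid,
          resname = g$resname, type = f$type)
      }
    }
  }
  hits <- if (length(hits) == 0) {
    tibble(frame = integer(), chain = character(), resid = integer(),
           resname = character(), type = character())
  } else {
    distinct(bind_rows(hits))
  }
  list(hits = arrange(hits, .data$frame, .data$chain, .data$resid,
                      .data$type),
       margin = margin)
}

# first-frame requirements: protein rings planar enough to be perceived,
# and distance-based bond inference recovers exactly the template bonds
frame1_topology_ok <- function(lig_xyz, prot_xyz, defs) {
  for (g in defs$groups) {
    if (g$kind == "aromatic" &&
        ring_planarity_rms(prot_xyz[g$rows, , drop = FALSE]) > 0.09) {
      return(FALSE)
    }
  }
  d <- as.matrix(dist(lig_xyz))
  n <- nrow(d)
  bonded <- matrix(FALSE, n, n)
  bonded[cbind(defs$lig_bonds$i, defs$lig_bonds$j)] <- TRUE
  bonded <- bonded | t(bonded)
  if (any(d[bonded] > 1.83)) return(FALSE)
  is_cl <- toupper(defs$lig_elements) %in% HALOGENS
  lim <- matrix(2.0, n, n)
  lim[is_cl, ] <- 2.3
  lim[, is_cl] <- 2.3
  nb <- !bonded
  diag(nb) <- FALSE
  if (any(d[nb] < lim[nb])) return(FALSE)
  TRUE
}

#' Library specification for screening-set generation
#'
#' @param n_actives number of active molecules.
#' @param decoys_per_active decoys generated per active (default 50).
#' @param decoys_total optional total decoy count overriding
#'   `decoys_per_active` (decoys are then assigned to parents round-robin).
#' @param heavy_tol,hbd_tol,hba_tol property-matching tolerances (heavy
#'   atoms, H-bond donors, H-bond acceptors); ring count and formal charge
#'   are matched exactly.
#' @param seed integer seed.
#' @return a `dynopharm_libspec` list.
#' @export
library_spec <- function(n_actives = 15, decoys_per_active = 50,
                         decoys_total = NULL, heavy_tol = 2, hbd_tol = 1,
                         hba_tol = 1, seed = 1) {
  stopifnot(n_actives >= 0, decoys_per_active >= 0)
  if (heavy_tol < 2) {
    dyn_abort("decoy-generation-failed",
              "heavy-atom tolerance below 2 cannot be satisfied")
  }
  structure(list(n_actives = as.integer(n_actives),
                 decoys_per_active = as.integer(decoys_per_active),
                 decoys_total = if (is.null(decoys_total)) NULL
                                else as.integer(decoys_total),
                 heavy_tol = heavy_tol, hbd_tol = hbd_tol,
                 hba_tol = hba_tol, seed = as.integer(seed)),
            class = "dynopharm_libspec")
}

#' Generate a labelled screening library
#'
#' Actives are feature-satisfying molecules built by placing
#' feature-bearing fragments at the model's feature centers (quaternary
#' nitrogen at the positive-ionizable feature, apolar fragments at the
#' hydrophobic features, benzene at the aromatic feature, hydroxyl /
#' chlorine termini at donor / halogen features) joined by alkyl linkers;
#' variants drop optional arms, extend the tail and apply small seeded
#' displacements. Decoys are property-matched (heavy atoms +/-2, ring count
#' and formal charge exact, donors/acceptors +/-1) but topologically
#' rearranged so that only a single apolar fragment exists -- the essential
#' hydrophobic feature and the either-group can then never be satisfied
#' simultaneously, in any conformer.
#'
#' @param model the `dynopharm_model` to build actives for (must have a PI
#'   feature and at least two essential features).
#' @param spec a [library_spec()].
#' @return library tibble with columns `id`, `label` ("active"/"decoy"),
#'   `parent` (decoys), `n_atoms`, `molecule`.
#' @export
generate_screening_library <- function(model, spec = library_spec()) {
  if (sum(model$features$flag == "essential") < 2 ||
      !any(model$features$type == "PI")) {
    dyn_abort("decoy-generation-failed",
              "model needs a PI feature and >= 2 essential features")
  }
  withr::local_seed(spec$seed)
  actives <- purrr::map(seq_len(spec$n_actives), function(i) {
    build_active_molecule(model, variant = i)
  })
  n_decoys <- if (!is.null(spec$decoys_total)) spec$decoys_total
              else spec$n_actives * spec$decoys_per_active
  parents <- if (spec$n_actives > 0) {
    rep(seq_len(spec$n_actives), length.out = n_decoys)
  } else integer(0)
  parent_props <- lapply(actives, molecule_properties)
  decoys <- purrr::map(seq_len(n_decoys), function(k) {
    parent <- actives[[parents[k]]]
    build_decoy_molecule(parent, spec, serial = k,
                         parent_props = parent_props[[parents[k]]])
  })
  lib <- tibble(
    id = c(vapply(actives, function(m) m$id, character(1)),
           vapply(decoys, function(m) m$id, character(1))),
    label = c(rep("active", length(actives)),
              rep("decoy", length(decoys))),
    parent = c(rep(NA_character_, length(actives)),
               vapply(parents, function(p) actives[[p]]$id, character(1))),
    molecule = c(actives, decoys))
  lib$n_atoms <- vapply(lib$molecule, function(m) nrow(m$atoms),
                        integer(1))
  lib
}

# pull named feature centers out of a flagged model
model_anchor_centers <- function(model) {
  ft <- model$features
  pi_i <- which(ft$type == "PI")[1]
  pic <- c(ft$x[pi_i], ft$y[pi_i], ft$z[pi_i])
  h_i <- which(ft$type == "H")
  hd <- sqrt((ft$x[h_i] - pic[1])^2 + (ft$y[h_i] - pic[2])^2 +
             (ft$z[h_i] - pic[3])^2)
  h_i <- h_i[order(hd)]
  list(
    pi = pic,
    h_essential = c(ft$x[h_i[1]], ft$y[h_i[1]], ft$z[h_i[1]]),
    h_other = lapply(h_i[-1], function(i) c(ft$x[i], ft$y[i], ft$z[i])),
    ar = if (any(ft$type == "AR")) {
      i <- which(ft$type == "AR")[1]; c(ft$x[i], ft$y[i], ft$z[i])
    },
    hbd = if (any(ft$type == "HBD")) {
      i <- which(ft$type == "HBD")[1]; c(ft$x[i], ft$y[i], ft$z[i])
    },
    xbd = if (any(ft$type == "XBD")) {
      i <- which(ft$type == "XBD")[1]; c(ft$x[i], ft$y[i], ft$z[i])
    })
}

build_active_molecule <- function(model, variant = 1) {
  anchors <- model_anchor_centers(model)
  wig <- function(v) v + stats::runif(3, -0.12, 0.12)
  atoms <- list(); bonds <- list(); xyz <- list()
  add <- function(element, pos, charge = 0L) {
    atoms[[length(atoms) + 1]] <<- tibble(element = element,
                                          charge = charge)
    xyz[[length(xyz) + 1]] <<- pos
    length(atoms)
  }
  bond <- function(i, j, order = 1L, aromatic = FALSE) {
    bonds[[length(bonds) + 1]] <<- tibble(i = i, j = j, order = order,
                                          aromatic = aromatic)
  }
  pic <- anchors$pi
  n1 <- add("N", pic, charge = 1L)
  unit <- function(v) v / sqrt(sum(v^2))
  perp <- function(u) {
    w <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    unit(pracma_cross(u, w))
  }
  # apolar two-carbon fragment centered on a hydrophobic target
  h_arm <- function(target, extra = FALSE) {
    u <- unit(target - pic)
    ca <- add("C", pic + 1.45 * u)
    if (!extra) {
      cb <- add("C", target - 0.725 * u)
      cc <- add("C", target + 0.725 * u)
      bond(ca, cb); bond(cb, cc)
    } else {
      cb <- add("C", target - 1.45 * u)
      cc <- add("C", target)
      cd <- add("C", target + 1.45 * u)
      bond(ca, cb); bond(cb, cc); bond(cc, cd)
    }
    bond(n1, ca)
  }
  stub <- function(dir) bond(n1, add("C", pic + 1.45 * unit(dir)))

  h_arm(wig(anchors$h_essential), extra = variant %% 4 == 3)
  # aromatic arm doubles as the either-group hydrophobic fragment
  if (!is.null(anchors$ar)) {
    ar <- wig(anchors$ar)
    u <- unit(ar - pic)
    v <- perp(u)
    ca <- add("C", pic + 1.45 * u)
    ring_idx <- integer(6)
    for (k in 1:6) {
      ang <- (k - 1) * pi / 3
      ring_idx[k] <- add("C", ar - 1.39 * cos(ang) * u +
                           1.39 * sin(ang) * v)
    }
    bond(ca, ring_idx[1]); bond(n1, ca)
    for (k in 1:6) {
      bond(ring_idx[k], ring_idx[(k %% 6) + 1],
           order = ifelse(k %% 2 == 1, 2L, 1L), aromatic = TRUE)
    }
  }
  if (!is.null(anchors$hbd) && variant %% 3 != 2) {
    hb <- wig(anchors$hbd)
    u <- unit(hb - pic)
    ca <- add("C", pic + 1.4 * u)
    cb <- add("C", pic + 2.8 * u)
    o <- add("O", hb)
    bond(n1, ca); bond(ca, cb); bond(cb, o)
  } else {
    stub(c(0, 1, -0.4))
  }
  if (!is.null(anchors$xbd) && variant %% 2 != 0) {
    xb <- wig(anchors$xbd)
    u <- unit(xb - pic)
    ca <- add("C", pic + 1.45 * u)
    cb <- add("C", pic + 2.9 * u)
    cl <- add("Cl", xb)
    bond(n1, ca); bond(ca, cb); bond(cb, cl)
  } else {
    stub(c(0, -1, -0.4))
  }
  molecule(id = sprintf("active_%02d", variant),
           atoms = bind_rows(atoms), bonds = bind_rows(bonds),
           conformers = list(do.call(rbind, xyz)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# topology-scrambled, property-matched decoy: keeps the ring, charge and
# acceptor count of the parent but fuses every apolar atom into (at most)
# one fragment attached to the ring, so the essential hydrophobic feature
# and the either-group cannot both be satisfied.
build_decoy_molecule <- function(parent, spec, serial,
                                 parent_props = NULL) {
  target_heavy <- nrow(parent$atoms) +
    sample(seq(-min(2, spec$heavy_tol), min(2, spec$heavy_tol)), 1)
  atoms <- list(); bonds <- list(); xyz <- list()
  add <- function(element, pos, charge = 0L) {
    atoms[[length(atoms) + 1]] <<- tibble(element = element,
                                          charge = charge)
    xyz[[length(xyz) + 1]] <<- pos
    length(atoms)
  }
  bond <- function(i, j, order = 1L, aromatic = FALSE) {
    bonds[[length(bonds) + 1]] <<- tibble(i = i, j = j, order = order,
                                          aromatic = aromatic)
  }
  n1 <- add("N", c(0, 0, 0), charge = 1L)
  # ring bonded directly to the charged nitrogen
  ctr <- c(2.89, 0, 0)
  ring_idx <- integer(6)
  for (k in 1:6) {
    ang <- pi + (k - 1) * pi / 3
    ring_idx[k] <- add("C", c(ctr[1] + 1.39 * cos(ang),
                              ctr[2] + 1.39 * sin(ang), 0))
  }
  bond(n1, ring_idx[1])
  for (k in 1:6) {
    bond(ring_idx[k], ring_idx[(k %% 6) + 1],
         order = ifelse(k %% 2 == 1, 2L, 1L), aromatic = TRUE)
  }
  has_cl <- any(parent$atoms$element == "Cl")
  if (has_cl) {
    v4 <- ring_idx[4]
    bond(v4, add("Cl", c(ctr[1] + 3.09, 0, 0)))
  }
  # ether chain reproduces the acceptor count without a donor
  c9 <- add("C", c(0, 0, 1.5)); bond(n1, c9)
  o11 <- add("O", c(0, 1.1, 2.3)); bond(c9, o11)
  c10 <- add("C", c(0, 2.5, 2.0)); bond(o11, c10)
  c13 <- add("C", c(0, 3.5, 3.0)); bond(c10, c13)
  # two nitrogen methyls keep the nitrogen quaternary
  bond(n1, add("C", c(-1.5, 0, 0)))
  bond(n1, add("C", c(0, -1.5, 0)))
  # pad with ring methyls (seeded positions) to hit the heavy-atom target
  pad_slots <- sample(c(2, 3, 5, 6))
  ang_of <- function(k) pi + (k - 1) * pi / 3
  while (length(atoms) < target_heavy && length(pad_slots) > 0) {
    k <- pad_slots[1]; pad_slots <- pad_slots[-1]
    ang <- ang_of(k)
    bond(ring_idx[k], add("C", c(ctr[1] + 2.89 * cos(ang),
                                 ctr[2] + 2.89 * sin(ang), 0)))
  }
  while (length(atoms) > target_heavy) {
    # drop the terminal chain methyl, then nitrogen methyls
    drop <- length(atoms)
    keep_b <- vapply(bonds, function(b) b$i != drop && b$j != drop,
                     logical(1))
    bonds <- bonds[keep_b]
    atoms <- atoms[-drop]; xyz <- xyz[-drop]
  }
  m <- molecule(id = sprintf("decoy_%s_%03d", parent$id, serial),
                atoms = bind_rows(atoms), bonds = bind_rows(bonds),
                conformers = list(do.call(rbind, xyz)))
  check_decoy(m, parent, spec, parent_props)
  m
}

check_decoy <- function(decoy, parent, spec, parent_props = NULL) {
  pd <- molecule_properties(decoy)
  pp <- parent_props %||% molecule_properties(parent)
  ok <- abs(pd$heavy_atoms - pp$heavy_atoms) <= spec$heavy_tol &&
    pd$rings == pp$rings &&
    abs(pd$hbd - pp$hbd) <= spec$hbd_tol &&
    abs(pd$hba - pp$hba) <= spec$hba_tol &&
    pd$charge == pp$charge
  if (!ok) {
    dyn_abort("decoy-generation-failed",
              sprintf("decoy %s violates property tolerances", decoy$id))
  }
  if (graphs_isomorphic(decoy, parent)) {
    dyn_abort("decoy-generation-failed",
              sprintf("decoy %s is topologically identical to its parent",
                      decoy$id))
  }
  invisible(TRUE)
}

graphs_isomorphic <- function(m1, m2) {
  if (nrow(m1$atoms) != nrow(m2$atoms)) return(FALSE)
  el <- sort(unique(c(m1$atoms$element, m2$atoms$element)))
  g1 <- mol_graph(m1); g2 <- mol_graph(m2)
  igraph::isomorphic(
    g1, g2, method = "vf2",
    vertex.color1 = match(m1$atoms$element, el),
    vertex.color2 = match(m2$atoms$element, el))
}
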