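# Frame-wise protein-ligand interaction detection. The engine is vectorized
# across frames: feature and group geometry are recomputed per frame from
# fixed source-atom sets, candidate pairs are formed by type compatibility
# and filtered by the geometric rules in bulk.

# feature type -> compatible protein group kind(s)
PAIR_COMPAT <- tibble(
  type = c("HBD", "HBA", "H", "AR", "PI", "PI", "XBD"),
  kind = c("acceptor", "donor", "hydrophobic", "aromatic", "aromatic",
           "neg_charge", "acceptor")
)

#' Detect interactions in a single frame
#'
#' Applies the geometric rules to perceived ligand features and protein
#' groups of one frame: hydrogen bonds by donor-acceptor distance (plus
#' D-H...A angle when an explicit hydrogen direction is available),
#' hydrophobic contacts by feature-centroid to apolar-atom distance,
#' aromatic interactions by ring-centroid distance with parallel or T-shaped
#' interplanar angles, cation-pi and ionic contacts (both reported under the
#' PI type), and halogen bonds by X...acceptor distance with a near-linear
#' C-X...A angle.
#'
#' @param frame frame index to stamp on the records (bookkeeping only).
#' @param lig_features ligand feature tibble from
#'   [perceive_ligand_features()].
#' @param protein_groups protein group tibble from
#'   [perceive_protein_groups()].
#' @param rules a [geometric_rules()] object.
#' @return interaction record tibble: `frame`, `feature`, `type`, `chain`,
#'   `resid`, `resname`, `distance`, and the ligand-side feature center
#'   `fx`, `fy`, `fz` (one record per ligand feature / residue / type).
#' @export
detect_frame_interactions <- function(frame = 1L, lig_features,
                                      protein_groups,
                                      rules = geometric_rules()) {
  feats <- mutate(lig_features, frame = as.integer(frame))
  # explicit-H donor position reconstructed from the stored direction
  feats <- mutate(feats,
                  hx = .data$x + .data$dx, hy = .data$y + .data$dy,
                  hz = .data$z + .data$dz)
  groups <- mutate(protein_groups, frame = as.integer(frame))
  pair_records(feats, groups, rules)
}

empty_records <- function() {
  tibble(frame = integer(), feature = character(), type = character(),
         chain = character(), resid = integer(), resname = character(),
         distance = double(), fx = double(), fy = double(), fz = double(),
         dx = double(), dy = double(), dz = double())
}

# vectorized pair filter over per-frame feature/group tables
pair_records <- function(feats, groups, rules) {
  if (nrow(feats) == 0 || nrow(groups) == 0) return(empty_records())
  f <- inner_join(feats, PAIR_COMPAT, by = "type",
                  relationship = "many-to-many")
  cand <- inner_join(
    rename(f, fx = "x", fy = "y", fz = "z",
           fdx = "dx", fdy = "dy", fdz = "dz"),
    rename(groups, gx = "x", gy = "y", gz = "z"),
    by = c("frame", "kind"), relationship = "many-to-many")
  if (nrow(cand) == 0) return(empty_records())
  cand <- mutate(cand,
    distance = sqrt((.data$fx - .data$gx)^2 + (.data$fy - .data$gy)^2 +
                    (.data$fz - .data$gz)^2))
  keep <- rep(FALSE, nrow(cand))

  sel <- cand$type == "HBD" & cand$kind == "acceptor"
  if (any(sel)) {
    ok <- cand$distance[sel] <= rules$hbond_dist_max
    has_h <- !is.na(cand$hx[sel])
    if (any(has_h)) {
      hx <- cand$hx[sel]; hy <- cand$hy[sel]; hz <- cand$hz[sel]
      v1x <- cand$fx[sel] - hx; v1y <- cand$fy[sel] - hy
      v1z <- cand$fz[sel] - hz
      v2x <- cand$gx[sel] - hx; v2y <- cand$gy[sel] - hy
      v2z <- cand$gz[sel] - hz
      cosa <- (v1x * v2x + v1y * v2y + v1z * v2z) /
        sqrt((v1x^2 + v1y^2 + v1z^2) * (v2x^2 + v2y^2 + v2z^2))
      ang <- acos(pmin(1, pmax(-1, cosa))) * 180 / pi
      ok <- ok & (!has_h | ang >= rules$hbond_angle_min)
    }
    keep[sel] <- ok
  }
  sel <- cand$type == "HBA" & cand$kind == "donor"
  keep[sel] <- cand$distance[sel] <= rules$hbond_dist_max
  sel <- cand$type == "H" & cand$kind == "hydrophobic"
  keep[sel] <- cand$distance[sel] <= rules$hydrophobic_dist_max
  sel <- cand$type == "AR" & cand$kind == "aromatic"
  if (any(sel)) {
    cosa <- abs(cand$fdx[sel] * cand$nx[sel] + cand$fdy[sel] * cand$ny[sel] +
                  cand$fdz[sel] * cand$nz[sel])
    ang <- acos(pmin(1, cosa)) * 180 / pi
    keep[sel] <- cand$distance[sel] <= rules$aromatic_centroid_max &
      (ang <= rules$parallel_angle_max | ang >= rules$tshape_angle_min)
  }
  sel <- cand$type == "PI" & cand$kind == "aromatic"
  keep[sel] <- cand$distance[sel] <= rules$cation_pi_max
  sel <- cand$type == "PI" & cand$kind == "neg_charge"
  keep[sel] <- cand$distance[sel] <= rules$ionic_dist_max
  sel <- cand$type == "XBD" & cand$kind == "acceptor"
  if (any(sel)) {
    # C-X...A angle: direction stored is the C->X unit vector, so the bond
    # angle is 180 minus the angle between that vector and X->A
    vx <- cand$gx[sel] - cand$fx[sel]; vy <- cand$gy[sel] - cand$fy[sel]
    vz <- cand$gz[sel] - cand$fz[sel]
    cosa <- (cand$fdx[sel] * vx + cand$fdy[sel] * vy + cand$fdz[sel] * vz) /
      sqrt(vx^2 + vy^2 + vz^2)
    ang <- acos(pmin(1, pmax(-1, cosa))) * 180 / pi
    keep[sel] <- cand$distance[sel] <= rules$halogen_dist_max &
      (180 - ang) >= rules$halogen_angle_min
  }

  hits <- cand[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_records())
  # one record per (frame, feature, residue, type), keeping the closest
  # group member's distance
  hits %>%
    arrange(.data$distance) %>%
    distinct(.data$frame, .data$feature, .data$type, .data$chain,
             .data$resid, .data$resname, .keep_all = TRUE) %>%
    select("frame", "feature", "type", "chain", "resid", "resname",
           "distance", "fx", "fy", "fz",
           dx = "fdx", dy = "fdy", dz = "fdz") %>%
    arrange(.data$frame, .data$chain, .data$resid, .data$type)
}

# per-frame ligand feature table for a whole trajectory. Feature identity
# (source atoms) is perceived once on `frame` = first analyzed frame and the
# geometry is recomputed for every frame.
ligand_feature_frames <- function(traj, mol = NULL, radii = feature_radii()) {
  if (is.null(mol)) mol <- ligand_topology(traj)
  feats0 <- perceive_ligand_features(mol, conformer = 1, radii = radii)
  lig_rows <- is_ligand_row(traj)
  cm <- traj_coord_mats(traj, lig_rows)
  nf <- length(cm$frames)
  nft <- nrow(feats0)
  acc <- function() vector("list", nft)
  xs <- acc(); ys <- acc(); zs <- acc(); dxs <- acc(); dys <- acc()
  dzs <- acc(); hxs <- acc(); hys <- acc(); hzs <- acc()
  roles <- NULL
  for (k in seq_len(nft)) {
    src <- feats0$source_atoms[[k]]
    xs[[k]] <- colMeans(cm$x[src, , drop = FALSE])
    ys[[k]] <- colMeans(cm$y[src, , drop = FALSE])
    zs[[k]] <- colMeans(cm$z[src, , drop = FALSE])
    dxs[[k]] <- dys[[k]] <- dzs[[k]] <- rep(NA_real_, nf)
    hxs[[k]] <- hys[[k]] <- hzs[[k]] <- rep(NA_real_, nf)
    if (feats0$type[k] == "AR") {
      nrm <- ring_normals_frames(cm, src)
      dxs[[k]] <- nrm[, 1]; dys[[k]] <- nrm[, 2]; dzs[[k]] <- nrm[, 3]
    } else if (feats0$type[k] == "XBD") {
      xi <- src[1]
      ci <- xbd_carbon_index(mol, xi)
      vx <- cm$x[xi, ] - cm$x[ci, ]; vy <- cm$y[xi, ] - cm$y[ci, ]
      vz <- cm$z[xi, ] - cm$z[ci, ]
      nl <- sqrt(vx^2 + vy^2 + vz^2)
      dxs[[k]] <- vx / nl; dys[[k]] <- vy / nl; dzs[[k]] <- vz / nl
    } else if (feats0$type[k] == "HBD" && !is.na(feats0$dx[k])) {
      if (is.null(roles)) roles <- mol_roles(mol)
      hcand <- roles$adjacency[[src[1]]]
      hcand <- hcand[roles$elements[hcand] == "H"]
      if (length(hcand) > 0) {
        hxs[[k]] <- cm$x[hcand[1], ]; hys[[k]] <- cm$y[hcand[1], ]
        hzs[[k]] <- cm$z[hcand[1], ]
      }
    }
  }
  tibble(
    frame = rep(cm$frames, times = nft),
    feature = rep(feats0$feature, each = nf),
    type = rep(feats0$type, each = nf),
    x = unlist(xs), y = unlist(ys), z = unlist(zs),
    radius = rep(feats0$radius, each = nf),
    dx = unlist(dxs), dy = unlist(dys), dz = unlist(dzs),
    hx = unlist(hxs), hy = unlist(hys), hz = unlist(hzs))
}

ring_normals_frames <- function(cm, src) {
  k <- length(src)
  nxt <- src[c(2:k, 1)]
  nx <- colSums(cm$y[src, , drop = FALSE] * cm$z[nxt, , drop = FALSE] -
                cm$z[src, , drop = FALSE] * cm$y[nxt, , drop = FALSE])
  ny <- colSums(cm$z[src, , drop = FALSE] * cm$x[nxt, , drop = FALSE] -
                cm$x[src, , drop = FALSE] * cm$z[nxt, , drop = FALSE])
  nz <- colSums(cm$x[src, , drop = FALSE] * cm$y[nxt, , drop = FALSE] -
                cm$y[src, , drop = FALSE] * cm$x[nxt, , drop = FALSE])
  nl <- sqrt(nx^2 + ny^2 + nz^2)
  cbind(nx / nl, ny / nl, nz / nl)
}

xbd_carbon_index <- function(mol, xi) {
  adj <- mol_adjacency(mol)
  cn <- adj[[xi]][toupper(mol$atoms$element[adj[[xi]]]) == "C"]
  cn[1]
}

# per-frame protein group table; group membership perceived on the first
# frame, geometry recomputed per frame. Residues whose first-frame minimum
# ligand distance is within +/- band of `near` are re-checked per frame.
protein_group_frames <- function(traj, near = 8, band = 1.0) {
  f1 <- get_frame(traj, traj_frames(traj)[1])
  groups0 <- perceive_protein_groups(f1, near = NULL)
  if (nrow(groups0) == 0) return(list(groups = groups0, frames = NULL))
  cm <- traj_coord_mats(traj)
  serial_row <- match(seq_len(max(cm$serial)), cm$serial)
  nf <- length(cm$frames)
  ng <- nrow(groups0)
  xs <- vector("list", ng); ys <- vector("list", ng)
  zs <- vector("list", ng); nxs <- vector("list", ng)
  nys <- vector("list", ng); nzs <- vector("list", ng)
  for (k in seq_len(ng)) {
    rows <- serial_row[groups0$atoms[[k]]]
    xs[[k]] <- colMeans(cm$x[rows, , drop = FALSE])
    ys[[k]] <- colMeans(cm$y[rows, , drop = FALSE])
    zs[[k]] <- colMeans(cm$z[rows, , drop = FALSE])
    if (groups0$kind[k] == "aromatic") {
      nrm <- ring_normals_frames(cm, rows)
      nxs[[k]] <- nrm[, 1]; nys[[k]] <- nrm[, 2]; nzs[[k]] <- nrm[, 3]
    } else {
      nxs[[k]] <- nys[[k]] <- nzs[[k]] <- rep(NA_real_, nf)
    }
  }
  gf <- tibble(
    frame = rep(cm$frames, times = ng),
    group = rep(groups0$group, each = nf),
    kind = rep(groups0$kind, each = nf),
    chain = rep(groups0$chain, each = nf),
    resid = rep(groups0$resid, each = nf),
    resname = rep(groups0$resname, each = nf),
    x = unlist(xs), y = unlist(ys), z = unlist(zs),
    nx = unlist(nxs), ny = unlist(nys), nz = unlist(nzs))
  if (!is.null(near)) {
    gf <- filter_groups_near(gf, traj, cm, near, band)
  }
  gf
}

filter_groups_near <- function(gf, traj, cm, near, band) {
  lig_rows <- which(is_ligand_row(traj)[order(traj$frame, traj$serial)][
    seq_len(length(cm$serial))])
  res_tbl <- distinct(gf, .data$chain, .data$resid)
  f1 <- 1L
  keep_static <- logical(nrow(res_tbl)); check <- logical(nrow(res_tbl))
  prot_key <- paste(traj$chain, traj$resid)[order(traj$frame, traj$serial)][
    seq_len(length(cm$serial))]
  for (r in seq_len(nrow(res_tbl))) {
    rows <- which(prot_key == paste(res_tbl$chain[r], res_tbl$resid[r]))
    d1 <- min_cross_dist(cm, rows, lig_rows, f1)
    if (d1 <= near - band) keep_static[r] <- TRUE
    else if (d1 > near + band) keep_static[r] <- FALSE
    else check[r] <- TRUE
  }
  res_tbl$keep <- keep_static
  gf2 <- inner_join(gf, res_tbl, by = c("chain", "resid"))
  if (!any(check)) {
    return(select(filter(gf2, .data$keep), -"keep"))
  }
  # borderline residues: per-frame minimum distance test
  extra <- list()
  for (r in which(check)) {
    rows <- which(prot_key == paste(res_tbl$chain[r], res_tbl$resid[r]))
    dmin <- vapply(seq_along(cm$frames), function(fi)
      min_cross_dist(cm, rows, lig_rows, fi), numeric(1))
    extra[[length(extra) + 1]] <- tibble(
      chain = res_tbl$chain[r], resid = res_tbl$resid[r],
      frame = cm$frames, ok = dmin <= near)
  }
  extra <- bind_rows(extra)
  gf2 <- left_join(gf2, extra, by = c("chain", "resid", "frame"))
  gf2$keep <- ifelse(is.na(gf2$ok), gf2$keep, gf2$ok)
  select(filter(gf2, .data$keep), -"keep", -"ok")
}

min_cross_dist <- function(cm, rows_a, rows_b, fi) {
  dx <- outer(cm$x[rows_a, fi], cm$x[rows_b, fi], "-")
  dy <- outer(cm$y[rows_a, fi], cm$y[rows_b, fi], "-")
  dz <- outer(cm$z[rows_a, fi], cm$z[rows_b, fi], "-")
  sqrt(min(dx^2 + dy^2 + dz^2))
}

#' Detect interactions across a trajectory
#'
#' Runs feature perception on the first analyzed frame, recomputes feature
#' and protein-group geometry for every frame in the window and applies the
#' geometric rules frame-wise.
#'
#' @param traj a `dynopharm_traj`.
#' @param rules a [geometric_rules()] object.
#' @param window integer vector of frame indices to analyze (values of the
#'   `frame` column), or `NULL` for all frames.
#' @param mol optional `dynopharm_mol` giving the ligand topology (atom order
#'   matching the trajectory's ligand atoms); inferred from interatomic
#'   distances when absent.
#' @param near protein perception cutoff around the ligand, A.
#' @return interaction record tibble, one row per (frame, ligand feature,
#'   residue, type).
#' @export
trajectory_interactions <- function(traj, rules = geometric_rules(),
                                    window = NULL, mol = NULL, near = 8) {
  window <- check_window(traj, window)
  sub <- as_trajectory(filter(as_tibble(traj), .data$frame %in% window),
                       ligand_resname(traj))
  feats <- ligand_feature_frames(sub, mol = mol)
  feats <- mutate(feats,
                  hx = ifelse(is.na(.data$hx), NA_real_, .data$hx),
                  hy = .data$hy, hz = .data$hz)
  groups <- protein_group_frames(sub, near = near)
  recs <- pair_records(feats, groups, rules)
  attr(recs, "n_frames") <- length(window)
  attr(recs, "window") <- window
  recs
}

check_window <- function(traj, window) {
  fr <- traj_frames(traj)
  if (is.null(window)) return(fr)
  window <- unique(as.integer(window))
  if (length(window) == 0 || !all(window %in% fr)) {
    dyn_abort("empty-window",
              "window must be a non-empty subset of trajectory frames")
  }
  sort(window)
}

#' Frames of the analysis window
#'
#' Convenience helper for "last fraction of the run" windows: returns the
#' last `frac` of the trajectory's frames (e.g. `frac = 0.2` selects the
#' frames covering the last 20 ns of a 100 ns run).
#'
#' @param traj a `dynopharm_traj`.
#' @param frac fraction in (0, 1].
#' @return integer vector of frame indices.
#' @export
window_last_frac <- function(traj, frac = 0.2) {
  stopifnot(frac > 0, frac <= 1)
  fr <- traj_frames(traj)
  n <- max(1L, as.integer(ceiling(length(fr) * frac)))
  tail(fr, n)
}

#' Build a pharmacophore model from one frame's interaction records
#'
#' One feature per record, placed at the ligand-side feature center and typed
#' by the interaction; the protein partner residue is stored with each
#' feature and the model's canonical signature is attached.
#'
#' @param records interaction records of a single frame.
#' @param radii feature radii, see [feature_radii()].
#' @return a `dynopharm_model` with attribute `signature`.
#' @export
frame_pharmacophore <- function(records, radii = feature_radii()) {
  if (nrow(records) == 0) {
    m <- pharmacophore()
    attr(m, "signature") <- ""
    return(m)
  }
  if (length(unique(records$frame)) != 1) {
    dyn_abort("bad-records", "records must come from a single frame")
  }
  feats <- transmute(
    records,
    type = .data$type, x = .data$fx, y = .data$fy, z = .data$fz,
    radius = unname(feature_radii()[.data$type]),
    dx = .data$dx, dy = .data$dy, dz = .data$dz,
    partner_chain = .data$chain, partner_resid = .data$resid,
    partner_resname = .data$resname)
  m <- pharmacophore(feats)
  attr(m, "signature") <- model_signature(records)
  m
}

#' Interaction occurrence table
#'
#' For every (residue, interaction type) pair, the percentage of analyzed
#' frames in which at least one such interaction is present -- the
#' per-residue relative occurrence table of a simulation.
#'
#' @inheritParams trajectory_interactions
#' @param records optional precomputed records from
#'   [trajectory_interactions()] (must carry the `n_frames` attribute);
#'   when supplied, `traj`/`rules`/`window` are not consulted.
#' @return tibble with columns `chain`, `resid`, `resname`, `type`,
#'   `n_frames`, `percent`, sorted by chain then residue.
#' @export
occurrence_table <- function(traj = NULL, rules = geometric_rules(),
                             window = NULL, records = NULL, mol = NULL) {
  if (is.null(records)) {
    records <- trajectory_interactions(traj, rules, window, mol = mol)
  }
  nfr <- attr(records, "n_frames")
  if (is.null(nfr)) dyn_abort("bad-records", "records lack frame count")
  if (nrow(records) == 0) {
    return(tibble(chain = character(), resid = integer(),
                  resname = character(), type = character(),
                  n_frames = integer(), percent = double()))
  }
  records %>%
    distinct(.data$frame, .data$chain, .data$resid, .data$resname,
             .data$type) %>%
    count(.data$chain, .data$resid, .data$resname, .data$type) %>%
    mutate(n_frames = as.integer(nfr),
           percent = 100 * .data$n / nfr) %>%
    select(-"n") %>%
    arrange(.data$chain, .data$resid, .data$type)
}

#' Histogram of unique per-frame pharmacophore models
#'
#' Counts how often each distinct interaction signature (set of
#' (type, residue) interactions) appears across the analyzed frames. Counts
#' sum to the number of analyzed frames; frames with no interaction
#' contribute the empty signature.
#'
#' @inheritParams occurrence_table
#' @return tibble with columns `signature`, `n_features`, `count`, sorted by
#'   decreasing count.
#' @export
model_histogram <- function(traj = NULL, rules = geometric_rules(),
                            window = NULL, records = NULL, mol = NULL) {
  if (is.null(records)) {
    records <- trajectory_interactions(traj, rules, window, mol = mol)
  }
  nfr <- attr(records, "n_frames")
  window <- attr(records, "window")
  if (is.null(nfr)) dyn_abort("bad-records", "records lack frame count")
  sig_by_frame <- records %>%
    group_by(.data$frame) %>%
    summarise(signature = signature_of(.data$type, .data$chain,
                                       .data$resid),
      n_features = n(), .groups = "drop")
  if (!is.null(window)) {
    missing_frames <- setdiff(window, sig_by_frame$frame)
  } else {
    missing_frames <- integer(0)
  }
  if (length(missing_frames) > 0 || nfr > nrow(sig_by_frame)) {
    n_empty <- nfr - nrow(sig_by_frame)
    sig_by_frame <- bind_rows(
      sig_by_frame,
      tibble(frame = rep(NA_integer_, n_empty), signature = "",
             n_features = 0L))
  }
  sig_by_frame %>%
    count(.data$signature, .data$n_features, name = "count") %>%
    arrange(desc(.data$count), desc(.data$n_features), .data$signature)
}

#' Select the most frequent pharmacophore models
#'
#' Picks the `k` most frequently occurring interaction signatures (ties
#' broken by more features, then lexicographic signature) and builds one
#' representative model per signature: each feature is placed at the
#' centroid of its per-frame ligand feature centers over that signature's
#' frames.
#'
#' @inheritParams occurrence_table
#' @param k number of models to select (default 4).
#' @return list of `dynopharm_model` objects, most frequent first, each with
#'   attributes `signature` and `count`. If fewer than `k` unique non-empty
#'   signatures exist, all are returned with a warning.
#' @export
select_frequent_models <- function(traj = NULL, k = 4,
                                   rules = geometric_rules(),
                                   window = NULL, records = NULL,
                                   mol = NULL) {
  stopifnot(k >= 1)
  if (is.null(records)) {
    records <- trajectory_interactions(traj, rules, window, mol = mol)
  }
  sig_by_frame <- records %>%
    group_by(.data$frame) %>%
    summarise(signature = signature_of(.data$type, .data$chain,
                                       .data$resid),
      n_features = n(), .groups = "drop")
  hist <- sig_by_frame %>%
    count(.data$signature, .data$n_features, name = "count") %>%
    filter(.data$signature != "") %>%
    arrange(desc(.data$count), desc(.data$n_features), .data$signature)
  if (nrow(hist) < k) {
    dyn_warn(sprintf("only %d unique model(s) available (requested %d)",
                     nrow(hist), k))
  }
  top <- head(hist, k)
  purrr::map(seq_len(nrow(top)), function(i) {
    sig <- top$signature[i]
    frames <- sig_by_frame$frame[sig_by_frame$signature == sig]
    sub <- records[records$frame %in% frames, ]
    feats <- sub %>%
      group_by(.data$feature, .data$type, .data$chain, .data$resid,
               .data$resname) %>%
      summarise(x = mean(.data$fx), y = mean(.data$fy), z = mean(.data$fz),
                dx = mean(.data$dx), dy = mean(.data$dy),
                dz = mean(.data$dz), .groups = "drop") %>%
      mutate(radius = unname(feature_radii()[.data$type]))
    # renormalize averaged directions; drop if degenerate
    nl <- sqrt(feats$dx^2 + feats$dy^2 + feats$dz^2)
    ok <- !is.na(nl) & nl > 1e-6
    feats$dx <- ifelse(ok, feats$dx / nl, NA_real_)
    feats$dy <- ifelse(ok, feats$dy / nl, NA_real_)
    feats$dz <- ifelse(ok, feats$dz / nl, NA_real_)
    m <- pharmacophore(transmute(
      feats, type = .data$type, x = .data$x, y = .data$y, z = .data$z,
      radius = .data$radius, dx = .data$dx, dy = .data$dy, dz = .data$dz,
      partner_chain = .data$chain, partner_resid = .data$resid,
      partner_resname = .data$resname))
    attr(m, "signature") <- sig
    attr(m, "count") <- top$count[i]
    m
  })
}
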