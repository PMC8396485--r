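# Trajectory stability metrics: global superposition onto the first frame,
# per-residue C-alpha RMSF, pairwise ligand RMSD matrices (no per-pair
# re-superposition, so the matrix is a true metric) and aromatic-ring
# centroid distance series.

#' Align every frame onto the first frame
#'
#' Least-squares rigid superposition (Kabsch) of each frame onto frame one,
#' fitted on a selection (by default the protein C-alpha atoms); the whole
#' frame -- ligand included -- is moved with the fitted transform, matching
#' the align-then-analyze order of standard trajectory workflows.
#'
#' @param traj a `dynopharm_traj`.
#' @param selection logical vector over one frame's atoms (serial order), or
#'   `NULL` for protein C-alpha atoms.
#' @return the aligned trajectory.
#' @export
align_to_first_frame <- function(traj, selection = NULL) {
  cm <- traj_coord_mats(traj)
  f1 <- get_frame(traj, traj_frames(traj)[1])
  if (is.null(selection)) {
    selection <- f1$name == "CA" & f1$resname != ligand_resname(traj)
  }
  sel <- which(selection)
  if (length(sel) < 3) {
    dyn_abort("degenerate-fit", "selection must contain at least 3 atoms")
  }
  ref <- cbind(cm$x[sel, 1], cm$y[sel, 1], cm$z[sel, 1])
  if (points_rank(ref) < 2) {
    dyn_abort("degenerate-fit", "selection atoms are collinear")
  }
  nf <- length(cm$frames)
  newx <- cm$x; newy <- cm$y; newz <- cm$z
  for (fi in seq_len(nf)) {
    mob <- cbind(cm$x[sel, fi], cm$y[sel, fi], cm$z[sel, fi])
    fit <- kabsch(mob, ref)
    all_xyz <- cbind(cm$x[, fi], cm$y[, fi], cm$z[, fi])
    moved <- apply_rigid(all_xyz, fit$rotation, fit$translation)
    newx[, fi] <- moved[, 1]; newy[, fi] <- moved[, 2]
    newz[, fi] <- moved[, 3]
  }
  out <- as_tibble(traj)
  ord <- order(out$frame, out$serial)
  out <- out[ord, ]
  out$x <- as.vector(newx); out$y <- as.vector(newy)
  out$z <- as.vector(newz)
  as_trajectory(out, ligand_resname(traj))
}

#' Per-residue C-alpha RMSF
#'
#' Root-mean-square fluctuation of each residue's C-alpha atom about its
#' trajectory-mean position: `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)`.
#' The trajectory should be aligned first (see [align_to_first_frame()]).
#'
#' @param traj an aligned `dynopharm_traj`.
#' @return tibble with columns `chain`, `resid`, `resname`, `rmsf` (A).
#'   Residues without a C-alpha atom are omitted with a warning.
#' @export
rmsf_per_residue <- function(traj) {
  prot <- as_tibble(traj)[!is_ligand_row(traj), ]
  res <- distinct(prot, .data$chain, .data$resid, .data$resname)
  ca <- prot[prot$name == "CA", ]
  res_ca <- distinct(ca, .data$chain, .data$resid)
  missing <- anti_join(res, res_ca, by = c("chain", "resid"))
  if (nrow(missing) > 0) {
    dyn_warn(sprintf("%d residue(s) lack a C-alpha atom and were omitted",
                     nrow(missing)))
  }
  ca %>%
    group_by(.data$chain, .data$resid, .data$resname) %>%
    summarise(rmsf = sqrt(mean((.data$x - mean(.data$x))^2 +
                               (.data$y - mean(.data$y))^2 +
                               (.data$z - mean(.data$z))^2)),
              .groups = "drop") %>%
    arrange(.data$chain, .data$resid)
}

#' Pairwise ligand RMSD matrix
#'
#' RMSD between the ligand coordinate sets of every pair of sampled frames,
#' computed in the common (first-frame-aligned) reference frame without
#' per-pair re-superposition, so binding-mode drift stays visible and the
#' matrix is symmetric, zero-diagonal and satisfies the triangle inequality.
#'
#' @param traj an aligned `dynopharm_traj`.
#' @param n_samples number of evenly distributed frames to use (default: all
#'   frames).
#' @return an `n x n` matrix (A) with the sampled frame indices as dimnames.
#' @export
pairwise_ligand_rmsd <- function(traj, n_samples = NULL) {
  if (!is.null(n_samples)) traj <- downsample(traj, n_samples)
  cm <- traj_coord_mats(traj, is_ligand_row(traj))
  natom <- length(cm$serial)
  # frames as rows of a flat coordinate matrix; gram trick for distances
  flat <- t(rbind(cm$x, cm$y, cm$z))
  sq <- rowSums(flat^2)
  d2 <- outer(sq, sq, "+") - 2 * flat %*% t(flat)
  d2[d2 < 0] <- 0
  out <- sqrt(d2 / natom)
  out <- (out + t(out)) / 2
  diag(out) <- 0
  dimnames(out) <- list(cm$frames, cm$frames)
  out
}

#' Aromatic ring centroid distance series
#'
#' Per frame, the Euclidean distance between the side-chain ring centroids
#' of requested residue pairs (for example the stacked phenylalanine pair of
#' each channel subunit, whose separation reports on side-chain rotation
#' events).
#'
#' @param traj a `dynopharm_traj`.
#' @param residue_pairs tibble with columns `chain1`, `resid1`, `chain2`,
#'   `resid2`.
#' @return tibble with columns `frame`, `pair`, `distance` (A).
#' @export
ring_distance_series <- function(traj, residue_pairs) {
  residue_pairs <- as_tibble(residue_pairs)
  stopifnot(all(c("chain1", "resid1", "chain2", "resid2") %in%
                  names(residue_pairs)))
  same <- residue_pairs$chain1 == residue_pairs$chain2 &
    residue_pairs$resid1 == residue_pairs$resid2
  if (any(same)) {
    dyn_abort("no-ring", "a residue cannot be paired with itself")
  }
  cm <- traj_coord_mats(traj)
  f1 <- get_frame(traj, traj_frames(traj)[1])
  centroid_series <- function(ch, rid) {
    at <- f1[f1$chain == ch & f1$resid == rid, ]
    if (nrow(at) == 0) {
      dyn_abort("no-ring", sprintf("residue %s/%d not found", ch, rid))
    }
    rn <- at$resname[1]
    ring_names <- RING_ATOMS[[rn]]
    if (is.null(ring_names)) {
      dyn_abort("no-ring", sprintf("residue %s %s/%d has no aromatic ring",
                                   rn, ch, rid))
    }
    serials <- at$serial[match(ring_names, at$name)]
    if (anyNA(serials)) {
      dyn_abort("no-ring", sprintf("incomplete ring atoms for %s %s/%d",
                                   rn, ch, rid))
    }
    rows <- match(serials, cm$serial)
    cbind(colMeans(cm$x[rows, , drop = FALSE]),
          colMeans(cm$y[rows, , drop = FALSE]),
          colMeans(cm$z[rows, , drop = FALSE]))
  }
  out <- purrr::map_dfr(seq_len(nrow(residue_pairs)), function(i) {
    c1 <- centroid_series(residue_pairs$chain1[i], residue_pairs$resid1[i])
    c2 <- centroid_series(residue_pairs$chain2[i], residue_pairs$resid2[i])
    tibble(
      frame = cm$frames,
      pair = sprintf("%s/%d-%s/%d", residue_pairs$chain1[i],
                     residue_pairs$resid1[i], residue_pairs$chain2[i],
                     residue_pairs$resid2[i]),
      distance = sqrt(rowSums((c1 - c2)^2)))
  })
  out
}
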