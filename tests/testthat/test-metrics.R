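test_that("alignment exactly recovers rigidly moved frames and is idempotent", {
  withr::local_seed(4)
  tbl <- ca_atom_tbl(5)
  base <- rbind(cbind(stats::rnorm(5, sd = 3), stats::rnorm(5, sd = 3),
                      stats::rnorm(5, sd = 3)), c(0.5, 0.5, 0.5))
  coords <- lapply(1:6, function(i) {
    r <- random_rotation()
    t(r %*% t(base)) + rep(stats::rnorm(3, sd = 4), each = nrow(base))
  })
  coords[[1]] <- base
  traj <- make_traj(tbl, coords, "LIG")
  aligned <- align_to_first_frame(traj)
  a <- tibble::as_tibble(aligned)
  for (fi in 2:6) {
    f <- a[a$frame == fi, ]
    expect_equal(cbind(f$x, f$y, f$z), base, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  twice <- align_to_first_frame(aligned)
  expect_equal(tibble::as_tibble(twice)$x, a$x, tolerance = 1e-9)
})

test_that("collinear selections are rejected as degenerate", {
  tbl <- ca_atom_tbl(4)
  coords <- lapply(1:3, function(i) ca_base_coords(4))
  traj <- make_traj(tbl, coords, "LIG")
  expect_error(align_to_first_frame(traj),
               class = "dynopharm_degenerate_fit")
})

test_that("Kabsch RMSD agrees with the quaternion superposition oracle", {
  withr::local_seed(8)
  for (rep in 1:10) {
    x <- matrix(stats::rnorm(30), ncol = 3)
    y <- matrix(stats::rnorm(30), ncol = 3)
    fit <- kabsch(x, y)
    expect_equal(fit$rmsd, quaternion_superpose_rmsd(x, y),
                 tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("RMSF is zero for frozen atoms and exact for two-state motion", {
  tbl <- ca_atom_tbl(3)
  base <- ca_base_coords(3)
  frozen <- make_traj(tbl, lapply(1:10, function(i) base), "LIG")
  expect_equal(rmsf_per_residue(frozen)$rmsf, rep(0, 3))

  # residue 2 oscillates +/- a along x in half of the frames
  a <- 0.8
  coords <- lapply(1:10, function(i) {
    out <- base
    out[2, 1] <- out[2, 1] + ifelse(i %% 2 == 0, a, -a)
    out
  })
  # bypass alignment: motions are already in a common frame
  osc <- make_traj(tbl, coords, "LIG")
  rmsf <- rmsf_per_residue(osc)
  expect_equal(rmsf$rmsf[rmsf$resid == 2], a, tolerance = 1e-9)
})

test_that("RMSF of isotropic Gaussian jitter approaches sigma * sqrt(3)", {
  withr::local_seed(14)
  sigma <- 0.5
  n_res <- 3; nf <- 5000
  tbl <- ca_atom_tbl(n_res)
  base <- ca_base_coords(n_res)
  coords <- lapply(seq_len(nf), function(i) {
    base + rbind(matrix(stats::rnorm(3 * n_res, 0, sigma), n_res, 3), 0)
  })
  traj <- make_traj(tbl, coords, "LIG")
  rmsf <- rmsf_per_residue(traj)
  expect_equal(rmsf$rmsf, rep(sigma * sqrt(3), n_res), tolerance = 0.05)
})

test_that("residues without C-alpha are omitted with a warning", {
  tbl <- ca_atom_tbl(2)
  tbl$name[2] <- "CB"
  traj <- make_traj(tbl, lapply(1:3, function(i) ca_base_coords(2)), "LIG")
  expect_warning(rmsf <- rmsf_per_residue(traj),
                 class = "dynopharm_warning")
  expect_equal(nrow(rmsf), 1)
})

ligand_cluster_traj <- function(n_a = 6, n_b = 6) {
  # 3-atom rigid ligand alternating between two poses 3 A apart (per-atom
  # displacement exactly 3 along x)
  tbl <- tibble::tibble(
    serial = 1:7,
    name = c(rep("CA", 4), "C1", "C2", "C3"),
    element = "C",
    resname = c(rep("ALA", 4), rep("LIG", 3)),
    resid = c(1:4, 1L, 1L, 1L),
    chain = c(rep("A", 4), rep("L", 3)))
  prot <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(0, 3.8, 0), c(1, 1, 2))
  lig_a <- rbind(c(8, 0, 0), c(9.5, 0, 0), c(8, 1.5, 0))
  lig_b <- lig_a + matrix(rep(c(3, 0, 0), each = 3), 3, 3)
  coords <- c(lapply(seq_len(n_a), function(i) rbind(prot, lig_a)),
              lapply(seq_len(n_b), function(i) rbind(prot, lig_b)))
  make_traj(tbl, coords, "LIG")
}

test_that("pairwise ligand RMSD resolves planted pose clusters", {
  traj <- ligand_cluster_traj()
  m <- pairwise_ligand_rmsd(traj)
  expect_equal(dim(m), c(12, 12))
  expect_equal(max(abs(m[1:6, 1:6])), 0, tolerance = 1e-12)
  expect_equal(max(abs(m[7:12, 7:12])), 0, tolerance = 1e-12)
  expect_equal(as.vector(m[1:6, 7:12]), rep(3, 36), tolerance = 1e-9)
})

test_that("pairwise RMSD equals a brute-force double loop and is a metric", {
  withr::local_seed(31)
  tbl <- ca_atom_tbl(1)
  tbl <- dplyr::bind_rows(
    tbl,
    tibble::tibble(serial = 3:4, name = c("C2", "C3"), element = "C",
                   resname = "LIG", resid = 1L, chain = "L"))
  tbl$resname[2] <- "LIG"; tbl$name[2] <- "C1"
  tbl <- tbl[c(1, 2, 3, 4), ]
  nf <- 20
  coords <- lapply(seq_len(nf), function(i) {
    matrix(stats::rnorm(12, sd = 2), 4, 3)
  })
  traj <- make_traj(tbl, coords, "LIG")
  m <- pairwise_ligand_rmsd(traj)
  lig_xyz <- lapply(coords, function(cc) cc[2:4, , drop = FALSE])
  brute <- matrix(0, nf, nf)
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    brute[i, j] <- sqrt(mean(rowSums((lig_xyz[[i]] - lig_xyz[[j]])^2)))
  }
  expect_equal(unname(m), brute, tolerance = 1e-9)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, nf), rownames(m)))
  for (k in 1:50) {
    ijk <- sample(nf, 3)
    expect_lte(m[ijk[1], ijk[3]],
               m[ijk[1], ijk[2]] + m[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("ring distance series tracks a planted separation change", {
  sch <- occupancy_schedule(p = c(h = 1), n_frames = 4, sigma = 0,
                            seed = 2)
  g <- generate_complex_trajectory(synthetic_ligand(), sch)
  traj <- tibble::as_tibble(g$trajectory)
  # push chain A PHE468 ring outward by +2 A x in the last two frames
  sel <- traj$chain == "A" & traj$resid == 468 &
    traj$name %in% c("CG", "CD1", "CE1", "CZ", "CE2", "CD2") &
    traj$frame >= 3
  traj$x[sel] <- traj$x[sel] + 2
  traj <- as_trajectory(traj, "LIG")
  series <- ring_distance_series(
    traj, tibble::tibble(chain1 = "A", resid1 = 464L,
                         chain2 = "A", resid2 = 468L))
  expect_equal(nrow(series), 4)
  expect_equal(series$distance[1], series$distance[2], tolerance = 1e-9)
  expect_gt(series$distance[3], series$distance[1] + 1)

  # centroid oracle: distance from independently recomputed centroids
  f3 <- get_frame(traj, 3)
  cen <- function(resid) {
    at <- f3[f3$chain == "A" & f3$resid == resid &
               f3$name %in% c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), ]
    c(mean(at$x), mean(at$y), mean(at$z))
  }
  expect_equal(series$distance[3],
               sqrt(sum((cen(464) - cen(468))^2)), tolerance = 1e-9)
})

test_that("ring distances reject self-pairs and ringless residues", {
  sch <- occupancy_schedule(p = c(h = 1), n_frames = 2, sigma = 0,
                            seed = 2)
  g <- generate_complex_trajectory(synthetic_ligand(), sch)
  expect_error(ring_distance_series(
    g$trajectory, tibble::tibble(chain1 = "A", resid1 = 464L,
                                 chain2 = "A", resid2 = 464L)),
    class = "dynopharm_no_ring")
  expect_error(ring_distance_series(
    g$trajectory, tibble::tibble(chain1 = "A", resid1 = 465L,
                                 chain2 = "A", resid2 = 468L)),
    class = "dynopharm_no_ring")
})
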