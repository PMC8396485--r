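# Independent oracles and fixture builders used across the suite. Each
# oracle is implemented with a different algorithm than the code it checks.

# Horn's quaternion method for optimal rigid superposition RMSD -- the
# independent check for the SVD-based Kabsch fit.
quaternion_superpose_rmsd <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  s <- t(xc) %*% yc
  k <- matrix(0, 4, 4)
  k[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  k[1, 2] <- k[2, 1] <- s[2, 3] - s[3, 2]
  k[1, 3] <- k[3, 1] <- s[3, 1] - s[1, 3]
  k[1, 4] <- k[4, 1] <- s[1, 2] - s[2, 1]
  k[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  k[2, 3] <- k[3, 2] <- s[1, 2] + s[2, 1]
  k[2, 4] <- k[4, 2] <- s[3, 1] + s[1, 3]
  k[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  k[3, 4] <- k[4, 3] <- s[2, 3] + s[3, 2]
  k[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(xc^2) + sum(yc^2) - 2 * lam) / nrow(x)
  sqrt(max(0, e2))
}

# union-find single-linkage clustering: merge any two points closer than
# tol, transitively
union_find_clusters <- function(xyz, tol) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# tie-corrected Mann-Whitney AUC
mann_whitney_auc <- function(scores, is_active) {
  pos <- scores[is_active]; neg <- scores[!is_active]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# simple explicit molecules --------------------------------------------------

make_benzene <- function(id = "benzene") {
  ang <- (0:5) * pi / 3
  molecule(
    id = id,
    atoms = tibble::tibble(element = rep("C", 6), charge = 0L),
    bonds = tibble::tibble(i = 1:6, j = c(2:6, 1),
                           order = rep(c(2L, 1L), 3), aromatic = TRUE),
    conformers = list(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)))
}

make_ethane <- function() {
  molecule(
    id = "ethane",
    atoms = tibble::tibble(element = c("C", "C"), charge = 0L),
    bonds = tibble::tibble(i = 1L, j = 2L, order = 1L, aromatic = FALSE),
    conformers = list(rbind(c(0, 0, 0), c(1.54, 0, 0))))
}

# quaternary ammonium head with a chlorophenyl arm (clofilium-like motif)
make_clofilium_like <- function() {
  ang <- (0:5) * pi / 3
  ring <- cbind(4.3 + 1.39 * cos(ang), 1.39 * sin(ang), 0)
  xyz <- rbind(
    c(0, 0, 0),                 # N+
    c(-1.0, 1.0, 0.6),          # methyls
    c(-1.0, -1.0, 0.6),
    c(0.4, 0.2, -1.45),
    c(1.45, 0, 0.35),           # CH2 linker
    ring,                       # phenyl (atom 6 nearest the linker)
    c(7.4, 0, 0))               # Cl on the para carbon
  molecule(
    id = "clofilium_like",
    atoms = tibble::tibble(
      element = c("N", "C", "C", "C", "C", rep("C", 6), "Cl"),
      charge = c(1L, rep(0L, 11))),
    bonds = tibble::tibble(
      i = c(1, 1, 1, 1, 5, 6, 7, 8, 9, 10, 11, 6),
      j = c(2, 3, 4, 5, 9, 7, 8, 9, 10, 11, 6, 12),
      order = c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L),
      aromatic = c(rep(FALSE, 5), rep(TRUE, 6), FALSE)),
    conformers = list(xyz))
}

# a one-residue protein frame (tibble in get_frame() shape)
make_residue_frame <- function(resname, names, elements, xyz,
                               chain = "A", resid = 1L,
                               ligand_resname = NULL) {
  out <- tibble::tibble(
    frame = 1L, serial = seq_along(names), name = names,
    element = elements, resname = resname, resid = resid, chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(out, "ligand_resname") <- ligand_resname
  out
}

make_tyr_frame <- function(center = c(0, 0, 0)) {
  ang <- (0:5) * pi / 3
  ring <- cbind(center[1] + 1.39 * cos(ang), center[2] + 1.39 * sin(ang),
                center[3])
  nm <- c("N", "CA", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "OH",
          "C", "O")
  el <- c("N", "C", "C", rep("C", 6), "O", "C", "O")
  xyz <- rbind(c(center[1] + 5.5, center[2], center[3] + 1.5),
               c(center[1] + 4.4, center[2], center[3] + 1.0),
               c(center[1] + 3.0, center[2], center[3] + 0.6),
               ring,
               c(center[1] - 2.75, center[2], center[3]),
               c(center[1] + 5.2, center[2] + 1.3, center[3] + 1.4),
               c(center[1] + 6.2, center[2] + 2.0, center[3] + 1.2))
  make_residue_frame("TYR", nm, el, xyz)
}

# minimal trajectory: given per-frame coordinate list for a fixed atom
# table (protein + one ligand atom set)
make_traj <- function(atom_tbl, coord_list, ligand_resname) {
  frames <- purrr::map_dfr(seq_along(coord_list), function(fi) {
    dplyr::mutate(atom_tbl, frame = fi,
                  x = coord_list[[fi]][, 1],
                  y = coord_list[[fi]][, 2],
                  z = coord_list[[fi]][, 3])
  })
  as_trajectory(frames, ligand_resname)
}

# atom table with n_res CA-only protein residues plus one ligand atom
ca_atom_tbl <- function(n_res = 4) {
  tibble::tibble(
    serial = seq_len(n_res + 1),
    name = c(rep("CA", n_res), "C1"),
    element = "C",
    resname = c(rep("ALA", n_res), "LIG"),
    resid = c(seq_len(n_res), 1L),
    chain = c(rep("A", n_res), "L"))
}

ca_base_coords <- function(n_res = 4) {
  rbind(cbind(seq_len(n_res) * 3.8, 0, 0), c(1, 1, 1))
}
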