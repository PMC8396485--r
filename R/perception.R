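# Pharmacophore feature perception. An open, documented rule set stands in
# for proprietary perception engines: aromatic rings, positive-ionizable
# nitrogens, H-bond donors/acceptors, contiguous apolar fragments and
# halogen-bond donors on the ligand side; typed interaction-capable groups
# per residue on the protein side.

POLAR_ELEMENTS <- c("N", "O", "S")
HALOGENS <- c("CL", "BR", "I")

# all simple rings of size <= max_size, as ordered atom index vectors.
# Edge-removal trick: drop each bond, shortest remaining path between its
# endpoints closes a minimal ring through that bond.
find_rings <- function(mol, max_size = 6) {
  if (nrow(mol$bonds) == 0) return(list())
  g <- mol_graph(mol)
  # bridge bonds cannot be part of any cycle
  br <- igraph::bridges(g)
  in_cycle <- !(seq_len(nrow(mol$bonds)) %in% as.integer(br))
  if (!any(in_cycle)) return(list())
  rings <- list(); seen <- character(0)
  for (k in which(in_cycle)) {
    i <- as.character(mol$bonds$i[k]); j <- as.character(mol$bonds$j[k])
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = i, to = j, output = "vpath")$vpath[[1]]
    )
    if (length(sp) == 0 || length(sp) > max_size) next
    ring <- as.integer(igraph::as_ids(sp))
    key <- paste(sort(ring), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1]] <- ring
  }
  rings
}

# per-bond aromatic flag. A ring is aromatic when its bonds say so (order 4
# or flagged), when it carries an alternating single/double (kekulized)
# pattern, or -- for geometry-only molecules (bonds inferred from a PDB
# frame, all orders unknown) -- when it is a 5/6-ring of C/N atoms planar
# within 0.1 A RMS in the first conformer.
perceive_bond_aromaticity <- function(mol, rings = NULL) {
  arom <- mol$bonds$aromatic
  if (nrow(mol$bonds) == 0) return(arom)
  if (is.null(rings)) rings <- find_rings(mol)
  bond_key <- paste(pmin(mol$bonds$i, mol$bonds$j),
                    pmax(mol$bonds$i, mol$bonds$j))
  for (ring in rings) {
    if (!length(ring) %in% c(5, 6)) next
    el <- toupper(mol$atoms$element[ring])
    if (!all(el %in% c("C", "N", "O", "S"))) next
    nxt <- c(ring[-1], ring[1])
    keys <- paste(pmin(ring, nxt), pmax(ring, nxt))
    kb <- match(keys, bond_key)
    if (anyNA(kb)) next
    orders <- mol$bonds$order[kb]
    is_arom <- all(mol$bonds$aromatic[kb] | orders == 4)
    kekulized <- length(ring) == 6 && sum(orders == 2) == 3 &&
      sum(orders == 1) == 3 && all(abs(diff(c(orders, orders[1]))) == 1)
    geometric <- FALSE
    if (!is_arom && !kekulized && mol$geometry_only &&
        length(mol$conformers) >= 1 && all(el %in% c("C", "N"))) {
      geometric <- ring_planarity_rms(mol$conformers[[1]][ring, ]) < 0.1
    }
    if (is_arom || kekulized || geometric) arom[kb] <- TRUE
  }
  arom
}

# per-atom chemical roles, geometry-free. Explicit hydrogens are used when
# present; otherwise heavy-atom-degree heuristics stand in (inputs are
# expected pre-protonated at physiological pH, so the heuristics are a
# fallback).
mol_roles <- function(mol) {
  el <- toupper(mol$atoms$element)
  n <- length(el)
  adj <- mol_adjacency(mol)
  deg_heavy <- vapply(seq_len(n), function(i) {
    sum(el[adj[[i]]] != "H")
  }, numeric(1))
  has_h <- vapply(seq_len(n), function(i) any(el[adj[[i]]] == "H"),
                  logical(1))
  any_explicit_h <- any(el == "H")
  bond_orders_at <- function(i) {
    sel <- mol$bonds$i == i | mol$bonds$j == i
    list(order = mol$bonds$order[sel], aromatic = mol$bonds$aromatic[sel])
  }
  charge <- mol$atoms$charge

  rings <- find_rings(mol)
  arom_bonds <- perceive_bond_aromaticity(mol, rings)
  bond_key <- paste(pmin(mol$bonds$i, mol$bonds$j),
                    pmax(mol$bonds$i, mol$bonds$j))
  aromatic_rings <- Filter(function(ring) {
    nxt <- c(ring[-1], ring[1])
    kb <- match(paste(pmin(ring, nxt), pmax(ring, nxt)), bond_key)
    !anyNA(kb) && all(arom_bonds[kb])
  }, rings)

  adjacent_carbonyl <- vapply(seq_len(n), function(i) {
    for (nb in adj[[i]]) {
      if (el[nb] != "C") next
      sel <- (mol$bonds$i == nb & el[mol$bonds$j] == "O" &
                mol$bonds$order == 2) |
             (mol$bonds$j == nb & el[mol$bonds$i] == "O" &
                mol$bonds$order == 2)
      if (any(sel)) return(TRUE)
    }
    FALSE
  }, logical(1))

  sp3_n <- vapply(seq_len(n), function(i) {
    if (el[i] != "N") return(FALSE)
    bo <- bond_orders_at(i)
    all(bo$order == 1) && !any(bo$aromatic)
  }, logical(1))

  # positive ionizable: formal +1 nitrogen, or neutral sp3 amine with a
  # (possibly implicit) hydrogen and no adjacent carbonyl
  pi_atoms <- which(
    (el == "N" & charge > 0) |
      (el == "N" & charge == 0 & sp3_n & !adjacent_carbonyl &
         (has_h | (!any_explicit_h & deg_heavy <= 2)))
  )

  donors <- which(
    (el %in% c("N", "O")) & charge >= 0 &
      (has_h |
         (!any_explicit_h &
            ((el == "O" & deg_heavy <= 1 & charge == 0) |
             (el == "N" & charge == 0 & deg_heavy <= 2 & sp3_n))))
  )
  # quaternary / fully substituted nitrogens cannot donate
  donors <- setdiff(donors, which(el == "N" & deg_heavy >= 4))

  acceptors <- which(
    (el == "O" & charge <= 0) |
      (el == "N" & charge <= 0 & deg_heavy <= 2 & !adjacent_carbonyl)
  )

  in_ring <- unique(unlist(rings))
  xbd <- which(el %in% HALOGENS &
                 vapply(seq_len(n), function(i) any(el[adj[[i]]] == "C"),
                        logical(1)))

  # contiguous apolar fragments: C/halogen atoms not bonded to any polar
  # atom, connected components with >= 2 heavy members
  apolar <- which((el == "C" | el %in% HALOGENS) &
                    !vapply(seq_len(n), function(i)
                      any(el[adj[[i]]] %in% POLAR_ELEMENTS), logical(1)))
  fragments <- list()
  if (length(apolar) > 0) {
    sub <- mol$bonds[mol$bonds$i %in% apolar & mol$bonds$j %in% apolar, ]
    gg <- igraph::graph_from_data_frame(
      sub[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = apolar))
    comp <- igraph::components(gg)
    for (cc in seq_len(comp$no)) {
      members <- as.integer(names(comp$membership)[comp$membership == cc])
      if (length(members) >= 2) fragments[[length(fragments) + 1]] <-
          sort(members)
    }
    fragments <- fragments[order(vapply(fragments, min, numeric(1)))]
  }

  list(aromatic_rings = aromatic_rings, pi_atoms = pi_atoms,
       donors = donors, acceptors = acceptors, xbd = xbd,
       fragments = fragments, adjacency = adj, elements = el,
       has_h = has_h, in_ring = in_ring)
}

empty_features <- function() {
  tibble(feature = character(), type = character(),
         x = double(), y = double(), z = double(), radius = double(),
         dx = double(), dy = double(), dz = double(),
         source_atoms = list(),
         partner_chain = character(), partner_resid = integer(),
         partner_resname = character())
}

#' Perceive pharmacophore features of a ligand conformer
#'
#' Applies the package's feature rules to one conformer: every aromatic ring
#' yields an AR feature at the ring centroid with the ring normal as
#' direction; +1 (or heuristically protonatable) nitrogens yield PI; N-H/O-H
#' groups yield HBD; N/O lone-pair acceptors yield HBA; contiguous apolar
#' carbon/halogen fragments of at least two heavy atoms yield one H feature
#' at the fragment centroid; C-Cl/Br/I yield XBD at the halogen with the C->X
#' direction. Fluorine is not treated as a halogen-bond donor.
#'
#' @param mol a `dynopharm_mol`.
#' @param conformer conformer index.
#' @param radii feature radii, see [feature_radii()].
#' @return a feature tibble (type, center, radius, optional unit direction,
#'   source atom indices).
#' @export
perceive_ligand_features <- function(mol, conformer = 1,
                                     radii = feature_radii()) {
  if (length(mol$conformers) < conformer || conformer < 1) {
    dyn_abort("no-geometry",
              sprintf("molecule %s has no conformer %s", mol$id, conformer))
  }
  xyz <- mol$conformers[[conformer]]
  roles <- mol_roles(mol)
  rows <- list()
  add <- function(type, center, source, dir = c(NA_real_, NA_real_, NA_real_)) {
    rows[[length(rows) + 1]] <<- tibble(
      feature = paste0(type, "_", length(rows) + 1),
      type = type, x = center[1], y = center[2], z = center[3],
      radius = unname(radii[type]),
      dx = dir[1], dy = dir[2], dz = dir[3],
      source_atoms = list(as.integer(source)),
      partner_chain = NA_character_, partner_resid = NA_integer_,
      partner_resname = NA_character_)
  }
  for (ring in roles$aromatic_rings) {
    add("AR", colMeans(xyz[ring, , drop = FALSE]), ring,
        ring_normal(xyz[ring, , drop = FALSE]))
  }
  for (i in roles$pi_atoms) add("PI", xyz[i, ], i)
  for (i in roles$donors) {
    h <- roles$adjacency[[i]][roles$elements[roles$adjacency[[i]]] == "H"]
    dir <- c(NA_real_, NA_real_, NA_real_)
    if (length(h) > 0) {
      v <- xyz[h[1], ] - xyz[i, ]
      dir <- v / sqrt(sum(v^2))
    }
    add("HBD", xyz[i, ], i, dir)
  }
  for (i in roles$acceptors) add("HBA", xyz[i, ], i)
  for (frag in roles$fragments) {
    add("H", colMeans(xyz[frag, , drop = FALSE]), frag)
  }
  for (i in roles$xbd) {
    cn <- roles$adjacency[[i]][roles$elements[roles$adjacency[[i]]] == "C"][1]
    v <- xyz[i, ] - xyz[cn, ]
    add("XBD", xyz[i, ], i, v / sqrt(sum(v^2)))
  }
  out <- if (length(rows) == 0) empty_features() else bind_rows(rows)
  out$feature <- paste0(out$type, "_", seq_len(nrow(out)))
  out
}

# residue chemistry lookup tables -------------------------------------------

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  TRP = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"),
  HIS = c("CG", "ND1", "CE1", "NE2", "CD2")
)

SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ", TRP = "NE1",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2")
)

SIDECHAIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2")
)

POS_CHARGE_ATOMS <- list(LYS = "NZ", ARG = "CZ")
NEG_CHARGE_ATOMS <- list(ASP = "CG", GLU = "CD")

HYDROPHOBIC_ATOMS <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "CE"), PRO = c("CB", "CG", "CD"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  GLU = c("CB", "CG"), GLN = c("CB", "CG"), ASP = "CB", ASN = "CB",
  THR = "CG2", CYS = "CB", HIS = "CB"
)

STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")

empty_groups <- function() {
  tibble(group = character(), kind = character(), chain = character(),
         resid = integer(), resname = character(),
         x = double(), y = double(), z = double(),
         nx = double(), ny = double(), nz = double(),
         atoms = list())
}

#' Perceive interaction-capable protein groups in a frame
#'
#' Maps standard residues to typed groups: Tyr/Phe/Trp/His side-chain rings
#' become aromatic groups (centroid + normal; rings must be planar within
#' 0.1 A RMS); Ser/Thr/Tyr hydroxyls are donor and acceptor; backbone C=O is
#' acceptor and backbone N-H donor (except proline); Lys/Arg are positive and
#' Asp/Glu negative charged groups; apolar side-chain carbons are individual
#' hydrophobic points. Nonstandard residues are skipped with a warning.
#'
#' @param frame one frame's atom tibble (from [get_frame()]), or a
#'   `dynopharm_traj` whose first frame is used.
#' @param near optional distance cutoff, A: only residues with at least one
#'   atom within `near` of any ligand atom are perceived (default 8 A when a
#'   ligand is identifiable, otherwise all residues).
#' @return a group tibble (kind, residue identity, center geometry, ring
#'   normals, member atom serials).
#' @export
perceive_protein_groups <- function(frame, near = 8) {
  if (inherits(frame, "dynopharm_traj")) {
    frame <- get_frame(frame, traj_frames(frame)[1])
  }
  lig_name <- attr(frame, "ligand_resname")
  prot <- frame
  if (!is.null(lig_name)) {
    lig <- frame[frame$resname == lig_name, ]
    prot <- frame[frame$resname != lig_name, ]
    if (!is.null(near) && nrow(lig) > 0) {
      lx <- cbind(lig$x, lig$y, lig$z)
      res_key <- paste(prot$chain, prot$resid)
      mind <- vapply(seq_len(nrow(prot)), function(i) {
        sqrt(min(colSums((t(lx) - c(prot$x[i], prot$y[i], prot$z[i]))^2)))
      }, numeric(1))
      keep_res <- unique(res_key[mind <= near])
      prot <- prot[res_key %in% keep_res, ]
    }
  }
  residues <- distinct(prot, .data$chain, .data$resid, .data$resname)
  nonstd <- residues$resname[!residues$resname %in% STANDARD_RESIDUES]
  if (length(nonstd) > 0) {
    dyn_warn(paste("skipping nonstandard residue(s):",
                   paste(unique(nonstd), collapse = ", ")))
    residues <- residues[residues$resname %in% STANDARD_RESIDUES, ]
  }
  rows <- list()
  for (r in seq_len(nrow(residues))) {
    ch <- residues$chain[r]; rid <- residues$resid[r]
    rn <- residues$resname[r]
    at <- prot[prot$chain == ch & prot$resid == rid, ]
    grab <- function(names) at[match(names, at$name), , drop = FALSE]
    add <- function(kind, center, serials,
                    normal = c(NA_real_, NA_real_, NA_real_)) {
      rows[[length(rows) + 1]] <<- tibble(
        group = paste(kind, ch, rid, length(rows) + 1, sep = "_"),
        kind = kind, chain = ch, resid = rid, resname = rn,
        x = center[1], y = center[2], z = center[3],
        nx = normal[1], ny = normal[2], nz = normal[3],
        atoms = list(as.integer(serials)))
    }
    ring_names <- RING_ATOMS[[rn]]
    if (!is.null(ring_names)) {
      ra <- grab(ring_names)
      if (!anyNA(ra$name)) {
        xyz <- cbind(ra$x, ra$y, ra$z)
        if (ring_planarity_rms(xyz) <= 0.1) {
          add("aromatic", colMeans(xyz), ra$serial, ring_normal(xyz))
        } else {
          dyn_warn(sprintf("non-planar ring skipped: %s %s%d", rn, ch, rid))
        }
      }
    }
    point_groups <- function(names, kind) {
      if (is.null(names)) return()
      pa <- grab(names)
      pa <- pa[!is.na(pa$name), , drop = FALSE]
      for (k in seq_len(nrow(pa))) {
        add(kind, c(pa$x[k], pa$y[k], pa$z[k]), pa$serial[k])
      }
    }
    point_groups(SIDECHAIN_DONORS[[rn]], "donor")
    point_groups(SIDECHAIN_ACCEPTORS[[rn]], "acceptor")
    point_groups("O", "acceptor")
    if (rn != "PRO") point_groups("N", "donor")
    point_groups(POS_CHARGE_ATOMS[[rn]], "pos_charge")
    point_groups(NEG_CHARGE_ATOMS[[rn]], "neg_charge")
    point_groups(HYDROPHOBIC_ATOMS[[rn]], "hydrophobic")
  }
  if (length(rows) == 0) return(empty_groups())
  bind_rows(rows)
}
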