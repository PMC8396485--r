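# Small-molecule container: explicit atoms (element, formal charge), bonds
# (order + aromatic flag) and zero or more 3D conformers. Hydrogens are
# optional; perception rules degrade to heavy-atom heuristics without them.

#' Construct a molecule
#'
#' @param id molecule identifier.
#' @param atoms tibble with columns `element` (character) and `charge`
#'   (integer formal charge).
#' @param bonds tibble with columns `i`, `j` (1-based atom indices), `order`
#'   (1, 2, 3 or 4 for aromatic) and optionally `aromatic` (logical; defaults
#'   to `order == 4`).
#' @param conformers list of n x 3 coordinate matrices, Angstroms.
#' @param geometry_only set to `TRUE` for molecules whose bonds were inferred
#'   from 3D distances (e.g. ligands lifted out of a PDB); enables geometric
#'   aromaticity perception.
#' @return an object of class `dynopharm_mol`.
#' @export
molecule <- function(id, atoms, bonds, conformers = list(),
                     geometry_only = FALSE) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  stopifnot(all(c("element", "charge") %in% names(atoms)))
  if (nrow(bonds) > 0) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    if (!"aromatic" %in% names(bonds)) bonds$aromatic <- bonds$order == 4
    if (any(bonds$i < 1 | bonds$i > nrow(atoms) |
            bonds$j < 1 | bonds$j > nrow(atoms))) {
      dyn_abort("bad-molecule", "bond indices out of range")
    }
  } else {
    bonds <- tibble(i = integer(), j = integer(), order = integer(),
                    aromatic = logical())
  }
  if (any(atoms$element == "" | is.na(atoms$element))) {
    dyn_abort("bad-molecule", "empty element symbol")
  }
  for (cf in conformers) {
    stopifnot(is.matrix(cf), ncol(cf) == 3, nrow(cf) == nrow(atoms))
    if (!all(is.finite(cf))) dyn_abort("bad-molecule", "non-finite conformer")
  }
  structure(
    list(id = id, atoms = atoms, bonds = bonds,
         conformers = unname(conformers), geometry_only = geometry_only),
    class = "dynopharm_mol"
  )
}

#' @export
print.dynopharm_mol <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms, %d bonds, %d conformer(s)>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    mol$bonds[, c("i", "j")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms)))
  )
}

# adjacency as a list of integer neighbour vectors
mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' 1D physicochemical property profile of a molecule
#'
#' The property vector used for decoy matching: heavy atom count, ring count
#' (smallest-set sense), hydrogen-bond donor and acceptor counts and net
#' formal charge.
#'
#' @param mol a `dynopharm_mol`.
#' @return one-row tibble with columns `id`, `heavy_atoms`, `rings`, `hbd`,
#'   `hba`, `charge`.
#' @export
molecule_properties <- function(mol) {
  heavy <- sum(mol$atoms$element != "H")
  g <- mol_graph(mol)
  n_rings <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::count_components(g)
  roles <- mol_roles(mol)
  hbd <- length(roles$donors)
  hba <- length(roles$acceptors)
  tibble(id = mol$id, heavy_atoms = heavy, rings = as.integer(n_rings),
         hbd = hbd, hba = hba, charge = sum(mol$atoms$charge))
}

covalent_radii <- c(H = 0.37, C = 0.77, N = 0.75, O = 0.73, S = 1.04,
                    P = 1.10, F = 0.71, CL = 0.99, BR = 1.14, I = 1.33)

#' Infer ligand bonds from 3D distances
#'
#' Builds a molecule for the ligand of a trajectory frame by bonding atom
#' pairs closer than 1.25 x the sum of their covalent radii. Nitrogens with
#' four heavy-atom bonds are assigned a +1 formal charge (quaternary
#' ammonium). Intended for PDB-derived ligands that carry no connectivity.
#'
#' @param traj a `dynopharm_traj`.
#' @param frame frame index to take coordinates from (default: first frame).
#' @return a `dynopharm_mol` flagged `geometry_only`, with one conformer and
#'   atom order matching the ligand atom order of the trajectory.
#' @export
ligand_topology <- function(traj, frame = NULL) {
  fr <- traj_frames(traj)
  f <- get_frame(traj, if (is.null(frame)) fr[1] else frame)
  lig <- f[f$resname == ligand_resname(traj), ]
  if (nrow(lig) == 0) dyn_abort("ligand-not-found", "no ligand atoms")
  el <- toupper(lig$element)
  rad <- covalent_radii[el]
  rad[is.na(rad)] <- 0.77
  xyz <- cbind(lig$x, lig$y, lig$z)
  d <- as.matrix(dist(xyz))
  cut <- 1.25 * outer(rad, rad, "+")
  hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  bonds <- tibble(i = hit[, 1], j = hit[, 2], order = 1L, aromatic = FALSE)
  deg <- tabulate(c(bonds$i, bonds$j), nbins = nrow(lig))
  charge <- ifelse(el == "N" & deg >= 4, 1L, 0L)
  molecule(
    id = ligand_resname(traj),
    atoms = tibble(element = lig$element, charge = charge),
    bonds = bonds,
    conformers = list(xyz),
    geometry_only = TRUE
  )
}

charge_from_sdf_code <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
           `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

#' Read a small-molecule library (SMILES or SDF)
#'
#' SMILES files (`.smi`, one record per line, optional whitespace-separated
#' id) are parsed through OpenBabel; SDF V2000 files are read directly.
#' Multiple SDF records sharing a title are treated as conformers of one
#' molecule. Unparsable records are skipped (not fatal); the skip count is
#' reported as an attribute and a warning, mirroring routine library curation.
#'
#' @param path path to a `.smi`/`.smiles` or `.sdf` file.
#' @return tibble with columns `id`, `n_atoms`, `n_conformers` and a
#'   list-column `molecule` of `dynopharm_mol` objects; attribute `skipped`
#'   holds the number of rejected records.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) dyn_abort("bad-model-file", paste("no file:", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "smiles", "txt")) {
    res <- read_library_smiles(path)
  } else {
    res <- read_library_sdf(path)
  }
  mols <- res$mols
  if (res$skipped > 0) {
    dyn_warn(sprintf("skipped %d unparsable record(s)", res$skipped))
  }
  out <- tibble(
    id = vapply(mols, function(m) m$id, character(1)),
    n_atoms = vapply(mols, function(m) nrow(m$atoms), integer(1)),
    n_conformers = vapply(mols, function(m) length(m$conformers), integer(1)),
    molecule = mols
  )
  attr(out, "skipped") <- res$skipped
  out
}

read_library_smiles <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    dyn_abort("missing-dependency",
              "SMILES input requires ChemmineR + ChemmineOB")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  mols <- list(); skipped <- 0L
  for (k in seq_along(lines)) {
    parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) > 1) parts[2] else paste0("mol_", k)
    if (!smiles_plausible(smi)) { skipped <- skipped + 1L; next }
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                    error = function(e) NULL)
    if (!is.null(sdf)) ChemmineR::cid(sdf) <- id
    ok <- !is.null(sdf) && length(sdf) == 1 &&
      isTRUE(all(tryCatch(ChemmineR::validSDF(sdf),
                          error = function(e) FALSE)))
    if (!ok) { skipped <- skipped + 1L; next }
    m <- sdf_to_molecule(sdf[[1]], id = id, keep_conformer = FALSE)
    if (is.null(m)) { skipped <- skipped + 1L; next }
    mols[[length(mols) + 1]] <- m
  }
  list(mols = mols, skipped = skipped)
}

# cheap well-formedness screen applied before handing a record to the
# parser: balanced brackets and no dangling bond symbol. OpenBabel silently
# "repairs" some malformed records, so curation rejects them up front.
smiles_plausible <- function(smi) {
  chars <- strsplit(smi, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
  if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
  if (length(chars) == 0) return(FALSE)
  !tail(chars, 1) %in% c("(", "-", "=", "#", "/", "\\", ".", "[")
}

read_library_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    dyn_abort("missing-dependency", "SDF input requires ChemmineR")
  }
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- tryCatch(ChemmineR::validSDF(sdfs), error = function(e)
    rep(FALSE, length(sdfs)))
  skipped <- sum(!valid)
  sdfs <- sdfs[valid]
  recs <- list()
  for (k in seq_along(sdfs)) {
    sdf <- sdfs[[k]]
    id <- trimws(ChemmineR::header(sdf)[["Molecule_Name"]])
    if (is.na(id) || !nzchar(id)) id <- paste0("mol_", k)
    m <- sdf_to_molecule(sdf, id = id, keep_conformer = TRUE)
    if (is.null(m)) { skipped <- skipped + 1L; next }
    recs[[length(recs) + 1]] <- m
  }
  # group records with the same title into one molecule with many conformers
  ids <- vapply(recs, function(m) m$id, character(1))
  mols <- list()
  for (id in unique(ids)) {
    grp <- recs[ids == id]
    base <- grp[[1]]
    base$conformers <- unlist(lapply(grp, function(m) m$conformers),
                              recursive = FALSE)
    mols[[length(mols) + 1]] <- base
  }
  list(mols = mols, skipped = skipped)
}

sdf_to_molecule <- function(sdf, id, keep_conformer = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  el <- gsub("_.*$", "", rownames(ab))
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  atoms <- tibble(element = el, charge = charge_from_sdf_code(charge_code))
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- tibble(i = integer(), j = integer(), order = integer(),
                    aromatic = logical())
  } else {
    bonds <- tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]))
    bonds$aromatic <- bonds$order == 4L
  }
  confs <- list()
  if (keep_conformer) {
    # 2D coordinate sets are kept as-is; screening requires genuine 3D
    # conformers, which SDF inputs are expected to provide
    xyz <- cbind(ab[, "C1"], ab[, "C2"], ab[, "C3"])
    confs <- list(unname(xyz))
  }
  m <- molecule(id = id, atoms = atoms, bonds = bonds, conformers = confs)
  m$bonds$aromatic <- perceive_bond_aromaticity(m)
  m
}

#' Write molecules to an SDF V2000 file
#'
#' Each conformer of each molecule becomes one SDF record titled with the
#' molecule id (so reading the file back regroups conformers by title).
#' Molecules without conformers are written once with zeroed coordinates.
#'
#' @param library tibble as returned by [read_library()], or a list of
#'   `dynopharm_mol` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(library, path) {
  mols <- if (is_tibble(library)) library$molecule else library
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    confs <- if (length(m$conformers) > 0) m$conformers else
      list(matrix(0, nrow(m$atoms), 3))
    for (cf in confs) {
      writeLines(sdf_record_text(m, cf), con)
    }
  }
  invisible(path)
}

sdf_record_text <- function(m, xyz) {
  na <- nrow(m$atoms); nb <- nrow(m$bonds)
  head <- c(m$id, "  dynopharm", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  code <- integer(na)
  code[m$atoms$charge == 1] <- 3L
  code[m$atoms$charge == 2] <- 2L
  code[m$atoms$charge == 3] <- 1L
  code[m$atoms$charge == -1] <- 5L
  code[m$atoms$charge == -2] <- 6L
  code[m$atoms$charge == -3] <- 7L
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                   xyz[, 1], xyz[, 2], xyz[, 3], m$atoms$element, code)
  bonds <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", m$bonds$i, m$bonds$j,
            ifelse(m$bonds$aromatic, 4L, m$bonds$order))
  } else character(0)
  chg <- which(m$atoms$charge != 0)
  chg_lines <- if (length(chg) > 0) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, m$atoms$charge[chg]),
                   collapse = ""))
  } else character(0)
  c(head, atoms, bonds, chg_lines, "M  END", "$$$$")
}
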