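# Trajectory container: a tidy tibble of atom records, one row per atom per
# frame, with the ligand identified by residue name. Atom order is identical
# in every frame (enforced on construction), so per-frame geometry can be
# manipulated with plain matrix reshapes.

#' Construct a trajectory from an atom table
#'
#' @param atoms tibble with columns `frame`, `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z` (coordinates in Angstroms);
#'   an optional `time_ps` column is kept if present.
#' @param ligand_resname residue name identifying the ligand.
#' @return a `dynopharm_traj` tibble (atom rows ordered by frame then serial)
#'   with the ligand residue name stored as an attribute.
#' @export
as_trajectory <- function(atoms, ligand_resname) {
  atoms <- as_tibble(atoms)
  need <- c("frame", "serial", "name", "element", "resname", "resid",
            "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    dyn_abort("bad-trajectory", paste("missing columns:",
                                      paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z))) {
    dyn_abort("bad-trajectory", "non-finite coordinates")
  }
  atoms <- arrange(atoms, .data$frame, .data$serial)
  ids <- split(paste(atoms$chain, atoms$resid, atoms$name), atoms$frame)
  if (length(unique(vapply(ids, length, integer(1)))) != 1) {
    dyn_abort("frame-mismatch", "atom count differs across frames")
  }
  ref <- ids[[1]]
  same <- vapply(ids, function(v) identical(v, ref), logical(1))
  if (!all(same)) {
    dyn_abort("frame-mismatch", "atom identity/order differs across frames")
  }
  if (!any(atoms$resname == ligand_resname)) {
    dyn_abort("ligand-not-found",
              paste0("no atoms with residue name '", ligand_resname, "'"))
  }
  if (all(atoms$resname == ligand_resname)) {
    dyn_abort("bad-trajectory", "trajectory contains no protein atoms")
  }
  structure(atoms,
            ligand_resname = ligand_resname,
            class = c("dynopharm_traj", class(tibble())))
}

#' @export
print.dynopharm_traj <- function(x, ...) {
  cat(sprintf("<dynopharm trajectory: %d frames, %d atoms/frame, ligand %s>\n",
              n_frames(x), nrow(x) / max(1, n_frames(x)),
              ligand_resname(x)))
  NextMethod()
}

#' Number of frames in a trajectory
#' @param traj a `dynopharm_traj`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(unique(traj$frame))

#' Ligand residue name of a trajectory
#' @param traj a `dynopharm_traj`.
#' @return character scalar.
#' @export
ligand_resname <- function(traj) attr(traj, "ligand_resname")

traj_frames <- function(traj) sort(unique(traj$frame))

#' Extract one frame of a trajectory
#' @param traj a `dynopharm_traj`.
#' @param index frame index as stored in the `frame` column.
#' @return tibble of that frame's atom rows.
#' @export
get_frame <- function(traj, index) {
  out <- filter(as_tibble(traj), .data$frame == index)
  if (nrow(out) == 0) dyn_abort("bad-frame", paste("no frame", index))
  attr(out, "ligand_resname") <- ligand_resname(traj)
  out
}

is_ligand_row <- function(traj) traj$resname == ligand_resname(traj)

# frame x atom coordinate matrices (atoms in serial order), used by the
# vectorized engines
traj_coord_mats <- function(traj, rows = rep(TRUE, nrow(traj))) {
  sub <- traj[rows, ]
  fr <- sort(unique(sub$frame))
  natom <- nrow(sub) / length(fr)
  ord <- order(sub$frame, sub$serial)
  sub <- sub[ord, ]
  list(
    frames = fr,
    serial = sub$serial[seq_len(natom)],
    x = matrix(sub$x, nrow = natom),
    y = matrix(sub$y, nrow = natom),
    z = matrix(sub$z, nrow = natom)
  )
}

#' Read a multi-model PDB file as a trajectory
#'
#' Models (MODEL/ENDMDL records) become frames in file order. The ligand is
#' selected by residue name; everything else is treated as protein.
#'
#' @param path path to a multi-model PDB file.
#' @param ligand_resname residue name of the ligand (must be present in every
#'   model).
#' @return a `dynopharm_traj`.
#' @export
read_trajectory <- function(path, ligand_resname) {
  if (!file.exists(path)) dyn_abort("bad-model-file", paste("no file:", path))
  check_models_text(path, ligand_resname)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  at <- pdb$atom
  natom <- nrow(at)
  xyz <- pdb$xyz
  frames <- rep(seq_len(nf), each = natom)
  idx <- matrix(seq_len(3 * natom), nrow = 3)
  atoms <- tibble(
    frame = frames,
    serial = rep(seq_len(natom), times = nf),
    name = rep(at$elety, times = nf),
    element = rep(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(trimws(at$elety), 1, 1), trimws(at$elesy)),
                  times = nf),
    resname = rep(trimws(at$resid), times = nf),
    resid = rep(at$resno, times = nf),
    chain = rep(ifelse(is.na(at$chain), " ", at$chain), times = nf),
    x = as.vector(t(xyz[, idx[1, ], drop = FALSE])),
    y = as.vector(t(xyz[, idx[2, ], drop = FALSE])),
    z = as.vector(t(xyz[, idx[3, ], drop = FALSE]))
  )
  as_trajectory(atoms, ligand_resname)
}

# cheap text pre-scan: per-MODEL ligand presence and atom-count consistency,
# reported with precise errors before handing the file to the PDB parser
check_models_text <- function(path, ligand_resname) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0) {
    model_id <- rep(1L, length(lines))
  } else {
    model_id <- findInterval(seq_along(lines), model_starts)
  }
  sel <- is_atom & model_id > 0
  resnames <- trimws(substr(lines[sel], 18, 20))
  mid <- model_id[sel]
  if (length(mid) == 0) dyn_abort("bad-model-file", "no ATOM records")
  has_lig <- tapply(resnames == ligand_resname, mid, any)
  if (!all(has_lig)) {
    dyn_abort("ligand-not-found",
              sprintf("residue '%s' absent from model(s) %s", ligand_resname,
                      paste(names(has_lig)[!has_lig], collapse = ", ")))
  }
  counts <- tapply(mid, mid, length)
  if (length(unique(counts)) != 1) {
    dyn_abort("frame-mismatch", "atom count differs across models")
  }
  invisible(TRUE)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `dynopharm_traj`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  fr <- traj_frames(traj)
  f1 <- get_frame(traj, fr[1])
  natom <- nrow(f1)
  xyz <- matrix(0, nrow = length(fr), ncol = 3 * natom)
  for (i in seq_along(fr)) {
    fi <- get_frame(traj, fr[i])
    xyz[i, ] <- as.vector(rbind(fi$x, fi$y, fi$z))
  }
  bio3d::write.pdb(
    file = path,
    xyz = bio3d::as.xyz(xyz),
    resno = f1$resid,
    resid = f1$resname,
    eleno = f1$serial,
    elety = f1$name,
    chain = f1$chain,
    elesy = f1$element
  )
  invisible(path)
}

#' Evenly downsample trajectory frames
#'
#' Keeps `n` frames at positions `floor(i * (F - 1) / (n - 1))` for
#' `i = 0..n-1` over the `F` stored frames, so the first and last frames are
#' always retained; used e.g. to reduce a production run to 500 evenly
#' distributed frames before pharmacophore analysis.
#'
#' @param traj a `dynopharm_traj`.
#' @param n number of frames to keep (`1 <= n <= n_frames(traj)`).
#' @return a `dynopharm_traj` with `n` frames in the original order.
#' @export
downsample <- function(traj, n) {
  fr <- traj_frames(traj)
  keep <- fr[downsample_indices(length(fr), n) + 1]
  out <- filter(as_tibble(traj), .data$frame %in% keep)
  as_trajectory(out, ligand_resname(traj))
}

# zero-based evenly spaced index set, endpoints always included
downsample_indices <- function(n_total, n) {
  if (n < 1 || n > n_total) {
    dyn_abort("too-few-frames",
              sprintf("requested %d of %d frames", n, n_total))
  }
  if (n == 1) return(0L)
  unique(as.integer(floor((seq_len(n) - 1) * (n_total - 1) / (n - 1))))
}
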