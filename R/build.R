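# Merging per-frame/per-ligand pharmacophore models, aligning merged models
# across ligands (with an explicit failure mode for divergent binding
# modes), flagging essential/optional features and generating exclusion
# volumes from the protein environment.

#' Merge overlapping pharmacophore models
#'
#' Pools the features of all input models and interpolates overlapping
#' same-type features: single-linkage clusters with center distance `tol`
#' or less are replaced by one feature at the cluster centroid, with radius
#' `max(member radii, cluster spread)`. Features of different types never
#' merge. Exclusion volumes are pooled unchanged. The result is independent
#' of input order.
#'
#' @param models list of `dynopharm_model` objects in a common coordinate
#'   frame.
#' @param tol merge tolerance, A (default 1.5).
#' @return a merged `dynopharm_model`.
#' @export
merge_models <- function(models, tol = 1.5) {
  if (inherits(models, "dynopharm_model")) models <- list(models)
  if (length(models) == 0) dyn_abort("no-models", "no models to merge")
  stopifnot(tol > 0)
  feats <- bind_rows(lapply(models, function(m) m$features))
  ev <- distinct(bind_rows(lapply(models, function(m) m$exclusion_volumes)))
  if (nrow(feats) == 0) return(pharmacophore(NULL, ev))
  merged <- feats %>%
    group_by(.data$type) %>%
    dplyr::group_modify(function(df, key) merge_feature_cluster(df, tol)) %>%
    ungroup() %>%
    arrange(.data$type, .data$x, .data$y, .data$z)
  pharmacophore(merged, ev)
}

merge_feature_cluster <- function(df, tol) {
  if (nrow(df) == 1) {
    cl <- 1L
  } else {
    xyz <- cbind(df$x, df$y, df$z)
    cl <- cutree(hclust(dist(xyz), method = "single"), h = tol)
  }
  purrr::map_dfr(unique(cl), function(cc) {
    sub <- df[cl == cc, , drop = FALSE]
    ctr <- colMeans(cbind(sub$x, sub$y, sub$z))
    spread <- max(sqrt((sub$x - ctr[1])^2 + (sub$y - ctr[2])^2 +
                       (sub$z - ctr[3])^2))
    dirm <- c(mean(sub$dx), mean(sub$dy), mean(sub$dz))
    nl <- sqrt(sum(dirm^2))
    if (anyNA(dirm) || nl < 1e-6) dirm <- rep(NA_real_, 3)
    else dirm <- dirm / nl
    partner_ok <- nrow(distinct(sub, .data$partner_chain,
                                .data$partner_resid)) == 1
    tibble(
      x = ctr[1], y = ctr[2], z = ctr[3],
      radius = max(max(sub$radius), spread),
      dx = dirm[1], dy = dirm[2], dz = dirm[3],
      partner_chain = if (partner_ok) sub$partner_chain[1]
                      else NA_character_,
      partner_resid = if (partner_ok) sub$partner_resid[1]
                      else NA_integer_,
      partner_resname = if (partner_ok) sub$partner_resname[1]
                        else NA_character_)
  })
}

#' Align one pharmacophore model onto another
#'
#' Searches type-compatible feature correspondences: candidate triplets of
#' feature pairs (required to include the positive-ionizable pair when both
#' models have a PI feature) seed a Kabsch superposition, which is extended
#' greedily with mutually nearest same-type pairs within `tol`. The best
#' correspondence by (pair count, then lowest paired-feature RMSD) is
#' returned. Alignment succeeds when at least `min_pairs` features pair
#' within an overall RMSD of `tol`; failure is a result (the divergent
#' binding-mode case), not an error.
#'
#' @param reference,other `dynopharm_model` objects.
#' @param min_pairs minimum number of paired features for success
#'   (default 3).
#' @param tol pairing tolerance and maximum paired-feature RMSD, A.
#' @return an object of class `dynopharm_alignment`: list with `success`,
#'   `rotation`, `translation`, `pairs` (tibble of paired feature indices
#'   and distances), `rmsd`, `n_pairs`.
#' @export
align_models <- function(reference, other, min_pairs = 3, tol = 1.5) {
  stopifnot(min_pairs >= 3)
  rf <- reference$features; of <- other$features
  fail <- structure(list(success = FALSE, rotation = diag(3),
                         translation = c(0, 0, 0),
                         pairs = tibble(ref = integer(), other = integer(),
                                        distance = double()),
                         rmsd = NA_real_, n_pairs = 0L),
                    class = "dynopharm_alignment")
  if (nrow(rf) < min_pairs || nrow(of) < min_pairs) return(fail)
  cand <- candidate_pairs(rf, of)
  pi_required <- any(rf$type == "PI") && any(of$type == "PI")
  best <- NULL
  combos <- utils::combn(seq_len(nrow(cand)), 3, simplify = FALSE)
  for (trip in combos) {
    sub <- cand[trip, ]
    if (length(unique(sub$ref)) < 3 || length(unique(sub$other)) < 3) next
    if (pi_required && !any(rf$type[sub$ref] == "PI")) next
    # internal-distance compatibility pruning
    dr <- dist(cbind(rf$x[sub$ref], rf$y[sub$ref], rf$z[sub$ref]))
    do <- dist(cbind(of$x[sub$other], of$y[sub$other], of$z[sub$other]))
    if (any(abs(dr - do) > 2 * tol)) next
    fit <- kabsch(cbind(of$x[sub$other], of$y[sub$other], of$z[sub$other]),
                  cbind(rf$x[sub$ref], rf$y[sub$ref], rf$z[sub$ref]))
    moved <- apply_rigid(cbind(of$x, of$y, of$z), fit$rotation,
                         fit$translation)
    pairs <- greedy_mutual_pairs(rf, moved, of$type, tol)
    if (nrow(pairs) < 3) next
    # refit on all pairs for the final transform and RMSD
    fit2 <- kabsch(cbind(of$x[pairs$other], of$y[pairs$other],
                         of$z[pairs$other]),
                   cbind(rf$x[pairs$ref], rf$y[pairs$ref],
                         rf$z[pairs$ref]))
    moved2 <- apply_rigid(cbind(of$x, of$y, of$z), fit2$rotation,
                          fit2$translation)
    pairs2 <- greedy_mutual_pairs(rf, moved2, of$type, tol)
    if (nrow(pairs2) == 0) next
    rmsd <- sqrt(mean(pairs2$distance^2))
    score <- list(n = nrow(pairs2), rmsd = rmsd, fit = fit2, pairs = pairs2)
    if (is.null(best) || score$n > best$n ||
        (score$n == best$n && score$rmsd < best$rmsd - 1e-12)) {
      best <- score
    }
  }
  if (is.null(best)) return(fail)
  structure(list(
    success = best$n >= min_pairs && best$rmsd <= tol,
    rotation = best$fit$rotation, translation = best$fit$translation,
    pairs = best$pairs, rmsd = best$rmsd, n_pairs = best$n),
    class = "dynopharm_alignment")
}

#' @export
print.dynopharm_alignment <- function(x, ...) {
  cat(sprintf("<model alignment: %s, %d pairs, RMSD %.3f A>\n",
              if (x$success) "success" else "FAILED", x$n_pairs,
              if (is.na(x$rmsd)) NaN else x$rmsd))
  invisible(x)
}

candidate_pairs <- function(rf, of) {
  out <- list()
  for (i in seq_len(nrow(rf))) {
    js <- which(of$type == rf$type[i])
    if (length(js) > 0) {
      out[[length(out) + 1]] <- tibble(ref = i, other = js)
    }
  }
  if (length(out) == 0) return(tibble(ref = integer(), other = integer()))
  bind_rows(out)
}

# deterministic mutual-nearest same-type pairing; tol may be a scalar or a
# per-reference-feature vector (e.g. feature radii)
greedy_mutual_pairs <- function(rf, moved_other, other_types, tol) {
  tol_vec <- if (length(tol) == 1) rep(tol, nrow(rf)) else tol
  cand <- list()
  for (i in seq_len(nrow(rf))) {
    js <- which(other_types == rf$type[i])
    if (length(js) == 0) next
    d <- sqrt((moved_other[js, 1] - rf$x[i])^2 +
              (moved_other[js, 2] - rf$y[i])^2 +
              (moved_other[js, 3] - rf$z[i])^2)
    ok <- d <= tol_vec[i]
    if (any(ok)) {
      cand[[length(cand) + 1]] <- tibble(ref = i, other = js[ok],
                                         distance = d[ok])
    }
  }
  if (length(cand) == 0) {
    return(tibble(ref = integer(), other = integer(), distance = double()))
  }
  cand <- arrange(bind_rows(cand), .data$distance, .data$ref, .data$other)
  used_r <- integer(0); used_o <- integer(0); keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$ref[k] %in% used_r || cand$other[k] %in% used_o) next
    keep[k] <- TRUE
    used_r <- c(used_r, cand$ref[k]); used_o <- c(used_o, cand$other[k])
  }
  cand[keep, ]
}

#' Default essential/optional flag specification
#'
#' The validated flag layout of the final merged model: the positive
#' ionizable feature and the hydrophobic feature nearest to it are
#' essential; the next two hydrophobic features (by distance to the PI
#' feature) form an either-group in which at least one must be matched; all
#' remaining features are optional.
#'
#' @return a flag specification list understood by [apply_flags()].
#' @export
default_flags_spec <- function() {
  list(essential_pi = TRUE, n_essential_h = 1L, either_h_pair = TRUE)
}

#' Apply essential/optional flags to a model
#'
#' @param model a `dynopharm_model`.
#' @param flags_spec either the declarative list of [default_flags_spec()],
#'   or a list with explicit integer vectors `essential` and (optionally)
#'   list of integer vectors `either_groups`.
#' @return the flagged model.
#' @export
apply_flags <- function(model, flags_spec = default_flags_spec()) {
  ft <- model$features
  ft$flag <- "optional"
  ft$either_group <- NA_integer_
  if (!is.null(flags_spec[["essential"]])) {
    ft$flag[flags_spec[["essential"]]] <- "essential"
    for (g in seq_along(flags_spec[["either_groups"]] %||% list())) {
      ft$either_group[flags_spec[["either_groups"]][[g]]] <- g
    }
  } else {
    pi_idx <- which(ft$type == "PI")
    if (isTRUE(flags_spec$essential_pi) && length(pi_idx) > 0) {
      ft$flag[pi_idx[1]] <- "essential"
    }
    h_idx <- which(ft$type == "H")
    if (length(pi_idx) > 0 && length(h_idx) > 0) {
      d <- sqrt((ft$x[h_idx] - ft$x[pi_idx[1]])^2 +
                (ft$y[h_idx] - ft$y[pi_idx[1]])^2 +
                (ft$z[h_idx] - ft$z[pi_idx[1]])^2)
      h_idx <- h_idx[order(d)]
    }
    ne <- min(flags_spec[["n_essential_h"]] %||% 1L, length(h_idx))
    if (ne > 0) ft$flag[h_idx[seq_len(ne)]] <- "essential"
    rest <- h_idx[-seq_len(ne)]
    if (isTRUE(flags_spec$either_h_pair) && length(rest) >= 2) {
      ft$either_group[rest[1:2]] <- 1L
    }
  }
  model$features <- ft
  model
}

#' Build the final merged pharmacophore model
#'
#' Aligns each merged per-ligand model onto the first, excluding models that
#' cannot be aligned (reported with their pair count and RMSD), merges the
#' alignable models, converts all vector features to sphere features and
#' applies the essential/optional flag specification.
#'
#' @param merged_models named list of per-ligand `dynopharm_model` objects.
#' @param flags_spec see [apply_flags()].
#' @param min_pairs,align_tol alignment acceptance criteria, see
#'   [align_models()].
#' @param merge_tol feature interpolation tolerance, A.
#' @return the final `dynopharm_model`, with attribute `excluded`: a tibble
#'   of excluded model ids and alignment diagnostics.
#' @export
build_final_model <- function(merged_models,
                              flags_spec = default_flags_spec(),
                              min_pairs = 3, align_tol = 1.5,
                              merge_tol = 1.5) {
  n <- length(merged_models)
  if (n < 2) dyn_abort("insufficient-models", "need at least 2 models")
  ids <- names(merged_models) %||% paste0("model_", seq_len(n))
  if (is.null(names(merged_models))) names(merged_models) <- ids
  ref <- merged_models[[1]]
  aligned <- list(ref)
  excluded <- tibble(id = character(), n_pairs = integer(),
                     rmsd = double())
  for (k in 2:n) {
    al <- align_models(ref, merged_models[[k]], min_pairs = min_pairs,
                       tol = align_tol)
    if (!al$success) {
      excluded <- bind_rows(excluded, tibble(
        id = ids[k], n_pairs = al$n_pairs, rmsd = al$rmsd))
      next
    }
    m <- merged_models[[k]]
    moved <- apply_rigid(cbind(m$features$x, m$features$y, m$features$z),
                         al$rotation, al$translation)
    m$features$x <- moved[, 1]; m$features$y <- moved[, 2]
    m$features$z <- moved[, 3]
    if (nrow(m$exclusion_volumes) > 0) {
      ev <- apply_rigid(cbind(m$exclusion_volumes$x, m$exclusion_volumes$y,
                              m$exclusion_volumes$z),
                        al$rotation, al$translation)
      m$exclusion_volumes$x <- ev[, 1]; m$exclusion_volumes$y <- ev[, 2]
      m$exclusion_volumes$z <- ev[, 3]
    }
    aligned[[length(aligned) + 1]] <- m
  }
  if (length(aligned) < 2) {
    dyn_abort("insufficient-models",
              paste("fewer than 2 alignable models; excluded:",
                    paste(excluded$id, collapse = ", ")))
  }
  final <- merge_models(aligned, tol = merge_tol)
  final$exclusion_volumes <- merge_exclusions(final$exclusion_volumes)
  final <- devectorize(final)
  final <- apply_flags(final, flags_spec)
  attr(final, "excluded") <- excluded
  final
}

#' Generate exclusion volumes from the protein environment
#'
#' Places one exclusion sphere on every protein heavy atom whose mean
#' position over the analysis window lies within `ligand_margin` of any
#' ligand atom's mean position, skipping atoms closer than
#' `feature_clearance` to any model feature center so that spheres never
#' forbid the model's own feature positions.
#'
#' @param traj a `dynopharm_traj`.
#' @param window frame window (see [trajectory_interactions()]).
#' @param model optional `dynopharm_model` providing feature centers for the
#'   clearance rule.
#' @param ligand_margin margin around the ligand, A (default 8).
#' @param radius exclusion sphere radius, A (default 1.2).
#' @param feature_clearance minimum sphere-to-feature-center distance, A.
#' @return tibble with columns `x`, `y`, `z`, `radius`.
#' @export
generate_exclusion_volumes <- function(traj, window = NULL, model = NULL,
                                       ligand_margin = 8, radius = 1.2,
                                       feature_clearance = 2.0) {
  window <- check_window(traj, window)
  sub <- as_tibble(traj)[traj$frame %in% window, ]
  mean_pos <- sub %>%
    group_by(.data$serial, .data$name, .data$element, .data$resname) %>%
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop")
  lig <- mean_pos[mean_pos$resname == ligand_resname(traj), ]
  prot <- mean_pos[mean_pos$resname != ligand_resname(traj) &
                     toupper(mean_pos$element) != "H", ]
  if (nrow(lig) == 0 || nrow(prot) == 0 || ligand_margin <= 0) {
    return(tibble(x = double(), y = double(), z = double(),
                  radius = double()))
  }
  lx <- cbind(lig$x, lig$y, lig$z)
  keep <- vapply(seq_len(nrow(prot)), function(i) {
    min(colSums((t(lx) - c(prot$x[i], prot$y[i], prot$z[i]))^2)) <=
      ligand_margin^2
  }, logical(1))
  prot <- prot[keep, ]
  if (!is.null(model) && nrow(model$features) > 0 && nrow(prot) > 0) {
    fx <- cbind(model$features$x, model$features$y, model$features$z)
    clear <- vapply(seq_len(nrow(prot)), function(i) {
      min(colSums((t(fx) - c(prot$x[i], prot$y[i], prot$z[i]))^2)) >
        feature_clearance^2
    }, logical(1))
    prot <- prot[clear, ]
  }
  tibble(x = prot$x, y = prot$y, z = prot$z, radius = radius)
}

# pool near-duplicate exclusion spheres from merged models into one sphere
# per single-linkage cluster (centroid position, maximum radius)
merge_exclusions <- function(ev, tol = 0.75) {
  if (nrow(ev) <= 1) return(ev)
  cl <- cutree(hclust(dist(cbind(ev$x, ev$y, ev$z)), method = "single"),
               h = tol)
  ev %>%
    mutate(cluster = cl) %>%
    group_by(.data$cluster) %>%
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              radius = max(.data$radius), .groups = "drop") %>%
    select(-dplyr::any_of("cluster")) %>%
    arrange(.data$x, .data$y, .data$z)
}
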