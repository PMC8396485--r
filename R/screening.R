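# Pharmacophore virtual screening: rigid placement of conformer features
# onto a query model (all essential features and at least one member of each
# either-group must match, zero omitted features by default), exclusion
# volume checks, pharmacophore-fit scoring and ROC/enrichment validation.

#' Screening settings
#'
#' Defaults mirror a strict retrieval protocol: match all query features
#' relevant to the flag specification, allow zero omitted essential
#' features, check exclusion volumes, and stop after the first matching
#' conformation of each molecule. The pharmacophore-fit score is
#' `w_match * M - w_rmsd * RMSD_feat` where `M` is the number of matched
#' features and `RMSD_feat` the RMS of paired feature-center distances after
#' placement; its role is relative ranking, not an absolute affinity.
#'
#' @param max_omitted_features maximum number of unmatched essential
#'   features tolerated (default 0).
#' @param check_exclusion_volumes reject placements that put any heavy atom
#'   inside an exclusion sphere (default `TRUE`).
#' @param stop_after_first_match stop trying conformers of a molecule after
#'   the first match (default `TRUE`).
#' @param w_match,w_rmsd score weights (defaults 10 and 3).
#' @return a `dynopharm_settings` list.
#' @export
screen_settings <- function(max_omitted_features = 0L,
                            check_exclusion_volumes = TRUE,
                            stop_after_first_match = TRUE,
                            w_match = 10, w_rmsd = 3) {
  stopifnot(max_omitted_features >= 0)
  structure(list(max_omitted_features = as.integer(max_omitted_features),
                 check_exclusion_volumes = check_exclusion_volumes,
                 stop_after_first_match = stop_after_first_match,
                 w_match = w_match, w_rmsd = w_rmsd),
            class = "dynopharm_settings")
}

#' Match one conformer against a pharmacophore model
#'
#' Searches rigid placements of the conformer's features onto the model:
#' type-compatible feature triplets (anchored on the PI feature, or the
#' largest-radius essential feature when the model has no PI) seed Kabsch
#' superpositions that are refined by greedy mutual-nearest pairing within
#' each model feature's radius. A placement is valid when every essential
#' feature is matched (up to `max_omitted_features`), at least one member of
#' every either-group is matched, and (when enabled) no conformer heavy atom
#' falls inside an exclusion sphere. The best valid placement by
#' pharmacophore-fit score is returned; `NULL` means no match.
#'
#' @param features conformer feature tibble from
#'   [perceive_ligand_features()].
#' @param model a `dynopharm_model`.
#' @param settings a [screen_settings()] object.
#' @param atoms_xyz optional conformer heavy-atom coordinates (n x 3) for
#'   the exclusion-volume check; feature centers are used when absent.
#' @return `NULL`, or a list with `rotation`, `translation`, `pairs`,
#'   `n_matched`, `rmsd_feat`, `fit_score`.
#' @export
match_conformer <- function(features, model,
                            settings = screen_settings(),
                            atoms_xyz = NULL) {
  mf <- model$features
  if (nrow(mf) == 0 || nrow(features) == 0) return(NULL)
  essential <- which(mf$flag == "essential")
  groups <- split(seq_len(nrow(mf))[!is.na(mf$either_group)],
                  mf$either_group[!is.na(mf$either_group)])
  # anchor: PI essential feature if present, else largest-radius essential,
  # else first feature
  anchor <- essential[mf$type[essential] == "PI"][1]
  if (is.na(anchor) && length(essential) > 0) {
    anchor <- essential[order(-mf$radius[essential])][1]
  }
  if (is.na(anchor) || length(anchor) == 0) anchor <- 1L
  other_idx <- setdiff(seq_len(nrow(mf)), anchor)
  # deterministic: required features first, then the rest
  pri <- order(!(other_idx %in% essential | !is.na(mf$either_group[other_idx])),
               other_idx)
  other_idx <- other_idx[pri]
  cxyz <- cbind(features$x, features$y, features$z)
  best <- NULL
  seconds <- utils::combn(other_idx, min(2, length(other_idx)),
                          simplify = FALSE)
  for (pair2 in seconds) {
    if (length(pair2) < 2) break
    m_tri <- c(anchor, pair2)
    c1s <- which(features$type == mf$type[m_tri[1]])
    c2s <- which(features$type == mf$type[m_tri[2]])
    c3s <- which(features$type == mf$type[m_tri[3]])
    for (c1 in c1s) for (c2 in c2s) for (c3 in c3s) {
      c_tri <- c(c1, c2, c3)
      if (length(unique(c_tri)) < 3) next
      ok <- TRUE
      for (a in 1:2) for (b in (a + 1):3) {
        dm <- sqrt(sum((cbind(mf$x, mf$y, mf$z)[m_tri[a], ] -
                        cbind(mf$x, mf$y, mf$z)[m_tri[b], ])^2))
        dc <- sqrt(sum((cxyz[c_tri[a], ] - cxyz[c_tri[b], ])^2))
        if (abs(dm - dc) > mf$radius[m_tri[a]] + mf$radius[m_tri[b]]) {
          ok <- FALSE
        }
      }
      if (!ok) next
      fit <- kabsch(cxyz[c_tri, , drop = FALSE],
                    cbind(mf$x, mf$y, mf$z)[m_tri, , drop = FALSE])
      placed <- apply_rigid(cxyz, fit$rotation, fit$translation)
      res <- evaluate_placement(mf, features$type, placed, essential,
                                groups, settings, model,
                                atoms_xyz, fit)
      if (!is.null(res) &&
          (is.null(best) || res$fit_score > best$fit_score + 1e-12)) {
        best <- res
      }
    }
  }
  best
}

evaluate_placement <- function(mf, conf_types, placed, essential, groups,
                               settings, model, atoms_xyz, fit) {
  pairs <- greedy_mutual_pairs(mf, placed, conf_types, tol = mf$radius)
  if (length(essential) > 0) {
    n_missing <- sum(!(essential %in% pairs$ref))
    if (n_missing > settings$max_omitted_features) return(NULL)
  }
  for (g in groups) {
    if (!any(g %in% pairs$ref)) return(NULL)
  }
  if (nrow(pairs) == 0) return(NULL)
  if (settings$check_exclusion_volumes &&
      nrow(model$exclusion_volumes) > 0) {
    pts <- if (!is.null(atoms_xyz)) {
      apply_rigid(atoms_xyz, fit$rotation, fit$translation)
    } else placed
    ev <- model$exclusion_volumes
    for (k in seq_len(nrow(ev))) {
      d2 <- (pts[, 1] - ev$x[k])^2 + (pts[, 2] - ev$y[k])^2 +
        (pts[, 3] - ev$z[k])^2
      if (any(d2 < ev$radius[k]^2)) return(NULL)
    }
  }
  rmsd_feat <- sqrt(mean(pairs$distance^2))
  list(rotation = fit$rotation, translation = fit$translation,
       pairs = pairs, n_matched = nrow(pairs), rmsd_feat = rmsd_feat,
       fit_score = settings$w_match * nrow(pairs) -
         settings$w_rmsd * rmsd_feat)
}

#' Screen a library against a pharmacophore model
#'
#' Tries each molecule's conformers in stored order (no conformer embedding
#' is performed); with `stop_after_first_match` the first matching
#' conformation is recorded. Deterministic given input order.
#'
#' @param library library tibble from [read_library()] or
#'   [generate_screening_library()] (columns `id`, `molecule`, optional
#'   `label`).
#' @param model a `dynopharm_model`.
#' @param settings a [screen_settings()] object.
#' @return tibble of screen records: `id`, `matched`, `fit_score` (NA when
#'   unmatched), `conformer`, `n_matched`, plus `label` when present in the
#'   library.
#' @export
screen_library <- function(library, model, settings = screen_settings()) {
  if (nrow(library) == 0) {
    return(tibble(id = character(), matched = logical(),
                  fit_score = double(), conformer = integer(),
                  n_matched = integer()))
  }
  rows <- purrr::map(seq_len(nrow(library)), function(i) {
    mol <- library$molecule[[i]]
    if (length(mol$conformers) == 0) {
      dyn_warn(sprintf("molecule %s has no conformers; unmatched", mol$id))
      return(tibble(id = mol$id, matched = FALSE, fit_score = NA_real_,
                    conformer = NA_integer_, n_matched = 0L))
    }
    best <- NULL; best_cf <- NA_integer_
    for (cf in seq_along(mol$conformers)) {
      feats <- perceive_ligand_features(mol, conformer = cf)
      heavy <- toupper(mol$atoms$element) != "H"
      res <- match_conformer(feats, model, settings,
                             atoms_xyz = mol$conformers[[cf]][heavy, ,
                                                             drop = FALSE])
      if (!is.null(res)) {
        if (is.null(best) || res$fit_score > best$fit_score) {
          best <- res; best_cf <- cf
        }
        if (settings$stop_after_first_match) break
      }
    }
    tibble(id = mol$id, matched = !is.null(best),
           fit_score = if (is.null(best)) NA_real_ else best$fit_score,
           conformer = best_cf,
           n_matched = if (is.null(best)) 0L else best$n_matched)
  })
  out <- bind_rows(rows)
  if ("label" %in% names(library)) {
    out <- left_join(out, select(library, "id", "label"), by = "id")
  }
  out
}

#' ROC / enrichment validation of a screen
#'
#' Ranks records matched-first by descending pharmacophore-fit score
#' (unmatched molecules rank after all matched ones, ties keep stable input
#' order) and computes: the enrichment factor
#' `EF_f = (a_f / n_f) / (A / N)` with `n_f = max(1, floor(f * N))` for each
#' requested fraction, and the ROC AUC by trapezoid over the score-ranked
#' list (score ties contribute diagonal segments, so the AUC equals the
#' tie-corrected Mann-Whitney statistic).
#'
#' @param records screen-record tibble with a `label` column
#'   ("active"/"decoy") or logical `active` column.
#' @param fractions screened-library fractions at which to report enrichment
#'   factors (default `c(0.01, 0.05, 0.1)`).
#' @return a `dynopharm_enrichment` object: list with `auc`, `ef` (tibble
#'   `fraction`, `n_top`, `actives_top`, `ef`), `roc` (cumulative TP/FP
#'   curve), `n`, `n_actives`, `tp`, `fp` (matched actives / matched decoys
#'   at full retrieval).
#' @export
enrichment_metrics <- function(records, fractions = c(0.01, 0.05, 0.1)) {
  if ("label" %in% names(records)) {
    act <- records$label == "active"
  } else if ("active" %in% names(records)) {
    act <- as.logical(records$active)
  } else {
    dyn_abort("degenerate-labels", "records carry no label column")
  }
  if (anyNA(act)) dyn_abort("degenerate-labels", "missing labels")
  n <- length(act); a <- sum(act)
  if (a == 0 || a == n) {
    dyn_abort("degenerate-labels",
              "need at least one active and one decoy")
  }
  score <- ifelse(records$matched, records$fit_score, -Inf)
  ord <- order(-score)  # stable: ties keep input order
  act_sorted <- act[ord]
  score_sorted <- score[ord]
  ef <- purrr::map_dfr(fractions, function(f) {
    n_top <- max(1L, as.integer(floor(f * n)))
    a_top <- sum(act_sorted[seq_len(n_top)])
    tibble(fraction = f, n_top = n_top, actives_top = a_top,
           ef = (a_top / n_top) / (a / n))
  })
  # ROC with tie groups: one step per distinct score
  grp <- cumsum(!duplicated(score_sorted))
  tp_g <- tapply(act_sorted, grp, sum)
  fp_g <- tapply(!act_sorted, grp, sum)
  tpr <- c(0, cumsum(tp_g) / a)
  fpr <- c(0, cumsum(fp_g) / (n - a))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  roc <- tibble(fpr = fpr, tpr = tpr)
  structure(list(
    auc = auc, ef = ef, roc = roc, n = n, n_actives = a,
    tp = sum(act & records$matched), fp = sum(!act & records$matched)),
    class = "dynopharm_enrichment")
}

#' @export
print.dynopharm_enrichment <- function(x, ...) {
  cat(sprintf(
    "<screen validation: N=%d (%d actives), AUC %.3f, retrieved %d actives / %d decoys>\n",
    x$n, x$n_actives, x$auc, x$tp, x$fp))
  for (i in seq_len(nrow(x$ef))) {
    cat(sprintf("  EF at %g%%: %.1f\n", 100 * x$ef$fraction[i],
                x$ef$ef[i]))
  }
  invisible(x)
}

#' @rdname enrichment_metrics
#' @param x a `dynopharm_enrichment` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.dynopharm_enrichment <- function(x, ...) {
  x$ef
}

#' @rdname enrichment_metrics
#' @exportS3Method generics::glance
glance.dynopharm_enrichment <- function(x, ...) {
  tibble(auc = x$auc, n = x$n, n_actives = x$n_actives,
         n_decoys = x$n - x$n_actives, tp = x$tp, fp = x$fp)
}

#' @rdname enrichment_metrics
#' @param object a `dynopharm_enrichment` object.
#' @export
autoplot.dynopharm_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#3B6FB6", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.2f)", object$auc),
      subtitle = sprintf("%d actives / %d decoys; EF%g%% = %.1f",
                         object$n_actives, object$n - object$n_actives,
                         100 * object$ef$fraction[1], object$ef$ef[1])) +
    ggplot2::theme_minimal()
}
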