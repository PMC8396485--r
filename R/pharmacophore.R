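# Pharmacophore model: typed features with tolerance radii and optional
# directions, exclusion volumes, essential/optional flags and either-groups
# (feature pairs where at least one member must be matched; both are
# individually optional, the group constraint is enforced at match time).

#' Construct a pharmacophore model
#'
#' @param features tibble with columns `type` (H/AR/PI/HBD/HBA/XBD), `x`,
#'   `y`, `z`, `radius`, optional `dx`, `dy`, `dz` (unit direction or NA),
#'   optional `flag` ("essential"/"optional"), optional `either_group`
#'   (integer group id or NA) and optional partner columns.
#' @param exclusion_volumes tibble with columns `x`, `y`, `z`, `radius`.
#' @return an object of class `dynopharm_model`.
#' @export
pharmacophore <- function(features = NULL, exclusion_volumes = NULL) {
  if (is.null(features) || nrow(features) == 0) {
    features <- empty_model_features()
  }
  features <- as_tibble(features)
  for (col in c("dx", "dy", "dz")) {
    if (!col %in% names(features)) features[[col]] <- NA_real_
  }
  if (!"flag" %in% names(features)) features$flag <- "optional"
  if (!"either_group" %in% names(features)) {
    features$either_group <- NA_integer_
  }
  for (col in c("partner_chain", "partner_resid", "partner_resname")) {
    if (!col %in% names(features)) {
      features[[col]] <- if (col == "partner_resid") NA_integer_
                         else NA_character_
    }
  }
  bad_type <- setdiff(unique(features$type), feature_types()$type)
  if (length(bad_type) > 0) {
    dyn_abort("bad-model", paste("unknown feature type:",
                                 paste(bad_type, collapse = ", ")))
  }
  if (nrow(features) > 0 && any(features$radius <= 0)) {
    dyn_abort("bad-model", "feature radii must be positive")
  }
  if (!all(features$flag %in% c("essential", "optional"))) {
    dyn_abort("bad-model", "flags must be 'essential' or 'optional'")
  }
  if (is.null(exclusion_volumes) || nrow(exclusion_volumes) == 0) {
    exclusion_volumes <- tibble(x = double(), y = double(), z = double(),
                                radius = double())
  }
  structure(
    list(features = as_tibble(features),
         exclusion_volumes = as_tibble(exclusion_volumes)),
    class = "dynopharm_model"
  )
}

empty_model_features <- function() {
  tibble(type = character(), x = double(), y = double(), z = double(),
         radius = double(), dx = double(), dy = double(), dz = double(),
         flag = character(), either_group = integer(),
         partner_chain = character(), partner_resid = integer(),
         partner_resname = character())
}

#' @export
print.dynopharm_model <- function(x, ...) {
  tf <- table(x$features$type)
  cat(sprintf(
    "<pharmacophore model: %d features (%s), %d essential, %d exclusion volumes>\n",
    nrow(x$features),
    if (length(tf) > 0) paste(names(tf), tf, sep = ":", collapse = " ")
    else "none",
    sum(x$features$flag == "essential"),
    nrow(x$exclusion_volumes)))
  invisible(x)
}

#' @rdname pharmacophore
#' @param x a `dynopharm_model`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.dynopharm_model <- function(x, ...) {
  x$features
}

#' @rdname pharmacophore
#' @exportS3Method generics::glance
glance.dynopharm_model <- function(x, ...) {
  tibble(
    n_features = nrow(x$features),
    n_essential = sum(x$features$flag == "essential"),
    n_either_groups = length(unique(stats::na.omit(x$features$either_group))),
    n_exclusion_volumes = nrow(x$exclusion_volumes),
    has_directions = any(!is.na(x$features$dx))
  )
}

#' Canonical interaction signature
#'
#' Order-independent identity of an interaction set: the sorted tuple of
#' (type, chain, residue id) items joined into a single string. Two per-frame
#' models are "the same model" when their signatures are equal; coordinate
#' jitter is deliberately ignored.
#'
#' @param x an interaction-record tibble (columns `type`, `chain`, `resid`)
#'   or a `dynopharm_model` whose features carry partner residues.
#' @return character scalar (empty string for an empty set).
#' @export
model_signature <- function(x) {
  if (inherits(x, "dynopharm_model")) x <- rename(
    x$features, chain = "partner_chain", resid = "partner_resid")
  if (nrow(x) == 0) return("")
  signature_of(x$type, x$chain, x$resid)
}

signature_of <- function(type, chain, resid) {
  if (length(type) == 0) return("")
  paste(sort(unique(paste0(type, ":", chain, ":", resid))),
        collapse = "+")
}

#' Drop feature directions (vector to sphere conversion)
#'
#' Converts every vector feature (donors, acceptors, aromatic-ring normals)
#' into a pure sphere feature: all direction fields are removed, feature
#' count, centers, radii and flags are unchanged.
#'
#' @param model a `dynopharm_model`.
#' @return the devectorized model.
#' @export
devectorize <- function(model) {
  model$features$dx <- NA_real_
  model$features$dy <- NA_real_
  model$features$dz <- NA_real_
  model
}

PHARMACOPHORE_FORMAT <- "dynopharm-pharmacophore"
PHARMACOPHORE_VERSION <- 1L

#' Write / read a pharmacophore model as JSON
#'
#' The documented, versioned JSON schema has top-level keys `format`,
#' `version`, `features` (array of objects with `type`, `center` [x,y,z],
#' `radius`, optional `direction`, `flag`, optional `either_group`, optional
#' `partner`) and `exclusion_volumes` (array of `{center, radius}`). The
#' round trip is lossless.
#'
#' @param model a `dynopharm_model`.
#' @param path file path.
#' @return `write_pharmacophore` returns `path` invisibly;
#'   `read_pharmacophore` returns the model.
#' @export
write_pharmacophore <- function(model, path) {
  feats <- purrr::pmap(model$features, function(type, x, y, z, radius,
                                               dx, dy, dz, flag,
                                               either_group, partner_chain,
                                               partner_resid,
                                               partner_resname, ...) {
    out <- list(type = type, center = c(x, y, z), radius = radius,
                flag = flag)
    if (!is.na(dx)) out$direction <- c(dx, dy, dz)
    if (!is.na(either_group)) out$either_group <- either_group
    if (!is.na(partner_resid)) {
      out$partner <- list(chain = partner_chain, resid = partner_resid,
                          resname = partner_resname)
    }
    out
  })
  ev <- purrr::pmap(model$exclusion_volumes, function(x, y, z, radius) {
    list(center = c(x, y, z), radius = radius)
  })
  jsonlite::write_json(
    list(format = PHARMACOPHORE_FORMAT, version = PHARMACOPHORE_VERSION,
         features = feats, exclusion_volumes = ev),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pharmacophore
#' @export
read_pharmacophore <- function(path) {
  if (!file.exists(path)) dyn_abort("bad-model-file", paste("no file:", path))
  obj <- tryCatch(jsonlite::read_json(path), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$format, PHARMACOPHORE_FORMAT) ||
      is.null(obj$version) || !("features" %in% names(obj))) {
    dyn_abort("bad-model-file",
              "missing format/version/features keys in pharmacophore JSON")
  }
  feats <- purrr::map_dfr(obj$features, function(f) {
    if (is.null(f$type) || is.null(f$center) || is.null(f$radius)) {
      dyn_abort("bad-model-file", "feature missing type/center/radius")
    }
    ctr <- unlist(f$center)
    dir <- if (!is.null(f$direction)) unlist(f$direction) else rep(NA_real_, 3)
    tibble(type = f$type, x = ctr[1], y = ctr[2], z = ctr[3],
           radius = f$radius, dx = dir[1], dy = dir[2], dz = dir[3],
           flag = f$flag %||% "optional",
           either_group = as.integer(f$either_group %||% NA_integer_),
           partner_chain = f$partner$chain %||% NA_character_,
           partner_resid = as.integer(f$partner$resid %||% NA_integer_),
           partner_resname = f$partner$resname %||% NA_character_)
  })
  ev <- purrr::map_dfr(obj$exclusion_volumes, function(e) {
    ctr <- unlist(e$center)
    tibble(x = ctr[1], y = ctr[2], z = ctr[3], radius = e$radius)
  })
  pharmacophore(feats, ev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
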