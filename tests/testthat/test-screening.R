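# a scalene three-feature query model: the asymmetric geometry admits
# essentially one placement, which makes exclusion-volume tests exact
scalene_model <- function(exclusions = NULL) {
  pharmacophore(
    tibble::tibble(
      type = c("PI", "H", "HBD"),
      x = c(0, 3.6, -1.1), y = c(0, 0.4, 2.9), z = c(0, -0.5, 0.6),
      radius = c(1.5, 1.5, 1.5),
      dx = NA_real_, dy = NA_real_, dz = NA_real_,
      flag = "essential", either_group = NA_integer_),
    exclusions)
}

scalene_features <- function(shift = c(0, 0, 0)) {
  tibble::tibble(
    feature = c("PI_1", "H_1", "HBD_1"),
    type = c("PI", "H", "HBD"),
    x = c(0, 3.6, -1.1) + shift[1], y = c(0, 0.4, 2.9) + shift[2],
    z = c(0, -0.5, 0.6) + shift[3],
    radius = 1.5, dx = NA_real_, dy = NA_real_, dz = NA_real_,
    source_atoms = list(1L, 2L, 3L),
    partner_chain = NA_character_, partner_resid = NA_integer_,
    partner_resname = NA_character_)
}

test_that("a conformer sitting exactly on the model matches with zero RMSD", {
  res <- match_conformer(scalene_features(), scalene_model())
  expect_false(is.null(res))
  expect_equal(res$n_matched, 3)
  expect_equal(res$rmsd_feat, 0, tolerance = 1e-9)
  expect_equal(res$fit_score, 30, tolerance = 1e-6)
})

test_that("exclusion volumes veto placements and can be disabled", {
  ev <- tibble::tibble(x = 3.6, y = 0.4, z = -0.5, radius = 1.2)
  model <- scalene_model(ev)
  feats <- scalene_features()
  atoms <- cbind(c(0, 3.6, -1.1), c(0, 0.4, 2.9), c(0, -0.5, 0.6))
  blocked <- match_conformer(feats, model, screen_settings(),
                             atoms_xyz = atoms)
  expect_null(blocked)
  open <- match_conformer(
    feats, model, screen_settings(check_exclusion_volumes = FALSE),
    atoms_xyz = atoms)
  expect_false(is.null(open))
})

test_that("a displaced essential feature prevents matching", {
  feats <- scalene_features()
  feats$x[feats$type == "PI"] <- 40
  expect_null(match_conformer(feats, scalene_model()))
})

test_that("either-groups require at least one member to match", {
  feats <- tibble::tibble(
    type = c("PI", "H", "H", "HBD"),
    x = c(0, 3.6, -3.4, -1.1), y = c(0, 0.4, 0.8, 2.9),
    z = c(0, -0.5, 0.3, 0.6), radius = 1.5,
    dx = NA_real_, dy = NA_real_, dz = NA_real_,
    flag = c("essential", "essential", "optional", "optional"),
    either_group = c(NA, NA, 1L, 1L))
  # second either member (an HBD at the same spot) completes the group
  feats$either_group[4] <- 1L
  model <- pharmacophore(feats)
  conf_all <- tibble::tibble(
    feature = c("PI_1", "H_1", "H_2", "HBD_1"),
    type = c("PI", "H", "H", "HBD"),
    x = c(0, 3.6, -3.4, -1.1), y = c(0, 0.4, 0.8, 2.9),
    z = c(0, -0.5, 0.3, 0.6), radius = 1.5,
    dx = NA_real_, dy = NA_real_, dz = NA_real_,
    source_atoms = list(1L, 2L, 3L, 4L),
    partner_chain = NA_character_, partner_resid = NA_integer_,
    partner_resname = NA_character_)
  expect_false(is.null(match_conformer(conf_all, model)))
  # drop both either members -> no match; keep one -> match
  expect_null(match_conformer(conf_all[1:2, ], model))
  expect_false(is.null(match_conformer(conf_all[c(1, 2, 4), ], model)))
})

test_that("screening is deterministic and respects planted labels", {
  sch <- occupancy_schedule(p = c(ar = 1, hb = 1, h = 1, x = 1),
                            n_frames = 30, sigma = 0.05, seed = 51)
  g <- generate_complex_trajectory(synthetic_ligand(), sch)
  res <- run_complex_analysis(
    g$trajectory, pipeline_config(frames = 30, window_frac = 1, top_k_models = 1))
  model <- apply_flags(devectorize(res$merged_model))
  lib <- generate_screening_library(
    model, library_spec(n_actives = 4, decoys_per_active = 10, seed = 6))
  records <- screen_library(lib, model)
  expect_equal(sort(records$id[records$matched]),
               sort(lib$id[lib$label == "active"]))
  expect_equal(screen_library(lib, model), records)
  expect_equal(nrow(screen_library(lib[0, ], model)), 0)
})

test_that("molecules without conformers are reported unmatched", {
  m <- make_ethane()
  m$conformers <- list()
  lib <- tibble::tibble(id = "e", molecule = list(m))
  expect_warning(rec <- screen_library(lib, scalene_model()),
                 class = "dynopharm_warning")
  expect_false(rec$matched)
})

test_that("the fit score is invariant under rigid motion of the conformer", {
  withr::local_seed(61)
  base <- match_conformer(scalene_features(), scalene_model())
  for (rep in 1:5) {
    r <- random_rotation(); tr <- stats::rnorm(3, sd = 8)
    feats <- scalene_features()
    xyz <- t(r %*% t(cbind(feats$x, feats$y, feats$z))) +
      rep(tr, each = 3)
    feats$x <- xyz[, 1]; feats$y <- xyz[, 2]; feats$z <- xyz[, 3]
    res <- match_conformer(feats, scalene_model())
    expect_false(is.null(res))
    expect_equal(res$fit_score, base$fit_score, tolerance = 1e-6)
  }
})

test_that("the enrichment factor reproduces the printed worked example", {
  # 463 compounds, 15 actives, 2 actives among the top floor(0.01*463)=4
  label <- rep("decoy", 463)
  label[c(1, 3)] <- "active"          # 2 actives in the top bin
  label[101:113] <- "active"          # the other 13 further down
  recs <- tibble::tibble(
    id = sprintf("m%04d", 1:463), matched = TRUE,
    fit_score = seq(463, 1), conformer = 1L, n_matched = 3L,
    label = label)
  expect_equal(sum(recs$label == "active"), 15)
  expect_equal(sum(recs$label[1:4] == "active"), 2)
  m <- enrichment_metrics(recs, fractions = 0.01)
  expect_equal(m$ef$n_top, 4L)
  expect_equal(m$ef$ef, (2 / 4) / (15 / 463), tolerance = 1e-12)
  expect_equal(round(m$ef$ef, 1), 15.4)
})

test_that("perfect ranking maximises EF and gives unit AUC", {
  recs <- tibble::tibble(
    id = sprintf("m%04d", 1:463), matched = TRUE,
    fit_score = seq(463, 1), conformer = 1L, n_matched = 3L,
    label = c(rep("active", 15), rep("decoy", 448)))
  m <- enrichment_metrics(recs, fractions = 0.01)
  expect_equal(m$ef$ef, (4 / 4) / (15 / 463), tolerance = 1e-12)
  expect_equal(round(m$ef$ef, 2), 30.87)
  expect_equal(m$auc, 1.0)
})

test_that("random scores give chance-level AUC on average", {
  withr::local_seed(71)
  aucs <- vapply(1:50, function(i) {
    recs <- tibble::tibble(
      id = as.character(1:2000), matched = TRUE,
      fit_score = stats::rnorm(2000), conformer = 1L, n_matched = 1L,
      label = c(rep("active", 200), rep("decoy", 1800)))
    enrichment_metrics(recs)$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("trapezoid AUC equals the Mann-Whitney statistic with ties", {
  withr::local_seed(77)
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # many ties
    act <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(act) == 0 || sum(act) == n) act[1:2] <- c(TRUE, FALSE)
    recs <- tibble::tibble(
      id = as.character(seq_len(n)), matched = TRUE, fit_score = scores,
      conformer = 1L, n_matched = 1L,
      label = ifelse(act, "active", "decoy"))
    m <- enrichment_metrics(recs)
    expect_equal(m$auc, mann_whitney_auc(scores, act), tolerance = 1e-9)
  }
})

test_that("unmatched molecules rank after matched ones", {
  recs <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    matched = c(FALSE, TRUE, TRUE, FALSE),
    fit_score = c(NA, 5, 50, NA), conformer = 1L, n_matched = 1L,
    label = c("active", "decoy", "active", "decoy"))
  m <- enrichment_metrics(recs, fractions = 0.5)
  expect_equal(m$ef$actives_top, 1L)  # top-2 = the two matched, one active
  expect_equal(m$tp, 1)
  expect_equal(m$fp, 1)
})

test_that("degenerate label sets are rejected", {
  recs <- tibble::tibble(id = "a", matched = TRUE, fit_score = 1,
                         conformer = 1L, n_matched = 1L, label = "active")
  expect_error(enrichment_metrics(recs),
               class = "dynopharm_degenerate_labels")
})

test_that("removing exclusion volumes never decreases retrieval", {
  sch <- occupancy_schedule(p = c(ar = 1, hb = 1, h = 1, x = 1),
                            n_frames = 20, sigma = 0.05, seed = 81)
  g <- generate_complex_trajectory(synthetic_ligand(), sch)
  res <- run_complex_analysis(
    g$trajectory, pipeline_config(frames = 20, window_frac = 1, top_k_models = 1))
  model <- apply_flags(devectorize(res$merged_model))
  lib <- generate_screening_library(
    model, library_spec(n_actives = 3, decoys_per_active = 8, seed = 5))
  on <- screen_library(lib, model, screen_settings())
  off <- screen_library(lib, model,
                        screen_settings(check_exclusion_volumes = FALSE))
  expect_gte(sum(off$matched & off$label == "decoy"),
             sum(on$matched & on$label == "decoy"))
  expect_gte(sum(off$matched), sum(on$matched))
})
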