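two_ring_inputs <- function(separation = 3.8, tilt_deg = 0) {
  feats <- perceive_ligand_features(make_benzene())
  ang <- (0:5) * pi / 3
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  r <- rotation_about_axis(c(1, 0, 0), tilt_deg)
  ring <- t(r %*% t(ring))
  ring[, 3] <- ring[, 3] + separation
  groups <- tibble::tibble(
    group = "ring", kind = "aromatic", chain = "A", resid = 468L,
    resname = "PHE",
    x = mean(ring[, 1]), y = mean(ring[, 2]), z = mean(ring[, 3]),
    nx = dynopharm:::ring_normal(ring)[1],
    ny = dynopharm:::ring_normal(ring)[2],
    nz = dynopharm:::ring_normal(ring)[3],
    atoms = list(1:6))
  list(feats = feats, groups = groups)
}

test_that("parallel stacked rings inside the distance bound are detected", {
  inp <- two_ring_inputs(separation = 3.8, tilt_deg = 0)
  recs <- detect_frame_interactions(1L, inp$feats, inp$groups)
  expect_equal(sum(recs$type == "AR"), 1)
  expect_equal(recs$resid[recs$type == "AR"], 468L)

  # inside the 30-60 degree dead band the contact is not called
  inp2 <- two_ring_inputs(separation = 3.8, tilt_deg = 45)
  recs2 <- detect_frame_interactions(1L, inp2$feats, inp2$groups)
  expect_equal(sum(recs2$type == "AR"), 0)

  # T-shaped orientation is accepted again
  inp3 <- two_ring_inputs(separation = 4.6, tilt_deg = 85)
  recs3 <- detect_frame_interactions(1L, inp3$feats, inp3$groups)
  expect_equal(sum(recs3$type == "AR"), 1)
})

test_that("donor-acceptor pairs beyond the distance bound are rejected", {
  feats <- tibble::tibble(
    feature = "HBD_1", type = "HBD", x = 0, y = 0, z = 0, radius = 1.5,
    dx = NA_real_, dy = NA_real_, dz = NA_real_,
    source_atoms = list(1L), partner_chain = NA_character_,
    partner_resid = NA_integer_, partner_resname = NA_character_)
  groups <- tibble::tibble(
    group = "og", kind = "acceptor", chain = "B", resid = 436L,
    resname = "SER", x = 5.0, y = 0, z = 0,
    nx = NA_real_, ny = NA_real_, nz = NA_real_, atoms = list(1L))
  expect_equal(nrow(detect_frame_interactions(1L, feats, groups)), 0)
  groups$x <- 3.0
  expect_equal(nrow(detect_frame_interactions(1L, feats, groups)), 1)
})

test_that("planted interactions are recovered exactly without jitter", {
  sch <- occupancy_schedule(p = c(ar = 0.7, hb = 0.5, h = 0.9, x = 0.4),
                            n_frames = 50, sigma = 0, seed = 3)
  g <- generate_complex_trajectory(synthetic_ligand(), sch)
  det <- dplyr::distinct(trajectory_interactions(g$trajectory),
                         frame, chain, resid, resname, type)
  keys <- c("frame", "chain", "resid", "resname", "type")
  expect_equal(nrow(dplyr::anti_join(det, g$ground_truth, by = keys)), 0)
  expect_equal(nrow(dplyr::anti_join(g$ground_truth, det, by = keys)), 0)
})

test_that("occurrence percentages recover a planted Bernoulli occupancy", {
  sch <- occupancy_schedule(p = c(hb = 0.6), n_frames = 500,
                            sigma = 0.05, seed = 21)
  g <- generate_complex_trajectory(synthetic_ligand(arms = c("hb", "h")),
                                   sch)
  occ <- occurrence_table(g$trajectory)
  p_hat <- occ$percent[occ$resid == 436 & occ$chain == "B" &
                         occ$type == "HBD"] / 100
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / 500))
})

fake_records <- function(sig_counts) {
  # sig_counts: list of list(records_per_frame, n_frames)
  rows <- list(); frame <- 0L
  for (sc in sig_counts) {
    for (k in seq_len(sc$count)) {
      frame <- frame + 1L
      if (nrow(sc$recs) > 0) {
        rows[[length(rows) + 1]] <- dplyr::mutate(sc$recs, frame = frame)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_frames") <- frame
  attr(out, "window") <- seq_len(frame)
  out
}

rec_tpl <- function(types, resids, chains) {
  tibble::tibble(
    feature = paste0(types, "_", seq_along(types)), type = types,
    chain = chains, resid = resids, resname = "ALA",
    distance = 3, fx = resids, fy = 0, fz = 0,
    dx = NA_real_, dy = NA_real_, dz = NA_real_)
}

test_that("the model histogram counts unique signatures and conserves frames", {
  recs <- fake_records(list(
    list(recs = rec_tpl(c("H", "HBD"), c(465L, 436L), c("C", "B")),
         count = 70),
    list(recs = rec_tpl("H", 465L, "C"), count = 20),
    list(recs = rec_tpl("AR", 468L, "A"), count = 10)))
  hist <- model_histogram(records = recs)
  expect_equal(hist$count, c(70, 20, 10))
  expect_equal(sum(hist$count), 100)

  # all-identical frames collapse into one signature
  recs2 <- fake_records(list(
    list(recs = rec_tpl("H", 465L, "C"), count = 25)))
  hist2 <- model_histogram(records = recs2)
  expect_equal(nrow(hist2), 1)
  expect_equal(hist2$count, 25)
})

test_that("signatures are order-independent", {
  r1 <- rec_tpl(c("H", "HBD"), c(465L, 436L), c("C", "B"))
  r2 <- r1[2:1, ]
  expect_equal(model_signature(r1), model_signature(r2))
  expect_equal(model_signature(r1[0, ]), "")
})

test_that("frequent-model selection ranks by count with feature-count ties", {
  recs <- fake_records(list(
    list(recs = rec_tpl(c("H", "HBD", "AR"), c(465L, 436L, 468L),
                        c("C", "B", "A")), count = 50),
    list(recs = rec_tpl(c("H", "HBD"), c(465L, 436L), c("C", "B")),
         count = 30),
    list(recs = rec_tpl("H", 465L, "C"), count = 15),
    list(recs = rec_tpl(c("AR", "XBD"), c(468L, 436L), c("A", "D")),
         count = 20),
    list(recs = rec_tpl("AR", 468L, "A"), count = 20)))
  models <- select_frequent_models(records = recs, k = 4)
  expect_length(models, 4)
  expect_equal(attr(models[[1]], "count"), 50)
  # rank-3/4 tie at count 20: the two-feature signature wins rank 3
  expect_equal(attr(models[[3]], "count"), 20)
  expect_equal(nrow(models[[3]]$features), 2)
  expect_equal(nrow(models[[4]]$features), 1)

  expect_warning(few <- select_frequent_models(records = recs, k = 10),
                 class = "dynopharm_warning")
  expect_length(few, 5)
})

test_that("frame models carry signatures and centroid geometry", {
  recs <- rec_tpl(c("H", "HBD"), c(465L, 436L), c("D", "B"))
  recs$frame <- 1L
  m <- frame_pharmacophore(recs)
  expect_equal(nrow(m$features), 2)
  expect_equal(attr(m, "signature"), "H:D:465+HBD:B:436")
  empty <- frame_pharmacophore(recs[0, ])
  expect_equal(nrow(empty$features), 0)
  expect_equal(attr(empty, "signature"), "")
})

test_that("records, tables and histograms are invariant to rigid motion", {
  sch <- occupancy_schedule(p = c(hb = 0.5, h = 0.8), n_frames = 40,
                            sigma = 0.05, seed = 9)
  g <- generate_complex_trajectory(synthetic_ligand(), sch)
  traj <- g$trajectory
  withr::local_seed(2)
  r <- random_rotation(); tr <- c(12, -5, 3)
  moved <- tibble::as_tibble(traj)
  xyz <- t(r %*% t(cbind(moved$x, moved$y, moved$z))) +
    rep(tr, each = nrow(moved))
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  traj2 <- as_trajectory(moved, "LIG")
  keys <- c("frame", "chain", "resid", "type")
  o1 <- occurrence_table(traj)
  o2 <- occurrence_table(traj2)
  expect_equal(o1, o2)
  h1 <- model_histogram(traj)
  h2 <- model_histogram(traj2)
  expect_equal(h1, h2)
})

test_that("loosening a distance cutoff never removes records", {
  sch <- occupancy_schedule(p = c(hb = 0.5, h = 0.5, ar = 0.5, x = 0.5),
                            n_frames = 30, sigma = 0.05, seed = 13)
  g <- generate_complex_trajectory(synthetic_ligand(), sch)
  tight <- trajectory_interactions(g$trajectory, geometric_rules())
  loose <- trajectory_interactions(
    g$trajectory,
    geometric_rules(hbond_dist_max = 4.2, hydrophobic_dist_max = 5.2,
                    aromatic_centroid_max = 6.2, cation_pi_max = 6.8,
                    halogen_dist_max = 4.5))
  keys <- c("frame", "feature", "chain", "resid", "type")
  expect_equal(nrow(dplyr::anti_join(tight, loose, by = keys)), 0)
  expect_gte(nrow(loose), nrow(tight))
})

test_that("empty analysis windows are rejected", {
  sch <- occupancy_schedule(p = c(h = 1), n_frames = 5, sigma = 0,
                            seed = 1)
  g <- generate_complex_trajectory(synthetic_ligand(), sch)
  expect_error(occurrence_table(g$trajectory, window = c(99L)),
               class = "dynopharm_empty_window")
})
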