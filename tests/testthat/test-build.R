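simple_model <- function(feats) {
  pharmacophore(feats)
}

h_feat <- function(x, y, z, type = "H", radius = 1.5) {
  tibble::tibble(type = type, x = x, y = y, z = z, radius = radius,
                 dx = NA_real_, dy = NA_real_, dz = NA_real_)
}

test_that("merging a model with itself preserves the feature count", {
  m <- simple_model(dplyr::bind_rows(
    h_feat(0, 0, 0, "PI"), h_feat(3, 0, 0), h_feat(0, 3, 0, "AR", 1.1)))
  merged <- merge_models(list(m, m))
  expect_equal(nrow(merged$features), 3)
  expect_equal(sort(merged$features$type), c("AR", "H", "PI"))
})

test_that("close same-type features interpolate to their midpoint", {
  m1 <- simple_model(h_feat(0, 0, 0))
  m2 <- simple_model(h_feat(0.5, 0, 0))
  merged <- merge_models(list(m1, m2), tol = 1.5)
  expect_equal(nrow(merged$features), 1)
  expect_equal(merged$features$x, 0.25)
  # radius grows to cover the cluster spread when it exceeds the members
  m3 <- simple_model(h_feat(0, 0, 0, radius = 0.2))
  m4 <- simple_model(h_feat(1.0, 0, 0, radius = 0.2))
  merged2 <- merge_models(list(m3, m4), tol = 1.5)
  expect_equal(merged2$features$radius, 0.5)
})

test_that("distinct feature types never merge", {
  m1 <- simple_model(h_feat(0, 0, 0, "H"))
  m2 <- simple_model(h_feat(0.2, 0, 0, "HBD"))
  merged <- merge_models(list(m1, m2))
  expect_equal(nrow(merged$features), 2)
})

test_that("merging matches a union-find single-linkage oracle", {
  withr::local_seed(19)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    xyz <- matrix(stats::rnorm(3 * n, sd = 2.5), ncol = 3)
    feats <- tibble::tibble(type = "H", x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], radius = 1.5,
                            dx = NA_real_, dy = NA_real_, dz = NA_real_)
    tol <- stats::runif(1, 0.8, 2.5)
    merged <- merge_models(list(simple_model(feats)), tol = tol)
    oracle <- union_find_clusters(xyz, tol)
    expect_equal(nrow(merged$features), length(unique(oracle)))
    # cluster centroids agree as sets
    got <- sort(round(merged$features$x, 9))
    want <- sort(round(as.numeric(tapply(xyz[, 1], oracle, mean)), 9))
    expect_equal(got, want)
  }
})

test_that("merge output is invariant to input model order", {
  withr::local_seed(23)
  models <- lapply(1:4, function(i) {
    simple_model(dplyr::bind_rows(
      h_feat(stats::rnorm(1), stats::rnorm(1), stats::rnorm(1)),
      h_feat(5 + stats::rnorm(1), 0, 0, "AR", 1.1)))
  })
  a <- merge_models(models)
  b <- merge_models(rev(models))
  expect_equal(a$features, b$features, tolerance = 1e-12)
})

test_that("devectorizing drops directions and nothing else", {
  feats <- dplyr::bind_rows(
    h_feat(0, 0, 0, "HBD"), h_feat(1, 2, 3, "AR", 1.1))
  feats$dx <- c(0, 0); feats$dy <- c(0, 0); feats$dz <- c(1, 1)
  m <- devectorize(simple_model(feats))
  expect_true(all(is.na(m$features$dx)))
  expect_equal(nrow(m$features), 2)
  expect_equal(m$features$x, feats$x)
  # persists through serialization
  path <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(m, path)
  expect_true(all(is.na(read_pharmacophore(path)$features$dx)))
})

ref_model <- function() {
  simple_model(dplyr::bind_rows(
    h_feat(0, 0, 0, "PI"),
    h_feat(3.4, 0.3, -0.4),
    h_feat(-3.1, 0.8, 0.2),
    h_feat(0.4, 4.1, 0.7, "HBD"),
    h_feat(4.4, 0, 0.5, "AR", 1.1)))
}

test_that("a rigidly moved copy aligns with all features paired", {
  withr::local_seed(27)
  ref <- ref_model()
  r <- random_rotation(); tr <- c(4, -7, 2)
  other <- ref
  xyz <- t(r %*% t(cbind(ref$features$x, ref$features$y,
                         ref$features$z))) +
    rep(tr, each = nrow(ref$features))
  other$features$x <- xyz[, 1]; other$features$y <- xyz[, 2]
  other$features$z <- xyz[, 3]
  al <- align_models(ref, other)
  expect_true(al$success)
  expect_equal(al$n_pairs, 5)
  expect_equal(al$rmsd, 0, tolerance = 1e-6)
  expect_equal(det(al$rotation), 1, tolerance = 1e-9)
  # symmetric for exact copies
  expect_true(align_models(other, ref)$success)
})

test_that("a divergent-binding-mode model fails to align as a result", {
  quin <- simple_model(dplyr::bind_rows(
    h_feat(0, 0, 0, "PI"), h_feat(9, 0, 0), h_feat(-9, 0, 0)))
  al <- align_models(ref_model(), quin)
  expect_false(al$success)
  expect_s3_class(al, "dynopharm_alignment")
})

test_that("alignment matches exhaustive correspondence enumeration", {
  withr::local_seed(33)
  for (rep in 1:3) {
    ref <- ref_model()
    other <- ref
    other$features$x <- other$features$x + stats::rnorm(5, sd = 0.3)
    other$features$y <- other$features$y + stats::rnorm(5, sd = 0.3)
    other$features$z <- other$features$z + stats::rnorm(5, sd = 0.3)
    r <- random_rotation(); tr <- stats::rnorm(3, sd = 5)
    xyz <- t(r %*% t(cbind(other$features$x, other$features$y,
                           other$features$z))) + rep(tr, each = 5)
    other$features$x <- xyz[, 1]; other$features$y <- xyz[, 2]
    other$features$z <- xyz[, 3]
    al <- align_models(ref, other, tol = 1.5)
    # oracle: enumerate every type-compatible pair triplet with no pruning
    rf <- ref$features; of <- other$features
    best_n <- 0; best_rmsd <- Inf
    for (i1 in 1:5) for (i2 in 1:5) for (i3 in 1:5) {
      if (length(unique(c(i1, i2, i3))) < 3) next
      for (j1 in 1:5) for (j2 in 1:5) for (j3 in 1:5) {
        if (length(unique(c(j1, j2, j3))) < 3) next
        if (!all(rf$type[c(i1, i2, i3)] == of$type[c(j1, j2, j3)])) next
        fit <- kabsch(cbind(of$x, of$y, of$z)[c(j1, j2, j3), ],
                      cbind(rf$x, rf$y, rf$z)[c(i1, i2, i3), ])
        moved <- t(fit$rotation %*% t(cbind(of$x, of$y, of$z))) +
          rep(fit$translation, each = 5)
        pairs <- dynopharm:::greedy_mutual_pairs(rf, moved, of$type, 1.5)
        if (nrow(pairs) >= 3) {
          fit2 <- kabsch(cbind(of$x, of$y, of$z)[pairs$other, ],
                         cbind(rf$x, rf$y, rf$z)[pairs$ref, ])
          moved2 <- t(fit2$rotation %*% t(cbind(of$x, of$y, of$z))) +
            rep(fit2$translation, each = 5)
          pairs2 <- dynopharm:::greedy_mutual_pairs(rf, moved2, of$type,
                                                    1.5)
          if (nrow(pairs2) > 0) {
            rmsd <- sqrt(mean(pairs2$distance^2))
            if (nrow(pairs2) > best_n ||
                (nrow(pairs2) == best_n && rmsd < best_rmsd)) {
              best_n <- nrow(pairs2); best_rmsd <- rmsd
            }
          }
        }
      }
    }
    expect_equal(al$n_pairs, best_n)
    expect_equal(al$rmsd, best_rmsd, tolerance = 1e-9)
  }
})

test_that("the default flag layout gives two essentials and one either-pair", {
  m <- simple_model(dplyr::bind_rows(
    h_feat(0, 0, 0, "PI"), h_feat(3.4, 0, 0), h_feat(-3.6, 0, 0),
    h_feat(0, -3.7, 0), h_feat(4.4, 0, 0.5, "AR", 1.1),
    h_feat(0, 4.1, 0.7, "HBD")))
  flagged <- apply_flags(m)
  expect_equal(sum(flagged$features$flag == "essential"), 2)
  expect_equal(flagged$features$flag[flagged$features$type == "PI"],
               "essential")
  # the essential hydrophobic is the one nearest the PI feature
  ess_h <- flagged$features$flag == "essential" &
    flagged$features$type == "H"
  expect_equal(flagged$features$x[ess_h], 3.4)
  expect_equal(sum(!is.na(flagged$features$either_group)), 2)
})

test_that("final model building excludes unalignable members with reasons", {
  withr::local_seed(41)
  mk <- function(noise) {
    m <- ref_model()
    m$features$x <- m$features$x + stats::rnorm(5, sd = noise)
    m$features$y <- m$features$y + stats::rnorm(5, sd = noise)
    m
  }
  quin <- simple_model(dplyr::bind_rows(
    h_feat(0, 0, 0, "PI"), h_feat(9, 0, 0), h_feat(-9, 0, 0),
    h_feat(0, 9, 0, "AR", 1.1)))
  models <- list(a = mk(0.1), b = mk(0.1), c = mk(0.1), d = mk(0.1),
                 quin = quin)
  final <- build_final_model(models)
  excluded <- attr(final, "excluded")
  expect_equal(excluded$id, "quin")
  expect_true(all(is.na(final$features$dx)))
  expect_equal(sum(final$features$flag == "essential"), 2)

  expect_error(build_final_model(models["a"]),
               class = "dynopharm_insufficient_models")
})

test_that("exclusion volumes line the pocket and respect clearances", {
  sch <- occupancy_schedule(p = c(h = 1, hb = 1), n_frames = 10,
                            sigma = 0.05, seed = 17)
  g <- generate_complex_trajectory(synthetic_ligand(), sch)
  traj <- g$trajectory
  ev <- generate_exclusion_volumes(traj, ligand_margin = 8)
  # oracle: recompute the margin rule directly from mean positions
  means <- tibble::as_tibble(traj) |>
    dplyr::group_by(serial, resname, element) |>
    dplyr::summarise(x = mean(x), y = mean(y), z = mean(z),
                     .groups = "drop")
  lig <- means[means$resname == "LIG", ]
  prot <- means[means$resname != "LIG", ]
  expected <- sum(vapply(seq_len(nrow(prot)), function(i) {
    min(sqrt((lig$x - prot$x[i])^2 + (lig$y - prot$y[i])^2 +
               (lig$z - prot$z[i])^2)) <= 8
  }, logical(1)))
  expect_equal(nrow(ev), expected)
  expect_true(all(ev$radius == 1.2))

  expect_equal(nrow(generate_exclusion_volumes(traj, ligand_margin = 0)), 0)

  model <- pharmacophore(h_feat(0, 4.1, 0.7, "HBD"))
  ev2 <- generate_exclusion_volumes(traj, model = model, ligand_margin = 8)
  d <- sqrt((ev2$x - 0)^2 + (ev2$y - 4.1)^2 + (ev2$z - 0.7)^2)
  expect_true(all(d > 2.0))
  expect_lt(nrow(ev2), nrow(ev) + 1)
})
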