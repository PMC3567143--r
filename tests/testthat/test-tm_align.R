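# Kabsch superposition, the TM-score and its d0 scale, and the pairwise
# alignment engine.

test_that("kabsch_superpose recovers rigid motions exactly", {
  set.seed(21)
  A <- matrix(rnorm(15 * 3, sd = 5), ncol = 3)

  res <- kabsch_superpose(A, A)
  expect_equal(res$rotation, diag(3), tolerance = 1e-9)
  expect_equal(res$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)

  B <- rotate_translate(A, angle = pi / 2)
  res2 <- kabsch_superpose(A, B)
  expect_equal(res2$rmsd, 0, tolerance = 1e-8)
  expect_equal(B %*% t(res2$rotation) +
                 matrix(res2$translation, nrow(B), 3, byrow = TRUE),
               A, tolerance = 1e-8)
  expect_equal(det(res2$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch rmsd matches a brute-force rotation-search oracle", {
  set.seed(22)
  for (r in 1:3) {
    A <- matrix(rnorm(4 * 3, sd = 3), ncol = 3)
    B <- A + matrix(rnorm(4 * 3, sd = 0.6), ncol = 3)
    res <- kabsch_superpose(A, B)
    expect_equal(res$rmsd, oracle_superpose_rmsd(A, B), tolerance = 1e-4)
  }
})

test_that("kabsch agrees with bio3d's least-squares fit", {
  set.seed(23)
  A <- matrix(rnorm(20 * 3, sd = 4), ncol = 3)
  B <- A + matrix(rnorm(20 * 3, sd = 0.5), ncol = 3)
  res <- kabsch_superpose(A, B)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(A)),
                                            mobile = as.numeric(t(B))))
  rmsd_bio3d <- sqrt(mean(rowSums((A - matrix(fitted, ncol = 3,
                                              byrow = TRUE))^2)))
  expect_equal(res$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("kabsch_superpose validates its inputs", {
  A <- matrix(rnorm(12), ncol = 3)
  expect_error(kabsch_superpose(A, A[1:3, ]), "matching dimensions")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("tm_d0 follows the standard closed form with a 0.5 floor", {
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(15), 0.5)
  # raw value at L = 21 is 1.24 * 6^(1/3) - 1.8 ~ 0.453 < 0.5, so floored
  expect_lt(1.24 * 6^(1 / 3) - 1.8, 0.5)
  expect_equal(tm_d0(21), 0.5)
})

test_that("tm_score_given_alignment reproduces analytic values", {
  set.seed(24)
  A <- matrix(rnorm(40 * 3, sd = 6), ncol = 3)
  expect_equal(tm_score_given_alignment(A, A, 40)$score, 1, tolerance = 1e-6)

  # every pair at distance exactly d0 under the optimal superposition:
  # widely separated anchors with balanced displacements leave the identity
  # optimal to leading order, and each term contributes 1/(1 + 1)
  d0 <- tm_d0(4)
  anchors <- rbind(c(50, 50, 0), c(50, -50, 0), c(-50, 50, 0), c(-50, -50, 0))
  shifts <- d0 * rbind(c(0, 0, 1), c(0, 0, -1), c(0, 0, -1), c(0, 0, 1))
  expect_equal(tm_score_given_alignment(anchors, anchors + shifts, 4)$score,
               0.5, tolerance = 1e-3)

  # half of L_norm aligned at distance zero, the rest unaligned
  m <- 20
  expect_equal(tm_score_given_alignment(A[1:m, ], A[1:m, ], 2 * m)$score,
               0.5, tolerance = 1e-9)

  expect_error(tm_score_given_alignment(A[1:2, ], A[1:2, ], 10),
               "at least 3")
})

test_that("alignment is invariant under rigid motions of one partner", {
  tmpl <- generate_toy_structures(
    structure_template_config("helix_bundle", n_residues = 80, seed = 31)
  )[[1]]
  set.seed(32)
  for (r in 1:3) {
    ang <- runif(1, 0, 2 * pi)
    shift <- rnorm(3, sd = 30)
    moved <- domain_structure("moved",
                              rotate_translate(tmpl$ca_coords, ang,
                                               shift = shift))
    res <- align_structures(tmpl, moved)
    expect_gt(res$tm_sym, 0.999)
    expect_lt(structural_distance(tmpl, moved), 1e-3)
    expect_equal(res$pairs[, 1], res$pairs[, 2])  # identity correspondence
  }
})

test_that("alignment result satisfies its structural invariants", {
  a <- generate_toy_structures(
    structure_template_config("beta_meander", n_residues = 70, seed = 33)
  )[[1]]
  b <- generate_toy_structures(
    structure_template_config("sandwich_jellyroll_like", n_residues = 90,
                              seed = 34)
  )[[1]]
  res <- align_structures(a, b)
  expect_true(all(diff(res$pairs[, 1]) > 0))
  expect_true(all(diff(res$pairs[, 2]) > 0))
  expect_equal(det(res$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(res$rotation), diag(3), tolerance = 1e-9)
  expect_true(all(res$per_pair_distance >= 0))
  expect_true(res$tm_norm_A > 0 && res$tm_norm_A <= 1)
  expect_true(res$tm_norm_B > 0 && res$tm_norm_B <= 1)
  expect_true(res$tm_sym > 0 && res$tm_sym <= 1)
  expect_identical(res$distance, 1 - res$tm_sym)
  expect_equal(res$tm_sym, (res$tm_norm_A + res$tm_norm_B) / 2,
               tolerance = 1e-12)
})

test_that("noisy self-alignment scores at least the identity correspondence", {
  tmpl <- generate_toy_structures(
    structure_template_config("sandwich_jellyroll_like", n_residues = 100,
                              seed = 35)
  )[[1]]
  set.seed(36)
  noisy <- domain_structure("noisy", tmpl$ca_coords +
                              matrix(rnorm(3 * tmpl$L, sd = 0.5), ncol = 3))
  identity_score <- mean(c(
    tm_score_given_alignment(tmpl$ca_coords, noisy$ca_coords, tmpl$L)$score,
    tm_score_given_alignment(tmpl$ca_coords, noisy$ca_coords, noisy$L)$score
  ))
  res <- align_structures(tmpl, noisy)
  expect_gte(res$tm_sym, identity_score - 1e-9)
})

test_that("mean tm_sym degrades monotonically with coordinate noise", {
  tmpl <- generate_toy_structures(
    structure_template_config("sandwich_jellyroll_like", n_residues = 120,
                              seed = 37)
  )[[1]]
  sigmas <- c(0, 0.5, 1, 2, 4)
  means <- vapply(sigmas, function(sig) {
    mean(vapply(1:5, function(r) {
      set.seed(1000 + 100 * which(sigmas == sig) + r)
      pert <- domain_structure("p", tmpl$ca_coords +
                                 matrix(rnorm(3 * tmpl$L, sd = sig), ncol = 3))
      align_structures(tmpl, pert)$tm_sym
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
})

test_that("short-structure alignments beat the exhaustive gapless-offset score", {
  for (r in 1:4) {
    a <- generate_toy_structures(
      structure_template_config("helix_bundle", 30, 0.3, 0, 1, seed = r)
    )[[1]]
    b <- generate_toy_structures(
      structure_template_config("helix_bundle", 30, 0.3, 0, 1, seed = r + 50)
    )[[1]]
    res <- align_structures(a, b)
    best <- 0
    L <- 30
    for (off in -(L - 4):(L - 4)) {
      ib <- max(1, 1 - off):min(L, L - off)
      ia <- ib + off
      if (length(ia) >= 3) {
        s <- mean(c(
          tm_score_given_alignment(a$ca_coords[ia, ], b$ca_coords[ib, ], L)$score,
          tm_score_given_alignment(a$ca_coords[ia, ], b$ca_coords[ib, ], L)$score
        ))
        best <- max(best, s)
      }
    }
    expect_gte(res$tm_sym, best - 1e-9)
  }
})

test_that("structural_distance is exactly symmetric and near zero on self", {
  a <- generate_toy_structures(
    structure_template_config("helix_bundle", 60, 0.5, 0, 2, seed = 38)
  )
  expect_lt(structural_distance(a[[1]], a[[1]]), 1e-3)
  expect_identical(structural_distance(a[[1]], a[[2]]),
                   structural_distance(a[[2]], a[[1]]))
})

test_that("distance_matrix matches serial recomputation and is well formed", {
  doms <- c(
    generate_toy_structures(
      structure_template_config("helix_bundle", 50, 0.2, 0, 2, seed = 39)),
    generate_toy_structures(
      structure_template_config("beta_meander", 55, 0.2, 0, 2, seed = 40)),
    generate_toy_structures(
      structure_template_config("sandwich_jellyroll_like", 60, 0.2, 0, 1,
                                seed = 41))
  )
  D <- distance_matrix(doms)
  expect_equal(dim(D), c(5L, 5L))
  expect_equal(diag(D), setNames(rep(0, 5), rownames(D)))
  expect_identical(D, t(D))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_identical(D[i, j], structural_distance(doms[[i]], doms[[j]]))
    }
  }
  # two lightly perturbed copies of one template stay close
  expect_lt(D[1, 2], 0.15)
  expect_error(distance_matrix(doms[1]), "at least 2")
})

test_that("alignment_table agrees with the distance matrix", {
  doms <- generate_toy_structures(
    structure_template_config("helix_bundle", 40, 0.5, 0, 3, seed = 44))
  tab <- alignment_table(doms)
  D <- distance_matrix(doms)
  expect_equal(nrow(tab), 3L)
  for (k in seq_len(nrow(tab))) {
    expect_identical(tab$distance[k], D[tab$id_a[k], tab$id_b[k]])
    expect_equal(tab$tm_sym[k], (tab$tm_a[k] + tab$tm_b[k]) / 2,
                 tolerance = 1e-12)
  }
})

test_that("templates from different folds are separated beyond 0.5", {
  hb <- generate_toy_structures(
    structure_template_config("helix_bundle", 120, seed = 42))[[1]]
  sj <- generate_toy_structures(
    structure_template_config("sandwich_jellyroll_like", 120, seed = 43))[[1]]
  expect_gt(structural_distance(hb, sj), 0.5)
})
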