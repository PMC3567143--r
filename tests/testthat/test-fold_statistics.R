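# Nearest-focus distances, the shared-folds statistic, ECDF curves and the
# permutation-test null.

test_that("nearest_focus_distance picks the minimum over the focus set", {
  ids <- c("f1", "f2", "o1", "o2")
  D <- matrix(c(0, 0.2, 0.5, 0.7,
                0.2, 0, 0.5, 0.3,
                0.5, 0.5, 0, 0.9,
                0.7, 0.3, 0.9, 0), 4, dimnames = list(ids, ids))
  nn <- nearest_focus_distance(c("f1", "f2"), c("o1", "o2"), D)
  expect_equal(nn, c(o1 = 0.5, o2 = 0.3))  # o1 equidistant to both foci

  nn1 <- nearest_focus_distance("f1", "o1", D)
  expect_equal(nn1, c(o1 = 0.5))

  expect_error(nearest_focus_distance(character(0), "o1", D), "non-empty")
  expect_error(nearest_focus_distance(c("f1", "o1"), c("o1"), D), "disjoint")
})

test_that("nearest_focus_distance equals a brute-force min scan", {
  D <- random_distance_matrix(20, 61)
  focus <- rownames(D)[1:6]
  others <- rownames(D)[7:20]
  nn <- nearest_focus_distance(focus, others, D)
  for (o in others) {
    expect_equal(nn[[o]], min(vapply(focus, function(f) D[o, f], numeric(1))))
  }
})

test_that("shared_folds counts distinct folds below the cutoff", {
  nn <- c(r1 = 0.3, r2 = 0.7, r3 = 0.5, r4 = 0.59)
  labs <- c(r1 = "b.1", r2 = "b.1", r3 = "c.2", r4 = "d.3")
  res <- shared_folds(nn, labs, cutoff = 0.6)
  expect_equal(res$n_relatives, 3L)
  expect_setequal(res$folds, c("b.1", "c.2", "d.3"))
  expect_equal(res$n_folds, 3L)

  res2 <- shared_folds(nn, labs, cutoff = 0.6, exclude_self = TRUE,
                       focus_folds = "c.2")
  expect_equal(res2$n_folds, 2L)
  expect_setequal(res2$excluded_self_folds, "c.2")

  res3 <- shared_folds(c(r1 = 0.8, r2 = 0.9), labs, cutoff = 0.6)
  expect_equal(res3$n_relatives, 0L)
  expect_equal(res3$n_folds, 0L)
})

test_that("unlabeled relatives count as relatives but contribute no fold", {
  nn <- c(r1 = 0.2, r2 = 0.3)
  labs <- c(r1 = "b.1")
  expect_message(res <- shared_folds(nn, labs, 0.6), "without fold label")
  expect_equal(res$n_relatives, 2L)
  expect_equal(res$n_folds, 1L)
})

test_that("shared folds grow monotonically with the cutoff", {
  D <- random_distance_matrix(30, 62)
  focus <- rownames(D)[1:8]
  others <- setdiff(rownames(D), focus)
  set.seed(63)
  labs <- setNames(sprintf("f%d", sample(1:6, 30, TRUE)), rownames(D))
  nn <- nearest_focus_distance(focus, others, D)
  grid <- seq(0.1, 0.9, by = 0.1)
  res <- lapply(grid, function(cu) shared_folds(nn, labs, cu))
  expect_true(all(diff(vapply(res, `[[`, integer(1), "n_relatives")) >= 0))
  expect_true(all(diff(vapply(res, `[[`, integer(1), "n_folds")) >= 0))
  # self-fold exclusion can only reduce the count
  for (cu in c(0.4, 0.6, 0.8)) {
    a <- shared_folds(nn, labs, cu)
    b <- shared_folds(nn, labs, cu, exclude_self = TRUE,
                      focus_folds = unique(labs[focus]))
    expect_lte(b$n_folds, a$n_folds)
  }
})

test_that("nn_ecdf builds a right-continuous step function ending at 1", {
  e1 <- nn_ecdf(c(a = 0.5))
  expect_equal(e1, data.frame(distance = 0.5, fraction = 1))

  e2 <- nn_ecdf(c(a = 0.2, b = 0.4, c = 0.4, d = 0.8))
  expect_equal(e2$distance, c(0.2, 0.4, 0.8))
  expect_equal(e2$fraction, c(0.25, 0.75, 1.0))

  set.seed(64)
  e3 <- nn_ecdf(setNames(runif(17), paste0("z", 1:17)))
  expect_equal(tail(e3$fraction, 1), 1)
  expect_error(nn_ecdf(numeric(0)), "non-empty")
})

test_that("permutation_test honours the one-tailed conventions", {
  ds <- generate_latent_dataset(latent_config(n_families = 10,
                                              members_per_family = 3,
                                              focus_families = 1L,
                                              focus_displacement = 0,
                                              seed = 65))
  ids <- rownames(ds$D)
  pt_hi <- permutation_test(ids, ds$fold_labels, ds$D, focus_size = 6,
                            n_perm = 50, observed = 1000L, seed = 5)
  expect_equal(pt_hi$p_raw, 1)

  pt_lo <- permutation_test(ids, ds$fold_labels, ds$D, focus_size = 6,
                            n_perm = 50, observed = -1L, seed = 5)
  expect_equal(pt_lo$p_raw, 0)
  expect_equal(pt_lo$p_conservative, 1 / 51)
  expect_output(print(pt_lo), "p <")

  expect_gte(pt_hi$p_conservative, pt_hi$p_raw)
  expect_error(permutation_test(ids, ds$fold_labels, ds$D, focus_size = 30,
                                n_perm = 10, observed = 0L), "smaller")
})

test_that("identical seeds reproduce the null exactly", {
  ds <- generate_latent_dataset(latent_config(n_families = 10,
                                              members_per_family = 3,
                                              focus_families = 1L,
                                              focus_displacement = 0,
                                              seed = 66))
  ids <- rownames(ds$D)
  a <- permutation_test(ids, ds$fold_labels, ds$D, 6, n_perm = 40,
                        observed = 3L, seed = 17)
  b <- permutation_test(ids, ds$fold_labels, ds$D, 6, n_perm = 40,
                        observed = 3L, seed = 17)
  expect_identical(a$null_counts, b$null_counts)
  c_ <- permutation_test(ids, ds$fold_labels, ds$D, 6, n_perm = 40,
                         observed = 3L, seed = 18)
  expect_false(identical(a$null_counts, c_$null_counts))
})

test_that("planted focus segregation yields a significant left tail", {
  ds <- generate_latent_dataset(latent_config(seed = 67))
  ids <- rownames(ds$D)
  focus <- ds$focus_ids
  nn <- nearest_focus_distance(focus, setdiff(ids, focus), ds$D)
  obs <- shared_folds(nn, ds$fold_labels, 0.6)$n_folds
  expect_equal(obs, 0L)  # displaced focus families have no close relatives
  pt <- permutation_test(ids, ds$fold_labels, ds$D,
                         focus_size = 20, n_perm = 200,
                         observed = obs, seed = 68)
  expect_lte(pt$p_conservative, 0.01)
})

test_that("null distribution TSV sums to the permutation count", {
  ds <- generate_latent_dataset(latent_config(n_families = 10,
                                              members_per_family = 3,
                                              focus_families = 1L,
                                              focus_displacement = 0,
                                              seed = 69))
  pt <- permutation_test(rownames(ds$D), ds$fold_labels, ds$D, 6,
                         n_perm = 60, observed = 2L, seed = 7)
  f <- tempfile(fileext = ".tsv")
  write_null_distribution(pt, f)
  df <- read.delim(f)
  expect_equal(sum(df$count), 60L)
})
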