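group_from <- function(mi_raw_rows, surr_rows, ...) {
  maps <- lapply(seq_along(mi_raw_rows), function(i)
    fake_map(mi_raw_rows[[i]], surr_rows[[i]], subject_id = paste0("S", i),
             age = c(3, 6, 9, 12, 18, 24, 36)[(i - 1) %% 7 + 1], ...))
  pac_group(maps)
}

test_that("group assembly requires identical grids", {
  m1 <- fake_map(0.2, 0.1)
  m2 <- fake_map(0.2, 0.1, lf = c(4, 8, 12))
  expect_error(pac_group(list(m1, m2)), "same channels")
  g <- pac_group(list(m1, m1, m1))
  expect_identical(dim(g$mi_raw), c(3L, 9L))
})

test_that("the paired t map matches the closed form and its symmetries", {
  g <- group_from(list(0.2, 0.3, 0.4), list(0.1, 0.1, 0.1))
  tp <- pac_t_map(g)
  expect_equal(unname(tp$t[1]), 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(unname(tp$t[1]), 3.464, tolerance = 1e-3)

  # identical conditions: zero-variance differences are flagged, not infinite
  g0 <- group_from(list(0.2, 0.3, 0.4), list(0.2, 0.3, 0.4))
  tp0 <- pac_t_map(g0)
  expect_true(all(tp0$zero_var))
  expect_false(any(threshold_mask(tp0)))

  # sign flip negates t, keeps p
  gneg <- group_from(list(0.1, 0.1, 0.1), list(0.2, 0.3, 0.4))
  tpn <- pac_t_map(gneg)
  expect_equal(tpn$t, -tp$t, tolerance = 1e-12)
  expect_equal(tpn$p, tp$p, tolerance = 1e-12)

  expect_error(pac_t_map(group_from(list(0.2, 0.3), list(0.1, 0.1))),
               "at least 3")
})

test_that("threshold masking is strict at alpha", {
  fake <- list(t = c(2, 2), p = c(0.049, 0.051), zero_var = c(FALSE, FALSE))
  expect_identical(threshold_mask(fake, 0.05), c(TRUE, FALSE))
})

test_that("4-connected labelling matches examples and a brute-force oracle", {
  m <- matrix(FALSE, 3, 3)
  m[1, 1] <- m[1, 2] <- m[3, 3] <- TRUE
  lab <- label_clusters(m)
  expect_identical(lab[1, 1], lab[1, 2])
  expect_true(lab[3, 3] != lab[1, 1])
  expect_identical(max(lab), 2L)

  diag2 <- matrix(FALSE, 2, 2)
  diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_identical(max(label_clusters(diag2)), 2L)

  set.seed(77)
  for (i in 1:200) {
    m <- matrix(runif(10 * 16) < 0.4, 10, 16)
    expect_true(same_partition(label_clusters(m), brute_label(m)))
  }
})

test_that("cluster masses subtract the critical t and add across cells", {
  t_crit <- qt(0.975, df = 19)
  expect_equal(t_crit, 2.093, tolerance = 1e-3)
  labs <- matrix(c(1L, 1L, 0L), 1)
  tv <- matrix(c(t_crit + 1, t_crit + 2, 0), 1)
  expect_equal(unname(cluster_masses(tv, labs, t_crit)), 3)
  expect_equal(unname(cluster_masses(matrix(t_crit + 1), matrix(1L), t_crit)),
               1)
})

test_that("flip-half is an involution on a random half of recordings", {
  g <- group_from(as.list(seq(0.2, 0.8, by = 0.1)),
                  as.list(rep(0.1, 7)))
  f <- flip_half(g, seed = 13)
  expect_length(attr(f, "flipped"), 3L)   # floor(7/2)
  pick <- attr(f, "flipped")
  expect_identical(f$mi_raw[pick, ], g$surr_mean[pick, ])
  expect_identical(f$surr_mean[pick, ], g$mi_raw[pick, ])
  f2 <- flip_half(f, seed = 13)
  attr(f2, "flipped") <- NULL
  attr(g, "flipped") <- NULL
  expect_identical(f2$mi_raw, g$mi_raw)
  expect_identical(f2$surr_mean, g$surr_mean)
})

test_that("a degenerate group yields an all-zero permutation null", {
  g <- group_from(list(0.2, 0.3, 0.4, 0.5), list(0.2, 0.3, 0.4, 0.5))
  null <- permutation_null(g, n_perm = 50, seed = 3)
  expect_true(all(null$masses == 0))
  expect_length(null$per_perm_max, 50)
})

test_that("the null distribution has 200 permutations by default", {
  g <- group_from(list(0.25, 0.3, 0.42, 0.5, 0.21), list(0.2, 0.31, 0.4, 0.45, 0.2))
  null <- permutation_null(g, seed = 5)
  expect_identical(null$n_perm, 200)
  expect_length(null$per_perm_max, 200)
  # reproducible
  null2 <- permutation_null(g, seed = 5)
  expect_identical(null$masses, null2$masses)
})

test_that("PAC+ retention keeps clusters at or above the 95th percentile", {
  clusters <- data.frame(channel = "Cz", cluster_id = 1:2,
                         n_cells = c(2L, 1L), mass = c(5, 0.5))
  labels <- c(1L, 1L, 2L, 0L)
  null <- list(masses = seq(0, 1, length.out = 101))  # 95th percentile 0.95
  pos <- pac_positive_mask(clusters, labels, null)
  expect_identical(pos$mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(pos$clusters$significant, c(TRUE, FALSE))

  # monotonicity: raising a retained cluster's mass never drops it
  clusters2 <- clusters
  clusters2$mass[1] <- clusters$mass[1] + 10
  pos2 <- pac_positive_mask(clusters2, labels, null)
  expect_true(all(pos$mask <= pos2$mask | pos$mask == pos2$mask))

  expect_error(
    pac_positive_mask(clusters, labels, list(masses = numeric(0))),
    "empty null"
  )
})

test_that("end-to-end clustering flags an injected coupled cell", {
  # strong coupling at (8, 64) on every recording, none elsewhere
  set.seed(41)
  maps <- lapply(1:8, function(i) {
    mi <- rep(0.01, 9) + rnorm(9, sd = 0.001)
    mi[5] <- 0.05 + rnorm(1, sd = 0.002)       # center cell (8, 64)
    fake_map(mi, rep(0.01, 9), subject_id = paste0("S", i))
  })
  cl <- pac_cluster(maps, seed = 19)
  cells <- cl$group$cells
  target <- cells$lf_hz == 8 & cells$hf_hz == 64
  expect_true(cl$pac_plus[target])
  expect_identical(unique(cells$channel[cl$pac_plus]), "Cz")
  expect_true(cl$fraction_selected >= 1 / 9)
})
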