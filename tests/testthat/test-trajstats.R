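planted_directions <- internal_directions

test_that("PCA recovers a planted direction and its variance fraction", {
  toy <- fx_toy()
  dirs <- planted_directions(toy$atoms, 1)
  amp <- matrix(4 * sin(seq_len(80) / 6), ncol = 1)
  trj <- make_mode_trajectory(toy$atoms, dirs, amp, noise = 0.01, seed = 2)
  # analyze without alignment interference: use all CA and no rigid motion
  fit <- traj_pca(trj)
  v1 <- fit$rotation[, 1]
  # the alignment step mixes in rigid-body compensation; overlap after
  # projecting the planted direction on the analyzed coordinates
  expect_gt(abs(sum(v1 * dirs[, 1])), 0.99)
  expect_gt(fit$var_frac[1], 0.98)
  expect_equal(sum(fit$var_frac), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$values) <= 1e-12))
})

test_that("two planted directions with 2:1 variance split recover their fractions", {
  toy <- fx_toy()
  dirs <- planted_directions(toy$atoms, 2)
  set.seed(9)
  amp <- cbind(rnorm(300, sd = sqrt(2)), rnorm(300, sd = 1))
  trj <- make_mode_trajectory(toy$atoms, dirs, amp, noise = 0, seed = 3)
  fit <- traj_pca(trj)
  expect_equal(fit$var_frac[1], 2 / 3, tolerance = 0.05)
  expect_equal(fit$var_frac[2], 1 / 3, tolerance = 0.05)
})

test_that("projection on the full PC basis reconstructs centered coordinates", {
  toy <- fx_toy()
  dirs <- planted_directions(toy$atoms, 2)
  amp <- cbind(sin(seq_len(20)), cos(seq_len(20) / 2))
  trj <- make_mode_trajectory(toy$atoms, dirs, amp, noise = 0.05, seed = 4)
  fit <- traj_pca(trj)
  pr <- project_frames(trj, fit, k = seq_along(fit$values))
  # rebuild frame 7 from scores
  sc <- pr$value[pr$frame == 7]
  rec <- fit$mean + as.numeric(fit$rotation %*% sc)
  fl <- dimerflex:::frame_list(trj)
  aligned <- dimerflex:::align_frames(fl$frames, fit$ref, fit$fit_idx)
  expect_equal(rec, as.numeric(t(aligned[[7]][fit$an_idx, ])), tolerance = 1e-6)
})

test_that("projections behave under mean and mirror", {
  toy <- fx_toy()
  dirs <- planted_directions(toy$atoms, 1)
  amp <- matrix(seq(-3, 3, length.out = 40), ncol = 1)
  trj <- make_mode_trajectory(toy$atoms, dirs, amp, seed = 6)
  fit <- traj_pca(trj)
  # the mean structure projects to 0
  mean_frame <- matrix(0, nrow(toy$atoms), 3)
  mean_frame[, ] <- Reduce(`+`, dimerflex:::frame_list(trj)$frames) / 40
  m <- dimerflex:::frames_to_atoms(toy$atoms, list(mean_frame))
  pm <- project_frames(m, fit, k = 1)
  expect_lt(abs(pm$value), 1e-4)
  # amplitude-negated trajectory projects with flipped sign
  trj2 <- make_mode_trajectory(toy$atoms, dirs, -amp, seed = 6)
  p1 <- project_frames(trj, fit, k = 1)
  p2 <- project_frames(trj2, fit, k = 1)
  expect_equal(p2$value, -p1$value, tolerance = 1e-3)
})

test_that("geosim frames span a comparable range on surrogate-ensemble PCs", {
  toy <- fx_toy()
  modes <- fx_modes()
  # surrogate ensemble wobbling along modes 7 and 8
  dirs <- modes$vectors[, 7:8]
  set.seed(12)
  amp <- cbind(rnorm(120, sd = 2), rnorm(120, sd = 1.2))
  surr <- make_mode_trajectory(toy$atoms, dirs, amp, noise = 0.05, seed = 8)
  fit <- traj_pca(surr)
  pr_geo <- project_frames(fx_geosim(7, "parallel"), fit, k = 1)
  rng_geo <- diff(range(pr_geo$value))
  rng_md <- diff(range(project_frames(surr, fit, k = 1)$value))
  expect_gt(rng_geo / rng_md, 0.3)
})

test_that("generalized dot products compare PC subspaces", {
  expect_equal(generalized_dot(c(1, 0, 0), c(1, 0, 0)), 1)
  expect_equal(generalized_dot(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_error(generalized_dot(1:3, 1:4), "length")
  # a rotated 2D basis covers each original vector exactly once
  set.seed(14)
  q <- qr.Q(qr(matrix(rnorm(60 * 2), ncol = 2)))
  th <- 0.7
  rot <- q %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(subspace_coverage(q[, 1], rot), 1, tolerance = 1e-9)
  expect_equal(subspace_coverage(q[, 2], rot), 1, tolerance = 1e-9)
})

test_that("cosine content flags diffusive series and clears structured ones", {
  n <- 1000
  t <- seq_len(n)
  expect_equal(cosine_content(cos(pi * (t - 0.5) / n)), 1, tolerance = 1e-9)
  # a full-period cosine is orthogonal to the half-period probe (its
  # content concentrates at index 2 instead)
  expect_lt(cosine_content(cos(2 * pi * (t - 0.5) / n)), 1e-6)
  expect_equal(cosine_content(cos(2 * pi * (t - 0.5) / n), i = 2), 1,
               tolerance = 1e-9)
  set.seed(15)
  expect_lt(cosine_content(rnorm(n)), 0.2)
  expect_equal(cosine_content(rep(3, 100)), 0)
  expect_error(cosine_content(1:3), "short")
  # bounded in [0, 1]
  for (s in 1:10) {
    set.seed(s)
    cc <- cosine_content(cumsum(rnorm(200)))
    expect_gte(cc, 0)
    expect_lte(cc, 1)
  }
})

test_that("windowed Pearson correlations behave and recover ground truth", {
  x <- seq_len(500) + rnorm(500)
  w <- windowed_pearson(x, -x, window = 50)
  expect_equal(w$windows$r, rep(-1, nrow(w$windows)))
  expect_equal(w$overall, -1)
  # independent noise: mean windowed R near zero
  set.seed(16)
  big <- windowed_pearson(rnorm(1e5), rnorm(1e5), window = 1e3)
  expect_lt(abs(big$mean_r), 0.01)
  # windowed R of (x, x) is 1 everywhere; negation antisymmetric
  w2 <- windowed_pearson(x, x, window = 50, stride = 25)
  expect_equal(w2$windows$r, rep(1, nrow(w2$windows)))
  s <- make_correlated_series(2000, 0.5, seed = 4)
  wp <- windowed_pearson(s$x, s$y, window = 200)
  wn <- windowed_pearson(s$x, -s$y, window = 200)
  expect_equal(wn$windows$r, -wp$windows$r)
  # zero-variance window reported missing, never 0
  z <- windowed_pearson(c(rep(1, 60), rnorm(60)), rnorm(120), window = 60)
  expect_true(is.na(z$windows$r[1]))
  expect_false(is.na(z$windows$r[2]))
  # burn-in exclusion drops the prefix
  wb <- windowed_pearson(x, -x, window = 50, burn_in = 100)
  expect_equal(min(wb$windows$start), 101)
})

test_that("frame clustering separates a two-state trajectory", {
  toy <- fx_toy()
  oc <- make_open_closed_pair(toy, 35)
  set.seed(17)
  mk <- function(base, k) lapply(seq_len(k), function(i) {
    coords(base) + matrix(rnorm(3 * nrow(base), sd = 0.15), ncol = 3)
  })
  frames <- c(mk(oc$open, 6), mk(oc$closed, 6))
  truth <- rep(1:2, each = 6)
  traj <- dimerflex:::frames_to_atoms(toy$atoms, frames)
  cl <- cluster_frames(traj, 2, fit_sel = list(name = "CA", res_seq = 1:60),
                       cluster_sel = list(name = "CA", res_seq = 64:88))
  tab <- table(cl$assignments$cluster, truth)
  expect_equal(max(tab[1, ]) + max(tab[2, ]), 12) # perfect up to relabel
  # permuted frame order yields the same partition up to relabeling
  perm <- sample(12)
  cl2 <- cluster_frames(dimerflex:::frames_to_atoms(toy$atoms, frames[perm]), 2,
                        fit_sel = list(name = "CA", res_seq = 1:60),
                        cluster_sel = list(name = "CA", res_seq = 64:88))
  back <- integer(12)
  back[perm] <- cl2$assignments$cluster
  expect_equal(length(unique(paste(cl$assignments$cluster, back))), 2)
  # single cluster: one medoid, all assigned to it
  c1 <- cluster_frames(traj, 1)
  expect_equal(unique(c1$assignments$cluster), 1L)
  expect_length(c1$medoids, 1)
  # duplicated frames: zero within-cluster distance
  dup <- dimerflex:::frames_to_atoms(toy$atoms,
                                     rep(list(coords(oc$open)), 4))
  cd <- cluster_frames(dup, 1)
  expect_equal(cd$avg_dist$mean_rmsd, 0)
  expect_error(cluster_frames(traj, 0), ">= 1")
  expect_error(cluster_frames(traj, 50), "fewer frames")
})
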