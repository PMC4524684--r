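# a fully tethered 8-site blob on a lattice (no steric contacts): one
# rigid cluster
rigid_blob <- function() {
  set.seed(2)
  xyz <- as.matrix(expand.grid(x = c(0, 3.8), y = c(0, 3.8), z = c(0, 3.8)))
  xyz <- xyz + matrix(runif(24, -0.2, 0.2), ncol = 3)
  at <- ca_atoms(xyz)
  pairs <- t(utils::combn(8, 2))
  cons <- tibble(i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
                 kind = "hydrophobic", bars = 1L, energy = NA_real_)
  net <- fake_network(at, cons)
  list(atoms = at, net = net, rig = pebble_game(net))
}

test_that("templates cover rigid clusters and joints", {
  rb <- rigid_blob()
  tpl <- build_templates(rb$atoms, rb$rig, rb$net)
  expect_equal(length(tpl$templates), 1)
  expect_equal(sort(tpl$templates[[1]]), 1:8)
  # two rigid clusters joined by one variable bond share the junction atoms
  tet <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 3.3, 0), c(1.9, 1.1, 3.1))
  xyz <- rbind(tet, sweep(tet, 2, c(7.5, 0, 0), `+`))
  at <- ca_atoms(xyz)
  cons <- dplyr::bind_rows(
    tibble(i = c(1L, 1L, 1L, 2L, 2L, 3L), j = c(2L, 3L, 4L, 3L, 4L, 4L),
           kind = "hydrophobic", bars = 1L, energy = NA_real_),
    tibble(i = c(5L, 5L, 5L, 6L, 6L, 7L), j = c(6L, 7L, 8L, 7L, 8L, 8L),
           kind = "hydrophobic", bars = 1L, energy = NA_real_),
    tibble(i = 4L, j = 5L, kind = "covalent", bars = 1L, energy = NA_real_)
  )
  net <- fake_network(at, cons)
  rig <- pebble_game(net)
  tpl2 <- build_templates(at, rig, net)
  expect_equal(length(tpl2$templates), 2)
  shared <- Reduce(intersect, tpl2$templates)
  expect_setequal(shared, c(4, 5))
  # reference geometry equals the input: zero violation at step 0
  steric <- dimerflex:::steric_setup(at, net, 0.85)
  expect_lt(dimerflex:::geo_violation(coords(at), tpl2, steric), 1e-9)
})

test_that("relaxation restores a perturbed satisfied configuration", {
  rb <- rigid_blob()
  tpl <- build_templates(rb$atoms, rb$rig, rb$net)
  cfg <- geosim_config()
  xyz <- coords(rb$atoms)
  xyz[3, ] <- xyz[3, ] + c(0.05, -0.03, 0.02)
  out <- relax_positions(xyz, tpl, rb$net, cfg)
  expect_true(out$converged)
  expect_lte(out$violation, cfg$relax_tolerance)
  # overlapping nonbonded atoms get pushed apart to near contact
  toy <- fx_toy()
  xyz2 <- coords(toy$atoms)
  a <- which(toy$atoms$chain == "A" & toy$atoms$res_seq == fx_toy()$params$res_tip)
  b <- which(toy$atoms$chain == "B" & toy$atoms$res_seq == fx_toy()$params$res_tip)
  xyz2[b, ] <- xyz2[a, ] + c(0.5, 0, 0) # deep overlap
  cfg2 <- geosim_config(max_relax_iters = 300)
  out2 <- relax_positions(xyz2, fx_tpl(), fx_net(), cfg2)
  d_ab <- sqrt(sum((out2$xyz[a, ] - out2$xyz[b, ])^2))
  contact <- 2 * 1.7 * cfg2$steric_scale
  expect_gte(d_ab, contact - cfg2$relax_tolerance)
  # an impossible drag with a single iteration reports non-convergence
  # (overlapping toy templates cannot reconcile a 10 A excursion in one pass)
  xyz3 <- coords(toy$atoms)
  tip <- which(toy$atoms$chain == "A" &
                 toy$atoms$res_seq == fx_toy()$params$res_tip)
  xyz3[tip, ] <- xyz3[tip, ] + c(10, 0, 0)
  out3 <- relax_positions(xyz3, fx_tpl(), fx_net(),
                          geosim_config(max_relax_iters = 1))
  expect_false(out3$converged)
})

test_that("zero steps and zero drive are fixed points", {
  toy <- fx_toy()
  zero_bias <- matrix(0, nrow(toy$atoms), 3)
  trj0 <- run_geosim(toy$atoms, zero_bias, fx_tpl(), fx_net(),
                     geosim_config(max_steps = 0))
  expect_equal(length(trj0$frames), 1)
  expect_false(trj0$jammed)
  expect_equal(trj0$frames[[1]], coords(toy$atoms))
  trj1 <- run_geosim(toy$atoms, zero_bias, fx_tpl(), fx_net(),
                     geosim_config(max_steps = 5, random_step = 0))
  expect_equal(trj1$frames[[length(trj1$frames)]], coords(toy$atoms),
               tolerance = 1e-12)
})

test_that("a pure translation bias drifts a rigid cluster without distortion", {
  rb <- rigid_blob()
  tpl <- build_templates(rb$atoms, rb$rig, rb$net)
  bias <- matrix(rep(c(0.05, 0, 0), each = 8), ncol = 3)
  trj <- run_geosim(rb$atoms, bias, tpl, rb$net,
                    geosim_config(bias_step = 0.05, random_step = 0,
                                  max_steps = 100, save_interval = 50))
  last <- trj$frames[[length(trj$frames)]]
  expect_false(trj$jammed)
  # centroid drifted along +x by ~steps * step
  drift <- colMeans(last) - colMeans(coords(rb$atoms))
  expect_gt(drift[1], 4)
  expect_lt(abs(drift[2]), 0.2)
  # internal geometry preserved within tolerance
  d0 <- dist(coords(rb$atoms))
  d1 <- dist(last)
  expect_lt(max(abs(d1 - d0)), 2 * geosim_config()$relax_tolerance)
})

test_that("parallel and antiparallel runs take opposite first steps", {
  toy <- fx_toy()
  bias <- atomize_bias(mode_vector(fx_modes(), 7), toy$atoms, step = 0.05)
  cfg <- function(dir) geosim_config(bias_step = 0.05, random_step = 0.01,
                                     max_steps = 1, save_interval = 1,
                                     direction = dir, seed = 123)
  tp <- run_geosim(toy$atoms, bias, fx_tpl(), fx_net(), cfg("parallel"))
  ta <- run_geosim(toy$atoms, bias, fx_tpl(), fx_net(), cfg("antiparallel"))
  bvec <- as.numeric(bias)
  dp <- sum((as.numeric(tp$frames[[length(tp$frames)]]) - as.numeric(coords(toy$atoms))) * as.numeric(t(bias)))
  dp2 <- sum(as.numeric(t(tp$frames[[length(tp$frames)]] - coords(toy$atoms))) * as.numeric(t(bias)))
  da2 <- sum(as.numeric(t(ta$frames[[length(ta$frames)]] - coords(toy$atoms))) * as.numeric(t(bias)))
  expect_gt(dp2, 0)
  expect_lt(da2, 0)
})

test_that("anti-symmetric bias closes one cleft and opens the other until useful amplitude", {
  toy <- fx_toy()
  trj <- fx_geosim(7, "parallel")
  ms <- tidyr::pivot_wider(measure_series(trj, toy$sites["intersite"]),
                           names_from = "measure", values_from = "value")
  # opposite monotone trends over the early, pre-curving part of the sweep
  half <- ms[seq_len(ceiling(nrow(ms) / 2)), ]
  expect_gt(abs(half$d_AB[nrow(half)] - half$d_AB[1]), 3)
  expect_lt(cor(half$d_AB, half$d_BA), -0.5)
  # every emitted frame satisfies the relaxation tolerance
  expect_true(all(trj$stats$violation <= trj$config$relax_tolerance + 1e-9))
  # covalent bond lengths stay within tolerance along the trajectory
  bonds <- dimerflex:::network_bonds(fx_net())
  for (f in trj$frames[c(1, length(trj$frames))]) {
    d <- sqrt(rowSums((f[bonds$i, ] - f[bonds$j, ])^2))
    d0 <- sqrt(rowSums((coords(toy$atoms)[bonds$i, ] -
                          coords(toy$atoms)[bonds$j, ])^2))
    expect_lt(max(abs(d - d0)), 2 * trj$config$relax_tolerance)
  }
})

test_that("driving the clefts closed past contact jams", {
  toy <- fx_toy()
  # tangent field of the cleft-closing hinge rotation on both chains: the
  # tips are driven into the partner cores, a steric wall with no escape
  xyz <- coords(toy$atoms)
  bias <- matrix(0, nrow(toy$atoms), 3)
  for (ch in c("A", "B")) {
    hg <- toy$hinge[[ch]]
    idx <- which(toy$atoms$chain == ch & toy$atoms$res_seq %in% hg$moving)
    for (i in idx) {
      bias[i, ] <- -dimerflex:::pracma_cross(hg$axis, xyz[i, ] - hg$origin)
    }
  }
  bias <- bias * 0.06 / sqrt(mean(rowSums(bias^2)))
  trj <- run_geosim(toy$atoms, bias, fx_tpl(), fx_net(),
                    geosim_config(bias_step = 0.06, random_step = 0.02,
                                  max_steps = 800, save_interval = 25,
                                  max_relax_iters = 40, jam_patience = 15,
                                  seed = 3))
  expect_true(trj$jammed)
  expect_true(is.finite(trj$jam_step))
  # amplitude before jamming is finite and the clefts closed substantially
  w <- tidyr::pivot_wider(measure_series(trj, toy$sites["intersite"]),
                          names_from = "measure", values_from = "value")
  expect_lt(min(w$d_AB), 10)
  expect_gt(min(w$d_AB), 3)
  # the emitted frames all satisfy constraints
  expect_true(all(trj$stats$converged))
})
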