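atoms_xyz <- function(xyz, name, element, res_seq = seq_len(nrow(xyz)),
                      res_name = "GLY", chain = "A") {
  tibble(
    model = 1L, serial = seq_len(nrow(xyz)), name = name, alt_loc = "",
    res_name = res_name, chain = chain, res_seq = as.integer(res_seq),
    i_code = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    element = element
  )
}

test_that("covalent detection follows element-distance rules", {
  at <- atoms_xyz(rbind(c(0, 0, 0), c(1.5, 0, 0), c(4.0, 0, 0)),
                  name = c("C1", "C2", "C3"), element = "C", res_seq = c(1, 1, 1))
  bonds <- detect_covalent(at)
  expect_equal(nrow(bonds), 1) # 1.5 A bonded, 2.5 A not
  expect_equal(unname(c(bonds$i, bonds$j)), c(1, 2))
  ss <- atoms_xyz(rbind(c(0, 0, 0), c(2.05, 0, 0), c(10, 0, 0)),
                  name = c("SG", "SG", "CA"), element = c("S", "S", "C"),
                  res_seq = c(1, 2, 3))
  expect_true(any(detect_covalent(ss)$i == 1 & detect_covalent(ss)$j == 2))
  # coarse: consecutive Calpha at 3.8 A are chain-bonded
  co <- detect_covalent(ca_atoms(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 1, 0))))
  expect_equal(nrow(co), 2)
  expect_false(any(co$peptide))
  # an atom with absurdly many bonds signals corruption
  blob <- atoms_xyz(matrix(rnorm(3 * 12, sd = 0.3), ncol = 3),
                    name = paste0("C", 1:12), element = "C", res_seq = rep(1, 12))
  expect_error(detect_covalent(blob), "corrupt")
})

test_that("hydrogen-bond energies follow the distance-angle well", {
  mk <- function(d_on, theta_dev) {
    # antecedent C, donor N, H along x, acceptor O at distance d with the
    # D-H...A axis bent by theta_dev degrees
    hx <- c(1.01, 0, 0)
    dir <- c(cos(theta_dev * pi / 180), sin(theta_dev * pi / 180), 0)
    atoms_xyz(rbind(c(-0.7, 1.0, 0), c(0, 0, 0), hx, hx + (d_on - 1.01) * dir),
              name = c("C", "N", "H", "O"),
              element = c("C", "N", "H", "O"), res_seq = c(1, 1, 1, 5))
  }
  # ideal near-linear geometry at the 2.8 A equilibrium: E = -D0 = -8
  ideal <- detect_hbonds(mk(2.8, 0))
  expect_equal(nrow(ideal), 1)
  expect_equal(ideal$energy, -8, tolerance = 0.05)
  expect_lt(ideal$energy, -2) # retained at the default cutoff
  # long 4.5 A contact is too weak for the -2 kcal/mol cutoff
  long <- detect_hbonds(mk(4.5, 0))
  expect_true(nrow(long) == 0 || all(long$energy > -2))
  # closed-form weak-well value at 4.5 A
  expect_equal(8 * (5 * (2.8 / 4.5)^12 - 6 * (2.8 / 4.5)^10), -0.285,
               tolerance = 0.01)
  # bending the donor angle to 90 degrees kills the bond
  bent <- detect_hbonds(mk(2.8, 90))
  expect_true(nrow(bent) == 0 || all(bent$energy > -0.5))
  # monotone penalty in the angular term
  e45 <- detect_hbonds(mk(2.8, 45))$energy
  expect_gt(e45, ideal$energy)
  expect_lt(e45, 0)
})

test_that("hydrophobic tethers connect only C/S atoms of different residues", {
  at <- atoms_xyz(rbind(c(0, 0, 0), c(3.6, 0, 0), c(0, 3.4, 0), c(8, 8, 8)),
                  name = c("CB", "CG", "ND", "CD"),
                  element = c("C", "C", "N", "C"), res_seq = c(1, 2, 3, 4))
  th <- detect_hydrophobic(at)
  expect_true(any(th$i == 1 & th$j == 2)) # C-C at vdW sum + 0.2
  expect_false(any(th$i == 3 | th$j == 3)) # nitrogen never tethers
  same <- atoms_xyz(rbind(c(0, 0, 0), c(3.6, 0, 0)),
                    name = c("CB", "CG"), element = "C", res_seq = c(1, 1))
  expect_equal(nrow(detect_hydrophobic(same)), 0) # same residue excluded
})

test_that("the energy cutoff selects nested hydrogen-bond sets", {
  pep <- fx("pep", make_toy_peptide(10))
  suppressWarnings({
    strong <- build_constraint_network(pep, e_cut = -2)
    weak <- build_constraint_network(pep, e_cut = -0.4)
    none <- build_constraint_network(pep, e_cut = -Inf)
  })
  key <- function(net) {
    hb <- dplyr::filter(net$constraints, kind == "hbond")
    paste(hb$i, hb$j)
  }
  expect_true(all(key(strong) %in% key(weak)))
  expect_gt(length(key(weak)), length(key(strong)))
  expect_equal(length(key(none)), 0)
  expect_true(all(dplyr::filter(strong$constraints, kind == "hbond")$energy <= -2))
})

test_that("pebble counts match Maxwell counting on tiny frameworks", {
  two_bars <- tibble(i = c(1L, 2L), j = c(2L, 3L), bars = 1L)
  expect_equal(dimerflex:::pebble_run(3, two_bars, k = 3)$floppy, 1)
  tri <- rbind(two_bars, tibble(i = 1L, j = 3L, bars = 1L))
  r <- dimerflex:::pebble_run(3, tri, k = 3)
  expect_equal(r$floppy, 0)
  expect_equal(r$redundant, 0)
})

test_that("pebble floppy counts equal the Jacobian rank oracle", {
  variants <- c("floppy", "redundant", "isostatic")
  for (s in 1:60) {
    n <- 6 + (s %% 7)
    fw <- make_framework(n, seed = 1000 + s, variant = variants[s %% 3 + 1])
    run <- dimerflex:::pebble_run(n, fw$edges, k = 3)
    expect_equal(run$floppy, rank_floppy(fw),
                 info = sprintf("framework seed %d", 1000 + s))
  }
})

test_that("pebble results are insertion-order invariant and F is monotone", {
  # independent frameworks: any insertion order accepts every bar
  fw <- make_framework(10, seed = 77, variant = "floppy")
  f0 <- dimerflex:::pebble_run(10, fw$edges, k = 3)$floppy
  set.seed(5)
  for (r in 1:5) {
    fs <- dimerflex:::pebble_run(10, fw$edges[sample(nrow(fw$edges)), ], k = 3)
    expect_equal(fs$floppy, f0)
  }
  # body-bar multigraphs are matroidal: order invariant including redundancy
  set.seed(8)
  ed <- tibble(i = sample(1:6, 25, TRUE), j = sample(1:6, 25, TRUE),
               bars = sample(1:6, 25, TRUE))
  ed <- ed[ed$i != ed$j, ]
  ed[, c("i", "j")] <- tibble(i = pmin(ed$i, ed$j), j = pmax(ed$i, ed$j))
  fb <- dimerflex:::pebble_run(6, ed, k = 6)$floppy
  for (r in 1:5) {
    expect_equal(dimerflex:::pebble_run(6, ed[sample(nrow(ed)), ], k = 6)$floppy, fb)
  }
  # floppy count never increases as constraints are added one at a time
  fw2 <- make_framework(9, seed = 21, variant = "redundant")
  f_seq <- sapply(seq_len(nrow(fw2$edges)), function(m) {
    dimerflex:::pebble_run(9, fw2$edges[seq_len(m), ], k = 3)$floppy
  })
  expect_true(all(diff(f_seq) <= 0))
})

test_that("the toy dimer decomposes into its designed rigid units", {
  toy <- fx_toy()
  rig <- fx_rig()
  lab <- dplyr::left_join(
    dplyr::bind_cols(rig$clusters, toy$atoms[, c("chain", "res_seq")]),
    toy$domains, by = c("chain", "res_seq"))
  # both interlocked cores form one rigid cluster
  cores <- dplyr::filter(lab, domain == "core")
  expect_equal(length(unique(cores$cluster)), 1)
  # each mobile domain is (a superset of) one rigid cluster
  for (ch in c("A", "B")) {
    mob <- dplyr::filter(lab, domain == "mobile", chain == ch)
    expect_equal(length(unique(mob$cluster)), 1)
    expect_false(unique(mob$cluster) %in% cores$cluster)
  }
  expect_gt(rig$floppy, 0)
  # linker bonds are variable, intra-domain bonds locked
  bl <- dplyr::mutate(rig$bond_labels,
                      r1 = toy$atoms$res_seq[i], r2 = toy$atoms$res_seq[j])
  linker <- dplyr::filter(bl, r1 >= 60, r2 <= 64)
  expect_true(all(!linker$locked))
  interior <- dplyr::filter(bl, r2 <= 59 | r1 >= 64)
  expect_gt(mean(interior$locked), 0.95)
})

test_that("the decomposition is invariant under rigid transforms", {
  toy <- fx_toy()
  R <- dimerflex:::rotation_about_axis(c(1, 1, 1), 63)
  rot <- set_coords(toy$atoms, sweep(coords(toy$atoms) %*% t(R), 2, c(3, 4, 5), `+`))
  net2 <- build_constraint_network(rot, domains = toy$domains)
  expect_equal(net2$constraints[, c("i", "j", "kind")],
               fx_net()$constraints[, c("i", "j", "kind")])
  rig2 <- pebble_game(net2)
  expect_equal(rig2$floppy, fx_rig()$floppy)
  expect_equal(rig2$clusters, fx_rig()$clusters)
})

test_that("an all-atom helix rigidifies through its hydrogen bonds", {
  pep <- fx("pep", make_toy_peptide(10))
  net <- build_constraint_network(pep)
  expect_equal(net$mode, "bodybar")
  hb <- dplyr::filter(net$constraints, kind == "hbond")
  expect_gte(nrow(hb), 4) # helical i,i+4 ladder
  rig <- pebble_game(net)
  expect_equal(rig$mode, "bodybar")
  sizes <- table(rig$clusters$cluster)
  expect_gt(max(sizes), nrow(pep) / 2)
  # without hydrogen bonds the backbone is floppier
  rig0 <- pebble_game(build_constraint_network(pep, e_cut = -Inf))
  expect_gt(rig0$floppy, rig$floppy)
})
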