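suppressMessages({
  library(dplyr)
  library(tibble)
  library(tidyr)
})

# Shared fixture cache: heavyweight objects (toy dimer, its constraint
# network, rigidity decomposition, modes, geosim runs) are computed once per
# test session.
.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_toy <- function() fx("toy", make_toy_dimer(seed = 1))
fx_net <- function() fx("net", build_constraint_network(fx_toy()$atoms,
                                                        domains = fx_toy()$domains))
fx_rig <- function() fx("rig", pebble_game(fx_net()))
fx_tpl <- function() fx("tpl", build_templates(fx_toy()$atoms, fx_rig(), fx_net()))
fx_modes <- function() fx("modes", compute_modes(build_enm(fx_toy()$atoms)))

fx_geosim <- function(mode, direction, steps = 300, seed = 7) {
  key <- sprintf("geo_%s_%s_%d_%d", mode, direction, steps, seed)
  fx(key, {
    toy <- fx_toy()
    bias <- atomize_bias(mode_vector(fx_modes(), mode), toy$atoms, step = 0.05)
    cfg <- geosim_config(bias_step = 0.05, random_step = 0.02,
                         max_steps = steps, save_interval = 20,
                         direction = direction, seed = seed)
    run_geosim(toy$atoms, bias, fx_tpl(), fx_net(), cfg)
  })
}

# intersite measures of parallel + antiparallel branches of one mode,
# concatenated into a single sweep (antiparallel branch reversed)
fx_mode_sweep <- function(mode) {
  toy <- fx_toy()
  mp <- measure_series(fx_geosim(mode, "parallel"), toy$sites["intersite"])
  ma <- measure_series(fx_geosim(mode, "antiparallel"), toy$sites["intersite"])
  wide <- function(m) tidyr::pivot_wider(m, names_from = "measure",
                                         values_from = "value")
  rbind(wide(ma)[rev(seq_len(nrow(wide(ma)))), ], wide(mp))
}

# Bare Calpha atom tables from a coordinate matrix.
ca_atoms <- function(xyz, chain = "A", res_seq = seq_len(nrow(xyz))) {
  n <- nrow(xyz)
  tibble(
    model = 1L, serial = seq_len(n), name = "CA", alt_loc = "",
    res_name = "GLY", chain = chain, res_seq = as.integer(res_seq),
    i_code = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, element = "C"
  )
}

# Random generic frameworks built by Henneberg-style 0-extensions (start
# from K4, attach each new vertex by 3 edges). Subgraphs of such graphs are
# generically independent, so deleting edges gives known floppy counts, and
# edges appended once the isostatic graph is complete are provably
# redundant. On this class the greedy sparsity game equals generic
# bar-joint rank.
make_framework <- function(n, seed, variant = c("floppy", "redundant", "isostatic")) {
  variant <- match.arg(variant)
  set.seed(seed)
  edges <- t(utils::combn(4, 2))
  if (n > 4) for (v in 5:n) edges <- rbind(edges, cbind(sample(v - 1, 3), v))
  if (variant == "floppy") {
    d <- sample(1:4, 1)
    edges <- edges[-sample(nrow(edges), d), , drop = FALSE]
  } else if (variant == "redundant") {
    all_pairs <- t(utils::combn(n, 2))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    avail <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% key, ,
                       drop = FALSE]
    extra <- sample(1:3, 1)
    edges <- rbind(edges, avail[sample(nrow(avail), extra), , drop = FALSE])
  }
  xyz <- matrix(stats::rnorm(3 * n), ncol = 3) * 5
  list(xyz = xyz,
       edges = tibble(i = as.integer(pmin(edges[, 1], edges[, 2])),
                      j = as.integer(pmax(edges[, 1], edges[, 2])),
                      bars = 1L))
}

# Independent numerical oracle: floppy modes = 3N - 6 - rank of the
# distance-constraint Jacobian at the realized coordinates.
rank_floppy <- function(fw, tol = 1e-6) {
  n <- nrow(fw$xyz)
  J <- matrix(0, nrow(fw$edges), 3 * n)
  for (r in seq_len(nrow(fw$edges))) {
    i <- fw$edges$i[r]
    j <- fw$edges$j[r]
    d <- fw$xyz[i, ] - fw$xyz[j, ]
    J[r, (3 * i - 2):(3 * i)] <- d
    J[r, (3 * j - 2):(3 * j)] <- -d
  }
  sv <- svd(J)$d
  3 * n - 6 - sum(sv > tol * max(sv))
}

# Orthonormal displacement directions orthogonal to the rigid-body
# subspace of `atoms` (so trajectory alignment does not eat the planted
# signal in PCA recovery tests).
internal_directions <- function(atoms, m = 2, seed = 5) {
  xyz <- coords(atoms)
  n <- nrow(xyz)
  cen <- sweep(xyz, 2, colMeans(xyz))
  rigid <- matrix(0, 3 * n, 6)
  for (a in 1:3) rigid[seq(a, 3 * n, by = 3), a] <- 1
  axes <- diag(3)
  for (a in 1:3) {
    rot <- t(apply(cen, 1, function(r) {
      c(axes[a, 2] * r[3] - axes[a, 3] * r[2],
        axes[a, 3] * r[1] - axes[a, 1] * r[3],
        axes[a, 1] * r[2] - axes[a, 2] * r[1])
    }))
    rigid[, 3 + a] <- as.numeric(t(rot))
  }
  rigid <- qr.Q(qr(rigid))
  set.seed(seed)
  raw <- matrix(rnorm(3 * n * m), ncol = m)
  raw <- raw - rigid %*% crossprod(rigid, raw)
  qr.Q(qr(raw))
}

# minimal constraint-network object for template tests
fake_network <- function(atoms, constraints, mode = "point") {
  structure(list(atoms = atoms, constraints = constraints, mode = mode,
                 e_cut = -2), class = "constraint_network")
}
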