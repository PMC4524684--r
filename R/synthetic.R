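# Synthetic fixtures with known ground truth: a C2-symmetric two-chain,
# two-domain "large core + small mobile domain" dimer with a designed hinge,
# plus mode-driven trajectories and correlated scalar series. Everything is
# seed-deterministic so the full pipeline is testable without any downloads.

# Boustrophedon walk over a rectangular grid: consecutive nodes are always
# exactly `spacing` apart, so the walk doubles as a chain trace.
snake_grid <- function(n, dims = c(4, 4, 4), spacing = 3.8) {
  stopifnot(n >= 1, n <= prod(dims))
  pos <- matrix(0, prod(dims), 3)
  i <- 0L
  for (zi in seq_len(dims[3])) {
    ys <- seq_len(dims[2])
    if (zi %% 2 == 0) ys <- rev(ys)
    for (k in seq_along(ys)) {
      yi <- ys[k]
      xs <- seq_len(dims[1])
      # flip x direction on every other row of the boustrophedon
      if ((zi + k) %% 2 == 0) xs <- rev(xs)
      for (xi in xs) {
        i <- i + 1L
        pos[i, ] <- c(xi - 1, yi - 1, zi - 1) * spacing
      }
    }
  }
  pos[seq_len(n), , drop = FALSE]
}

C2_Z <- diag(c(-1, -1, 1)) # two-fold rotation about the dimer (z) axis

toy_atom_tbl <- function(xyz, chain, res_seq) {
  n <- nrow(xyz)
  tibble(
    model = 1L, serial = seq_len(n), name = "CA", alt_loc = "",
    res_name = "GLY", chain = chain, res_seq = as.integer(res_seq),
    i_code = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, element = "C"
  )
}

#' Generate a synthetic two-domain homodimer with a designed hinge
#'
#' Builds a Calpha-resolution, C2-symmetric dimer: two interlocked rigid core
#' domains form the main body, and each chain carries a small mobile domain on
#' a short zig-zag linker, hovering over the partner chain's core. This
#' creates two equivalent binding clefts whose opening and closing is governed
#' by rotation of the mobile domains about their hinges, mimicking the
#' architecture of domain-swapped homodimeric enzymes. Measure sites (cleft
#' tip, cleft partner, hinge triple, distance-RMS pairs) are designated at
#' construction and returned as ready-to-use measure specs.
#'
#' The hinge geometry is exact by design: the pre-hinge site, the hinge
#' centre, and the mobile tip all lie in the plane perpendicular to the hinge
#' axis, so a rigid rotation of the mobile domain by `theta` degrees changes
#' the hinge-angle measure by exactly `theta`.
#'
#' @param n_core residues per core domain (max 64).
#' @param n_mobile residues per mobile domain (max 27).
#' @param seed integer seed for the small coordinate jitter that keeps the
#'   lattice generic.
#' @param jitter amplitude (Angstrom) of the uniform jitter.
#' @param spacing Calpha-Calpha spacing of the lattice walk (Angstrom).
#' @return an object of class `toy_dimer`: a list with `atoms` (tidy atom
#'   table), `sites` (list of measure specs: `intersite`, `hinge`, `cleft`,
#'   `drms`), `domains` (tibble chain/res_seq/domain), `hinge` (per-chain
#'   rotation origin and axis), and the generating parameters.
#' @examples
#' toy <- make_toy_dimer()
#' measure_sites(toy$atoms, toy$sites$intersite)
#' @export
make_toy_dimer <- function(n_core = 60, n_mobile = 25, seed = 1,
                           jitter = 0.25, spacing = 3.8) {
  stopifnot(n_core >= 12, n_core <= 64, n_mobile >= 8, n_mobile <= 27)
  s <- spacing

  core <- snake_grid(n_core, c(4, 4, 4), s)
  # centre the core so the dimer axis (z) runs between the two cores with a
  # face-to-face gap wide enough to avoid steric contact, then make sure the
  # chain walk ENDS on the inner face (where the linker attaches)
  core[, 1] <- core[, 1] + 2.8
  core[, 2] <- core[, 2] - 1.5 * s
  core[, 3] <- core[, 3] - 3 * s
  attach <- core[n_core, ]
  if (attach[1] > mean(range(core[, 1]))) {
    core[, 1] <- sum(range(core[, 1])) - core[, 1]
    attach <- core[n_core, ]
  }
  top_z <- max(core[, 3])

  # zig-zag linker 60 -> L1 -> H -> L3 -> mobile#1: bond directions have
  # alternating y components (so torsional axes are generic, giving the
  # mobile domain real tipping freedom), but the hinge centre H returns to
  # the attachment's y plane
  b1 <- s * c(0.15, 0.35, sqrt(1 - 0.15^2 - 0.35^2))
  b2 <- s * c(0.15, -0.35, sqrt(1 - 0.15^2 - 0.35^2))
  b3 <- s * c(-0.15, 0.35, sqrt(1 - 0.15^2 - 0.35^2))
  b4 <- s * c(-0.55, -0.35, sqrt(1 - 0.55^2 - 0.35^2))
  l1 <- attach + b1
  hinge <- l1 + b2
  l3 <- hinge + b3
  m1 <- l3 + b4

  mob <- snake_grid(n_mobile, c(3, 3, 3), s)
  # anchor the walk's first node (the residue bonded to the linker) at m1;
  # the blob then extends toward the partner core (-x), upward in z, and
  # keeps its first y layer in the hinge's y plane
  mob <- sweep(mob, 2, mob[1, ])
  mob[, 1] <- m1[1] + mob[, 1]
  mob[, 2] <- m1[2] + abs(mob[, 2])
  mob[, 3] <- m1[3] + mob[, 3]

  n_linker <- 3L
  n_chain <- n_core + n_linker + n_mobile
  xyz_a <- rbind(core, l1, hinge, l3, mob)
  # offset the whole chain along y before the C2 image is taken: the cores
  # stay close enough to interlock (tethers across the dimer interface),
  # while the two mobile domains are pushed outside each other's elastic
  # cutoff so their hinge motions are not artificially coupled
  xyz_a[, 2] <- xyz_a[, 2] + 4.2

  res_attach <- n_core                   # pre-hinge measure site
  res_hinge <- n_core + 2L               # hinge centre
  res_mob1 <- n_core + n_linker + 1L

  # designated tip: mobile node in the hinge's y plane, furthest toward the
  # partner core, lowest z (deterministic)
  mob_res <- seq(res_mob1, n_chain)
  in_plane <- which(abs(mob[, 2] - hinge[2]) < 1e-9)
  ord <- in_plane[order(mob[in_plane, 1], mob[in_plane, 3])]
  res_tip <- mob_res[ord[1]]

  # jitter chain A for genericity; the linker and the y components of the
  # designated hinge-plane sites are left exact so hinge rotations map onto
  # the hinge-angle measure without error
  set.seed(derive_seed(seed, 1L))
  jit <- matrix(stats::runif(3 * n_chain, -jitter, jitter), ncol = 3)
  jit[(n_core + 1):(n_core + n_linker), ] <- 0
  jit[res_attach, 2] <- 0
  jit[res_tip, 2] <- 0
  xyz_a <- xyz_a + jit

  xyz_b <- xyz_a %*% t(C2_Z)
  atoms <- dplyr::bind_rows(
    toy_atom_tbl(xyz_a, "A", seq_len(n_chain)),
    toy_atom_tbl(xyz_b, "B", seq_len(n_chain))
  )
  atoms$serial <- seq_len(nrow(atoms))

  # cleft partner: core node of the partner chain closest to the tip
  tip_a <- xyz_a[res_tip, ]
  core_b <- xyz_b[seq_len(n_core), , drop = FALSE]
  dists <- sqrt(rowSums(sweep(core_b, 2, tip_a)^2))
  res_partner <- order(dists)[1]
  partner_near <- order(dists)[2:3]      # two more cross-cleft sites for dRMS

  domains <- dplyr::bind_rows(lapply(c("A", "B"), function(ch) {
    tibble(
      chain = ch, res_seq = seq_len(n_chain),
      domain = rep(c("core", "linker", "mobile"), c(n_core, n_linker, n_mobile))
    )
  }))

  sites <- list(
    intersite = intersite_spec(a_res = res_tip, b_res = res_partner),
    hinge = hinge_spec(c(res_attach, res_hinge, res_tip)),
    cleft = cleft_spec(tip_res = res_tip, hinge_res = res_hinge),
    drms = drms_spec(
      n_res = c(res_tip, res_mob1),
      c_res = c(res_partner, partner_near)
    )
  )

  structure(list(
    atoms = atoms,
    sites = sites,
    domains = domains,
    hinge = list(
      A = list(origin = as.numeric(xyz_a[res_hinge, ]), axis = c(0, 1, 0),
               moving = seq(n_core + n_linker, n_chain)),
      B = list(origin = as.numeric(C2_Z %*% xyz_a[res_hinge, ]),
               axis = as.numeric(C2_Z %*% c(0, 1, 0)),
               moving = seq(n_core + n_linker, n_chain))
    ),
    params = list(n_core = n_core, n_mobile = n_mobile, n_linker = n_linker,
                  seed = seed, jitter = jitter, spacing = spacing,
                  res_tip = res_tip, res_partner = res_partner,
                  res_hinge = res_hinge, res_attach = res_attach)
  ), class = "toy_dimer")
}

#' @export
print.toy_dimer <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<toy_dimer> 2 chains x %d residues (core %d / linker %d / mobile %d), seed %s\n",
    p$n_core + p$n_linker + p$n_mobile, p$n_core, p$n_linker, p$n_mobile, p$seed
  ))
  invisible(x)
}

#' Open/closed conformer pair related by a rigid hinge rotation
#'
#' The closed conformer is the open toy with both mobile domains (and the
#' distal linker residue) rigidly rotated about their hinge axes by
#' `hinge_rotation` degrees in the cleft-closing direction, applied
#' C2-symmetrically. Ground-truth measure values before and after are
#' returned alongside.
#'
#' @param toy a [make_toy_dimer()] object.
#' @param hinge_rotation rotation angle, degrees (positive closes the clefts).
#' @return list with `open` and `closed` atom tables and `ground_truth`
#'   (rotation, open/closed intersite distances and hinge angles).
#' @export
make_open_closed_pair <- function(toy, hinge_rotation = 35) {
  stopifnot(inherits(toy, "toy_dimer"))
  atoms <- toy$atoms
  closed <- atoms
  for (ch in c("A", "B")) {
    hg <- toy$hinge[[ch]]
    idx <- which(closed$chain == ch & closed$res_seq %in% hg$moving)
    # positive rotation about the hinge axis swings the tip toward the
    # partner core (closing); the C2-image axis flips sign, so the same
    # signed angle closes both clefts symmetrically
    R <- rotation_about_axis(hg$axis, -hinge_rotation)
    xyz <- as.matrix(closed[idx, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, hg$origin) %*% t(R), 2, hg$origin, `+`)
    closed[idx, c("x", "y", "z")] <- as.data.frame(xyz)
  }
  # construction-time clash guard between the rotated mobile domains and the
  # rest of the structure
  mob <- dplyr::semi_join(closed,
    dplyr::filter(toy$domains, .data$domain == "mobile"),
    by = c("chain", "res_seq"))
  rest <- dplyr::anti_join(closed,
    dplyr::filter(toy$domains, .data$domain != "core"),
    by = c("chain", "res_seq"))
  if (nrow(mob) > 0 && nrow(rest) > 0) {
    dmin <- min(proxy_dist(coords(mob), coords(rest)))
    if (dmin < 2.5) {
      abort(sprintf("hinge rotation of %g deg causes a steric clash (min distance %.2f A)",
                    hinge_rotation, dmin))
    }
  }
  gt <- list(
    rotation = hinge_rotation,
    intersite_open = measure_sites(atoms, toy$sites$intersite)$value,
    intersite_closed = measure_sites(closed, toy$sites$intersite)$value,
    hinge_open = measure_sites(atoms, toy$sites$hinge)$value,
    hinge_closed = measure_sites(closed, toy$sites$hinge)$value
  )
  list(open = atoms, closed = closed, ground_truth = gt)
}

# all-pairs Euclidean distances between two coordinate sets
proxy_dist <- function(a, b) {
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b), 0))
}

#' Synthetic all-atom helical peptide
#'
#' Builds an idealized backbone-only helix (N, CA, C, O and amide H per
#' residue) by internal-coordinate chain extension with standard bond
#' lengths and angles. The helical dihedrals put the i, i+4 carbonyl/amide
#' pairs in hydrogen-bonding geometry, so the all-atom code paths (covalent
#' detection, Mayo-style hydrogen-bond scoring, body-bar rigidity,
#' templates) can be exercised on a small structure with no downloads.
#'
#' @param n_res number of residues.
#' @param phi,psi,omega backbone dihedrals, degrees.
#' @return single-model atom tibble.
#' @export
make_toy_peptide <- function(n_res = 8, phi = -57, psi = -47, omega = 180) {
  stopifnot(n_res >= 3)
  place <- function(A, B, C, bond, angle, dihedral) {
    bc <- unit(C - B)
    n <- unit(pracma_cross(B - A, bc))
    m <- pracma_cross(n, bc)
    th <- angle * pi / 180
    ph <- dihedral * pi / 180
    C + bond * (-cos(th) * bc + sin(th) * cos(ph) * m + sin(th) * sin(ph) * n)
  }
  rows <- list()
  add <- function(name, element, res, pos) {
    rows[[length(rows) + 1]] <<- tibble(
      model = 1L, serial = length(rows) + 1L, name = name, alt_loc = "",
      res_name = "ALA", chain = "A", res_seq = as.integer(res), i_code = "",
      x = pos[1], y = pos[2], z = pos[3], occupancy = 1, element = element)
    pos
  }
  N <- add("N", "N", 1, c(0, 0, 0))
  CA <- add("CA", "C", 1, c(1.458, 0, 0))
  C <- add("C", "C", 1, CA + 1.525 * c(cos((180 - 111) * pi / 180),
                                       sin((180 - 111) * pi / 180), 0))
  O <- add("O", "O", 1, place(N, CA, C, 1.231, 120.5, psi + 180))
  for (r in 2:n_res) {
    N2 <- place(N, CA, C, 1.329, 116.6, psi)
    H2 <- place(CA, C, N2, 1.01, 119.5, 0)
    CA2 <- place(CA, C, N2, 1.458, 121.7, omega)
    C2 <- place(C, N2, CA2, 1.525, 111, phi)
    O2 <- place(N2, CA2, C2, 1.231, 120.5, psi + 180)
    add("N", "N", r, N2)
    add("H", "H", r, H2)
    add("CA", "C", r, CA2)
    add("C", "C", r, C2)
    add("O", "O", r, O2)
    N <- N2
    CA <- CA2
    C <- C2
  }
  dplyr::bind_rows(rows)
}

#' Trajectory with planted collective directions
#'
#' Frames are the input coordinates displaced along a set of orthonormal 3N
#' directions with prescribed per-frame amplitudes, plus isotropic Gaussian
#' noise - the ground truth for PCA recovery tests.
#'
#' @param atoms single-model atom table (N atoms).
#' @param directions 3N x m matrix of orthonormal displacement directions
#'   (x1,y1,z1,x2,... ordering).
#' @param amplitudes T x m matrix of per-frame amplitudes (Angstrom).
#' @param noise per-coordinate Gaussian noise sd (Angstrom).
#' @param seed integer seed.
#' @return multi-model atom table with T models.
#' @export
make_mode_trajectory <- function(atoms, directions, amplitudes, noise = 0,
                                 seed = 1) {
  assert_atoms(atoms)
  directions <- as.matrix(directions)
  amplitudes <- as.matrix(amplitudes)
  n3 <- 3 * nrow(atoms)
  stopifnot(nrow(directions) == n3, ncol(amplitudes) == ncol(directions))
  gram <- crossprod(directions)
  if (max(abs(gram - diag(ncol(directions)))) > 1e-6) {
    abort("`directions` must be orthonormal columns")
  }
  base <- coords(atoms)
  set.seed(derive_seed(seed, 2L))
  frames <- lapply(seq_len(nrow(amplitudes)), function(t) {
    disp <- directions %*% amplitudes[t, ]
    f <- base + matrix(disp, ncol = 3, byrow = TRUE)
    if (noise > 0) f <- f + matrix(stats::rnorm(n3, sd = noise), ncol = 3)
    f
  })
  frames_to_atoms(atoms, frames)
}

#' Paired series with a prescribed population correlation
#'
#' Draws bivariate normal pairs with population Pearson correlation `rho`
#' (unit variances, zero means) - ground truth for windowed-correlation
#' estimators.
#'
#' @param n series length.
#' @param rho target population correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @return tibble with columns `t`, `x`, `y`.
#' @export
make_correlated_series <- function(n, rho, seed = 1) {
  if (!is.finite(rho) || abs(rho) > 1) abort("`rho` must lie in [-1, 1]")
  set.seed(derive_seed(seed, 3L))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  tibble(t = seq_len(n), x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
}
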