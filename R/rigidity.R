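# Constraint-network construction and rigid-cluster decomposition.
#
# Two resolutions are supported. All-atom networks use the body-bar
# convention (covalent, hydrogen-bond and hydrophobic constraints with bar
# multiplicities); coarse Calpha networks (synthetic toys, Calpha-only
# inputs) use plain distance bars: chain bonds, next-neighbour angle bars,
# and intra-domain tethers that make designed domains rigid.

COVALENT_RADII <- c(H = 0.31, C = 0.77, N = 0.70, O = 0.66, S = 1.04,
                    P = 1.07, SE = 1.20, F = 0.57, CL = 1.02, BR = 1.20)
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85)

radius_of <- function(element, table, default) {
  r <- unname(table[toupper(element)])
  r[is.na(r)] <- default
  r
}

is_coarse <- function(atoms) all(atoms$name == "CA")

one_model <- function(atoms) {
  assert_atoms(atoms)
  if (n_models(atoms) != 1) {
    atoms <- select_atoms(atoms, model = atoms$model[1])
  }
  atoms
}

#' Detect covalent bonds
#'
#' All-atom structures: two atoms are bonded when their separation is below
#' the sum of covalent radii plus 0.4 A (and above 0.4 A). Coarse
#' (Calpha-only) structures: consecutive residues of a chain are bonded when
#' within 4.5 A.
#'
#' @param atoms single-model atom tibble.
#' @return tibble with row indices `i`, `j` (i < j), distance `d`, and
#'   `peptide` (logical: inter-residue C-N backbone link).
#' @export
detect_covalent <- function(atoms) {
  atoms <- one_model(atoms)
  xyz <- coords(atoms)
  if (is_coarse(atoms)) {
    i <- seq_len(nrow(atoms) - 1)
    j <- i + 1
    ok <- atoms$chain[i] == atoms$chain[j] &
      atoms$res_seq[j] - atoms$res_seq[i] == 1
    d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
    ok <- ok & d <= 4.5
    return(tibble(i = i[ok], j = j[ok], d = d[ok], peptide = FALSE))
  }
  r <- radius_of(atoms$element, COVALENT_RADII, 0.77)
  d <- proxy_dist(xyz, xyz)
  thr <- outer(r, r, `+`) + 0.4
  hit <- which(upper.tri(d) & d <= thr & d > 0.4, arr.ind = TRUE)
  i <- as.integer(hit[, 1])
  j <- as.integer(hit[, 2])
  deg <- tabulate(c(i, j), nbins = nrow(atoms))
  if (any(deg > 8)) {
    abort(sprintf("atom %d has %d covalent bonds; coordinates look corrupt",
                  which.max(deg), max(deg)))
  }
  same_res <- atoms$chain[i] == atoms$chain[j] &
    atoms$res_seq[i] == atoms$res_seq[j] & atoms$i_code[i] == atoms$i_code[j]
  peptide <- !same_res &
    ((atoms$name[i] == "C" & atoms$name[j] == "N") |
       (atoms$name[i] == "N" & atoms$name[j] == "C"))
  tibble(i = i, j = j, d = d[hit], peptide = peptide)
}

# graph distance <= 3 exclusion set for sterics/hydrophobics, returned as a
# logical adjacency-within-3-bonds matrix
bonded_within <- function(n, bonds, depth = 3) {
  A <- matrix(FALSE, n, n)
  if (nrow(bonds) > 0) {
    A[cbind(bonds$i, bonds$j)] <- TRUE
    A[cbind(bonds$j, bonds$i)] <- TRUE
  }
  reach <- A
  step <- A
  for (it in seq_len(depth - 1)) {
    step <- (step %*% A) > 0
    reach <- reach | step
  }
  diag(reach) <- TRUE
  reach
}

#' Detect hydrogen bonds and score them
#'
#' Candidate donors are N/O/S atoms carrying a covalently bound hydrogen
#' (any N/O/S when `fallback` is on and hydrogens are absent); acceptors are
#' N/O/S. Energies come from a Mayo-style distance-angle well,
#' `E = D0 (5 (R0/R)^12 - 6 (R0/R)^10) f(theta)` with well depth `D0 = 8`
#' kcal/mol and equilibrium donor-acceptor distance `R0 = 2.8` A. With an
#' explicit hydrogen the angular factor is `cos^2` of the donor-H-acceptor
#' deviation from linearity (zero beyond 90 degrees); without hydrogens a
#' frame built on the donor's heavy-atom antecedent is used and a warning is
#' issued. Salt-bridge pairs (charged N donor to carboxylate O) receive a
#' fixed favourable energy offset.
#'
#' @param atoms single-model atom tibble.
#' @param d_max donor-acceptor candidate cutoff, A.
#' @param d0 well depth, kcal/mol.
#' @param r0 equilibrium donor-acceptor distance, A.
#' @param salt_offset energy added to salt-bridge pairs, kcal/mol.
#' @param fallback allow heavy-atom geometry when hydrogens are missing.
#' @return tibble `i` (donor row), `j` (acceptor row), `h` (hydrogen row or
#'   NA), `d`, `energy` (kcal/mol), sorted by energy.
#' @export
detect_hbonds <- function(atoms, d_max = 3.6, d0 = 8, r0 = 2.8,
                          salt_offset = -2, fallback = TRUE) {
  atoms <- one_model(atoms)
  xyz <- coords(atoms)
  bonds <- detect_covalent(atoms)
  nbrs <- function(a) c(bonds$j[bonds$i == a], bonds$i[bonds$j == a])
  polar <- atoms$element %in% c("N", "O", "S")
  has_h <- vapply(seq_len(nrow(atoms)), function(a) {
    polar[a] && any(atoms$element[nbrs(a)] == "H")
  }, logical(1))
  any_h <- any(atoms$element == "H")
  if (!any_h && !fallback) {
    abort("no hydrogens in structure and heavy-atom fallback is disabled")
  }
  if (!any_h) {
    warn("no hydrogens present; hydrogen-bond geometry estimated from heavy-atom frames")
  }
  donors <- which(if (any_h) has_h else polar)
  acceptors <- which(polar)
  if (length(donors) == 0 || length(acceptors) == 0) {
    return(tibble(i = integer(), j = integer(), h = integer(),
                  d = numeric(), energy = numeric()))
  }
  near <- bonded_within(nrow(atoms), bonds)
  out <- list()
  charged_donor <- atoms$res_name %in% c("LYS", "ARG", "HIS") &
    atoms$element == "N" & !(atoms$name %in% c("N"))
  carboxylate <- atoms$res_name %in% c("ASP", "GLU") &
    grepl("^O(D|E)", atoms$name)
  for (dn in donors) {
    dn_nbrs <- nbrs(dn)
    hs <- dn_nbrs[atoms$element[dn_nbrs] == "H"]
    heavy <- dn_nbrs[atoms$element[dn_nbrs] != "H"]
    for (ac in acceptors) {
      if (ac == dn || near[dn, ac]) next
      R <- vnorm(xyz[ac, ] - xyz[dn, ])
      if (R > d_max) next
      if (length(hs) > 0) {
        # best (most linear) hydrogen
        th <- vapply(hs, function(h) vec_angle(xyz[dn, ], xyz[h, ], xyz[ac, ]),
                     numeric(1))
        theta_dev <- 180 - max(th)
        h_used <- hs[which.max(th)]
      } else {
        if (length(heavy) == 0) next
        # approximate: ideal antecedent-donor-acceptor angle ~115 degrees
        th <- vec_angle(xyz[heavy[1], ], xyz[dn, ], xyz[ac, ])
        theta_dev <- abs(th - 115)
        h_used <- NA_integer_
      }
      fang <- if (theta_dev >= 90) 0 else cos(theta_dev * pi / 180)^2
      e <- d0 * (5 * (r0 / R)^12 - 6 * (r0 / R)^10) * fang
      if (charged_donor[dn] && carboxylate[ac]) e <- e + salt_offset
      out[[length(out) + 1]] <- tibble(i = dn, j = ac, h = h_used, d = R,
                                       energy = e)
    }
  }
  res <- if (length(out) > 0) dplyr::bind_rows(out) else {
    tibble(i = integer(), j = integer(), h = integer(), d = numeric(),
           energy = numeric())
  }
  dplyr::arrange(res, .data$energy)
}

#' Detect hydrophobic tethers
#'
#' Carbon/sulfur atom pairs of different residues within the sum of their
#' van der Waals radii plus `pad`, excluding pairs within three covalent
#' bonds. Coarse structures use a plain distance rule between residues at
#' least 3 apart in sequence (or on different chains), restricted to the
#' same designed domain when `domains` is given.
#'
#' @param atoms single-model atom tibble.
#' @param pad distance padding over the vdW sum, A (all-atom mode).
#' @param tether_cutoff distance cutoff, A (coarse mode).
#' @param domains optional tibble chain/res_seq/domain; coarse tethers are
#'   restricted to pairs of the same domain, with the two `core` domains of
#'   a dimer treated as one interlocked body, and `linker` residues never
#'   tethered.
#' @return tibble `i`, `j`, `d`.
#' @export
detect_hydrophobic <- function(atoms, pad = 0.25, tether_cutoff = 7,
                               domains = NULL) {
  atoms <- one_model(atoms)
  xyz <- coords(atoms)
  if (is_coarse(atoms)) {
    d <- proxy_dist(xyz, xyz)
    hit <- which(upper.tri(d) & d <= tether_cutoff, arr.ind = TRUE)
    i <- as.integer(hit[, 1])
    j <- as.integer(hit[, 2])
    apart <- atoms$chain[i] != atoms$chain[j] |
      abs(atoms$res_seq[i] - atoms$res_seq[j]) >= 3
    keep <- apart
    if (!is.null(domains)) {
      dm <- dplyr::left_join(atoms[, c("chain", "res_seq")], domains,
                             by = c("chain", "res_seq"))$domain
      same_unit <- !is.na(dm[i]) & !is.na(dm[j]) & dm[i] != "linker" &
        dm[j] != "linker" &
        (paste(atoms$chain[i], dm[i]) == paste(atoms$chain[j], dm[j]) |
           (dm[i] == "core" & dm[j] == "core"))
      keep <- keep & same_unit
    }
    return(tibble(i = i[keep], j = j[keep], d = d[hit][keep]))
  }
  hydro <- atoms$element %in% c("C", "S")
  r <- radius_of(atoms$element, VDW_RADII, 1.7)
  d <- proxy_dist(xyz, xyz)
  thr <- outer(r, r, `+`) + pad
  near <- bonded_within(nrow(atoms), detect_covalent(atoms))
  hit <- which(upper.tri(d) & d <= thr, arr.ind = TRUE)
  i <- as.integer(hit[, 1])
  j <- as.integer(hit[, 2])
  keep <- hydro[i] & hydro[j] & !near[cbind(i, j)] &
    !(atoms$chain[i] == atoms$chain[j] & atoms$res_seq[i] == atoms$res_seq[j] &
        atoms$i_code[i] == atoms$i_code[j])
  tibble(i = i[keep], j = j[keep], d = d[hit][keep])
}

#' Assemble the full constraint network
#'
#' Combines covalent bonds, hydrogen bonds at or below the energy cutoff,
#' and hydrophobic tethers into one constraint table with bar
#' multiplicities. All-atom (body-bar) multiplicities: rotatable covalent
#' bond 5 bars, peptide and bonds to terminal atoms 6 (locked), hydrogen
#' bond/salt bridge 5, hydrophobic tether 2. Coarse Calpha networks are
#' bar-joint point frameworks: every constraint is a single distance bar,
#' and next-neighbour (i, i+2) angle bars are added along each chain.
#'
#' @param atoms single-model atom tibble.
#' @param e_cut hydrogen-bond energy cutoff, kcal/mol (default -2.0; more
#'   negative keeps fewer, stronger bonds).
#' @param domains optional domain annotation for coarse tethers (see
#'   [detect_hydrophobic()]).
#' @param tether_cutoff coarse tether distance cutoff, A.
#' @param ... further arguments passed to [detect_hbonds()].
#' @return object of class `constraint_network`: `atoms`, `constraints`
#'   (tibble i, j, kind, bars, energy), `mode` (`"bodybar"` or `"point"`),
#'   `e_cut`.
#' @examples
#' toy <- make_toy_dimer()
#' net <- build_constraint_network(toy$atoms, domains = toy$domains)
#' dplyr::count(net$constraints, kind)
#' @export
build_constraint_network <- function(atoms, e_cut = -2.0, domains = NULL,
                                     tether_cutoff = 7, ...) {
  atoms <- one_model(atoms)
  bonds <- detect_covalent(atoms)
  coarse <- is_coarse(atoms)
  if (coarse) {
    cons <- tibble(i = bonds$i, j = bonds$j, kind = "covalent", bars = 1L,
                   energy = NA_real_)
    # angle bars between next neighbours along each chain
    if (nrow(bonds) > 1) {
      nxt <- dplyr::inner_join(bonds, bonds, by = c("j" = "i"),
                               suffix = c("", ".2"))
      cons <- dplyr::bind_rows(cons, tibble(i = nxt$i, j = nxt$j.2,
                                            kind = "angle", bars = 1L,
                                            energy = NA_real_))
    }
    teth <- detect_hydrophobic(atoms, tether_cutoff = tether_cutoff,
                               domains = domains)
    cons <- dplyr::bind_rows(cons, tibble(i = teth$i, j = teth$j,
                                          kind = "hydrophobic", bars = 1L,
                                          energy = NA_real_))
    hb <- NULL
  } else {
    deg <- tabulate(c(bonds$i, bonds$j), nbins = nrow(atoms))
    terminal <- deg[bonds$i] == 1 | deg[bonds$j] == 1
    cons <- tibble(
      i = bonds$i, j = bonds$j,
      kind = ifelse(bonds$peptide, "peptide", "covalent"),
      bars = ifelse(bonds$peptide | terminal, 6L, 5L),
      energy = NA_real_
    )
    hb <- detect_hbonds(atoms, ...)
    hb <- dplyr::filter(hb, .data$energy <= e_cut)
    if (nrow(hb) > 0) {
      cons <- dplyr::bind_rows(cons, tibble(i = hb$i, j = hb$j, kind = "hbond",
                                            bars = 5L, energy = hb$energy))
    }
    teth <- detect_hydrophobic(atoms)
    if (nrow(teth) > 0) {
      cons <- dplyr::bind_rows(cons, tibble(i = teth$i, j = teth$j,
                                            kind = "hydrophobic", bars = 2L,
                                            energy = NA_real_))
    }
  }
  # canonical order, one row per (i, j, kind)
  cons <- dplyr::distinct(dplyr::mutate(cons,
    i2 = pmin(.data$i, .data$j), j2 = pmax(.data$i, .data$j), i = NULL, j = NULL
  ))
  cons <- dplyr::rename(cons, i = "i2", j = "j2")
  cons <- dplyr::arrange(cons[, c("i", "j", "kind", "bars", "energy")],
                         .data$i, .data$j, .data$kind)
  structure(list(atoms = atoms, constraints = cons,
                 mode = if (coarse) "point" else "bodybar", e_cut = e_cut),
            class = "constraint_network")
}

#' @export
print.constraint_network <- function(x, ...) {
  cnt <- dplyr::count(x$constraints, .data$kind)
  cat(sprintf("<constraint_network> %s mode, %d atoms, E_cut %g kcal/mol\n",
              x$mode, nrow(x$atoms), x$e_cut))
  for (r in seq_len(nrow(cnt))) {
    cat(sprintf("  %-12s %d\n", cnt$kind[r], cnt$n[r]))
  }
  invisible(x)
}

#' Rigid-cluster decomposition by the pebble game
#'
#' Matches degrees of freedom against bonding constraints: body-bar
#' (k = 6) for all-atom networks, bar-joint points (k = 3) for coarse
#' networks. Returns the internal floppy mode count, a partition of atoms
#' into rigid clusters (each atom labelled by the largest rigid component
#' containing it; cluster 1 is the largest), and a locked/variable label
#' for every covalent bond. The result is independent of the order in which
#' constraints are inserted.
#'
#' @param network a [build_constraint_network()] object.
#' @return object of class `rigid_decomposition`: `floppy` (F), `clusters`
#'   (tibble atom/cluster), `components` (list of rigid component vertex
#'   sets, possibly overlapping at hinges), `bond_labels` (tibble i, j,
#'   kind, locked), `n_redundant`, `mode`.
#' @examples
#' toy <- make_toy_dimer()
#' net <- build_constraint_network(toy$atoms, domains = toy$domains)
#' rig <- pebble_game(net)
#' rig$floppy
#' @export
pebble_game <- function(network) {
  stopifnot(inherits(network, "constraint_network"))
  cons <- network$constraints
  if (nrow(cons) == 0) abort("empty constraint network")
  n <- nrow(network$atoms)
  k <- if (network$mode == "point") 3L else 6L
  run <- pebble_run(n, cons, k = k, l = 6L)
  pairs <- dplyr::distinct(cons[, c("i", "j")])
  cmp <- pebble_components(run, pairs)

  comps <- cmp$components
  sizes <- vapply(comps, length, integer(1))
  ord <- order(-sizes)
  cluster <- rep(NA_integer_, n)
  next_id <- 0L
  for (ci in ord) {
    next_id <- next_id + 1L
    members <- comps[[ci]]
    fresh <- members[is.na(cluster[members])]
    cluster[fresh] <- next_id
  }
  for (a in which(is.na(cluster))) {
    next_id <- next_id + 1L
    cluster[a] <- next_id
  }

  pair_key <- paste(pairs$i, pairs$j)
  locked_of <- stats::setNames(cmp$locked, pair_key)
  bonds <- dplyr::filter(cons, .data$kind %in% c("covalent", "peptide"))
  bond_labels <- tibble(
    i = bonds$i, j = bonds$j, kind = bonds$kind,
    locked = unname(locked_of[paste(bonds$i, bonds$j)])
  )
  structure(list(floppy = run$floppy, clusters = tibble(atom = seq_len(n),
                                                        cluster = cluster),
                 components = comps, bond_labels = bond_labels,
                 n_redundant = run$redundant, n_independent = run$independent,
                 mode = network$mode),
            class = "rigid_decomposition")
}

#' @export
print.rigid_decomposition <- function(x, ...) {
  sizes <- sort(table(x$clusters$cluster), decreasing = TRUE)
  cat(sprintf("<rigid_decomposition> %s mode: F = %d, %d clusters (largest %d atoms), %d redundant bars\n",
              x$mode, x$floppy, length(sizes), sizes[1], x$n_redundant))
  invisible(x)
}

#' @export
tidy.rigid_decomposition <- function(x, ...) x$clusters

#' @export
glance.rigid_decomposition <- function(x, ...) {
  tibble(floppy = x$floppy, n_clusters = length(unique(x$clusters$cluster)),
         largest_cluster = max(table(x$clusters$cluster)),
         n_redundant = x$n_redundant, mode = x$mode)
}

#' Export a rigid decomposition alongside its structure
#'
#' Writes a per-atom CSV (serial, chain, res_seq, name, cluster) and,
#' optionally, a PDB whose B-factor column carries the cluster index.
#'
#' @param rigid a [pebble_game()] result.
#' @param atoms the atom tibble the network was built on.
#' @param csv,pdb output paths (`NULL` to skip).
#' @return invisibly, the per-atom cluster tibble.
#' @export
write_rigid_clusters <- function(rigid, atoms, csv = NULL, pdb = NULL) {
  atoms <- one_model(atoms)
  out <- dplyr::bind_cols(
    atoms[, c("serial", "chain", "res_seq", "name")],
    rigid$clusters["cluster"]
  )
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  if (!is.null(pdb)) {
    bio3d::write.pdb(
      file = pdb, xyz = as.numeric(t(coords(atoms))),
      resno = atoms$res_seq, resid = atoms$res_name, eleno = atoms$serial,
      elety = atoms$name, chain = ifelse(atoms$chain == "", " ", atoms$chain),
      o = atoms$occupancy, b = rigid$clusters$cluster, elesy = atoms$element
    )
  }
  invisible(out)
}
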