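# Template-based geometric simulation of flexible motion. Rigid clusters
# and local joint neighbourhoods become overlapping rigid templates; each
# simulation step perturbs all atoms along a normal-mode bias direction plus
# a small random step, then relaxes positions by iteratively fitting the
# templates (least-squares rigid superposition), averaging their proposals,
# and resolving steric overlaps. Motion proceeds through an initial phase of
# easy motion and halts at "jamming", when the bias direction can no longer
# be reconciled with bonding and steric constraints.

#' Geometric-simulation configuration
#'
#' @param bias_step RMS per-atom displacement along the bias per step, A.
#' @param random_step radius of the isotropic random per-atom step, A.
#' @param direction `"parallel"` or `"antiparallel"` to the bias vector.
#' @param max_steps maximum number of perturbation steps.
#' @param relax_tolerance maximum allowed constraint mismatch, A.
#' @param max_relax_iters relaxation iterations per step.
#' @param jam_patience consecutive failed relaxations that declare a jam.
#' @param save_interval record a frame every this many accepted steps.
#' @param steric_scale hard-sphere radii are scaled by this factor
#'   (FRODA-style soft sterics).
#' @param seed integer seed for the random step.
#' @return list of class `geosim_config`.
#' @export
geosim_config <- function(bias_step = 0.01, random_step = 0.01,
                          direction = c("parallel", "antiparallel"),
                          max_steps = 5000, relax_tolerance = 0.125,
                          max_relax_iters = 200, jam_patience = 20,
                          save_interval = 100, steric_scale = 0.85,
                          seed = 1) {
  direction <- match.arg(direction)
  stopifnot(bias_step > 0, random_step >= 0, max_steps >= 0,
            relax_tolerance > 0, max_relax_iters >= 1, jam_patience >= 1,
            save_interval >= 1)
  structure(list(bias_step = bias_step, random_step = random_step,
                 direction = direction, max_steps = max_steps,
                 relax_tolerance = relax_tolerance,
                 max_relax_iters = max_relax_iters,
                 jam_patience = jam_patience, save_interval = save_interval,
                 steric_scale = steric_scale, seed = seed),
            class = "geosim_config")
}

network_bonds <- function(network) {
  dplyr::filter(network$constraints, .data$kind %in% c("covalent", "peptide"))
}

#' Build overlapping rigid templates from a rigid decomposition
#'
#' One template per rigid cluster (extended by the covalent neighbours of
#' its members, so adjacent templates share the junction atoms), one local
#' template per joint atom carrying a variable bond (the atom plus its
#' bonded neighbours, which maintains bond lengths and bond angles at the
#' joint while leaving torsions free), and pair templates for any remaining
#' variable bonds. Template reference geometry is the input structure, so
#' the initial configuration has zero violation.
#'
#' @param atoms single-model atom tibble.
#' @param rigid a [pebble_game()] decomposition of the same atoms.
#' @param network the [build_constraint_network()] the decomposition came
#'   from.
#' @return object of class `template_set`: `templates` (list of integer
#'   atom-index vectors), `ref` (list of reference coordinate matrices),
#'   `atoms`.
#' @export
build_templates <- function(atoms, rigid, network) {
  atoms <- one_model(atoms)
  xyz <- coords(atoms)
  n <- nrow(atoms)
  bonds <- network_bonds(network)
  nbr <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    nbr[[bonds$i[r]]] <- c(nbr[[bonds$i[r]]], bonds$j[r])
    nbr[[bonds$j[r]]] <- c(nbr[[bonds$j[r]]], bonds$i[r])
  }
  lk <- rigid$bond_labels
  variable_at <- rep(FALSE, n)
  if (nrow(lk) > 0) {
    vb <- lk[!lk$locked, , drop = FALSE]
    variable_at[unique(c(vb$i, vb$j))] <- TRUE
  }
  tpl <- list()
  clus <- split(rigid$clusters$atom, rigid$clusters$cluster)
  for (members in clus) {
    if (length(members) < 2) next
    ext <- sort(unique(c(members, unlist(nbr[members]))))
    tpl[[length(tpl) + 1]] <- ext
  }
  for (a in which(variable_at)) {
    if (length(nbr[[a]]) >= 1) {
      tpl[[length(tpl) + 1]] <- sort(unique(c(a, nbr[[a]])))
    }
  }
  if (nrow(lk) > 0) {
    for (r in which(!lk$locked)) {
      tpl[[length(tpl) + 1]] <- sort(c(lk$i[r], lk$j[r]))
    }
  }
  if (length(tpl) == 0) abort("no templates could be built")
  # drop templates wholly contained in another
  keep <- rep(TRUE, length(tpl))
  ord <- order(-vapply(tpl, length, integer(1)))
  seen <- list()
  for (t in ord) {
    contained <- any(vapply(seen, function(s) all(tpl[[t]] %in% s), logical(1)))
    if (contained) keep[t] <- FALSE else seen[[length(seen) + 1]] <- tpl[[t]]
  }
  tpl <- tpl[keep]
  tpl <- lapply(tpl, as.integer)
  uncovered <- setdiff(seq_len(n), unique(unlist(tpl)))
  if (length(uncovered) > 0) {
    abort(sprintf("atom(s) not covered by any template: %s",
                  paste(utils::head(uncovered, 5), collapse = ", ")))
  }
  structure(list(
    templates = tpl,
    ref = lapply(tpl, function(ix) xyz[ix, , drop = FALSE]),
    atoms = atoms
  ), class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  sizes <- vapply(x$templates, length, integer(1))
  cat(sprintf("<template_set> %d templates over %d atoms (sizes %d..%d)\n",
              length(sizes), nrow(x$atoms), min(sizes), max(sizes)))
  invisible(x)
}

steric_setup <- function(atoms, network, steric_scale) {
  r <- radius_of(atoms$element, VDW_RADII, 1.7) * steric_scale
  bonds <- network_bonds(network)
  excl <- bonded_within(nrow(atoms), bonds, depth = 2) # 1-2 and 1-3 pairs
  list(radii = r, excluded = excl)
}

# One violation evaluation: worst template mismatch after optimal rigid
# fitting, and worst steric interpenetration beyond the contact distance.
geo_violation <- function(xyz, templates, steric) {
  tv <- 0
  for (t in seq_along(templates$templates)) {
    ix <- templates$templates[[t]]
    fit <- kabsch(templates$ref[[t]], xyz[ix, , drop = FALSE])
    moved <- apply_rigid(templates$ref[[t]], fit$R, fit$t)
    tv <- max(tv, sqrt(max(rowSums((moved - xyz[ix, , drop = FALSE])^2))))
  }
  d <- proxy_dist(xyz, xyz)
  contact <- outer(steric$radii, steric$radii, `+`)
  over <- contact - d
  over[steric$excluded] <- 0
  over[lower.tri(over, diag = TRUE)] <- 0
  max(tv, max(over, 0))
}

#' Relax atomic positions onto templates and steric exclusion
#'
#' Iterates: fit every template to the current coordinates by least-squares
#' rigid superposition; move each atom to the average of its templates'
#' proposals; separate sterically overlapping nonbonded pairs symmetrically.
#' Stops when the worst mismatch drops to `relax_tolerance` or the iteration
#' budget is exhausted (non-convergence is reported in the return value,
#' never as an error).
#'
#' @param xyz n x 3 coordinate matrix.
#' @param templates a [build_templates()] set.
#' @param network the constraint network (for bonded steric exclusions).
#' @param config a [geosim_config()].
#' @return list: `xyz` (relaxed coordinates), `converged`, `violation`
#'   (final worst mismatch, A), `iters`.
#' @export
relax_positions <- function(xyz, templates, network, config = geosim_config()) {
  steric <- steric_setup(templates$atoms, network, config$steric_scale)
  relax_engine(xyz, templates, steric, config)
}

relax_engine <- function(xyz, templates, steric, config) {
  tol <- config$relax_tolerance
  for (it in seq_len(config$max_relax_iters)) {
    viol <- geo_violation(xyz, templates, steric)
    if (viol <= tol) {
      return(list(xyz = xyz, converged = TRUE, violation = viol, iters = it - 1L))
    }
    acc <- matrix(0, nrow(xyz), 3)
    cnt <- numeric(nrow(xyz))
    for (t in seq_along(templates$templates)) {
      ix <- templates$templates[[t]]
      fit <- kabsch(templates$ref[[t]], xyz[ix, , drop = FALSE])
      moved <- apply_rigid(templates$ref[[t]], fit$R, fit$t)
      acc[ix, ] <- acc[ix, ] + moved
      cnt[ix] <- cnt[ix] + 1
    }
    xyz <- acc / cnt
    # resolve steric overlaps pairwise and symmetrically
    d <- proxy_dist(xyz, xyz)
    contact <- outer(steric$radii, steric$radii, `+`)
    over <- contact - d
    over[steric$excluded] <- 0
    over[lower.tri(over, diag = TRUE)] <- 0
    hits <- which(over > 1e-9, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      for (h in seq_len(nrow(hits))) {
        a <- hits[h, 1]
        b <- hits[h, 2]
        dir <- xyz[b, ] - xyz[a, ]
        nd <- vnorm(dir)
        dir <- if (nd < 1e-9) c(1, 0, 0) else dir / nd
        push <- (contact[a, b] - nd) / 2
        xyz[a, ] <- xyz[a, ] - dir * push
        xyz[b, ] <- xyz[b, ] + dir * push
      }
    }
  }
  viol <- geo_violation(xyz, templates, steric)
  list(xyz = xyz, converged = viol <= tol, violation = viol,
       iters = config$max_relax_iters)
}

#' Run a mode-biased geometric simulation
#'
#' Each step displaces every atom along the (fixed) bias field plus an
#' isotropic random step, then relaxes onto the template and steric
#' constraints. Steps whose relaxation fails are rejected (coordinates
#' revert); `jam_patience` consecutive failures end the trajectory with the
#' jam flag set. All emitted frames satisfy the relaxation tolerance.
#'
#' @param atoms single-model atom tibble (the starting structure).
#' @param bias per-atom displacement field from [atomize_bias()] (n x 3,
#'   already scaled to the bias step).
#' @param templates a [build_templates()] set for `atoms`.
#' @param network the constraint network.
#' @param config a [geosim_config()]; `direction = "antiparallel"` negates
#'   the bias while reusing the same random sequence.
#' @return object of class `geosim_trajectory`: `atoms` (identity table),
#'   `frames` (list of coordinate matrices; frame 1 is the input),
#'   `stats` (tibble step/violation/converged per emitted frame), `jammed`,
#'   `jam_step`, `bias_label`, `config`.
#' @examples
#' \donttest{
#' toy <- make_toy_dimer()
#' net <- build_constraint_network(toy$atoms, domains = toy$domains)
#' rig <- pebble_game(net)
#' tpl <- build_templates(toy$atoms, rig, net)
#' modes <- compute_modes(build_enm(toy$atoms))
#' bias <- atomize_bias(mode_vector(modes, 7), toy$atoms, step = 0.05)
#' trj <- run_geosim(toy$atoms, bias, tpl, net,
#'                   geosim_config(max_steps = 50, save_interval = 10))
#' }
#' @export
run_geosim <- function(atoms, bias, templates, network,
                       config = geosim_config()) {
  atoms <- one_model(atoms)
  if (!is.matrix(bias) || nrow(bias) != nrow(atoms) || ncol(bias) != 3) {
    abort("`bias` must be an n x 3 per-atom displacement field matching `atoms`")
  }
  steric <- steric_setup(atoms, network, config$steric_scale)
  sgn <- if (config$direction == "antiparallel") -1 else 1
  pos <- coords(atoms)
  set.seed(derive_seed(config$seed, 17L))
  frames <- list(pos)
  stats <- list(tibble(step = 0L,
                       violation = geo_violation(pos, templates, steric),
                       converged = TRUE))
  fails <- 0L
  jammed <- FALSE
  jam_step <- NA_integer_
  accepted <- 0L
  step <- 0L
  while (step < config$max_steps) {
    step <- step + 1L
    rnd <- random_sphere(nrow(pos), config$random_step)
    trial <- pos + sgn * bias + rnd
    rel <- relax_engine(trial, templates, steric, config)
    if (rel$converged) {
      pos <- rel$xyz
      fails <- 0L
      accepted <- accepted + 1L
      if (accepted %% config$save_interval == 0) {
        frames[[length(frames) + 1]] <- pos
        stats[[length(stats) + 1]] <- tibble(step = step,
                                             violation = rel$violation,
                                             converged = TRUE)
      }
    } else {
      fails <- fails + 1L
      if (fails >= config$jam_patience) {
        jammed <- TRUE
        jam_step <- step
        break
      }
    }
  }
  # always emit the final satisfied configuration
  if (!identical(frames[[length(frames)]], pos)) {
    frames[[length(frames) + 1]] <- pos
    stats[[length(stats) + 1]] <- tibble(
      step = step, violation = geo_violation(pos, templates, steric),
      converged = TRUE)
  }
  structure(list(atoms = atoms, frames = frames,
                 stats = dplyr::bind_rows(stats), jammed = jammed,
                 jam_step = jam_step,
                 bias_label = attr(bias, "label") %||% "bias",
                 config = config),
            class = "geosim_trajectory")
}

random_sphere <- function(n, radius) {
  if (radius <= 0) return(matrix(0, n, 3))
  out <- matrix(0, n, 3)
  got <- 0L
  while (got < n) {
    cand <- matrix(stats::runif(3 * (n - got), -1, 1), ncol = 3)
    ok <- rowSums(cand^2) <= 1
    take <- which(ok)
    if (length(take) > 0) {
      out[(got + 1):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out * radius
}

#' @export
print.geosim_trajectory <- function(x, ...) {
  cat(sprintf("<geosim_trajectory> bias %s (%s), %d frames, %s\n",
              x$bias_label, x$config$direction, length(x$frames),
              if (x$jammed) sprintf("jammed at step %d", x$jam_step)
              else "no jam"))
  invisible(x)
}

#' @export
tidy.geosim_trajectory <- function(x, ...) x$stats

#' @export
glance.geosim_trajectory <- function(x, ...) {
  tibble(bias = x$bias_label, direction = x$config$direction,
         n_frames = length(x$frames), jammed = x$jammed,
         jam_step = x$jam_step,
         max_violation = max(x$stats$violation))
}

#' Convert a geosim trajectory to a multi-model atom tibble
#' @param x a `geosim_trajectory`.
#' @param ... unused.
#' @return atom tibble with one model per saved frame.
#' @export
as_tibble.geosim_trajectory <- function(x, ...) {
  frames_to_atoms(x$atoms, x$frames)
}

#' Write a geosim trajectory as multi-model PDB plus a CSV sidecar
#'
#' @param trj a `geosim_trajectory`.
#' @param pdb,csv output paths (`NULL` to skip either).
#' @param header_json optional path for a JSON run header recording the
#'   configuration and bias label.
#' @return invisibly, the sidecar tibble.
#' @export
write_geosim <- function(trj, pdb = NULL, csv = NULL, header_json = NULL) {
  stopifnot(inherits(trj, "geosim_trajectory"))
  if (!is.null(pdb)) write_trajectory(as_tibble(trj), pdb)
  side <- dplyr::mutate(trj$stats, jammed = trj$jammed, bias = trj$bias_label)
  if (!is.null(csv)) utils::write.csv(side, csv, row.names = FALSE)
  if (!is.null(header_json)) {
    jsonlite::write_json(
      list(bias = trj$bias_label, jammed = trj$jammed,
           jam_step = trj$jam_step, config = unclass(trj$config)),
      header_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(side)
}
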