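# Structural descriptors of cleft closure and domain attitude, computed on
# any structure or trajectory frame. Measures are data-driven: a "site spec"
# tibble names the atoms (chain, residue, atom name) entering each measure,
# so the same machinery serves DcpS-style intersite distances, hinge angles,
# citrate-synthase-style cleft angles/dihedrals, and synthetic toys.

#' Site specifications for named measures
#'
#' A site spec is a tibble with columns `measure`, `point`, `chain`,
#' `res_seq`, `name`; measures with 2, 3, and 4 points are evaluated as a
#' distance (Angstrom), an interior angle at the middle point (degrees), and
#' a signed dihedral (degrees, IUPAC convention) respectively.
#'
#' `intersite_spec()` builds the pair of cross-subunit active-site-closure
#' distances d(AB) and d(BA) (defaults: Calpha Trp175 of one chain to Calpha
#' Asp111 of the other, the DcpS convention, where the "A-B" site is formed
#' by Trp175 of chain A with Asp111 of chain B). `hinge_spec()` builds one
#' three-point hinge angle per chain (defaults Tyr143-Arg145-Arg149, with
#' Arg145 the hinge centre). `cleft_spec()` builds the tip-hinge-hinge-tip
#' quartet giving two cleft-closing angles ABC, BCD and the inter-domain
#' dihedral ABCD (defaults Gly312 tip / Gly386 hinge, the citrate synthase
#' convention). `drms_spec()` builds the set of cross-cleft distance pairs
#' whose root-mean-square is the dRMS measure (defaults: Calpha Asn110 and
#' Thr130 against Calpha Trp175', His279', Asp205').
#'
#' @param a_res,b_res residue numbers of the two intersite partners.
#' @param res three residue numbers (pre-hinge, hinge centre, post-hinge).
#' @param tip_res,hinge_res residue numbers of the small-domain tip and hinge.
#' @param n_res,c_res residue numbers on the mobile (2) and partner (3) side
#'   of the cleft.
#' @param chains two chain identifiers, first the "A" role.
#' @param name atom name used at every site.
#' @return a site spec tibble.
#' @name site_specs
NULL

spec_row <- function(measure, point, chain, res_seq, name) {
  tibble(measure = measure, point = as.integer(point), chain = chain,
         res_seq = as.integer(res_seq), name = name)
}

#' @rdname site_specs
#' @export
intersite_spec <- function(a_res = 175, b_res = 111, chains = c("A", "B"),
                           name = "CA") {
  dplyr::bind_rows(
    spec_row("d_AB", 1:2, c(chains[1], chains[2]), c(a_res, b_res), name),
    spec_row("d_BA", 1:2, c(chains[2], chains[1]), c(a_res, b_res), name)
  )
}

#' @rdname site_specs
#' @export
hinge_spec <- function(res = c(143, 145, 149), chains = c("A", "B"),
                       name = "CA") {
  stopifnot(length(res) == 3)
  dplyr::bind_rows(
    spec_row("hinge_A", 1:3, chains[1], res, name),
    spec_row("hinge_B", 1:3, chains[2], res, name)
  )
}

#' @rdname site_specs
#' @export
cleft_spec <- function(tip_res = 312, hinge_res = 386, chains = c("A", "B"),
                       name = "CA") {
  a <- chains[1]
  b <- chains[2]
  dplyr::bind_rows(
    spec_row("ABC", 1:3, c(a, a, b), c(tip_res, hinge_res, hinge_res), name),
    spec_row("BCD", 1:3, c(a, b, b), c(hinge_res, hinge_res, tip_res), name),
    spec_row("ABCD", 1:4, c(a, a, b, b),
             c(tip_res, hinge_res, hinge_res, tip_res), name)
  )
}

#' @rdname site_specs
#' @export
drms_spec <- function(n_res = c(110, 130), c_res = c(175, 279, 205),
                      chains = c("B", "A"), name = "CA") {
  grid <- expand.grid(n = n_res, c = c_res)
  out <- purrr::map2(grid$n, grid$c, function(nr, cr) {
    spec_row(sprintf("pair_%d_%d", nr, cr), 1:2, c(chains[1], chains[2]),
             c(nr, cr), name)
  })
  structure(dplyr::bind_rows(out), class = c("drms_spec", class(out[[1]])))
}

resolve_sites <- function(atoms_model, spec) {
  hit <- dplyr::left_join(
    spec, dplyr::mutate(atoms_model, .row = dplyr::row_number()),
    by = c("chain", "res_seq", "name")
  )
  if (anyNA(hit$.row)) {
    miss <- hit[is.na(hit$.row), ]
    abort(sprintf(
      "unresolvable measure site(s): %s",
      paste(sprintf("%s %s%d:%s", miss$measure, miss$chain, miss$res_seq,
                    miss$name), collapse = "; ")
    ))
  }
  dup <- dplyr::count(hit, .data$measure, .data$point)
  if (any(dup$n > 1)) abort("ambiguous measure site: multiple matching atoms")
  hit
}

eval_measure <- function(pts) {
  # pts: k x 3 matrix in point order
  k <- nrow(pts)
  if (k == 2) {
    vnorm(pts[1, ] - pts[2, ])
  } else if (k == 3) {
    vec_angle(pts[1, ], pts[2, ], pts[3, ])
  } else if (k == 4) {
    vec_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  } else {
    abort("a measure needs 2, 3, or 4 points")
  }
}

#' Evaluate named site measures on every model of a structure
#'
#' @param atoms atom tibble (any number of models).
#' @param spec site spec tibble, see [site_specs].
#' @return tibble with columns `model`, `measure`, `value` (Angstrom for
#'   2-point measures, degrees otherwise). A `drms_spec` collapses to a
#'   single `drms` value per model (the root mean square of its pair
#'   distances).
#' @examples
#' toy <- make_toy_dimer()
#' measure_sites(toy$atoms, toy$sites$hinge)
#' @export
measure_sites <- function(atoms, spec) {
  assert_atoms(atoms)
  out <- dplyr::bind_rows(lapply(split(atoms, atoms$model), function(m) {
    hit <- resolve_sites(m, spec)
    hit <- dplyr::arrange(hit, .data$measure, .data$point)
    vals <- vapply(split(hit, hit$measure), function(h) {
      eval_measure(as.matrix(m[h$.row, c("x", "y", "z")]))
    }, numeric(1))
    tibble(model = m$model[1], measure = names(vals), value = unname(vals))
  }))
  if (inherits(spec, "drms_spec")) {
    out <- dplyr::summarise(dplyr::group_by(out, .data$model),
                            measure = "drms",
                            value = sqrt(mean(.data$value^2)), .groups = "drop")
  }
  dplyr::arrange(out, .data$model)
}

#' Evaluate a list of measure specs along a trajectory
#'
#' @param x a multi-model atom tibble or a [run_geosim()] trajectory.
#' @param specs named list of site specs.
#' @return tidy tibble with columns `frame`, `measure`, `value`.
#' @export
measure_series <- function(x, specs) {
  atoms <- as_trajectory_atoms(x)
  out <- purrr::imap(specs, function(sp, nm) measure_sites(atoms, sp))
  out <- dplyr::bind_rows(out)
  dplyr::arrange(dplyr::rename(out, frame = "model"), .data$frame)
}

# accept either a multi-model atom tibble or a geosim trajectory
as_trajectory_atoms <- function(x) {
  if (inherits(x, "geosim_trajectory")) {
    frames_to_atoms(x$atoms, x$frames)
  } else {
    assert_atoms(x)
    x
  }
}

#' Least-squares rigid superposition of two structures
#'
#' Kabsch superposition of `mobile` onto `reference` over corresponding
#' atoms of the fit selection; correspondence is established by atom
#' identity (chain, residue, insertion code, atom name). The RMSD is
#' reported over the fit selection, or over a separate report selection
#' (e.g. fit on the core, report on the mobile domain).
#'
#' @param mobile,reference single-model atom tibbles.
#' @param fit_sel,report_sel selections as named lists of
#'   [select_atoms()] arguments, e.g. `list(name = "CA", chain = "A")`.
#' @return list of class `superposition`: `atoms` (transformed mobile),
#'   `R`, `t`, and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, reference, fit_sel = list(name = "CA"),
                      report_sel = NULL) {
  assert_atoms(mobile)
  assert_atoms(reference)
  pair <- match_selection(mobile, reference, fit_sel)
  if (nrow(pair$m) < 3) abort("fewer than 3 correspondence points for superposition")
  fit <- kabsch(coords(pair$m), coords(pair$r))
  moved <- set_coords(mobile, apply_rigid(coords(mobile), fit$R, fit$t))
  rmsd <- fit$rmsd
  if (!is.null(report_sel)) {
    rep_pair <- match_selection(moved, reference, report_sel)
    rmsd <- rmsd_xyz(coords(rep_pair$m), coords(rep_pair$r))
  }
  structure(list(atoms = moved, R = fit$R, t = fit$t, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.3f A over matched selection\n", x$rmsd))
  invisible(x)
}

match_selection <- function(mobile, reference, sel) {
  m <- do.call(select_atoms, c(list(mobile), sel))
  r <- do.call(select_atoms, c(list(reference), sel))
  key_m <- atom_identity(m)
  key_r <- atom_identity(r)
  common <- intersect(key_m, key_r)
  if (length(common) == 0) abort("no corresponding atoms in selection")
  m <- m[match(common, key_m), ]
  r <- r[match(common, key_r), ]
  list(m = m, r = r)
}

#' Read or write a measure spec as YAML
#'
#' @param path YAML file path.
#' @param spec site spec tibble.
#' @return `read_measure_spec()` returns a site spec tibble;
#'   `write_measure_spec()` returns `path` invisibly.
#' @export
read_measure_spec <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- purrr::imap(y$measures, function(pts, nm) {
    dplyr::bind_rows(purrr::imap(pts, function(p, i) {
      spec_row(nm, i, p$chain, p$res_seq, p$name %||% "CA")
    }))
  })
  out <- dplyr::bind_rows(rows)
  if (isTRUE(y$drms)) class(out) <- c("drms_spec", class(out))
  out
}

#' @rdname read_measure_spec
#' @export
write_measure_spec <- function(spec, path) {
  measures <- lapply(split(spec, spec$measure), function(h) {
    h <- dplyr::arrange(h, .data$point)
    lapply(seq_len(nrow(h)), function(i) {
      list(chain = h$chain[i], res_seq = h$res_seq[i], name = h$name[i])
    })
  })
  yaml::write_yaml(list(drms = inherits(spec, "drms_spec"),
                        measures = measures), path)
  invisible(path)
}
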