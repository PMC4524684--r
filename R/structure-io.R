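# Reading, writing and manipulating protein structures as tidy atom tables.
#
# A "structure" throughout this package is a tibble with one row per atom and
# per model, carrying the PDB identity columns plus Cartesian coordinates in
# Angstrom. Multi-model files (NMR ensembles, trajectories) simply stack
# models, distinguished by the `model` column.

ATOM_COLS <- c("model", "serial", "name", "alt_loc", "res_name", "chain",
               "res_seq", "i_code", "x", "y", "z", "occupancy", "element")

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3")

assert_atoms <- function(atoms, arg = "atoms") {
  if (!is.data.frame(atoms)) abort(sprintf("`%s` must be a data frame of atom records", arg))
  missing <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing) > 0) {
    abort(sprintf("`%s` lacks atom columns: %s", arg, paste(missing, collapse = ", ")))
  }
  invisible(atoms)
}

atom_identity <- function(atoms) {
  paste(atoms$chain, atoms$res_seq, atoms$i_code, atoms$name, sep = "|")
}

#' Number of models in an atom table
#' @param atoms atom tibble.
#' @return integer count of distinct models.
#' @export
n_models <- function(atoms) {
  assert_atoms(atoms)
  length(unique(atoms$model))
}

#' Read a PDB structure into a tidy atom table
#'
#' Parses ATOM (and optionally non-water HETATM) records via [bio3d::read.pdb()]
#' and returns one row per atom per model. Alternate locations are reduced to a
#' single conformer per atom by keeping the highest occupancy (ties broken by
#' the alphabetically first alt-loc identifier), so downstream rigidity and
#' simulation stages always see a single-conformer model. Waters are always
#' excluded.
#'
#' @param path path to a PDB file.
#' @param include_ligands keep non-water HETATM records (default `FALSE`:
#'   protein ATOM records only).
#' @return tibble of atom records with columns
#'   `model, serial, name, alt_loc, res_name, chain, res_seq, i_code,
#'    x, y, z, occupancy, element` and attribute `source_id` (the file name).
#' @examples
#' toy <- make_toy_dimer()
#' f <- tempfile(fileext = ".pdb")
#' write_trajectory(toy$atoms, f)
#' atoms <- read_structure(f)
#' nrow(atoms)
#' @export
read_structure <- function(path, include_ligands = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) abort(sprintf("unreadable PDB file %s: %s", path, conditionMessage(e)))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) abort(sprintf("no ATOM records in %s", path))
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L

  element <- at$elesy
  bad <- is.na(element) | element == ""
  if (any(bad)) {
    # fall back on the first alphabetic character of the atom name
    element[bad] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[bad])
  }
  base <- tibble(
    serial = as.integer(at$eleno),
    name = at$elety,
    alt_loc = ifelse(is.na(at$alt), "", at$alt),
    res_name = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    res_seq = as.integer(at$resno),
    i_code = ifelse(is.na(at$insert), "", at$insert),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = toupper(element),
    type = at$type
  )
  if (any(base$element == "" | is.na(base$element))) abort("atom with empty element symbol")

  keep <- base$type == "ATOM" & !(base$res_name %in% WATER_RESNAMES)
  if (include_ligands) {
    keep <- keep | (base$type == "HETATM" & !(base$res_name %in% WATER_RESNAMES))
  }
  # alt-loc reduction: highest occupancy, ties alphabetical
  idx <- which(keep)
  sel <- base[idx, ]
  key <- paste(sel$chain, sel$res_seq, sel$i_code, sel$name, sep = "|")
  ord <- order(key, -sel$occupancy, sel$alt_loc)
  dup <- duplicated(key[ord])
  keep_rows <- sort(idx[ord][!dup])

  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  out <- purrr::map(seq_len(nmod), function(m) {
    crd <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    dplyr::bind_cols(
      tibble(model = m),
      base[keep_rows, setdiff(names(base), "type")],
      tibble(x = crd[keep_rows, 1], y = crd[keep_rows, 2], z = crd[keep_rows, 3])
    )
  })
  out <- dplyr::bind_rows(out)[, ATOM_COLS]
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    abort("non-finite coordinates in PDB file")
  }
  attr(out, "source_id") <- basename(path)
  out
}

#' Write an atom table (single- or multi-model) as a PDB file
#'
#' Every model becomes a `MODEL`/`ENDMDL` block (a single model is written as a
#' plain PDB without MODEL wrappers). ATOM record formatting is delegated to
#' [bio3d::write.pdb()], so a `read_structure()` round trip reproduces
#' coordinates to the fixed-width PDB precision of 3 decimals.
#'
#' @param atoms atom tibble; models must share one atom identity list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(atoms, path) {
  assert_atoms(atoms)
  if (nrow(atoms) == 0) abort("empty atom table")
  models <- split(atoms, atoms$model)
  id1 <- atom_identity(models[[1]])
  for (m in models) {
    if (!identical(atom_identity(m), id1)) {
      abort("models do not share one atom identity list")
    }
  }
  fmt_model <- function(m) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    bio3d::write.pdb(
      file = tmp,
      xyz = as.numeric(t(as.matrix(m[, c("x", "y", "z")]))),
      resno = m$res_seq, resid = m$res_name, eleno = m$serial,
      elety = m$name, chain = ifelse(m$chain == "", " ", m$chain),
      insert = ifelse(m$i_code == "", "", m$i_code),
      alt = ifelse(m$alt_loc == "", "", m$alt_loc),
      o = m$occupancy, b = rep(0, nrow(m)), elesy = m$element,
      end = FALSE
    )
    grep("^(ATOM|HETATM|TER)", readLines(tmp), value = TRUE)
  }
  blocks <- purrr::map(models, fmt_model)
  if (length(blocks) == 1) {
    lines <- c(blocks[[1]], "END")
  } else {
    lines <- c(
      unlist(purrr::imap(blocks, function(b, i) {
        c(sprintf("MODEL     %4d", as.integer(i)), b, "ENDMDL")
      }), use.names = FALSE),
      "END"
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Exchange two chain identities
#'
#' Relabels chains without touching any coordinate, producing e.g. the
#' "swapped" closed reference of a homodimer in which the A and B identities
#' are reversed. Applying the same swap twice restores the input.
#'
#' @param atoms atom tibble.
#' @param id1,id2 chain identifiers to exchange.
#' @return atom tibble with chain labels exchanged.
#' @export
swap_chains <- function(atoms, id1 = "A", id2 = "B") {
  assert_atoms(atoms)
  present <- unique(atoms$chain)
  for (id in c(id1, id2)) {
    if (!id %in% present) abort(sprintf("chain '%s' not present in structure", id))
  }
  dplyr::mutate(atoms, chain = dplyr::case_when(
    .data$chain == id1 ~ id2,
    .data$chain == id2 ~ id1,
    TRUE ~ .data$chain
  ))
}

#' Select atoms by chain, residue range, atom name, and model
#'
#' Filters are combined with AND; `NULL` means "no filter". The result keeps
#' the input row order, so the same selection on the same structure always
#' yields the same ordered atom list.
#'
#' @param atoms atom tibble.
#' @param chain chain identifier(s).
#' @param res_seq residue numbers (author numbering), e.g. `5:60`.
#' @param name atom name(s), e.g. `"CA"`.
#' @param model model number(s).
#' @return filtered atom tibble.
#' @export
select_atoms <- function(atoms, chain = NULL, res_seq = NULL, name = NULL,
                         model = NULL) {
  assert_atoms(atoms)
  out <- atoms
  if (!is.null(chain)) out <- dplyr::filter(out, .data$chain %in% !!chain)
  if (!is.null(res_seq)) out <- dplyr::filter(out, .data$res_seq %in% !!res_seq)
  if (!is.null(name)) out <- dplyr::filter(out, .data$name %in% !!name)
  if (!is.null(model)) out <- dplyr::filter(out, .data$model %in% !!model)
  out
}

#' Extract a coordinate matrix from a single-model atom table
#' @param atoms atom tibble restricted to one model.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(atoms) {
  assert_atoms(atoms)
  if (n_models(atoms) != 1) abort("coords() expects a single model; filter with select_atoms(model=)")
  as.matrix(atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a single-model atom table
#' @param atoms atom tibble restricted to one model.
#' @param xyz n x 3 matrix of replacement coordinates.
#' @return atom tibble with updated `x`, `y`, `z`.
#' @export
set_coords <- function(atoms, xyz) {
  assert_atoms(atoms)
  stopifnot(nrow(xyz) == nrow(atoms), ncol(xyz) == 3)
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

# Stack a list of coordinate matrices into a multi-model atom table sharing
# the identity columns of `template` (a single-model atom tibble).
frames_to_atoms <- function(template, frames) {
  assert_atoms(template)
  dplyr::bind_rows(purrr::imap(frames, function(f, i) {
    m <- set_coords(template, f)
    m$model <- as.integer(i)
    m
  }))
}
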