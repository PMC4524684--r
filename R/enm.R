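# Coarse-grained elastic network model: one site per residue at the Calpha
# position, uniform springs between all site pairs within a distance cutoff
# (default 12 A). Diagonalizing the resulting 3Nx3N second-derivative matrix
# yields 6 trivial zero-frequency modes (rigid-body motions) and 3N-6
# nontrivial modes; with modes numbered from 1 in ascending frequency, the
# first informative mode is mode 7. The spring constant sets only the
# eigenvalue scale, never the mode shapes.

#' Build a Calpha elastic network
#'
#' @param atoms single-model atom tibble; sites are its `CA` atoms.
#' @param cutoff interaction distance cutoff in Angstrom. Springs connect all
#'   site pairs (within and across chains) with separation <= `cutoff`.
#' @param k uniform spring constant (arbitrary units).
#' @return object of class `elastic_network`: `sites` (tibble with chain,
#'   res_seq, i_code, x, y, z), `springs` (tibble i, j, d0), `cutoff`, `k`.
#' @examples
#' toy <- make_toy_dimer()
#' enm <- build_enm(toy$atoms)
#' nrow(enm$springs)
#' @export
build_enm <- function(atoms, cutoff = 12, k = 1) {
  assert_atoms(atoms)
  ca <- select_atoms(atoms, name = "CA", model = atoms$model[1])
  if (nrow(ca) < 3) abort("elastic network needs at least 3 Calpha sites")
  xyz <- coords(ca)
  d <- proxy_dist(xyz, xyz)
  if (any(d[upper.tri(d)] < 1e-6)) abort("duplicate site coordinates")
  if (qr(sweep(xyz, 2, colMeans(xyz)))$rank < 2) {
    abort("Calpha sites are collinear; the network has no well-defined modes")
  }
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  springs <- tibble(i = pairs[, 1], j = pairs[, 2],
                    d0 = d[cbind(pairs[, 1], pairs[, 2])])
  sites <- dplyr::mutate(
    ca[, c("chain", "res_seq", "i_code", "x", "y", "z")],
    site = dplyr::row_number(), .before = 1
  )
  structure(list(sites = sites, springs = springs, cutoff = cutoff, k = k),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("<elastic_network> %d sites, %d springs, cutoff %g A, k = %g\n",
              nrow(x$sites), nrow(x$springs), x$cutoff, x$k))
  invisible(x)
}

enm_connected <- function(enm) {
  n <- nrow(enm$sites)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(enm$springs))) {
    a <- find(enm$springs$i[r])
    b <- find(enm$springs$j[r])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1
}

#' Hessian of an elastic network
#'
#' The standard isotropic second-derivative matrix of the harmonic network
#' energy `sum k/2 (|r_ij| - d0_ij)^2`: each spring contributes the rank-1
#' block `k e e^T` (e the unit bond vector) to the diagonal blocks and its
#' negative to the off-diagonal blocks.
#'
#' @param enm an [build_enm()] object.
#' @return symmetric 3N x 3N matrix.
#' @export
enm_hessian <- function(enm) {
  stopifnot(inherits(enm, "elastic_network"))
  xyz <- as.matrix(enm$sites[, c("x", "y", "z")])
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(enm$springs))) {
    i <- enm$springs$i[r]
    j <- enm$springs$j[r]
    e <- unit(xyz[j, ] - xyz[i, ])
    blk <- enm$k * tcrossprod(e)
    ii <- (3 * i - 2):(3 * i)
    jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  H
}

#' Normal modes of an elastic network
#'
#' @param enm an [build_enm()] object; the network must be connected (a
#'   disconnected network has more than 6 zero modes and is rejected unless
#'   `allow_disconnected`).
#' @param n_modes number of lowest-frequency modes to retain (default all).
#' @param allow_disconnected keep going on a disconnected network.
#' @return object of class `enm_modes`: `values` (eigenvalues, ascending),
#'   `vectors` (orthonormal 3N-columns, one per mode, mode m in column m),
#'   `n_trivial` (count of numerically zero modes), `sites` (the network's
#'   site table).
#' @examples
#' toy <- make_toy_dimer()
#' modes <- compute_modes(build_enm(toy$atoms))
#' modes$n_trivial
#' @export
compute_modes <- function(enm, n_modes = NULL, allow_disconnected = FALSE) {
  stopifnot(inherits(enm, "elastic_network"))
  if (!allow_disconnected && !enm_connected(enm)) {
    abort("elastic network is disconnected (> 6 zero modes); raise the cutoff")
  }
  H <- enm_hessian(enm)
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values) # ascending
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  n_trivial <- sum(abs(values) < 1e-8 * max(abs(values)))
  if (!allow_disconnected && n_trivial != 6) {
    abort(sprintf("expected 6 trivial zero modes, found %d", n_trivial))
  }
  keep <- if (is.null(n_modes)) length(values) else min(n_modes, length(values))
  structure(list(values = values[seq_len(keep)],
                 vectors = vectors[, seq_len(keep), drop = FALSE],
                 n_trivial = n_trivial, sites = enm$sites,
                 cutoff = enm$cutoff, k = enm$k),
            class = "enm_modes")
}

#' @export
print.enm_modes <- function(x, ...) {
  cat(sprintf("<enm_modes> %d modes over %d sites (%d trivial); mode 7 eigenvalue %.4g\n",
              length(x$values), nrow(x$sites), x$n_trivial,
              if (length(x$values) >= 7) x$values[7] else NA))
  invisible(x)
}

#' @export
tidy.enm_modes <- function(x, ...) {
  n <- nrow(x$sites)
  out <- purrr::map(seq_along(x$values), function(m) {
    v <- matrix(x$vectors[, m], ncol = 3, byrow = TRUE)
    dplyr::bind_cols(
      tibble(mode = m, eigenvalue = x$values[m]),
      x$sites[, c("site", "chain", "res_seq")],
      tibble(dx = v[, 1], dy = v[, 2], dz = v[, 3])
    )
  })
  dplyr::bind_rows(out)
}

#' @export
glance.enm_modes <- function(x, ...) {
  tibble(n_sites = nrow(x$sites), n_modes = length(x$values),
         n_trivial = x$n_trivial, cutoff = x$cutoff, k = x$k)
}

new_bias <- function(v, sites, label) {
  structure(as.numeric(v), sites = sites, label = label, class = "enm_bias")
}

#' @export
print.enm_bias <- function(x, ...) {
  cat(sprintf("<enm_bias> %s over %d sites (unit norm)\n",
              attr(x, "label"), nrow(attr(x, "sites"))))
  invisible(x)
}

#' Extract one mode as a bias direction
#' @param modes an [compute_modes()] object.
#' @param mode mode number (1-based, counting the 6 trivial modes).
#' @return unit-norm bias vector of class `enm_bias`.
#' @export
mode_vector <- function(modes, mode) {
  combine_modes(modes, stats::setNames(1, mode))
}

#' Normalized linear combination of normal modes
#'
#' Builds composite bias directions such as `(e8 + e7)/sqrt(2)` or
#' `(e9 - e7)/sqrt(2)`: the weighted sum of the chosen orthonormal
#' eigenvectors, renormalized to unit length (so an equal-weight sum of two
#' modes carries the 1/sqrt(2) factor automatically).
#'
#' @param modes an [compute_modes()] object.
#' @param coefficients named numeric vector: names are mode numbers
#'   (nontrivial, i.e. > `n_trivial`), values are weights, e.g.
#'   `c("7" = 1, "8" = 1)`.
#' @return unit-norm bias vector of class `enm_bias` with a human-readable
#'   label (e.g. `"8+7"`).
#' @export
combine_modes <- function(modes, coefficients) {
  stopifnot(inherits(modes, "enm_modes"))
  idx <- as.integer(names(coefficients))
  if (length(idx) == 0 || anyNA(idx)) abort("`coefficients` must be named by mode number")
  if (all(coefficients == 0)) abort("all-zero mode weights")
  if (any(idx <= modes$n_trivial)) {
    abort(sprintf("mode indices must be nontrivial (> %d)", modes$n_trivial))
  }
  if (any(idx > length(modes$values))) abort("mode index beyond computed modes")
  v <- modes$vectors[, idx, drop = FALSE] %*% coefficients
  ord <- order(-abs(coefficients), -sign(coefficients), idx)
  lab <- paste0(ifelse(sign(coefficients[ord]) < 0, "-", "+"), idx[ord])
  lab <- sub("^\\+", "", paste(lab, collapse = ""))
  new_bias(unit(v), modes$sites, lab)
}

#' Spread a per-residue bias over all atoms of a structure
#'
#' Every atom of residue i is displaced along the bias component of site i;
#' the field is scaled so the root-mean-square per-atom displacement equals
#' `step` (Angstrom). For Calpha-only structures this is the identity
#' mapping up to scale.
#'
#' @param bias an `enm_bias` vector (carries its site table).
#' @param atoms single-model atom tibble; every residue must map to a bias
#'   site.
#' @param step RMS per-atom displacement in Angstrom.
#' @return N x 3 displacement matrix (rows follow `atoms`).
#' @export
atomize_bias <- function(bias, atoms, step = 0.01) {
  stopifnot(inherits(bias, "enm_bias"))
  assert_atoms(atoms)
  sites <- attr(bias, "sites")
  key_atoms <- paste(atoms$chain, atoms$res_seq, atoms$i_code, sep = "|")
  key_sites <- paste(sites$chain, sites$res_seq, sites$i_code, sep = "|")
  site_of <- match(key_atoms, key_sites)
  if (anyNA(site_of)) {
    miss <- unique(key_atoms[is.na(site_of)])
    abort(sprintf("residue(s) absent from mode indexing: %s",
                  paste(utils::head(miss, 5), collapse = ", ")))
  }
  per_site <- matrix(as.numeric(bias), ncol = 3, byrow = TRUE)
  disp <- per_site[site_of, , drop = FALSE]
  rms <- sqrt(mean(rowSums(disp^2)))
  if (rms < .Machine$double.eps) abort("bias field is zero on this structure")
  disp * (step / rms)
}

#' Overlap of normal modes with a conformational transition
#'
#' Superposes the target onto the start structure over the selection, forms
#' the Calpha difference vector on the mode's sites, and reports the
#' normalized inner product of every mode with that direction (values in
#' `[-1, 1]`; eigenvector sign is arbitrary, so compare magnitudes).
#'
#' @param modes an [compute_modes()] object computed on `start`.
#' @param start,target single-model atom tibbles sharing the selected
#'   Calpha set.
#' @param fit_sel selection used for the rigid superposition (named list of
#'   [select_atoms()] arguments).
#' @return tibble with columns `mode`, `eigenvalue`, `overlap`, sorted by
#'   mode number; trivial modes are excluded.
#' @export
transition_overlap <- function(modes, start, target,
                               fit_sel = list(name = "CA")) {
  stopifnot(inherits(modes, "enm_modes"))
  sup <- superpose(target, start, fit_sel = fit_sel)
  key_sites <- paste(modes$sites$chain, modes$sites$res_seq,
                     modes$sites$i_code, sep = "|")
  pick <- function(at) {
    ca <- select_atoms(at, name = "CA")
    key <- paste(ca$chain, ca$res_seq, ca$i_code, sep = "|")
    idx <- match(key_sites, key)
    if (anyNA(idx)) abort("start/target do not cover the mode site list")
    coords(ca)[idx, , drop = FALSE]
  }
  diff <- pick(sup$atoms) - pick(start)
  dvec <- unit(as.numeric(t(diff)))
  nontrivial <- seq(modes$n_trivial + 1, length(modes$values))
  tibble(
    mode = nontrivial,
    eigenvalue = modes$values[nontrivial],
    overlap = as.numeric(crossprod(modes$vectors[, nontrivial, drop = FALSE], dvec))
  )
}

#' Write or read a mode set as CSV at full precision
#'
#' Columns: mode, eigenvalue, site, chain, res_seq, dx, dy, dz. Values are
#' written with 17 significant digits so a read round trip is
#' bit-equivalent.
#'
#' @param modes an `enm_modes` object.
#' @param path CSV file path.
#' @return `read_modes()` returns an `enm_modes` object.
#' @export
write_modes <- function(modes, path) {
  td <- tidy(modes)
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "mode,eigenvalue,site,chain,res_seq,dx,dy,dz",
    sprintf("%d,%s,%d,%s,%d,%s,%s,%s", td$mode, num(td$eigenvalue), td$site,
            td$chain, td$res_seq, num(td$dx), num(td$dy), num(td$dz))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_modes
#' @export
read_modes <- function(path) {
  td <- utils::read.csv(path, colClasses = c(chain = "character"))
  sites <- dplyr::distinct(td[, c("site", "chain", "res_seq")])
  sites <- dplyr::arrange(sites, .data$site)
  sites$i_code <- ""
  n_modes <- length(unique(td$mode))
  vecs <- matrix(0, 3 * nrow(sites), n_modes)
  vals <- numeric(n_modes)
  for (m in seq_len(n_modes)) {
    h <- td[td$mode == m, ]
    h <- h[order(h$site), ]
    vecs[, m] <- as.numeric(t(as.matrix(h[, c("dx", "dy", "dz")])))
    vals[m] <- h$eigenvalue[1]
  }
  n_trivial <- sum(abs(vals) < 1e-8 * max(abs(vals)))
  structure(list(values = vals, vectors = vecs, n_trivial = n_trivial,
                 sites = tibble::as_tibble(sites), cutoff = NA_real_, k = NA_real_),
            class = "enm_modes")
}
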