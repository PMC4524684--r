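# Ensemble statistics for characterizing cooperativity: principal component
# analysis of trajectories (essential dynamics), projections onto PC
# subspaces, PC-subspace comparison via generalized dot products, cosine
# content, windowed Pearson correlations, and frame clustering.

frame_list <- function(x, sel = NULL) {
  atoms <- as_trajectory_atoms(x)
  models <- split(atoms, atoms$model)
  template <- models[[1]]
  if (!is.null(sel)) {
    idx <- do.call(select_atoms,
                   c(list(dplyr::mutate(template, .row = dplyr::row_number())),
                     sel))$.row
  } else {
    idx <- seq_len(nrow(template))
  }
  list(frames = lapply(models, coords), idx = idx, template = template)
}

sel_rows <- function(template, sel) {
  do.call(select_atoms,
          c(list(dplyr::mutate(template, .row = dplyr::row_number())), sel))$.row
}

align_frames <- function(frames, ref_xyz, fit_idx) {
  lapply(frames, function(f) {
    fit <- kabsch(f[fit_idx, , drop = FALSE], ref_xyz[fit_idx, , drop = FALSE])
    apply_rigid(f, fit$R, fit$t)
  })
}

#' Principal component analysis of a trajectory
#'
#' Every frame is rigid-body aligned onto the first frame over the alignment
#' selection; the coordinate covariance is then accumulated over the
#' analysis selection (e.g. align on the stable core domains, analyze the
#' mobile domains) and diagonalized. Mass-unweighted Cartesian PCA, the
#' essential-dynamics convention.
#'
#' @param x multi-model atom tibble or [run_geosim()] trajectory with at
#'   least 2 frames.
#' @param align_sel,analyze_sel selections (named lists of [select_atoms()]
#'   arguments).
#' @return object of class `traj_pca`: `mean` (3M mean coordinates),
#'   `rotation` (3M x r orthonormal eigenvectors, descending eigenvalue),
#'   `values` (variances), `var_frac` (fractions summing to 1), `ref`
#'   (alignment reference frame), selections, and the analyzed atom rows.
#' @examples
#' toy <- make_toy_dimer()
#' dirs <- cbind(unit(stats::rnorm(3 * sum(toy$atoms$chain == "A") * 2)))
#' trj <- make_mode_trajectory(toy$atoms, dirs, matrix(sin(1:50 / 5)), noise = 0.01)
#' fit <- traj_pca(trj)
#' fit$var_frac[1]
#' @export
traj_pca <- function(x, align_sel = list(name = "CA"),
                     analyze_sel = list(name = "CA")) {
  fl <- frame_list(x)
  if (length(fl$frames) < 2) abort("PCA needs at least 2 frames")
  fit_idx <- sel_rows(fl$template, align_sel)
  an_idx <- sel_rows(fl$template, analyze_sel)
  if (length(fit_idx) < 3 || length(an_idx) < 1) abort("empty PCA selection")
  ref <- fl$frames[[1]]
  aligned <- align_frames(fl$frames, ref, fit_idx)
  X <- t(vapply(aligned, function(f) as.numeric(t(f[an_idx, , drop = FALSE])),
                numeric(3 * length(an_idx))))
  if (max(abs(sweep(X, 2, X[1, ]))) < 1e-12) {
    abort("all frames are identical; covariance is degenerate")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  values <- pc$sdev^2
  keep <- values > 1e-12 * values[1]
  structure(list(mean = pc$center, rotation = pc$rotation[, keep, drop = FALSE],
                 values = values[keep], var_frac = values[keep] / sum(values),
                 ref = ref, align_sel = align_sel, analyze_sel = analyze_sel,
                 fit_idx = fit_idx, an_idx = an_idx,
                 template = fl$template),
            class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  cat(sprintf("<traj_pca> %d components over %d coordinates; PC1 %.1f%%, PC2 %.1f%%\n",
              length(x$values), length(x$mean), 100 * x$var_frac[1],
              if (length(x$var_frac) > 1) 100 * x$var_frac[2] else 0))
  invisible(x)
}

#' @export
tidy.traj_pca <- function(x, ...) {
  tibble(pc = seq_along(x$values), variance = x$values,
         var_frac = x$var_frac, cum_frac = cumsum(x$var_frac))
}

#' @export
glance.traj_pca <- function(x, ...) {
  tibble(n_components = length(x$values), pc1_frac = x$var_frac[1],
         pc2_frac = if (length(x$var_frac) > 1) x$var_frac[2] else NA_real_)
}

#' Project trajectory frames onto principal components
#'
#' Frames (from the same system, possibly from a different simulation
#' method - e.g. geometric-simulation frames projected on MD-derived PCs)
#' are aligned to the PCA's reference frame and projected on the chosen
#' eigenvectors.
#'
#' @param x multi-model atom tibble or geosim trajectory.
#' @param pca a [traj_pca()] object.
#' @param k component indices.
#' @return tibble with columns `frame`, `pc`, `value` (Angstrom).
#' @export
project_frames <- function(x, pca, k = 1:2) {
  stopifnot(inherits(pca, "traj_pca"))
  fl <- frame_list(x)
  if (nrow(fl$template) != nrow(pca$template)) {
    abort("frames do not match the PCA's atom list")
  }
  k <- k[k <= ncol(pca$rotation)]
  aligned <- align_frames(fl$frames, pca$ref, pca$fit_idx)
  out <- purrr::imap(aligned, function(f, i) {
    v <- as.numeric(t(f[pca$an_idx, , drop = FALSE])) - pca$mean
    tibble(frame = as.integer(i), pc = as.integer(k),
           value = as.numeric(crossprod(pca$rotation[, k, drop = FALSE], v)))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$frame, .data$pc)
}

#' Generalized dot product between principal component eigenvectors
#'
#' The plain inner product formed by summing products of corresponding
#' entries; `subspace_coverage()` sums the squared dots of one vector
#' against a set (how much of the vector lies in the set's span - exactly 1
#' when the set is a rotation of a basis containing it).
#'
#' @param v1,v2 numeric vectors of equal length.
#' @param basis matrix whose columns form the comparison vector set.
#' @return scalar.
#' @export
generalized_dot <- function(v1, v2) {
  if (length(v1) != length(v2)) abort("vectors differ in length")
  sum(v1 * v2)
}

#' @rdname generalized_dot
#' @export
subspace_coverage <- function(v1, basis) {
  basis <- as.matrix(basis)
  if (nrow(basis) != length(v1)) abort("vector and basis differ in length")
  sum(as.numeric(crossprod(basis, v1))^2)
}

#' Cosine content of a projection series
#'
#' The squared normalized inner product of the (centered) series with a
#' half-period cosine `cos(i pi t / T)`, the essential-dynamics diagnostic:
#' values near 1 indicate random-diffusion-like sampling, values near 0 a
#' converged, non-cosine motion.
#'
#' @param series numeric vector, length >= 4.
#' @param i cosine index (default 1: half period over the series).
#' @return value in `[0, 1]`; 0 for a constant series.
#' @export
cosine_content <- function(series, i = 1) {
  n <- length(series)
  if (n < 4) abort("series too short for cosine content")
  x <- series - mean(series)
  ss <- sum(x^2)
  if (ss < .Machine$double.eps) return(0)
  tt <- (seq_len(n) - 0.5) / n
  cc <- cos(i * pi * tt)
  (sum(x * cc)^2 / sum(cc^2)) / ss
}

#' Windowed Pearson correlation between two measure series
#'
#' Pearson R (sample convention) over sliding windows, plus the overall R.
#' Windows with zero variance in either series yield `NA`, never 0. An
#' optional burn-in prefix is excluded from both the windows and the
#' overall value.
#'
#' @param x,y numeric vectors of equal length.
#' @param window window length in frames.
#' @param stride window stride in frames (default: non-overlapping).
#' @param burn_in frames to drop from the start.
#' @return object of class `correlation_series`: `windows` (tibble
#'   start/end/r), `overall`, `mean_r`, `sd_r`, and the parameters.
#' @examples
#' s <- make_correlated_series(1000, rho = 0.8)
#' windowed_pearson(s$x, s$y, window = 100)
#' @export
windowed_pearson <- function(x, y, window, stride = window, burn_in = 0) {
  if (length(x) != length(y)) abort("series differ in length")
  if (length(x) - burn_in < window) abort("series shorter than one window")
  x <- x[(burn_in + 1):length(x)]
  y <- y[(burn_in + 1):length(y)]
  starts <- seq(1, length(x) - window + 1, by = stride)
  r <- vapply(starts, function(s) {
    xs <- x[s:(s + window - 1)]
    ys <- y[s:(s + window - 1)]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_
    else stats::cor(xs, ys)
  }, numeric(1))
  overall <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
             else stats::cor(x, y)
  structure(list(
    windows = tibble(window = seq_along(starts), start = starts + burn_in,
                     end = starts + burn_in + window - 1, r = r),
    overall = overall, mean_r = mean(r, na.rm = TRUE),
    sd_r = stats::sd(r, na.rm = TRUE),
    window = window, stride = stride, burn_in = burn_in
  ), class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("<correlation_series> overall R %.3f; windows (%d frames): %.2f +/- %.2f\n",
              x$overall, x$window, x$mean_r, x$sd_r))
  invisible(x)
}

#' @export
tidy.correlation_series <- function(x, ...) x$windows

#' @export
glance.correlation_series <- function(x, ...) {
  tibble(overall_r = x$overall, mean_r = x$mean_r, sd_r = x$sd_r,
         n_windows = nrow(x$windows), window = x$window, stride = x$stride,
         burn_in = x$burn_in)
}

#' Hierarchical clustering of trajectory frames
#'
#' Average-linkage agglomeration on the pairwise RMSD matrix: frames are
#' fitted on the fit selection and RMSD is measured over the cluster
#' selection (e.g. fit on the core, cluster on the mobile domains). The
#' representative of each cluster is its medoid.
#'
#' @param x multi-model atom tibble or geosim trajectory.
#' @param n_clusters number of clusters (>= 1).
#' @param fit_sel,cluster_sel selections (named lists of [select_atoms()]
#'   arguments).
#' @return list of class `frame_clustering`: `assignments` (tibble
#'   frame/cluster), `medoids` (frame index per cluster), `avg_dist`
#'   (tibble cluster/mean RMSD to medoid), `rmsd` (the distance matrix).
#' @export
cluster_frames <- function(x, n_clusters, fit_sel = list(name = "CA"),
                           cluster_sel = list(name = "CA")) {
  if (n_clusters < 1) abort("`n_clusters` must be >= 1")
  fl <- frame_list(x)
  nT <- length(fl$frames)
  if (nT < n_clusters) abort("fewer frames than requested clusters")
  fit_idx <- sel_rows(fl$template, fit_sel)
  cl_idx <- sel_rows(fl$template, cluster_sel)
  D <- matrix(0, nT, nT)
  for (a in seq_len(nT - 1)) {
    for (b in (a + 1):nT) {
      fit <- kabsch(fl$frames[[b]][fit_idx, , drop = FALSE],
                    fl$frames[[a]][fit_idx, , drop = FALSE])
      moved <- apply_rigid(fl$frames[[b]], fit$R, fit$t)
      D[a, b] <- D[b, a] <- rmsd_xyz(moved[cl_idx, , drop = FALSE],
                                     fl$frames[[a]][cl_idx, , drop = FALSE])
    }
  }
  assign <- if (n_clusters == 1) rep(1L, nT) else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    as.integer(stats::cutree(hc, k = n_clusters))
  }
  medoids <- vapply(seq_len(n_clusters), function(cl) {
    members <- which(assign == cl)
    members[which.min(rowMeans(D[members, members, drop = FALSE]))]
  }, integer(1))
  avg <- vapply(seq_len(n_clusters), function(cl) {
    members <- which(assign == cl)
    mean(D[members, medoids[cl]])
  }, numeric(1))
  structure(list(
    assignments = tibble(frame = seq_len(nT), cluster = assign),
    medoids = medoids,
    avg_dist = tibble(cluster = seq_len(n_clusters), mean_rmsd = avg),
    rmsd = D
  ), class = "frame_clustering")
}

#' @export
print.frame_clustering <- function(x, ...) {
  cat(sprintf("<frame_clustering> %d clusters over %d frames; mean RMSD to medoid %.2f A\n",
              nrow(x$avg_dist), nrow(x$assignments), mean(x$avg_dist$mean_rmsd)))
  invisible(x)
}

#' @export
tidy.frame_clustering <- function(x, ...) x$assignments
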