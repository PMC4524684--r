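# Pebble games for rigidity analysis of constraint multigraphs. Two
# instantiations are used:
#
#   * body-bar (k = 6, l = 6): atoms are 3D bodies, constraints are bars
#     with multiplicity (rotatable covalent bond 5, locked/peptide bond 6,
#     hydrogen bond 5, hydrophobic tether 2). Since l + 1 = 7 <= 2k, the
#     standard matroidal rule applies: a bar is independent iff 7 free
#     pebbles can be gathered on its endpoints, and the stalled search
#     region of a locked pair is its rigid component.
#   * bar-joint points (k = 3, l = 6): sites are 3D points, constraints are
#     single distance bars (coarse Calpha networks: chain bonds, angle bars,
#     tethers). Here l + 1 = 7 exceeds the 2k = 6 pebbles two points can
#     hold, so after pinning 3 + 3 at the endpoints the seventh pebble is
#     sought at the constraint neighbours of the pair, accumulating pinned
#     pebbles until 7 certify independence. This is the molecular-framework
#     variant of the game: exact for bond-bending-style networks (every
#     internal site carries bond and angle constraints), which is the class
#     the coarse networks in this package belong to; general 3D bar-joint
#     rigidity has no exact combinatorial test.
#
# A bar incident to a site with no placed constraint is always independent
# (a fresh point contributes three degrees of freedom and the bar removes
# one), which also covers the first bar of an isolated pair.

pebble_engine <- function(n, k) {
  env <- new.env(parent = emptyenv())
  env$n <- n
  env$k <- k
  env$pebbles <- rep(as.integer(k), n)
  env$pins <- integer(n)
  env$deg <- integer(n) # placed-bar degree
  env$out <- vector("list", n)
  for (i in seq_len(n)) env$out[[i]] <- integer(0)
  env
}

# DFS over the pebble orientation from `root`, looking for an unpinned free
# pebble. On success the path is reversed and the pebble migrates to `root`.
# `within` (optional logical mask) restricts the traversal to a vertex
# subset. Returns list(found, visited).
pebble_take <- function(eng, root, within = NULL) {
  visited <- logical(eng$n)
  pred <- integer(eng$n)
  stack <- root
  visited[root] <- TRUE
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in unique(eng$out[[v]])) {
      if (!visited[w] && (is.null(within) || within[w])) {
        visited[w] <- TRUE
        pred[w] <- v
        if (eng$pebbles[w] > eng$pins[w]) {
          path <- w
          while (pred[path[1]] != 0L) path <- c(pred[path[1]], path)
          for (t in seq_len(length(path) - 1)) {
            a <- path[t]
            b <- path[t + 1]
            hit <- match(b, eng$out[[a]])
            eng$out[[a]] <- eng$out[[a]][-hit]
            eng$out[[b]] <- c(eng$out[[b]], a)
          }
          eng$pebbles[w] <- eng$pebbles[w] - 1L
          eng$pebbles[root] <- eng$pebbles[root] + 1L
          return(list(found = TRUE, visited = visited))
        }
        stack <- c(stack, w)
      }
    }
  }
  list(found = FALSE, visited = visited)
}

# Maximize (and pin) free pebbles on u and v. Returns the pinned total and
# the union of failed-search regions.
pebble_gather <- function(eng, u, v) {
  eng$pins[u] <- eng$pebbles[u]
  eng$pins[v] <- eng$pebbles[v]
  region <- logical(eng$n)
  region[c(u, v)] <- TRUE
  repeat {
    moved <- FALSE
    for (x in c(u, v)) {
      if (eng$pebbles[x] < eng$k) {
        s <- pebble_take(eng, x)
        if (s$found) {
          eng$pins[x] <- eng$pebbles[x]
          moved <- TRUE
        } else {
          region <- region | s$visited
        }
      }
    }
    if (!moved || eng$pebbles[u] + eng$pebbles[v] >= 2 * eng$k) break
  }
  list(tot = eng$pebbles[u] + eng$pebbles[v], region = region)
}

# Test whether one more bar between u and v would be independent; `nbrs`
# supplies the constraint neighbourhood used by the point game's
# seventh-pebble stage. With `star_only`, that stage may only collect and
# route pebbles within the pair's immediate neighbourhood: the conservative
# variant used for locked-pair/rigid-component queries, which prevents a
# spare degree of freedom elsewhere in the framework (reachable through a
# bridging constraint) from masquerading as flexibility of the pair.
# Clears all pins before returning. Returns list(indep, region).
pebble_test <- function(eng, u, v, l, nbrs = NULL, star_only = FALSE) {
  on.exit(eng$pins[] <- 0L)
  if (eng$deg[u] == 0L || eng$deg[v] == 0L) {
    return(list(indep = TRUE, region = NULL))
  }
  g <- pebble_gather(eng, u, v)
  pinned <- g$tot
  if (pinned >= l + 1) return(list(indep = TRUE, region = NULL))
  region <- g$region
  if (!is.null(nbrs) && pinned == 2 * eng$k) {
    # point game: hunt the (l+1)th pebble in the pair's neighbourhood
    cand <- setdiff(nbrs, c(u, v))
    within <- NULL
    if (star_only) {
      within <- logical(eng$n)
      within[c(u, v, cand)] <- TRUE
    }
    for (x in cand) {
      repeat {
        if (eng$pebbles[x] > eng$pins[x]) {
          eng$pins[x] <- eng$pins[x] + 1L
          pinned <- pinned + 1L
          if (pinned >= l + 1) return(list(indep = TRUE, region = NULL))
        } else {
          s <- pebble_take(eng, x, within = within)
          if (s$found) next
          region <- region | s$visited
          break
        }
      }
    }
    region[cand] <- TRUE
  }
  list(indep = FALSE, region = which(region))
}

#' Low-level pebble-game run on a bar multigraph
#'
#' @param n number of sites/bodies.
#' @param edges tibble or data frame with integer columns `i`, `j` and
#'   `bars` (multiplicity); processed in row order.
#' @param k pebbles (degrees of freedom) per site: 3 for bar-joint points,
#'   6 for body-bar.
#' @param l trivial motion count (6 in three dimensions).
#' @return list: `floppy` (internal floppy mode count, total free pebbles
#'   minus `l`), `independent`/`redundant` (bar counts), `engine` (game
#'   state for component queries), `nbr` (constraint adjacency).
#' @keywords internal
pebble_run <- function(n, edges, k, l = 6) {
  eng <- pebble_engine(n, k)
  nbr <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    nbr[[edges$i[r]]] <- c(nbr[[edges$i[r]]], edges$j[r])
    nbr[[edges$j[r]]] <- c(nbr[[edges$j[r]]], edges$i[r])
  }
  nbr <- lapply(nbr, function(x) sort(unique(x)))
  indep <- 0L
  redun <- 0L
  point <- k * 2 < l + 1
  for (r in seq_len(nrow(edges))) {
    u <- edges$i[r]
    v <- edges$j[r]
    if (u == v) abort("self-constraint in network")
    nb <- edges$bars[r]
    for (b in seq_len(nb)) {
      t <- pebble_test(eng, u, v, l,
                       nbrs = if (point) c(nbr[[u]], nbr[[v]]) else NULL)
      if (t$indep) {
        if (eng$pebbles[u] > 0) {
          eng$pebbles[u] <- eng$pebbles[u] - 1L
          eng$out[[u]] <- c(eng$out[[u]], v)
        } else {
          eng$pebbles[v] <- eng$pebbles[v] - 1L
          eng$out[[v]] <- c(eng$out[[v]], u)
        }
        eng$deg[u] <- eng$deg[u] + 1L
        eng$deg[v] <- eng$deg[v] + 1L
        indep <- indep + 1L
      } else {
        redun <- redun + nb - b + 1L
        break # remaining bars of this constraint are redundant too
      }
    }
  }
  list(floppy = sum(eng$pebbles) - l, independent = indep, redundant = redun,
       engine = eng, l = l, nbr = nbr, point = point)
}

# Merge vertex sets that overlap in >= 3 sites: two rigid sets sharing
# three generic points are mutually rigid.
merge_regions <- function(comps) {
  nc <- length(comps)
  if (nc == 0) return(list())
  parent <- seq_len(nc)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nc > 1) {
    for (a in seq_len(nc - 1)) {
      for (b in (a + 1):nc) {
        if (find(a) != find(b) &&
            length(intersect(comps[[a]], comps[[b]])) >= 3) {
          parent[find(a)] <- find(b)
        }
      }
    }
  }
  roots <- vapply(seq_len(nc), find, integer(1))
  lapply(unique(roots), function(rt) sort(unique(unlist(comps[roots == rt]))))
}

# Rigid components.
#
# Body-bar game: the failed-search region of a locked pair (fewer than l+1
# pebbles gatherable on its endpoints) is a tight set; regions collected
# over all network pairs and merged give the components.
#
# Point game: components are built constructively. A constraint triangle is
# rigid; a vertex carrying >= 3 bars into a rigid set is generically
# rigidly attached (0-extension); rigid sets sharing >= 3 sites merge.
# Only components of >= 4 sites are reported (every bonded pair or
# triangle is trivially rigid and says nothing about larger structure), so
# a covalent bond is "locked" exactly when it is interior to a component
# large enough to block torsion about the bond axis.
pebble_components <- function(run, pairs) {
  eng <- run$engine
  n <- eng$n
  if (run$point) {
    adj <- run$nbr
    comps <- list()
    member <- vector("list", n)
    for (r in seq_len(nrow(pairs))) {
      u <- pairs$i[r]
      v <- pairs$j[r]
      if (length(intersect(member[[u]], member[[v]])) > 0) next
      w <- intersect(adj[[u]], adj[[v]])
      if (length(w) == 0) next
      S <- logical(n)
      S[c(u, v, w[1])] <- TRUE
      repeat {
        outside <- which(!S)
        cnt <- vapply(outside, function(o) sum(S[adj[[o]]]), integer(1))
        grow <- outside[cnt >= 3]
        if (length(grow) == 0) break
        S[grow] <- TRUE
      }
      if (sum(S) >= 4) {
        id <- length(comps) + 1L
        comps[[id]] <- which(S)
        for (m in comps[[id]]) member[[m]] <- c(member[[m]], id)
      }
    }
    merged <- merge_regions(comps)
  } else {
    comp_of <- vector("list", n)
    comps <- list()
    for (r in seq_len(nrow(pairs))) {
      u <- pairs$i[r]
      v <- pairs$j[r]
      if (length(intersect(comp_of[[u]], comp_of[[v]])) > 0) next
      t <- pebble_test(eng, u, v, run$l)
      if (!t$indep && length(t$region) >= 2) {
        id <- length(comps) + 1L
        comps[[id]] <- t$region
        for (w in t$region) comp_of[[w]] <- c(comp_of[[w]], id)
      }
    }
    merged <- merge_regions(comps)
  }
  in_same <- function(u, v) {
    any(vapply(merged, function(m) (u %in% m) && (v %in% m), logical(1)))
  }
  locked <- vapply(seq_len(nrow(pairs)), function(r) {
    in_same(pairs$i[r], pairs$j[r])
  }, logical(1))
  list(components = merged, locked = locked)
}
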