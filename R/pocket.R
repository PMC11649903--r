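#' Grid definition for pocket-volume measurement
#'
#' The inclusion region is a sphere centered on the axis between two
#' atom pairs: the center is the midpoint of the segment connecting the
#' midpoints of `pair1` and `pair2`. The sphere is flooded with an
#' axis-aligned grid anchored at the center (points at
#' `center + spacing * (i, j, k)`); points within `exclusion` of any
#' heavy atom are deleted (strictly closer than the cutoff; exact ties
#' are retained), points outside the convex hull of the heavy atoms are
#' removed when `hull_prune` is on, and the volume is the surviving
#' point count times `spacing^3`.
#'
#' @param pair1,pair2 Each a 2-element character vector of
#'   `"chain:resno:atom"` selectors defining the axis.
#' @param radius Sphere radius, A (default 12).
#' @param spacing Grid spacing, A (default 0.5; must be < radius).
#' @param exclusion Heavy-atom exclusion radius, A (default 1.09).
#' @param hull_prune Remove grid points outside the heavy-atom convex
#'   hull (default TRUE).
#' @return An object of class `pocket_spec`.
#' @export
pocket_spec <- function(pair1, pair2, radius = 12, spacing = 0.5,
                        exclusion = 1.09, hull_prune = TRUE) {
  stopifnot(is.character(pair1), length(pair1) == 2L,
            is.character(pair2), length(pair2) == 2L,
            radius > 0, spacing > 0, exclusion > 0)
  if (spacing >= radius) stop("grid spacing must be smaller than the radius")
  structure(list(pair1 = pair1, pair2 = pair2, radius = radius,
                 spacing = spacing, exclusion = exclusion,
                 hull_prune = isTRUE(hull_prune)),
            class = "pocket_spec")
}

#' Pocket volume by grid flooding
#'
#' Implements the grid-flood cavity measurement on one (pre-aligned)
#' frame: flood the spherical inclusion region with an equidistant
#' grid, delete points within the exclusion radius of any heavy atom
#' (element other than hydrogen), optionally prune points outside the
#' convex hull of the heavy atoms, and report the remaining volume.
#'
#' @param frame A [md_frame], already superposed onto the ensemble
#'   reference.
#' @param spec A [pocket_spec].
#' @return List of class `pocket_volume`: `volume` (A^3), `n_points`,
#'   `n_sphere` (grid points in the sphere before pruning),
#'   `n_removed_atoms`, `n_removed_hull`, `center`, `spacing`, `grid`
#'   (matrix of surviving points).
#' @export
pocket_volume <- function(frame, spec) {
  stopifnot(inherits(frame, "md_frame"), inherits(spec, "pocket_spec"))
  mid <- function(pair) {
    a <- .atom_xyz(frame, .resolve_atom(frame, pair[1L]))[1L, ]
    b <- .atom_xyz(frame, .resolve_atom(frame, pair[2L]))[1L, ]
    (a + b) / 2
  }
  center <- (mid(spec$pair1) + mid(spec$pair2)) / 2

  s <- spec$spacing
  r <- spec$radius
  kmax <- floor(r / s)
  offs <- s * seq(-kmax, kmax)
  grid <- as.matrix(expand.grid(x = offs, y = offs, z = offs))
  inside <- rowSums(grid^2) <= r^2 + 1e-9        # boundary points retained
  grid <- grid[inside, , drop = FALSE]
  grid <- sweep(grid, 2L, center, "+")
  n_sphere <- nrow(grid)

  heavy <- which(frame$elem != "H")
  alive <- rep(TRUE, n_sphere)
  if (length(heavy)) {
    axyz <- .atom_xyz(frame, heavy)
    ex2 <- spec$exclusion^2
    for (i in seq_len(nrow(axyz))) {
      d2 <- (grid[, 1L] - axyz[i, 1L])^2 + (grid[, 2L] - axyz[i, 2L])^2 +
        (grid[, 3L] - axyz[i, 3L])^2
      alive <- alive & (d2 >= ex2 - 1e-9)        # strict <: ties retained
    }
  }
  n_removed_atoms <- sum(!alive)

  n_removed_hull <- 0L
  if (spec$hull_prune) {
    if (!length(heavy))
      stop("hull pruning requires at least one heavy atom")
    hull <- .convex_hull3d(.atom_xyz(frame, heavy))
    idx_alive <- which(alive)
    if (length(idx_alive)) {
      inhull <- .points_in_hull(grid[idx_alive, , drop = FALSE], hull)
      n_removed_hull <- sum(!inhull)
      alive[idx_alive[!inhull]] <- FALSE
    }
  }

  keep <- which(alive)
  structure(list(volume = length(keep) * s^3, n_points = length(keep),
                 n_sphere = n_sphere, n_removed_atoms = n_removed_atoms,
                 n_removed_hull = n_removed_hull, center = center,
                 spacing = s, grid = grid[keep, , drop = FALSE]),
            class = "pocket_volume")
}

#' @export
print.pocket_volume <- function(x, ...) {
  cat(sprintf(
    "Pocket volume %.1f A^3 (%d of %d grid points at %.2f A spacing;\n",
    x$volume, x$n_points, x$n_sphere, x$spacing))
  cat(sprintf("  %d removed near heavy atoms, %d outside the hull)\n",
              x$n_removed_atoms, x$n_removed_hull))
  invisible(x)
}

# ---- 3D convex hull (incremental quickhull) ------------------------------
# Returns list(normals = F x 3 unit outward normals, offsets = F,
# vertices) with facet planes n.x <= d for interior points.

.convex_hull3d <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 4L) stop("convex hull needs >= 4 non-coplanar points")
  scale <- max(apply(pts, 2L, function(c) diff(range(c))), 1e-12)
  eps <- 1e-9 * scale

  # initial simplex from extreme points
  i1 <- which.min(pts[, 1L]); i2 <- which.max(pts[, 1L])
  if (i1 == i2) stop("degenerate point set (all x equal)")
  d_line <- function(p, a, b) {
    ab <- b - a
    .vnorm(.cross3(p - a, ab)) / .vnorm(ab)
  }
  dl <- vapply(seq_len(n), function(i) d_line(pts[i, ], pts[i1, ],
                                              pts[i2, ]), numeric(1L))
  i3 <- which.max(dl)
  if (dl[i3] < eps) stop("degenerate point set (collinear)")
  nrm <- .cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / .vnorm(nrm)
  dp <- abs(as.vector((pts - matrix(pts[i1, ], n, 3L, byrow = TRUE)) %*%
                        nrm))
  i4 <- which.max(dp)
  if (dp[i4] < eps) stop("degenerate point set (coplanar)")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  mk_facet <- function(a, b, c) {
    nn <- .cross3(pts[b, ] - pts[a, ], pts[c, ] - pts[a, ])
    nn <- nn / .vnorm(nn)
    if (sum(nn * (interior - pts[a, ])) > 0) { nn <- -nn
      tmp <- b; b <- c; c <- tmp }
    list(v = c(a, b, c), n = nn, d = sum(nn * pts[a, ]))
  }
  facets <- list(mk_facet(i1, i2, i3), mk_facet(i1, i2, i4),
                 mk_facet(i1, i3, i4), mk_facet(i2, i3, i4))

  # assign points to facets they lie outside of
  outside_of <- function(f, cand) {
    if (!length(cand)) return(integer(0))
    above <- as.vector(pts[cand, , drop = FALSE] %*% f$n) - f$d > eps
    cand[above]
  }
  cand0 <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (k in seq_along(facets))
    facets[[k]]$out <- outside_of(facets[[k]], cand0)

  repeat {
    fi <- which(vapply(facets, function(f) length(f$out) > 0,
                       logical(1L)))[1L]
    if (is.na(fi)) break
    f <- facets[[fi]]
    h <- as.vector(pts[f$out, , drop = FALSE] %*% f$n) - f$d
    apex <- f$out[which.max(h)]
    visible <- which(vapply(facets, function(g)
      sum(g$n * pts[apex, ]) - g$d > eps, logical(1L)))
    # horizon: edges belonging to exactly one visible facet
    edges <- do.call(rbind, lapply(facets[visible], function(g)
      rbind(sort(g$v[c(1L, 2L)]), sort(g$v[c(2L, 3L)]),
            sort(g$v[c(1L, 3L)]))))
    ekey <- paste(edges[, 1L], edges[, 2L])
    horizon <- edges[ekey %in% names(which(table(ekey) == 1L)), ,
                     drop = FALSE]
    orphan <- unique(unlist(lapply(facets[visible], `[[`, "out")))
    orphan <- setdiff(orphan, apex)
    facets <- facets[-visible]
    for (e in seq_len(nrow(horizon))) {
      nf <- mk_facet(horizon[e, 1L], horizon[e, 2L], apex)
      nf$out <- outside_of(nf, orphan)
      facets[[length(facets) + 1L]] <- nf
    }
    # points outside no facet are interior; drop them implicitly
  }

  list(normals = do.call(rbind, lapply(facets, `[[`, "n")),
       offsets = vapply(facets, `[[`, numeric(1L), "d"),
       vertices = sort(unique(unlist(lapply(facets, `[[`, "v")))),
       eps = eps)
}

# membership test: inside (or on) every facet plane
.points_in_hull <- function(pts, hull, tol = NULL) {
  if (is.null(tol)) tol <- hull$eps
  pts <- as.matrix(pts)
  proj <- pts %*% t(hull$normals)
  apply(sweep(proj, 2L, hull$offsets) <= tol, 1L, all)
}
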