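## ---------------------------------------------------------------------------
## Structured-grid tetrahedralisation (Kuhn/Freudenthal split)
## ---------------------------------------------------------------------------

# Six-simplex split of the unit cube along the (0,0,0)-(1,1,1) diagonal.
# Corner index is 1 + dx + 2*dy + 4*dz.  Adjacent cells in a structured grid
# triangulated this way share face diagonals (low corner -> high corner), so
# the global mesh is conforming, including across a periodic seam.
.kuhn_corners <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  e <- diag(3)
  out <- matrix(0L, 6L, 4L)
  for (p in seq_along(perms)) {
    s <- perms[[p]]
    c0 <- c(0, 0, 0)
    c1 <- c0 + e[s[1], ]
    c2 <- c1 + e[s[2], ]
    c3 <- c(1, 1, 1)
    out[p, ] <- vapply(list(c0, c1, c2, c3),
                       function(v) 1L + as.integer(v[1] + 2 * v[2] + 4 * v[3]),
                       integer(1))
  }
  out
})

# hex8: n_cells x 8 matrix of vertex ids (corner order 1 + dx + 2dy + 4dz).
# Returns the 6*n_cells x 4 tetrahedra; degenerate ones (repeated ids,
# from collapsed apex rings) are dropped by the caller.
.kuhn_split <- function(hex8) {
  nc <- nrow(hex8)
  tets <- matrix(0L, 6L * nc, 4L)
  for (p in 1:6) {
    tets[seq.int(p, by = 6L, length.out = nc), ] <- hex8[, .kuhn_corners[p, ]]
  }
  tets
}

# Signed volumes of tetrahedra (mm^3).
tet_signed_volumes <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 2], , drop = FALSE] - a
  c_ <- vertices[tets[, 3], , drop = FALSE] - a
  d <- vertices[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# Boundary faces: triangles appearing in exactly one tetrahedron.
.boundary_faces <- function(tets) {
  faceidx <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  faces <- matrix(0L, 4L * nrow(tets), 3L)
  for (f in 1:4) {
    faces[seq.int(f, by = 4L, length.out = nrow(tets)), ] <-
      tets[, faceidx[f, ]]
  }
  key <- apply(faces, 1L, function(r) paste(sort.int(r), collapse = "_"))
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

.finalize_mesh <- function(vertices, tets) {
  # drop degenerate tets (collapsed apex corners), orient positively
  dup <- (tets[, 1] == tets[, 2]) | (tets[, 1] == tets[, 3]) |
         (tets[, 1] == tets[, 4]) | (tets[, 2] == tets[, 3]) |
         (tets[, 2] == tets[, 4]) | (tets[, 3] == tets[, 4])
  tets <- tets[!dup, , drop = FALSE]
  v <- tet_signed_volumes(vertices, tets)
  neg <- v < 0
  if (any(neg)) {
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
    v[neg] <- -v[neg]
  }
  keep <- v > 1e-12 * max(v)
  tets <- tets[keep, , drop = FALSE]
  v <- v[keep]
  structure(
    list(vertices = vertices, tetrahedra = tets,
         boundary_faces = .boundary_faces(tets), cell_volumes = v),
    class = "bv_mesh")
}

#' Tetrahedral mesh of an axis-aligned box (internal test helper)
#'
#' Conforming Kuhn triangulation of `[0, L] x [0, W] x [0, H]`; used for
#' manufactured-solution convergence studies where homogeneous Neumann data
#' can be imposed exactly.
#'
#' @param lengths box edge lengths (mm), length 3.
#' @param n cells per direction, length 3 (or scalar).
#' @return a `bv_mesh`.
#' @keywords internal
mesh_box <- function(lengths = c(1, 1, 1), n = c(4, 4, 4)) {
  n <- rep_len(as.integer(n), 3L)
  stopifnot(all(n >= 1), all(lengths > 0))
  xs <- seq(0, lengths[1], length.out = n[1] + 1L)
  ys <- seq(0, lengths[2], length.out = n[2] + 1L)
  zs <- seq(0, lengths[3], length.out = n[3] + 1L)
  vid <- function(i, j, k) 1L + i + (n[1] + 1L) * (j + (n[2] + 1L) * k)
  g <- expand.grid(i = 0:n[1], j = 0:n[2], k = 0:n[3])
  vertices <- cbind(xs[g$i + 1L], ys[g$j + 1L], zs[g$k + 1L])
  cg <- expand.grid(i = 0:(n[1] - 1L), j = 0:(n[2] - 1L), k = 0:(n[3] - 1L))
  hex8 <- matrix(0L, nrow(cg), 8L)
  corner <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  for (cidx in 1:8) {
    hex8[, cidx] <- vid(cg$i + corner$dx[cidx], cg$j + corner$dy[cidx],
                        cg$k + corner$dz[cidx])
  }
  .finalize_mesh(vertices, .kuhn_split(hex8))
}

## ---------------------------------------------------------------------------
## Biventricular shell generator
## ---------------------------------------------------------------------------

# Point on the shell: phi azimuth, t in [0,1] meridional (t=1 apex),
# w in [0,1] radial (0 inner surface, 1 outer surface).
.shell_point <- function(phi, t, w, inner, outer, trunc_height) {
  ax <- inner[1] + (outer[1] - inner[1]) * w
  ay <- inner[2] + (outer[2] - inner[2]) * w
  az <- inner[3] + (outer[3] - inner[3]) * w
  th_top <- acos(trunc_height / az)
  th <- th_top + t * (pi - th_top)
  cbind(ax * sin(th) * cos(phi), ay * sin(th) * sin(phi), az * cos(th))
}

# Volume of the part of an ellipsoid (semi-axes a,b,c) below the plane z = h.
ellipsoid_cap_volume <- function(axes, h) {
  a <- axes[1]; b <- axes[2]; c_ <- axes[3]
  stopifnot(abs(h) <= c_)
  pi * a * b * (h - h^3 / (3 * c_^2) + 2 * c_ / 3)
}

#' Generate a synthetic biventricular porous domain
#'
#' Builds a watertight tetrahedral mesh of a truncated ellipsoidal shell that
#' stands in for the biventricular myocardium treated as a porous medium:
#' the wall between an inner (endocardial) and an outer (epicardial)
#' ellipsoid, cut by the basal plane `z = trunc_height`.  Default dimensions
#' give a wall volume of roughly 150 mL.
#'
#' The mesh is a conforming Kuhn triangulation of a structured
#' azimuth/meridian/transmural grid, with the apex rings collapsed to single
#' vertices, so refinement is fully deterministic.
#'
#' @param outer_axes semi-axes (mm) of the epicardial ellipsoid, length 3.
#' @param inner_axes semi-axes (mm) of the endocardial ellipsoid; must be
#'   strictly inside `outer_axes`.
#' @param trunc_height basal truncation plane height z (mm); must satisfy
#'   `abs(trunc_height) < inner_axes[3]`.
#' @param target_edge requested mean edge length (mm).
#' @return an object of class `bv_mesh` with fields `vertices` (n x 3, mm),
#'   `tetrahedra` (m x 4 vertex indices, positively oriented),
#'   `boundary_faces` (triangles on the boundary) and `cell_volumes` (mm^3).
#' @examples
#' m <- generate_biventricle(target_edge = 14)
#' sum(m$cell_volumes) / 1000  # myocardial volume in mL
#' @export
generate_biventricle <- function(outer_axes = c(40, 40, 60),
                                 inner_axes = c(29, 29, 51),
                                 trunc_height = 18,
                                 target_edge = 8) {
  stopifnot(length(outer_axes) == 3, length(inner_axes) == 3,
            all(outer_axes > 0), all(inner_axes > 0), target_edge > 0)
  if (any(inner_axes >= outer_axes)) {
    stop("degenerate geometry: inner_axes must be strictly inside outer_axes")
  }
  if (abs(trunc_height) >= inner_axes[3]) {
    stop("degenerate geometry: |trunc_height| must be < inner_axes[3]")
  }

  # Kuhn cells mix grid edges with face/body diagonals; the mean tet edge of
  # a cube of spacing s is about 1.25 s, hence the spacing correction.
  h <- target_edge / 1.25
  mid <- (outer_axes + inner_axes) / 2
  th_top_mid <- acos(trunc_height / mid[3])
  circ <- 2 * pi * sqrt((mid[1]^2 + mid[2]^2) / 2) * sin(min(th_top_mid + 0.5 *
            (pi - th_top_mid), pi / 2 + (pi - th_top_mid) / 4))
  # numerical meridian length at mid-wall
  ts <- seq(0, 1, length.out = 65)
  mer <- .shell_point(0, ts, 0.5, inner_axes, outer_axes, trunc_height)
  mer_len <- sum(sqrt(rowSums(diff(mer)^2)))
  thick <- mean(outer_axes - inner_axes)
  n_phi <- max(8L, as.integer(round(circ / h)))
  n_t <- max(4L, as.integer(round(mer_len / h)))
  n_w <- max(2L, as.integer(round(thick / h)))

  n_ring <- n_phi * (n_w + 1L)           # vertices per non-apex meridian level
  apex_base <- n_ring * n_t
  vid <- function(iphi, it, iw) {
    ifelse(it < n_t,
           1L + (iphi %% n_phi) + n_phi * iw + n_ring * it,
           apex_base + iw + 1L)
  }

  # vertex coordinates
  g <- expand.grid(iphi = 0:(n_phi - 1L), iw = 0:n_w, it = 0:(n_t - 1L))
  ring_pts <- .shell_point(2 * pi * g$iphi / n_phi, g$it / n_t, g$iw / n_w,
                           inner_axes, outer_axes, trunc_height)
  apex_pts <- .shell_point(rep(0, n_w + 1L), rep(1, n_w + 1L), (0:n_w) / n_w,
                           inner_axes, outer_axes, trunc_height)
  vertices <- rbind(ring_pts, apex_pts)

  cg <- expand.grid(iphi = 0:(n_phi - 1L), it = 0:(n_t - 1L),
                    iw = 0:(n_w - 1L))
  hex8 <- matrix(0L, nrow(cg), 8L)
  corner <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  for (cidx in 1:8) {
    hex8[, cidx] <- vid(cg$iphi + corner$dx[cidx], cg$it + corner$dy[cidx],
                        cg$iw + corner$dz[cidx])
  }
  mesh <- .finalize_mesh(vertices, .kuhn_split(hex8))
  mesh$geom <- list(outer_axes = outer_axes, inner_axes = inner_axes,
                    trunc_height = trunc_height, target_edge = target_edge)
  mesh
}

#' @export
print.bv_mesh <- function(x, ...) {
  cat("Biventricular porous-domain mesh\n")
  cat(sprintf("  vertices: %d, tetrahedra: %d, boundary faces: %d\n",
              nrow(x$vertices), nrow(x$tetrahedra), nrow(x$boundary_faces)))
  cat(sprintf("  total volume: %.1f mL, mean edge: %.2f mm\n",
              sum(x$cell_volumes) / 1000, mean_edge_length(x)))
  invisible(x)
}

#' Mean tetrahedral edge length of a mesh (mm)
#' @param mesh a `bv_mesh`.
#' @return mean edge length over unique edges (mm).
#' @export
mean_edge_length <- function(mesh) {
  ei <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  edges <- matrix(0L, 6L * nrow(mesh$tetrahedra), 2L)
  for (e in 1:6) {
    pair <- mesh$tetrahedra[, ei[e, ], drop = FALSE]
    edges[seq.int(e, by = 6L, length.out = nrow(pair)), ] <-
      cbind(pmin(pair[, 1], pair[, 2]), pmax(pair[, 1], pair[, 2]))
  }
  edges <- unique(edges)
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
       mesh$vertices[edges[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Cell centroids of a tetrahedral mesh
#' @param mesh a `bv_mesh`.
#' @return m x 3 matrix of centroids (mm).
#' @export
cell_centroids <- function(mesh) {
  (mesh$vertices[mesh$tetrahedra[, 1], , drop = FALSE] +
   mesh$vertices[mesh$tetrahedra[, 2], , drop = FALSE] +
   mesh$vertices[mesh$tetrahedra[, 3], , drop = FALSE] +
   mesh$vertices[mesh$tetrahedra[, 4], , drop = FALSE]) / 4
}

## ---------------------------------------------------------------------------
## Perfusion territories
## ---------------------------------------------------------------------------

#' Partition the myocardium into non-overlapping perfusion regions
#'
#' Assigns every cell to the nearest coronary terminal seed (Euclidean
#' distance to the cell centroid), i.e. a Voronoi partition of the domain
#' into the territories fed by each terminal epicardial vessel.  Ties are
#' broken deterministically towards the lowest seed index.
#'
#' @param mesh a `bv_mesh`.
#' @param seeds J x 3 matrix of terminal-vessel seed points (mm); rows must
#'   be distinct.
#' @return an object of class `perfusion_regions` with `labels` (one integer
#'   in `1..J` per cell), `seeds`, and `region_volumes` (mm^3, length J).
#' @export
partition_regions <- function(mesh, seeds) {
  seeds <- as.matrix(seeds)
  stopifnot(ncol(seeds) == 3, nrow(seeds) >= 1)
  if (anyDuplicated(seeds)) stop("duplicate seeds are not allowed")
  cen <- cell_centroids(mesh)
  J <- nrow(seeds)
  d2 <- matrix(0, nrow(cen), J)
  for (j in seq_len(J)) {
    d2[, j] <- (cen[, 1] - seeds[j, 1])^2 + (cen[, 2] - seeds[j, 2])^2 +
               (cen[, 3] - seeds[j, 3])^2
  }
  labels <- max.col(-d2, ties.method = "first")
  region_volumes <- vapply(seq_len(J), function(j)
    sum(mesh$cell_volumes[labels == j]), numeric(1))
  structure(list(labels = labels, seeds = seeds,
                 region_volumes = region_volumes),
            class = "perfusion_regions")
}

#' @export
print.perfusion_regions <- function(x, ...) {
  cat(sprintf("Perfusion partition: %d territories\n", nrow(x$seeds)))
  cat(sprintf("  volumes (mL): %s\n",
              paste(sprintf("%.1f", x$region_volumes / 1000), collapse = ", ")))
  invisible(x)
}

#' Deterministic coronary terminal seeds on the epicardial surface
#'
#' Places J seed points on the outer ellipsoid with a golden-angle
#' (Fibonacci) lattice between the basal plane and the apex, and tags each
#' with the feeding artery: seeds in the azimuthal sector conventionally
#' supplied by the right coronary artery (about 35% of the circumference)
#' are tagged `"RCA"`, the rest `"LCA"`.
#'
#' @param J number of terminal vessels (default 20).
#' @param outer_axes,trunc_height epicardial ellipsoid and basal plane, as in
#'   [generate_biventricle()].
#' @return list with `seeds` (J x 3 matrix, mm) and `side` (character,
#'   `"LCA"`/`"RCA"`).
#' @export
coronary_seeds <- function(J = 20,
                           outer_axes = c(40, 40, 60),
                           trunc_height = 18) {
  stopifnot(J >= 1)
  k <- seq_len(J)
  ct_top <- trunc_height / outer_axes[3]
  ct <- ct_top + (k - 0.5) / J * (-0.95 - ct_top)   # cos(theta), apex margin
  th <- acos(ct)
  golden <- (sqrt(5) - 1) / 2
  phi <- 2 * pi * ((k * golden) %% 1)
  seeds <- cbind(outer_axes[1] * sin(th) * cos(phi),
                 outer_axes[2] * sin(th) * sin(phi),
                 outer_axes[3] * cos(th))
  side <- ifelse(phi / (2 * pi) < 0.35, "RCA", "LCA")
  if (J >= 2 && length(unique(side)) == 1L) side[which.min(phi)] <- "RCA"
  list(seeds = seeds, side = side)
}
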