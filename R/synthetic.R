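# Synthetic "virtual worm" generator: closed meshes with analytically (or
# independently-oracle) known volumes, grouped into tissues, plus the
# calibration cube and a matching anatomy table — so the whole pipeline is
# testable without downloading any anatomy model.

#' Axis-aligned box mesh
#'
#' 8 vertices, 12 outward-oriented triangles; the signed volume is exactly
#' the product of the edge lengths (up to float multiplication). The
#' 100-model-unit cube doubles as the calibration reference ("100 µm cube",
#' 100 x 100 x 100 = 1,000,000 µm³).
#'
#' @param edges length-3 positive edge lengths (a scalar is recycled).
#' @param center box centre (default: corner at the origin, i.e. centre at
#'   `edges / 2`).
#' @param name,collection passed to [triangle_mesh()].
#' @return A [triangle_mesh()].
#' @examples
#' signed_volume(make_box(c(100, 100, 100)))  # 1e6
#' @export
make_box <- function(edges, center = NULL, name = "box",
                     collection = NA_character_) {
  if (length(edges) == 1L) edges <- rep(edges, 3L)
  if (any(edges <= 0)) stop("edges must be positive")
  v <- as.matrix(expand.grid(x = c(0, edges[1L]), y = c(0, edges[2L]),
                             z = c(0, edges[3L])))
  if (!is.null(center))
    v <- v + matrix(rep(center - edges / 2, each = 8L), 8L, 3L)
  # outward CCW faces for the expand.grid vertex order
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = 0 (bottom, normal -z)
             c(5, 6, 8), c(5, 8, 7),   # z = top
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 7, 8), c(3, 8, 4),   # y = top
             c(1, 5, 7), c(1, 7, 3),   # x = 0
             c(2, 4, 8), c(2, 8, 6))   # x = top
  triangle_mesh(v, f, name = name, collection = collection)
}

#' Icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times, vertices projected onto the
#' sphere of radius `radius`. Watertight and consistently outward-oriented by
#' construction; as an inscribed polyhedron its volume is strictly below the
#' smooth-sphere value 4*pi*r^3/3 and increases monotonically with
#' subdivision level.
#'
#' @param radius sphere radius (> 0).
#' @param subdivisions 0 (icosahedron, 20 faces) to 6.
#' @param center sphere centre.
#' @param name,collection passed to [triangle_mesh()].
#' @return A [triangle_mesh()].
#' @export
make_icosphere <- function(radius = 1, subdivisions = 2, center = c(0, 0, 0),
                           name = "icosphere", collection = NA_character_) {
  if (radius <= 0) stop("radius must be positive")
  if (subdivisions < 0 || subdivisions > 6) stop("subdivisions must be in 0..6")
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- 1L + rbind(c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
                  c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
                  c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
                  c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      idx <- nv + length(newv)
      midcache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(4L * k - 3L):(4L * k), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                              c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  v <- v * radius + matrix(rep(center, each = nrow(v)), ncol = 3L)
  triangle_mesh(v, f, name = name, collection = collection)
}

#' Capsule (tube with hemispherical caps) mesh
#'
#' A cylinder of length `length` and radius `radius` along z, capped with
#' hemispheres — the schematic stand-in for elongated cells and for the
#' germline rachis. Smooth closed form `pi*r^2*L + 4/3*pi*r^3` is an upper
#' bound on the mesh volume; the mesh-exact value comes from
#' [convex_volume_oracle()].
#'
#' @param radius tube radius (> 0).
#' @param length cylinder length (>= 0, excluding the caps).
#' @param n_theta segments around the axis (>= 3).
#' @param n_phi rings per hemisphere (>= 1).
#' @param center capsule centre.
#' @param name,collection passed to [triangle_mesh()].
#' @return A [triangle_mesh()].
#' @export
make_capsule <- function(radius = 1, length = 2, n_theta = 16L, n_phi = 6L,
                         center = c(0, 0, 0), name = "capsule",
                         collection = NA_character_) {
  if (radius <= 0 || length < 0) stop("radius must be > 0 and length >= 0")
  if (n_theta < 3L || n_phi < 1L) stop("n_theta >= 3 and n_phi >= 1 required")
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  ring <- function(rad, z) cbind(rad * cos(theta), rad * sin(theta), z)
  alphas <- pi / 2 * seq_len(n_phi) / n_phi
  rings <- list()
  for (a in alphas)                      # bottom hemisphere, pole -> equator
    rings[[length(rings) + 1L]] <- ring(radius * sin(a), -length / 2 - radius * cos(a))
  for (a in rev(alphas))                 # top hemisphere, equator -> pole side
    rings[[length(rings) + 1L]] <- ring(radius * sin(a), length / 2 + radius * cos(a))
  v <- rbind(c(0, 0, -length / 2 - radius),
             do.call(rbind, rings),
             c(0, 0, length / 2 + radius))
  nr <- length(rings)
  ring_idx <- function(r) 1L + (r - 1L) * n_theta + seq_len(n_theta)
  f <- list()
  # bottom fan (outward = seen from below clockwise in ring order)
  r1 <- ring_idx(1L)
  for (i in seq_len(n_theta))
    f[[length(f) + 1L]] <- c(1L, r1[i %% n_theta + 1L], r1[i])
  # quad strips
  for (r in seq_len(nr - 1L)) {
    lo <- ring_idx(r); hi <- ring_idx(r + 1L)
    for (i in seq_len(n_theta)) {
      j <- i %% n_theta + 1L
      f[[length(f) + 1L]] <- c(lo[i], lo[j], hi[j])
      f[[length(f) + 1L]] <- c(lo[i], hi[j], hi[i])
    }
  }
  # top fan
  rn <- ring_idx(nr)
  top <- nrow(v)
  for (i in seq_len(n_theta))
    f[[length(f) + 1L]] <- c(top, rn[i], rn[i %% n_theta + 1L])
  v <- v + matrix(rep(center, each = nrow(v)), ncol = 3L)
  m <- triangle_mesh(v, do.call(rbind, f), name = name, collection = collection)
  repair_orientation(m)   # guarantee outward orientation regardless of fan winding
}

#' Convex hull mesh of a point cloud (brute force)
#'
#' Facet enumeration by exhaustive triple testing: a point triple is a hull
#' facet iff every other point lies strictly on one side of its plane.
#' O(n^4) — intended for the small clouds (<= ~50 points) the synthetic
#' generator uses, where exhaustiveness beats cleverness. Requires points in
#' general position (no 4 coplanar on the hull), which random continuous
#' clouds satisfy almost surely. Facets are oriented outward (away from the
#' centroid).
#'
#' @param points n x 3 numeric matrix, n >= 4.
#' @param name,collection passed to [triangle_mesh()].
#' @return A [triangle_mesh()] (input points kept as the vertex list;
#'   interior points are simply unreferenced).
#' @export
make_hull <- function(points, name = "hull", collection = NA_character_) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points")
  n <- nrow(points)
  scale <- max(abs(points)) + 1
  eps <- 1e-12 * scale
  ctr <- colMeans(points)
  faces <- list()
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    e1 <- points[j, ] - points[i, ]
    e2 <- points[k, ] - points[i, ]
    nrm <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
             e1[3L] * e2[1L] - e1[1L] * e2[3L],
             e1[1L] * e2[2L] - e1[2L] * e2[1L])
    if (sum(nrm^2) < eps^2) next
    d <- (points[-c(i, j, k), , drop = FALSE] -
            matrix(points[i, ], n - 3L, 3L, byrow = TRUE)) %*% nrm
    if (all(d < -eps)) {
      faces[[length(faces) + 1L]] <- c(i, j, k)       # normal already outward
    } else if (all(d > eps)) {
      faces[[length(faces) + 1L]] <- c(i, k, j)       # flip to outward
    }
  }
  if (length(faces) < 4L)
    stop("degenerate point cloud: could not enumerate hull facets")
  triangle_mesh(points, do.call(rbind, faces), name = name,
                collection = collection)
}

#' Independent convex-volume oracle (centroid tetrahedron decomposition)
#'
#' Volume of a convex closed mesh computed by a route deliberately different
#' from [signed_volume()]: tetrahedra are anchored at the vertex centroid
#' (not the origin) and their absolute volumes are summed, so the result is
#' independent of face winding. Used for the ground-truth manifest of the
#' synthetic generator and as a cross-check in property tests. Only valid
#' for convex (or star-shaped about the centroid) meshes.
#'
#' @param mesh a [triangle_mesh()].
#' @return Volume in model units cubed.
#' @export
convex_volume_oracle <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  used <- sort(unique(as.vector(f)))
  ctr <- colMeans(v[used, , drop = FALSE])
  a <- v[f[, 1L], , drop = FALSE] - matrix(ctr, nrow(f), 3L, byrow = TRUE)
  b <- v[f[, 2L], , drop = FALSE] - matrix(ctr, nrow(f), 3L, byrow = TRUE)
  c3 <- v[f[, 3L], , drop = FALSE] - matrix(ctr, nrow(f), 3L, byrow = TRUE)
  contrib <- a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) +
             a[, 2L] * (b[, 3L] * c3[, 1L] - b[, 1L] * c3[, 3L]) +
             a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])
  sum(abs(contrib)) / 6
}

#' Perturb a mesh to exercise validation paths
#'
#' @param mesh a [triangle_mesh()].
#' @param kind `"jitter"` (Gaussian vertex noise, sd `sigma`), `"puncture"`
#'   (remove `n_faces` faces, creating boundary edges), `"flip_all"` (reverse
#'   every winding: negates the signed volume exactly), `"flip_one"` (reverse
#'   one face: breaks orientation consistency).
#' @param sigma jitter standard deviation in model units.
#' @param n_faces number of faces to remove for `"puncture"`.
#' @param seed RNG seed for `"jitter"`/`"puncture"` face choice.
#' @return The perturbed mesh.
#' @export
perturb <- function(mesh, kind = c("jitter", "puncture", "flip_all", "flip_one"),
                    sigma = 0, n_faces = 1L, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    jitter = {
      if (sigma == 0) return(mesh)
      set.seed(seed)
      mesh$vertices <- mesh$vertices +
        matrix(stats::rnorm(length(mesh$vertices), sd = sigma),
               nrow(mesh$vertices), 3L)
      mesh
    },
    puncture = {
      if (n_faces >= nrow(mesh$faces))
        stop("cannot puncture ", n_faces, " of ", nrow(mesh$faces), " faces")
      set.seed(seed)
      drop <- sample(nrow(mesh$faces), n_faces)
      mesh$faces <- mesh$faces[-drop, , drop = FALSE]
      mesh
    },
    flip_all = flip_faces(mesh),
    flip_one = {
      mesh$faces[1L, ] <- mesh$faces[1L, c(1L, 3L, 2L)]
      mesh
    })
}
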