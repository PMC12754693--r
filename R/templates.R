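# Schematic bone template primitives.
#
# Long-bone cross-sections are deliberately non-circular: a circular section
# leaves the rotation about the long axis unidentifiable in per-bone
# Procrustes alignment.
#
# Each of the 14 bones is a fixed-topology triangulated primitive (ellipsoid
# or box grid) in its own local frame, with the long anatomical axis along
# local +X unless noted. Templates are vertex-symmetric under y -> -y and
# z -> -z, so their vertex covariance is diagonal to machine precision and
# principal axes are exact; the calcaneus additionally carries two designed
# landmark clusters (plantar tuberosity, anterior inferior process) that the
# radiographic operators select deterministically. Anatomy is schematic by
# design: the pipeline validates statistics and angle operators, not
# anatomical realism.

# Latitude/longitude triangulation of an ellipsoid with poles on the X axis.
ellipsoid_mesh <- function(rx, ry, rz, n_lat = 14, n_lon = 20) {
  stopifnot(n_lat >= 3, n_lon >= 8, n_lon %% 4 == 0)
  u <- seq(-pi / 2, pi / 2, length.out = n_lat + 1)[-c(1, n_lat + 1)]
  v <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  ring <- function(ui) cbind(rx * sin(ui),
                             ry * cos(ui) * cos(v),
                             rz * cos(ui) * sin(v))
  verts <- do.call(rbind, lapply(u, ring))
  pole_s <- c(-rx, 0, 0)
  pole_n <- c(rx, 0, 0)
  verts <- rbind(verts, pole_s, pole_n)
  n_ring <- length(u)
  is_ <- nrow(verts) - 1L  # south pole index
  in_ <- nrow(verts)       # north pole index
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  faces <- list()
  # pole fans
  for (j in seq_len(n_lon)) {
    faces[[length(faces) + 1L]] <- c(is_, idx(1, j + 1), idx(1, j))
    faces[[length(faces) + 1L]] <- c(in_, idx(n_ring, j), idx(n_ring, j + 1))
  }
  # quad strips between rings
  for (i in seq_len(n_ring - 1L)) {
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1)
      c_ <- idx(i + 1, j + 1); d <- idx(i + 1, j)
      faces[[length(faces) + 1L]] <- c(a, b, c_)
      faces[[length(faces) + 1L]] <- c(a, c_, d)
    }
  }
  f <- do.call(rbind, faces)
  orient_outward(verts, f)
}

# Watertight surface grid of an axis-aligned box with half-extents
# (hx, hy, hz) and nx/ny/nz subdivisions per edge. Vertices shared on edges.
box_mesh <- function(hx, hy, hz, nx = 4, ny = 4, nz = 4) {
  xs <- seq(-hx, hx, length.out = nx + 1)
  ys <- seq(-hy, hy, length.out = ny + 1)
  zs <- seq(-hz, hz, length.out = nz + 1)
  key <- function(i, j, k) paste(i, j, k, sep = ",")
  vmap <- new.env(parent = emptyenv())
  verts <- list()
  get_v <- function(i, j, k) {
    kk <- key(i, j, k)
    if (!is.null(vmap[[kk]])) return(vmap[[kk]])
    verts[[length(verts) + 1L]] <<- c(xs[i], ys[j], zs[k])
    vmap[[kk]] <- length(verts)
    length(verts)
  }
  faces <- list()
  quad <- function(a, b, c_, d) {
    faces[[length(faces) + 1L]] <<- c(a, b, c_)
    faces[[length(faces) + 1L]] <<- c(a, c_, d)
  }
  # y = -hy (bottom) and y = +hy (top)
  for (i in seq_len(nx)) for (k in seq_len(nz)) {
    quad(get_v(i, 1, k), get_v(i + 1, 1, k),
         get_v(i + 1, 1, k + 1), get_v(i, 1, k + 1))
    quad(get_v(i, ny + 1, k), get_v(i, ny + 1, k + 1),
         get_v(i + 1, ny + 1, k + 1), get_v(i + 1, ny + 1, k))
  }
  # x = -hx and x = +hx
  for (j in seq_len(ny)) for (k in seq_len(nz)) {
    quad(get_v(1, j, k), get_v(1, j, k + 1),
         get_v(1, j + 1, k + 1), get_v(1, j + 1, k))
    quad(get_v(nx + 1, j, k), get_v(nx + 1, j + 1, k),
         get_v(nx + 1, j + 1, k + 1), get_v(nx + 1, j, k + 1))
  }
  # z = -hz and z = +hz
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    quad(get_v(i, j, 1), get_v(i, j + 1, 1),
         get_v(i + 1, j + 1, 1), get_v(i + 1, j, 1))
    quad(get_v(i, j, nz + 1), get_v(i + 1, j, nz + 1),
         get_v(i + 1, j + 1, nz + 1), get_v(i, j + 1, nz + 1))
  }
  v <- do.call(rbind, verts)
  f <- do.call(rbind, faces)
  orient_outward(v, f)
}

# Flip triangles whose outward normal points toward the origin. Valid for
# convex primitives centered on the origin (applied before any landmark
# displacement).
orient_outward <- function(verts, faces) {
  v1 <- verts[faces[, 1], , drop = FALSE]
  v2 <- verts[faces[, 2], , drop = FALSE]
  v3 <- verts[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ctr <- (v1 + v2 + v3) / 3
  flip <- rowSums(nrm * ctr) < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  list(vertices = v_as_matrix(verts), faces = faces)
}

v_as_matrix <- function(v) {
  v <- as.matrix(v)
  dimnames(v) <- NULL
  storage.mode(v) <- "double"
  v
}

# Calcaneus: 80 x 30 x 20 mm box grid with two displaced landmark clusters on
# the inferior surface, both at the same local height (y = -29) and centered
# on the midline (z = 0):
#   * plantar tuberosity cluster around x = -44 (posterior, slightly behind
#     the box) -- target of the "most plantar-posterior point" selection;
#   * anterior inferior process cluster around x = +20 -- the most plantar
#     point of the anterior third over the full planted-angle range.
# Equal cluster heights make the inferior calcaneal line horizontal in the
# template, so a posed calcaneus measures exactly its planted pitch.
calcaneus_template <- function() {
  m <- box_mesh(40, 15, 10, nx = 12, ny = 4, nz = 6)
  v <- m$vertices
  xs <- seq(-40, 40, length.out = 13)
  zs <- seq(-10, 10, length.out = 7)
  cluster <- function(ix_set, iz_set, x_new, z_new, y_new) {
    for (a in seq_along(ix_set)) for (b in seq_along(iz_set)) {
      hit <- which(abs(v[, 1] - xs[ix_set[a]]) < 1e-9 &
                   abs(v[, 2] + 15) < 1e-9 &
                   abs(v[, 3] - zs[iz_set[b]]) < 1e-9)
      stopifnot(length(hit) == 1L)
      v[hit, ] <<- c(x_new[a], y_new, z_new[b])
    }
  }
  # posterior tuberosity: 3 x 3 vertices, centroid (-44, -29, 0)
  cluster(c(1, 2, 3), c(3, 4, 5),
          x_new = c(-45.5, -44, -42.5), z_new = c(-1.5, 0, 1.5), y_new = -29)
  # anterior inferior process: 3 x 3 vertices, centroid (20, -29, 0)
  cluster(c(9, 10, 11), c(3, 4, 5),
          x_new = c(18.5, 20, 21.5), z_new = c(-1.5, 0, 1.5), y_new = -29)
  list(vertices = v, faces = m$faces)
}

#' Names of the 14 foot and ankle bones
#'
#' Fixed anatomical vocabulary used throughout the package: calcaneus,
#' cuboid, the three cuneiforms, fibula, metatarsals 1-5, navicular, talus
#' and tibia.
#'
#' @return character vector of length 14.
#' @export
bone_names <- function() {
  c("calcaneus", "cuboid",
    "cuneiform_intermediate", "cuneiform_lateral", "cuneiform_medial",
    "fibula",
    paste0("metatarsal_", 1:5),
    "navicular", "talus", "tibia")
}

# Template meshes for all 14 bones in their local frames. Deterministic and
# memoised per session (fixed topology is the correspondence contract).
bone_templates <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    t <- list(
      calcaneus              = calcaneus_template(),
      cuboid                 = box_mesh(11, 9, 9, 5, 5, 5),
      cuneiform_intermediate = ellipsoid_mesh(9, 11, 7, 10, 16),
      cuneiform_lateral      = ellipsoid_mesh(9, 11, 7, 10, 16),
      cuneiform_medial       = ellipsoid_mesh(10, 12, 8, 10, 16),
      fibula                 = {
        m <- ellipsoid_mesh(55, 8, 6.5, 16, 20)
        m$vertices <- m$vertices[, c(2, 1, 3)]
        m$vertices[, 3] <- -m$vertices[, 3]
        m
      },
      metatarsal_1           = ellipsoid_mesh(32, 9, 8, 14, 20),
      metatarsal_2           = ellipsoid_mesh(30, 7, 6.2, 14, 20),
      metatarsal_3           = ellipsoid_mesh(29, 7, 6.2, 14, 20),
      metatarsal_4           = ellipsoid_mesh(28, 7, 6.2, 14, 20),
      metatarsal_5           = ellipsoid_mesh(26, 7, 6.2, 14, 20),
      navicular              = ellipsoid_mesh(9, 13, 16, 12, 16),
      talus                  = ellipsoid_mesh(25, 14, 16, 14, 20),
      tibia                  = {
        m <- ellipsoid_mesh(60, 14, 12, 16, 20)
        # long axis along local +Y (tibia is vertical)
        m$vertices <- m$vertices[, c(2, 1, 3)]
        m$vertices[, 3] <- -m$vertices[, 3]  # keep right-handed orientation
        m
      }
    )
    cache <<- t
    t
  }
})
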