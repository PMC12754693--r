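# Core mesh containers and rigid geometry: BoneMesh / FootModel constructors
# with validity checks, sagittal mirroring, principal axes and ICP.

#' Construct a bone surface mesh
#'
#' A `bone_mesh` is a triangulated surface in the shared anatomical frame
#' (+X anterior, +Y superior, +Z right-lateral, floor at Y = 0), labelled
#' with one of the 14 bone names and a side. Counter-clockwise winding is
#' outward.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @param label bone name; one of [bone_names()].
#' @param side `"left"` or `"right"`.
#' @return object of class `bone_mesh`.
#' @export
bone_mesh <- function(vertices, faces, label, side) {
  vertices <- v_as_matrix(vertices)
  faces <- as.matrix(faces)
  dimnames(faces) <- NULL
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stopf("faces must be an M x 3 matrix")
  if (nrow(vertices) < 4L) stopf("bone mesh needs >= 4 vertices, got %d",
                                 nrow(vertices))
  if (nrow(faces) < 1L) stopf("empty mesh: no faces")
  if (any(!is.finite(vertices))) stopf("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stopf("face indices out of range [1, %d]", nrow(vertices))
  if (!label %in% bone_names())
    stopf("unknown bone label '%s'; see bone_names()", label)
  if (!side %in% c("left", "right")) stopf("side must be 'left' or 'right'")
  a <- triangle_areas(vertices, faces)
  if (any(a <= 1e-12))
    stopf("degenerate (zero-area) faces in '%s': %s", label,
          paste(utils::head(which(a <= 1e-12), 5), collapse = ", "))
  structure(list(vertices = vertices, faces = faces,
                 label = label, side = side),
            class = "bone_mesh")
}

triangle_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(nx^2 + ny^2 + nz^2)
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf("<bone_mesh> %s (%s): %d vertices, %d faces\n",
              x$label, x$side, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Signed volume of a closed triangulated surface
#'
#' Divergence-theorem volume: positive for outward-oriented winding.
#'
#' @param mesh a [bone_mesh()].
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  d <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
       v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
       v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(d) / 6
}

#' Construct a 14-bone foot model
#'
#' @param bones named list of [bone_mesh()] objects covering all 14 bones.
#' @param side `"left"` or `"right"` (all bones must agree).
#' @param group optional group label (e.g. `"rectus"`, `"cavus"`, `"CAI"`).
#' @param subject_id optional subject identifier.
#' @param ground_truth optional generator ground truth (planted angles).
#' @return object of class `foot_model`.
#' @export
foot_model <- function(bones, side, group = NULL, subject_id = NULL,
                       ground_truth = NULL) {
  need <- bone_names()
  if (!setequal(names(bones), need))
    stopf("foot_model requires exactly the 14 bones; missing: %s",
          paste(setdiff(need, names(bones)), collapse = ", "))
  bones <- bones[need]
  for (b in bones) {
    if (!inherits(b, "bone_mesh")) stopf("all bones must be bone_mesh objects")
    if (b$side != side) stopf("bone '%s' side (%s) disagrees with foot side (%s)",
                              b$label, b$side, side)
  }
  structure(list(bones = bones, side = side, group = group,
                 subject_id = subject_id, ground_truth = ground_truth),
            class = "foot_model")
}

#' @export
print.foot_model <- function(x, ...) {
  nv <- sum(vapply(x$bones, function(b) nrow(b$vertices), 0L))
  cat(sprintf("<foot_model> %s%s: 14 bones, %d vertices total%s\n",
              x$side,
              if (is.null(x$group)) "" else paste0(", group=", x$group),
              nv,
              if (is.null(x$ground_truth)) "" else
                sprintf(" (planted MA=%.1f HAA=%.1f CI=%.1f)",
                        x$ground_truth$ma, x$ground_truth$haa,
                        x$ground_truth$ci)))
  invisible(x)
}

#' Pool all bone vertices of a foot into one point cloud
#'
#' Vertices are stacked in [bone_names()] order.
#'
#' @param foot a [foot_model()].
#' @return N x 3 matrix (mm).
#' @export
pooled_vertices <- function(foot) {
  do.call(rbind, lapply(foot$bones[bone_names()], function(b) b$vertices))
}

#' Mirror a left foot to right-sided anatomy
#'
#' Negates the Z coordinate (sagittal reflection in the shared anatomical
#' frame) and flips triangle winding so the surface stays outward-oriented.
#' Only left feet can be mirrored; mirroring a right foot errors to prevent
#' silent double-mirroring.
#'
#' @param foot a [foot_model()] with `side == "left"`.
#' @return the mirrored right-sided [foot_model()].
#' @export
mirror_foot <- function(foot) {
  if (!inherits(foot, "foot_model")) stopf("mirror_foot expects a foot_model")
  if (foot$side != "left")
    stopf("refusing to mirror a %s foot (already right-sided?)", foot$side)
  bones <- lapply(foot$bones, function(b) {
    v <- b$vertices
    v[, 3] <- -v[, 3]
    f <- b$faces[, c(1, 3, 2), drop = FALSE]
    bone_mesh(v, f, b$label, "right")
  })
  foot_model(bones, side = "right", group = foot$group,
             subject_id = foot$subject_id, ground_truth = foot$ground_truth)
}

#' Principal axes of a point set
#'
#' Eigenvectors of the vertex covariance, ordered by descending eigenvalue.
#' The first axis is sign-flipped if needed so it points along
#' `orientation_hint`; the remaining axes are flipped to keep a right-handed
#' frame.
#'
#' @param points N x 3 matrix.
#' @param orientation_hint unit 3-vector disambiguating the first axis sign.
#' @return list with `axes` (3 x 3, rows = axes), `values` (eigenvalues),
#'   `centroid`.
#' @export
principal_axes <- function(points, orientation_hint = c(1, 0, 0)) {
  points <- v_as_matrix(points)
  if (nrow(points) < 3L) stopf("principal_axes needs >= 3 points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  cv <- crossprod(x) / (nrow(x) - 1)
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[2] <= e$values[1] * 1e-10)
    stopf("rank-deficient covariance: directions 2 and 3 are degenerate (collinear points)")
  if (e$values[3] < 0) e$values[3] <- 0
  axes <- t(e$vectors)  # rows are axes
  if (sum(axes[1, ] * orientation_hint) < 0) axes[1, ] <- -axes[1, ]
  # right-handed completion: fix axis 2 sign by hint-free convention, axis 3
  # by cross product
  if (axes[2, which.max(abs(axes[2, ]))] < 0) axes[2, ] <- -axes[2, ]
  axes[3, ] <- c(axes[1, 2] * axes[2, 3] - axes[1, 3] * axes[2, 2],
                 axes[1, 3] * axes[2, 1] - axes[1, 1] * axes[2, 3],
                 axes[1, 1] * axes[2, 2] - axes[1, 2] * axes[2, 1])
  list(axes = axes, values = e$values, centroid = ctr)
}

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stopf("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stopf("rotation determinant is %.6f, not +1", det(rotation))
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
transform_points <- function(transform, points) {
  apply_transform(v_as_matrix(points), transform$rotation,
                  transform$translation)
}

# Closed-form rigid Procrustes: rotation/translation minimising
# || R x + t - y ||^2 over paired point sets (Kabsch / SVD solution).
kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  h <- crossprod(sweep(x, 2, cx), sweep(y, 2, cy))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = r, translation = as.numeric(cy - r %*% cx))
}

# Nearest-neighbour indices from each row of `from` into `to` (brute force,
# chunked to bound memory).
nearest_indices <- function(from, to, chunk = 512L) {
  n <- nrow(from)
  out <- integer(n)
  t2 <- rowSums(to^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    blk <- from[s:e, , drop = FALSE]
    d <- outer(rowSums(blk^2), t2, "+") - 2 * tcrossprod(blk, to)
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

#' Iterative closest point rigid alignment
#'
#' Aligns a source point set to a target by alternating single-direction
#' nearest-neighbour correspondence (source vertices to target vertices) with
#' the closed-form SVD rigid Procrustes solution. Scaling is never applied.
#' The RMS of matched distances is non-increasing across iterations.
#'
#' @param source,target N x 3 point matrices (>= 3 non-collinear points each).
#' @param max_iter maximum iterations (default 100).
#' @param tol stop when the RMS improvement falls below this value (mm,
#'   default 1e-6).
#' @return list with `transform` ([rigid_transform()]), `rms` (final RMS, mm),
#'   `trace` (per-iteration RMS), `iterations`.
#' @export
icp_align <- function(source, target, max_iter = 100L, tol = 1e-6) {
  source <- v_as_matrix(source)
  target <- v_as_matrix(target)
  for (nm in list(source, target)) {
    if (nrow(nm) < 3L) stopf("ICP needs >= 3 points in each set")
    pv <- eigen(stats::cov(nm), symmetric = TRUE, only.values = TRUE)$values
    if (pv[2] <= max(pv[1], 1e-300) * 1e-10)
      stopf("ICP input is degenerate (collinear or coincident points)")
  }
  r <- diag(3)
  t <- c(0, 0, 0)
  cur <- source
  trace <- numeric(0)
  prev <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    nn <- nearest_indices(cur, target)
    matched <- target[nn, , drop = FALSE]
    step <- kabsch(cur, matched)
    cur <- sweep(cur %*% t(step$rotation), 2, -step$translation)
    r <- step$rotation %*% r
    t <- as.numeric(step$rotation %*% t + step$translation)
    rms <- sqrt(mean(rowSums((cur - matched)^2)))
    trace <- c(trace, rms)
    if (prev - rms < tol) break
    prev <- rms
  }
  list(transform = rigid_transform(r, t), rms = trace[length(trace)],
       trace = trace, iterations = it)
}
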