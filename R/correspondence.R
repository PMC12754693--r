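# Correspondence particle systems and Procrustes alignment.
#
# Correspondence across subjects comes from the shared template topology:
# particles are a fixed subsample of template vertex indices, so particle k
# lies on the same template vertex for every subject. Whole-foot generalized
# Procrustes (with scaling) produces the world frame; per-bone rigid-only
# Procrustes produces the local (shape) frame; their contrast separates
# alignment from intrinsic shape differences.

# Fixed per-bone index permutation (deterministic across sessions).
particle_index_permutation <- function(n, bone_idx) {
  with_seed(971203L + bone_idx, sample.int(n))
}

# Deterministic particle vertex indices: uniform stride over the fixed
# permutation, returned sorted so that counts == n yields the identity.
particle_indices <- function(n_vertices, count, bone_idx) {
  perm <- particle_index_permutation(n_vertices, bone_idx)
  sort(perm[floor(seq(1, n_vertices, length.out = count))])
}

#' Extract correspondence particles from a cohort of feet
#'
#' Subsamples each bone's vertices at fixed template indices, identical for
#' every subject, giving cross-subject correspondence by construction. All
#' subjects must share the template topology (equal per-bone vertex counts).
#'
#' @param cohort list of [foot_model()] objects.
#' @param counts particles per bone: a single integer or a named vector over
#'   [bone_names()]. Default 128 per bone.
#' @return object of class `particle_set`: per-subject particle matrices
#'   (bone-major rows), layout table, subject/group metadata.
#' @export
extract_particles <- function(cohort, counts = 128L) {
  stopifnot(length(cohort) >= 1L)
  nv_ref <- vapply(cohort[[1]]$bones[bone_names()],
                   function(b) nrow(b$vertices), 0L)
  for (i in seq_along(cohort)) {
    nv <- vapply(cohort[[i]]$bones[bone_names()],
                 function(b) nrow(b$vertices), 0L)
    bad <- which(nv != nv_ref)
    if (length(bad))
      stopf("template topology mismatch for subject %d at bone '%s' (%d vs %d vertices)",
            i, bone_names()[bad[1]], nv[bad[1]], nv_ref[bad[1]])
  }
  if (length(counts) == 1L) {
    counts <- rep(as.integer(counts), 14L)
    names(counts) <- bone_names()
  }
  counts <- counts[bone_names()]
  if (any(is.na(counts))) stopf("counts must cover all 14 bones")
  over <- which(counts > nv_ref)
  if (length(over))
    stopf("requested %d particles for '%s' but the template has only %d vertices",
          counts[over[1]], bone_names()[over[1]], nv_ref[over[1]])
  if (any(counts < 3L)) stopf("each bone needs >= 3 particles")

  idx <- lapply(seq_along(bone_names()), function(b)
    particle_indices(nv_ref[b], counts[b], b))
  layout <- data.frame(bone = bone_names(), count = as.integer(counts),
                       offset = cumsum(c(0L, as.integer(counts)))[1:14],
                       stringsAsFactors = FALSE)
  raw <- lapply(cohort, function(f)
    do.call(rbind, lapply(seq_along(bone_names()), function(b)
      f$bones[[bone_names()[b]]]$vertices[idx[[b]], , drop = FALSE])))
  structure(list(
    subjects = vapply(seq_along(cohort), function(i)
      cohort[[i]]$subject_id %||% sprintf("S%03d", i), ""),
    groups = vapply(cohort, function(f) f$group %||% NA_character_, ""),
    layout = layout,
    raw = raw, world = NULL, local = NULL,
    centroid_size = NULL, mean_world = NULL),
    class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d subjects, %d particles (%s frames)\n",
              length(x$raw), sum(x$layout$count),
              paste(c("raw", if (!is.null(x$world)) "world",
                      if (!is.null(x$local)) "local"), collapse = ", ")))
  invisible(x)
}

frobenius <- function(m) sqrt(sum(m^2))

# Optimal rotation (no translation/scale) of centered config x onto y.
procrustes_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Iterative Procrustes alignment of a list of centered configurations to
# their evolving mean. Returns aligned configs, the (optionally
# unit-normalised) mean, and the per-iteration objective trace.
gpa_engine <- function(configs, normalise_mean, tol, max_iter) {
  # order-invariant initialisation keeps the converged gauge independent of
  # subject ordering
  mean_cfg <- Reduce(`+`, configs) / length(configs)
  objective <- numeric(0)
  delta <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    target <- if (normalise_mean) mean_cfg / frobenius(mean_cfg) else mean_cfg
    configs <- lapply(configs, function(x) x %*% procrustes_rotation(x, target))
    new_mean <- Reduce(`+`, configs) / length(configs)
    obj <- sum(vapply(configs, function(x) sum((x - new_mean)^2), 0))
    plateau <- length(objective) > 0 &&
      objective[length(objective)] - obj < 1e-12 * max(obj, 1e-300)
    objective <- c(objective, obj)
    delta <- frobenius(new_mean - mean_cfg)
    mean_cfg <- new_mean
    if (delta < tol || plateau) break
  }
  if (delta >= tol && !plateau)
    warnf("Procrustes iteration did not converge in %d iterations (last mean change %.3g)",
          max_iter, delta)
  if (normalise_mean) mean_cfg <- mean_cfg / frobenius(mean_cfg)
  list(configs = configs, mean = mean_cfg, objective = objective,
       iterations = it)
}

#' Generalized Procrustes analysis of a particle cohort
#'
#' Centers every configuration, optionally scales each to unit centroid
#' size, then iteratively rotates all configurations to the evolving mean
#' until the mean stabilises. The resulting world-frame coordinates are
#' dimensionless when scaling is applied; the mean configuration has zero
#' centroid and unit centroid size.
#'
#' @param pset a [extract_particles()] result.
#' @param with_scaling remove centroid size (default TRUE).
#' @param tol convergence threshold on the mean change (default 1e-8).
#' @param max_iter iteration cap (default 100); non-convergence warns.
#' @return `pset` with `world`, `mean_world`, `centroid_size` and the GPA
#'   objective trace (`gpa_objective`) filled in.
#' @export
generalized_procrustes <- function(pset, with_scaling = TRUE, tol = 1e-8,
                                   max_iter = 100L) {
  stopifnot(inherits(pset, "particle_set"))
  if (length(pset$raw) < 2L) stopf("GPA needs >= 2 subjects")
  centered <- lapply(pset$raw, function(x) sweep(x, 2, colMeans(x)))
  sizes <- vapply(centered, frobenius, 0)
  if (any(sizes <= 0)) stopf("degenerate configuration with zero centroid size")
  configs <- if (with_scaling)
    Map(function(x, s) x / s, centered, sizes) else centered
  fit <- gpa_engine(configs, normalise_mean = TRUE, tol = tol,
                    max_iter = max_iter)
  pset$world <- fit$configs
  pset$mean_world <- fit$mean
  pset$centroid_size <- sizes
  pset$gpa_objective <- fit$objective
  pset$scaled <- with_scaling
  pset
}

#' Per-bone rigid alignment: the local (shape) frame
#'
#' For each bone independently, aligns that bone's world-frame particles
#' across subjects to the bone's cohort mean by rigid-only (no scaling)
#' Procrustes. The aligned residual coordinates, re-anchored at the bone's
#' mean world centroid, form the local frame; world coordinates are kept
#' unchanged.
#'
#' @param pset a [generalized_procrustes()] result.
#' @param tol,max_iter iteration controls as in [generalized_procrustes()].
#' @return `pset` with `local` filled in.
#' @export
per_bone_local_frames <- function(pset, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(pset, "particle_set"))
  if (is.null(pset$world)) stopf("world frame not computed; run generalized_procrustes() first")
  n <- length(pset$world)
  local <- lapply(seq_len(n), function(i)
    matrix(NA_real_, sum(pset$layout$count), 3))
  for (b in seq_len(nrow(pset$layout))) {
    cnt <- pset$layout$count[b]
    if (cnt < 3L) stopf("bone '%s' has fewer than 3 particles", pset$layout$bone[b])
    rows <- pset$layout$offset[b] + seq_len(cnt)
    bone_cfgs <- lapply(pset$world, function(w) w[rows, , drop = FALSE])
    centres <- lapply(bone_cfgs, colMeans)
    centered <- Map(function(x, c) sweep(x, 2, c), bone_cfgs, centres)
    fit <- gpa_engine(centered, normalise_mean = FALSE, tol = tol,
                      max_iter = max_iter)
    anchor <- colMeans(do.call(rbind, centres))
    for (i in seq_len(n))
      local[[i]][rows, ] <- sweep(fit$configs[[i]], 2, -anchor)
  }
  pset$local <- local
  pset
}

#' Flatten a particle frame into a shape matrix
#'
#' Column ordering contract: bone-major, particle-minor, XYZ innermost
#' (x1, y1, z1, x2, ...). The mapping back to (bone, particle, axis) is
#' provided by [shape_matrix_map()].
#'
#' @param pset a `particle_set` with the requested frame computed.
#' @param frame `"world"`, `"local"` or `"raw"`.
#' @return n_subjects x (3 * n_particles) matrix of class `shape_matrix`
#'   with the frame and layout attached as attributes.
#' @export
flatten_particles <- function(pset, frame = c("world", "local", "raw")) {
  frame <- match.arg(frame)
  configs <- pset[[frame]]
  if (is.null(configs)) stopf("frame '%s' not computed", frame)
  m <- do.call(rbind, lapply(configs, function(x) as.vector(t(x))))
  if (any(!is.finite(m))) stopf("non-finite particle coordinates in frame '%s'", frame)
  rownames(m) <- pset$subjects
  structure(m, frame = frame, layout = pset$layout, groups = pset$groups,
            class = c("shape_matrix", class(m)))
}

#' Reshape one flattened shape vector back to particles
#'
#' @param v numeric vector of length 3 * n_particles (the column order of
#'   [flatten_particles()]).
#' @return n_particles x 3 matrix.
#' @export
unflatten_particles <- function(v) {
  matrix(v, ncol = 3, byrow = TRUE)
}

#' Column map of a flattened shape matrix
#'
#' @param layout the layout table of a `particle_set` (bone, count, offset).
#' @return data.frame with one row per column: bone, particle index within
#'   bone, axis.
#' @export
shape_matrix_map <- function(layout) {
  data.frame(
    bone = rep(rep(layout$bone, layout$count), each = 3),
    particle = rep(sequence(layout$count), each = 3),
    axis = rep(c("x", "y", "z"), sum(layout$count)),
    stringsAsFactors = FALSE)
}

#' Write particle files for a cohort
#'
#' One plain-text XYZ file per subject per bone (one `x y z` row per
#' particle) plus a cohort-level JSON index.
#'
#' @param pset a `particle_set` with the requested frame computed.
#' @param dir output directory.
#' @param frame which frame to export (default `"world"`).
#' @return the JSON index path, invisibly.
#' @export
write_particles <- function(pset, dir, frame = c("world", "local", "raw")) {
  frame <- match.arg(frame)
  configs <- pset[[frame]]
  if (is.null(configs)) stopf("frame '%s' not computed", frame)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- list(frame = frame, layout = pset$layout, subjects = list())
  for (i in seq_along(configs)) {
    sid <- pset$subjects[i]
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    files <- character(0)
    for (b in seq_len(nrow(pset$layout))) {
      rows <- pset$layout$offset[b] + seq_len(pset$layout$count[b])
      p <- file.path(sdir, paste0(pset$layout$bone[b], ".particles"))
      utils::write.table(configs[[i]][rows, , drop = FALSE], p,
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, p)
    }
    index$subjects[[sid]] <- list(group = pset$groups[i], files = files)
  }
  ip <- file.path(dir, "particles_index.json")
  jsonlite::write_json(index, ip, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(ip)
}
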