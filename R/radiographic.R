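# Computational derivation of radiographic angles from 3D bone meshes.
#
# All operators work in the shared anatomical frame (+X anterior, +Y
# superior, +Z right-lateral, floor at Y = 0) and report degrees. Extreme
# landmark points are taken as the centroid of all vertices within a small
# band of the extreme value, which makes the landmarks robust to
# vertex-level surface noise while remaining exact on noiseless meshes.

# lateral direction sign: +Z is lateral for a right foot, medial for a left
lateral_sign_of <- function(side) if (side == "left") -1 else 1

axis_elongation_min <- 1.2  # below this first/second eigenvalue ratio a
                            # longitudinal axis is considered undefined

longitudinal_axis <- function(mesh, hint) {
  pa <- principal_axes(mesh$vertices, orientation_hint = hint)
  if (pa$values[1] < axis_elongation_min * pa$values[2])
    stopf("degenerate longitudinal axis for '%s': bone is near-spherical (eigenvalue ratio %.2f)",
          mesh$label, pa$values[1] / pa$values[2])
  pa$axes[1, ]
}

# centroid of vertices within `band` of the minimum of `score`
band_extreme <- function(verts, score, band) {
  sel <- score <= min(score) + band
  colMeans(verts[sel, , drop = FALSE])
}

#' Meary's angle from 3D meshes
#'
#' Sagittal-plane angle between the talar and first-metatarsal longitudinal
#' axes (covariance principal axes, oriented anteriorly). Positive when the
#' first metatarsal is plantarflexed relative to the talar axis (apex
#' dorsal, the cavus sense); ~0 for a rectus foot.
#'
#' @param foot a [foot_model()].
#' @return Meary's angle in degrees.
#' @export
meary_angle <- function(foot) {
  stopifnot(inherits(foot, "foot_model"))
  tal <- longitudinal_axis(foot$bones$talus, c(1, 0, 0))
  met <- longitudinal_axis(foot$bones$metatarsal_1, c(1, 0, 0))
  wrap_angle(sagittal_elevation(tal) - sagittal_elevation(met))
}

#' Calcaneal inclination from 3D meshes
#'
#' Pitch of the inferior calcaneal line: from the most plantar point of the
#' posterior third to the most plantar point of the anterior third (thirds
#' by anterior-coordinate span), measured against the floor plane in the
#' sagittal projection. Positive when the anterior end is higher.
#'
#' @param foot a [foot_model()].
#' @param band vertical band (mm) defining the robust plantar-extreme
#'   centroid; default 3.
#' @return calcaneal inclination in degrees.
#' @export
calcaneal_inclination <- function(foot, band = 3) {
  stopifnot(inherits(foot, "foot_model"))
  v <- foot$bones$calcaneus$vertices
  xr <- range(v[, 1])
  third <- diff(xr) / 3
  post <- v[v[, 1] <= xr[1] + third, , drop = FALSE]
  ant <- v[v[, 1] >= xr[2] - third, , drop = FALSE]
  p_post <- band_extreme(post, post[, 2], band)
  p_ant <- band_extreme(ant, ant[, 2], band)
  rad2deg(atan2(p_ant[2] - p_post[2], p_ant[1] - p_post[1]))
}

#' Hindfoot alignment angle from 3D meshes
#'
#' Coronal-plane angle between the tibial longitudinal axis (oriented
#' superiorly) and the calcaneal hindfoot axis (line from the most
#' plantar-posterior tuberosity point up to the calcaneal centroid). Signed
#' so that lateral deviation of the distal calcaneus (valgus) is positive,
#' on either side.
#'
#' @param foot a [foot_model()].
#' @param band band (mm) on the plantar-posterior score defining the robust
#'   tuberosity centroid; default 6.
#' @return hindfoot alignment angle in degrees.
#' @export
hindfoot_alignment_angle <- function(foot, band = 6) {
  stopifnot(inherits(foot, "foot_model"))
  ls <- lateral_sign_of(foot$side)
  tib <- longitudinal_axis(foot$bones$tibia, c(0, 1, 0))
  v <- foot$bones$calcaneus$vertices
  tuber <- band_extreme(v, v[, 1] + v[, 2], band)
  d <- colMeans(v) - tuber
  wrap_angle(coronal_inclination(tib, ls) - coronal_inclination(d, ls))
}

#' Classify foot type from Meary's angle
#'
#' Rectus for -4.5 <= MA <= 4.5 (inclusive bounds), cavus for MA > 4.5,
#' otherwise `"other"` (planus-direction deviation).
#'
#' @param ma Meary's angle in degrees (finite).
#' @return one of `"rectus"`, `"cavus"`, `"other"` (vectorised).
#' @export
classify_foot_type <- function(ma) {
  if (any(!is.finite(ma))) stopf("non-finite Meary's angle")
  ifelse(ma > 4.5, "cavus", ifelse(ma >= -4.5, "rectus", "other"))
}

#' All three radiographic angles for one foot
#'
#' @param foot a [foot_model()].
#' @return one-row data.frame: `ma`, `haa`, `ci` (degrees) and `foot_type`.
#' @export
angle_measures <- function(foot) {
  ma <- meary_angle(foot)
  haa <- hindfoot_alignment_angle(foot)
  ci <- calcaneal_inclination(foot)
  stopifnot(is.finite(ma), is.finite(haa), is.finite(ci))
  data.frame(ma = ma, haa = haa, ci = ci,
             foot_type = classify_foot_type(ma),
             stringsAsFactors = FALSE)
}

#' Radiographic angle table for a cohort
#'
#' @param cohort list of [foot_model()] objects.
#' @return data.frame with subject, group, side, MA, HAA, CI and foot type.
#' @export
measure_cohort <- function(cohort) {
  rows <- lapply(seq_along(cohort), function(i) {
    f <- cohort[[i]]
    cbind(data.frame(subject = f$subject_id %||% sprintf("S%03d", i),
                     group = f$group %||% NA_character_,
                     side = f$side, stringsAsFactors = FALSE),
          angle_measures(f))
  })
  do.call(rbind, rows)
}

#' Group summary of radiographic angles
#'
#' Per-group mean, SD, min and max plus a pooled all-data column computed
#' with [pooled_group_stats()].
#'
#' @param angles data.frame from [measure_cohort()].
#' @param measures columns to summarise (default ma, haa, ci).
#' @return data.frame in long layout (measure x group).
#' @export
summarize_angles <- function(angles, measures = c("ma", "haa", "ci")) {
  groups <- unique(angles$group)
  out <- list()
  for (m in measures) {
    per <- lapply(groups, function(g) {
      x <- angles[[m]][angles$group == g]
      data.frame(measure = m, group = g, n = length(x), mean = mean(x),
                 sd = stats::sd(x), min = min(x), max = max(x),
                 stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, per)
    pooled <- pooled_group_stats(per$mean, per$sd, per$n)
    out[[m]] <- rbind(per, data.frame(
      measure = m, group = "all", n = sum(per$n),
      mean = pooled$mean, sd = pooled$sd,
      min = min(per$min), max = max(per$max), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Pool per-group means and SDs into overall statistics
#'
#' Exact pooling of group summaries: the overall mean is the size-weighted
#' group mean and the overall SD comes from the total sum of squares
#' \eqn{SS = \sum_i [(n_i-1) s_i^2 + n_i (m_i - M)^2]}, \eqn{SD =
#' \sqrt{SS / (\sum n_i - 1)}}.
#'
#' @param means,sds,ns per-group means, SDs and sizes (equal lengths;
#'   `ns >= 2`, `sds >= 0`).
#' @return list with `mean` and `sd`.
#' @export
pooled_group_stats <- function(means, sds, ns) {
  if (length(means) != length(sds) || length(means) != length(ns))
    stopf("means, sds and ns must have equal lengths")
  if (any(ns < 2)) stopf("all group sizes must be >= 2")
  if (any(sds < 0)) stopf("SDs must be non-negative")
  n <- sum(ns)
  m <- sum(ns * means) / n
  ss <- sum((ns - 1) * sds^2 + ns * (means - m)^2)
  list(mean = m, sd = sqrt(ss / (n - 1)))
}
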