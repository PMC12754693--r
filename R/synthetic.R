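# Synthetic weight-bearing cohort generator.
#
# Feet are built from the fixed bone templates by a deterministic kinematic
# construction that plants the three radiographic angles exactly:
#   1. calcaneal pitch (CI), applied about the mediolateral axis with an
#      analytic pre-compensation so the sagittal-projected inferior line
#      measures exactly CI after the subsequent coronal tilt;
#   2. first-ray pitch (MA), as plantarflexion of the forefoot chain
#      relative to the talar axis;
#   3. hindfoot coronal tilt (HAA) of the calcaneus under a vertical tibia.
# Surface noise is added in each bone's local template frame before posing,
# so world-frame group differences remain attributable to the planted
# angles. Correspondence across subjects is inherited from the shared
# template topology.

#' Generator parameters for a synthetic cohort
#'
#' Defaults reproduce the study conditions: group sizes 28 rectus /
#' 29 cavus / 23 CAI; Meary's angle means 0.2 / 17 / 12 (SD 2.6 / 8.6 /
#' 8.6); hindfoot alignment means 9.8 / 5.9 / 6.0 (SD 3.4 / 4.1 / 3.9);
#' calcaneal inclination means 19 / 21 / 22 (SD 3.6 / 3.1 / 3.1), all in
#' degrees; 46% left feet.
#'
#' @param group_names group labels (order defines subject order).
#' @param group_sizes subjects per group (each >= 2).
#' @param ma_mean,ma_sd per-group Meary's angle mean/SD (degrees).
#' @param haa_mean,haa_sd per-group hindfoot alignment mean/SD (degrees).
#' @param ci_mean,ci_sd per-group calcaneal inclination mean/SD (degrees).
#' @param left_fraction probability that a subject is a left foot.
#' @param noise_sd isotropic per-vertex surface noise SD (mm).
#' @param scale_sd SD of the log-normal global scale jitter (unitless).
#' @param seed global integer seed; per-subject substreams are derived as
#'   `seed + subject index`.
#' @return validated object of class `generator_params`.
#' @export
generator_params <- function(group_names = c("rectus", "cavus", "CAI"),
                             group_sizes = c(28L, 29L, 23L),
                             ma_mean = c(0.2, 17, 12),
                             ma_sd = c(2.6, 8.6, 8.6),
                             haa_mean = c(9.8, 5.9, 6.0),
                             haa_sd = c(3.4, 4.1, 3.9),
                             ci_mean = c(19, 21, 22),
                             ci_sd = c(3.6, 3.1, 3.1),
                             left_fraction = 0.46,
                             noise_sd = 0.3,
                             scale_sd = 0.05,
                             seed = 1L) {
  k <- length(group_names)
  for (nm in c("group_sizes", "ma_mean", "ma_sd", "haa_mean", "haa_sd",
               "ci_mean", "ci_sd")) {
    x <- get(nm)
    if (length(x) != k) stopf("%s must have length %d (one per group)", nm, k)
    if (any(!is.finite(x))) stopf("%s contains non-finite values", nm)
  }
  if (any(group_sizes < 2)) stopf("group sizes must be >= 2")
  if (any(c(ma_sd, haa_sd, ci_sd) < 0)) stopf("SDs must be non-negative")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (scale_sd < 0) stopf("scale_sd must be non-negative")
  if (left_fraction < 0 || left_fraction > 1)
    stopf("left_fraction must be in [0, 1]")
  structure(list(group_names = group_names,
                 group_sizes = as.integer(group_sizes),
                 ma_mean = ma_mean, ma_sd = ma_sd,
                 haa_mean = haa_mean, haa_sd = haa_sd,
                 ci_mean = ci_mean, ci_sd = ci_sd,
                 left_fraction = left_fraction,
                 noise_sd = noise_sd, scale_sd = scale_sd,
                 seed = as.integer(seed)),
            class = "generator_params")
}

# fixed template centres in the assembly frame (right foot, forefoot level)
forefoot_centres <- list(
  navicular              = c(42, 30, 0),
  cuneiform_medial       = c(60, 30, -12),
  cuneiform_intermediate = c(62, 32, -2),
  cuneiform_lateral      = c(60, 30, 8),
  cuboid                 = c(48, 24, 14),
  metatarsal_1           = c(100, 28, -22),
  metatarsal_2           = c(100, 28, -11),
  metatarsal_3           = c(100, 28, 0),
  metatarsal_4           = c(100, 28, 11),
  metatarsal_5           = c(100, 28, 22))
forefoot_pivot <- c(40, 30, 0)   # naviculocuneiform pitch pivot
talus_centre <- c(10, 42, 0)
tibia_centre <- c(10, 115, 0)
fibula_centre <- c(5, 112, 28)   # lateral malleolus side (right foot)
calcaneus_centre <- c(-5, 18, 0)

#' Build one parametric foot with exactly planted radiographic angles
#'
#' On a noiseless foot the measurement operators [meary_angle()],
#' [hindfoot_alignment_angle()] and [calcaneal_inclination()] recover the
#' planted values to numerical precision; this fixed point is the
#' generator's contract. Left feet are the mirrored right-foot construction.
#'
#' @param ma,haa,ci planted angles (degrees, finite).
#' @param scale global scale factor (> 0); angles are scale-invariant.
#' @param side `"right"` or `"left"`.
#' @param noise_sd isotropic vertex noise SD (mm), applied in each bone's
#'   local template frame before posing.
#' @param seed integer seed for the noise draws.
#' @return a [foot_model()] with ground truth attached.
#' @export
build_parametric_foot <- function(ma, haa, ci, scale = 1, side = "right",
                                  noise_sd = 0, seed = 1L) {
  if (any(!is.finite(c(ma, haa, ci)))) stopf("planted angles must be finite")
  if (!is.finite(scale) || scale <= 0) stopf("scale must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (!side %in% c("left", "right")) stopf("side must be 'left' or 'right'")

  tpl <- bone_templates()
  noisy <- with_seed(seed, lapply(bone_names(), function(nm) {
    v <- tpl[[nm]]$vertices
    if (noise_sd > 0)
      v <- v + matrix(stats::rnorm(length(v), 0, noise_sd), nrow(v), 3)
    v
  }))
  names(noisy) <- bone_names()

  theta_tal <- -(5 + ci / 2)          # talar declination
  theta_met <- theta_tal - ma         # first-ray pitch plants MA
  # pre-compensated calcaneal pitch: after the coronal HAA tilt the
  # sagittal-projected inferior line measures exactly ci
  ci_star <- rad2deg(atan(tan(deg2rad(ci)) / cos(deg2rad(haa))))

  posed <- list()
  r_ff <- rot_z(theta_met)
  for (nm in names(forefoot_centres)) {
    v0 <- sweep(noisy[[nm]], 2, -forefoot_centres[[nm]])  # place at centre
    v0 <- sweep(v0, 2, forefoot_pivot)                    # pivot to origin
    posed[[nm]] <- sweep(v0 %*% t(r_ff), 2, -forefoot_pivot)
  }
  posed$talus <- sweep(noisy$talus %*% t(rot_z(theta_tal)), 2, -talus_centre)
  posed$tibia <- sweep(noisy$tibia, 2, -tibia_centre)
  posed$fibula <- sweep(noisy$fibula, 2, -fibula_centre)
  r_cal <- rot_x(-haa) %*% rot_z(ci_star)
  posed$calcaneus <- sweep(noisy$calcaneus %*% t(r_cal), 2, -calcaneus_centre)

  # global scale about the origin, then rest the foot on the floor Y = 0
  posed <- lapply(posed, function(v) v * scale)
  floor_y <- min(vapply(posed, function(v) min(v[, 2]), 0))
  posed <- lapply(posed, function(v) { v[, 2] <- v[, 2] - floor_y; v })

  mirrored <- side == "left"
  bones <- lapply(bone_names(), function(nm) {
    v <- posed[[nm]]
    f <- tpl[[nm]]$faces
    if (mirrored) {
      v[, 3] <- -v[, 3]
      f <- f[, c(1, 3, 2), drop = FALSE]
    }
    bone_mesh(v, f, nm, side)
  })
  names(bones) <- bone_names()
  foot_model(bones, side = side,
             ground_truth = list(ma = ma, haa = haa, ci = ci,
                                 side = side, scale = scale))
}

#' Sample a group-structured synthetic cohort
#'
#' Draws per-subject (MA, HAA, CI) independently from each group's normal
#' distributions and builds each foot with [build_parametric_foot()].
#' Subject i uses the reproducible substream `seed + i`, so the cohort is
#' invariant to regeneration order.
#'
#' @param params a [generator_params()] object.
#' @return list of [foot_model()] objects (class `foot_cohort`) with group
#'   labels and ground truth attached.
#' @export
sample_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  groups <- rep(params$group_names, params$group_sizes)
  gidx <- rep(seq_along(params$group_names), params$group_sizes)
  n <- length(groups)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gidx[i]
    draw <- with_seed(params$seed + i, {
      list(ma = stats::rnorm(1, params$ma_mean[g], params$ma_sd[g]),
           haa = stats::rnorm(1, params$haa_mean[g], params$haa_sd[g]),
           ci = stats::rnorm(1, params$ci_mean[g], params$ci_sd[g]),
           left = stats::runif(1) < params$left_fraction,
           scale = exp(stats::rnorm(1, 0, params$scale_sd)),
           noise_seed = sample.int(.Machine$integer.max - 1L, 1))
    })
    foot <- build_parametric_foot(draw$ma, draw$haa, draw$ci,
                                  scale = draw$scale,
                                  side = if (draw$left) "left" else "right",
                                  noise_sd = params$noise_sd,
                                  seed = draw$noise_seed)
    foot$group <- groups[i]
    foot$subject_id <- sprintf("S%03d", i)
    cohort[[i]] <- foot
  }
  structure(cohort, class = c("foot_cohort", "list"))
}

#' @export
print.foot_cohort <- function(x, ...) {
  g <- table(vapply(x, function(f) f$group %||% "?", ""))
  cat(sprintf("<foot_cohort> %d subjects (%s)\n", length(x),
              paste(sprintf("%s: %d", names(g), g), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk as one mesh file per bone plus a manifest
#'
#' @param cohort a [sample_cohort()] result (or any list of foot models).
#' @param dir output directory (created if needed).
#' @param format `"ply"` (default), `"stl"` or `"obj"`.
#' @param binary use the binary dialect where the format has one.
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("ply", "stl", "obj"),
                         binary = FALSE) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(cohort)) {
    f <- cohort[[i]]
    sid <- f$subject_id %||% sprintf("S%03d", i)
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    paths <- vapply(bone_names(), function(nm) {
      p <- file.path(sdir, paste0(nm, ".", format))
      write_mesh(f$bones[[nm]], p, binary = binary)
      p
    }, "")
    gt <- f$ground_truth
    rows[[i]] <- data.frame(
      subject = sid, group = f$group %||% NA_character_, side = f$side,
      planted_ma = gt$ma %||% NA_real_, planted_haa = gt$haa %||% NA_real_,
      planted_ci = gt$ci %||% NA_real_, scale = gt$scale %||% NA_real_,
      mesh_dir = sdir, format = format, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path path to the manifest CSV.
#' @return a `foot_cohort` list of [foot_model()] objects.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stopf("manifest not found: %s", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  cohort <- lapply(seq_len(nrow(man)), function(i) {
    r <- man[i, ]
    bones <- lapply(bone_names(), function(nm)
      read_mesh(file.path(r$mesh_dir, paste0(nm, ".", r$format)), nm, r$side))
    names(bones) <- bone_names()
    gt <- if (is.finite(r$planted_ma))
      list(ma = r$planted_ma, haa = r$planted_haa, ci = r$planted_ci,
           side = r$side, scale = r$scale)
    foot_model(bones, side = r$side,
               group = if (is.na(r$group)) NULL else r$group,
               subject_id = r$subject, ground_truth = gt)
  })
  structure(cohort, class = c("foot_cohort", "list"))
}
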