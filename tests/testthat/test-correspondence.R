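# Particle extraction, generalized Procrustes, local frames and flattening.

test_that("particle extraction is a fixed template subsample", {
  co <- lapply(1:2, function(i) fixture_foot(ma = 5 * i, noise_sd = 0))
  ps <- extract_particles(co, 16L)
  expect_equal(sum(ps$layout$count), 16L * 14L)
  # full vertex counts: particles equal vertices
  nv <- vapply(co[[1]]$bones[bone_names()], function(b) nrow(b$vertices), 0L)
  ps_full <- extract_particles(co, nv)
  expect_identical(ps_full$raw[[1]], pooled_vertices(co[[1]]))
  # correspondence: particle k sits on the same template vertex for both
  # subjects (noiseless feet with equal planted CI/HAA share hindfoot pose)
  co2 <- lapply(1:2, function(i) fixture_foot(ma = 5, noise_sd = 0))
  ps2 <- extract_particles(co2, 16L)
  expect_identical(ps2$raw[[1]], ps2$raw[[2]])
  # errors
  expect_error(extract_particles(co, 10000L), "only")
  bad <- co
  bad[[2]]$bones$talus$vertices <- bad[[2]]$bones$talus$vertices[-1, ]
  bad[[2]]$bones$talus$faces <-
    bad[[2]]$bones$talus$faces[apply(bad[[2]]$bones$talus$faces <=
      nrow(bad[[2]]$bones$talus$vertices), 1, all), ]
  expect_error(extract_particles(bad, 16L), "talus")
})

test_that("GPA aligns identical shapes at different scales and poses", {
  base <- extract_particles(list(fixture_foot()), 12L)$raw[[1]]
  mk <- function(s, rot, tr) sweep(s * base %*% t(rot), 2, -tr)
  raw <- list(base, mk(2, rot_y(30), c(50, 0, 0)),
              mk(0.5, rot_z(15) %*% rot_x(10), c(-10, 20, 5)))
  ps <- structure(list(subjects = paste0("S", 1:3), groups = rep("g", 3),
                       layout = data.frame(bone = "talus", count = nrow(base),
                                           offset = 0L),
                       raw = raw, world = NULL, local = NULL),
                  class = "particle_set")
  ps <- generalized_procrustes(ps)
  for (i in 2:3)
    expect_lt(max(abs(ps$world[[i]] - ps$world[[1]])), 1e-9)
  # unit centroid size, zero centroid of the mean
  expect_equal(sqrt(sum(ps$mean_world^2)), 1, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(ps$mean_world))), 1e-9)
  for (w in ps$world) expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-9)
  # objective monotone non-increasing
  expect_true(all(diff(ps$gpa_objective) <= 1e-12))
})

test_that("GPA is insensitive to subject order at convergence", {
  co <- fixture_cohort(sizes = c(3, 3, 2), seed = 21)
  ps <- generalized_procrustes(extract_particles(co, 12L))
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  ps_p <- generalized_procrustes(extract_particles(co[perm], 12L))
  for (i in seq_along(perm))
    expect_lt(max(abs(ps$world[[perm[i]]] - ps_p$world[[i]])), 1e-6)
})

test_that("GPA mean of noisy copies is closer to the template than the copies",
{
  skip_if_not_installed("vegan")
  set.seed(31)
  tmpl <- extract_particles(list(fixture_foot()), 8L)$raw[[1]]
  raw <- lapply(1:50, function(i) {
    noisy <- tmpl + matrix(rnorm(length(tmpl), 0, 1.5), nrow(tmpl), 3)
    sweep(noisy %*% t(rot_y(runif(1, -20, 20))), 2, runif(3, -10, 10))
  })
  ps <- structure(list(subjects = paste0("S", 1:50), groups = rep("g", 50),
                       layout = data.frame(bone = "talus", count = nrow(tmpl),
                                           offset = 0L),
                       raw = raw, world = NULL, local = NULL),
                  class = "particle_set")
  ps <- generalized_procrustes(ps)
  # independent two-configuration Procrustes distance oracle (vegan)
  pd <- function(a, b) vegan::procrustes(a, b, symmetric = TRUE)$ss
  d_mean <- pd(tmpl, ps$mean_world)
  d_copies <- vapply(raw, function(x) pd(tmpl, x), 0)
  expect_gte(mean(d_copies > d_mean), 0.95)
})

test_that("local frame removes rigid per-subject bone repositioning", {
  base <- fixture_foot(noise_sd = 0)
  co <- lapply(1:6, function(i) {
    f <- base
    # rigidly reposition one bone per subject, identical shape
    v <- f$bones$navicular$vertices
    ctr <- colMeans(v)
    v <- sweep(sweep(v, 2, ctr) %*% t(rot_z(3 * i)), 2, -(ctr + c(i, 0, 0)))
    f$bones$navicular <- bone_mesh(v, f$bones$navicular$faces, "navicular",
                                   "right")
    f$subject_id <- sprintf("S%03d", i)
    f
  })
  ps <- per_bone_local_frames(generalized_procrustes(extract_particles(co, 12L),
                                                     with_scaling = FALSE))
  rows <- with(ps$layout, offset[bone == "navicular"] +
                 seq_len(count[bone == "navicular"]))
  loc <- lapply(ps$local, function(m) m[rows, ])
  wld <- lapply(ps$world, function(m) m[rows, ])
  for (i in 2:6) {
    expect_lt(max(abs(loc[[i]] - loc[[1]])), 1e-6)
    expect_gt(max(abs(wld[[i]] - wld[[1]])), 1e-3)
  }
})

test_that("identical feet give zero variance in both frames", {
  co <- lapply(1:3, function(i) fixture_foot(noise_sd = 0))
  ps <- per_bone_local_frames(generalized_procrustes(extract_particles(co, 8L)))
  w <- flatten_particles(ps, "world")
  l <- flatten_particles(ps, "local")
  expect_lt(max(apply(w, 2, var)), 1e-18)
  expect_lt(max(apply(l, 2, var)), 1e-18)
})

test_that("a planted pose shift loads world, not local, variance", {
  co <- c(lapply(1:6, function(i) fixture_foot(ma = 0, noise_sd = 0.1,
                                               seed = i)),
          lapply(1:6, function(i) fixture_foot(ma = 12, noise_sd = 0.1,
                                               seed = 100 + i)))
  for (i in seq_along(co)) co[[i]]$group <- if (i <= 6) "a" else "b"
  ps <- fixture_particles(co, 12L)
  rows <- with(ps$layout, offset[bone == "metatarsal_1"] +
                 seq_len(count[bone == "metatarsal_1"]))
  bv <- function(frame) {
    cfg <- vapply(ps[[frame]], function(m) as.vector(m[rows, ]), numeric(36))
    ga <- rowMeans(cfg[, 1:6]); gb <- rowMeans(cfg[, 7:12])
    sum((ga - gb)^2)
  }
  expect_gt(bv("world") / bv("local"), 10)
})

test_that("flattening honours the documented column order and inverts", {
  cfg1 <- rbind(c(1, 2, 3), c(4, 5, 6))
  cfg2 <- rbind(c(7, 8, 9), c(10, 11, 12))
  ps <- structure(list(subjects = c("a", "b"), groups = c("g", "g"),
                       layout = data.frame(bone = "talus", count = 2L,
                                           offset = 0L),
                       raw = list(cfg1, cfg2), world = list(cfg1, cfg2),
                       local = NULL),
                  class = "particle_set")
  m <- flatten_particles(ps, "world")
  expect_equal(dim(m), c(2L, 6L))
  expect_equal(unname(m[1, ]), c(1, 2, 3, 4, 5, 6))  # x1 y1 z1 x2 y2 z2
  expect_equal(unflatten_particles(m[2, ]), cfg2)
  map <- shape_matrix_map(ps$layout)
  expect_equal(map$axis, rep(c("x", "y", "z"), 2))
  expect_equal(map$particle, rep(1:2, each = 3))
  expect_error(flatten_particles(ps, "local"), "not computed")
})

test_that("particle export writes per-bone XYZ files and an index", {
  co <- lapply(1:2, function(i) fixture_foot(ma = 2 * i))
  ps <- generalized_procrustes(extract_particles(co, 8L))
  d <- withr::local_tempdir()
  ip <- write_particles(ps, d, "world")
  expect_true(file.exists(ip))
  f1 <- file.path(d, "S001", "talus.particles")
  expect_true(file.exists(f1))
  back <- as.matrix(read.table(f1))
  rows <- with(ps$layout, offset[bone == "talus"] + seq_len(count[bone == "talus"]))
  expect_equal(unname(back), unname(ps$world[[1]][rows, ]), tolerance = 1e-12)
})
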