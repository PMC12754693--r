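# Shared fixtures, all generated in code at test time.

# a small noiseless right foot with known planted angles
fixture_foot <- function(ma = 12, haa = 6, ci = 22, side = "right",
                         noise_sd = 0, seed = 1L, scale = 1) {
  build_parametric_foot(ma, haa, ci, scale = scale, side = side,
                        noise_sd = noise_sd, seed = seed)
}

# tetrahedron bone mesh (minimal valid mesh)
fixture_tetra <- function(label = "talus", side = "right") {
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  bone_mesh(v, f, label, side)
}

# small cohort helper with reduced group sizes (defaults otherwise)
fixture_cohort <- function(sizes = c(8, 8, 6), seed = 11L, noise_sd = 0.3,
                           ...) {
  sample_cohort(generator_params(group_sizes = sizes, seed = seed,
                                 noise_sd = noise_sd, ...))
}

# aligned particle set (world + local frames) for a cohort
fixture_particles <- function(cohort, count = 16L) {
  ps <- extract_particles(cohort, count)
  ps <- generalized_procrustes(ps)
  per_bone_local_frames(ps)
}
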