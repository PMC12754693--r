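# Configuration-driven orchestration of the full analysis: generate or
# ingest a cohort, mirror left feet, measure radiographic angles, ICP-align
# to a reference subject, extract correspondence particles, generalized
# Procrustes, PCA with parallel-analysis retention, per-mode group
# statistics, per-particle significance maps, and a machine-readable report.

#' Default pipeline configuration values
#' @return named list of defaults accepted by [validate_config()].
#' @export
pipeline_defaults <- function() {
  list(
    input = "synthetic",           # "synthetic" | "mesh_dir"
    manifest = NULL,               # manifest CSV for mesh_dir input
    generator = list(),            # overrides for generator_params()
    particle_count = 128L,
    icp = TRUE,
    icp_max_points = 600L,
    icp_max_iter = 50L,
    icp_tol = 1e-6,
    gpa_tol = 1e-8,
    n_permutations = 1000L,
    percentile = 95,
    alpha = 0.05,
    fdr_method = "BH",
    comparisons = list(c("CAI", "rectus"), c("cavus", "rectus"),
                       c("CAI", "cavus")),
    out_dir = NULL,
    seed = 1L)
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a list; fills defaults, checks ranges
#' and rejects unknown keys. All schema violations are reported together,
#' not first-failure.
#'
#' @param config path to a YAML/JSON config file, or a named list
#'   (possibly empty for all defaults).
#' @return validated config list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext == "json") jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    if (is.null(config)) config <- list()
    if (!is.null(config$comparisons))
      config$comparisons <- lapply(seq_len(NROW(config$comparisons)),
                                   function(i) if (is.matrix(config$comparisons))
                                     config$comparisons[i, ] else
                                       unlist(config$comparisons[[i]]))
  }
  if (!is.list(config)) stopf("config must be a list or a YAML/JSON path")
  defaults <- pipeline_defaults()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)],
                           keep.null = TRUE)
  if (!cfg$input %in% c("synthetic", "mesh_dir"))
    errors <- c(errors, "input must be 'synthetic' or 'mesh_dir'")
  if (cfg$input == "mesh_dir" && is.null(cfg$manifest))
    errors <- c(errors, "mesh_dir input requires 'manifest'")
  gen_ok <- names(formals(generator_params))
  gbad <- setdiff(names(cfg$generator), gen_ok)
  if (length(gbad))
    errors <- c(errors, sprintf("unknown generator key(s): %s",
                                paste(gbad, collapse = ", ")))
  num_checks <- list(
    c("alpha", 0, 1), c("percentile", 50, 100))
  for (ck in num_checks) {
    v <- cfg[[ck[1]]]
    if (!is.numeric(v) || length(v) != 1 || v <= as.numeric(ck[2]) ||
        v >= as.numeric(ck[3]))
      errors <- c(errors, sprintf("%s must be a number in (%s, %s)",
                                  ck[1], ck[2], ck[3]))
  }
  for (nm in c("icp_tol", "gpa_tol"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      errors <- c(errors, sprintf("%s must be > 0", nm))
  for (nm in c("particle_count", "icp_max_points", "icp_max_iter",
               "n_permutations", "seed"))
    if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] < 1))
      errors <- c(errors, sprintf("%s must be a positive integer", nm))
  if (!identical(cfg$fdr_method, "BH"))
    errors <- c(errors, "fdr_method: only 'BH' is supported")
  if (!is.logical(cfg$icp) || length(cfg$icp) != 1)
    errors <- c(errors, "icp must be TRUE or FALSE")
  for (cp in cfg$comparisons)
    if (length(cp) != 2)
      errors <- c(errors, "each comparison must name exactly two groups")
  if (length(errors))
    stopf("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Stable content hash of a configuration
#' @param config a validated config list.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # canonical serialisation: sorted keys, text dump
  dump_cfg <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x) %||% seq_along(x))]
      paste0("{", paste(names(x), vapply(x, dump_cfg, ""), sep = ":",
                        collapse = ","), "}")
    } else paste(format(x, digits = 17), collapse = ",")
  }
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # storage location does not affect analysis identity
  writeLines(dump_cfg(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full multi-bone shape analysis pipeline
#'
#' Executes all stages in order (cohort, mirroring, radiographic
#' measurement, ICP alignment, particles, GPA, PCA + parallel analysis,
#' per-mode statistics, particle significance maps) and returns a report.
#' Stage results are cached in `out_dir/cache`, content-addressed by the
#' configuration hash, so re-running an unchanged configuration skips
#' completed stages. All randomness derives from `config$seed`.
#'
#' @param config a [validate_config()] result (or anything it accepts).
#' @param quiet suppress per-stage progress messages.
#' @return report list of class `analysis_report` (also written as
#'   `report.json` when `out_dir` is set).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  hash <- config_hash(config)
  cache_dir <- if (!is.null(config$out_dir)) {
    d <- file.path(config$out_dir, "cache")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("%s_%s.rds", name, substr(hash, 1, 12)))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      say("[%s] cached", name)
      return(readRDS(cache_file))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    if (!is.null(cache_file)) saveRDS(res, cache_file)
    res
  }

  cohort <- stage("cohort", {
    if (config$input == "synthetic") {
      gen <- do.call(generator_params,
                     utils::modifyList(list(seed = config$seed),
                                       config$generator))
      sample_cohort(gen)
    } else read_cohort(config$manifest)
  })
  say("[cohort] %d subjects", length(cohort))

  cohort <- stage("mirror", {
    structure(lapply(cohort, function(f)
      if (f$side == "left") mirror_foot(f) else f),
      class = c("foot_cohort", "list"))
  })

  angles <- stage("radiographic", measure_cohort(cohort))
  groups <- angles$group
  group_names <- unique(groups)
  angle_summary <- summarize_angles(angles)
  angle_tests <- stage("radiographic_tests", {
    lapply(c(ma = "ma", haa = "haa", ci = "ci"), function(m) {
      gs <- lapply(group_names, function(g) angles[[m]][groups == g])
      names(gs) <- group_names
      w <- welch_anova(gs)
      gh <- games_howell(gs)
      gh$hedges_g <- apply(utils::combn(length(gs), 2), 2, function(ij)
        hedges_g(gs[[ij[1]]], gs[[ij[2]]])$g)
      list(welch = w, games_howell = gh)
    })
  })

  if (isTRUE(config$icp)) {
    cohort <- stage("icp", {
      ref_group <- group_names[1]
      ref_idx <- which(groups == ref_group)[1] %||% 1L
      target <- pooled_vertices(cohort[[ref_idx]])
      sub <- function(m, k) m[floor(seq(1, nrow(m), length.out = min(k, nrow(m)))), , drop = FALSE]
      target_s <- sub(target, config$icp_max_points * 4L)
      out <- lapply(seq_along(cohort), function(i) {
        if (i == ref_idx) return(cohort[[i]])
        src <- sub(pooled_vertices(cohort[[i]]), config$icp_max_points)
        fit <- icp_align(src, target_s, max_iter = config$icp_max_iter,
                         tol = config$icp_tol)
        f <- cohort[[i]]
        f$bones <- lapply(f$bones, function(b) {
          b$vertices <- transform_points(fit$transform, b$vertices)
          b
        })
        f
      })
      structure(out, class = c("foot_cohort", "list"))
    })
  }

  pset <- stage("particles", extract_particles(cohort, config$particle_count))
  pset <- stage("gpa", {
    p <- generalized_procrustes(pset, with_scaling = TRUE,
                                tol = config$gpa_tol)
    per_bone_local_frames(p, tol = config$gpa_tol)
  })

  world <- flatten_particles(pset, "world")
  model <- stage("pca", {
    m <- pca_fit(world)
    m$retained <- parallel_analysis(world,
                                    n_permutations = config$n_permutations,
                                    percentile = config$percentile,
                                    seed = config$seed)
    m
  })
  say("[pca] %d modes retained (mode 1: %.1f%% variance)",
      model$retained, model$percent_variance[1])

  mode_stats <- stage("mode_stats", {
    if (model$retained >= 1L) mode_group_stats(model, groups)
    else list(per_mode = list(), summary = NULL)
  })

  maps <- stage("particle_maps", {
    lapply(config$comparisons, function(cp)
      particle_significance_map(pset, cp[1], cp[2], alpha = config$alpha))
  })

  report <- list(
    provenance = list(config_hash = hash, seed = config$seed,
                      package_version = as.character(utils::packageVersion("footmorph")),
                      n_subjects = length(cohort)),
    groups = as.list(table(groups)),
    retained_modes = model$retained,
    percent_variance = model$percent_variance[seq_len(min(10, length(model$percent_variance)))],
    mode_stats = if (!is.null(mode_stats$summary)) mode_stats$summary,
    tukey = if (model$retained >= 1L)
      lapply(mode_stats$per_mode, function(r) r$tukey),
    particle_maps = lapply(maps, function(m)
      list(comparison = paste(m$comparison, collapse = "_vs_"),
           percentages = as.list(m$percentages),
           n_singular = m$n_singular)),
    radiographic = list(summary = angle_summary,
                        tests = lapply(angle_tests, function(t)
                          list(welch_f = t$welch$f, welch_p = t$welch$p,
                               games_howell = t$games_howell))))
  class(report) <- c("analysis_report", "list")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(angles, file.path(config$out_dir, "angles.csv"),
                     row.names = FALSE)
    utils::write.csv(angle_summary,
                     file.path(config$out_dir, "angle_summary.csv"),
                     row.names = FALSE)
    if (!is.null(mode_stats$summary))
      utils::write.csv(mode_stats$summary,
                       file.path(config$out_dir, "mode_summary.csv"),
                       row.names = FALSE)
    for (m in maps)
      utils::write.csv(m$particles,
                       file.path(config$out_dir,
                                 sprintf("particle_map_%s_vs_%s.csv",
                                         m$comparison[1], m$comparison[2])),
                       row.names = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns",
                         pretty = TRUE)
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d subjects; %d retained modes; mode 1 explains %.1f%% variance\n",
              x$provenance$n_subjects, x$retained_modes,
              x$percent_variance[1]))
  if (!is.null(x$mode_stats))
    print(x$mode_stats, digits = 3)
  for (m in x$particle_maps)
    cat(sprintf("  %s: %.1f%% alignment only, %.1f%% shape only, %.2f%% both\n",
                m$comparison, m$percentages$alignment_only,
                m$percentages$shape_only, m$percentages$alignment_and_shape))
  invisible(x)
}
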