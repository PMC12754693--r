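# Shape-model statistics: PCA of flattened particle matrices, parallel
# analysis for mode retention, per-mode group tests with effect sizes,
# per-particle Hotelling T2 significance maps with FDR control, and the
# alignment-vs-shape particle classification.

#' Principal component analysis of a shape matrix
#'
#' Column-mean-centered SVD. At most n - 1 non-null modes are kept; scores
#' are the centered data projected on the modes, so the score variance of
#' mode k equals its eigenvalue.
#'
#' @param x n x p shape matrix (n >= 3 rows, finite entries).
#' @return object of class `shape_model`: `mean`, `modes` (p x m,
#'   orthonormal columns), `eigenvalues` (descending), `scores` (n x m),
#'   `percent_variance`, `retained` (NA until set by [parallel_analysis()]).
#' @export
pca_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stopf("PCA needs >= 3 subjects, got %d", nrow(x))
  if (any(!is.finite(x))) stopf("shape matrix contains non-finite values")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  s <- svd(xc, nu = nrow(x), nv = min(dim(x)))
  m <- min(nrow(x) - 1L, ncol(x))
  d <- s$d[seq_len(m)]
  tol <- max(d) * 1e-12
  m <- max(sum(d > tol), 1L)
  d <- s$d[seq_len(m)]
  modes <- s$v[, seq_len(m), drop = FALSE]
  scores <- xc %*% modes
  ev <- d^2 / (nrow(x) - 1)
  structure(list(mean = ctr, modes = modes, eigenvalues = ev,
                 scores = scores,
                 percent_variance = 100 * ev / sum(ev),
                 n = nrow(x), retained = NA_integer_,
                 groups = attr(x, "groups"), layout = attr(x, "layout"),
                 frame = attr(x, "frame")),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %d subjects, %d modes; mode 1 explains %.1f%%%s\n",
              x$n, length(x$eigenvalues), x$percent_variance[1],
              if (is.na(x$retained)) "" else
                sprintf("; %d modes retained", x$retained)))
  invisible(x)
}

# eigenvalues of the column-centered matrix (covariance scale), via the
# small-side Gram matrix
cov_eigenvalues <- function(xc) {
  n <- nrow(xc)
  g <- tcrossprod(xc)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values / (n - 1)
  pmax(ev[seq_len(min(n - 1L, ncol(xc)))], 0)
}

#' Parallel analysis for PCA mode retention
#'
#' Permutation-based null: each column of the centered matrix is
#' independently row-permuted per replicate, destroying inter-column
#' covariance while keeping marginals. A mode is retained while its observed
#' eigenvalue strictly exceeds the given percentile of null eigenvalues at
#' the same rank; the retained count is the longest such prefix.
#'
#' @param x n x p shape matrix.
#' @param n_permutations permutation replicates (>= 100; default 1000).
#' @param percentile null percentile threshold (default 95).
#' @param seed RNG seed for the permutations.
#' @return integer retained mode count.
#' @export
parallel_analysis <- function(x, n_permutations = 1000L, percentile = 95,
                              seed = 1L) {
  x <- as.matrix(x)
  if (n_permutations < 100L) stopf("n_permutations must be >= 100")
  xc <- sweep(x, 2, colMeans(x))
  if (max(abs(xc)) == 0) return(0L)
  obs <- cov_eigenvalues(xc)
  n <- nrow(xc)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(r) {
      xp <- xc
      for (j in seq_len(ncol(xc))) xp[, j] <- xc[sample.int(n), j]
      cov_eigenvalues(xp)
    }, numeric(length(obs)))
  })
  thr <- apply(nulls, 1, stats::quantile, probs = percentile / 100,
               names = FALSE)
  keep <- obs > thr  # strict: a tie is not retained
  if (!keep[1]) 0L else which.min(c(keep, FALSE)) - 1L
}

#' Kolmogorov-Smirnov normality check of PCA scores
#'
#' One-sample KS statistic against a normal with the sample's own mean and
#' SD, with the asymptotic KS p-value; optionally the Lilliefors-corrected
#' variant (which accounts for the estimated parameters).
#'
#' @param x numeric vector (n >= 5, non-zero variance).
#' @param lilliefors use the Lilliefors correction (requires nortest).
#' @return list with `statistic` (D) and `p`.
#' @export
ks_normality <- function(x, lilliefors = FALSE) {
  if (length(x) < 5L) stopf("KS normality needs >= 5 values")
  if (stats::sd(x) == 0) stopf("zero-variance sample")
  if (lilliefors) {
    t <- nortest::lillie.test(x)
    return(list(statistic = unname(t$statistic), p = t$p.value))
  }
  t <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(t$statistic), p = t$p.value)
}

check_groups <- function(groups, min_n = 2L) {
  if (length(groups) < 2L) stopf("need >= 2 groups")
  ns <- unname(vapply(groups, length, 0L))
  if (any(ns < min_n)) stopf("every group needs n >= %d", min_n)
  ns
}

#' Classical one-way ANOVA
#'
#' Equal-variance one-way ANOVA with explicit sums of squares,
#' F = (SS_b/df_b) / (SS_w/df_w).
#'
#' @param groups list of numeric vectors (each n >= 2).
#' @return list with `f`, `p`, `ss_between`, `ss_within`, `ss_total`,
#'   `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  ns <- check_groups(groups)
  all_x <- unlist(groups, use.names = FALSE)
  gm <- mean(all_x)
  ss_t <- sum((all_x - gm)^2)
  if (ss_t == 0) stopf("all observations equal: F undefined (SS_total = 0)")
  means <- unname(vapply(groups, mean, 0))
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- ss_t - ss_b
  df_b <- length(groups) - 1L
  df_w <- length(all_x) - length(groups)
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       ss_between = ss_b, ss_within = ss_w, ss_total = ss_t,
       df_between = df_b, df_within = df_w)
}

#' Tukey's HSD post hoc test (Tukey-Kramer for unequal n)
#'
#' Studentized-range pairwise p-values with Tukey-Kramer standard errors
#' from the pooled within-group mean square.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @return data.frame: group_a, group_b, diff, q, p_adj.
#' @export
tukey_hsd <- function(groups) {
  ns <- check_groups(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  a <- anova_oneway(groups)
  msw <- a$ss_within / a$df_within
  if (msw <= 0) stopf("zero within-group variance: Tukey HSD undefined")
  k <- length(groups)
  means <- unname(vapply(groups, mean, 0))
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(msw / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    c(diff = means[i] - means[j], q = q,
      p_adj = stats::ptukey(q, k, a$df_within, lower.tail = FALSE))
  })
  data.frame(group_a = names(groups)[pairs[1, ]],
             group_b = names(groups)[pairs[2, ]],
             diff = out["diff", ], q = out["q", ], p_adj = out["p_adj", ],
             stringsAsFactors = FALSE)
}

#' Eta-squared effect size from ANOVA sums of squares
#'
#' eta^2 = SS_between / SS_total, with Cohen-style benchmark labels:
#' >= 0.01 small, >= 0.06 medium, >= 0.14 large.
#'
#' @param ss_between,ss_total sums of squares (`ss_total > 0`).
#' @return list with `eta_sq` and `label`.
#' @export
eta_squared <- function(ss_between, ss_total) {
  if (ss_total <= 0) stopf("SS_total must be > 0")
  e <- ss_between / ss_total
  label <- if (e >= 0.14) "large" else if (e >= 0.06) "medium"
           else if (e >= 0.01) "small" else "negligible"
  list(eta_sq = e, label = label)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Weights w_i = n_i / s_i^2 with the Welch-Satterthwaite denominator
#' degrees of freedom; robust to unequal group variances.
#'
#' @param groups list of numeric vectors (each n >= 2, variance > 0).
#' @return list with `f`, `p`, `df1`, `df2`.
#' @export
welch_anova <- function(groups) {
  ns <- check_groups(groups)
  vars <- unname(vapply(groups, stats::var, 0))
  if (any(vars <= 0)) stopf("zero within-group variance: Welch ANOVA undefined")
  means <- unname(vapply(groups, mean, 0))
  k <- length(groups)
  w <- ns / vars
  mw <- sum(w * means) / sum(w)
  a <- sum(w * (means - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (ns - 1))
  f <- a / (1 + 2 * (k - 2) / (k^2 - 1) * lam)
  df2 <- (k^2 - 1) / (3 * lam)
  list(f = f, p = stats::pf(f, k - 1, df2, lower.tail = FALSE),
       df1 = k - 1, df2 = df2)
}

#' Games-Howell post hoc test
#'
#' Pairwise Welch t statistics with per-pair Welch-Satterthwaite degrees of
#' freedom, referred to the studentized range distribution via q = t * sqrt(2).
#'
#' @param groups named list of numeric vectors (each n >= 2, variance > 0).
#' @return data.frame: group_a, group_b, diff, t, df, p_adj.
#' @export
games_howell <- function(groups) {
  ns <- check_groups(groups)
  vars <- unname(vapply(groups, stats::var, 0))
  if (any(vars <= 0)) stopf("zero within-group variance: Games-Howell undefined")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  means <- unname(vapply(groups, mean, 0))
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- vars[i] / ns[i] + vars[j] / ns[j]
    t <- abs(means[i] - means[j]) / sqrt(se2)
    df <- se2^2 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                     (vars[j] / ns[j])^2 / (ns[j] - 1))
    c(diff = means[i] - means[j], t = t, df = df,
      p_adj = stats::ptukey(t * sqrt(2), k, df, lower.tail = FALSE))
  })
  data.frame(group_a = names(groups)[pairs[1, ]],
             group_b = names(groups)[pairs[2, ]],
             diff = out["diff", ], t = out["t", ], df = out["df", ],
             p_adj = out["p_adj", ], stringsAsFactors = FALSE)
}

#' Hedges' g standardized mean difference
#'
#' g = (mean_a - mean_b) / s_pooled * J with the small-sample correction
#' J = 1 - 3 / (4 (n_a + n_b) - 9). Benchmark labels: |g| > 0.2 small,
#' > 0.5 medium, > 0.8 large.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return list with `g`, `j` and `label`.
#' @export
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stopf("Hedges g needs n >= 2 per group")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stopf("zero pooled variance: Hedges g undefined")
  j <- 1 - 3 / (4 * (na + nb) - 9)
  g <- (mean(a) - mean(b)) / sqrt(sp2) * j
  label <- if (abs(g) > 0.8) "large" else if (abs(g) > 0.5) "medium"
           else if (abs(g) > 0.2) "small" else "negligible"
  list(g = g, j = j, label = label)
}

#' Two-sample Hotelling T2 test
#'
#' T2 = (n_a n_b)/(n_a + n_b) d' S_pooled^-1 d with d the mean difference
#' and S_pooled the pooled covariance; referred to an F distribution with
#' (p, n_a + n_b - p - 1) degrees of freedom.
#'
#' @param a,b n x p matrices (here p = 3 coordinates per particle);
#'   `n_a + n_b >= p + 2` so the denominator df is >= 1.
#' @return list with `t2`, `f`, `p` (the p-value) and `df`.
#' @export
hotelling_t2_two_sample <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  p <- ncol(a)
  na <- nrow(a); nb <- nrow(b)
  if (ncol(b) != p) stopf("dimension mismatch between samples")
  if (na < 2L || nb < 2L) stopf("Hotelling T2 needs n >= 2 per group")
  if (na + nb < p + 2L)
    stopf("Hotelling T2 needs n_a + n_b >= %d for %d variables", p + 2L, p)
  s_pool <- ((na - 1) * stats::cov(a) + (nb - 1) * stats::cov(b)) / (na + nb - 2)
  d <- colMeans(a) - colMeans(b)
  si <- tryCatch(solve(s_pool, d), error = function(e) NULL)
  if (is.null(si) || !all(is.finite(si)))
    stop(structure(class = c("footmorph_singular", "error", "condition"),
                   list(message = "singular pooled covariance", call = NULL)))
  t2 <- (na * nb) / (na + nb) * sum(d * si)
  df2 <- na + nb - p - 1
  f <- t2 * df2 / (p * (na + nb - 2))
  list(t2 = t2, f = f, p = stats::pf(f, p, df2, lower.tail = FALSE),
       df = c(p, df2))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values with a significance mask at `alpha`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list with `adjusted` and `significant` (logical mask).
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, significant = !is.na(adj) & adj <= alpha)
}

#' Per-particle Hotelling T2 significance map
#'
#' Runs the two-sample Hotelling T2 test at every correspondence particle in
#' the world frame (whole-foot aligned: pose + relative bone position) and
#' the local frame (per-bone aligned: intrinsic shape only), applies
#' Benjamini-Hochberg FDR separately within each frame, and classifies each
#' particle: significant in world only = `alignment_only`, local only =
#' `shape_only`, both = `alignment_and_shape`, neither = `none`. Particles
#' with a singular pooled covariance are logged and classified `none`.
#'
#' @param pset a `particle_set` with world and local frames computed.
#' @param group_a,group_b group labels to compare.
#' @param alpha FDR level (default 0.05).
#' @return object of class `particle_map`: per-particle table (bone,
#'   class, raw/adjusted p per frame) and class percentages.
#' @export
particle_significance_map <- function(pset, group_a, group_b, alpha = 0.05) {
  stopifnot(inherits(pset, "particle_set"))
  if (is.null(pset$world) || is.null(pset$local))
    stopf("both world and local frames must be computed")
  ia <- which(pset$groups == group_a)
  ib <- which(pset$groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stopf("groups '%s'/'%s' need >= 2 subjects each", group_a, group_b)
  n_part <- sum(pset$layout$count)
  frame_p <- function(frame) {
    configs <- pset[[frame]]
    arr_a <- simplify2array(configs[ia])  # p x 3 x n_a
    arr_b <- simplify2array(configs[ib])
    p <- numeric(n_part)
    singular <- integer(0)
    for (k in seq_len(n_part)) {
      res <- tryCatch(
        hotelling_t2_two_sample(t(arr_a[k, , ]), t(arr_b[k, , ])),
        footmorph_singular = function(e) NULL)
      if (is.null(res)) { p[k] <- NA_real_; singular <- c(singular, k) }
      else p[k] <- res$p
    }
    list(p = p, singular = singular)
  }
  w <- frame_p("world")
  l <- frame_p("local")
  sing <- union(w$singular, l$singular)
  if (length(sing))
    warnf("%d particle(s) with singular pooled covariance classified 'none'",
          length(sing))
  adj_w <- fdr_bh(w$p, alpha)
  adj_l <- fdr_bh(l$p, alpha)
  cls <- rep("none", n_part)
  cls[adj_w$significant & !adj_l$significant] <- "alignment_only"
  cls[!adj_w$significant & adj_l$significant] <- "shape_only"
  cls[adj_w$significant & adj_l$significant] <- "alignment_and_shape"
  cls[sing] <- "none"
  levels <- c("alignment_only", "shape_only", "alignment_and_shape", "none")
  pct <- vapply(levels, function(lv) 100 * sum(cls == lv) / n_part, 0)
  tab <- data.frame(
    particle = seq_len(n_part),
    bone = rep(pset$layout$bone, pset$layout$count),
    class = cls,
    p_world = w$p, p_world_adj = adj_w$adjusted,
    p_local = l$p, p_local_adj = adj_l$adjusted,
    stringsAsFactors = FALSE)
  structure(list(comparison = c(group_a, group_b), alpha = alpha,
                 particles = tab, percentages = pct,
                 n_singular = length(sing)),
            class = "particle_map")
}

#' @export
print.particle_map <- function(x, ...) {
  cat(sprintf("<particle_map> %s vs %s: %.1f%% alignment only, %.1f%% shape only, %.2f%% alignment and shape\n",
              x$comparison[1], x$comparison[2],
              x$percentages["alignment_only"], x$percentages["shape_only"],
              x$percentages["alignment_and_shape"]))
  invisible(x)
}

#' Reconstruct the shape at a multiple of a mode's standard deviation
#'
#' mean + sd_multiple * sqrt(eigenvalue) * mode, reshaped to particles, with
#' the per-particle Euclidean displacement from the mean configuration (the
#' surface-distance field displayed along a mode).
#'
#' @param model a [pca_fit()] result.
#' @param mode mode index (within the fitted modes).
#' @param sd_multiple multiple of the mode SD, in \[-3, 3\].
#' @return list with `configuration` (p x 3), `mean_configuration`,
#'   `distance` (per-particle, same units as the input frame).
#' @export
reconstruct_mode_shape <- function(model, mode, sd_multiple) {
  stopifnot(inherits(model, "shape_model"))
  if (mode < 1L || mode > length(model$eigenvalues))
    stopf("mode %d out of range (1..%d)", mode, length(model$eigenvalues))
  if (abs(sd_multiple) > 3) stopf("|sd_multiple| must be <= 3")
  v <- model$mean + sd_multiple * sqrt(model$eigenvalues[mode]) *
    model$modes[, mode]
  cfg <- unflatten_particles(v)
  mean_cfg <- unflatten_particles(model$mean)
  list(configuration = cfg, mean_configuration = mean_cfg,
       distance = sqrt(rowSums((cfg - mean_cfg)^2)))
}

#' Per-mode group statistics for retained modes
#'
#' For each retained mode: per-group KS normality of the scores, one-way
#' ANOVA with Tukey post hoc, and eta-squared with its benchmark label.
#'
#' @param model a [pca_fit()] result (with `groups` attached or given).
#' @param groups group label per subject.
#' @param n_modes number of modes to test (default the retained count).
#' @return list of per-mode results plus a summary data.frame.
#' @export
mode_group_stats <- function(model, groups = model$groups,
                             n_modes = model$retained) {
  if (is.null(groups) || all(is.na(groups))) stopf("group labels required")
  if (is.na(n_modes)) stopf("retained mode count not set; run parallel_analysis()")
  n_modes <- min(n_modes, length(model$eigenvalues))
  gl <- unique(groups)
  per_mode <- lapply(seq_len(n_modes), function(m) {
    sc <- model$scores[, m]
    gs <- lapply(gl, function(g) sc[groups == g])
    names(gs) <- gl
    ks <- vapply(gs, function(x)
      if (length(x) >= 5L && stats::sd(x) > 0) ks_normality(x)$p
      else NA_real_, 0)
    a <- anova_oneway(gs)
    tk <- tukey_hsd(gs)
    e <- eta_squared(a$ss_between, a$ss_total)
    list(mode = m, ks_p = ks, anova = a, tukey = tk, eta = e)
  })
  summary <- do.call(rbind, lapply(per_mode, function(r) {
    data.frame(mode = r$mode,
               percent_variance = model$percent_variance[r$mode],
               f = r$anova$f, p = r$anova$p,
               eta_sq = r$eta$eta_sq, eta_label = r$eta$label,
               min_ks_p = suppressWarnings(min(r$ks_p, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  list(per_mode = per_mode, summary = summary)
}
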