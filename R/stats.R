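# Center-to-pole stiffness-ratio statistics and standard group
# comparisons.

#' Construct a group sample
#'
#' Per-chamber stiffness summaries for one genotype and region; replicates
#' are egg chambers from different flies.
#'
#' @param values numeric vector of per-chamber summaries (kPa), all > 0.
#' @return object of class `group_sample`.
#' @export
group_sample <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 1, all(is.finite(values)), all(values > 0))
  structure(list(values = values, n = length(values)),
            class = "group_sample")
}

#' @keywords internal
as_group <- function(x) {
  if (inherits(x, "group_sample")) x else group_sample(x)
}

#' @keywords internal
sem_of <- function(g) stats::sd(g$values) / sqrt(g$n)

#' Center-to-pole stiffness ratio with propagated SEM
#'
#' R = mean(center) / mean(pole); the standard error of the ratio follows
#' from first-order error propagation,
#' sem_R = R * sqrt((SEM_c/mean_c)^2 + (SEM_p/mean_p)^2), with
#' SEM = sd/sqrt(n) in each group.
#'
#' @param center,pole [group_sample]s (or numeric vectors) of per-chamber
#'   stiffness summaries; each needs n >= 2 for a SEM.
#' @return list with `ratio` and `sem`.
#' @export
ratio_sem <- function(center, pole) {
  center <- as_group(center); pole <- as_group(pole)
  if (center$n < 2 || pole$n < 2) stop("need n >= 2 in both groups")
  mc <- mean(center$values); mp <- mean(pole$values)
  if (mp <= 0) stop("pole mean must be positive")
  R <- mc / mp
  sem <- R * sqrt((sem_of(center) / mc)^2 + (sem_of(pole) / mp)^2)
  list(ratio = R, sem = sem)
}

#' Welch-Satterthwaite effective degrees of freedom for the ratio
#'
#' With the two relative variance components of the ratio,
#' a_c = (SEM_c/mean_c)^2 and a_p = (SEM_p/mean_p)^2,
#' nu_eff = (a_c + a_p)^2 / (a_c^2/(n_c - 1) + a_p^2/(n_p - 1)).
#' For symmetric inputs (a_c = a_p, n_c = n_p = n) this reduces exactly to
#' 2 (n - 1).
#'
#' @param center,pole [group_sample]s (or numeric vectors).
#' @return effective degrees of freedom (non-integer in general).
#' @export
welch_satterthwaite_dof <- function(center, pole) {
  center <- as_group(center); pole <- as_group(pole)
  if (center$n < 2 || pole$n < 2) stop("need n >= 2 in both groups")
  ac <- (sem_of(center) / mean(center$values))^2
  ap <- (sem_of(pole) / mean(pole$values))^2
  (ac + ap)^2 / (ac^2 / (center$n - 1) + ap^2 / (pole$n - 1))
}

#' Center-to-pole stiffness-ratio test
#'
#' Tests whether the mean center-to-pole stiffness ratio differs from 1:
#' T = (R - 1) / sem_R, referred to a two-tailed t distribution with
#' Welch-Satterthwaite effective degrees of freedom.
#'
#' @param center,pole [group_sample]s (or numeric vectors).
#' @return list (class `ratio_test_result`): `ratio`, `sem`, `T`, `dof`,
#'   `p`, `degenerate` (TRUE when sem_R = 0).
#' @export
ratio_test <- function(center, pole) {
  center <- as_group(center); pole <- as_group(pole)
  rs <- ratio_sem(center, pole)
  if (rs$sem == 0) {
    p <- if (rs$ratio == 1) 1 else 0
    return(structure(list(ratio = rs$ratio, sem = 0,
                          T = if (rs$ratio == 1) 0 else Inf,
                          dof = NA_real_, p = p, degenerate = TRUE),
                     class = "ratio_test_result"))
  }
  dof <- welch_satterthwaite_dof(center, pole)
  T <- (rs$ratio - 1) / rs$sem
  p <- 2 * stats::pt(abs(T), dof, lower.tail = FALSE)
  structure(list(ratio = rs$ratio, sem = rs$sem, T = T, dof = dof, p = p,
                 degenerate = FALSE),
            class = "ratio_test_result")
}

#' @export
print.ratio_test_result <- function(x, ...) {
  cat(sprintf(
    "<ratio_test> R = %.4f +/- %.4f (SEM), T = %.3f, dof = %.2f, p = %.4g\n",
    x$ratio, x$sem, x$T, x$dof, x$p))
  invisible(x)
}

#' Standard two-group (or one-sample) comparison
#'
#' Two-sided tests as used for the group comparisons: Welch's unpaired
#' t-test, the Wilcoxon rank sum test (exact enumeration below n = 8 per
#' group, normal approximation without continuity correction otherwise),
#' or a one-sample t-test against zero (used for per-chamber
#' topography-stiffness correlation coefficients).
#'
#' @param x numeric vector or [group_sample].
#' @param y numeric vector or [group_sample]; ignored for
#'   `one_sample_t_zero`.
#' @param method one of `"welch_t"`, `"wilcoxon_rank_sum"`,
#'   `"one_sample_t_zero"`.
#' @return two-sided p value.
#' @export
group_compare <- function(x, y = NULL,
                          method = c("welch_t", "wilcoxon_rank_sum",
                                     "one_sample_t_zero")) {
  method <- match.arg(method)
  xv <- if (inherits(x, "group_sample")) x$values else as.numeric(x)
  yv <- if (inherits(y, "group_sample")) y$values else
    if (!is.null(y)) as.numeric(y) else NULL
  switch(method,
    welch_t = stats::t.test(xv, yv, var.equal = FALSE)$p.value,
    wilcoxon_rank_sum = {
      exact <- min(length(xv), length(yv)) < 8
      stats::wilcox.test(xv, yv, exact = exact, correct = FALSE)$p.value
    },
    one_sample_t_zero = stats::t.test(xv, mu = 0)$p.value
  )
}

#' Monte-Carlo size of the ratio test under a null
#'
#' Draws `n_reps` pairs of lognormal samples with equal means and returns
#' the fraction of two-sided ratio-test p values below `alpha` (the
#' empirical type-I error). Fully vectorized.
#'
#' @param n_reps replicates.
#' @param n per-group sample size.
#' @param cv lognormal coefficient of variation.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return list: `type1` (empirical size), `p` (all p values).
#' @export
ratio_test_calibration <- function(n_reps = 10000, n = 8, cv = 0.2,
                                   alpha = 0.05, seed = 1) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function() matrix(stats::rlnorm(n_reps * n, 0, sdlog), n_reps, n)
  xc <- draw(); xp <- draw()
  mc <- rowMeans(xc); mp <- rowMeans(xp)
  vc <- (rowSums(xc^2) - n * mc^2) / (n - 1)
  vp <- (rowSums(xp^2) - n * mp^2) / (n - 1)
  ac <- vc / n / mc^2
  ap <- vp / n / mp^2
  R <- mc / mp
  sem <- R * sqrt(ac + ap)
  dof <- (ac + ap)^2 / (ac^2 / (n - 1) + ap^2 / (n - 1))
  T <- (R - 1) / sem
  p <- 2 * stats::pt(abs(T), dof, lower.tail = FALSE)
  list(type1 = mean(p < alpha), p = p)
}
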