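#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Shapiro-Wilk test used as the
#' normality diagnostic before repeated-measures ANOVA.
#'
#' @param x numeric sample, 3 <= n <= 5000, not all identical.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("shapiro_wilk: sample size must be in [3, 5000]", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("shapiro_wilk: all values identical", call. = FALSE)
  }
  res <- stats::shapiro.test(x)
  list(W = unname(res$statistic), p = res$p.value)
}

# Orthonormal polynomial-free contrasts for a k-level within factor.
orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

# Sphericity diagnostics from an n x q matrix of orthonormal contrast
# scores: Mauchly's W with its chi-square p, and the Greenhouse-Geisser
# epsilon.
sphericity_from_scores <- function(D) {
  n <- nrow(D)
  q <- ncol(D)
  S <- stats::cov(D)
  tr <- sum(diag(S))
  if (!all(is.finite(S)) || tr <= 0) {
    stop("sphericity: degenerate contrast covariance (no variance); ",
         "check for constant data or too few subjects", call. = FALSE)
  }
  eps <- tr^2 / (q * sum(S * S))
  if (q == 1) {
    return(list(W = 1, p = 1, epsilon = 1))
  }
  detS <- det(S)
  if (detS <= 0) {
    stop("sphericity: rank-deficient contrast covariance; ",
         "you need more subjects than within-factor levels", call. = FALSE)
  }
  W <- detS / (tr / q)^q
  dfc <- q * (q + 1) / 2 - 1
  cf <- 1 - (2 * q^2 + q + 2) / (6 * q * (n - 1))
  chi <- -(n - 1) * cf * log(W)
  list(W = W, p = stats::pchisq(chi, dfc, lower.tail = FALSE), epsilon = eps)
}

#' Mauchly's test of sphericity
#'
#' Tests sphericity of a within-subject factor from the covariance of k-1
#' orthonormal contrasts of the subject-by-level score matrix. With two
#' levels sphericity cannot be violated (W = 1, p = 1).
#'
#' @param scores n x k numeric matrix: one row per subject, one column per
#'   within-factor level.
#' @return List with `W` and `p`.
#' @export
mauchly_test <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 2) stop("mauchly_test: need at least 2 levels", call. = FALSE)
  if (nrow(scores) <= k - 1) {
    stop("mauchly_test: need more subjects than within-factor contrasts",
         call. = FALSE)
  }
  res <- sphericity_from_scores(scores %*% orthonormal_contrasts(k))
  list(W = res$W, p = res$p)
}

#' Greenhouse-Geisser epsilon
#'
#' `epsilon = tr(C)^2 / ((k - 1) * tr(C^2))` for the covariance C of the
#' k-1 orthonormal contrasts; bounded in \[1/(k-1), 1\], and exactly 1 for
#' a 2-level factor. Corrected degrees of freedom are `epsilon * df`.
#'
#' @inheritParams mauchly_test
#' @return Epsilon (scalar).
#' @export
greenhouse_geisser_epsilon <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 2) stop("greenhouse_geisser_epsilon: need at least 2 levels",
                  call. = FALSE)
  if (nrow(scores) <= k - 1) {
    stop("greenhouse_geisser_epsilon: need more subjects than contrasts",
         call. = FALSE)
  }
  sphericity_from_scores(scores %*% orthonormal_contrasts(k))$epsilon
}

#' Two-way repeated-measures ANOVA
#'
#' Full within-subjects decomposition for a complete balanced
#' subject x A x B design with one observation per cell: sums of squares
#' for subjects, both main effects, the interaction, and each effect's
#' subject-interaction error term. Each F uses its own error term
#' (`MS_effect / MS_effect:subject`) and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. For within factors with three or
#' more levels, Mauchly's test and the Greenhouse-Geisser epsilon are
#' computed from the effect's contrast scores, and the Greenhouse-Geisser
#' corrected p is reported (`p_report`) whenever Mauchly's p < `alpha`;
#' two-level effects always have epsilon 1 and no correction.
#'
#' @param data data frame in long format.
#' @param subject,a,b,value column names for the subject id, the first
#'   within factor (e.g. arm condition), the second within factor (e.g.
#'   slope) and the outcome.
#' @param alpha significance level used to trigger the
#'   Greenhouse-Geisser correction. Default 0.05.
#' @return Object of class `rm_anova`: a list with `table` (one row per
#'   effect: `effect`, `df1`, `df2`, `SS`, `SS_err`, `F`, `p`, `pes`,
#'   `epsilon`, `mauchly_W`, `mauchly_p`, `gg_applied`, `p_gg`,
#'   `p_report`), `n` and the factor levels. Degenerate (zero-variance)
#'   data yield `NA` statistics with a `degenerate` flag.
#' @export
rm_anova_2way <- function(data, subject = "subject", a = "arms", b = "slope",
                          value = "value", alpha = 0.05) {
  d <- data.frame(s = factor(data[[subject]]), A = factor(data[[a]]),
                  B = factor(data[[b]]), y = as.numeric(data[[value]]))
  if (anyNA(d$y)) stop("rm_anova_2way: missing values are not supported",
                       call. = FALSE)
  tab <- table(d$s, d$A, d$B)
  if (any(tab != 1)) {
    stop("rm_anova_2way: design must be complete and balanced with one ",
         "value per subject x cell", call. = FALSE)
  }
  n <- nlevels(d$s)
  ka <- nlevels(d$A)
  kb <- nlevels(d$B)
  if (n < 2) stop("rm_anova_2way: need at least 2 subjects", call. = FALSE)

  grand <- mean(d$y)
  m_s <- tapply(d$y, d$s, mean)
  m_a <- tapply(d$y, d$A, mean)
  m_b <- tapply(d$y, d$B, mean)
  m_sa <- tapply(d$y, list(d$s, d$A), mean)
  m_sb <- tapply(d$y, list(d$s, d$B), mean)
  m_ab <- tapply(d$y, list(d$A, d$B), mean)

  ss_a <- n * kb * sum((m_a - grand)^2)
  ss_b <- n * ka * sum((m_b - grand)^2)
  ss_s <- ka * kb * sum((m_s - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, kb)) -
                    outer(rep(1, ka), m_b) + grand)^2)
  ss_as <- kb * sum((m_sa - outer(m_s, rep(1, ka)) -
                     outer(rep(1, n), m_a) + grand)^2)
  ss_bs <- ka * sum((m_sb - outer(m_s, rep(1, kb)) -
                     outer(rep(1, n), m_b) + grand)^2)
  ss_tot <- sum((d$y - grand)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  ss_abs <- max(ss_abs, 0)

  # per-subject score matrices for sphericity diagnostics
  Y_a <- matrix(m_sa, nrow = n)                 # subjects x A levels
  Y_b <- matrix(m_sb, nrow = n)                 # subjects x B levels
  Ma <- orthonormal_contrasts(ka)
  Mb <- orthonormal_contrasts(kb)
  cells <- tapply(d$y, list(d$s, d$A, d$B), mean) # n x ka x kb
  D_ab <- matrix(NA_real_, n, (ka - 1) * (kb - 1))
  for (i in seq_len(n)) {
    D_ab[i, ] <- as.vector(t(Ma) %*% cells[i, , ] %*% Mb)
  }

  effect_row <- function(name, ss, ss_err, df1, df2, scores_D) {
    degenerate <- ss_err <= .Machine$double.eps * max(1, ss_tot)
    Fv <- if (degenerate) NA_real_ else (ss / df1) / (ss_err / df2)
    p <- if (degenerate) NA_real_ else stats::pf(Fv, df1, df2, lower.tail = FALSE)
    pes <- if (ss + ss_err == 0) NA_real_ else ss / (ss + ss_err)
    sph <- if (degenerate) list(W = NA_real_, p = NA_real_, epsilon = NA_real_)
           else tryCatch(sphericity_from_scores(scores_D),
                         error = function(e) list(W = NA_real_, p = NA_real_,
                                                  epsilon = NA_real_))
    if (df1 < 2) { sph$epsilon <- 1; sph$W <- 1; sph$p <- 1 }
    applied <- !degenerate && df1 >= 2 && is.finite(sph$p) && sph$p < alpha
    p_gg <- if (!degenerate && is.finite(sph$epsilon)) {
      stats::pf(Fv, sph$epsilon * df1, sph$epsilon * df2, lower.tail = FALSE)
    } else NA_real_
    data.frame(effect = name, df1 = df1, df2 = df2, SS = ss, SS_err = ss_err,
               F = Fv, p = p, pes = pes, epsilon = sph$epsilon,
               mauchly_W = sph$W, mauchly_p = sph$p, gg_applied = applied,
               p_gg = p_gg,
               p_report = if (applied) p_gg else p,
               degenerate = degenerate)
  }

  tab_out <- rbind(
    effect_row(a, ss_a, ss_as, ka - 1, (ka - 1) * (n - 1), Y_a %*% Ma),
    effect_row(b, ss_b, ss_bs, kb - 1, (kb - 1) * (n - 1), Y_b %*% Mb),
    effect_row(paste0(a, ":", b), ss_ab, ss_abs,
               (ka - 1) * (kb - 1), (ka - 1) * (kb - 1) * (n - 1), D_ab)
  )
  structure(list(table = tab_out, n = n,
                 levels = list(a = levels(d$A), b = levels(d$B)),
                 factors = c(a = a, b = b)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (n = %d subjects)\n", x$n))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-14s F(%g, %g) = %.2f, p = %.4g, pes = %.3f%s\n",
                tb$effect[i], tb$df1[i], tb$df2[i], tb$F[i], tb$p_report[i],
                tb$pes[i],
                if (isTRUE(tb$gg_applied[i]))
                  sprintf(" [GG, eps = %.3f]", tb$epsilon[i]) else ""))
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise post-hoc tests
#'
#' All pairwise paired t-tests between the levels of one within factor on
#' subject-level means collapsed over the other factor (or, with
#' `by_level`, simple-effects tests within each level of the other
#' factor). Corrected p is `min(1, p * n_comparisons)` with the number of
#' comparisons counted within each family.
#'
#' @param data long-format data frame as for [rm_anova_2way()].
#' @param factor_col within factor whose levels are compared (default
#'   `"arms"`).
#' @param other_col the other within factor (default `"slope"`).
#' @param subject,value column names.
#' @param by_level if `TRUE`, run simple-effects comparisons within each
#'   level of `other_col` instead of collapsing.
#' @return Data frame with columns `family`, `level_1`, `level_2`,
#'   `mean_diff`, `t`, `df`, `p`, `p_bonferroni`.
#' @export
bonferroni_pairwise <- function(data, factor_col = "arms", other_col = "slope",
                                subject = "subject", value = "value",
                                by_level = FALSE) {
  d <- data.frame(s = factor(data[[subject]]),
                  f = factor(data[[factor_col]]),
                  g = factor(data[[other_col]]),
                  y = as.numeric(data[[value]]))
  families <- if (by_level) levels(d$g) else "all"
  out <- NULL
  for (fam in families) {
    dd <- if (by_level) d[d$g == fam, ] else d
    m <- tapply(dd$y, list(dd$s, dd$f), mean)
    lev <- colnames(m)
    pairs <- utils::combn(lev, 2)
    n_cmp <- ncol(pairs)
    for (j in seq_len(n_cmp)) {
      x1 <- m[, pairs[1, j]]
      x2 <- m[, pairs[2, j]]
      diffs <- x1 - x2
      if (stats::sd(diffs) == 0) {
        tt <- list(statistic = if (mean(diffs) == 0) NA_real_ else Inf,
                   parameter = length(diffs) - 1,
                   p.value = if (mean(diffs) == 0) 1 else 0)
      } else {
        tt <- stats::t.test(x1, x2, paired = TRUE)
      }
      out <- rbind(out, data.frame(
        family = fam, level_1 = pairs[1, j], level_2 = pairs[2, j],
        mean_diff = mean(diffs), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value,
        p_bonferroni = min(1, tt$p.value * n_cmp)))
    }
  }
  out
}
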