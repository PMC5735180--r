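#' Relative cytotoxicity percentage from photon counts
#'
#' Tumor-cell killing relative to an untreated baseline:
#' `100 * (1 - mean(treated) / mean(untreated))`, with a delta-method standard
#' error combining the per-arm standard errors of the means:
#' `se = 100 * r * sqrt((se_t/m_t)^2 + (se_u/m_u)^2)` where `r` is the mean
#' ratio.
#'
#' @param treated Photon counts of the treated wells (n >= 2 for an SE).
#' @param untreated Photon counts of the untreated wells; mean must be > 0.
#' @return A list with `percent` and `se`.
#' @export
cytotoxicity_percent <- function(treated, untreated) {
  mu <- mean(untreated)
  if (!is.finite(mu) || mu <= 0) {
    stop("untreated mean must be positive", call. = FALSE)
  }
  mt <- mean(treated)
  r <- mt / mu
  se_t <- if (length(treated) > 1) stats::sd(treated) / sqrt(length(treated))
          else 0
  se_u <- if (length(untreated) > 1)
            stats::sd(untreated) / sqrt(length(untreated)) else 0
  rel2 <- (se_u / mu)^2
  if (mt != 0) rel2 <- rel2 + (se_t / mt)^2
  se <- if (mt != 0) 100 * abs(r) * sqrt(rel2) else 100 * se_t / mu
  list(percent = 100 * (1 - r), se = se)
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper over [stats::t.test()] (Welch-Satterthwaite degrees of
#' freedom, two-sided) returning the statistic, df and p-value as plain
#' numbers.  When both groups have zero variance and equal means the test is
#' degenerate and `p = 1` is returned by convention (t = 0).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    stop("both groups are constant with different means; t is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-way ANOVA with Bonferroni-corrected pairwise Welch tests
#'
#' Standard one-way analysis of variance (equal-variance F test via
#' [stats::aov()]) across the groups, followed by pairwise Welch t-tests whose
#' p-values are Bonferroni-adjusted (`p * m`, capped at 1) to control the
#' family-wise error rate.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of group labels, same length.
#' @param m_comparisons Number of comparisons `m` used by the Bonferroni
#'   correction; defaults to the number of pairs actually tested.
#' @return A list with `F`, `df1`, `df2`, `p` and a data.frame `pairwise`
#'   (`group1`, `group2`, `t`, `df`, `p_raw`, `p_adjusted`).
#' @export
one_way_anova_bonferroni <- function(values, groups, m_comparisons = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  n_by <- table(groups)
  if (any(n_by < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  if (all(tapply(values, groups, stats::var) == 0)) {
    stop("all groups have zero within-group variance; F is degenerate",
         call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  pairs <- utils::combn(levels(groups), 2)
  m <- if (is.null(m_comparisons)) ncol(pairs) else m_comparisons
  pw <- apply(pairs, 2, function(p) {
    wt <- welch_t_test(values[groups == p[1]], values[groups == p[2]])
    data.frame(group1 = p[1], group2 = p[2], t = wt$t, df = wt$df,
               p_raw = wt$p, p_adjusted = min(wt$p * m, 1),
               stringsAsFactors = FALSE)
  })
  list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
       p = s[["Pr(>F)"]][1], pairwise = do.call(rbind, pw))
}

#' Pearson product-moment correlation
#'
#' Wrapper over [stats::cor.test()] returning `r` and the p-value from the t
#' transform.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return A list with `r`, `n`, `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = unname(ct$p.value))
}

#' Biodistribution report: group means, errors and pairwise tests
#'
#' Summarises a per-sample biodistribution table (from [quantify_study()]) per
#' organ and timepoint: group means with standard errors (between-animal SE
#' for individually measured samples; the NMR noise-based SE for pooled
#' samples, which contribute a single tube), and pairwise Welch t-tests on
#' apparent cell numbers between groups.  Below-LOD samples are excluded from
#' the tests and annotated; a comparison whose data are all below the LOD is
#' reported as `not testable` rather than raising an error.
#'
#' @param records data.frame from [quantify_study()] (columns `group`,
#'   `timepoint_d`, `organ`, `apparent_cells`, `cells_se`, `percent_id`,
#'   `pooled_n`, `below_lod`).
#' @param alpha Family-wise significance threshold used for the annotation
#'   column.
#' @return A list of class `biodist_report` with data.frames `summary` and
#'   `tests`.
#' @export
biodistribution_report <- function(records, alpha = 0.05) {
  needed <- c("group", "timepoint_d", "organ", "apparent_cells", "cells_se",
              "pooled_n", "below_lod")
  if (!all(needed %in% names(records))) {
    stop("`records` is missing required columns", call. = FALSE)
  }
  key <- interaction(records$organ, records$timepoint_d, records$group,
                     drop = TRUE)
  summary_rows <- lapply(split(records, key), function(d) {
    pooled <- any(d$pooled_n > 1)
    n <- nrow(d)
    mean_cells <- mean(d$apparent_cells)
    se <- if (pooled || n == 1) sqrt(mean(d$cells_se^2))
          else stats::sd(d$apparent_cells) / sqrt(n)
    data.frame(
      organ = d$organ[1], timepoint_d = d$timepoint_d[1], group = d$group[1],
      n = n, mean_cells = mean_cells, se_cells = se,
      mean_percent_id = if ("percent_id" %in% names(d))
        mean(d$percent_id) else NA_real_,
      pooled = pooled, n_below_lod = sum(d$below_lod),
      stringsAsFactors = FALSE
    )
  })
  summ <- do.call(rbind, summary_rows)
  rownames(summ) <- NULL
  summ <- summ[order(summ$organ, summ$timepoint_d, summ$group), ]

  groups <- unique(records$group)
  tests <- list()
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    for (org in unique(records$organ)) {
      for (tp in unique(records$timepoint_d)) {
        d <- records[records$organ == org & records$timepoint_d == tp, ]
        if (!nrow(d)) next
        for (j in seq_len(ncol(pairs))) {
          a <- d[d$group == pairs[1, j] & !d$below_lod, "apparent_cells"]
          b <- d[d$group == pairs[2, j] & !d$below_lod, "apparent_cells"]
          if (length(a) >= 2 && length(b) >= 2 &&
              (stats::var(a) > 0 || stats::var(b) > 0)) {
            wt <- welch_t_test(a, b)
            tests[[length(tests) + 1L]] <- data.frame(
              organ = org, timepoint_d = tp,
              group1 = pairs[1, j], group2 = pairs[2, j],
              n1 = length(a), n2 = length(b),
              t = wt$t, df = wt$df, p = wt$p,
              significant = wt$p < alpha, note = "",
              stringsAsFactors = FALSE
            )
          } else {
            tests[[length(tests) + 1L]] <- data.frame(
              organ = org, timepoint_d = tp,
              group1 = pairs[1, j], group2 = pairs[2, j],
              n1 = length(a), n2 = length(b),
              t = NA_real_, df = NA_real_, p = NA_real_,
              significant = NA,
              note = "not testable (below LOD or too few samples)",
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(organ = character(), timepoint_d = numeric(),
               group1 = character(), group2 = character(),
               n1 = integer(), n2 = integer(), t = numeric(), df = numeric(),
               p = numeric(), significant = logical(), note = character())
  structure(list(summary = summ, tests = tests, alpha = alpha),
            class = "biodist_report")
}

#' @export
print.biodist_report <- function(x, ...) {
  cat(sprintf("<biodist_report> %d summary rows, %d pairwise tests (alpha %g)\n",
              nrow(x$summary), nrow(x$tests), x$alpha))
  invisible(x)
}

# format a p-value to 4 significant figures, never printing 0
format_pval <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 1e-12, "< 1e-12", signif(p, 4)))
}

#' Render a biodistribution report as markdown
#'
#' @param report A [biodistribution_report()] result.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
render_report_md <- function(report, path) {
  stopifnot(inherits(report, "biodist_report"))
  lines <- c(
    "# Biodistribution report", "",
    "Apparent labeled-cell numbers per organ (mean +/- SE per group and",
    "timepoint).  Pooled samples carry the NMR noise-based SE; samples below",
    "the limit of detection are counted but excluded from tests.", "",
    "## Group summaries", "",
    "| organ | day | group | n | apparent cells | SE | %ID | pooled | below LOD |",
    "|---|---|---|---|---|---|---|---|---|"
  )
  s <- report$summary
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "| %s | %g | %s | %d | %.3g | %.2g | %s | %s | %d |",
      s$organ[i], s$timepoint_d[i], s$group[i], s$n[i], s$mean_cells[i],
      s$se_cells[i],
      if (is.na(s$mean_percent_id[i])) "" else sprintf("%.2f", s$mean_percent_id[i]),
      if (s$pooled[i]) "yes" else "", s$n_below_lod[i]
    ))
  }
  lines <- c(lines, "", "## Pairwise Welch tests (apparent cells)", "",
             "| organ | day | comparison | t | df | p | |",
             "|---|---|---|---|---|---|---|")
  t <- report$tests
  for (i in seq_len(nrow(t))) {
    lines <- c(lines, sprintf(
      "| %s | %g | %s vs %s | %s | %s | %s | %s |",
      t$organ[i], t$timepoint_d[i], t$group1[i], t$group2[i],
      if (is.na(t$t[i])) "" else sprintf("%.3f", t$t[i]),
      if (is.na(t$df[i])) "" else sprintf("%.2f", t$df[i]),
      format_pval(t$p[i]),
      if (isTRUE(t$significant[i])) "*" else if (nzchar(t$note[i])) t$note[i] else ""
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
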