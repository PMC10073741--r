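# Cohort-level statistics: normality-gated two-group comparison, Spearman
# correlation with interpretation bins, and simple/multiple linear
# regression for predicting TKE. The testing machinery (Shapiro-Wilk,
# Welch t, Mann-Whitney U, OLS) is base R; this layer adds the gating,
# summaries and table structure.

#' Two-group comparison with a normality gate
#'
#' Shapiro-Wilk is applied to each group at alpha = 0.05; if both groups
#' are compatible with normality a Welch (unequal-variance) two-sample
#' t-test is used and groups are summarised as mean +/- sd, otherwise a
#' two-sided Mann-Whitney U test (exact for group sizes <= 20 without
#' ties, normal approximation with tie correction above) with median
#' [q1, q3] summaries. Constant groups, for which normality is undefined,
#' fall to Mann-Whitney.
#'
#' @param x,y Numeric samples for the two groups (n >= 3 each).
#' @param alpha Normality-gate significance level.
#' @return List of class `GroupComparisonResult`: `test_used` (`"t"` or
#'   `"mann_whitney"`), `statistic`, `p_value`, `summary_x`, `summary_y`
#'   (named vectors matching the test family), `normal` (gate outcome).
#' @export
compareGroups <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) stop("both groups need n >= 3")
  swp <- function(v) {
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  px <- swp(x); py <- swp(y)
  normal <- !is.na(px) && !is.na(py) && px > alpha && py > alpha
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    res <- list(test_used = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value,
                summary_x = c(mean = mean(x), sd = stats::sd(x)),
                summary_y = c(mean = mean(y), sd = stats::sd(y)),
                normal = TRUE)
  } else {
    exact <- max(length(x), length(y)) <= 20L
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    qx <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    qy <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
    res <- list(test_used = "mann_whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value,
                summary_x = c(median = qx[2], q1 = qx[1], q3 = qx[3]),
                summary_y = c(median = qy[2], q1 = qy[1], q3 = qy[3]),
                normal = FALSE)
  }
  structure(res, class = "GroupComparisonResult")
}

#' Interpretation label for a Spearman coefficient
#'
#' Bins on `|rho|`, left-closed: `[0, 0.2)` very weak, `[0.2, 0.4)` weak,
#' `[0.4, 0.6)` moderate, `[0.6, 0.8)` strong, `[0.8, 1]` very strong.
#'
#' @param rho Correlation coefficient in `[-1, 1]`.
#' @return One of the five labels.
#' @export
interpretRho <- function(rho) {
  a <- abs(rho)
  if (is.na(a) || a > 1 + 1e-12) stop("rho must lie in [-1, 1]")
  labs <- c("very weak", "weak", "moderate", "strong", "very strong")
  labs[min(findInterval(a, c(0, 0.2, 0.4, 0.6, 0.8)), 5L)]
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged). The
#' p-value uses the exact permutation distribution for n <= 10 without
#' ties and the t approximation `t = rho * sqrt((n-2) / (1-rho^2))` on
#' n - 2 degrees of freedom otherwise.
#'
#' @param x,y Equal-length numeric vectors, n >= 4.
#' @return List of class `CorrelationResult`: `rho`, `p_value`, `n`,
#'   `interpretation`.
#' @export
spearmanCorrelation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L || length(y) != n) stop("need equal-length vectors with n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Spearman rho is undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 10L && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = min(p, 1), n = n,
                 interpretation = interpretRho(rho)),
            class = "CorrelationResult")
}

#' Simple and multiple linear regressions predicting TKE
#'
#' Fits, on the requested subset of a cohort table and region, ordinary
#' least squares with intercept for (i) `TKE ~ Helicity`, (ii)
#' `TKE ~ Velocity` and (iii) `TKE ~ Helicity + Velocity`, with
#' coefficient p-values from the t distribution on residual degrees of
#' freedom.
#'
#' @param table Cohort table (see [buildCohortTable()]): columns `group`,
#'   `region`, `helicity`, `tke`, `velocity`.
#' @param region Region name.
#' @param subset `"Young"`, `"Old"` or `"Young+Old"`.
#' @return Named list of three `RegressionResult` lists
#'   (`simple_helicity`, `simple_velocity`, `multiple`), each with
#'   `model`, `coefficients` (estimate, p_value per term), `r_squared`,
#'   `n`.
#' @export
fitTkeRegressions <- function(table, region, subset = "Young+Old") {
  rows <- table$region == region &
    (subset == "Young+Old" | table$group == subset)
  d <- table[rows, c("helicity", "velocity", "tke")]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 4L) stop("subset has fewer than 4 rows")
  if (abs(stats::cor(d$helicity, d$velocity)) > 1 - 1e-12) {
    collinear <- TRUE
  } else {
    collinear <- FALSE
  }
  wrap <- function(fit, label) {
    sm <- summary(fit)
    co <- sm$coefficients
    structure(list(model = label,
                   coefficients = data.frame(term = rownames(co),
                                             estimate = co[, 1],
                                             p_value = co[, 4],
                                             row.names = NULL),
                   r_squared = sm$r.squared, n = nrow(d)),
              class = "RegressionResult")
  }
  out <- list(
    simple_helicity = wrap(stats::lm(tke ~ helicity, data = d), "simple_helicity"),
    simple_velocity = wrap(stats::lm(tke ~ velocity, data = d), "simple_velocity")
  )
  if (collinear) {
    stop("helicity and velocity are perfectly collinear: multiple model is unidentifiable")
  }
  out$multiple <- wrap(stats::lm(tke ~ helicity + velocity, data = d), "multiple")
  out
}

# The pairings reported in the correlation table, in presentation order.
correlationPairs <- function() {
  list(
    c("tortuosity", "helicity"), c("tortuosity", "tke"),
    c("tortuosity", "velocity"), c("tortuosity", "reynolds"),
    c("tortuosity", "diameter_mm"),
    c("helicity", "tke"), c("helicity", "velocity"),
    c("helicity", "reynolds"), c("helicity", "diameter_mm"),
    c("tke", "velocity"), c("tke", "reynolds"),
    c("velocity", "diameter_mm"), c("reynolds", "diameter_mm")
  )
}

#' Correlation matrix of the studied parameters for one region
#'
#' Spearman correlations for the thirteen reported parameter pairings
#' (tortuosity, helicity, TKE, velocity, Reynolds number and diameter),
#' in presentation order.
#'
#' @param table Cohort table.
#' @param region Region name (including `"Whole"`).
#' @return data.frame with columns `parameter_a`, `parameter_b`, `rho`,
#'   `p_value`, `n`, `interpretation`.
#' @export
correlationMatrix <- function(table, region) {
  d <- table[table$region == region, ]
  rows <- lapply(correlationPairs(), function(pr) {
    r <- spearmanCorrelation(d[[pr[1]]], d[[pr[2]]])
    data.frame(parameter_a = pr[1], parameter_b = pr[2], rho = r$rho,
               p_value = r$p_value, n = r$n,
               interpretation = r$interpretation, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-summary table for a cohort
#'
#' For every metric and region: the gated two-group comparison with its
#' test, p-value and per-group summaries (Table-2-style layout).
#'
#' @param table Cohort table.
#' @param metrics Metric columns to compare.
#' @return data.frame, one row per metric x region.
#' @export
summarizeCohort <- function(table,
                            metrics = c("tortuosity", "diameter_mm",
                                        "helicity", "tke", "velocity",
                                        "reynolds")) {
  regions <- unique(table$region)
  rows <- list()
  for (m in metrics) {
    for (rg in regions) {
      d <- table[table$region == rg, ]
      cmp <- compareGroups(d[[m]][d$group == "Young"],
                           d[[m]][d$group == "Old"])
      fmt <- function(s) {
        if ("mean" %in% names(s)) sprintf("%.3g +/- %.2g", s["mean"], s["sd"])
        else sprintf("%.3g [%.3g, %.3g]", s["median"], s["q1"], s["q3"])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = m, region = rg, test = cmp$test_used,
        young = fmt(cmp$summary_x), old = fmt(cmp$summary_y),
        young_mean = mean(d[[m]][d$group == "Young"], na.rm = TRUE),
        old_mean = mean(d[[m]][d$group == "Old"], na.rm = TRUE),
        p_value = cmp$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
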