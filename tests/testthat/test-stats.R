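# Cohort statistics: the normality gate, Spearman correlation with
# interpretation bins, TKE regressions, and the correlation table. Brute
# force enumeration oracles live in helper-oracles.R.

test_that("identical groups compare as indistinguishable", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.9)
  res <- compareGroups(x, x)
  expect_gt(res$p_value, 0.95)
  expect_equal(res$summary_x, res$summary_y)
})

test_that("group comparison matches brute-force rank enumeration", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- compareGroups(x, y)
  # n = 3 per group: the gate cannot reject normality, Welch t is used;
  # force the rank test for the enumeration cross-check
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
  expect_equal(wt$p.value, bruteMannWhitneyP(x, y))
  expect_equal(bruteMannWhitneyP(x, y), 2 / 20)  # 2 of C(6,3) assignments as extreme
  set.seed(8)
  for (rep in 1:5) {
    a <- rnorm(6); b <- rnorm(7, 0.5)
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    expect_equal(wt$p.value, bruteMannWhitneyP(a, b), tolerance = 1e-12)
  }
})

test_that("the normality gate selects the test family and summaries", {
  set.seed(21)
  a <- rnorm(20); b <- rnorm(20, 0.3)
  res <- compareGroups(a, b)
  expect_equal(res$test_used, "t")
  expect_named(res$summary_x, c("mean", "sd"))
  skewed <- exp(rnorm(20, 0, 1.5))
  res2 <- compareGroups(skewed, b)
  expect_equal(res2$test_used, "mann_whitney")
  expect_named(res2$summary_x, c("median", "q1", "q3"))
  # constant data: normality undefined -> rank test
  res3 <- compareGroups(rep(1, 5), b[1:5])
  expect_equal(res3$test_used, "mann_whitney")
})

test_that("Spearman rho matches the rank-formula oracle and handles monotone limits", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearmanCorrelation(x, x^3)$rho, 1)
  expect_equal(spearmanCorrelation(x, x^3)$interpretation, "very strong")
  expect_equal(spearmanCorrelation(x, rev(x)^3)$rho, -1)
  set.seed(14)
  for (rep in 1:5) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(spearmanCorrelation(a, b)$rho, bruteSpearmanRho(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearmanCorrelation(rep(1, 5), x), "variance")
  expect_error(spearmanCorrelation(1:3, 3:1), "n >= 4")
})

test_that("exact Spearman p-values match permutation enumeration at small n", {
  set.seed(15)
  for (rep in 1:3) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(spearmanCorrelation(a, b)$p_value, bruteSpearmanP(a, b),
                 tolerance = 1e-10)
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(16)
  a <- rnorm(15); b <- rnorm(15)
  r0 <- spearmanCorrelation(a, b)$rho
  expect_equal(spearmanCorrelation(exp(a), b)$rho, r0)
  expect_equal(spearmanCorrelation(a, b^3)$rho, r0)
  expect_equal(spearmanCorrelation(rank(a), atan(b))$rho, r0)
})

test_that("interpretation bins partition [0, 1] left-closed", {
  expect_equal(interpretRho(0.86), "very strong")
  expect_equal(interpretRho(-0.45), "moderate")
  expect_equal(interpretRho(0), "very weak")
  expect_equal(interpretRho(0.4), "moderate")     # boundary goes up
  expect_equal(interpretRho(0.2), "weak")
  expect_equal(interpretRho(0.8), "very strong")
  expect_equal(interpretRho(1), "very strong")
  expect_equal(interpretRho(-1), "very strong")
  # every rho maps to exactly one of the five labels
  labs <- vapply(seq(-1, 1, by = 0.01), interpretRho, character(1))
  expect_true(all(labs %in% c("very weak", "weak", "moderate", "strong",
                              "very strong")))
})

test_that("TKE regressions recover exact linear data and the normal equations", {
  tab <- data.frame(group = "Young", region = "Whole",
                    helicity = c(0.2, 0.3, 0.25, 0.4, 0.5, 0.35, 0.6, 0.45),
                    velocity = c(1.0, 0.9, 1.2, 0.8, 0.7, 1.1, 0.6, 0.95))
  tab$tke <- 2 + 3 * tab$velocity
  fits <- suppressWarnings(fitTkeRegressions(tab, "Whole", "Young"))
  expect_equal(fits$simple_velocity$coefficients$estimate, c(2, 3),
               tolerance = 1e-10)
  expect_equal(fits$simple_velocity$r_squared, 1, tolerance = 1e-10)

  set.seed(30)
  tab$tke <- 5 - 10 * tab$helicity + 8 * tab$velocity + rnorm(8, 0, 0.5)
  fits <- fitTkeRegressions(tab, "Whole", "Young")
  expect_equal(fits$simple_helicity$coefficients$estimate,
               unname(bruteOlsCoef(tab$helicity, tab$tke)), tolerance = 1e-10)
  expect_equal(fits$multiple$coefficients$estimate,
               unname(bruteOlsCoef(cbind(tab$helicity, tab$velocity), tab$tke)),
               tolerance = 1e-10)
  # OLS residuals are orthogonal to each predictor
  co <- fits$multiple$coefficients$estimate
  resid <- tab$tke - co[1] - co[2] * tab$helicity - co[3] * tab$velocity
  expect_lt(abs(sum(resid * tab$helicity)), 1e-9)
  expect_lt(abs(sum(resid * tab$velocity)), 1e-9)

  tab$velocity <- 2 * tab$helicity + 1           # perfectly collinear
  expect_error(fitTkeRegressions(tab, "Whole", "Young"), "collinear")
})

test_that("the correlation table covers the reported pairings in order", {
  set.seed(31)
  n <- 12
  tab <- data.frame(group = rep(c("Young", "Old"), each = n / 2),
                    region = "Whole",
                    tortuosity = rnorm(n, 80, 20))
  tab$helicity <- 0.2 + 0.002 * tab$tortuosity + rnorm(n, 0, 0.01)
  tab$velocity <- rnorm(n, 0.7, 0.1)
  tab$tke <- 40 * tab$velocity + rnorm(n, 0, 2)
  tab$diameter_mm <- rnorm(n, 20, 2)
  tab$reynolds <- computeReynolds(tab$velocity, tab$diameter_mm)
  cm <- correlationMatrix(tab, "Whole")
  expect_equal(nrow(cm), 13L)
  expect_equal(cm$parameter_a[1], "tortuosity")
  expect_equal(cm$parameter_b[1], "helicity")
  expect_gt(cm$rho[1], 0.8)                       # built-in coupling
  expect_gt(cm$rho[cm$parameter_a == "tke" & cm$parameter_b == "velocity"], 0.8)
  # self-pairing sanity through the same estimator
  expect_equal(spearmanCorrelation(tab$tke, tab$tke)$rho, 1)
})

test_that("synthetic cohorts separate tortuosity between groups with power", {
  # ground-truth whole-aorta tortuosity proxies straight from the sampler:
  # significance in >= 90% of master seeds at n = 10/10
  hits <- 0L
  for (s in 1:20) {
    tt <- generateCohort(cohortSpec(seed = as.integer(400 + s)),
                         generate = FALSE)$truthTable
    res <- compareGroups(tt$asc_angle[tt$group == "Young"],
                         tt$asc_angle[tt$group == "Old"])
    hits <- hits + (res$p_value < 0.05)
  }
  expect_gte(hits, 18L)
})
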