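test_that("Lilliefors: statistic matches the reference implementation, degenerate input errors", {
  expect_error(lilliefors_test(rep(2, 10)), class = "ssmpca_degeneracy_error")

  skip_if_not_installed("nortest")
  set.seed(51)
  for (rep in 1:5) {
    x <- rnorm(25) + rexp(25)
    ours <- lilliefors_test(x, n_mc = 100, seed = 1)
    ref <- nortest::lillie.test(x)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("Lilliefors Monte-Carlo p is calibrated under normality and powerful against bimodality", {
  set.seed(52)
  rejections <- 0
  for (rep in 1:1000) {
    x <- rnorm(20)
    if (lilliefors_test(x, n_mc = 2000)$p_value < 0.05)
      rejections <- rejections + 1
  }
  expect_gt(rejections / 1000, 0.03)
  expect_lt(rejections / 1000, 0.07)

  power <- 0
  for (rep in 1:200) {
    x <- c(rnorm(25, -5), rnorm(25, 5))
    if (lilliefors_test(x, n_mc = 500)$p_value < 0.05) power <- power + 1
  }
  expect_gte(power / 200, 0.95)

  # seeded: identical p for identical seed
  x <- rnorm(15)
  expect_identical(lilliefors_test(x, n_mc = 500, seed = 3)$p_value,
                   lilliefors_test(x, n_mc = 500, seed = 3)$p_value)
})

test_that("Levene: zero statistic on within-group constants, decision agrees with exact permutation", {
  r0 <- levene_test(list(c(3, 3, 3), c(7, 7, 7, 7)))
  expect_equal(r0$statistic, 0)

  g1 <- c(1, 2, 3); g2 <- c(10, 20, 30)
  obs <- levene_test(list(g1, g2))
  # exact permutation oracle: all 20 assignments of 6 values to groups of 3
  y <- c(g1, g2)
  combs <- combn(6, 3)
  stat_of <- function(a, b) {
    z <- c(abs(a - mean(a)), abs(b - mean(b)))
    g <- factor(rep(1:2, c(length(a), length(b))))
    anova(lm(z ~ g))[1, "F value"]
  }
  perm_stats <- apply(combs, 2, function(ix) stat_of(y[ix], y[-ix]))
  p_perm <- mean(perm_stats >= obs$statistic - 1e-12)
  expect_identical(obs$p_value < 0.05, p_perm < 0.05)

  # permuting subjects within their groups leaves the statistic unchanged
  r1 <- levene_test(list(g1[c(3, 1, 2)], g2[c(2, 3, 1)]))
  expect_equal(r1$statistic, obs$statistic, tolerance = 1e-12)

  expect_error(levene_test(list(1, c(2, 3))),
               class = "ssmpca_validation_error")
})

test_that("one-way ANOVA: F equals the squared pooled t for two groups, location-invariant", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- oneway_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$statistic, 13.5, tolerance = 1e-2)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)

  res2 <- oneway_anova(list(a + 100, b + 100))
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-8)

  expect_error(oneway_anova(list(c(1, 1), c(2, 2))),
               class = "ssmpca_degeneracy_error")
})

test_that("one-way ANOVA type-I error is calibrated at the nominal level", {
  set.seed(53)
  rejections <- 0
  for (rep in 1:1000) {
    g <- lapply(1:3, function(i) rnorm(10))
    if (oneway_anova(g)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / 1000, 0.03)
  expect_lt(rejections / 1000, 0.07)
})

test_that("Kruskal-Wallis: hand-computed H, rank invariance, null calibration", {
  # groups [1,2],[3,4],[5,6]: rank means 1.5/3.5/5.5 -> H = 32/7 = 4.571
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 4.571, tolerance = 1e-3)

  # any strictly monotone transform leaves H unchanged
  res2 <- kruskal_wallis(list(exp(c(1, 2)), exp(c(3, 4)), exp(c(5, 6))))
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))),
               class = "ssmpca_degeneracy_error")

  set.seed(54)
  rejections <- 0
  for (rep in 1:500) {
    g <- lapply(1:3, function(i) rnorm(8))
    if (kruskal_wallis(g)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / 500, 0.02)
  expect_lt(rejections / 500, 0.08)
})

test_that("Mann-Whitney: exact enumeration for small n, U symmetries", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-3)

  # identical multisets: U = n_a n_b / 2
  expect_equal(unname(mann_whitney(c(1, 2, 3), c(1, 2, 3))$statistic), 4.5)

  # swapping samples maps U to n_a n_b - U
  set.seed(55)
  a <- rnorm(7); b <- rnorm(9)
  u1 <- mann_whitney(a, b)$statistic
  u2 <- mann_whitney(b, a)$statistic
  expect_equal(unname(u1 + u2), 7 * 9)

  expect_error(mann_whitney(numeric(0), 1),
               class = "ssmpca_validation_error")
})

test_that("Holm adjustment: hand case, monotonicity, simulated FWER control", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)

  set.seed(56)
  p <- runif(10)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj <= 1))
  expect_error(holm_adjust(c(0.5, 1.2)), class = "ssmpca_validation_error")

  # FWER on a 6-pair all-null family
  fw <- 0
  for (rep in 1:2000) {
    if (any(holm_adjust(runif(6)) < 0.05)) fw <- fw + 1
  }
  expect_lte(fw / 2000, 0.07)
})

test_that("Spearman correlation: exact monotone cases, t approximation, calibration", {
  expect_equal(spearman_corr(c(1, 2, 3), c(3, 2, 1))$statistic, -1)
  expect_equal(spearman_corr(1:10, exp(1:10))$statistic, 1)
  expect_error(spearman_corr(c(1, 1, 1), 1:3),
               class = "ssmpca_degeneracy_error")

  set.seed(57)
  x <- rnorm(30); y <- rnorm(30)
  ours <- spearman_corr(x, y)
  ref <- cor.test(x, y, method = "spearman")
  expect_equal(ours$statistic, unname(ref$estimate), tolerance = 1e-12)

  rejections <- 0
  for (rep in 1:1000) {
    if (spearman_corr(rnorm(30), rnorm(30))$p_value < 0.05)
      rejections <- rejections + 1
  }
  expect_gt(rejections / 1000, 0.03)
  expect_lt(rejections / 1000, 0.07)
})

test_that("compare_groups gates to the parametric or nonparametric branch", {
  set.seed(58)
  tab <- data.frame(group = rep(c("A", "B", "C"), each = 15),
                    z_score = rnorm(45) + rep(c(0, 1, 2), each = 15))
  cmp <- compare_groups(tab, n_mc = 500, seed = 58)
  expect_identical(cmp$branch, "parametric")
  expect_identical(cmp$omnibus$test, "one-way ANOVA")
  expect_true(cmp$omnibus$reject)
  expect_equal(nrow(cmp$posthoc), 3)

  # gross variance heterogeneity forces the nonparametric branch
  tab2 <- tab
  tab2$z_score[tab2$group == "C"] <- rnorm(15, sd = 40)
  cmp2 <- compare_groups(tab2, n_mc = 500, seed = 58)
  expect_identical(cmp2$branch, "nonparametric")
  expect_identical(cmp2$omnibus$test, "Kruskal-Wallis")

  # two groups: exactly one post-hoc pair
  tab3 <- tab[tab$group != "C", ]
  cmp3 <- compare_groups(tab3, n_mc = 500, seed = 58)
  expect_equal(nrow(cmp3$posthoc), 1)

  expect_error(compare_groups(tab[tab$group == "A", ]),
               class = "ssmpca_validation_error")
})

test_that("chlorpromazine equivalents are the ratio-weighted dose sum", {
  tab <- data.frame(drug = c("a", "b"), multiplier = c(2, 0.5),
                    source = "x")
  expect_equal(cpz_equivalent(data.frame(drug = "a", dose_mg = 300), tab), 600)
  expect_equal(cpz_equivalent(data.frame(drug = character(0),
                                         dose_mg = numeric(0)), tab), 0)
  expect_equal(cpz_equivalent(
    data.frame(drug = c("b", "a"), dose_mg = c(400, 100)), tab),
    400 * 0.5 + 100 * 2)
  expect_error(cpz_equivalent(data.frame(drug = "zzz", dose_mg = 1), tab),
               "zzz", class = "ssmpca_lookup_error")

  f <- system.file("extdata", "cpz_ratios_example.csv", package = "ssmpca")
  rt <- read_ratio_table(f)
  expect_true(all(c("drug", "multiplier", "source") %in% names(rt)))
  expect_equal(cpz_equivalent(
    data.frame(drug = "chlorpromazine", dose_mg = 150), rt), 150)
})
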