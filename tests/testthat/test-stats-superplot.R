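spTable <- function(...) {
  # build a superplot table from condition -> experiment -> values
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(condition = r$cond, experiment = r$exp,
               cell = seq_along(r$v), value = r$v)))
}

test_that("superplot aggregation follows the experiment-mean convention", {
  tab <- spTable(list(cond = "a", exp = "e1", v = c(0.2, 0.4, 0.6)))
  out <- aggregateSuperplot(tab, "experiment")
  expect_equal(out$mean, 0.4)
  expect_false(out$sd_defined)  # single experiment: SD undefined
  expect_true(is.na(out$sd))
  # equal cell counts: experiment-level mean equals the per-cell mean
  tab2 <- spTable(list(cond = "a", exp = "e1", v = c(0.1, 0.3)),
                  list(cond = "a", exp = "e2", v = c(0.5, 0.7)))
  expect_equal(aggregateSuperplot(tab2, "experiment")$mean,
               aggregateSuperplot(tab2, "cell")$mean)
  # unequal counts: the two levels weight experiments differently
  tab3 <- spTable(list(cond = "a", exp = "e1", v = c(0, 0)),
                  list(cond = "a", exp = "e2", v = c(1, 1, 1, 1)))
  expect_equal(aggregateSuperplot(tab3, "experiment")$mean, 0.5)
  expect_equal(aggregateSuperplot(tab3, "cell")$mean, 2 / 3)
})

test_that("experiment aggregation is invariant to cell order", {
  set.seed(9)
  tab <- spTable(list(cond = "a", exp = "e1", v = runif(7)),
                 list(cond = "a", exp = "e2", v = runif(5)))
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(aggregateSuperplot(tab, "experiment")$mean,
               aggregateSuperplot(shuf, "experiment")$mean)
})

test_that("Student's t matches the pooled-variance formula", {
  out <- studentsT(c(1, 2, 3), c(4, 5, 6))
  # pooled s^2 = 1, se = sqrt(2/3), t = -3/se
  expect_equal(out$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(out$df, 4)
  swapped <- studentsT(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$statistic, -out$statistic)
  expect_equal(swapped$p, out$p)
  ident <- studentsT(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
  expect_error(studentsT(c(1, 1), c(2, 2)), "degenerate")
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  out <- oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(4, 5, 6)))
  expect_equal(out$statistic, 7.0, tolerance = 1e-10)
  expect_equal(out$df, 2)
  expect_equal(out$df2, 6)
  # identical groups
  same <- oneWayAnova(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # degenerate: zero within-group variance, different means
  deg <- oneWayAnova(list(c(1, 1), c(2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("two-group ANOVA F equals the squared t statistic", {
  set.seed(14)
  for (rep in 1:5) {
    a <- rnorm(6); b <- rnorm(8, 0.5)
    f <- oneWayAnova(list(a, b))$statistic
    t <- studentsT(a, b)$statistic
    expect_equal(f, t^2, tolerance = 1e-10)
  }
})

test_that("ANOVA matches the brute-force oracle on random groups", {
  set.seed(15)
  for (rep in 1:5) {
    g <- lapply(1:4, function(i) rnorm(sample(4:9, 1), mean = i / 4))
    expect_equal(oneWayAnova(g)$statistic, bruteForceAnovaF(g),
                 tolerance = 1e-10)
  }
})

test_that("Tukey HSD controls the family and orders p-values sensibly", {
  set.seed(16)
  g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 20)
  out <- tukeyHsd(g)
  expect_equal(nrow(out), 3)
  shifted <- out[grepl("c", out$pair), ]
  expect_true(all(shifted$adj_p < 1e-4))
  expect_gt(out$adj_p[out$pair == "a vs b"], 0.05)
  # adjusted p >= unadjusted pairwise t p
  praw <- studentsT(g$a, g$b)$p
  expect_gte(out$adj_p[out$pair == "a vs b"], praw)
  # identical groups: all p = 1
  same <- tukeyHsd(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_true(all(same$adj_p == 1))
})

test_that("Tukey HSD agrees with an independent implementation", {
  skip_if_not_installed("multcomp")
  set.seed(17)
  g <- list(a = rnorm(9), b = rnorm(7, 0.8), c = rnorm(8, 1.5))
  out <- tukeyHsd(g)
  v <- unlist(g)
  f <- factor(rep(names(g), lengths(g)))
  fit <- stats::lm(v ~ f)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(f = "Tukey"))
  ref <- summary(glht)$test$pvalues
  expect_equal(sort(out$adj_p), sort(as.numeric(ref)), tolerance = 0.01)
})

test_that("Monte-Carlo Dunnett reduces to the t-test for one treatment", {
  set.seed(18)
  a <- rnorm(10); b <- rnorm(10, 0.6)
  d <- dunnettMC(a, list(b), nMc = 5e4, seed = 3)
  expect_equal(d$adj_p, d$p, tolerance = 0.01)
  # identical treatment: adjusted p near 1
  d0 <- dunnettMC(c(1, 2, 3, 4), list(c(1, 2, 3, 4)), nMc = 2e4, seed = 4)
  expect_gt(d0$adj_p, 0.95)
})

test_that("Monte-Carlo Dunnett is reproducible and respects monotonicity", {
  set.seed(19)
  ctrl <- rnorm(10)
  trts <- list(t1 = rnorm(10, 0.2), t2 = rnorm(10, 1), t3 = rnorm(10, 2.5))
  d1 <- dunnettMC(ctrl, trts, nMc = 2e4, seed = 7)
  d2 <- dunnettMC(ctrl, trts, nMc = 2e4, seed = 7)
  expect_identical(d1, d2)
  expect_true(all(d1$adj_p >= d1$p))
  expect_true(all(d1$adj_p >= 0 & d1$adj_p <= 1))
  # larger shift, smaller adjusted p
  expect_true(d1$adj_p[3] <= d1$adj_p[2])
})

test_that("Monte-Carlo Dunnett agrees with an independent implementation", {
  skip_if_not_installed("multcomp")
  set.seed(20)
  ctrl <- rnorm(10)
  trts <- list(t1 = rnorm(10, 0.9), t2 = rnorm(10, 1.4))
  d <- dunnettMC(ctrl, trts, nMc = 1e5, seed = 8)
  v <- c(ctrl, trts$t1, trts$t2)
  f <- factor(rep(c("ctrl", "t1", "t2"), each = 10),
              levels = c("ctrl", "t1", "t2"))
  fit <- stats::lm(v ~ f)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(f = "Dunnett"))
  ref <- as.numeric(summary(glht)$test$pvalues)
  expect_equal(d$adj_p, ref, tolerance = 0.02)
})

test_that("star coding follows the four-tier scheme", {
  tab <- studentsT(c(1, 2, 3), c(4, 5, 6))
  expect_true(tab$stars %in% c("*", "**", "***", "****"))
  same <- studentsT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$stars, "ns")
})
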