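test_that("gg_epsilon is 1 for two levels and under compound symmetry, bounded otherwise", {
  expect_equal(gg_epsilon(diag(2) + 0.3), 1)
  # compound symmetry: equal variances, equal covariances
  S <- matrix(0.4, 4, 4); diag(S) <- 1
  expect_equal(gg_epsilon(S), 1, tolerance = 1e-12)
  # rank-1 dominant covariance approaches the 1/(k-1) lower bound
  u <- c(1, -0.5, -0.5)
  S1 <- tcrossprod(u) + diag(1e-8, 3)
  expect_equal(gg_epsilon(S1), 0.5, tolerance = 1e-4)
  set.seed(31)
  for (k in 2:5) {
    X <- matrix(stats::rnorm(40 * k), ncol = k) %*%
      matrix(stats::rnorm(k * k), k)
    S <- stats::cov(X)
    e <- gg_epsilon(S)
    expect_gte(e, 1 / (k - 1))
    expect_lte(e, 1)
    # shift invariance: adding a constant to all scores leaves S unchanged
    expect_equal(gg_epsilon(stats::cov(X + 100)), e, tolerance = 1e-9)
  }
  expect_error(gg_epsilon(matrix(1, 2, 3)), "square")
})

test_that("mixed_anova matches aov on balanced designs to 1e-8", {
  set.seed(7)
  for (r in 1:5) {
    d <- make_mixed_table(ng = c(4, 4, 4), k1 = 2, k2 = 3,
                          within_effect = 0.3)
    mine <- mixed_anova(d, "y", "subject", "group", within = c("w1", "w2"))
    a <- summary(stats::aov(y ~ group * w1 * w2 +
                              Error(factor(subject) / (w1 * w2)), data = d))
    ref <- c(group = a[[1]][[1]]["group", "F value"],
             w1 = a[[2]][[1]]["w1", "F value"],
             `group:w1` = a[[2]][[1]]["group:w1", "F value"],
             w2 = a[[3]][[1]]["w2", "F value"],
             `group:w2` = a[[3]][[1]]["group:w2", "F value"],
             `w1:w2` = a[[4]][[1]]["w1:w2", "F value"],
             `group:w1:w2` = a[[4]][[1]]["group:w1:w2", "F value"])
    got <- stats::setNames(mine$F, mine$effect)[names(ref)]
    expect_equal(unname(got), unname(ref), tolerance = 1e-8)
  }
})

test_that("mixed_anova matches the SPSS-style type-III oracle on unbalanced designs", {
  skip_if_not_installed("car")
  set.seed(11)
  for (r in 1:3) {
    ng <- c(5, 3, 4)
    d <- make_mixed_table(ng = ng, k1 = 2, k2 = 3, within_effect = 0.5)
    mine <- mixed_anova(d, "y", "subject", "group", within = c("w1", "w2"))
    N <- sum(ng)
    d$cell <- paste(d$w1, d$w2)
    cells <- as.vector(outer(unique(d$w1), unique(d$w2), paste))
    Y <- matrix(NA_real_, N, length(cells))
    for (j in seq_along(cells)) {
      sub <- d[d$cell == cells[j], ]
      Y[sub$subject, j] <- sub$y
    }
    grp <- factor(rep(c("G1", "G2", "G3"), ng))
    idata <- expand.grid(w1 = factor(unique(d$w1)),
                         w2 = factor(unique(d$w2)))
    mod <- stats::lm(Y ~ grp, contrasts = list(grp = stats::contr.sum))
    s <- summary(car::Anova(mod, idata = idata, idesign = ~ w1 * w2,
                            type = 3),
                 multivariate = FALSE)
    ut <- s$univariate.tests
    map <- c(group = "grp", w1 = "w1", `group:w1` = "grp:w1", w2 = "w2",
             `group:w2` = "grp:w2", `w1:w2` = "w1:w2",
             `group:w1:w2` = "grp:w1:w2")
    for (nm in names(map)) {
      i <- match(nm, mine$effect)
      expect_equal(mine$F[i], unname(ut[map[nm], "F value"]),
                   tolerance = 1e-8, label = paste("F", nm))
      expect_equal(mine$ss_effect[i], unname(ut[map[nm], "Sum Sq"]),
                   tolerance = 1e-8, label = paste("SS", nm))
    }
    pa <- s$pval.adjustments
    expect_equal(mine$epsilon[match("w2", mine$effect)],
                 unname(pa["w2", "GG eps"]), tolerance = 1e-8)
    expect_equal(mine$p[match("w2", mine$effect)],
                 unname(pa["w2", "Pr(>F[GG])"]), tolerance = 1e-8)
  }
})

test_that("sums of squares partition the total on balanced designs", {
  set.seed(19)
  d <- make_mixed_table(ng = c(3, 3, 3), k1 = 2, k2 = 3)
  an <- mixed_anova(d, "y", "subject", "group", within = c("w1", "w2"))
  ss_total <- sum((d$y - mean(d$y))^2)
  # each within stratum's error appears once; the between stratum once
  ss_all <- sum(an$ss_effect) + sum(an$ss_error[!duplicated(an$ss_error)])
  expect_equal(ss_all, ss_total, tolerance = 1e-8)
})

test_that("a two-group design reduces to the squared pooled t statistic", {
  set.seed(23)
  d <- data.frame(subject = 1:6, group = rep(c("A", "B"), each = 3),
                  y = stats::rnorm(6))
  an <- mixed_anova(d, "y", "subject", "group")
  tt <- stats::t.test(y ~ group, data = d, var.equal = TRUE)
  expect_equal(an$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p[1], tt$p.value, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  d <- make_mixed_table(ng = c(3, 3, 3), k1 = 2)
  expect_error(mixed_anova(d[-1, ], "y", "subject", "group", within = "w1"),
               "one observation per cell")
  expect_error(mixed_anova(d, "z", "subject", "group", within = "w1"),
               "column not found")
  d1 <- d; d1$group <- "same"
  expect_error(mixed_anova(d1, "y", "subject", "group", within = "w1"),
               ">= 2 levels")
})

test_that("Bonferroni post-hocs multiply p by the family size and cap at 1", {
  set.seed(29)
  d <- data.frame(subject = 1:12, group = rep(c("A", "B", "C"), each = 4),
                  y = stats::rnorm(12))
  ph <- bonferroni_posthoc(d, "y", "subject", "group", design = "between")
  expect_equal(nrow(ph), 3)
  raw <- stats::t.test(d$y[d$group == "A"], d$y[d$group == "B"],
                       var.equal = TRUE)$p.value
  expect_equal(ph$p_bonferroni[ph$level1 == "A" & ph$level2 == "B"],
               min(1, raw * 3))
  # identical groups -> adjusted p = 1
  d2 <- d; d2$y <- rep(stats::rnorm(4), 3) + 0.001 * stats::rnorm(12)
  d2$y[d2$group != "A"] <- d2$y[d2$group == "A"]
  ph2 <- bonferroni_posthoc(d2, "y", "subject", "group", design = "between")
  expect_true(all(ph2$p_bonferroni == 1))
  expect_error(bonferroni_posthoc(d[d$group == "A", ], "y", "subject",
                                  "group"), ">= 2 levels")
  # hand-computed paired t on a 4-subject toy table
  d3 <- data.frame(subject = rep(1:4, 2),
                   cond = rep(c("c1", "c2"), each = 4),
                   y = c(10, 12, 9, 11, 13, 14, 12, 15))
  ph3 <- bonferroni_posthoc(d3, "y", "subject", "cond", design = "within")
  dif <- c(10, 12, 9, 11) - c(13, 14, 12, 15)
  t_hand <- mean(dif) / (stats::sd(dif) / 2)
  expect_equal(ph3$t, t_hand, tolerance = 1e-12)
  expect_equal(ph3$p_bonferroni,
               min(1, 2 * stats::pt(abs(t_hand), 3, lower.tail = FALSE)))
  expect_equal(ph3$cohens_d, abs(mean(dif)) / stats::sd(dif))
})

test_that("cohens_d follows the documented conventions", {
  expect_equal(cohens_d(5, 2, 10, 5, 2, 10), 0)
  expect_equal(cohens_d(8, 2, 10, 5, 4, 10),
               3 / sqrt((4 + 16) / 2))
  # doubling both sds halves d
  expect_equal(cohens_d(8, 4, 10, 5, 8, 10),
               cohens_d(8, 2, 10, 5, 4, 10) / 2)
  expect_equal(cohens_d(3, 1.5, design = "within"), 2)
  expect_error(cohens_d(1, 0, 5, 2, 1, 5), "> 0")
})

test_that("rt_analysis recovers the behavioral pattern", {
  # noiseless cohort: Novel slower than Standard, Deviant ~ Standard
  tr <- simulate_cohort_rts(n_young = 4, n_middle = 4, n_old = 4,
                            master_seed = 3,
                            task = task_config(n_pairs = 120),
                            rt = rt_model(trial_sd = 0, miss_prob = 0),
                            between_sd_scale = 0)
  ra <- rt_analysis(tr)
  cm <- tapply(ra$cell_means$rt, ra$cell_means$condition, mean)
  expect_gt(cm["Novel"] - cm["Standard"], 20)
  expect_lt(abs(cm["Deviant"] - cm["Standard"]), 5)
  # all-equal RTs -> all F = 0
  tr0 <- tr
  tr0$rt[!is.na(tr0$rt)] <- 500
  ra0 <- rt_analysis(tr0)
  expect_equal(ra0$anova$F, rep(0, 3), tolerance = 1e-20)
})

test_that("the RT group effect is detected with near-certain power at the printed effect size", {
  # Monte-Carlo at the emulated means/SDs: group effect significant at
  # alpha = .05 in (essentially) every replicate
  hits <- 0
  nrep <- 40
  for (r in seq_len(nrep)) {
    tr <- simulate_cohort_rts(master_seed = 100 + r,
                              task = task_config(n_pairs = 150))
    ra <- rt_analysis(tr)
    hits <- hits + (ra$anova$p[ra$anova$effect == "group"] < 0.05)
  }
  expect_gte(hits / nrep, 0.99)
})
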