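anova_ss_oracle <- function(values, groups) {
  # explicit between/within sum-of-squares computation
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  flat <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(flat$F, 0)

  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  got <- one_way_anova(vals, grp)
  orc <- anova_ss_oracle(vals, grp)
  expect_equal(got$F, orc$F, tolerance = 1e-12)
  expect_equal(got$p, orc$p, tolerance = 1e-12)
  expect_identical(got$df_between, 2L)
  expect_identical(got$df_within, 6L)

  # two-group F equals the squared pooled-variance t statistic
  set.seed(2)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  two <- one_way_anova(c(x, y), rep(c("x", "y"), c(10, 12)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(two$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(two$p, tt$p.value, tolerance = 1e-12)

  # invariance to shift; F unchanged under scaling
  v2 <- one_way_anova(vals + 100, grp)
  v3 <- one_way_anova(vals * 7, grp)
  expect_equal(v2$F, got$F, tolerance = 1e-10)
  expect_equal(v3$F, got$F, tolerance = 1e-10)

  expect_error(one_way_anova(1:5, c("a", "a", "a", "a", "b")),
               "at least 2 observations")
  expect_error(one_way_anova(1:5, rep("a", 5)), "2 groups")
})

test_that("association regression matches closed-form least squares", {
  x <- 1:5
  perfect <- glm_assoc(x, 2 * x)
  expect_equal(perfect$coefficient, 2, tolerance = 1e-12)

  expect_error(glm_assoc(rep(1, 10), rnorm(10)), "constant predictor")
  expect_error(glm_assoc(1:2, 1:2), "at least 3")

  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(20); y <- rnorm(20)
    got <- glm_assoc(x, y, measure = "m", outcome = "o", group = "g")
    # normal-equations + standard-error oracle
    beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - beta * mean(x)
    s2 <- sum((y - a - beta * x)^2) / (20 - 2)
    se <- sqrt(s2 / sum((x - mean(x))^2))
    expect_equal(got$coefficient, beta, tolerance = 1e-8)
    expect_equal(got$t, beta / se, tolerance = 1e-8)
    expect_equal(got$p, 2 * stats::pt(abs(beta / se), 18, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

bh_stepup_oracle <- function(p) {
  # literal 1995 step-up definition
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run_min <- 1
  for (i in m:1) {
    run_min <- min(run_min, m / i * p[o[i]])
    adj[o[i]] <- run_min
  }
  adj
}

test_that("BH adjustment matches the literal step-up definition", {
  expect_equal(bh_fdr(0.03)$adjusted, 0.03)
  expect_equal(bh_fdr(rep(0.2, 6))$adjusted, rep(0.2, 6))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4))

  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    res <- bh_fdr(p)
    expect_equal(res$adjusted, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(res$adjusted >= p - 1e-12))
    expect_true(all(res$adjusted <= 1))
    # monotone in the raw p-values
    expect_true(all(diff(res$adjusted[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # adjusted: 0.002, 0.04, 0.0533 (= 0.04 * 4/3), 0.5
  expect_identical(bh_fdr(c(0.0005, 0.02, 0.04, 0.5))$stars,
                   c("***", "**", "*", ""))
})

test_that("synthetic cohorts sit on the simplex and separate when told to", {
  co <- generate_cohort(seed = 4)
  expect_identical(nrow(co), 32L)
  expect_equal(unname(rowSums(co[, paste0("AL", 0:3)])), rep(100, 32),
               tolerance = 1e-9)
  expect_true(all(co$entropy >= 0 & co$entropy <= log(4)))
  expect_true(all(co$n_contacts >= 0 & co$n_contacts <= 10))
  expect_identical(co, generate_cohort(seed = 4))

  expect_error(generate_cohort(sam_means = rbind(c(50, 50, 50, 50),
                                                 c(25, 25, 25, 25),
                                                 c(25, 25, 25, 25))),
               "sum to 100")

  # deterministic group separation beats any alpha at modest n
  sep <- generate_cohort(group_sizes = c(a = 8, b = 8, c = 8),
                         sam_means = rbind(c(80, 10, 5, 5),
                                           c(10, 80, 5, 5),
                                           c(5, 5, 80, 10)),
                         noise_sd = 1e-6, concentration = 5000, seed = 6)
  expect_lt(one_way_anova(sep$AL0, sep$group)$p, 1e-6)
})

test_that("the association grid has Table-style shape and FDR columns", {
  co <- generate_cohort(seed = 12)
  grid <- association_grid(co)
  expect_identical(nrow(grid), 120L)  # 5 measures x 8 outcomes x 3 groups
  expect_true(all(grid$p_adj >= grid$p - 1e-12))
  expect_true(all(grid$p_adj <= 1))
  expect_true(all(grid$stars[grid$p_adj < 0.01] == "***"))
  expect_true(all(grid$stars[grid$p_adj >= 0.1] == ""))

  by_group <- association_grid(co, fdr_family = "group")
  expect_identical(nrow(by_group), 120L)
  one_group <- by_group[by_group$group == "control", ]
  expect_equal(one_group$p_adj, bh_stepup_oracle(one_group$p),
               tolerance = 1e-12)

  tab <- anova_table(co)
  expect_identical(nrow(tab), 15L)  # 5 measures x (overall + 2 pairwise)
  expect_true(all(tab$F >= 0) && all(tab$p >= 0 & tab$p <= 1))
})
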