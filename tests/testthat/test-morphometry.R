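test_that("compare_groups gates on residual normality", {
  set.seed(21)
  normal <- c(rnorm(50, 10), rnorm(50, 12))
  g <- rep(c("a", "b"), each = 50)
  res <- compare_groups(normal, g)
  expect_identical(res$branch, "anova")
  expect_true(res$significant)
  expect_identical(nrow(res$posthoc), 1L)
  expect_lt(res$posthoc$p_value, 0.001)

  heavy <- c(rlnorm(50, 0, 1.5), rlnorm(50, 2, 1.5))
  res2 <- compare_groups(heavy, g)
  expect_identical(res2$branch, "kruskal")

  # identical groups: no significance, no post hoc table
  same <- rep(c(1.0, 1.1, 0.9, 1.05, 0.95), 4)
  res3 <- compare_groups(same, rep(c("a", "b"), each = 10))
  expect_false(res3$significant)
  expect_null(res3$posthoc)
  expect_error(compare_groups(rnorm(5), c("a", "a", "a", "b", "b")),
               "insufficient")
})

test_that("branch selection tracks the distribution shape", {
  set.seed(22)
  kw <- mean(vapply(1:100, function(i) {
    x <- c(rlnorm(50, 0, 1.2), rlnorm(50, 0, 1.2))
    compare_groups(x, rep(c("a", "b"), each = 50))$branch == "kruskal"
  }, logical(1L)))
  expect_gte(kw, 0.9)
})

test_that("Poisson stack-count model matches its closed forms", {
  # intercept-only fit equals the log sample mean
  g <- simulate_grana_dataset(200, c(WT = 4.57), c(WT = 500), seed = 9L)
  fit <- fit_stack_count_model(g)
  expect_equal(fit$coefficients$estimate[1L], log(mean(g$n_layers)),
               tolerance = 1e-10)
  expect_identical(fit$family, "poisson_log")

  # two genotypes: the genotype coefficient is the log rate ratio
  g2 <- simulate_grana_dataset(500, c(WT = 4.57, mut = 3.75),
                               c(WT = 500, mut = 356), seed = 10L)
  fit2 <- fit_stack_count_model(g2)
  co <- fit2$coefficients
  expect_identical(nrow(co), 2L)
  means <- tapply(g2$n_layers, g2$genotype, mean)
  expect_equal(co$estimate[2L], log(means[["mut"]] / means[["WT"]]),
               tolerance = 1e-8)
  expect_true(all(co$std_error > 0))
  expect_error(fit_stack_count_model(
    data.frame(genotype = "a", n_layers = c(0, 1, 2))), "domain")
})

test_that("genotype x covariate interaction terms are fitted on demand", {
  set.seed(23)
  n <- 150
  d <- data.frame(genotype = rep(c("WT", "mut"), each = n),
                  grana_count = rep(1:5, 2 * n / 5))
  mu <- exp(1.4 - 0.1 * d$grana_count -
              0.15 * (d$genotype == "mut") * d$grana_count)
  d$n_layers <- 1L + rpois(2 * n, mu)
  fit <- fit_stack_count_model(d, covariate = "grana_count")
  expect_identical(nrow(fit$coefficients), 4L)
  expect_true(any(grepl(":", fit$coefficients$term)))
})

test_that("width model reports the genotype contrast exactly", {
  d <- data.frame(genotype = rep(c("WT", "mut"), each = 5),
                  width_nm = rep(c(500, 356), each = 5))
  fit <- fit_width_model(d)
  expect_equal(fit$coefficients$estimate[2L], -144)
  same <- data.frame(genotype = rep(c("WT", "mut"), each = 5),
                     width_nm = rep(c(400, 420, 380, 410, 390), 2))
  expect_equal(fit_width_model(same)$coefficients$estimate[2L], 0,
               tolerance = 1e-12)
  expect_error(fit_width_model(
    data.frame(genotype = rep(c("a", "b"), 3), width_nm = rep(1, 6))),
    "degenerate")
})

test_that("a -144 nm width effect is recovered from noisy data", {
  set.seed(24)
  est <- vapply(1:100, function(i) {
    d <- simulate_grana_dataset(160, c(WT = 4.57, mut = 3.75),
                                c(WT = 500, mut = 356), width_sd = 80,
                                seed = 1000L + i)
    fit_width_model(d)$coefficients$estimate[2L]
  }, numeric(1L))
  expect_gte(mean(abs(est + 144) <= 20), 0.95)
})

test_that("the null Poisson genotype effect is rarely significant", {
  z <- vapply(1:300, function(i) {
    d <- simulate_grana_dataset(50, c(a = 4.5, b = 4.5),
                                c(a = 500, b = 500), seed = 2000L + i)
    fit_stack_count_model(d)$coefficients$statistic[2L]
  }, numeric(1L))
  expect_gte(mean(abs(z) < 1.96), 0.92)
  expect_lte(mean(abs(z) < 1.96), 0.995)
})
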