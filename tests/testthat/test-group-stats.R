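tab4 <- read_metrics_table(table4_path())

test_that("ols_simple reproduces published trend fits on the bundled table", {
  oral_k <- tab4$k_mean[tab4$modality == "oral"]
  fit <- ols_simple(1:5, oral_k)
  expect_near(fit$slope, -0.2243, 4)
  expect_near(fit$intercept, 7.3379, 4)
  expect_near(fit$R2, 0.8077, 4)
  expect_near(fit$p_slope, 0.038, 3)

  wr_nd <- tab4$ND[tab4$modality == "written"]
  fit2 <- ols_simple(1:5, wr_nd)
  expect_near(fit2$slope, -0.0014, 4)
  expect_near(fit2$R2, 0.98, 2)

  perfect <- ols_simple(1:6, 2 + 3 * (1:6))
  expect_equal(perfect$R2, 1)
  expect_equal(perfect$slope, 3)
  expect_error(ols_simple(rep(1, 5), 1:5), "constant",
               class = "syntnet_validation_error")
  expect_error(ols_simple(1:2, 1:2), class = "syntnet_validation_error")
})

test_that("ols_simple matches stats::lm on random data", {
  set.seed(50)
  for (rep in 1:10) {
    x <- rnorm(sample(5:30, 1))
    y <- 2 - x + rnorm(length(x))
    got <- ols_simple(x, y)
    ref <- summary(stats::lm(y ~ x))
    expect_equal(got$slope, unname(coef(ref)["x", "Estimate"]))
    expect_equal(got$intercept, unname(coef(ref)["(Intercept)", "Estimate"]))
    expect_equal(got$R2, ref$r.squared)
    expect_equal(got$p_slope, unname(coef(ref)["x", "Pr(>|t|)"]))
  }
})

test_that("t_test2 reproduces published cross-modality comparisons", {
  a <- tab4$k_mean[tab4$modality == "written" & tab4$level != "native"]
  b <- tab4$k_mean[tab4$modality == "oral" & tab4$level != "native"]
  w <- t_test2(a, b, "welch")
  expect_near(abs(w$t), 6.234, 3)
  expect_near(w$df, 4.454, 3)
  expect_lt(w$p, 0.005)

  al <- tab4$L[tab4$modality == "written" & tab4$level != "native"]
  bl <- tab4$L[tab4$modality == "oral" & tab4$level != "native"]
  p <- t_test2(al, bl, "pooled")
  expect_near(abs(p$t), 5.991, 3)
  expect_equal(p$df, 6)
  expect_near(p$mean_a, 3.043, 3)
  expect_near(p$mean_b, 3.273, 3)
})

test_that("t_test2 matches stats::t.test and its invariants", {
  set.seed(60)
  for (rep in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), sd = 2)
    for (variant in c("pooled", "welch")) {
      got <- t_test2(a, b, variant)
      ref <- stats::t.test(a, b, var.equal = variant == "pooled")
      expect_equal(got$t, unname(ref$statistic))
      expect_equal(got$df, unname(ref$parameter))
      expect_equal(got$p, ref$p.value)
    }
    # Welch df never exceeds pooled df
    expect_lte(t_test2(a, b, "welch")$df, t_test2(a, b, "pooled")$df)
  }
  # identical samples: t = 0, p = 1
  x <- c(1, 2, 3)
  same <- t_test2(x, x, "pooled")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # equal-variance equal-n: pooled and welch coincide
  a <- c(1, 2, 3, 4); b <- a + 1
  expect_equal(t_test2(a, b, "pooled")$t, t_test2(a, b, "welch")$t)
  expect_error(t_test2(c(1, 1), c(1, 1)), "undefined",
               class = "syntnet_validation_error")
})

test_that("pearson_r behaves on printed counts and pure lines", {
  wr_n <- tab4$N[tab4$modality == "written" & tab4$level != "native"]
  got <- pearson_r(1:4, wr_n)
  expect_gt(got$r, 0.97)
  expect_lt(got$p, 0.05)
  expect_equal(pearson_r(1:5, 2 * (1:5))$r, 1)
  expect_equal(pearson_r(1:5, -(1:5))$r, -1)
  expect_error(pearson_r(1:5, rep(2, 5)), "constant",
               class = "syntnet_validation_error")
  ref <- stats::cor.test(1:4, wr_n)
  expect_equal(got$p, ref$p.value)
})

test_that("regression on reversed levels negates the slope, preserves R2", {
  y <- tab4$C[tab4$modality == "oral"]
  f1 <- ols_simple(1:5, y)
  f2 <- ols_simple(6 - (1:5), y)
  expect_equal(f2$slope, -f1$slope)
  expect_equal(f2$R2, f1$R2)
})

test_that("run_battery reproduces the published battery and validates input", {
  rep <- run_battery(tab4)
  nc_w <- rep$metrics$NC$regression$written
  expect_near(nc_w$slope, 0.025, 3)
  expect_near(nc_w$intercept, 0.156, 3)
  expect_near(abs(rep$metrics$ND$t_test$t), 7.503, 3)
  expect_equal(rep$metrics$ND$t_test$df, 6)
  # variants follow the plan
  expect_equal(rep$metrics$k_mean$t_test$variant, "welch")
  expect_equal(rep$metrics$L$t_test$variant, "pooled")

  expect_error(run_battery(tab4[tab4$label != "O3", ]), "O|level",
               class = "syntnet_validation_error")

  flat <- battery_as_table(rep)
  expect_equal(nrow(flat), 6)
  expect_setequal(flat$metric, c("k_mean", "gamma_prime", "C", "L", "ND", "NC"))
})

test_that("the battery is calibrated: no modality difference, few rejections", {
  metrics <- c("k_mean", "gamma_prime", "C", "L", "ND", "NC")
  set.seed(77)
  hits <- matrix(NA, nrow = 50, ncol = length(metrics),
                 dimnames = list(NULL, metrics))
  for (r in 1:50) {
    tab <- expand.grid(level = c(as.character(1:4), "native"),
                       modality = c("written", "oral"),
                       stringsAsFactors = FALSE)
    tab$label <- paste0(toupper(substr(tab$modality, 1, 1)), tab$level)
    code <- level_code_test(tab$level)
    for (m in metrics) tab[[m]] <- 5 - 0.3 * code + rnorm(10, sd = 0.2)
    rep <- run_battery(tab)
    for (m in metrics) {
      tt <- rep$metrics[[m]]$t_test
      hits[r, m] <- abs(tt$t) <= stats::qt(0.975, tt$df)
    }
  }
  for (m in metrics) expect_gte(mean(hits[, m]), 0.9)
})
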