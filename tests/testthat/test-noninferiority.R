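test_that("identical series are declared non-inferior at any positive margin", {
  set.seed(2)
  inter <- runif(32, 0.3, 0.8)
  res <- noninferiority_p(inter, inter, "higher_better", margin = 0.2)
  expect_lt(res$p, 0.05)
  expect_equal(res$deltas, rep(0.2, 32))

  # lower-better orientation: identical AVD series, margin 3 ml
  res2 <- noninferiority_p(inter * 10, inter * 10, "lower_better", margin = 3)
  expect_lt(res2$p, 0.05)
})

test_that("a model exactly at the margin boundary cannot be declared non-inferior", {
  inter <- seq(0.4, 0.8, length.out = 32)
  model <- inter - 0.2
  res <- noninferiority_p(inter, model, "higher_better", margin = 0.2)
  expect_equal(res$p, 1)
  expect_equal(res$test_used, "degenerate")
})

test_that("a clearly inferior model rarely passes", {
  set.seed(3)
  rejections <- replicate(100, {
    inter <- runif(32, 0.4, 0.8)
    model <- inter - 0.4 + rnorm(32, 0, 0.05)  # worse by 2x margin
    noninferiority_p(inter, model, "higher_better", margin = 0.2)$p < 0.05
  })
  expect_gte(mean(!rejections), 0.95)
})

test_that("orientation flips correctly for lower-better metrics", {
  set.seed(4)
  inter <- runif(32, 5, 15)       # e.g. HD95 in mm
  worse <- inter + 9              # 3x the 3 mm margin
  better <- inter - 2
  expect_gt(noninferiority_p(inter, worse, "lower_better", margin = 3)$p, 0.5)
  expect_lt(noninferiority_p(inter, better, "lower_better", margin = 3)$p, 0.01)
})

test_that("pairwise-complete deletion and the minimum-n rule apply", {
  inter <- c(NA, runif(5)); model <- c(runif(5), NA)
  expect_error(noninferiority_p(inter, model, "higher_better", 0.2),
               "at least 5")
  inter2 <- c(runif(8), NA, NA)
  model2 <- c(runif(8), 0.5, 0.5)
  res <- noninferiority_p(inter2, model2 + 1, "higher_better", 0.2)
  expect_equal(res$n_used, 8)
})

test_that("the Shapiro gate selects the recorded test", {
  set.seed(6)
  inter <- runif(40, 0.3, 0.7)
  model_norm <- inter + rnorm(40, 0, 0.02)
  expect_equal(
    noninferiority_p(inter, model_norm, "higher_better", 0.2)$test_used,
    "paired_t"
  )
  model_skew <- inter + rexp(40, 2)^2
  expect_equal(
    noninferiority_p(inter, model_skew, "higher_better", 0.2)$test_used,
    "wilcoxon"
  )
})

test_that("the battery fills adjusted p-values and decisions per metric", {
  set.seed(8)
  n <- 32
  vals <- runif(n, 0.4, 0.8)
  ag <- dplyr::bind_rows(lapply(metric_battery()$metric, function(m) {
    v <- if (m %in% c("AVD", "HD95")) vals * 20 else vals
    make_agreement(v, v, metric = m)
  }))
  res <- run_noninferiority_battery(ag, noninferiority_config(n_boot = 1000))
  expect_s3_class(res, "noninf_battery")
  expect_equal(nrow(res), 7)
  expect_true(all(res$non_inferior))
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_equal(res$margin, c(0.2, 3, 0.2, 0.2, 0.2, 3, 0.2))
  # adjusted ordering is monotone in the raw ordering
  o <- order(res$p_raw)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-15))

  g <- glance(res)
  expect_equal(g$n_non_inferior, 7)
  td <- tidy(res)
  expect_false(inherits(td, "noninf_battery"))
})

test_that("a metric with only undefined values is reported but not tested", {
  set.seed(9)
  vals <- runif(12, 0.4, 0.8)
  ag <- dplyr::bind_rows(
    make_agreement(vals, vals, metric = "Dice"),
    make_agreement(rep(NA_real_, 12), vals, metric = "HD95")
  )
  res <- run_noninferiority_battery(ag, noninferiority_config(n_boot = 1000))
  hd <- res[res$metric == "HD95", ]
  expect_equal(hd$n_cases_used, 0L)
  expect_true(is.na(hd$p_raw))
  expect_true(res$non_inferior[res$metric == "Dice"])
})

test_that("an explicit larger Holm family inflates adjusted p-values", {
  set.seed(10)
  vals <- runif(20, 0.4, 0.8)
  ag <- make_agreement(vals, vals - 0.12, metric = "Dice")
  r1 <- run_noninferiority_battery(ag, noninferiority_config(n_boot = 1000))
  r2 <- run_noninferiority_battery(
    ag, noninferiority_config(n_boot = 1000, holm_family_size = 10)
  )
  expect_equal(r2$p_adjusted, pmin(1, r1$p_raw * 10))
  expect_gte(r2$p_adjusted, r1$p_adjusted)
})

test_that("derived margins recover constructed inter-expert variability", {
  n <- 20
  base <- seq(0.3, 0.8, length.out = n)
  tab_a <- tibble::tibble(case_id = sprintf("c%02d", 1:n), metric = "Dice",
                          value = base, defined = TRUE)
  tab_b <- tab_a
  tab_b$value <- base - 0.19   # constant absolute difference
  m <- derive_margins(tab_a, tab_b)
  expect_equal(m$margin_derived[m$family == "unit_interval"], 0.19)
  expect_equal(m$margin_default[m$family == "unit_interval"], 0.2)

  expect_warning(derive_margins(tab_a, tab_a), "identical")

  # SI-unit family averaged separately
  tab_a2 <- dplyr::bind_rows(
    tab_a,
    tibble::tibble(case_id = tab_a$case_id, metric = "AVD",
                   value = base * 10, defined = TRUE),
    tibble::tibble(case_id = tab_a$case_id, metric = "HD95",
                   value = base * 20, defined = TRUE)
  )
  tab_b2 <- tab_a2
  tab_b2$value <- tab_a2$value + rep(c(0.1, 2, 3), each = n)
  m2 <- derive_margins(tab_a2, tab_b2)
  expect_equal(m2$margin_derived[m2$family == "si_units"], 2.5)
  expect_equal(m2$margin_derived[m2$family == "unit_interval"], 0.1)
})
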