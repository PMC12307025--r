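test_that("Wilcoxon rank-sum: identity, separation, invariances", {
  x <- c(3, 1, 4, 1, 5)
  same <- wilcoxon_ranksum(x, x)
  expect_gt(same$p, 0.9)
  expect_lt(same$effect_r, 0.1)

  sep <- wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12), exact = TRUE)
  expect_equal(sep$p, 0.1)    # 2/C(6,3) at complete separation

  set.seed(71)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  w1 <- wilcoxon_ranksum(a, b)
  w2 <- wilcoxon_ranksum(2 * a, 2 * b)
  expect_equal(w1$W, w2$W)
  expect_equal(w1$p, w2$p)
  w3 <- wilcoxon_ranksum(exp(a), exp(b))   # monotone transform of pooled data
  expect_equal(w1$p, w3$p)

  # agreement with the reference implementation
  ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(w1$U, unname(ref$statistic))
  expect_equal(w1$p, ref$p.value, tolerance = 1e-10)

  expect_error(wilcoxon_ranksum(numeric(0), b), "observation")
})

test_that("score outliers use the k-SD rule", {
  sc <- c(rep(c(10, 11, 12, 13), 5), 100)
  expect_equal(detect_score_outliers(sc), 21L)
  expect_true(abs(sc[21] - mean(sc)) > 3 * sd(sc))   # direct mean/SD oracle
  expect_length(detect_score_outliers(sc[-21]), 0)
  expect_length(detect_score_outliers(rep(7, 10)), 0)
  expect_length(detect_score_outliers(sc, k = Inf), 0)
  expect_error(detect_score_outliers(c(1, 2)), "3 scores")
})

make_table <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    age_group = rep(c("younger", "older"), each = n / 2),
    sex = rep_len(c("female", "male"), n),
    band = "delta",
    dwpli_mean = runif(n),
    clustering = runif(n),
    modularity = runif(n),
    path_length = runif(n, 1, 10),
    small_world = runif(n, 0.5, 2)
  )
}

test_that("noiseless planted regressions are recovered to machine precision", {
  tab <- make_table(60, seed = 72)
  z <- as.numeric(scale(tab$dwpli_mean))
  older <- as.numeric(tab$age_group == "older")
  tab$semantic_fluency <- 25 + 2 * z - 3 * older + 1.5 * z * older
  m <- fit_model(tab, "dwpli", "delta", "semantic_fluency")
  co <- suppressWarnings(tidy(m))   # summary() warns on an exact fit
  expect_equal(co$estimate[co$term == "(Intercept)"], 25, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "dwpli_mean"], 2, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "age_groupolder"], -3, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "dwpli_mean:age_groupolder"], 1.5,
               tolerance = 1e-8)
})

test_that("swapping reference levels flips the group effect but not the fit", {
  tab <- make_table(40, seed = 73)
  set.seed(74)
  tab$semantic_fluency <- 20 - 2.5 * (tab$age_group == "older") + rnorm(40)
  m1 <- fit_model(tab, "dwpli", "delta", "semantic_fluency")
  m2 <- fit_model(tab, "dwpli", "delta", "semantic_fluency",
                  ref_age = "older", ref_sex = "male")
  c1 <- tidy(m1); c2 <- tidy(m2)
  expect_equal(c1$estimate[c1$term == "age_groupolder"],
               -c2$estimate[c2$term == "age_groupyounger"], tolerance = 1e-10)
  expect_equal(sort(stats::fitted(m1$fit)), sort(stats::fitted(m2$fit)),
               tolerance = 1e-10)
  expect_equal(glance(m1)$adj.r.squared, glance(m2)$adj.r.squared)
})

test_that("model fit is invariant to affine rescaling of raw metrics", {
  tab <- make_table(50, seed = 75)
  set.seed(76)
  tab$semantic_fluency <- 22 + 1.2 * scale(tab$clustering)[, 1] + rnorm(50, 0, 2)
  m1 <- fit_model(tab, "segregation", "delta", "semantic_fluency")
  tab2 <- tab
  tab2$clustering <- 100 * tab2$clustering - 7
  tab2$modularity <- 0.01 * tab2$modularity + 3
  m2 <- fit_model(tab2, "segregation", "delta", "semantic_fluency")
  expect_equal(glance(m1)$adj.r.squared, glance(m2)$adj.r.squared,
               tolerance = 1e-10)
  expect_equal(glance(m1)$statistic, glance(m2)$statistic, tolerance = 1e-10)
  expect_equal(tidy(m1)$statistic, tidy(m2)$statistic, tolerance = 1e-8)
})

test_that("rank-deficient designs error with the collinear terms named", {
  tab <- make_table(30, seed = 77)
  tab$modularity <- tab$clustering        # perfectly collinear
  tab$semantic_fluency <- rpois(30, 20)
  expect_error(fit_model(tab, "segregation", "delta", "semantic_fluency"),
               "collinear|rank")
})

test_that("leverage filtering removes extreme hat values once and only once", {
  tab <- make_table(40, seed = 78)
  tab$dwpli_mean[1] <- 100          # far outside [0,1]: huge leverage
  set.seed(79)
  tab$semantic_fluency <- rpois(40, 20)
  m <- fit_model(tab, "dwpli", "delta", "semantic_fluency")
  h <- stats::hatvalues(m$fit)
  p1 <- ncol(stats::model.matrix(m$fit))
  expect_gt(h[1], 2 * p1 / 40)      # hat-matrix oracle flags row 1
  m2 <- leverage_filter_refit(m)
  expect_gte(m2$n_leverage_removed, 1)
  # the extreme scaled value is gone from the refit data
  expect_lt(max(abs(m2$data$dwpli_mean)), 3)

  # idempotence on the cleaned balanced design
  m3 <- leverage_filter_refit(m2)
  expect_equal(m3$n_leverage_removed, m2$n_leverage_removed)

  # a purely factorial balanced design has equal hat values -> no removals
  bal <- tibble::tibble(
    age_group = rep(c("younger", "older"), each = 8),
    sex = rep(c("female", "male"), 8),
    dwpli_mean = rep(c(-1, -1, 1, 1), times = 4),
    semantic_fluency = rpois(16, 20)
  )
  mb <- fit_model(bal, "dwpli", "delta", "semantic_fluency")
  hb <- stats::hatvalues(mb$fit)
  expect_lt(diff(range(hb)), 1e-10)
  expect_equal(leverage_filter_refit(mb)$n_leverage_removed, 0)
})

test_that("the model grid yields 32 summaries and skips absent bands with a warning", {
  set.seed(80)
  n <- 48
  metrics <- dplyr::bind_rows(lapply(c("delta", "theta", "alpha", "beta"),
    function(b) dplyr::mutate(make_table(n, seed = match(b, c("delta","theta","alpha","beta"))), band = b))) |>
    dplyr::select(-"age_group", -"sex")
  behavioural <- tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    age_group = rep(c("younger", "older"), each = n / 2),
    sex = rep_len(c("female", "male"), n),
    semantic_fluency = rpois(n, 23),
    letter_fluency = rpois(n, 14)
  )
  models <- run_all_models(metrics, behavioural)
  expect_length(models, 32)
  expect_setequal(unique(vapply(models, function(m) m$band, character(1))),
                  c("delta", "theta", "alpha", "beta"))

  expect_warning(
    m24 <- run_all_models(metrics[metrics$band != "theta", ], behavioural),
    "theta")
  expect_length(m24, 24)

  tblout <- model_summary_table(models)
  expect_true(all(c("term", "estimate", "std.error", "statistic", "p.value")
                  %in% names(tblout)))
  expect_equal(length(unique(tblout$model_id)), 32)
})
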