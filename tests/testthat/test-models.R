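# Cooperation-model fitting, BIC, and the relative-BIC decision rule.

test_that("closed-form additive least squares matches the normal equations", {
  fit <- ols_additive(c(1, 2, 3), c(3, 5, 7))
  expect_equal(fit$alpha, 2)
  expect_equal(fit$beta, 1)
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  # constant P -> slope 0, intercept at the constant
  fit <- ols_additive(1:5, rep(4, 5))
  expect_equal(fit$alpha, 0)
  expect_equal(fit$beta, 4)
  # noisy 7-point instance vs hand-solved normal equations
  set.seed(2)
  S <- sort(runif(7, 0, 10)); P <- 1.7 * S + 3 + rnorm(7)
  fit <- ols_additive(S, P)
  X <- cbind(1, S)
  beta_hat <- solve(t(X) %*% X, t(X) %*% P)
  expect_equal(fit$beta, beta_hat[1], tolerance = 1e-10)
  expect_equal(fit$alpha, beta_hat[2], tolerance = 1e-10)
  expect_error(ols_additive(rep(2, 5), 1:5), "constant")
})

test_that("the global optimizer recovers noiseless generating parameters", {
  S <- 1:7
  fit <- fit_cooperation_model(S, 2 * S + 1, "additive", seed = 1)
  expect_lte(fit$rss, 1e-8)
  expect_equal(fit$params$alpha, 2, tolerance = 1e-6)
  expect_equal(fit$params$beta, 1, tolerance = 1e-6)

  fit <- fit_cooperation_model(S, exp(S), "exponential", seed = 1)
  expect_equal(fit$params$alpha, 1, tolerance = 1e-6)
  expect_equal(fit$params$beta, 0, tolerance = 1e-5, ignore_attr = TRUE)
  expect_lte(fit$rss / sum(exp(S)^2), 1e-12)

  # logistic: forward-simulate then refit; forward values must match
  S <- c(-2, -1, 0, 1, 2, 3, 4)
  P <- 4 / (1 + exp(-(1 * S + 0)))
  fit <- fit_cooperation_model(S, P, "logistic", seed = 1)
  pred <- fit$params$delta /
    (1 + exp(-(fit$params$alpha * S + fit$params$beta)))
  expect_equal(pred, P, tolerance = 1e-4)

  expect_error(fit_cooperation_model(rep(1, 7), 1:7, "additive"),
               "unfittable")
  expect_error(fit_cooperation_model(c(1:6, NA), 1:7, "additive"),
               "domain error")
})

test_that("fits are deterministic given the seed", {
  set.seed(99)
  S <- sort(runif(7, 0, 5)); P <- exp(0.5 * S + 1) * exp(rnorm(7, 0, 0.1))
  f1 <- fit_cooperation_model(S, P, "exponential", seed = 7)
  f2 <- fit_cooperation_model(S, P, "exponential", seed = 7)
  expect_identical(f1[c("params", "rss", "bic")], f2[c("params", "rss", "bic")])
  g1 <- classify_gene(S, P, seed = 7)
  g2 <- classify_gene(S, P, seed = 7)
  expect_identical(glance(g1), glance(g2))
})

test_that("BIC follows n ln(rss/n) + (k+1) ln(n) with the epsilon floor", {
  expect_equal(compute_bic(7, 7, 2), 3 * log(7))
  expect_equal(compute_bic(7, 7, 3) - compute_bic(7, 7, 2), log(7))
  expect_true(is.finite(compute_bic(0, 7, 2)))
  expect_equal(compute_bic(0, 7, 2), 7 * log(1e-12 / 7) + 3 * log(7))
  expect_error(compute_bic(1, 2, 2), ">= 3")
})

test_that("relative-BIC buckets follow the printed thresholds exactly", {
  rb <- encoop:::relbic_class
  eps <- 1e-9
  expect_equal(rb(2 + eps), "synergistic")
  expect_equal(rb(2), "ambiguous")       # closed interval
  expect_equal(rb(0), "ambiguous")
  expect_equal(rb(1), "ambiguous")
  expect_equal(rb(-eps), "additive")
  expect_equal(rb(5, threshold = 10), "ambiguous")
})

test_that("the decision rule classifies generating models and runs the exclusion round", {
  S <- 1:7
  # noiseless line -> additive with negative relative BIC
  g <- classify_gene(S, 2 * S + 3, seed = 1)
  expect_equal(g$final_class, "additive")
  expect_lt(g$relative_bic, 0)
  expect_true(is.na(g$excluded_point))

  # noiseless exponential -> synergistic with relative BIC > 2
  g <- classify_gene(0:6, exp(0.7 * (0:6)), seed = 1)
  expect_equal(g$final_class, "synergistic")
  expect_gt(g$relative_bic, 2)

  # saturating logistic -> logistic after one exclusion round on 6 points
  S <- 0:6
  P <- 10 / (1 + exp(-(2 * S - 6)))
  g <- classify_gene(S, P, time_hr = c(0, 12, 24, 30, 36, 72, 96), seed = 1)
  expect_equal(g$final_class, "logistic")
  expect_equal(g$excluded_point, 96)       # max-S point, latest time on ties
  expect_equal(length(g$used_idx), 6L)
  expect_equal(g$fits$additive$n, 6L)

  # constant inputs are unfittable
  expect_equal(classify_gene(rep(1, 7), 1:7)$final_class, "unfittable")
  expect_equal(classify_gene(1:7, rep(2, 7))$final_class, "unfittable")

  # max-S tie broken toward the latest time point
  S_tie <- c(1, 2, 3, 4, 5, 6, 6)
  P_sat <- 10 / (1 + exp(-(3 * S_tie - 9)))
  g <- classify_gene(S_tie, P_sat, time_hr = c(0, 12, 24, 30, 36, 72, 96),
                     seed = 1)
  if (!is.na(g$excluded_point)) expect_equal(g$excluded_point, 96)
})

test_that("classification is invariant under rescaling of enhancer activities", {
  set.seed(4)
  S <- c(3, 5, 9, 14, 30, 68, 70)
  cases <- list(
    additive = (1.2 * S + 8) * exp(rnorm(7, 0, 0.05)),
    exponential = exp(0.08 * S + 1) * exp(rnorm(7, 0, 0.05)),
    logistic = 40 / (1 + exp(-(0.2 * (S - 30)))) * exp(rnorm(7, 0, 0.05)))
  for (nm in names(cases)) {
    base_class <- classify_gene(S, cases[[nm]], seed = 2)$final_class
    for (c_mult in c(0.5, 2, 10)) {
      expect_equal(classify_gene(S * c_mult, cases[[nm]], seed = 2)$final_class,
                   base_class, label = sprintf("%s x%g", nm, c_mult))
    }
  }
})

test_that("the additive fit never loses to closed-form least squares", {
  set.seed(31)
  for (i in 1:50) {
    S <- sort(runif(7, 0, 20)) + rnorm(7, 0, 0.01)
    P <- runif(1, -2, 2) * S + runif(1, -10, 10) + rnorm(7, 0, 2)
    fit <- fit_cooperation_model(S, P, "additive", seed = i)
    expect_lte(fit$rss, ols_additive(S, P)$rss * (1 + 1e-6))
  }
})

test_that("summed enhancer activity uses replicate means over paired enhancers", {
  prof <- rbind(e1 = c(1, 2, 3), e2 = c(3, 2, 1), g = c(9, 9, 9))
  act <- activity_from_profiles(prof, c(0, 12, 24))
  pairs <- tibble::tibble(enhancer_id = c("e1", "e2"), gene_id = "g")
  S <- sum_enhancer_activity("g", pairs, act)
  expect_equal(S$S, c(4, 4, 4))
  expect_equal(sum_enhancer_activity("g", pairs[1, ], act)$S, c(1, 2, 3))
  # replicates (2, 4) at one time point contribute their mean, 3
  act2 <- tibble::tibble(unit_id = "e1", assay = "TTseq", time_hr = 0,
                         replicate = 1:2, value = c(2, 4))
  expect_equal(sum_enhancer_activity("g", pairs[1, ], act2)$S, 3)
  expect_error(sum_enhancer_activity("zz", pairs, act), "no paired")
})

test_that("classify_all applies the 2-20 enhancer range and the top-75% correlation filter", {
  # 8 genes: one with 1 enhancer, one with 21, six eligible
  set.seed(6)
  tp <- c(0, 12, 24, 30, 36, 72, 96)
  profs <- list(); pairs <- list()
  mk_gene <- function(gid, k, rho_rank) {
    S <- seq(10, 100, length.out = 7)
    for (j in seq_len(k)) {
      profs[[sprintf("%s_e%02d", gid, j)]] <<- S / k
    }
    # decreasing rho across genes: add increasing rank-scrambling noise
    profs[[gid]] <<- (2 * S + 5) + rho_rank * c(0, 30, -30, 0, 30, -30, 0)
    pairs[[gid]] <<- tibble::tibble(
      enhancer_id = sprintf("%s_e%02d", gid, seq_len(k)), gene_id = gid)
  }
  mk_gene("g_single", 1, 0)
  mk_gene("g_many", 21, 0)
  for (i in 1:6) mk_gene(sprintf("g%02d", i), 2, i - 1)
  act <- activity_from_profiles(do.call(rbind, profs), tp)
  cl <- classify_all(dplyr::bind_rows(pairs), act, seed = 1)
  expect_false("g_single" %in% cl$gene_id)
  expect_false("g_many" %in% cl$gene_id)
  # floor(6 * 0.75) = 4 retained, the most-correlated ones
  expect_equal(nrow(cl), 4L)
  expect_setequal(cl$gene_id, sprintf("g%02d", 1:4))
  expect_s3_class(cl, "encoop_classification")
  counts <- glance(cl)
  expect_equal(counts$n_genes, 4L)
})

test_that("the logarithmic control behaves as a negative control", {
  S <- 1:7
  ctl <- log_model_control(S, 2 * S + 1, seed = 1)
  expect_lt(ctl$relative_bic, 0)
  ctl <- log_model_control(S, 3 * log(S) + 1, seed = 1)
  expect_gt(ctl$relative_bic, 2)
})
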