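# Design construction, OLS fitting, F tests, BH, direction, QQ.

test_that("build_design encodes the model for the minimal cohort", {
  X <- build_design(tiny_sheet(1, 1))
  expect_equal(matrix(X, 4, 4),
               matrix(c(1, 0, 0, 0,
                        1, 0, 1, 0,
                        0, 1, 0, 0,
                        0, 1, 0, 1), 4, byrow = TRUE))
  expect_equal(colnames(X), c("swd_intercept", "ctrl_intercept",
                              "swd_vacation", "ctrl_vacation"))
  # the two intercept columns partition the samples
  expect_true(all(X[, 1] + X[, 2] == 1))
})

test_that("degenerate and collinear nuisance columns are pruned", {
  sheet <- tiny_sheet(2, 2)
  sheet$sex <- "male"
  expect_warning(X <- build_design(sheet, "sex"),
                 class = "pairedEWAS_design_warning")
  expect_false("sex" %in% colnames(X))
  # a covariate identical to group membership is collinear with the core
  sheet$dup <- ifelse(sheet$group == "swd", "a", "b")
  expect_warning(X2 <- build_design(sheet, "dup"),
                 class = "pairedEWAS_design_warning")
  expect_equal(attr(X2, "rank"), ncol(X2))
})

test_that("design rank matches an independent decomposition on a cohort", {
  sheet <- generate_cohort(cohort_config(seed = 8))
  X <- suppressWarnings(build_design(
    sheet, c("age", "sex", "plate", "alcohol", "smoking")))
  sv <- svd(X)$d
  expect_equal(attr(X, "rank"), sum(sv > max(sv) * 1e-10))
  expect_equal(attr(X, "rank"), ncol(X))    # survivors are independent
  expect_error(build_design(sheet[sheet$period == "work", ]),
               class = "pairedEWAS_design_error")
})

test_that("fit_probe agrees with the normal-equations oracle", {
  sheet <- generate_cohort(cohort_config(seed = 10))
  X <- suppressWarnings(build_design(sheet, c("age", "sex", "plate")))
  set.seed(21)
  for (i in 1:20) {
    y <- rnorm(nrow(X))
    fit <- fit_probe(y, X)
    oracle <- ols_oracle(y, X)
    expect_equal(unname(fit$coefficients), unname(oracle$beta),
                 tolerance = 1e-8)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
    expect_equal(fit$df_resid, nrow(X) - ncol(X))
  }
})

test_that("fit_probe handles constants, planted effects and bad input", {
  X <- build_design(tiny_sheet(2, 2))
  y <- rep(3, nrow(X))
  fit <- fit_probe(y, X)
  expect_equal(unname(fit$coefficients[1:2]), c(3, 3))
  expect_equal(unname(fit$coefficients[3:4]), c(0, 0))
  expect_equal(fit$rss, 0)
  # noiseless planted SWD vacation effect of 1
  y2 <- ifelse(X[, "swd_vacation"] == 1, 1, 0)
  expect_equal(unname(fit_probe(y2, X)$coefficients[["swd_vacation"]]), 1,
               tolerance = 1e-8)
  expect_error(fit_probe(y[1:3], X), class = "pairedEWAS_contract_error")
  expect_error(fit_probe(rnorm(4), build_design(tiny_sheet(1, 1))),
               class = "pairedEWAS_fit_error")   # saturated: df = 0
})

test_that("f_test matches the t-test for single restrictions", {
  sheet <- generate_cohort(cohort_config(seed = 12))
  X <- suppressWarnings(build_design(sheet, c("age", "sex")))
  set.seed(33)
  for (i in 1:20) {
    y <- rnorm(nrow(X)) + 0.3 * X[, "swd_vacation"]
    full <- fit_probe(y, X)
    null <- fit_probe(y, X[, colnames(X) != "swd_vacation"])
    p_f <- f_test(full, null)
    lmfit <- summary(stats::lm(y ~ 0 + X))
    p_t <- lmfit$coefficients["Xswd_vacation", "Pr(>|t|)"]
    expect_equal(p_f, p_t, tolerance = 1e-10)
  }
})

test_that("f_test edge cases follow the contract", {
  f1 <- structure(list(rss = 2, df_resid = 10, rank = 4), class = "probe_fit")
  f0 <- structure(list(rss = 2, df_resid = 11, rank = 3), class = "probe_fit")
  expect_equal(f_test(f1, f0), 1)
  # F quantile oracle: F(1,10) upper 5% point
  fq <- stats::qf(0.95, 1, 10)
  f0b <- structure(list(rss = 2 * (1 + fq / 10), df_resid = 11, rank = 3),
                   class = "probe_fit")
  expect_equal(f_test(f1, f0b), 0.05, tolerance = 1e-10)
  expect_error(f_test(f1, f1), class = "pairedEWAS_contract_error")
  sat <- structure(list(rss = 0, df_resid = 10, rank = 4), class = "probe_fit")
  expect_warning(p <- f_test(sat, f0), class = "pairedEWAS_fit_warning")
  expect_equal(p, 0)
})

test_that("test_probe_hypotheses implements the composite max-p null", {
  sheet <- generate_cohort(cohort_config(seed = 14))
  X <- build_design(sheet)
  set.seed(5)
  for (i in 1:10) {
    y <- rnorm(nrow(X))
    p <- test_probe_hypotheses(y, X)
    expect_identical(p[["p_both"]], max(p[["p_swd"]], p[["p_ctrl"]]))
    expect_true(all(p >= 0 & p <= 1))
  }
  # SWD-only effect: p_swd stochastically smaller than p_ctrl
  ps <- replicate(50, {
    y <- rnorm(nrow(X)) + 1.0 * X[, "swd_vacation"]
    test_probe_hypotheses(y, X)[c("p_swd", "p_ctrl")]
  })
  expect_lt(median(ps["p_swd", ]), median(ps["p_ctrl", ]))
})

test_that("bh_adjust matches the step-up oracle and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "pairedEWAS_contract_error")
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"))        # independent oracle
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))    # monotone in p-order
  }
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
})

test_that("classify_direction uses the sign convention", {
  expect_equal(classify_direction(c(0.3, -0.3, 0)),
               c("hypo_at_work", "hyper_at_work", "none"))
})

test_that("run_ewas calibrates, aligns, and skips degenerate probes", {
  w <- sim_world(seed = 101, n_probes = 1000, frac_affected_swd = 0,
                 frac_affected_ctrl = 0, recovery_probe_ids = character(0))
  tab <- suppressWarnings(run_ewas(w$matrix, w$sheet))
  expect_equal(nrow(tab), 1000L)
  # binomial 99% band at alpha = 0.05, n = 1000
  for (h in c("p_swd", "p_ctrl")) {
    expect_gt(mean(tab[[h]] < 0.05), 0.03)
    expect_lt(mean(tab[[h]] < 0.05), 0.07)
  }
  expect_true(all(tab$q_swd >= tab$p_swd))
  expect_true(all(tab$p_both >= tab$p_swd & tab$p_both >= tab$p_ctrl))
  # direction partition
  expect_equal(sum(tab$direction_swd %in%
                     c("hypo_at_work", "hyper_at_work", "none")), 1000L)

  # misalignment
  bad <- w$matrix
  colnames(bad)[1] <- "ghost"
  expect_error(run_ewas(bad, w$sheet), class = "pairedEWAS_alignment_error")

  # zero-variance and missing-value probes are skipped with reasons
  m2 <- w$matrix[1:10, ]
  m2[1, ] <- 7
  m2[2, 1:60] <- NA
  tab2 <- suppressWarnings(run_ewas(m2, w$sheet))
  sk <- attr(tab2, "skipped")
  expect_setequal(sk$probe_id, rownames(m2)[1:2])
  expect_equal(nrow(tab2), 8L)

  # empty matrix: empty table, no error
  tab0 <- run_ewas(w$matrix[0, , drop = FALSE], w$sheet)
  expect_equal(nrow(tab0), 0L)
})

test_that("complete-case fits equal the per-probe path", {
  w <- sim_world(seed = 55, n_probes = 20)
  m <- w$matrix
  m[3, c(2, 10)] <- NA                       # incomplete probe
  tab <- suppressWarnings(run_ewas(m, w$sheet))
  X <- suppressWarnings(build_design(w$sheet, c("age", "sex", "plate",
                                                "alcohol", "smoking")))
  p <- suppressWarnings(test_probe_hypotheses(m[3, ], X))
  row <- tab[tab$probe_id == rownames(m)[3], ]
  expect_equal(row$p_swd, p[["p_swd"]], tolerance = 1e-12)
  expect_equal(row$p_either, p[["p_either"]], tolerance = 1e-12)
})

test_that("vacation coefficient recovery is unbiased", {
  # scaled-down version of the 100-replicate acceptance study
  est <- vapply(1:30, function(i) {
    sheet <- generate_cohort(cohort_config(seed = 7000 + i))
    ec <- effect_config(n_probes = 50, frac_affected_swd = 0.2,
                        frac_positive_swd = 1, effect_size_mean = 1,
                        effect_size_sd = 1e-9, noise_sd = 0.5,
                        recovery_probe_ids = character(0))
    sim <- generate_methylome(sheet, ec)
    tab <- suppressWarnings(run_ewas(sim$matrix, sheet))
    mean(tab$beta_vw_swd[sim$truth$affected_swd])
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1), 2 * se + 1e-9)
})

test_that("summarize_ewas reports the printed-style percentages", {
  tab <- crafted_table(1000, n_dmp_swd = 65, n_hypo_dmp_swd = 51,
                       n_hypo_swd = 670, n_dmp_ctrl = 37,
                       n_hypo_dmp_ctrl = 10, n_hypo_ctrl = 400)
  s <- summarize_ewas(tab, alpha = 0.05)
  expect_equal(s$swd$pct_dmp, 6.5)
  expect_equal(s$swd$pct_hypo, 67)
  expect_equal(s$swd$pct_hypo_dmp, 78)       # 51/65
  expect_equal(s$control$pct_dmp, 3.7)
  # empty DMP set: hypo-among-DMP percentage is missing
  tab0 <- crafted_table(10, 0, 0, 5)
  expect_true(is.na(summarize_ewas(tab0)$swd$pct_hypo_dmp))
})

test_that("qq_points lie on the identity for a uniform grid", {
  n <- 200
  p <- (seq_len(n) - 0.5) / n
  qq <- qq_points(sample(p))
  expect_equal(qq$observed, qq$expected, tolerance = 1e-12)
  one <- qq_points(0.5)
  expect_equal(one$expected, log10(2), tolerance = 1e-12)
  expect_equal(one$observed, log10(2), tolerance = 1e-12)
  expect_error(qq_points(numeric(0)), class = "pairedEWAS_contract_error")
})
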