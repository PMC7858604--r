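# Symptom change scores, recovery grouping, Spearman correlation,
# working-period ANOVA, and the t-SNE embedding.

test_that("change_symptoms arithmetic and antisymmetry", {
  expect_equal(change_symptoms(4, 4, 2, 2), 4L)
  expect_equal(change_symptoms(3, 2, 3, 2), 0L)
  expect_equal(change_symptoms(2, 2, 4, 4), -change_symptoms(4, 4, 2, 2))
  expect_true(is.na(change_symptoms(NA, 2, 1, 1)))
})

test_that("assign_recovery_groups uses tertiles and explicit thresholds", {
  g <- assign_recovery_groups(c(a = 0, b = 2, c = 4))
  expect_equal(as.character(g), c("poor", "recovered", "well"))
  g2 <- assign_recovery_groups(c(x = -1, y = 1, z = 3, w = 5),
                               thresholds = c(0, 2))
  expect_equal(as.character(g2), c("poor", "recovered", "well", "well"))
  # permutation invariance
  s <- c(a = 3, b = 0, c = 5, d = 1, e = 4, f = 2)
  g3 <- assign_recovery_groups(s)
  g4 <- assign_recovery_groups(rev(s))
  expect_equal(g3[names(s)], g4[names(s)])
  expect_warning(assign_recovery_groups(c(a = 1, b = 1, c = 1)),
                 class = "pairedEWAS_degenerate_warning")
})

test_that("spearman_test matches cor.test and handles structure", {
  # perfectly monotone pairs
  st <- spearman_test(1:8, (1:8)^3)
  expect_equal(st$r, 1)
  expect_equal(st$p, 2 / factorial(8))   # only the two extreme orderings
  # n = 5 exact enumeration vs cor.test's exact p
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    st <- spearman_test(x, y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(st$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(st$p, ct$p.value, tolerance = 1e-12)
  }
  # t-approximation branch agrees with cor.test for n >= 10
  for (i in 1:10) {
    x <- rnorm(21); y <- rnorm(21)
    st <- spearman_test(x, y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    expect_equal(st$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(st$p, ct$p.value, tolerance = 1e-8)
  }
  # ties via average ranks
  x <- c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  y <- rnorm(12)
  expect_equal(spearman_test(x, y)$r, cor(x, y, method = "spearman"))
  # invariance under strictly monotone transforms
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(spearman_test(exp(x), y)$r, spearman_test(x, y)$r)
  expect_equal(spearman_test(x, 3 * y + 2)$p, spearman_test(x, y)$p)
  # zero variance
  expect_true(is.na(spearman_test(rep(1, 6), rnorm(6))$r))
})

test_that("correlate_recovery is antisymmetric under period swap", {
  w <- sim_world(seed = 61, n_probes = 60, recovery_link_strength = 0.9)
  mc <- methylation_change(w$matrix, w$sheet)
  cs <- symptom_change(w$sheet)
  swd <- unique(w$sheet$subject[w$sheet$group == "swd"])
  probes <- rownames(w$matrix)[1:10]
  rc <- correlate_recovery(probes, mc, cs, subjects = swd)
  # swapping periods negates both scores; r is unchanged, and flips sign
  # against the unswapped symptom scores
  sheet_sw <- w$sheet
  sheet_sw$period <- ifelse(sheet_sw$period == "work", "vacation", "work")
  mc_sw <- methylation_change(w$matrix, sheet_sw)
  expect_equal(mc_sw, -mc[, colnames(mc_sw)])
  rc_sw <- correlate_recovery(probes, mc_sw, cs, subjects = swd)
  expect_equal(rc_sw$r, -rc$r, tolerance = 1e-12)
  expect_equal(rc_sw$p, rc$p, tolerance = 1e-10)
  expect_true(all(rc$q >= rc$p - 1e-15, na.rm = TRUE))
  expect_error(correlate_recovery(probes, mc[, 1:3], cs[1:3]),
               class = "pairedEWAS_contract_error")
})

test_that("work_period_anova equals the pooled t-test for two groups", {
  w <- sim_world(seed = 71, n_probes = 30)
  res <- work_period_anova(w$matrix, w$sheet)
  work <- w$sheet[w$sheet$period == "work", ]
  for (j in c(1, 7, 19)) {
    y <- w$matrix[j, work$sample_id]
    tt <- stats::t.test(y[work$group == "swd"], y[work$group == "control"],
                        var.equal = TRUE)
    expect_equal(res$p[j], tt$p.value, tolerance = 1e-10)
    expect_equal(res$f[j], unname(tt$statistic)^2, tolerance = 1e-10)
  }
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  # degenerate probe: no variance anywhere
  m <- w$matrix
  m[1, ] <- 5
  res2 <- work_period_anova(m, w$sheet, rownames(m)[1])
  expect_true(is.na(res2$p))
  expect_match(res2$note, "degenerate")
  # undersized group
  sheet_small <- w$sheet[w$sheet$subject %in%
                           c(unique(w$sheet$subject[w$sheet$group == "swd"]),
                             "S022"), ]
  expect_warning(res3 <- work_period_anova(w$matrix, sheet_small),
                 class = "pairedEWAS_degenerate_warning")
  expect_true(all(is.na(res3$p)))
})

test_that("a planted work-period difference is detected (scaled-down)", {
  hits <- vapply(1:10, function(i) {
    sheet <- generate_cohort(cohort_config(seed = 1100 + i))
    ec <- effect_config(n_probes = 101, frac_affected_swd = 0,
                        recovery_probe_ids = character(0))
    sim <- generate_methylome(sheet, ec)
    m <- sim$matrix
    work_swd <- sheet$group == "swd" & sheet$period == "work"
    m[1, work_swd] <- m[1, work_swd] + 2
    res <- work_period_anova(m, sheet)
    which.min(res$p) == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("summarize_recovery counts significant hits", {
  res <- data.frame(probe_id = paste0("cg", 1:5), gene = NA,
                    r = c(-0.62, -0.49, -0.48, 0.1, 0.2),
                    p = c(0.003, 0.023, 0.026, 0.3, 0.8),
                    q = c(0.205, 0.488, 0.488, 0.6, 0.9), n = 21)
  s <- summarize_recovery(res)
  expect_equal(s$n_p_sig, 3L)
  expect_equal(s$n_q_sig, 0L)
  expect_equal(summarize_recovery(res, alpha = 1)$n_p_sig, 5L)
  s0 <- summarize_recovery(res[0, ])
  expect_equal(s0$n_tested, 0L)
  expect_equal(s0$n_p_sig, 0L)
})

test_that("embedding is deterministic, complete, and separates structure", {
  # two well-separated Gaussian clusters of samples
  set.seed(202)
  n_per <- 12
  sheet <- tiny_sheet(n_per / 2, n_per / 2)
  m <- matrix(rnorm(40 * 2 * n_per, sd = 0.3), nrow = 40,
              dimnames = list(paste0("cg", 1:40), sheet$sample_id))
  clust <- rep(c(0, 8), each = n_per)
  m <- m + matrix(clust, nrow = 40, ncol = 2 * n_per, byrow = TRUE)
  e1 <- embed_global_profiles(m, sheet, perplexity = 3, iterations = 1000,
                              seed = 4)
  e2 <- embed_global_profiles(m, sheet, perplexity = 3, iterations = 1000,
                              seed = 4)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 2 * n_per)
  # silhouette of the true cluster labels in the embedding
  xy <- as.matrix(e1[, c("x", "y")])
  d <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    own <- clust == clust[i]
    a <- mean(d[i, own & seq_along(clust) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(embed_global_profiles(m, sheet, perplexity = 10,
                                     iterations = 10, seed = 1),
               class = "pairedEWAS_contract_error")
})
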