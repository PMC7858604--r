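# Shared fixtures and independent oracles, built in code at test time.

# minimal hand-written paired sheet: n_swd + n_ctrl subjects, both periods,
# rows ordered subject-major with work first
tiny_sheet <- function(n_swd = 1L, n_ctrl = 1L) {
  n <- n_swd + n_ctrl
  subject <- sprintf("S%02d", seq_len(n))
  group <- rep(c("swd", "control"), c(n_swd, n_ctrl))
  idx <- rep(seq_len(n), each = 2L)
  data.frame(
    sample_id = paste0(subject[idx], "_", rep(c("work", "vacation"), n)),
    subject = subject[idx],
    group = group[idx],
    period = rep(c("work", "vacation"), n),
    stringsAsFactors = FALSE
  )
}

# small simulated world reused across tests
sim_world <- function(seed = 42L, n_probes = 300L, ...) {
  cc <- cohort_config(seed = seed)
  sheet <- generate_cohort(cc)
  ec <- effect_config(n_probes = n_probes, ...)
  sim <- generate_methylome(sheet, ec)
  sheet <- generate_symptoms(sheet, sim$truth, ec)
  list(sheet = sheet, matrix = sim$matrix, truth = sim$truth, effects = ec)
}

# independent OLS oracle: explicit normal equations
ols_oracle <- function(y, X) {
  beta <- solve(crossprod(X), crossprod(X, y))
  rss <- sum((y - X %*% beta)^2)
  list(beta = drop(beta), rss = rss)
}

# exhaustive hypergeometric upper-tail oracle: P(X >= ov)
hyper_tail_oracle <- function(N, K, n, ov) {
  ks <- ov:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# crafted EWAS-like result table with exact DMP / direction counts per group
crafted_table <- function(n, n_dmp_swd, n_hypo_dmp_swd, n_hypo_swd,
                          n_dmp_ctrl = 0L, n_hypo_dmp_ctrl = 0L,
                          n_hypo_ctrl = 0L) {
  mk <- function(n_dmp, n_hypo_dmp, n_hypo) {
    p <- c(rep(0.01, n_dmp), rep(0.5, n - n_dmp))
    beta <- numeric(n)
    beta[seq_len(n_hypo_dmp)] <- 1                      # hypo among DMPs
    extra <- n_hypo - n_hypo_dmp
    beta[n_dmp + seq_len(extra)] <- 1                   # hypo among non-DMPs
    beta[beta == 0] <- -1
    list(p = p, beta = beta)
  }
  s <- mk(n_dmp_swd, n_hypo_dmp_swd, n_hypo_swd)
  c2 <- mk(n_dmp_ctrl, n_hypo_dmp_ctrl, n_hypo_ctrl)
  out <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n)),
    beta_vw_swd = s$beta, beta_vw_ctrl = c2$beta,
    p_swd = s$p, p_ctrl = c2$p,
    p_either = pmin(s$p, c2$p), p_both = pmax(s$p, c2$p),
    stringsAsFactors = FALSE)
  out$dmp_swd <- out$p_swd < 0.05
  out$dmp_ctrl <- out$p_ctrl < 0.05
  out$direction_swd <- classify_direction(out$beta_vw_swd)
  out$direction_ctrl <- classify_direction(out$beta_vw_ctrl)
  class(out) <- c("ewas_result", "data.frame")
  out
}
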