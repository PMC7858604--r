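# Paired vacation-effect EWAS.
#
# Model per probe j over samples i (one work + one vacation sample per
# subject):
#
#   y_ij = (1-h_i) b_swd + h_i b_ctrl
#        + (1-h_i) v_i b_vw_swd + h_i v_i b_vw_ctrl
#        + D_i b_D + e_ij,      e iid N(0, s^2)
#
# h_i = 1 for controls, v_i = 1 for vacation samples.  The two vacation
# coefficients are the quantities of interest; four null hypotheses are
# tested by nested-model variance-ratio F tests:
#   swd:    b_vw_swd = 0                  (drop the SWD x vacation column)
#   ctrl:   b_vw_ctrl = 0                 (drop the control x vacation column)
#   either: b_vw_swd = 0 and b_vw_ctrl = 0   (2-df joint test)
#   both:   b_vw_swd = 0 or  b_vw_ctrl = 0   (union null; intersection-union
#                                             max-p construction)

CORE_COLS <- c("swd_intercept", "ctrl_intercept", "swd_vacation",
               "ctrl_vacation")

#' Build the group-specific vacation-effect design matrix
#'
#' Columns are, in order: SWD intercept `(1-h)`, control intercept `h`,
#' SWD x vacation `(1-h)v`, control x vacation `h v`, then the requested
#' nuisance covariates (age continuous as sampled; sex, plate, alcohol,
#' smoking as reference-coded indicators, lexicographically first level as
#' reference).  Constant or collinear nuisance columns are pruned with a
#' warning; the four core columns are never pruned.
#'
#' @param sheet Sample sheet (`subject`, `group`, `period`, covariates).
#' @param covariates Character vector of covariate names to include
#'   (subset of `age`, `sex`, `plate`, `alcohol`, `smoking`, or any other
#'   sheet column; numeric columns enter as-is, others as indicators).
#' @return Numeric matrix with attributes `rank` (column rank) and `pruned`
#'   (names of dropped nuisance columns).
#' @export
build_design <- function(sheet, covariates = character(0)) {
  check_sheet(sheet)
  for (g in c("swd", "control")) for (p in c("work", "vacation")) {
    if (!any(sheet$group == g & sheet$period == p)) {
      pw_stop(sprintf("design cell %s x %s has no samples", g, p),
              "pairedEWAS_design_error")
    }
  }
  h <- as.numeric(sheet$group == "control")
  v <- as.numeric(sheet$period == "vacation")
  X <- cbind(swd_intercept = 1 - h, ctrl_intercept = h,
             swd_vacation = (1 - h) * v, ctrl_vacation = h * v)

  pruned <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(sheet)) {
      pw_stop(sprintf("covariate '%s' not found in sample sheet", cv),
              "pairedEWAS_schema_error")
    }
    x <- sheet[[cv]]
    if (is.numeric(x)) {
      cols <- matrix(x, ncol = 1, dimnames = list(NULL, cv))
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2L) {
        pruned <- c(pruned, cv)
        next
      }
      cols <- vapply(lev[-1], function(l) as.numeric(x == l),
                     numeric(nrow(sheet)))
      colnames(cols) <- paste0(cv, "_", lev[-1])
    }
    keep <- apply(cols, 2L, function(z) sd(z) > 0)
    pruned <- c(pruned, colnames(cols)[!keep])
    cols <- cols[, keep, drop = FALSE]
    # greedy collinearity check against what is already in the design
    for (k in seq_len(ncol(cols))) {
      cand <- cbind(X, cols[, k])
      if (qr(cand)$rank > qr(X)$rank) {
        X <- cand
        colnames(X)[ncol(X)] <- colnames(cols)[k]
      } else {
        pruned <- c(pruned, colnames(cols)[k])
      }
    }
  }
  if (length(pruned) > 0L) {
    pw_warn(sprintf("pruned degenerate/collinear design column(s): %s",
                    paste(pruned, collapse = ", ")),
            "pairedEWAS_design_warning")
  }
  attr(X, "rank") <- qr(X)$rank
  attr(X, "pruned") <- pruned
  X
}

#' Ordinary-least-squares fit of one probe
#'
#' @param y M-value vector (one entry per design row); `NA`s are dropped
#'   together with the matching design rows (complete-case fit).
#' @param X Design matrix from [build_design()].
#' @return A `probe_fit` list: `coefficients`, `rss`, `df_resid`, `rank`,
#'   `n_used`.
#' @export
fit_probe <- function(y, X) {
  if (length(y) != nrow(X)) {
    pw_stop("length(y) must equal nrow(X)", "pairedEWAS_contract_error")
  }
  ok <- !is.na(y)
  yc <- y[ok]
  Xc <- X[ok, , drop = FALSE]
  dec <- qr(Xc)
  df <- length(yc) - dec$rank
  if (df <= 0L) {
    pw_stop(sprintf("residual df = %d <= 0 (n = %d, rank = %d)",
                    df, length(yc), dec$rank), "pairedEWAS_fit_error")
  }
  coef <- qr.coef(dec, yc)
  res <- qr.resid(dec, yc)
  structure(list(
    coefficients = coef,
    rss = sum(res^2),
    df_resid = df,
    rank = dec$rank,
    n_used = length(yc)
  ), class = "probe_fit")
}

#' Variance-ratio (F) test of nested OLS fits
#'
#' `F = ((RSS_null - RSS_full) / d_df) / (RSS_full / df_full)`, with the
#' p-value from the upper tail of the F distribution.  A saturated full fit
#' (`RSS_full = 0`) yields p = 0 when the null fits worse and p = 1 when it
#' does not, with a warning.
#'
#' @param fit_full,fit_null `probe_fit` objects, null nested in full.
#' @return The p-value.
#' @export
f_test <- function(fit_full, fit_null) {
  ddf <- fit_null$df_resid - fit_full$df_resid
  if (ddf <= 0L) {
    pw_stop("null model is not nested in the full model (no df difference)",
            "pairedEWAS_contract_error")
  }
  if (fit_null$rss < fit_full$rss - 1e-8 * max(1, fit_full$rss)) {
    pw_stop("RSS_null < RSS_full: models are not nested",
            "pairedEWAS_contract_error")
  }
  if (fit_full$rss <= 0) {
    pw_warn("saturated full model (RSS = 0); F test degenerate",
            "pairedEWAS_fit_warning")
    return(if (fit_null$rss > 0) 0 else 1)
  }
  f <- ((fit_null$rss - fit_full$rss) / ddf) / (fit_full$rss / fit_full$df_resid)
  pf(f, ddf, fit_full$df_resid, lower.tail = FALSE)
}

#' Test the four vacation-effect null hypotheses for one probe
#'
#' @inheritParams fit_probe
#' @return Named numeric: `p_swd`, `p_ctrl`, `p_either`, `p_both`.
#'   `p_both = max(p_swd, p_ctrl)` (intersection-union test of the union
#'   null "no effect in at least one group").
#' @export
test_probe_hypotheses <- function(y, X) {
  full <- fit_probe(y, X)
  drop_fit <- function(cols) fit_probe(y, X[, setdiff(colnames(X), cols),
                                             drop = FALSE])
  p_swd <- f_test(full, drop_fit("swd_vacation"))
  p_ctrl <- f_test(full, drop_fit("ctrl_vacation"))
  p_either <- f_test(full, drop_fit(c("swd_vacation", "ctrl_vacation")))
  c(p_swd = p_swd, p_ctrl = p_ctrl, p_either = p_either,
    p_both = max(p_swd, p_ctrl))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up construction with enforced monotonicity
#' (`q_(i) = min_{k >= i} p_(k) n / k`, capped at 1), order-preserving in the
#' input; `NA`s are carried through and excluded from the family size.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    pw_stop("p-values must lie in [0, 1]", "pairedEWAS_contract_error")
  }
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  n <- length(pp)
  if (n > 0L) {
    o <- order(pp)
    qq <- pmin(1, rev(cummin(rev(pp[o] * n / seq_len(n)))))
    q[ok][o] <- qq
  }
  q
}

#' Classify the direction of the vacation effect
#'
#' A positive vacation-minus-work coefficient means methylation is gained on
#' vacation, i.e. the probe is hypomethylated during work; a negative one
#' means hypermethylated during work; exactly zero is unclassified.
#'
#' @param beta_vw Vacation-minus-work coefficient(s), M-value units.
#' @return Character vector: `"hypo_at_work"`, `"hyper_at_work"`, `"none"`.
#' @export
classify_direction <- function(beta_vw) {
  out <- rep(NA_character_, length(beta_vw))
  out[!is.na(beta_vw) & beta_vw > 0] <- "hypo_at_work"
  out[!is.na(beta_vw) & beta_vw < 0] <- "hyper_at_work"
  out[!is.na(beta_vw) & beta_vw == 0] <- "none"
  out
}

# residual sums of squares for every probe at once, via the thin-Q trick:
# RSS = |y|^2 - |Q'y|^2 for Q an orthonormal basis of col(X)
rss_all <- function(Y, X) {
  Q <- qr.Q(qr(X))
  colSums(Y^2) - colSums(crossprod(Q, Y)^2)
}

#' Run the paired EWAS over a methylome matrix
#'
#' Fits the group-specific vacation-effect model to every probe, tests the
#' four null hypotheses, adjusts each hypothesis family separately with
#' Benjamini-Hochberg across probes, flags differentially methylated
#' positions (DMPs, unadjusted p < `alpha` per group), and classifies the
#' direction of the effect.  Probes with zero variance are skipped (the F
#' statistic is undefined); probes with missing values are fitted on
#' complete cases when at least `rank + 2` observations remain, otherwise
#' skipped.  Skipped probes are recorded in `attr(, "skipped")`.
#'
#' @param matrix Probes x samples M-value matrix with probe rownames and
#'   sample-id colnames.
#' @param sheet Sample sheet; `sample_id` must match the matrix columns 1:1.
#' @param covariates Covariate names passed to [build_design()].
#' @param alpha Unadjusted significance threshold defining a DMP.
#' @return A `data.frame` of class `ewas_result`, one row per retained
#'   probe: coefficients (`beta_swd_work`, `beta_ctrl_work`, `beta_vw_swd`,
#'   `beta_vw_ctrl`), p-values and q-values for the four hypotheses, DMP
#'   flags and direction labels per group.
#' @export
run_ewas <- function(matrix, sheet,
                     covariates = c("age", "sex", "plate", "alcohol",
                                    "smoking"),
                     alpha = 0.05) {
  check_sheet(sheet)
  orphans_m <- setdiff(colnames(matrix), sheet$sample_id)
  orphans_s <- setdiff(sheet$sample_id, colnames(matrix))
  if (length(orphans_m) > 0L || length(orphans_s) > 0L) {
    pw_stop(sprintf(
      "sample mismatch between matrix and sheet; matrix-only: [%s], sheet-only: [%s]",
      paste(orphans_m, collapse = ", "), paste(orphans_s, collapse = ", ")),
      "pairedEWAS_alignment_error")
  }
  matrix <- matrix[, sheet$sample_id, drop = FALSE]
  covariates <- intersect(covariates, names(sheet))
  X <- suppressWarnings(build_design(sheet, covariates))

  empty <- data.frame(
    probe_id = character(0), beta_swd_work = numeric(0),
    beta_ctrl_work = numeric(0), beta_vw_swd = numeric(0),
    beta_vw_ctrl = numeric(0), p_swd = numeric(0), p_ctrl = numeric(0),
    p_either = numeric(0), p_both = numeric(0), stringsAsFactors = FALSE)
  if (nrow(matrix) == 0L) {
    return(finish_ewas_table(empty, alpha, X))
  }

  probes <- rownames(matrix) %||% probe_ids_for(nrow(matrix))
  n_na <- rowSums(is.na(matrix))
  vr <- apply(matrix, 1L, function(r) var(r, na.rm = TRUE))
  zero_var <- !is.na(vr) & vr == 0
  skipped <- data.frame(probe_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (any(zero_var)) {
    skipped <- rbind(skipped, data.frame(probe_id = probes[zero_var],
                                         reason = "zero variance"))
  }

  rk <- attr(X, "rank")
  Xd <- list(
    full = X,
    swd = X[, setdiff(colnames(X), "swd_vacation"), drop = FALSE],
    ctrl = X[, setdiff(colnames(X), "ctrl_vacation"), drop = FALSE],
    either = X[, setdiff(colnames(X), c("swd_vacation", "ctrl_vacation")),
               drop = FALSE]
  )

  res <- NULL
  complete <- n_na == 0L & !zero_var
  if (any(complete)) {
    Y <- t(matrix[complete, , drop = FALSE])
    dec <- qr(X)
    B <- qr.coef(dec, Y)
    rss <- lapply(Xd, function(x) pmax(0, rss_all(Y, x)))
    dff <- nrow(X) - rk
    fp <- function(r0, ddf) {
      f <- ((r0 - rss$full) / ddf) / (rss$full / dff)
      p <- pf(f, ddf, dff, lower.tail = FALSE)
      # saturated fits: p = 0 if the null fits worse, else 1
      sat <- rss$full <= 1e-12
      p[sat] <- ifelse(r0[sat] > 1e-12, 0, 1)
      p
    }
    p_swd <- fp(rss$swd, 1L)
    p_ctrl <- fp(rss$ctrl, 1L)
    p_either <- fp(rss$either, 2L)
    res <- data.frame(
      probe_id = probes[complete],
      beta_swd_work = B["swd_intercept", ],
      beta_ctrl_work = B["ctrl_intercept", ],
      beta_vw_swd = B["swd_vacation", ],
      beta_vw_ctrl = B["ctrl_vacation", ],
      p_swd = p_swd, p_ctrl = p_ctrl, p_either = p_either,
      p_both = pmax(p_swd, p_ctrl),
      stringsAsFactors = FALSE, row.names = NULL)
  }

  incomplete <- which(n_na > 0L & !zero_var)
  for (i in incomplete) {
    y <- matrix[i, ]
    if (sum(!is.na(y)) < rk + 2L) {
      skipped <- rbind(skipped, data.frame(probe_id = probes[i],
                                           reason = "too few complete cases"))
      next
    }
    p <- tryCatch(suppressWarnings(test_probe_hypotheses(y, X)),
                  error = function(e) NULL)
    if (is.null(p)) {
      skipped <- rbind(skipped, data.frame(probe_id = probes[i],
                                           reason = "fit failed"))
      next
    }
    fit <- fit_probe(y, X)
    res <- rbind(res, data.frame(
      probe_id = probes[i],
      beta_swd_work = fit$coefficients[["swd_intercept"]],
      beta_ctrl_work = fit$coefficients[["ctrl_intercept"]],
      beta_vw_swd = fit$coefficients[["swd_vacation"]],
      beta_vw_ctrl = fit$coefficients[["ctrl_vacation"]],
      p_swd = p[["p_swd"]], p_ctrl = p[["p_ctrl"]],
      p_either = p[["p_either"]], p_both = p[["p_both"]],
      stringsAsFactors = FALSE, row.names = NULL))
  }
  if (is.null(res)) res <- empty
  res <- res[match(intersect(probes, res$probe_id), res$probe_id), ]
  rownames(res) <- NULL
  out <- finish_ewas_table(res, alpha, X)
  attr(out, "skipped") <- skipped
  out
}

finish_ewas_table <- function(res, alpha, X) {
  res$q_swd <- bh_adjust(res$p_swd)
  res$q_ctrl <- bh_adjust(res$p_ctrl)
  res$q_either <- bh_adjust(res$p_either)
  res$q_both <- bh_adjust(res$p_both)
  res$dmp_swd <- res$p_swd < alpha
  res$dmp_ctrl <- res$p_ctrl < alpha
  res$direction_swd <- classify_direction(res$beta_vw_swd)
  res$direction_ctrl <- classify_direction(res$beta_vw_ctrl)
  attr(res, "alpha") <- alpha
  attr(res, "design_rank") <- attr(X, "rank")
  class(res) <- c("ewas_result", "data.frame")
  res
}

#' Summarize an EWAS result table
#'
#' Per group: probe and DMP counts, the DMP percentage (one decimal), and
#' hypomethylated-during-work counts/percentages overall and among DMPs
#' (integer percent, the style used in prose summaries).  Percentages with a
#' zero denominator are reported as missing.
#'
#' @param table An `ewas_result` table.
#' @param alpha DMP threshold (unadjusted p).
#' @return A list of class `ewas_summary` with one entry per group.
#' @export
summarize_ewas <- function(table, alpha = 0.05) {
  one <- function(p, dir) {
    n <- length(p)
    dmp <- !is.na(p) & p < alpha
    hypo <- !is.na(dir) & dir == "hypo_at_work"
    list(
      n_probes = n,
      n_dmp = sum(dmp),
      pct_dmp = pct1(sum(dmp), n),
      n_hypo = sum(hypo),
      pct_hypo = pct0(sum(hypo), n),
      n_hypo_dmp = sum(hypo & dmp),
      pct_hypo_dmp = pct0(sum(hypo & dmp), sum(dmp))
    )
  }
  structure(list(
    swd = one(table$p_swd, table$direction_swd),
    control = one(table$p_ctrl, table$direction_ctrl),
    alpha = alpha
  ), class = "ewas_summary")
}

#' @export
print.ewas_summary <- function(x, ...) {
  for (g in c("swd", "control")) {
    s <- x[[g]]
    cat(sprintf(
      "%-8s %s/%s DMPs (%.1f%%); hypomethylated at work: %s%% of probes, %s%% of DMPs\n",
      g, format(s$n_dmp, big.mark = ","), format(s$n_probes, big.mark = ","),
      s$pct_dmp, s$pct_hypo,
      ifelse(is.na(s$pct_hypo_dmp), "NA", s$pct_hypo_dmp)))
  }
  invisible(x)
}

#' Quantile-quantile points for a p-value family
#'
#' Observed p-values sorted ascending against the uniform expectation
#' `(k - 0.5) / n`, both on the `-log10` scale.
#'
#' @param p Non-empty p-value vector (`NA`s dropped).
#' @return `data.frame` with columns `expected` and `observed`.
#' @export
qq_points <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) {
    pw_stop("no p-values to plot", "pairedEWAS_contract_error")
  }
  n <- length(p)
  data.frame(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(p))
  )
}
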