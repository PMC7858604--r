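# Post-hoc recovery analyses: symptom change scores, recovery grouping,
# probe-wise Spearman correlation of methylation change with symptom change,
# one-way ANOVA at the working period, and summary reporting.

#' Questionnaire symptom change score
#'
#' `CHANGE_SYMPTOMS = (A + B)_work - (A + B)_vacation` for the two Likert
#' recovery questions; positive values mean more symptoms at work than
#' after vacation (i.e. improvement on vacation).  Vectorized; any missing
#' answer gives `NA` (the subject is excluded downstream).
#'
#' @param a_work,b_work,a_vacation,b_vacation Likert answers (1-5).
#' @return Integer change score(s).
#' @export
change_symptoms <- function(a_work, b_work, a_vacation, b_vacation) {
  as.integer((a_work + b_work) - (a_vacation + b_vacation))
}

#' Per-subject symptom change from a sample sheet
#'
#' @param sheet Sample sheet with filled `answer_a`, `answer_b`.
#' @return Named integer vector (subject -> change score; `NA` when an
#'   answer is missing).
#' @export
symptom_change <- function(sheet) {
  check_sheet(sheet)
  w <- sheet[sheet$period == "work", ]
  v <- sheet[sheet$period == "vacation", ]
  subjects <- intersect(w$subject, v$subject)
  iw <- match(subjects, w$subject)
  iv <- match(subjects, v$subject)
  setNames(change_symptoms(w$answer_a[iw], w$answer_b[iw],
                           v$answer_a[iv], v$answer_b[iv]),
           subjects)
}

#' Per-subject methylation change matrix
#'
#' `CHANGE_METHYLATION = M_work - M_vacation` per probe and subject, for
#' subjects with both samples present.
#'
#' @param matrix Probes x samples M-value matrix.
#' @param sheet Sample sheet.
#' @return Probes x subjects numeric matrix.
#' @export
methylation_change <- function(matrix, sheet) {
  check_sheet(sheet)
  w <- sheet[sheet$period == "work", ]
  v <- sheet[sheet$period == "vacation", ]
  subjects <- intersect(w$subject, v$subject)
  chg <- matrix[, w$sample_id[match(subjects, w$subject)], drop = FALSE] -
    matrix[, v$sample_id[match(subjects, v$subject)], drop = FALSE]
  colnames(chg) <- subjects
  chg
}

#' Assign recovery groups from symptom change scores
#'
#' Higher change scores mean better recovery.  With explicit `thresholds =
#' c(poor_max, recovered_max)`, scores `<= poor_max` are "poor", scores
#' `<= recovered_max` are "recovered", the rest "well".  Default: tertile
#' cutpoints (lower empirical third poor, middle recovered, upper well),
#' with ties going to the lower group.  Labels depend only on score values,
#' never on input order.
#'
#' @param scores Named numeric vector (subject -> change score).
#' @param thresholds Optional length-2 numeric cutpoints.
#' @return Named factor with levels `poor < recovered < well`.
#' @export
assign_recovery_groups <- function(scores, thresholds = NULL) {
  s <- scores[!is.na(scores)]
  if (is.null(thresholds)) {
    if (length(s) < 3L) {
      pw_stop("need >= 3 scored subjects for tertile grouping (or explicit thresholds)",
              "pairedEWAS_contract_error")
    }
    thresholds <- unname(quantile(s, c(1, 2) / 3, type = 1))
    if (length(unique(s)) == 1L) {
      pw_warn("all symptom change scores identical; single recovery group",
              "pairedEWAS_degenerate_warning")
    }
  }
  lab <- ifelse(scores <= thresholds[1], "poor",
                ifelse(scores <= thresholds[2], "recovered", "well"))
  setNames(factor(lab, levels = c("poor", "recovered", "well")),
           names(scores))
}

# Cache of full permutation matrices for the exact Spearman test (n < 10).
.perm_cache <- new.env(parent = emptyenv())

perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  pm <- if (n == 1L) matrix(1L) else {
    sub <- perm_matrix(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(i, matrix(rest[sub], nrow(sub)))
    }))
  }
  .perm_cache[[key]] <- pm
  pm
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Ties are handled by average ranks.  The two-tailed p-value comes from
#' exhaustive permutation enumeration for `n < 10` and from the
#' t-approximation `t = r sqrt((n-2)/(1-r^2))` otherwise.  Zero variance in
#' either vector gives `r = NA`, `p = NA`.
#'
#' @param x,y Numeric vectors of equal length (pairs with any `NA` dropped).
#' @return List with `r`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (n < 10L) {
    pm <- perm_matrix(n)
    ry_perm <- matrix(ry[pm], nrow(pm))
    s <- as.numeric(ry_perm %*% (rx - mean(rx)))
    r_perm <- s / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    p <- mean(abs(r_perm) >= abs(r) - 1e-12)
  } else {
    tt <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
    p <- 2 * pt(-abs(tt), n - 2)
  }
  list(r = r, p = min(1, p), n = n)
}

#' Correlate methylation change with symptom change across subjects
#'
#' For each probe in `dmps`, the Spearman correlation between the subjects'
#' `CHANGE_METHYLATION` and `CHANGE_SYMPTOMS`, two-tailed p, and BH q across
#' the probe set.  Intended for the SWD subjects (pass SWD subject ids via
#' `subjects` or pre-restricted inputs); subjects with a missing score are
#' dropped.
#'
#' @param dmps Character vector of probe ids to test.
#' @param changes Probes x subjects change matrix from
#'   [methylation_change()].
#' @param scores Named subject change scores from [symptom_change()].
#' @param subjects Optional subject ids to restrict to (e.g. the SWD group).
#' @param annotation Optional probe annotation used to attach gene symbols.
#' @return `data.frame`: `probe_id`, `gene`, `r`, `p`, `q`, `n`.
#' @export
correlate_recovery <- function(dmps, changes, scores, subjects = NULL,
                               annotation = NULL) {
  subjects <- subjects %||% intersect(colnames(changes), names(scores))
  subjects <- intersect(subjects, intersect(colnames(changes), names(scores)))
  subjects <- subjects[!is.na(scores[subjects])]
  if (length(subjects) < 4L) {
    pw_stop("need >= 4 subjects with both change scores",
            "pairedEWAS_contract_error")
  }
  missing <- setdiff(dmps, rownames(changes))
  if (length(missing) > 0L) {
    pw_stop(sprintf("probe(s) not in change matrix: %s",
                    paste(head(missing, 5), collapse = ", ")),
            "pairedEWAS_contract_error")
  }
  sy <- as.numeric(scores[subjects])
  rows <- lapply(dmps, function(pr) {
    st <- spearman_test(changes[pr, subjects], sy)
    data.frame(probe_id = pr, r = st$r, p = st$p, n = st$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$gene <- if (!is.null(annotation)) {
    idx <- match(res$probe_id, annotation$probe_id)
    annotation$gene_symbols[idx]
  } else NA_character_
  res <- res[, c("probe_id", "gene", "r", "p", "q", "n")]
  rownames(res) <- NULL
  res
}

#' One-way ANOVA of working-period methylation across groups
#'
#' For each requested probe, a one-way ANOVA of the M-values measured during
#' the working period across a grouping factor (default: SWD vs control;
#' pass a subject-named vector for e.g. the three recovery groups plus
#' controls), with BH adjustment across tested probes.  A grouping level
#' with fewer than 2 work samples invalidates the test (all rows flagged).
#'
#' @param matrix Probes x samples M-value matrix.
#' @param sheet Sample sheet.
#' @param dmps Probe ids to test (default: all rows of `matrix`).
#' @param grouping Either `NULL` (uses `sheet$group`) or a vector of labels
#'   named by subject.
#' @return `data.frame`: `probe_id`, `f`, `p`, `q`, `note`.
#' @export
work_period_anova <- function(matrix, sheet, dmps = rownames(matrix),
                              grouping = NULL) {
  check_sheet(sheet)
  w <- sheet[sheet$period == "work", ]
  g <- if (is.null(grouping)) w$group else as.character(grouping[w$subject])
  keep <- !is.na(g)
  w <- w[keep, ]; g <- g[keep]
  tab <- table(g)
  if (length(tab) < 2L) {
    pw_stop("need >= 2 groups for ANOVA", "pairedEWAS_contract_error")
  }
  small <- names(tab)[tab < 2L]
  Y <- matrix[dmps, w$sample_id, drop = FALSE]
  if (length(small) > 0L) {
    pw_warn(sprintf("group(s) with < 2 work samples: %s",
                    paste(small, collapse = ", ")),
            "pairedEWAS_degenerate_warning")
    res <- data.frame(probe_id = dmps, f = NA_real_, p = NA_real_,
                      q = NA_real_,
                      note = sprintf("group '%s' has < 2 samples", small[1]),
                      stringsAsFactors = FALSE)
    return(res)
  }
  gf <- factor(g)
  k <- nlevels(gf)
  N <- ncol(Y)
  counts <- as.numeric(tab[levels(gf)])
  gm <- rowsum(t(Y), gf) / counts          # k x probes group means
  grand <- rowMeans(Y)                     # per-probe grand mean
  ssb <- colSums(counts * sweep(gm, 2L, grand)^2)
  sst <- rowSums((Y - grand)^2)
  ssw <- pmax(0, sst - ssb)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(f, k - 1, N - k, lower.tail = FALSE)
  note <- rep("", length(dmps))
  deg <- ssw <= 1e-12
  if (any(deg)) {
    note[deg & ssb > 1e-12] <- "zero within-group variance"
    p[deg & ssb > 1e-12] <- 0
    f[deg & ssb > 1e-12] <- Inf
    note[deg & ssb <= 1e-12] <- "degenerate: no variance"
    p[deg & ssb <= 1e-12] <- NA
    f[deg & ssb <= 1e-12] <- NA
  }
  data.frame(probe_id = dmps, f = f, p = p, q = bh_adjust(p), note = note,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize a recovery correlation table
#'
#' @param results Table from [correlate_recovery()].
#' @param alpha Significance threshold.
#' @return List of class `recovery_summary`: `n_tested`, `n_p_sig`
#'   (p < alpha), `n_q_sig` (q < alpha), and the top hits sorted by p.
#' @export
summarize_recovery <- function(results, alpha = 0.05) {
  sig <- !is.na(results$p) & results$p < alpha
  top <- results[order(results$p), , drop = FALSE]
  structure(list(
    n_tested = nrow(results),
    n_p_sig = sum(sig),
    n_q_sig = sum(!is.na(results$q) & results$q < alpha),
    alpha = alpha,
    top = head(top, 10L)
  ), class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("recovery correlations: %d tested, %d at p < %g, %d at q < %g\n",
              x$n_tested, x$n_p_sig, x$alpha, x$n_q_sig, x$alpha))
  if (nrow(x$top) > 0L) {
    print(utils::head(x$top, 5L), row.names = FALSE)
  }
  invisible(x)
}
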