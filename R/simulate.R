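# Synthetic paired methylome cohorts.
#
# Randomness discipline: every generator draws from its own RNG stream
# derived from the root seed with sub_seed(seed, k):
#   k = 1 cohort, 2 methylome, 3 symptoms, 4 annotation/GMT.
# Adding draws to one generator therefore never shifts another's output.

probe_ids_for <- function(n) sprintf("cg%08d", seq_len(n))

#' Generate a paired work/vacation sample sheet
#'
#' Draws a synthetic cohort of shift workers (SWD cases and controls), two
#' blood samples per subject (one during a working period, one at the end of
#' a vacation), with ages, sex, plate assignment and lifestyle covariates.
#' Covariates are constant within subject across periods except the plate,
#' which is drawn per sample: the two draws are months apart and may land on
#' different array plates.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` (sample sheet) with one row per sample and columns
#'   `sample_id`, `subject`, `group` (`"swd"`/`"control"`), `period`
#'   (`"work"`/`"vacation"`), `age`, `sex`, `plate`, `alcohol`, `smoking`,
#'   and empty symptom answer columns `answer_a`, `answer_b` (filled by
#'   [generate_symptoms()]).  The root seed is kept in `attr(, "seed")`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    pw_stop("'config' must be a cohort_config object", "pairedEWAS_config_error")
  }
  n_sub <- config$n_swd + config$n_control
  with_seed(sub_seed(config$seed, 1L), {
    subject <- sprintf("S%03d", seq_len(n_sub))
    group <- rep(c("swd", "control"), c(config$n_swd, config$n_control))
    age <- round(c(
      rnorm(config$n_swd, config$age_mean_swd, config$age_sd_swd),
      rnorm(config$n_control, config$age_mean_ctrl, config$age_sd_ctrl)
    ), 1)
    age <- pmin(pmax(age, 20), 65)      # working-age plausibility clamp
    sex <- ifelse(rbinom(n_sub, 1L, config$frac_female) == 1L,
                  "female", "male")
    alcohol <- ifelse(rbinom(n_sub, 1L, config$frac_alcohol) == 1L, "yes", "no")
    smoking <- ifelse(rbinom(n_sub, 1L, config$frac_smokers) == 1L, "yes", "no")

    idx <- rep(seq_len(n_sub), each = 2L)
    period <- rep(c("work", "vacation"), n_sub)
    plate <- sprintf("P%d", sample.int(config$n_plates, 2L * n_sub,
                                       replace = TRUE))
    sheet <- data.frame(
      sample_id = sprintf("%s_%s", subject[idx], period),
      subject = subject[idx],
      group = group[idx],
      period = period,
      age = age[idx],
      sex = sex[idx],
      plate = plate,
      alcohol = alcohol[idx],
      smoking = smoking[idx],
      answer_a = NA_integer_,
      answer_b = NA_integer_,
      stringsAsFactors = FALSE
    )
    attr(sheet, "seed") <- config$seed
    sheet
  })
}

# floor(frac * n) indices drawn without replacement: the exact, testable
# materialization rule for "fraction of probes affected".
pick_floor_frac <- function(n, frac, from = seq_len(n)) {
  k <- floor(frac * n)
  if (k == 0L) return(integer(0))
  sort(sample(from, k))
}

#' Generate a synthetic M-value methylome with planted vacation effects
#'
#' Simulates a probes x samples M-value matrix over a paired sample sheet:
#' per-probe baselines drawn from a bimodal mixture (mimicking the
#' methylated/unmethylated modes of array M-values), planted vacation
#' effects per group, optional nuisance-covariate effects, an optional
#' subject-level random intercept, and iid Gaussian noise.  Affected probes
#' are materialized as `floor(frac * n_probes)` draws without replacement;
#' the positive (gain-on-vacation) subset uses the same floor rule.
#'
#' Designated recovery probes additionally carry a subject-varying SWD
#' vacation effect `beta_j + effect_size_mean * g_i`, where `g_i` is the
#' subject's latent recovery degree; [generate_symptoms()] links the
#' questionnaire change score to this planted change.
#'
#' @param sheet Sample sheet from [generate_cohort()].
#' @param effects An [effect_config()].
#' @param seed Optional override; defaults to the sheet's root seed.
#' @return A list with `matrix` (probes x samples, M-values, dimnames set)
#'   and `truth`, a `synthetic_truth` object recording the planted per-group
#'   coefficients, affected flags, recovery probes, latent recovery degrees,
#'   and the planted per-subject work-minus-vacation change at the recovery
#'   probes.
#' @export
generate_methylome <- function(sheet, effects, seed = attr(sheet, "seed")) {
  if (!inherits(effects, "effect_config")) {
    pw_stop("'effects' must be an effect_config object", "pairedEWAS_config_error")
  }
  check_sheet(sheet)
  J <- effects$n_probes
  n <- nrow(sheet)
  probes <- probe_ids_for(J)
  subjects <- unique(sheet$subject)
  swd_subjects <- unique(sheet$subject[sheet$group == "swd"])

  with_seed(sub_seed(seed %||% 1L, 2L), {
    affected_swd <- logical(J)
    affected_swd[pick_floor_frac(J, effects$frac_affected_swd)] <- TRUE
    affected_ctrl <- logical(J)
    affected_ctrl[pick_floor_frac(J, effects$frac_affected_ctrl)] <- TRUE

    draw_betas <- function(affected, frac_pos) {
      beta <- numeric(J)
      k <- sum(affected)
      if (k > 0L) {
        mag <- abs(rnorm(k, effects$effect_size_mean, effects$effect_size_sd))
        sign <- rep(-1, k)
        sign[pick_floor_frac(k, frac_pos)] <- 1
        beta[affected] <- sign * mag
      }
      beta
    }
    beta_swd <- draw_betas(affected_swd, effects$frac_positive_swd)
    beta_ctrl <- draw_betas(affected_ctrl, effects$frac_positive_ctrl)

    # designated recovery probes: default = up to 3 positive affected SWD
    # probes; character(0) disables the recovery link entirely
    rec <- effects$recovery_probe_ids
    if (is.null(rec)) {
      cand <- probes[affected_swd & beta_swd > 0]
      rec <- head(cand, 3L)
    }
    rec <- intersect(rec, probes)

    g <- setNames(rnorm(length(swd_subjects)), swd_subjects)

    # baseline M-values: methylated / unmethylated / intermediate modes
    mode <- sample.int(3L, J, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    mu <- rnorm(J, mean = c(-3, 3, 0)[mode], sd = 1)

    v <- as.numeric(sheet$period == "vacation")
    is_swd <- sheet$group == "swd"
    eff <- outer(beta_swd, v * is_swd) + outer(beta_ctrl, v * !is_swd)

    tau <- effects$effect_size_mean
    if (length(rec) > 0L) {
      ji <- match(rec, probes)
      for (s in swd_subjects) {
        cols <- which(sheet$subject == s & sheet$period == "vacation")
        eff[ji, cols] <- eff[ji, cols] + tau * g[[s]]
      }
    }

    # nuisance effects on standardized covariates
    D <- covariate_matrix(sheet)
    if (ncol(D) > 0L && effects$covariate_effect_scale > 0) {
      beta_D <- matrix(rnorm(J * ncol(D), 0, effects$covariate_effect_scale),
                       nrow = J)
      eff <- eff + beta_D %*% t(D)
    }

    if (effects$subject_intercept_sd > 0) {
      b <- setNames(rnorm(length(subjects), 0, effects$subject_intercept_sd),
                    subjects)
      eff <- eff + matrix(b[sheet$subject], nrow = J, ncol = n, byrow = TRUE)
    }

    y <- mu + eff + matrix(rnorm(J * n, 0, effects$noise_sd), nrow = J)
    dimnames(y) <- list(probes, sheet$sample_id)

    planted_change <- NULL
    if (length(rec) > 0L) {
      # planted work - vacation change per SWD subject at recovery probes
      ji <- match(rec, probes)
      planted_change <- -(matrix(beta_swd[ji], length(rec), length(swd_subjects)) +
                            tau * matrix(g, length(rec), length(swd_subjects),
                                         byrow = TRUE))
      dimnames(planted_change) <- list(rec, swd_subjects)
    }

    truth <- structure(list(
      probe_ids = probes,
      beta_vw_swd = beta_swd,
      beta_vw_ctrl = beta_ctrl,
      affected_swd = affected_swd,
      affected_ctrl = affected_ctrl,
      recovery_probe_ids = rec,
      recovery_degree = g,
      planted_recovery_change = planted_change,
      effects = effects
    ), class = "synthetic_truth")

    list(matrix = y, truth = truth)
  })
}

# standardized numeric covariate matrix used for planting nuisance effects
covariate_matrix <- function(sheet) {
  age <- sheet$age
  age_z <- if (sd(age) > 0) (age - mean(age)) / sd(age) else age * 0
  cols <- list(
    age = age_z,
    sex_female = as.numeric(sheet$sex == "female"),
    alcohol = as.numeric(sheet$alcohol == "yes"),
    smoking = as.numeric(sheet$smoking == "yes")
  )
  plates <- sort(unique(sheet$plate))
  for (p in plates[-1]) {
    cols[[paste0("plate_", p)]] <- as.numeric(sheet$plate == p)
  }
  keep <- vapply(cols, function(x) sd(x) > 0, logical(1))
  do.call(cbind, cols[keep])
}

#' Generate questionnaire symptom answers linked to planted recovery
#'
#' Fills the sample sheet's Likert answers to the two recovery questions
#' ("How often do you not feel fresh after sleep?", "How often do you feel
#' daytime sleepiness?", both 1-5) so that the derived change score
#' `CHANGE_SYMPTOMS = (A+B)_work - (A+B)_vacation` correlates, across SWD
#' subjects, with the planted work-to-vacation M-value change at the
#' designated recovery probes with magnitude approximately
#' `recovery_link_strength` (negative sign: more methylation regained on
#' vacation goes with a larger symptom improvement).  Answers are clamped to
#' the 1-5 scale after the linear link; controls receive unlinked answers.
#'
#' @param sheet Sample sheet from [generate_cohort()].
#' @param truth `synthetic_truth` from [generate_methylome()].
#' @param effects The same [effect_config()] used to generate the methylome.
#' @param seed Optional override; defaults to the sheet's root seed.
#' @return The sample sheet with `answer_a`, `answer_b` filled.
#' @export
generate_symptoms <- function(sheet, truth, effects,
                              seed = attr(sheet, "seed")) {
  check_sheet(sheet)
  subjects <- unique(sheet$subject)
  swd_subjects <- names(truth$recovery_degree)
  s <- effects$recovery_link_strength

  with_seed(sub_seed(seed %||% 1L, 3L), {
    z <- setNames(rnorm(length(subjects)), subjects)
    if (length(truth$recovery_probe_ids) > 0L && s > 0 &&
        length(swd_subjects) > 1L) {
      # latent recovery signal = planted vacation gain at recovery probes
      gain <- colMeans(-truth$planted_recovery_change)
      gain <- (gain - mean(gain)) / sd(gain)
      z[swd_subjects] <- s * gain + sqrt(1 - s^2) * z[swd_subjects]
    }
    change_total <- pmin(4L, pmax(-4L, as.integer(round(2 * z))))

    a_vac <- setNames(sample(1:3, length(subjects), replace = TRUE), subjects)
    b_vac <- setNames(sample(1:3, length(subjects), replace = TRUE), subjects)
    clamp <- function(x) setNames(pmin(5L, pmax(1L, as.integer(x))), names(x))
    a_work <- clamp(a_vac + ceiling(change_total / 2))
    b_work <- clamp(b_vac + floor(change_total / 2))

    work <- sheet$period == "work"
    sheet$answer_a <- ifelse(work, a_work[sheet$subject], clamp(a_vac)[sheet$subject])
    sheet$answer_b <- ifelse(work, b_work[sheet$subject], clamp(b_vac)[sheet$subject])
    sheet
  })
}

#' Generate a probe annotation table and a matching GMT gene-set library
#'
#' Builds a synthetic 450K-style annotation (probe id, chromosome, 1-based
#' coordinate, semicolon-joined gene symbols) plus a gene-set library whose
#' pathways draw from the annotated genes, so that pathway CpG universes have
#' the scale of real array pathways (for example 15 genes x ~30 probes each
#' gives a universe of a few hundred CpGs).  A small fraction of probes
#' (5%) is annotated to two genes to exercise deduplication rules.
#'
#' @param n_probes,n_genes,n_pathways Counts (>= 1).
#' @param probes_per_gene Probes assigned per gene (genes get fewer if
#'   probes run out).
#' @param genes_per_pathway Genes per pathway (capped at `n_genes`).
#' @param seed Integer seed (own stream; byte-identical output per seed).
#' @return A list with `annotation` (data.frame: `probe_id`, `chr`,
#'   `pos_1based`, `gene_symbols`) and `gmt` (named list of character gene
#'   vectors with a `description` attribute).
#' @export
generate_annotation_and_gmt <- function(n_probes, n_genes, n_pathways,
                                        probes_per_gene = 30L,
                                        genes_per_pathway = 15L,
                                        seed = 1L) {
  n_probes <- check_count(n_probes, "n_probes")
  n_genes <- check_count(n_genes, "n_genes")
  n_pathways <- check_count(n_pathways, "n_pathways")
  probes_per_gene <- check_count(probes_per_gene, "probes_per_gene")
  genes_per_pathway <- min(check_count(genes_per_pathway, "genes_per_pathway"),
                           n_genes)
  probes <- probe_ids_for(n_probes)
  genes <- sprintf("GENE%04d", seq_len(n_genes))

  with_seed(sub_seed(seed, 4L), {
    gene_of <- rep(NA_character_, n_probes)
    ord <- sample.int(n_probes)
    take <- min(n_probes, n_genes * probes_per_gene)
    gene_of[ord[seq_len(take)]] <-
      genes[ceiling(seq_len(take) / probes_per_gene)]

    second <- !is.na(gene_of) & runif(n_probes) < 0.05 & n_genes > 1L
    sym <- gene_of
    if (any(second)) {
      extra <- vapply(gene_of[second], function(g) {
        sample(setdiff(genes, g), 1L)
      }, character(1))
      sym[second] <- paste(gene_of[second], extra, sep = ";")
    }
    sym[is.na(sym)] <- ""

    annotation <- data.frame(
      probe_id = probes,
      chr = as.character(sample(1:22, n_probes, replace = TRUE)),
      pos_1based = sample.int(2.8e8, n_probes, replace = TRUE),
      gene_symbols = sym,
      stringsAsFactors = FALSE
    )

    gmt <- lapply(seq_len(n_pathways), function(i) {
      sort(sample(genes, genes_per_pathway))
    })
    names(gmt) <- sprintf("PW%03d", seq_len(n_pathways))
    attr(gmt, "description") <- setNames(
      rep("synthetic pathway", n_pathways), names(gmt))
    list(annotation = annotation, gmt = gmt)
  })
}

check_sheet <- function(sheet) {
  required <- c("sample_id", "subject", "group", "period")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    pw_stop(sprintf("sample sheet is missing column(s): %s",
                    paste(missing, collapse = ", ")),
            "pairedEWAS_schema_error")
  }
  bad <- setdiff(unique(sheet$period), c("work", "vacation"))
  if (length(bad) > 0L) {
    pw_stop(sprintf("unknown period level(s): %s", paste(bad, collapse = ", ")),
            "pairedEWAS_schema_error")
  }
  bad <- setdiff(unique(sheet$group), c("swd", "control"))
  if (length(bad) > 0L) {
    pw_stop(sprintf("unknown group level(s): %s", paste(bad, collapse = ", ")),
            "pairedEWAS_schema_error")
  }
  invisible(sheet)
}
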