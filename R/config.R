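#' Cohort configuration for the synthetic paired methylome simulator
#'
#' Describes the subject-level structure of a paired (work/vacation)
#' occupational cohort: group sizes, age distributions, and the frequencies of
#' the nuisance covariates carried into the design matrix.  The defaults
#' mirror the airline shift-worker cohort the pipeline was designed around:
#' 21 subjects with shift work disorder (SWD, age 41.0 +/- 8.9 years) and 11
#' symptom-free controls (age 49.2 +/- 9.1 years), about a quarter women, two
#' array plates.
#'
#' @param n_swd Number of SWD subjects (>= 1).
#' @param n_control Number of control subjects (>= 1).
#' @param age_mean_swd,age_sd_swd Age distribution of the SWD group, years.
#' @param age_mean_ctrl,age_sd_ctrl Age distribution of the controls, years.
#' @param frac_female Proportion of women in `[0, 1]`.
#' @param n_plates Number of array plates samples are randomized onto.
#' @param frac_smokers Proportion of current smokers.
#' @param frac_alcohol Proportion of subjects reporting regular alcohol use.
#' @param seed Root seed; all simulator randomness is derived from it via
#'   documented sub-streams, so identical seeds give identical cohorts.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_swd = 21L, n_control = 11L,
                          age_mean_swd = 41.0, age_sd_swd = 8.9,
                          age_mean_ctrl = 49.2, age_sd_ctrl = 9.1,
                          frac_female = 0.25, n_plates = 2L,
                          frac_smokers = 0.3, frac_alcohol = 0.5,
                          seed = 1L) {
  cfg <- list(
    n_swd = check_count(n_swd, "n_swd"),
    n_control = check_count(n_control, "n_control"),
    age_mean_swd = age_mean_swd, age_sd_swd = check_positive(age_sd_swd, "age_sd_swd"),
    age_mean_ctrl = age_mean_ctrl, age_sd_ctrl = check_positive(age_sd_ctrl, "age_sd_ctrl"),
    frac_female = check_proportion(frac_female, "frac_female"),
    n_plates = check_count(n_plates, "n_plates"),
    frac_smokers = check_proportion(frac_smokers, "frac_smokers"),
    frac_alcohol = check_proportion(frac_alcohol, "frac_alcohol"),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "cohort_config")
}

#' Effect configuration for the synthetic methylome
#'
#' Describes the planted vacation effects on the M-value scale: which
#' fraction of probes carries a true effect per group, the sign balance
#' (positive = methylation gained on vacation = hypomethylated during work),
#' effect magnitudes, noise, and the designated "recovery" probes whose
#' work-to-vacation change is linked to the questionnaire symptom change.
#'
#' Defaults state a world with effects concentrated in the SWD group (5% of
#' probes affected, 78% of them positive), no control-group effects, effect
#' size 1.0 +/- 0.25 M-value units over noise 0.5, and strictly independent
#' errors (`subject_intercept_sd = 0`), matching the iid assumption of the
#' downstream OLS model.
#'
#' @param n_probes Number of CpG probes to simulate.
#' @param frac_affected_swd,frac_affected_ctrl Fraction of probes with a true
#'   vacation effect in each group; materialized as
#'   `floor(frac * n_probes)` probes drawn without replacement.
#' @param frac_positive_swd,frac_positive_ctrl Fraction of affected probes
#'   whose effect is positive (gain on vacation); same floor rule.
#' @param effect_size_mean,effect_size_sd Magnitude distribution of planted
#'   effects, M-value units.
#' @param noise_sd Residual standard deviation, M-value units (> 0).
#' @param subject_intercept_sd Standard deviation of an optional shared
#'   subject-level intercept; 0 keeps errors exactly iid.
#' @param covariate_effect_scale Standard deviation of per-probe nuisance
#'   coefficients (age is standardized internally before effects are applied).
#' @param recovery_probe_ids Probe ids whose change is linked to symptom
#'   change; `NULL` picks 3 positive affected SWD probes at generation time.
#' @param recovery_link_strength Target magnitude, in `[0, 1]`, of the
#'   correlation between planted methylation change and symptom change.
#'
#' @return An object of class `effect_config`.
#' @seealso [generate_methylome()], [generate_symptoms()]
#' @export
effect_config <- function(n_probes = 10000L,
                          frac_affected_swd = 0.05, frac_affected_ctrl = 0,
                          frac_positive_swd = 0.78, frac_positive_ctrl = 0.5,
                          effect_size_mean = 1.0, effect_size_sd = 0.25,
                          noise_sd = 0.5, subject_intercept_sd = 0,
                          covariate_effect_scale = 0.05,
                          recovery_probe_ids = NULL,
                          recovery_link_strength = 0.6) {
  if (!is.numeric(n_probes) || n_probes < 1) {
    pw_stop("'n_probes' must be >= 1", "pairedEWAS_config_error")
  }
  cfg <- list(
    n_probes = check_count(n_probes, "n_probes"),
    frac_affected_swd = check_proportion(frac_affected_swd, "frac_affected_swd"),
    frac_affected_ctrl = check_proportion(frac_affected_ctrl, "frac_affected_ctrl"),
    frac_positive_swd = check_proportion(frac_positive_swd, "frac_positive_swd"),
    frac_positive_ctrl = check_proportion(frac_positive_ctrl, "frac_positive_ctrl"),
    effect_size_mean = effect_size_mean,
    effect_size_sd = check_positive(effect_size_sd, "effect_size_sd"),
    noise_sd = check_positive(noise_sd, "noise_sd"),
    subject_intercept_sd = subject_intercept_sd,
    covariate_effect_scale = covariate_effect_scale,
    recovery_probe_ids = recovery_probe_ids,
    recovery_link_strength = check_proportion(recovery_link_strength,
                                              "recovery_link_strength")
  )
  if (cfg$subject_intercept_sd < 0) {
    pw_stop("'subject_intercept_sd' must be >= 0", "pairedEWAS_config_error")
  }
  structure(cfg, class = "effect_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "cohort_config: %d SWD + %d control subjects (%d samples), seed %d\n",
    x$n_swd, x$n_control, 2L * (x$n_swd + x$n_control), x$seed))
  invisible(x)
}

#' @export
print.effect_config <- function(x, ...) {
  cat(sprintf(
    paste0("effect_config: %d probes; affected SWD %.1f%% / ctrl %.1f%%; ",
           "effect %.2f+/-%.2f over noise %.2f\n"),
    x$n_probes, 100 * x$frac_affected_swd, 100 * x$frac_affected_ctrl,
    x$effect_size_mean, x$effect_size_sd, x$noise_sd))
  invisible(x)
}
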