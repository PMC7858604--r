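# End-to-end driver: simulate -> ewas -> pathways -> recovery -> embed ->
# report, each stage writing its plain-text output under the configured
# output directory.

#' Pipeline configuration
#'
#' Either point the pipeline at existing inputs (`matrix_path`,
#' `samples_path`, `annotation_path`, `gmt_path`) or leave them `NULL` to
#' simulate a synthetic cohort with the given `cohort`/`effects`
#' configurations.  All randomness flows from `seed`.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Root seed.
#' @param matrix_path,samples_path,annotation_path,gmt_path Optional input
#'   files; all four must be given to skip simulation.
#' @param cohort,effects Simulator configurations (used when simulating).
#' @param n_genes,n_pathways,probes_per_gene,genes_per_pathway Annotation /
#'   library shape for the simulated world.
#' @param covariates Covariates for the EWAS design.
#' @param alpha DMP threshold.
#' @param n_top,p_cut Top-gene ranking parameters for enrichment.
#' @param recovery_thresholds Optional explicit recovery-group cutpoints.
#' @param perplexity,tsne_iterations Embedding parameters.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            matrix_path = NULL, samples_path = NULL,
                            annotation_path = NULL, gmt_path = NULL,
                            cohort = cohort_config(seed = seed),
                            effects = effect_config(),
                            n_genes = 300L, n_pathways = 12L,
                            probes_per_gene = 10L, genes_per_pathway = 15L,
                            covariates = c("age", "sex", "plate", "alcohol",
                                           "smoking"),
                            alpha = 0.05, n_top = 30L, p_cut = 1e-5,
                            recovery_thresholds = NULL,
                            perplexity = 10, tsne_iterations = 10000L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    pw_stop("'alpha' must lie in (0, 1)", "pairedEWAS_config_error")
  }
  paths <- list(matrix_path, samples_path, annotation_path, gmt_path)
  given <- !vapply(paths, is.null, logical(1))
  if (any(given) && !all(given)) {
    pw_stop("give all of matrix/samples/annotation/gmt paths, or none",
            "pairedEWAS_config_error")
  }
  structure(list(
    outdir = outdir, seed = check_count(seed, "seed", min = 0L),
    matrix_path = matrix_path, samples_path = samples_path,
    annotation_path = annotation_path, gmt_path = gmt_path,
    cohort = cohort, effects = effects,
    n_genes = n_genes, n_pathways = n_pathways,
    probes_per_gene = probes_per_gene,
    genes_per_pathway = genes_per_pathway,
    covariates = covariates, alpha = alpha,
    n_top = n_top, p_cut = p_cut,
    recovery_thresholds = recovery_thresholds,
    perplexity = perplexity, tsne_iterations = tsne_iterations
  ), class = "pipeline_config")
}

# stable hash of the serialized scientific config (output location
# excluded), for provenance
config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  s <- jsonlite::toJSON(lapply(x, unclass), auto_unbox = TRUE,
                        digits = NA, null = "null")
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' Executes simulate (unless input paths are configured), the paired EWAS,
#' pathway enrichment and scoring, recovery correlation + working-period
#' ANOVA on the top-scoring pathway's DMPs, and the global t-SNE embedding.
#' Every stage writes its table under `outdir`; a `report.json` ties the
#' numbers together.  Identical config + seed reproduce byte-identical
#' stage outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly also written to
#'   `outdir/report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  report <- list(provenance = list(config_hash = config_hash(config),
                                   seed = config$seed,
                                   timestamp = format(Sys.time(), tz = "UTC")))

  stage <- "simulate"
  res <- tryCatch({
    if (is.null(config$matrix_path)) {
      sheet <- generate_cohort(config$cohort)
      sim <- generate_methylome(sheet, config$effects)
      sheet <- generate_symptoms(sheet, sim$truth, config$effects)
      ag <- generate_annotation_and_gmt(
        config$effects$n_probes, config$n_genes, config$n_pathways,
        config$probes_per_gene, config$genes_per_pathway,
        seed = config$seed)
      write_matrix(sim$matrix, out("matrix.tsv"))
      write_samples(sheet, out("samples.csv"))
      write_annotation(ag$annotation, out("annotation.tsv"))
      write_gmt(ag$gmt, out("library.gmt"))
      write_truth(sim$truth, out("truth.json"))
      list(matrix = sim$matrix, sheet = sheet,
           annotation = ag$annotation, gmt = ag$gmt)
    } else {
      list(matrix = read_matrix(config$matrix_path),
           sheet = read_samples(config$samples_path),
           annotation = read_annotation(config$annotation_path),
           gmt = read_gmt(config$gmt_path))
    }
  }, error = function(e) {
    pw_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "pairedEWAS_pipeline_error")
  })
  report$simulate <- list(n_probes = nrow(res$matrix),
                          n_samples = ncol(res$matrix),
                          n_subjects = length(unique(res$sheet$subject)),
                          n_pathways = length(res$gmt))

  stage <- "ewas"
  table <- tryCatch({
    tab <- suppressWarnings(
      run_ewas(res$matrix, res$sheet, config$covariates, config$alpha))
    write_table_tsv(tab, out("ewas.tsv"))
    for (hyp in c("swd", "ctrl", "either", "both")) {
      write_table_tsv(qq_points(tab[[paste0("p_", hyp)]]),
                      out(sprintf("qq_%s.tsv", hyp)))
    }
    tab
  }, error = function(e) {
    pw_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "pairedEWAS_pipeline_error")
  })
  es <- summarize_ewas(table, config$alpha)
  report$ewas <- list(n_tested = nrow(table),
                      n_skipped = nrow(attr(table, "skipped") %||%
                                         data.frame()),
                      summary = unclass(es)[c("swd", "control")])
  jsonlite::write_json(report$ewas, out("ewas_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  stage <- "pathways"
  pw <- tryCatch({
    top_genes <- suppressWarnings(
      rank_top_genes(table, res$annotation, "swd",
                     n_top = config$n_top, p_cut = config$p_cut))
    idx <- match(table$probe_id, res$annotation$probe_id)
    background <- unique(unlist(split_symbols(
      res$annotation$gene_symbols[idx])))
    enr <- if (length(top_genes) > 0L) {
      enrich_terms(top_genes, res$gmt, background)
    } else {
      data.frame(term = character(0), n_term = integer(0),
                 overlap = integer(0), p = numeric(0), q = numeric(0),
                 overlap_genes = character(0))
    }
    scores <- do.call(rbind, lapply(names(res$gmt), function(term) {
      tryCatch(pathway_scores(term, res$gmt, res$annotation, table,
                              alpha = config$alpha),
               error = function(e) NULL)
    }))
    write_table_tsv(enr, out("enrichment.tsv"))
    write_table_tsv(scores, out("pathway_scores.tsv"))
    list(top_genes = top_genes, enrichment = enr, scores = scores)
  }, error = function(e) {
    pw_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "pairedEWAS_pipeline_error")
  })
  swd_scores <- pw$scores[pw$scores$group == "swd", , drop = FALSE]
  top_term <- if (nrow(swd_scores) > 0L) {
    swd_scores$term[order(-swd_scores$enrichment_score_pct,
                          swd_scores$term)][1L]
  } else NA_character_
  report$pathways <- list(
    n_top_genes = length(pw$top_genes),
    top_enriched_terms = head(pw$enrichment$term, 5L),
    top_score_term = top_term,
    scores = if (nrow(swd_scores) > 0L) {
      utils::head(swd_scores[order(-swd_scores$enrichment_score_pct), ], 5L)
    })

  stage <- "recovery"
  rec <- tryCatch({
    dmps <- if (!is.na(top_term)) {
      u <- intersect(pathway_cpg_universe(top_term, res$gmt, res$annotation),
                     table$probe_id)
      u[table$dmp_swd[match(u, table$probe_id)]]
    } else character(0)
    if (length(dmps) == 0L) {
      dmps <- head(table$probe_id[order(table$p_swd)], 38L)
    }
    changes <- methylation_change(res$matrix, res$sheet)
    scores <- symptom_change(res$sheet)
    swd_subjects <- unique(res$sheet$subject[res$sheet$group == "swd"])
    cor_tab <- correlate_recovery(dmps, changes, scores,
                                  subjects = swd_subjects,
                                  annotation = res$annotation)
    groups <- assign_recovery_groups(scores[swd_subjects],
                                     config$recovery_thresholds)
    anova_tab <- suppressWarnings(
      work_period_anova(res$matrix, res$sheet, dmps))
    write_table_tsv(cor_tab, out("recovery.tsv"))
    write_table_tsv(anova_tab, out("anova.tsv"))
    list(cor = cor_tab, groups = groups, anova = anova_tab, dmps = dmps)
  }, error = function(e) {
    pw_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "pairedEWAS_pipeline_error")
  })
  rs <- summarize_recovery(rec$cor, config$alpha)
  report$recovery <- list(n_dmps = length(rec$dmps),
                          n_p_sig = rs$n_p_sig, n_q_sig = rs$n_q_sig,
                          groups = table(rec$groups))

  stage <- "embed"
  emb <- tryCatch({
    e <- embed_global_profiles(res$matrix, res$sheet,
                               perplexity = config$perplexity,
                               iterations = config$tsne_iterations,
                               seed = config$seed)
    write_table_tsv(e, out("embedding.tsv"))
    e
  }, error = function(e) {
    pw_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "pairedEWAS_pipeline_error")
  })
  report$embed <- list(n_samples = nrow(emb))

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `ewas`, `pathways`, `recovery`, `embed`, `run`.
#' Run with no arguments (or `--help`) for usage.  A thin launcher script is
#' installed under `system.file("cli", "pairedEWAS.R", package =
#' "pairedEWAS")`.
#'
#' @param args Character vector of command-line arguments (first element:
#'   the subcommand).
#' @return Exit status, invisibly (0 on success).
#' @export
pewas_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pairedEWAS <subcommand> [options]",
    "subcommands:",
    "  simulate  --outdir DIR --seed INT [--n-probes N]",
    "  ewas      --matrix TSV --samples CSV [--covariates LIST] [--alpha A] --out TSV",
    "  pathways  --ewas TSV --gmt FILE --annotation TSV [--group swd] [--top N]",
    "            [--pcut P] [--alpha A] --out TSV",
    "  recovery  --matrix TSV --samples CSV --dmps FILE [--alpha A] --out TSV",
    "  embed     --matrix TSV --samples CSV [--perplexity P] [--iterations N]",
    "            [--seed INT] --out TSV",
    "  run       --outdir DIR [--seed INT] [--config JSON]",
    sep = "\n")
  if (length(args) == 0L || args[1L] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  opt <- function(spec) optparse::parse_args(
    optparse::OptionParser(option_list = spec), args = rest)

  o <- optparse::make_option
  status <- switch(cmd,
    simulate = {
      a <- opt(list(o("--outdir", type = "character"),
                    o("--seed", type = "integer", default = 1L),
                    o("--n-probes", type = "integer", default = 10000L,
                      dest = "n_probes")))
      cfg <- pipeline_config(a$outdir, seed = a$seed,
                             cohort = cohort_config(seed = a$seed),
                             effects = effect_config(n_probes = a$n_probes))
      sheet <- generate_cohort(cfg$cohort)
      sim <- generate_methylome(sheet, cfg$effects)
      sheet <- generate_symptoms(sheet, sim$truth, cfg$effects)
      ag <- generate_annotation_and_gmt(cfg$effects$n_probes, cfg$n_genes,
                                        cfg$n_pathways, cfg$probes_per_gene,
                                        cfg$genes_per_pathway, seed = a$seed)
      dir.create(a$outdir, recursive = TRUE, showWarnings = FALSE)
      write_matrix(sim$matrix, file.path(a$outdir, "matrix.tsv"))
      write_samples(sheet, file.path(a$outdir, "samples.csv"))
      write_annotation(ag$annotation, file.path(a$outdir, "annotation.tsv"))
      write_gmt(ag$gmt, file.path(a$outdir, "library.gmt"))
      write_truth(sim$truth, file.path(a$outdir, "truth.json"))
      0L
    },
    ewas = {
      a <- opt(list(o("--matrix", type = "character"),
                    o("--samples", type = "character"),
                    o("--covariates", type = "character",
                      default = "age,sex,plate,alcohol,smoking"),
                    o("--alpha", type = "double", default = 0.05),
                    o("--out", type = "character")))
      tab <- suppressWarnings(run_ewas(
        read_matrix(a$matrix), read_samples(a$samples),
        strsplit(a$covariates, ",")[[1L]], a$alpha))
      write_table_tsv(tab, a$out)
      print(summarize_ewas(tab, a$alpha))
      0L
    },
    pathways = {
      a <- opt(list(o("--ewas", type = "character"),
                    o("--gmt", type = "character"),
                    o("--annotation", type = "character"),
                    o("--group", type = "character", default = "swd"),
                    o("--top", type = "integer", default = 30L),
                    o("--pcut", type = "double", default = 1e-5),
                    o("--alpha", type = "double", default = 0.05),
                    o("--out", type = "character")))
      tab <- read_ewas_tsv(a$ewas)
      gmt <- read_gmt(a$gmt)
      ann <- read_annotation(a$annotation)
      scores <- do.call(rbind, lapply(names(gmt), function(term) {
        tryCatch(pathway_scores(term, gmt, ann, tab, alpha = a$alpha),
                 error = function(e) NULL)
      }))
      write_table_tsv(scores, a$out)
      0L
    },
    recovery = {
      a <- opt(list(o("--matrix", type = "character"),
                    o("--samples", type = "character"),
                    o("--dmps", type = "character"),
                    o("--alpha", type = "double", default = 0.05),
                    o("--out", type = "character")))
      m <- read_matrix(a$matrix)
      sheet <- read_samples(a$samples)
      dmps <- readLines(a$dmps)
      swd <- unique(sheet$subject[sheet$group == "swd"])
      tab <- correlate_recovery(dmps, methylation_change(m, sheet),
                                symptom_change(sheet), subjects = swd)
      write_table_tsv(tab, a$out)
      print(summarize_recovery(tab, a$alpha))
      0L
    },
    embed = {
      a <- opt(list(o("--matrix", type = "character"),
                    o("--samples", type = "character"),
                    o("--perplexity", type = "double", default = 10),
                    o("--iterations", type = "integer", default = 10000L),
                    o("--seed", type = "integer", default = 1L),
                    o("--out", type = "character")))
      e <- embed_global_profiles(read_matrix(a$matrix),
                                 read_samples(a$samples),
                                 a$perplexity, a$iterations, a$seed)
      write_table_tsv(e, a$out)
      0L
    },
    run = {
      a <- opt(list(o("--outdir", type = "character"),
                    o("--seed", type = "integer", default = 1L),
                    o("--config", type = "character", default = NULL)))
      extra <- if (!is.null(a$config)) {
        jsonlite::read_json(a$config, simplifyVector = TRUE)
      } else list()
      cfg <- do.call(pipeline_config,
                     modifyList(list(outdir = a$outdir, seed = a$seed),
                                extra))
      run_pipeline(cfg)
      0L
    },
    {
      message(usage)
      1L
    })
  invisible(status)
}

#' Read back an EWAS result TSV written by [write_table_tsv()]
#'
#' @param path File path.
#' @return `ewas_result` data.frame.
#' @export
read_ewas_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  for (j in grep("^(p|q)_|^beta_", names(dt), value = TRUE)) {
    dt[[j]] <- as.numeric(dt[[j]])
  }
  for (j in grep("^dmp_", names(dt), value = TRUE)) {
    dt[[j]] <- as.logical(dt[[j]])
  }
  class(dt) <- c("ewas_result", "data.frame")
  dt
}
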