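# Gene-set enrichment and pathway-level DMP scoring.
#
# Gene symbols are matched after uppercasing and whitespace stripping; no
# alias resolution is attempted.

norm_symbol <- function(x) toupper(gsub("\\s+", "", x))

# table columns use the short "ctrl" suffix for the control group
group_suffix <- function(group) c(swd = "swd", control = "ctrl")[[group]]

# probe -> character vector of gene symbols (possibly empty)
split_symbols <- function(gene_symbols) {
  lapply(strsplit(ifelse(is.na(gene_symbols), "", gene_symbols), ";",
                  fixed = TRUE),
         function(g) unique(norm_symbol(g[nzchar(g)])))
}

check_annotation <- function(annotation) {
  required <- c("probe_id", "gene_symbols")
  missing <- setdiff(required, names(annotation))
  if (length(missing) > 0L) {
    pw_stop(sprintf("annotation is missing column(s): %s",
                    paste(missing, collapse = ", ")),
            "pairedEWAS_schema_error")
  }
  if (anyDuplicated(annotation$probe_id)) {
    pw_stop("annotation probe ids are not unique", "pairedEWAS_schema_error")
  }
  invisible(annotation)
}

#' Rank genes by their best probe p-value
#'
#' Every gene is scored by the minimum unadjusted p-value among its probes
#' under the chosen group's hypothesis (genes with several probes are
#' deduplicated to the best probe).  Genes are filtered to `p_cut`, sorted
#' by ascending p (ties broken lexicographically), and truncated to `n_top`
#' -- the construction behind "top 30 genes ranked by significance".
#'
#' @param table An `ewas_result` table.
#' @param annotation Probe annotation (`probe_id`, `gene_symbols`).
#' @param group `"swd"` or `"control"` (selects `p_swd` / `p_ctrl`).
#' @param n_top Maximum number of genes returned (`Inf` for all).
#' @param p_cut Unadjusted p-value cutoff (default `1e-5`).
#' @return Character vector of gene symbols, best first, with the scores in
#'   `attr(, "p")`.
#' @export
rank_top_genes <- function(table, annotation, group = c("swd", "control"),
                           n_top = 30, p_cut = 1e-5) {
  group <- match.arg(group)
  check_annotation(annotation)
  pcol <- paste0("p_", group_suffix(group))
  idx <- match(table$probe_id, annotation$probe_id)
  genes <- split_symbols(annotation$gene_symbols[idx])
  k <- lengths(genes)
  long <- data.frame(gene = unlist(genes),
                     p = rep(table[[pcol]], k),
                     stringsAsFactors = FALSE)
  long <- long[!is.na(long$p), , drop = FALSE]
  if (nrow(long) == 0L) {
    pw_warn("no annotated probes with p-values", "pairedEWAS_empty_warning")
    return(character(0))
  }
  best <- tapply(long$p, long$gene, min)
  best <- best[best < p_cut]
  if (length(best) == 0L) {
    pw_warn(sprintf("no gene passes p < %g", p_cut), "pairedEWAS_empty_warning")
    return(character(0))
  }
  o <- order(best, names(best))
  best <- best[o]
  if (is.finite(n_top)) best <- head(best, n_top)
  structure(names(best), p = unname(best))
}

#' Over-representation test of a gene list against a GMT library
#'
#' One-sided hypergeometric upper-tail p per term on the 2x2 table
#' (list-and-term, list-not-term, term-not-list, rest of the background),
#' Benjamini-Hochberg adjusted across terms, sorted by p.  Symbols are
#' case-normalized; list genes outside the background are dropped with a
#' warning.
#'
#' @param gene_list Character vector of query genes.
#' @param library Named list of gene-set character vectors (GMT).
#' @param background Character vector: the gene universe.
#' @return `data.frame`: `term`, `n_term` (term genes in background),
#'   `overlap`, `p`, `q`, plus the overlapping genes in
#'   `overlap_genes` (semicolon-joined).
#' @export
enrich_terms <- function(gene_list, library, background) {
  background <- unique(norm_symbol(background))
  if (length(background) == 0L) {
    pw_stop("background gene universe is empty", "pairedEWAS_contract_error")
  }
  gene_list <- unique(norm_symbol(gene_list))
  out_of_bg <- setdiff(gene_list, background)
  if (length(out_of_bg) > 0L) {
    pw_warn(sprintf("%d query gene(s) outside the background dropped",
                    length(out_of_bg)), "pairedEWAS_contract_warning")
    gene_list <- intersect(gene_list, background)
  }
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(library), function(term) {
    tg <- intersect(unique(norm_symbol(library[[term]])), background)
    ov <- intersect(gene_list, tg)
    K <- length(tg)
    # P(X >= overlap), X ~ Hypergeom(N, K, n)
    p <- if (K == 0L) 1 else phyper(length(ov) - 1L, K, N - K, n,
                                    lower.tail = FALSE)
    data.frame(term = term, n_term = K, overlap = length(ov),
               p = min(1, p),
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res <- res[order(res$p, res$term), c("term", "n_term", "overlap", "p", "q",
                                       "overlap_genes")]
  rownames(res) <- NULL
  res
}

#' CpG universe of a pathway
#'
#' The union of all probes annotated to any member gene of the term; probes
#' annotated to several member genes are counted once.
#'
#' @param term Term name present in `library`.
#' @param library Named list of gene sets.
#' @param annotation Probe annotation.
#' @return Character vector of probe ids.
#' @export
pathway_cpg_universe <- function(term, library, annotation) {
  check_annotation(annotation)
  if (!term %in% names(library)) {
    pw_stop(sprintf("unknown term '%s'", term), "pairedEWAS_lookup_error")
  }
  tg <- unique(norm_symbol(library[[term]]))
  genes <- split_symbols(annotation$gene_symbols)
  hit <- vapply(genes, function(g) any(g %in% tg), logical(1))
  unique(annotation$probe_id[hit])
}

#' Pathway-level DMP enrichment and hypomethylation scores
#'
#' For one pathway and group: the DMP enrichment score is the percentage of
#' the pathway's tested CpGs that are DMPs (unadjusted group p < `alpha`),
#' and the hypomethylation score is the percentage of those DMPs that are
#' hypomethylated during work (positive vacation effect).  Both are rounded
#' to one decimal; the hypomethylation score is missing when the pathway has
#' no DMPs.
#'
#' @param term Term name.
#' @param library Named list of gene sets.
#' @param annotation Probe annotation.
#' @param table An `ewas_result` table.
#' @param group `"swd"`, `"control"`, or both (the default computes both).
#' @param alpha DMP threshold.
#' @return One-row `data.frame` per group, bound together: `term`, `group`,
#'   `n_cpgs`, `n_genes`, `n_dmps`, `enrichment_score_pct`, `n_hypo_dmps`,
#'   `hypo_score_pct`.
#' @export
pathway_scores <- function(term, library, annotation, table,
                           group = c("swd", "control"), alpha = 0.05) {
  universe <- pathway_cpg_universe(term, library, annotation)
  universe <- intersect(universe, table$probe_id)
  if (length(universe) == 0L) {
    pw_stop(sprintf("pathway '%s' has no tested CpGs", term),
            "pairedEWAS_contract_error")
  }
  sub <- table[match(universe, table$probe_id), , drop = FALSE]
  n_genes <- length(unique(norm_symbol(library[[term]])))
  rows <- lapply(group, function(g) {
    p <- sub[[paste0("p_", group_suffix(g))]]
    dir <- sub[[paste0("direction_", group_suffix(g))]]
    dmp <- !is.na(p) & p < alpha
    hypo <- dmp & !is.na(dir) & dir == "hypo_at_work"
    data.frame(
      term = term, group = g,
      n_cpgs = length(universe), n_genes = n_genes,
      n_dmps = sum(dmp),
      enrichment_score_pct = pct1(sum(dmp), length(universe)),
      n_hypo_dmps = sum(hypo),
      hypo_score_pct = pct1(sum(hypo), sum(dmp)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volcano-plot points for a pathway's CpGs
#'
#' @param table An `ewas_result` table.
#' @param universe Probe ids (must all be present in the table).
#' @param group `"swd"` or `"control"`.
#' @return `data.frame`: `probe_id`, `effect` (vacation-minus-work
#'   coefficient), `neglog10_p`, `dmp` flag.
#' @export
volcano_points <- function(table, universe, group = c("swd", "control")) {
  group <- match.arg(group)
  missing <- setdiff(universe, table$probe_id)
  if (length(missing) > 0L) {
    pw_stop(sprintf("universe probe(s) not in table: %s",
                    paste(head(missing, 5), collapse = ", ")),
            "pairedEWAS_contract_error")
  }
  sub <- table[match(universe, table$probe_id), , drop = FALSE]
  sfx <- group_suffix(group)
  data.frame(
    probe_id = sub$probe_id,
    effect = sub[[paste0("beta_vw_", sfx)]],
    neglog10_p = -log10(sub[[paste0("p_", sfx)]]),
    dmp = sub[[paste0("dmp_", sfx)]],
    stringsAsFactors = FALSE, row.names = NULL)
}
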