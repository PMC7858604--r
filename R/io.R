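# Plain-text readers/writers: M-value matrix TSV, sample sheet CSV, probe
# annotation TSV, GMT gene-set libraries, truth JSON.  Numeric values are
# written with "%.17g" so that write -> read round-trips are exact.

fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write / read a probes x samples M-value matrix (TSV)
#'
#' First column `probe_id`, remaining columns one per sample.  Values are
#' written at full double precision, so a round-trip reproduces the matrix
#' exactly.
#'
#' @param matrix Numeric matrix with probe rownames and sample colnames.
#' @param path Output file.
#' @export
write_matrix <- function(matrix, path) {
  dt <- data.table::data.table(probe_id = rownames(matrix))
  for (j in colnames(matrix)) dt[[j]] <- fmt_full(matrix[, j])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @return `read_matrix`: the numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L) {
    pw_stop(sprintf("matrix file '%s' is missing or empty", path),
            "pairedEWAS_format_error")
  }
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE,
                      colClasses = list(character = 1L)),
    error = function(e) pw_stop(sprintf("malformed matrix TSV '%s': %s",
                                        path, conditionMessage(e)),
                                "pairedEWAS_format_error"))
  if (nrow(dt) == 0L || ncol(dt) < 2L) {
    pw_stop(sprintf("matrix file '%s' has no data", path),
            "pairedEWAS_format_error")
  }
  ids <- dt[[1L]]
  dup <- which(duplicated(ids))
  if (length(dup) > 0L) {
    pw_stop(sprintf("duplicate probe id '%s' at line %d of '%s'",
                    ids[dup[1L]], dup[1L] + 1L, path),
            "pairedEWAS_format_error")
  }
  m <- as.matrix(dt[, -1L])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write / read a sample sheet (CSV)
#'
#' Required columns: `sample_id`, `subject`, `group`, `period`; any further
#' covariate and answer columns are carried through.  `period` is normalized
#' to lower case (`work`/`vacation`) and `group` to `swd`/`control`.
#'
#' @param sheet Sample sheet `data.frame`.
#' @param path File path.
#' @export
write_samples <- function(sheet, path) {
  data.table::fwrite(data.table::as.data.table(sheet), path, quote = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  required <- c("sample_id", "subject", "group", "period")
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0L) {
    pw_stop(sprintf("sample sheet '%s' is missing column(s): %s",
                    path, paste(missing, collapse = ", ")),
            "pairedEWAS_schema_error")
  }
  dt$period <- tolower(dt$period)
  g <- tolower(dt$group)
  g[g %in% c("ctrl", "controls")] <- "control"
  dt$group <- g
  check_sheet(dt)
  dt
}

#' Write / read a probe annotation table (TSV)
#'
#' Columns `probe_id`, `chr`, `pos_1based`, `gene_symbols` (semicolon-joined
#' when a probe maps to several genes).  A headerless four-column file in
#' the order probe id, chromosome, coordinate, gene symbol(s) is also
#' accepted on read.
#'
#' @param annotation Annotation `data.frame`.
#' @param path File path.
#' @export
write_annotation <- function(annotation, path) {
  data.table::fwrite(data.table::as.data.table(annotation), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("probe_id", first, fixed = TRUE)
  dt <- data.table::fread(path, sep = "\t", header = has_header,
                          data.table = FALSE,
                          colClasses = list(character = if (has_header) "chr" else 2L))
  if (!has_header) {
    if (ncol(dt) != 4L) {
      pw_stop(sprintf("headerless annotation '%s' must have 4 columns", path),
              "pairedEWAS_schema_error")
    }
    names(dt) <- c("probe_id", "chr", "pos_1based", "gene_symbols")
  }
  missing <- setdiff(c("probe_id", "chr", "pos_1based", "gene_symbols"),
                     names(dt))
  if (length(missing) > 0L) {
    pw_stop(sprintf("annotation '%s' is missing column(s): %s",
                    path, paste(missing, collapse = ", ")),
            "pairedEWAS_schema_error")
  }
  dt$chr <- as.character(dt$chr)
  dt$gene_symbols <- as.character(dt$gene_symbols)
  dt$gene_symbols[is.na(dt$gene_symbols)] <- ""
  check_annotation(dt)
  dt
}

#' Write / read a GMT gene-set library
#'
#' Standard tab-separated format: term name, description, then one gene
#' symbol per field.
#'
#' @param gmt Named list of character gene vectors; an optional
#'   `description` attribute (named character) supplies the second field.
#' @param path File path.
#' @export
write_gmt <- function(gmt, path) {
  desc <- attr(gmt, "description") %||%
    setNames(rep("", length(gmt)), names(gmt))
  lines <- vapply(names(gmt), function(term) {
    paste(c(term, desc[[term]] %||% "", gmt[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    pw_stop(sprintf("GMT file '%s' is empty", path), "pairedEWAS_format_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    pw_stop(sprintf("GMT line %d has no genes", bad[1L]),
            "pairedEWAS_format_error")
  }
  terms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(terms)) {
    pw_stop("duplicate term names in GMT", "pairedEWAS_format_error")
  }
  gmt <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(gmt) <- terms
  attr(gmt, "description") <- setNames(
    vapply(parts, `[[`, character(1), 2L), terms)
  gmt
}

#' Write / read the synthetic ground truth (JSON)
#'
#' @param truth A `synthetic_truth` object.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$effects <- unclass(x$effects)
  x$recovery_degree <- as.list(x$recovery_degree)   # keep subject names
  if (!is.null(x$planted_recovery_change)) {
    x$planted_recovery_change <- list(
      probe_ids = rownames(x$planted_recovery_change),
      subjects = colnames(x$planted_recovery_change),
      values = unname(as.data.frame(x$planted_recovery_change)))
  }
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$planted_recovery_change)) {
    pc <- x$planted_recovery_change
    m <- as.matrix(as.data.frame(pc$values))
    dimnames(m) <- list(pc$probe_ids, pc$subjects)
    x$planted_recovery_change <- m
  }
  x$recovery_degree <- unlist(x$recovery_degree)
  if (!is.null(x$effects$recovery_probe_ids)) {
    x$effects$recovery_probe_ids <-
      as.character(unlist(x$effects$recovery_probe_ids))
  }
  x$effects <- do.call(effect_config, x$effects)
  structure(x, class = "synthetic_truth")
}

#' Write an EWAS result table (TSV)
#'
#' Numeric columns are written at full precision.
#'
#' @param table `ewas_result` (or any data.frame).
#' @param path File path.
#' @export
write_table_tsv <- function(table, path) {
  dt <- data.table::as.data.table(table)
  for (j in names(dt)) {
    if (is.double(dt[[j]])) dt[[j]] <- fmt_full(dt[[j]])
  }
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
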