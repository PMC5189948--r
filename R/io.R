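# TSV is the canonical dialect; CSV is accepted by sniffing the delimiter
# on the first non-comment line. Decimal points only (no locale commas).
sniff_sep <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  first <- lines[!startsWith(lines, "#")][1]
  if (is.na(first)) stop(sprintf("'%s' has no header line", path))
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

read_delim_checked <- function(path, required = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"")
  if (!is.null(required)) {
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols))
      stop(sprintf("'%s' is missing required column(s): %s", path,
                   paste(missing_cols, collapse = ", ")))
  }
  df
}

stop_if_exists <- function(path, force) {
  if (file.exists(path) && !force)
    stop(sprintf("output file '%s' exists; use force = TRUE to overwrite", path))
}

#' Read a fold-change table from TSV/CSV
#'
#' Accepts either the fold-change dialect (columns `gene_id`,
#' `fold_change`) or the paired-expression dialect (`gene_id`,
#' `expr_stress`, `expr_control`, converted via [compute_fold_changes()]).
#' The delimiter (tab or comma) is sniffed. Duplicate gene ids are an
#' error naming the gene and data line.
#'
#' @param path file path.
#' @param comparison_label label for the table; defaults to the file name
#'   without extension.
#' @param pseudocount used for the paired-expression dialect.
#' @return A [fold_change_table()].
#' @export
read_fold_change_table <- function(path, comparison_label = NULL, pseudocount = 0) {
  if (is.null(comparison_label))
    comparison_label <- sub("\\.[^.]*$", "", basename(path))
  df <- read_delim_checked(path, required = "gene_id")
  dup <- duplicated(df$gene_id)
  if (any(dup))
    stop(sprintf("duplicate gene_id '%s' at data line %d of %s",
                 df$gene_id[which(dup)[1]], which(dup)[1], path))
  if ("fold_change" %in% names(df)) {
    fold_change_table(stats::setNames(as.numeric(df$fold_change), df$gene_id),
                      comparison_label)
  } else if (all(c("expr_stress", "expr_control") %in% names(df))) {
    compute_fold_changes(stats::setNames(as.numeric(df$expr_stress), df$gene_id),
                         stats::setNames(as.numeric(df$expr_control), df$gene_id),
                         pseudocount = pseudocount,
                         comparison_label = comparison_label)
  } else {
    stop(sprintf("'%s' needs either a 'fold_change' column or 'expr_stress' + 'expr_control'",
                 path))
  }
}

#' Read a fold-change table from a spreadsheet column
#'
#' Thin adapter for deposited spreadsheet supplements: reads one sheet and
#' extracts a gene-id column and a fold-change column into a
#' [fold_change_table()]. Requires the readxl package.
#'
#' @param path path to an .xlsx file.
#' @param sheet sheet name or index.
#' @param gene_col,fc_col column names (or indices) of the gene identifier
#'   and fold-change columns.
#' @param comparison_label label for the table; defaults to the column name.
#' @return A [fold_change_table()].
#' @export
read_fold_change_xlsx <- function(path, sheet = 1, gene_col = 1, fc_col = 2,
                                  comparison_label = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("the readxl package is required to read .xlsx files")
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  genes <- as.character(df[[gene_col]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene_id '%s' in %s", genes[duplicated(genes)][1], path))
  if (is.null(comparison_label))
    comparison_label <- if (is.character(fc_col)) fc_col else names(df)[fc_col]
  fold_change_table(stats::setNames(suppressWarnings(as.numeric(df[[fc_col]])), genes),
                    comparison_label)
}

#' Write a fold-change table to TSV
#'
#' @param fc a [fold_change_table()].
#' @param path output path.
#' @param force overwrite an existing file.
#' @export
write_fold_change_table <- function(fc, path, force = FALSE) {
  stop_if_exists(path, force)
  df <- data.frame(gene_id = names(fc$fc), fold_change = fmt6(unname(fc$fc)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a decay time course from TSV/CSV
#'
#' Expects columns `time_min` and one `rep*` column per replicate, plus
#' optional `# condition=<label>` and `# stress_pre_treatment_min=<x>`
#' comment lines.
#'
#' @param path file path.
#' @return A [decay_timecourse()].
#' @export
read_decay_timecourse <- function(path) {
  header <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "="), header, value = TRUE)
    if (length(hit)) sub(paste0("^#\\s*", key, "="), "", hit[1]) else default
  }
  df <- read_delim_checked(path, required = "time_min")
  reps <- grep("^rep", names(df), value = TRUE)
  if (!length(reps)) stop(sprintf("'%s' has no replicate ('rep*') columns", path))
  decay_timecourse(df$time_min, as.matrix(df[reps]),
                   condition_label = get_meta("condition", ""),
                   stress_pre_treatment_min =
                     as.numeric(get_meta("stress_pre_treatment_min", NA)))
}

#' Write a decay time course to TSV
#'
#' @param tc a [decay_timecourse()].
#' @param path output path.
#' @param force overwrite an existing file.
#' @export
write_decay_timecourse <- function(tc, path, force = FALSE) {
  stop_if_exists(path, force)
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(tc$condition_label))
    writeLines(sprintf("# condition=%s", tc$condition_label), con)
  if (!is.na(tc$stress_pre_treatment_min))
    writeLines(sprintf("# stress_pre_treatment_min=%s",
                       fmt6(tc$stress_pre_treatment_min)), con)
  df <- cbind(data.frame(time_min = fmt6(tc$times)),
              as.data.frame(apply(tc$intensities, 2, fmt6)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Ct table from TSV/CSV
#'
#' Expects columns `sample`, `target`, `role` and one or more `ct*`
#' columns (technical replicates); empty/NA Ct cells are dropped per
#' record.
#'
#' @param path file path.
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path) {
  df <- read_delim_checked(path, required = c("sample", "target", "role"))
  ct_cols <- grep("^ct", names(df), value = TRUE)
  if (!length(ct_cols)) stop(sprintf("'%s' has no Ct ('ct*') columns", path))
  cts <- lapply(seq_len(nrow(df)), function(i) {
    v <- suppressWarnings(as.numeric(unlist(df[i, ct_cols])))
    v[is.finite(v)]
  })
  ct_table(df$sample, df$target, df$role, cts)
}

#' Write a Ct table to TSV
#'
#' @param tab a [ct_table()].
#' @param path output path.
#' @param force overwrite an existing file.
#' @export
write_ct_table <- function(tab, path, force = FALSE) {
  stop_if_exists(path, force)
  nct <- max(lengths(tab$ct))
  mat <- t(vapply(tab$ct, function(v) {
    out <- rep("", nct); out[seq_along(v)] <- fmt6(v); out
  }, character(nct)))
  colnames(mat) <- paste0("ct", seq_len(nct))
  df <- cbind(data.frame(sample = tab$sample, target = tab$target,
                         role = tab$role, stringsAsFactors = FALSE), mat)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write overlap results to a deterministic TSV report
#'
#' One row per `overlap_z` with the 13 documented columns, floats at 6
#' significant digits; re-running with identical inputs and seed produces
#' byte-identical files.
#'
#' @param results an `overlap_z`, a `condition_comparison`, or a list of
#'   either.
#' @param path output path.
#' @param force overwrite an existing file.
#' @export
write_overlap_report <- function(results, path, force = FALSE) {
  if (inherits(results, c("overlap_z", "condition_comparison")))
    results <- list(results)
  if (!length(results)) stop("no results to write")
  df <- do.call(rbind, lapply(results, as.data.frame))
  if (is.null(df) || !nrow(df)) stop("no results to write")
  stop_if_exists(path, force)
  for (col in c("null_mean", "null_sd", "z")) df[[col]] <- fmt6(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write half-life fits to a deterministic TSV report
#'
#' @param fits a `halflife_fit` or list of them.
#' @param path output path.
#' @param force overwrite an existing file.
#' @export
write_halflife_report <- function(fits, path, force = FALSE) {
  if (inherits(fits, "halflife_fit")) fits <- list(fits)
  if (!length(fits)) stop("no results to write")
  stop_if_exists(path, force)
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(condition = f$condition_label,
               t_half_min = fmt6(f$t_half), k_per_min = fmt6(f$k),
               r_squared = fmt6(f$r_squared),
               n_replicates = f$n_replicates,
               flags = paste(f$flags, collapse = ";"),
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
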