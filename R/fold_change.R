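#' Fold-change table for one stress / non-stress comparison
#'
#' Container for per-gene expression ratios (stress over non-stress) from a
#' single comparison. Non-finite or non-positive ratios cannot be placed on
#' the log scale the downstream cutoffs assume, so they are removed at
#' construction and counted in `n_excluded`.
#'
#' @param fold_changes numeric vector of ratios, named by gene identifier.
#'   Gene identifiers are opaque, case-sensitive strings.
#' @param comparison_label short label for the comparison (e.g. "NaCl_60min").
#' @param n_excluded count of genes already excluded upstream (added to the
#'   count of genes excluded here).
#'
#' @return An object of class `fold_change_table`: a list with elements
#'   `comparison_label`, `fc` (named numeric, all finite and > 0) and
#'   `n_excluded`.
#' @seealso [compute_fold_changes()], [classify_directional_sets()]
#' @export
#' @examples
#' fold_change_table(c(gA = 4, gB = 0.5), "demo")
fold_change_table <- function(fold_changes, comparison_label = "", n_excluded = 0L) {
  check_named_numeric(fold_changes, "fold_changes")
  bad <- !is.finite(fold_changes) | fold_changes <= 0
  structure(
    list(comparison_label = as.character(comparison_label)[1],
         fc = fold_changes[!bad],
         n_excluded = as.integer(n_excluded) + sum(bad)),
    class = "fold_change_table")
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("Fold-change table '%s': %d genes (%d excluded as missing/non-positive)\n",
              x$comparison_label, length(x$fc), x$n_excluded))
  invisible(x)
}

#' @export
length.fold_change_table <- function(x) length(x$fc)

#' @export
as.data.frame.fold_change_table <- function(x, ...) {
  data.frame(gene_id = names(x$fc), fold_change = unname(x$fc),
             stringsAsFactors = FALSE)
}

#' Compute per-gene fold-changes from paired expression tables
#'
#' Forms (stress + pseudocount) / (control + pseudocount) for every gene
#' present in both tables. Genes absent from either table are dropped; genes
#' whose denominator is zero (or whose ratio is non-positive) are excluded
#' and counted in the result's `n_excluded`.
#'
#' @param expr_stress,expr_control numeric vectors of expression values,
#'   named by gene identifier.
#' @param pseudocount non-negative value added to numerator and denominator;
#'   default 0 (users integrating count data choose their own).
#' @param comparison_label label stored in the returned table.
#'
#' @return A [fold_change_table()] with attribute `n_dropped` = number of
#'   genes present in only one of the two tables.
#' @export
#' @examples
#' compute_fold_changes(c(gA = 40, gB = 5), c(gA = 10, gB = 10))
compute_fold_changes <- function(expr_stress, expr_control, pseudocount = 0,
                                 comparison_label = "") {
  check_named_numeric(expr_stress, "expr_stress")
  check_named_numeric(expr_control, "expr_control")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("'pseudocount' must be a single non-negative number")
  common <- intersect(names(expr_stress), names(expr_control))
  if (length(common) == 0L) stop("no common genes")
  n_dropped <- (length(expr_stress) - length(common)) +
    (length(expr_control) - length(common))
  num <- expr_stress[common] + pseudocount
  den <- expr_control[common] + pseudocount
  zero_den <- den == 0
  fc <- num[!zero_den] / den[!zero_den]
  out <- fold_change_table(fc, comparison_label, n_excluded = sum(zero_den))
  attr(out, "n_dropped") <- as.integer(n_dropped)
  out
}

#' Classify genes into directional regulated sets
#'
#' Applies strict fold-change cutoffs: up-regulated genes have ratio
#' strictly greater than `up_cutoff` (default 2), down-regulated genes
#' strictly less than `down_cutoff` (default 0.5). Genes exactly at a cutoff
#' belong to neither set. The universe is every gene in the table.
#'
#' @param fc a [fold_change_table()].
#' @param up_cutoff,down_cutoff ratios with `up_cutoff > 1 > down_cutoff > 0`.
#'
#' @return An object of class `directional_gene_sets`: list with `up`,
#'   `down` and `universe` (character vectors of gene ids) plus the cutoffs
#'   and the source label.
#' @export
#' @examples
#' fc <- fold_change_table(c(g1 = 3, g2 = 2, g3 = 0.4, g4 = 1, g5 = 0.5, g6 = 2.5))
#' classify_directional_sets(fc)
classify_directional_sets <- function(fc, up_cutoff = 2, down_cutoff = 0.5) {
  if (!inherits(fc, "fold_change_table")) stop("'fc' must be a fold_change_table")
  if (length(fc$fc) == 0L) stop("empty fold-change table")
  if (!(up_cutoff > 1 && down_cutoff < 1 && down_cutoff > 0))
    stop("cutoffs must satisfy up_cutoff > 1 > down_cutoff > 0")
  structure(
    list(up = names(fc$fc)[fc$fc > up_cutoff],
         down = names(fc$fc)[fc$fc < down_cutoff],
         universe = names(fc$fc),
         up_cutoff = up_cutoff, down_cutoff = down_cutoff,
         comparison_label = fc$comparison_label),
    class = "directional_gene_sets")
}

#' @export
print.directional_gene_sets <- function(x, ...) {
  cat(sprintf("Directional gene sets '%s': %d up (> %g), %d down (< %g), universe %d\n",
              x$comparison_label, length(x$up), x$up_cutoff,
              length(x$down), x$down_cutoff, length(x$universe)))
  invisible(x)
}
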