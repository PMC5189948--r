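#' Relative expression by the comparative Ct (delta-delta-Ct) method
#'
#' Computes the fold change of a target transcript in a treated sample
#' relative to a control sample, normalized against a reference gene (an
#' endogenous control such as 16S rRNA), assuming perfect amplification
#' efficiency (factor 2 per cycle):
#' `2^-((CtT,treated - CtR,treated) - (CtT,control - CtR,control))`.
#'
#' Each argument may be a vector of technical replicate Ct values; these
#' are averaged to a mean Ct before the formula is applied.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Ct value(s) for target/reference in the treated/control condition.
#' @return The fold change (dimensionless, > 0).
#' @export
#' @examples
#' relative_expression_ddct(25, 10, 22, 10) # 2^-3 = 0.125
relative_expression_ddct <- function(ct_target_treated, ct_ref_treated,
                                     ct_target_control, ct_ref_control) {
  cts <- list(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(vapply(cts, function(v) length(v) == 0 || any(!is.finite(v)), logical(1))))
    stop("all Ct values must be finite and non-empty")
  m <- vapply(cts, mean, numeric(1))
  ddct <- (m[1] - m[2]) - (m[3] - m[4])
  2^(-ddct)
}

#' ChIP-qPCR percent of input
#'
#' Expresses immunoprecipitated DNA as a percentage of the total input
#' chromatin. The input aliquot is only a fraction of the IP material, so
#' the input Ct is first adjusted to 100% by subtracting
#' `log2(1 / input_fraction)` cycles; the result is
#' `100 * 2^(adjusted_input_ct - ct_ip)`.
#'
#' @param ct_input Ct value(s) of the input (total chromatin) reaction;
#'   technical replicates are averaged.
#' @param ct_ip Ct value(s) of the immunoprecipitated sample; technical
#'   replicates are averaged.
#' @param input_fraction fraction of the sample used as input, in (0, 1];
#'   default 0.05 (a 5% input).
#' @return Percent of input (>= 0).
#' @export
#' @examples
#' percent_input(20, 22, 0.05) # 1.25
percent_input <- function(ct_input, ct_ip, input_fraction = 0.05) {
  if (!is.numeric(input_fraction) || length(input_fraction) != 1L ||
      input_fraction <= 0 || input_fraction > 1)
    stop("'input_fraction' must lie in (0, 1]")
  if (any(!is.finite(ct_input)) || any(!is.finite(ct_ip)))
    stop("Ct values must be finite")
  adjusted_input <- mean(ct_input) - log2(1 / input_fraction)
  100 * 2^(adjusted_input - mean(ct_ip))
}

#' Relative occupancy between two percent-of-input values
#'
#' Occupancy of a binding site in one condition expressed as a percentage
#' of a baseline condition.
#'
#' @param percent_input_condition percent of input in the condition of
#'   interest (>= 0).
#' @param percent_input_baseline percent of input in the baseline
#'   condition (> 0).
#' @return Percent of baseline occupancy.
#' @export
#' @examples
#' relative_occupancy(0.225, 1.25) # 18
relative_occupancy <- function(percent_input_condition, percent_input_baseline) {
  if (!is.numeric(percent_input_baseline) || percent_input_baseline <= 0)
    stop("'percent_input_baseline' must be > 0")
  if (percent_input_condition < 0) stop("percent of input cannot be negative")
  100 * percent_input_condition / percent_input_baseline
}

#' Ct table constructor
#'
#' Long-format container of qPCR cycle-threshold measurements: one row per
#' (sample, target) with its technical replicate Ct values.
#'
#' @param sample,target,role character vectors (recycled to a common
#'   length); `role` is one of "target", "reference", "input", "ip".
#' @param ct list (or matrix with one row per record) of technical
#'   replicate Ct values, all finite and > 0.
#' @return A data.frame of class `ct_table` with columns `sample`,
#'   `target`, `role` and list-column `ct`.
#' @export
ct_table <- function(sample, target, role, ct) {
  if (is.matrix(ct)) ct <- lapply(seq_len(nrow(ct)), function(i) ct[i, ])
  if (!is.list(ct)) ct <- list(ct)
  n <- max(length(sample), length(target), length(role), length(ct))
  df <- data.frame(sample = rep_len(as.character(sample), n),
                   target = rep_len(as.character(target), n),
                   role = rep_len(as.character(role), n),
                   stringsAsFactors = FALSE)
  ct <- rep_len(ct, n)
  ok_role <- df$role %in% c("target", "reference", "input", "ip")
  if (!all(ok_role))
    stop("role must be one of target, reference, input, ip")
  for (v in ct) {
    v <- as.numeric(v)
    if (length(v) < 1 || any(!is.finite(v)) || any(v <= 0))
      stop("every record needs >= 1 finite positive Ct value")
  }
  df$ct <- lapply(ct, as.numeric)
  class(df) <- c("ct_table", "data.frame")
  df
}

ct_record <- function(tab, sample, target) {
  i <- which(tab$sample == sample & tab$target == target)
  if (length(i) != 1L)
    stop(sprintf("expected exactly one record for sample '%s', target '%s' (found %d)",
                 sample, target, length(i)))
  tab$ct[[i]]
}

#' Relative expression for every target in a Ct table
#'
#' Applies [relative_expression_ddct()] to each non-reference target of
#' each treated sample against the control sample, normalizing with the
#' reference target. Technical replicates are averaged to a mean Ct; their
#' spread is propagated (assuming perfect efficiency) to a multiplicative
#' uncertainty factor `2^se`, where `se` is the standard error of the
#' delta-delta-Ct in cycles.
#'
#' @param tab a [ct_table()].
#' @param ref_target name of the reference (endogenous control) target.
#' @param control_sample name of the untreated/control sample.
#' @return data.frame with columns `sample`, `target`, `value` (fold
#'   change), `basis` ("ddct") and `uncertainty` (multiplicative factor;
#'   the band is value / uncertainty to value * uncertainty).
#' @export
quantify_expression <- function(tab, ref_target, control_sample) {
  if (!inherits(tab, "ct_table")) stop("'tab' must be a ct_table")
  if (!ref_target %in% tab$target) stop(sprintf("reference target '%s' not found", ref_target))
  if (!control_sample %in% tab$sample) stop(sprintf("control sample '%s' not found", control_sample))
  samples <- setdiff(unique(tab$sample), control_sample)
  targets <- setdiff(unique(tab$target), ref_target)
  out <- list()
  for (s in samples) for (tg in targets) {
    cts <- list(ct_record(tab, s, tg), ct_record(tab, s, ref_target),
                ct_record(tab, control_sample, tg),
                ct_record(tab, control_sample, ref_target))
    val <- relative_expression_ddct(cts[[1]], cts[[2]], cts[[3]], cts[[4]])
    # var of a mean Ct = sd^2 / n; ddct variance is the sum of the four
    se <- sqrt(sum(vapply(cts, function(v)
      if (length(v) > 1) stats::var(v) / length(v) else 0, numeric(1))))
    out[[length(out) + 1L]] <- data.frame(
      sample = s, target = tg, value = val, basis = "ddct",
      uncertainty = 2^se, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Percent of input for every IP record in a Ct table
#'
#' Pairs each `role = "ip"` record with the `role = "input"` record of the
#' same sample and target and applies [percent_input()].
#'
#' @param tab a [ct_table()] containing matched `input` and `ip` records.
#' @param input_fraction see [percent_input()].
#' @return data.frame with columns `sample`, `target`, `value` (percent of
#'   input) and `basis` ("percent_input").
#' @export
quantify_percent_input <- function(tab, input_fraction = 0.05) {
  if (!inherits(tab, "ct_table")) stop("'tab' must be a ct_table")
  ips <- which(tab$role == "ip")
  if (!length(ips)) stop("no role = 'ip' records")
  out <- lapply(ips, function(i) {
    j <- which(tab$role == "input" & tab$sample == tab$sample[i] &
               tab$target == tab$target[i])
    if (length(j) != 1L)
      stop(sprintf("no unique input record for sample '%s', target '%s'",
                   tab$sample[i], tab$target[i]))
    data.frame(sample = tab$sample[i], target = tab$target[i],
               value = percent_input(tab$ct[[j]], tab$ct[[i]], input_fraction),
               basis = "percent_input", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
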