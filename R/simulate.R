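#' Simulate a pair of fold-change tables with a planted shared regulon
#'
#' Generates two stress/non-stress comparisons over one genome-sized gene
#' universe. A planted set of shared genes (one random draw) responds in
#' both comparisons — the common regulon; condition-specific genes are
#' drawn independently for each comparison from the remaining genes, so
#' with no shared genes the two regulons are independent (the null); every
#' other gene fluctuates around 1. Effects and noise are log-normal:
#' a responding gene gets fold-change `2^x` with
#' `x ~ Normal(effect_log2fc_mean, effect_log2fc_sd)` (sign flipped for
#' down-regulated genes); null genes get `x ~ Normal(0, null_log2fc_sd)`.
#'
#' The defaults emulate a genome of ~4000 genes in which two related
#' stresses share a regulon of a few hundred up- and down-regulated genes,
#' the regime in which the intersection z-score is used.
#'
#' @param n_genes universe size; default 4000.
#' @param n_up_shared,n_down_shared planted genes responding in both
#'   tables; defaults 400 and 280.
#' @param n_up_specific,n_down_specific genes responding in only one table
#'   (each table gets its own disjoint block); defaults 70 each.
#' @param effect_log2fc_mean,effect_log2fc_sd log2 effect size of
#'   responding genes; defaults 2 and 0.3.
#' @param null_log2fc_sd log2 spread of non-responding genes; default 0.3.
#' @param seed integer seed (required); the generator is bit-reproducible.
#' @param labels length-2 character vector of comparison labels.
#' @return A list of two [fold_change_table()] objects.
#' @export
#' @examples
#' pair <- simulate_regulon_pair(n_genes = 500, n_up_shared = 50,
#'   n_down_shared = 30, n_up_specific = 10, n_down_specific = 10, seed = 1)
#' compare_conditions(pair[[1]], pair[[2]], n_mc = 500, seed = 2)
simulate_regulon_pair <- function(n_genes = 4000,
                                  n_up_shared = 400, n_down_shared = 280,
                                  n_up_specific = 70, n_down_specific = 70,
                                  effect_log2fc_mean = 2, effect_log2fc_sd = 0.3,
                                  null_log2fc_sd = 0.3, seed,
                                  labels = c("conditionA", "conditionB")) {
  if (missing(seed)) stop("'seed' is required")
  if (effect_log2fc_sd < 0 || null_log2fc_sd < 0) stop("sds must be >= 0")
  n_shared <- n_up_shared + n_down_shared
  n_specific <- n_up_specific + n_down_specific
  if (n_shared + n_specific > n_genes)
    stop("planted shared + specific gene counts exceed n_genes")
  genes <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    # shared regulon: one random draw, regulated in both conditions.
    # condition-specific genes: independent draws from the remainder, so a
    # zero-shared spec yields two genuinely independent regulons (the null).
    shared <- sample.int(n_genes, n_shared)
    sh_up <- shared[seq_len(n_up_shared)]
    sh_down <- shared[n_up_shared + seq_len(n_down_shared)]
    avail <- setdiff(seq_len(n_genes), shared)
    draw_effect <- function(n, sign)
      sign * stats::rnorm(n, effect_log2fc_mean, effect_log2fc_sd)
    one_table <- function(label) {
      spec <- avail[sample.int(length(avail), n_specific)]
      up_idx <- c(sh_up, spec[seq_len(n_up_specific)])
      down_idx <- c(sh_down, spec[n_up_specific + seq_len(n_down_specific)])
      x <- stats::rnorm(n_genes, 0, null_log2fc_sd)
      x[up_idx] <- draw_effect(length(up_idx), +1)
      x[down_idx] <- draw_effect(length(down_idx), -1)
      fold_change_table(stats::setNames(2^x, genes), label)
    }
    list(one_table(labels[1]), one_table(labels[2]))
  })
}

#' Simulate a translation shut-off decay time course
#'
#' Single-exponential decay with multiplicative log-normal noise:
#' `intensity(rep, t) = exp(-ln(2) * t / t_half) * eps` with `eps`
#' log-normal with mean 1 and coefficient of variation `noise_cv`,
#' independent per replicate and time point.
#'
#' @param t_half true half-life in minutes (> 0); default 26.
#' @param times sampling grid in minutes starting at 0; default every
#'   10 min up to 60.
#' @param n_replicates number of replicates; default 3.
#' @param noise_cv coefficient of variation of the multiplicative noise;
#'   default 0.1 (10% densitometry error). 0 gives a noiseless curve.
#' @param seed integer seed (required).
#' @param condition_label label stored on the time course.
#' @return A [decay_timecourse()] (raw scale, not yet normalized).
#' @export
#' @examples
#' fit_half_life(simulate_decay(t_half = 26, seed = 1))
simulate_decay <- function(t_half = 26, times = seq(0, 60, by = 10),
                           n_replicates = 3, noise_cv = 0.1, seed,
                           condition_label = "") {
  if (missing(seed)) stop("'seed' is required")
  if (t_half <= 0) stop("'t_half' must be > 0")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  mu <- exp(-log(2) * times / t_half)
  with_seed(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      meanlog <- -sdlog^2 / 2 # lognormal with mean exactly 1
      eps <- matrix(stats::rlnorm(length(times) * n_replicates, meanlog, sdlog),
                    nrow = length(times))
    } else {
      eps <- matrix(1, nrow = length(times), ncol = n_replicates)
    }
    decay_timecourse(times, mu * eps, condition_label = condition_label)
  })
}

#' Simulate a comparative-Ct qPCR experiment
#'
#' Builds a [ct_table()] for a treated and a control sample from known
#' true expression ratios. Each target's Ct is
#' `base_ct - log2(relative template) + Normal(0, ct_noise_sd)` per
#' technical replicate; the control sample has relative template 1 for
#' every target, and a reference target with ratio 1 in both samples is
#' added for normalization.
#'
#' @param true_fold_changes numeric vector of true treated/control ratios
#'   (> 0), named by target.
#' @param base_ct baseline cycle threshold; default 20.
#' @param ct_noise_sd technical noise in cycles; default 0.2.
#' @param n_technical technical replicates per reaction; default 3.
#' @param seed integer seed (required).
#' @return A [ct_table()] with samples "treated" and "control" and a
#'   reference target named "reference".
#' @export
#' @examples
#' tab <- simulate_ct_table(c(sciP = 0.125), ct_noise_sd = 0, seed = 1)
#' quantify_expression(tab, "reference", "control")
simulate_ct_table <- function(true_fold_changes, base_ct = 20,
                              ct_noise_sd = 0.2, n_technical = 3, seed) {
  if (missing(seed)) stop("'seed' is required")
  check_named_numeric(true_fold_changes, "true_fold_changes")
  if (any(true_fold_changes <= 0)) stop("ratios must be > 0")
  targets <- c(names(true_fold_changes), "reference")
  ratio <- c(true_fold_changes, reference = 1)
  with_seed(seed, {
    rows <- list()
    for (s in c("treated", "control")) for (tg in targets) {
      template <- if (s == "treated") ratio[[tg]] else 1
      cts <- base_ct - log2(template) +
        stats::rnorm(n_technical, 0, ct_noise_sd)
      rows[[length(rows) + 1L]] <- list(
        sample = s, target = tg,
        role = if (tg == "reference") "reference" else "target", ct = cts)
    }
    ct_table(sample = vapply(rows, `[[`, "", "sample"),
             target = vapply(rows, `[[`, "", "target"),
             role = vapply(rows, `[[`, "", "role"),
             ct = lapply(rows, `[[`, "ct"))
  })
}
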