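new_overlap_z <- function(n1, n2, N, k_observed, null_mean, null_sd, z,
                          degenerate, n_mc, seed, method,
                          set1_label = "", set2_label = "", direction = "") {
  structure(
    list(n1 = as.integer(n1), n2 = as.integer(n2), N = as.integer(N),
         k_observed = as.integer(k_observed),
         null_mean = null_mean, null_sd = null_sd, z = z,
         degenerate = isTRUE(degenerate),
         n_mc = if (is.null(n_mc)) NA_integer_ else as.integer(n_mc),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         method = method,
         set1_label = set1_label, set2_label = set2_label,
         direction = direction),
    class = "overlap_z")
}

# Sample n_mc intersection sizes of two independent uniform random subsets
# (sizes n1, n2) of a universe of size N. Both sets are redrawn every
# iteration; conditioning one set fixed gives the same hypergeometric null.
mc_intersection_sizes <- function(N, n1, n2, n_mc) {
  ks <- integer(n_mc)
  for (i in seq_len(n_mc))
    ks[i] <- sum(sample.int(N, n1) %in% sample.int(N, n2))
  ks
}

#' Monte-Carlo intersection z-score between two gene sets
#'
#' Scores how far the observed intersection of two gene sets departs from a
#' random intersection. The null distribution is sampled by repeatedly
#' drawing two independent uniform random subsets of the universe with the
#' same sizes as the observed sets and recording their intersection size;
#' the z-score is the number of (sample) standard deviations the observed
#' intersection lies from the null mean. The z is signed: positive for
#' enrichment, negative for depletion.
#'
#' The null is hypergeometric, so [analytic_overlap_z()] provides an exact
#' closed-form cross-check.
#'
#' @param set_a,set_b character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe character vector of all measurable gene ids.
#' @param n_mc number of Monte-Carlo iterations (>= 2); default 10000.
#' @param seed integer seed; mandatory, for reproducibility. The caller's
#'   RNG state is preserved.
#' @param set1_label,set2_label,direction labels carried into reports.
#'
#' @return An object of class `overlap_z` with elements `n1`, `n2`, `N`,
#'   `k_observed`, `null_mean`, `null_sd`, `z`, `degenerate`, `n_mc`,
#'   `seed`, `method`. When the null has zero spread (e.g. an empty or
#'   saturated set) `z` is `NA` and `degenerate` is `TRUE`.
#' @export
#' @examples
#' u <- paste0("g", 1:100)
#' mc_overlap_z(u[1:10], u[5:20], u, n_mc = 1000, seed = 1)
mc_overlap_z <- function(set_a, set_b, universe, n_mc = 10000, seed,
                         set1_label = "", set2_label = "", direction = "") {
  universe <- unique(as.character(universe))
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  if (!all(set_a %in% universe)) stop("set_a is not a subset of the universe")
  if (!all(set_b %in% universe)) stop("set_b is not a subset of the universe")
  if (n_mc < 2) stop("'n_mc' must be >= 2")
  if (missing(seed) || is.null(seed)) stop("'seed' is required for the Monte-Carlo null")
  N <- length(universe); n1 <- length(set_a); n2 <- length(set_b)
  k_obs <- length(intersect(set_a, set_b))
  ks <- with_seed(seed, {
    if (n1 == 0L || n2 == 0L) integer(n_mc) else mc_intersection_sizes(N, n1, n2, n_mc)
  })
  m <- mean(ks); s <- stats::sd(ks)
  degen <- !is.finite(s) || s == 0
  new_overlap_z(n1, n2, N, k_obs, m, if (degen) 0 else s,
                if (degen) NA_real_ else (k_obs - m) / s,
                degen, n_mc, seed, "monte_carlo",
                set1_label, set2_label, direction)
}

#' Analytic (hypergeometric) intersection z-score
#'
#' Closed-form oracle for [mc_overlap_z()]. The intersection of two
#' independent uniform random subsets of sizes `n1` and `n2` drawn from a
#' universe of size `N` is hypergeometric with mean `n1*n2/N` and variance
#' `n1*n2*(N-n1)*(N-n2) / (N^2*(N-1))`.
#'
#' @param n1,n2 set sizes (0 <= n1, n2 <= N).
#' @param N universe size (>= 2).
#' @param k_observed observed intersection size (0 <= k <= min(n1, n2)).
#' @inheritParams mc_overlap_z
#' @return An `overlap_z` object with `method = "analytic"`.
#' @export
#' @examples
#' analytic_overlap_z(5, 8, 20, 4) # z ~ 2.0548
analytic_overlap_z <- function(n1, n2, N, k_observed,
                               set1_label = "", set2_label = "", direction = "") {
  if (N < 2) stop("'N' must be >= 2")
  if (n1 < 0 || n2 < 0 || n1 > N || n2 > N) stop("set sizes must lie in [0, N]")
  if (k_observed < 0 || k_observed > min(n1, n2))
    stop("k_observed must lie in [0, min(n1, n2)]")
  # double arithmetic: the variance product overflows integers at genome scale
  n1 <- as.double(n1); n2 <- as.double(n2); N <- as.double(N)
  mu <- n1 * n2 / N
  v <- n1 * n2 * (N - n1) * (N - n2) / (N^2 * (N - 1))
  degen <- v <= 0
  new_overlap_z(n1, n2, N, k_observed, mu, sqrt(max(v, 0)),
                if (degen) NA_real_ else (k_observed - mu) / sqrt(v),
                degen, NULL, NULL, "analytic",
                set1_label, set2_label, direction)
}

#' @export
print.overlap_z <- function(x, ...) {
  cat(sprintf("Intersection z-score (%s%s)\n", x$method,
              if (x$method == "monte_carlo") sprintf(", n_mc = %d, seed = %d", x$n_mc, x$seed) else ""))
  if (nzchar(x$set1_label) || nzchar(x$set2_label))
    cat(sprintf("  %s vs %s%s\n", x$set1_label, x$set2_label,
                if (nzchar(x$direction)) paste0(" [", x$direction, "]") else ""))
  cat(sprintf("  |A| = %d, |B| = %d, universe N = %d, observed overlap k = %d\n",
              x$n1, x$n2, x$N, x$k_observed))
  cat(sprintf("  null mean = %.4g, null sd = %.4g\n", x$null_mean, x$null_sd))
  if (x$degenerate) cat("  z = undefined (degenerate null: zero spread)\n")
  else cat(sprintf("  z = %.4g\n", x$z))
  invisible(x)
}

#' @export
as.data.frame.overlap_z <- function(x, ...) {
  data.frame(set1_label = x$set1_label, set2_label = x$set2_label,
             direction = x$direction, n1 = x$n1, n2 = x$n2, N = x$N,
             k_observed = x$k_observed, null_mean = x$null_mean,
             null_sd = x$null_sd, z = x$z, n_mc = x$n_mc, seed = x$seed,
             method = x$method, stringsAsFactors = FALSE)
}

#' Compare two stress comparisons by directional regulon overlap
#'
#' Classifies both fold-change tables over a shared universe and scores the
#' similarity of their up-regulated sets and of their down-regulated sets
#' with intersection z-scores. The default universe is the genes measured
#' in both tables, which is what makes comparisons across platforms (e.g.
#' RNA-seq vs microarray) fair; `universe = "union"` is available.
#'
#' @param fc1,fc2 [fold_change_table()] objects sharing at least 2 genes.
#' @param up_cutoff,down_cutoff passed to [classify_directional_sets()].
#' @param universe `"intersection"` (default) or `"union"` of the genes in
#'   the two tables.
#' @param n_mc,seed Monte-Carlo settings (see [mc_overlap_z()]); `seed` is
#'   required when `method = "monte_carlo"`.
#' @param method `"monte_carlo"` (default) or `"analytic"` (hypergeometric
#'   closed form, no randomness).
#'
#' @return An object of class `condition_comparison`: a list with `up` and
#'   `down`, each an `overlap_z`.
#' @export
compare_conditions <- function(fc1, fc2, up_cutoff = 2, down_cutoff = 0.5,
                               universe = c("intersection", "union"),
                               n_mc = 10000, seed = NULL,
                               method = c("monte_carlo", "analytic")) {
  universe <- match.arg(universe)
  method <- match.arg(method)
  if (!inherits(fc1, "fold_change_table") || !inherits(fc2, "fold_change_table"))
    stop("'fc1' and 'fc2' must be fold_change_table objects")
  uni <- if (universe == "intersection") intersect(names(fc1$fc), names(fc2$fc))
         else union(names(fc1$fc), names(fc2$fc))
  if (length(uni) < 2) stop("the two tables share fewer than 2 genes")
  restrict <- function(fc) {
    keep <- names(fc$fc) %in% uni
    fold_change_table(fc$fc[keep], fc$comparison_label)
  }
  s1 <- classify_directional_sets(restrict(fc1), up_cutoff, down_cutoff)
  s2 <- classify_directional_sets(restrict(fc2), up_cutoff, down_cutoff)
  one <- function(a, b, dir) {
    if (method == "monte_carlo")
      mc_overlap_z(a, b, uni, n_mc = n_mc, seed = seed,
                   set1_label = fc1$comparison_label,
                   set2_label = fc2$comparison_label, direction = dir)
    else
      analytic_overlap_z(length(a), length(b), length(uni),
                         length(intersect(a, b)),
                         set1_label = fc1$comparison_label,
                         set2_label = fc2$comparison_label, direction = dir)
  }
  structure(list(up = one(s1$up, s2$up, "up"),
                 down = one(s1$down, s2$down, "down")),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  print(x$up); print(x$down)
  invisible(x)
}

#' @export
as.data.frame.condition_comparison <- function(x, ...) {
  rbind(as.data.frame(x$up), as.data.frame(x$down))
}
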