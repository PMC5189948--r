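# shared fixture builders

make_universe <- function(n) sprintf("g%05d", seq_len(n))

# fold-change table with prescribed up/down genes and quiet background
make_fc <- function(n_genes, up_idx = integer(0), down_idx = integer(0),
                    label = "fc") {
  genes <- make_universe(n_genes)
  fc <- rep(1, n_genes)
  fc[up_idx] <- 4
  fc[down_idx] <- 0.25
  fold_change_table(stats::setNames(fc, genes), label)
}

# exhaustive moments of the intersection-size null from the hypergeometric
# pmf written out with binomial coefficients (independent of the package's
# closed form)
enum_hyper_moments <- function(N, n1, n2) {
  ks <- max(0, n1 + n2 - N):min(n1, n2)
  p <- choose(n1, ks) * choose(N - n1, n2 - ks) / choose(N, n2)
  m <- sum(ks * p)
  list(mean = m, sd = sqrt(sum((ks - m)^2 * p)), p = p)
}
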