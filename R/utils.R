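# internal helpers shared across modules

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (length(seed) != 1L || is.na(seed)) stop("'seed' must be a single integer")
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Assert a named numeric vector of expression values / fold-changes.
check_named_numeric <- function(x, what) {
  if (!is.numeric(x) || is.null(names(x)) || any(names(x) == "") || any(is.na(names(x))))
    stop(sprintf("'%s' must be a numeric vector named by gene_id", what))
  if (anyDuplicated(names(x)))
    stop(sprintf("duplicate gene_ids in '%s': %s", what,
                 paste(unique(names(x)[duplicated(names(x))]), collapse = ", ")))
  invisible(x)
}

# Deterministic 6-significant-digit formatting for report files.
fmt6 <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else if (is.infinite(v)) ifelse(v > 0, "Inf", "-Inf")
    else sprintf("%.6g", v)
  }, character(1))
}
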