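# Internal helpers shared across modules.

# Linear-interpolation percentile (between order statistics; quantile type 7).
# p is on the 0-100 scale. This convention is used everywhere a percentile
# enters a result: hot-pixel capping, rSD, 0-1 scaling.
.pctile <- function(x, p) {
  stats::quantile(x, probs = p / 100, type = 7, names = FALSE, na.rm = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses (and advances) the
# session RNG.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Working intensity assay: the most processed pre-transform matrix.
.working_assay <- function(ct) {
  if ("compensated" %in% assayNames(ct)) "compensated" else "raw"
}

.assert_scalar_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop("'", nm, "' must be TRUE or FALSE")
}
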