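# Internal helpers shared across modules.

# Chromosome ordering: chr1..chr22, chrX, chrY, then anything else.
.chrom_rank <- function(chrom) {
  key <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(key))
  rank <- ifelse(!is.na(num), num,
                 ifelse(key == "X", 23L, ifelse(key == "Y", 24L, 25L)))
  rank
}

.order_by_position <- function(chrom, pos) {
  order(.chrom_rank(chrom), chrom, pos)
}

# Evaluate `expr` with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so seeded functions compose without interference.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stopf("'%s' must be a single value in [0, 1]", name)
}

# Dirichlet draws via independent gammas (rows = draws).
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
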