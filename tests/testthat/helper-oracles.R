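# Independent oracles: deliberately naive re-derivations used to check the
# package implementations against first principles.

# Benjamini-Hochberg step-up by direct enumeration of the definition:
# p_adj(i) = min over j with p_(j) >= p_(i) of n * p_(j) / j, clamped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(n * ranked[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Per-probe OLS via explicit normal equations.
oracle_ols <- function(M, X) {
  XtXi <- solve(t(X) %*% X)
  coefs <- t(XtXi %*% t(X) %*% t(M))
  res <- M - coefs %*% t(X)
  df <- nrow(X) - ncol(X)
  list(coefficients = coefs, sigma = sqrt(rowSums(res^2) / df),
       df = df, xtx_inv = XtXi)
}

# AUC by brute-force pairwise counting.
oracle_auc <- function(cases, controls) {
  wins <- 0
  for (a in cases) for (b in controls) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(cases) * length(controls))
}

# Greedy correlation pruning re-implemented literally from its definition.
oracle_prune <- function(X, ids, threshold) {
  kept <- sort(ids)
  repeat {
    if (length(kept) < 2) break
    C <- abs(stats::cor(t(X[kept, , drop = FALSE])))
    diag(C) <- 0
    if (max(C) <= threshold) break
    best <- NULL
    for (i in seq_along(kept)) for (j in seq_along(kept)) {
      if (i < j && C[i, j] == max(C) && is.null(best)) best <- c(i, j)
    }
    mi <- mean(C[best[1], -best[1]])
    mj <- mean(C[best[2], -best[2]])
    drop_i <- if (mi > mj) best[1] else if (mj > mi) best[2] else max(best)
    kept <- kept[-drop_i]
  }
  kept
}

# Tiny deterministic beta matrix fixture.
tiny_beta <- function(p = 4, n = 3, seed = 1) {
  set.seed(seed)
  v <- matrix(round(runif(p * n, 0.05, 0.95), 4), p, n,
              dimnames = list(sprintf("cg%03d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  beta_matrix(v)
}

# Shared small simulated cohort, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- sim_config(n_background_probes = 1500,
                      planted_regions = claes_jensen_regions(),
                      n_chrx_probes = 60, seed = 417)
    man <- generate_manifest(cfg)
    cfg$planted_probe_effects <-
      sample_probe_effects(cfg, man, 80, delta_min = 0.2, delta_max = 0.35)
    cohort <- simulate_cohort(cfg, man)
    .fixture_env$cohort <- list(config = cfg, manifest = man,
                                beta = cohort$beta, sheet = cohort$sheet,
                                truth = cohort$truth)
  }
  .fixture_env$cohort
}

# Classifier-grade cohort: low noise so that every planted probe fully
# separates patients from controls.
classifier_cohort <- function() {
  if (is.null(.fixture_env$clf)) {
    cfg <- sim_config(n_background_probes = 800, noise_sd = 0.12,
                      n_chrx_probes = 20, seed = 902)
    man <- generate_manifest(cfg)
    cfg$planted_probe_effects <-
      sample_probe_effects(cfg, man, 60, delta_min = 0.2, delta_max = 0.35)
    cohort <- simulate_cohort(cfg, man)
    .fixture_env$clf <- list(config = cfg, manifest = man,
                             beta = cohort$beta, sheet = cohort$sheet,
                             truth = cohort$truth)
  }
  .fixture_env$clf
}
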