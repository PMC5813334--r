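# Per-probe differential methylation on M-values: ordinary least squares per
# probe, empirical-Bayes variance moderation, Benjamini-Hochberg correction,
# and the dual significance gate (adjusted p < 0.01 AND |delta beta| > 0.10,
# the delta measured on the beta scale).

#' Build a patient-vs-control design matrix with cell-fraction covariates
#'
#' Columns: intercept, group indicator (patient = 1, control = 0), and the
#' first `K - 1` cell-type fractions (the last type is dropped because the
#' fractions sum to one and would be collinear with the intercept).
#'
#' @param sheet a validated sample sheet.
#' @param sample_ids samples (columns of the M matrix) in order; all must be
#'   labeled `patient` or `control`.
#' @param fractions optional samples x cell-types fraction matrix from
#'   [estimate_cell_fractions()].
#' @return numeric design matrix with rows aligned to `sample_ids`.
#' @export
build_design_matrix <- function(sheet, sample_ids, fractions = NULL) {
  sheet <- validate_sample_sheet(sheet)
  grp <- sheet$group[match(sample_ids, sheet$sample_id)]
  if (anyNA(grp))
    .stopf("sample(s) missing from sheet: %s",
           paste(utils::head(sample_ids[is.na(grp)], 3), collapse = ", "))
  if (!all(grp %in% c("patient", "control")))
    .stopf("design matrix supports patient/control samples only; found: %s",
           paste(setdiff(unique(grp), c("patient", "control")), collapse = ", "))
  X <- cbind(intercept = 1, group = as.numeric(grp == "patient"))
  if (!is.null(fractions)) {
    fr <- fractions[match(sample_ids, rownames(fractions)), , drop = FALSE]
    if (anyNA(fr)) .stopf("cell fractions missing for some samples")
    X <- cbind(X, fr[, -ncol(fr), drop = FALSE])
  }
  rownames(X) <- sample_ids
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    .stopf("design matrix is rank deficient; collinear column(s): %s",
           paste(dropped, collapse = ", "))
  }
  X
}

#' Fit per-probe ordinary least squares models on M-values
#'
#' One OLS fit per probe against a shared design matrix. Returns the group
#' coefficient, residual standard deviation, residual degrees of freedom and
#' the unscaled variance of the group coefficient (the corresponding diagonal
#' entry of \eqn{(X^T X)^{-1}}).
#'
#' @param M probes x samples matrix of M-values.
#' @param design design matrix from [build_design_matrix()] (rows = samples).
#' @param coef name of the coefficient of interest (default `"group"`).
#' @return list with `coefficients`, `sigma`, `df_residual`,
#'   `stdev_unscaled` and `probe_ids`.
#' @export
fit_probe_models <- function(M, design, coef = "group") {
  if (ncol(M) != nrow(design))
    .stopf("M has %d samples but design has %d rows", ncol(M), nrow(design))
  if (nrow(design) <= ncol(design))
    .stopf("need more samples (%d) than design columns (%d)",
           nrow(design), ncol(design))
  if (!coef %in% colnames(design))
    .stopf("design has no column named '%s'", coef)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    .stopf("design matrix is rank deficient; collinear column(s): %s",
           paste(dropped, collapse = ", "))
  }
  coefs <- t(qr.coef(qrX, t(M)))            # probes x k
  res <- t(qr.resid(qrX, t(M)))
  df <- nrow(design) - qrX$rank
  sigma <- sqrt(rowSums(res^2) / df)
  xtx_inv <- chol2inv(chol(crossprod(design)))
  v <- xtx_inv[match(coef, colnames(design)), match(coef, colnames(design))]
  list(coefficients = coefs[, coef], sigma = unname(sigma),
       df_residual = rep(df, nrow(M)), stdev_unscaled = sqrt(v),
       probe_ids = rownames(M))
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear.
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Estimates a scaled inverse-chi-squared prior (`d0` prior degrees of
#' freedom, `s0_sq` prior variance) for the residual variances by the method
#' of moments on `log(s_g^2)` (digamma/trigamma inversion), forms posterior
#' variances `s_post^2 = (d0 s0_sq + df s_g^2) / (d0 + df)`, and returns
#' moderated t-statistics with `d0 + df` degrees of freedom (capped at 1e6
#' when `d0` is infinite, i.e. when the variances show no excess spread and
#' every posterior variance equals `s0_sq`). Probes with zero residual
#' variance are excluded from prior estimation but still receive a posterior
#' variance from the prior.
#'
#' @param fit output of [fit_probe_models()].
#' @return list with `params` (`d0`, `s0_sq`), `t_mod`, `p`, `s_post_sq`
#'   and `df_total`.
#' @export
ebayes_moderate <- function(fit) {
  sigma <- fit$sigma
  df <- fit$df_residual
  ok <- is.finite(sigma) & sigma > 0 & df > 0
  if (sum(ok) < 10)
    .stopf("need at least 10 probes with positive residual variance (have %d)",
           sum(ok))
  z <- log(sigma[ok]^2)
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  s_post_sq <- if (is.finite(d0))
    (d0 * s0_sq + df * sigma^2) / (d0 + df) else rep(s0_sq, length(sigma))
  df_total <- pmin(d0 + df, 1e6)
  t_mod <- fit$coefficients / (sqrt(s_post_sq) * fit$stdev_unscaled)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  list(params = list(d0 = d0, s0_sq = s0_sq),
       t_mod = t_mod, p = p, s_post_sq = s_post_sq, df_total = df_total)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control:
#' `p_adj(i) = min_{j >= i} (n p_(j) / j)`, clamped at 1 and mapped back to
#' the input order (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated probes with the dual threshold
#'
#' Retains probes with BH-adjusted p below `p_adj_cut` AND an absolute
#' methylation difference above `delta_cut`. The test statistic comes from
#' the M-value model; the effect-size gate is computed on the beta scale as
#' the difference of group mean betas (patients minus controls), which is the
#' scale used for biological interpretation.
#'
#' @param fit output of [fit_probe_models()].
#' @param mod output of [ebayes_moderate()] for the same fit.
#' @param beta the [beta_matrix()] the M-values came from.
#' @param sheet a validated sample sheet identifying patients and controls.
#' @param p_adj_cut adjusted-p cutoff (default 0.01).
#' @param delta_cut absolute beta-difference cutoff (default 0.10).
#' @param keep_all if `TRUE`, return all probes with a `significant` column
#'   instead of only the retained ones.
#' @return data frame (the epi-signature) with one row per retained probe:
#'   `probe_id`, `delta_beta`, `coef_m`, `s_g`, `df_g`, `t_mod`, `p`,
#'   `p_adj`, `direction` (`hypo`/`hyper`), sorted by `p`.
#' @export
call_dmps <- function(fit, mod, beta, sheet, p_adj_cut = 0.01,
                      delta_cut = 0.10, keep_all = FALSE) {
  stopifnot(inherits(beta, "beta_matrix"))
  sheet <- validate_sample_sheet(sheet)
  ids <- colnames(beta$values)
  grp <- sheet$group[match(ids, sheet$sample_id)]
  pat <- ids[!is.na(grp) & grp == "patient"]
  ctl <- ids[!is.na(grp) & grp == "control"]
  if (!length(pat) || !length(ctl))
    .stopf("need both patient and control samples in the beta matrix")
  db <- rowMeans(beta$values[, pat, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta$values[, ctl, drop = FALSE], na.rm = TRUE)
  db <- db[fit$probe_ids]
  tab <- data.frame(
    probe_id = fit$probe_ids,
    delta_beta = unname(db),
    coef_m = unname(fit$coefficients),
    s_g = fit$sigma,
    df_g = fit$df_residual,
    t_mod = unname(mod$t_mod),
    p = unname(mod$p),
    p_adj = bh_adjust(mod$p),
    stringsAsFactors = FALSE)
  tab$direction <- ifelse(tab$delta_beta < 0, "hypo", "hyper")
  tab$significant <- tab$p_adj < p_adj_cut & abs(tab$delta_beta) > delta_cut
  tab <- tab[order(tab$p, tab$probe_id), , drop = FALSE]
  rownames(tab) <- NULL
  if (keep_all) return(tab)
  out <- tab[tab$significant, setdiff(names(tab), "significant"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-call moderated differential methylation analysis
#'
#' Convenience wrapper: transforms betas to M-values, builds the design
#' (patients vs controls, optional cell-fraction covariates), fits the
#' per-probe models, moderates, adjusts and applies the dual gate.
#'
#' @param beta a [beta_matrix()] (already QC-filtered).
#' @param sheet a validated sample sheet; only its patient/control samples
#'   present in `beta` are used.
#' @param fractions optional cell-fraction matrix.
#' @inheritParams call_dmps
#' @return list with `table` (the retained probes), `full` (all probes),
#'   `fit`, `moderation` and `design`.
#' @export
run_dmp <- function(beta, sheet, fractions = NULL, p_adj_cut = 0.01,
                    delta_cut = 0.10) {
  sheet <- validate_sample_sheet(sheet)
  ids <- colnames(beta$values)
  grp <- sheet$group[match(ids, sheet$sample_id)]
  use <- ids[!is.na(grp) & grp %in% c("patient", "control")]
  sub <- beta_matrix(beta$values[, use, drop = FALSE])
  design <- build_design_matrix(sheet, use, fractions)
  M <- beta_to_m(sub)
  fit <- fit_probe_models(M, design)
  mod <- ebayes_moderate(fit)
  list(table = call_dmps(fit, mod, sub, sheet, p_adj_cut, delta_cut),
       full = call_dmps(fit, mod, sub, sheet, p_adj_cut, delta_cut,
                        keep_all = TRUE),
       fit = fit, moderation = mod, design = design)
}

#' Cluster purity of a signature on patients and controls
#'
#' Hierarchically clusters samples (Euclidean distance on the signature-probe
#' betas, average linkage), cuts the tree into two clusters and reports the
#' best-matching agreement between cluster and patient/control label.
#' Carriers, if present, take part in the clustering and their cluster
#' assignments are attached as the `"carriers"` attribute, but they do not
#' enter the purity computation.
#'
#' @param beta a [beta_matrix()].
#' @param sheet a validated sample sheet.
#' @param probes signature probe ids (at least 2).
#' @return purity in `[0, 1]` (1 = complete separation), with attribute
#'   `carriers` giving the carriers' cluster memberships.
#' @export
signature_cluster_purity <- function(beta, sheet, probes) {
  stopifnot(inherits(beta, "beta_matrix"))
  sheet <- validate_sample_sheet(sheet)
  if (length(probes) < 2) .stopf("need at least 2 signature probes")
  miss <- setdiff(probes, rownames(beta$values))
  if (length(miss)) .stopf("signature probe(s) missing from beta matrix: %s",
                           paste(utils::head(miss, 3), collapse = ", "))
  ids <- colnames(beta$values)
  grp <- sheet$group[match(ids, sheet$sample_id)]
  use <- !is.na(grp) & grp %in% c("patient", "carrier", "control")
  if (sum(grp[use] == "patient") < 2 || sum(grp[use] == "control") < 2)
    .stopf("need at least 2 patients and 2 controls")
  X <- t(beta$values[probes, use, drop = FALSE])
  cl <- cutree(hclust(dist(X), method = "average"), k = 2)
  pc <- grp[use] %in% c("patient", "control")
  tab <- table(factor(cl[pc], levels = 1:2),
               factor(grp[use][pc], levels = c("patient", "control")))
  purity <- max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / sum(tab)
  attr(purity, "carriers") <- cl[grp[use] == "carrier"]
  purity
}
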