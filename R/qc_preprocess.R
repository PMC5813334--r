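# Probe/sample quality filters, the beta <-> M transform, and reference-based
# blood cell-composition estimation.

#' Filter probes by detection quality and blacklist flags
#'
#' Removes probes in a fixed order, each probe attributed to the first rule
#' that claims it: (1) detection p-value above `detection_threshold` in more
#' than `max_failure_fraction` of samples (only when a detection matrix is
#' present; the default 0 removes a probe failing in any sample), (2) chrX/Y
#' probes, (3) SNP-overlapping probes, (4) cross-reactive probes, (5) probes
#' with any missing beta. The operation is idempotent.
#'
#' @param beta a [beta_matrix()].
#' @param manifest a validated probe manifest covering every probe in `beta`.
#' @param detection_threshold detection p-value cutoff (default 0.01).
#' @param max_failure_fraction maximum tolerated fraction of samples failing
#'   detection before a probe is removed (default 0 = any sample).
#' @return list with `beta` (filtered) and `report`: per-rule removal counts
#'   and the removed probe ids.
#' @export
filter_probes <- function(beta, manifest, detection_threshold = 0.01,
                          max_failure_fraction = 0) {
  stopifnot(inherits(beta, "beta_matrix"))
  .assert_scalar_prob(max_failure_fraction, "max_failure_fraction")
  ids <- rownames(beta$values)
  rows <- match(ids, manifest$probe_id)
  if (anyNA(rows))
    .stopf("probe(s) in beta matrix absent from manifest: %s",
           paste(utils::head(ids[is.na(rows)], 3), collapse = ", "))
  man <- manifest[rows, , drop = FALSE]
  removed <- factor(rep(NA_character_, length(ids)),
                    levels = c("detection", "xy", "snp", "crossreactive", "missing"))
  if (!is.null(beta$detection_p)) {
    fail_frac <- rowMeans(beta$detection_p > detection_threshold)
    removed[fail_frac > max_failure_fraction] <- "detection"
  }
  removed[is.na(removed) & man$flag_xy] <- "xy"
  removed[is.na(removed) & man$flag_snp] <- "snp"
  removed[is.na(removed) & man$flag_crossreactive] <- "crossreactive"
  removed[is.na(removed) & rowSums(is.na(beta$values)) > 0] <- "missing"
  keep <- is.na(removed)
  counts <- table(removed)
  report <- list(
    probes_removed_by = stats::setNames(as.integer(counts), names(counts)),
    removed_ids = split(ids[!keep], removed[!keep]),
    probes_in = length(ids), probes_out = sum(keep))
  out <- beta_matrix(beta$values[keep, , drop = FALSE],
                     if (!is.null(beta$detection_p))
                       beta$detection_p[keep, , drop = FALSE])
  list(beta = out, report = report)
}

#' Predict sample sex from chrX methylation and flag discordance
#'
#' In females, X inactivation leaves one allele methylated and one not, so
#' chrX CpGs sit at intermediate beta values; in males they stay at the
#' bimodal extremes. A sample is predicted female when at least `female_frac`
#' of its chrX betas fall in `[mid_lo, mid_hi]`. Run this before chrX/Y probes
#' are filtered out. Discordant samples are flagged, not removed.
#'
#' @param beta a [beta_matrix()] still containing chrX probes.
#' @param manifest a validated probe manifest.
#' @param sheet a validated sample sheet with `labeled_sex`.
#' @param mid_lo,mid_hi the intermediate-methylation window (defaults
#'   0.25 / 0.75).
#' @param female_frac minimum fraction of chrX probes in the window to call
#'   a sample female (default 0.20).
#' @return data frame with per-sample `chrx_mid_fraction`, `predicted_sex`,
#'   `labeled_sex` and `flagged`.
#' @export
check_sample_sex <- function(beta, manifest, sheet,
                             mid_lo = 0.25, mid_hi = 0.75, female_frac = 0.20) {
  stopifnot(inherits(beta, "beta_matrix"))
  sheet <- validate_sample_sheet(sheet)
  xids <- manifest$probe_id[manifest$chrom == "chrX"]
  xids <- intersect(xids, rownames(beta$values))
  ids <- colnames(beta$values)
  lab <- sheet$labeled_sex[match(ids, sheet$sample_id)]
  if (length(xids) == 0) {
    warning("no chrX probes available; predicted sex set to unknown",
            call. = FALSE)
    return(data.frame(sample_id = ids, chrx_mid_fraction = NA_real_,
                      predicted_sex = "unknown", labeled_sex = lab,
                      flagged = FALSE, stringsAsFactors = FALSE))
  }
  xb <- beta$values[xids, , drop = FALSE]
  midfrac <- colMeans(xb >= mid_lo & xb <= mid_hi, na.rm = TRUE)
  pred <- ifelse(midfrac >= female_frac, "F", "M")
  data.frame(sample_id = ids, chrx_mid_fraction = unname(midfrac),
             predicted_sex = pred, labeled_sex = lab,
             flagged = !is.na(lab) & pred != lab, stringsAsFactors = FALSE)
}

#' Flag samples deviating from the genome-wide bimodal beta density
#'
#' Healthy array profiles are bimodal (most CpGs near 0 or 1). Per sample,
#' the share of betas falling in the mid range `(mid_lo, mid_hi)` is computed;
#' samples with a mid-fraction above `max_mid_fraction` are flagged as
#' deviating from bimodality.
#'
#' @param beta a [beta_matrix()] with at least 100 probes.
#' @param mid_lo,mid_hi the mid-methylation window (defaults 0.3 / 0.7).
#' @param max_mid_fraction flagging cutoff on the mid-fraction (default 0.35).
#' @return data frame with per-sample `mid_fraction` and `flagged`.
#' @export
check_density_bimodality <- function(beta, mid_lo = 0.3, mid_hi = 0.7,
                                     max_mid_fraction = 0.35) {
  stopifnot(inherits(beta, "beta_matrix"))
  if (nrow(beta$values) < 100)
    .stopf("bimodality check needs at least 100 probes (have %d)",
           nrow(beta$values))
  mid <- colMeans(beta$values > mid_lo & beta$values < mid_hi, na.rm = TRUE)
  data.frame(sample_id = colnames(beta$values), mid_fraction = unname(mid),
             flagged = unname(mid > max_mid_fraction), stringsAsFactors = FALSE)
}

#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))`, after clipping betas to `[eps, 1 - eps]` to
#' avoid infinities. The transform is strictly increasing, and
#' [m_to_beta()] inverts it exactly (to floating-point accuracy) inside the
#' clipped range.
#'
#' @param beta numeric vector/matrix of betas, or a [beta_matrix()].
#' @param eps clipping bound (default 1e-3).
#' @return M-values with the same shape (a plain matrix for a `beta_matrix`).
#' @export
beta_to_m <- function(beta, eps = 1e-3) {
  if (inherits(beta, "beta_matrix")) beta <- beta$values
  b <- .clip(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' M-value to beta transform (inverse of [beta_to_m()])
#' @param m numeric vector/matrix of M-values.
#' @return beta values with the same shape.
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Estimate blood cell-type fractions by constrained projection
#'
#' For each sample, solves the least-squares projection of its marker-probe
#' betas onto the reference profiles subject to non-negative fractions that
#' sum to one (Houseman-style constrained projection). The sum-to-one
#' constraint is imposed through a heavily weighted augmentation row in the
#' non-negative least-squares system, followed by exact renormalization.
#'
#' @param beta a [beta_matrix()] containing at least `K` of the reference
#'   marker probes.
#' @param reference a `cell_type_reference`.
#' @return samples x cell-types matrix of fractions (rows sum to 1).
#' @export
estimate_cell_fractions <- function(beta, reference) {
  stopifnot(inherits(beta, "beta_matrix"),
            inherits(reference, "cell_type_reference"))
  shared <- intersect(reference$probe_ids, rownames(beta$values))
  K <- length(reference$cell_types)
  if (length(shared) < K)
    .stopf("only %d marker probes shared with the reference; need at least %d",
           length(shared), K)
  shared <- sort(shared)    # invariant to input probe order
  A <- reference$profiles[shared, , drop = FALSE]
  w <- 1000
  Aaug <- rbind(A, w)
  Y <- beta$values[shared, , drop = FALSE]
  frac <- t(apply(Y, 2, function(y) {
    f <- pracma::lsqnonneg(Aaug, c(y, w))$x
    s <- sum(f)
    if (s <= 0) rep(1 / K, K) else f / s
  }))
  rownames(frac) <- colnames(beta$values)
  colnames(frac) <- reference$cell_types
  frac
}
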