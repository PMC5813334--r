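# Signature probe selection (AUC = 1 retention + correlation pruning) and a
# three-class RBF-SVM with per-class probability scores. The SVM fit itself
# is delegated to libsvm via e1071; fold construction, grid search, sigmoid
# calibration of the one-vs-one decision values, pairwise coupling into class
# probabilities and the RBF decision function used at predict time are
# implemented here so that training and scoring are fully deterministic
# under a fixed seed.

.CLASS_LEVELS <- c("patient", "carrier", "control")

#' Rank-based ROC AUC for one probe
#'
#' Mann-Whitney formulation:
#' `auc = (#{(i, j): case_i > control_j} + 0.5 #ties) / (n_case n_control)`.
#'
#' @param values per-sample measurements.
#' @param labels logical (or two-level) vector; `TRUE` marks the case class.
#' @return AUC in `[0, 1]`.
#' @export
probe_auc <- function(values, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    .stopf("AUC needs both classes non-empty (cases: %d, controls: %d)", n1, n0)
  r <- rank(values)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select a fully separating, non-redundant probe subset
#'
#' Two steps over the signature probes, using patients and controls only
#' (carriers enter the analysis only at SVM training): (1) retain probes
#' whose direction-folded AUC (`max(auc, 1 - auc)`) is at least
#' `1 - auc_tol`, i.e. probes that fully separate patients from controls;
#' (2) greedy redundancy pruning on the absolute Pearson correlation across
#' the retained probes: repeatedly locate the most-correlated remaining pair
#' with `|r| > sqrt(r2_cut)` and drop the member with the larger mean
#' absolute correlation to the other remaining probes, breaking ties by
#' probe id order.
#'
#' @param beta a [beta_matrix()].
#' @param sheet a validated sample sheet.
#' @param probes signature probe ids (from the differential methylation
#'   stage).
#' @param auc_tol tolerance on full separation (default 1e-9).
#' @param r2_cut squared-correlation cutoff (default 0.8, i.e.
#'   `|r| > 0.894`).
#' @return list with `auc` (folded AUC per input probe),
#'   `retained_after_auc`, `retained_after_pruning` and
#'   `pruning_threshold`.
#' @export
select_features <- function(beta, sheet, probes, auc_tol = 1e-9, r2_cut = 0.8) {
  stopifnot(inherits(beta, "beta_matrix"))
  sheet <- validate_sample_sheet(sheet)
  miss <- setdiff(probes, rownames(beta$values))
  if (length(miss)) .stopf("probe(s) missing from beta matrix: %s",
                           paste(utils::head(miss, 3), collapse = ", "))
  ids <- colnames(beta$values)
  grp <- sheet$group[match(ids, sheet$sample_id)]
  pc <- !is.na(grp) & grp %in% c("patient", "control")
  X <- beta$values[probes, pc, drop = FALSE]
  case <- grp[pc] == "patient"
  auc <- apply(X, 1, probe_auc, labels = case)
  folded <- pmax(auc, 1 - auc)
  kept <- probes[folded >= 1 - auc_tol]
  if (!length(kept))
    .stopf(paste0("no probe reaches AUC = 1 between patients and controls; ",
                  "review the signature or the auc_tol threshold"))
  thr <- sqrt(r2_cut)
  kept <- kept[order(kept)]
  C <- abs(cor(t(X[kept, , drop = FALSE])))
  diag(C) <- 0
  while (length(kept) > 1 && max(C) > thr) {
    mx <- max(C)
    hits <- which(C == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(rownames(C)[hits[, 1]], rownames(C)[hits[, 2]]), ,
                 drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    mean_i <- mean(C[i, -i])
    mean_j <- mean(C[j, -j])
    drop_idx <- if (mean_i > mean_j) i
      else if (mean_j > mean_i) j
      else max(i, j)                   # tie: drop the later probe id
    kept <- kept[-drop_idx]
    C <- C[-drop_idx, -drop_idx, drop = FALSE]
  }
  list(auc = stats::setNames(folded, probes),
       retained_after_auc = probes[folded >= 1 - auc_tol],
       retained_after_pruning = kept,
       pruning_threshold = thr)
}

# Stratified fold assignment: within each class, shuffled members are dealt
# round-robin over folds, so folds are balanced but small classes may be
# absent from some held-out folds (never from a training split).
.stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
  }
  fold
}

.scale_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

.scale_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

# Extract the fields needed to evaluate the one-vs-one RBF decision
# functions independently of the e1071 object.
.svm_core <- function(fit) {
  list(SV = unname(as.matrix(fit$SV)),
       coefs = unname(as.matrix(fit$coefs)),
       rho = as.numeric(fit$rho),
       nSV = as.integer(fit$nSV),
       class_order = as.character(fit$levels[fit$labels]),
       gamma = as.numeric(fit$gamma))
}

# One-vs-one decision values from the stored core, in libsvm pair order
# over core$class_order; columns named "A/B" (positive value favors A).
.decision_values <- function(core, X) {
  d2 <- outer(rowSums(X^2), rowSums(core$SV^2), "+") - 2 * X %*% t(core$SV)
  K <- exp(-core$gamma * pmax(d2, 0))
  k <- length(core$nSV)
  starts <- cumsum(c(0L, core$nSV))
  pairs <- combn(k, 2)
  dec <- matrix(0, nrow(X), ncol(pairs))
  nm <- character(ncol(pairs))
  for (pidx in seq_len(ncol(pairs))) {
    i <- pairs[1, pidx]; j <- pairs[2, pidx]
    si <- starts[i] + seq_len(core$nSV[i])
    sj <- starts[j] + seq_len(core$nSV[j])
    dec[, pidx] <- K[, si, drop = FALSE] %*% core$coefs[si, j - 1] +
      K[, sj, drop = FALSE] %*% core$coefs[sj, i] - core$rho[pidx]
    nm[pidx] <- paste(core$class_order[i], core$class_order[j], sep = "/")
  }
  colnames(dec) <- nm
  dec
}

# Platt scaling with regularized targets: fits p(y = first | f) =
# 1 / (1 + exp(a f + b)) by Newton iteration with backtracking.
.platt_fit <- function(f, y) {
  prior1 <- sum(y); prior0 <- sum(!y)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y, hi, lo)
  a <- 0
  b <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(a, b) {
    fab <- a * f + b
    sum(ifelse(fab >= 0, t * fab + log1p(exp(-fab)),
               (t - 1) * fab + log1p(exp(fab))))
  }
  fv <- fval(a, b)
  for (it in 1:100) {
    fab <- a * f + b
    p <- ifelse(fab >= 0, exp(-fab) / (1 + exp(-fab)), 1 / (1 + exp(fab)))
    q <- 1 - p
    d1 <- p * q
    g1 <- sum(f * (t - p))
    g2 <- sum(t - p)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(f * f * d1) + 1e-12
    h22 <- sum(d1) + 1e-12
    h21 <- sum(f * d1)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      na <- a + step * dA; nb <- b + step * dB
      nf <- fval(na, nb)
      if (nf < fv + 1e-4 * step * gd) {
        a <- na; b <- nb; fv <- nf
        break
      }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  list(a = a, b = b)
}

.platt_apply <- function(sig, f) {
  fab <- sig$a * f + sig$b
  ifelse(fab >= 0, exp(-fab) / (1 + exp(-fab)), 1 / (1 + exp(fab)))
}

# Pairwise coupling of one-vs-one probabilities into class probabilities
# (Wu, Lin & Weng second approach, as used by libsvm).
.couple_probabilities <- function(r) {
  k <- nrow(r)
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(r[-t, t]^2)
    for (j in seq_len(k)) if (j != t) Q[t, j] <- -r[j, t] * r[t, j]
  }
  p <- rep(1 / k, k)
  for (it in 1:100) {
    Qp <- as.numeric(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < 1e-10) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p / sum(p)
}

# Canonical pair list over the fixed class levels.
.canonical_pairs <- function(levels = .CLASS_LEVELS) {
  idx <- combn(length(levels), 2)
  lapply(seq_len(ncol(idx)), function(i)
    c(levels[idx[1, i]], levels[idx[2, i]]))
}

# Reorient a decision-value matrix (columns "A/B") to the canonical pair
# orientation; returns a matrix with one column per canonical pair.
.orient_decisions <- function(dec, levels = .CLASS_LEVELS) {
  pairs <- .canonical_pairs(levels)
  out <- matrix(NA_real_, nrow(dec), length(pairs))
  for (i in seq_along(pairs)) {
    fwd <- paste(pairs[[i]][1], pairs[[i]][2], sep = "/")
    rev <- paste(pairs[[i]][2], pairs[[i]][1], sep = "/")
    if (fwd %in% colnames(dec)) out[, i] <- dec[, fwd]
    else if (rev %in% colnames(dec)) out[, i] <- -dec[, rev]
  }
  colnames(out) <- vapply(pairs, paste, character(1), collapse = "/")
  out
}

#' Train the three-class RBF-SVM signature classifier
#'
#' Stratified `folds`-fold cross-validation over a `(cost, gamma)` grid
#' selects the hyperparameters with the best mean CV accuracy (ties broken
#' towards the smallest cost, then the smallest gamma). Features (beta
#' values of the selected probes) are standardized with training-fold
#' statistics inside CV and with full-training statistics in the final
#' refit. Out-of-fold one-vs-one decision values at the selected
#' hyperparameters calibrate one Platt sigmoid per class pair; at scoring
#' time the sigmoid pair probabilities are coupled into three class
#' probabilities that sum to one. When the largest class has fewer members
#' than `folds` the fold count is reduced with a warning; classes smaller
#' than `folds` (the carrier class here) simply leave some held-out folds
#' without members of that class.
#'
#' @param beta a [beta_matrix()] of the training cohort.
#' @param sheet a validated sample sheet; samples labeled patient, carrier
#'   or control and present in `beta` are used.
#' @param probes the selected feature probes (see [select_features()]).
#' @param folds number of CV folds (default 10).
#' @param cost_grid,gamma_grid hyperparameter grids; `gamma_grid` defaults
#'   to `c(1/p, 0.01, 0.001)` with `p` the number of features.
#' @param seed RNG seed for fold assignment.
#' @return a `signature_model`: probe list, scaling, SVM core (support
#'   vectors, dual coefficients, rho, gamma), per-pair sigmoids, class
#'   levels, `cv_accuracy` (fraction in `[0, 1]`), the CV grid results and
#'   training metadata.
#' @export
train_svm <- function(beta, sheet, probes, folds = 10,
                      cost_grid = c(0.1, 1, 10, 100), gamma_grid = NULL,
                      seed = 1) {
  stopifnot(inherits(beta, "beta_matrix"))
  sheet <- validate_sample_sheet(sheet)
  miss <- setdiff(probes, rownames(beta$values))
  if (length(miss)) .stopf("probe(s) missing from beta matrix: %s",
                           paste(utils::head(miss, 3), collapse = ", "))
  ids <- colnames(beta$values)
  grp <- sheet$group[match(ids, sheet$sample_id)]
  use <- !is.na(grp) & grp %in% .CLASS_LEVELS
  if (length(setdiff(.CLASS_LEVELS, unique(grp[use]))))
    .stopf("training needs all three classes; missing: %s",
           paste(setdiff(.CLASS_LEVELS, unique(grp[use])), collapse = ", "))
  X <- t(beta$values[probes, use, drop = FALSE])
  y <- factor(grp[use], levels = .CLASS_LEVELS)
  counts <- table(y)
  if (max(counts) < folds) {
    folds_new <- max(2L, as.integer(max(counts)))
    warning(sprintf("largest class has %d members; reducing folds from %d to %d",
                    max(counts), folds, folds_new), call. = FALSE)
    folds <- folds_new
  }
  if (any(counts < folds))
    warning(sprintf("class(es) smaller than the fold count (%s); some folds have no held-out member of them",
                    paste(names(counts)[counts < folds], collapse = ", ")),
            call. = FALSE)
  gamma_grid <- gamma_grid %||% c(1 / length(probes), 0.01, 0.001)
  fold_id <- .with_seed(seed, .stratified_folds(as.character(y), folds))
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cv_one <- function(cost, gamma, collect_dec = FALSE) {
    correct <- 0
    dec_all <- NULL; lab_all <- NULL
    for (fd in seq_len(folds)) {
      tr <- fold_id != fd
      sc <- .scale_fit(X[tr, , drop = FALSE])
      fit <- e1071::svm(.scale_apply(X[tr, , drop = FALSE], sc), y[tr],
                        type = "C-classification", kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      Xte <- .scale_apply(X[!tr, , drop = FALSE], sc)
      pred <- stats::predict(fit, Xte)
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
      if (collect_dec) {
        dec <- .orient_decisions(.decision_values(.svm_core(fit), Xte))
        dec_all <- rbind(dec_all, dec)
        lab_all <- c(lab_all, as.character(y[!tr]))
      }
    }
    list(accuracy = correct / nrow(X), dec = dec_all, labels = lab_all)
  }
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i)
    cv_one(grid$cost[i], grid$gamma[i])$accuracy, numeric(1))
  best <- grid[order(-grid$accuracy, grid$cost, grid$gamma), ][1, ]
  oof <- cv_one(best$cost, best$gamma, collect_dec = TRUE)
  sigmoids <- lapply(.canonical_pairs(), function(pr) {
    sel <- oof$labels %in% pr
    f <- oof$dec[sel, paste(pr, collapse = "/")]
    sig <- .platt_fit(f, oof$labels[sel] == pr[1])
    list(first = pr[1], second = pr[2], a = sig$a, b = sig$b)
  })
  sc <- .scale_fit(X)
  fit <- e1071::svm(.scale_apply(X, sc), y, type = "C-classification",
                    kernel = "radial", cost = best$cost, gamma = best$gamma,
                    scale = FALSE)
  structure(list(
    probes = probes,
    class_levels = .CLASS_LEVELS,
    scaling = sc,
    svm_core = .svm_core(fit),
    sigmoids = sigmoids,
    cost = best$cost,
    cv_accuracy = best$accuracy,
    cv_grid = grid,
    folds = folds,
    seed = seed,
    n_training = nrow(X)), class = "signature_model")
}

#' Score samples with a trained signature model
#'
#' Emits, per sample, three class-probability scores in `[0, 1]` summing to
#' one (patient / carrier / control), the argmax class, and an `ambiguous`
#' flag raised when the top score falls below the 0.5 reporting cutoff.
#'
#' @param model a `signature_model`.
#' @param beta a [beta_matrix()] containing all model probes.
#' @return data frame with `sample_id`, `score_patient`, `score_carrier`,
#'   `score_control`, `predicted_class`, `ambiguous`.
#' @export
predict_scores <- function(model, beta) {
  stopifnot(inherits(model, "signature_model"), inherits(beta, "beta_matrix"))
  miss <- setdiff(model$probes, rownames(beta$values))
  if (length(miss))
    .stopf("model probe(s) missing from beta matrix: %s",
           paste(utils::head(miss, 5), collapse = ", "))
  X <- t(beta$values[model$probes, , drop = FALSE])
  Xs <- .scale_apply(X, model$scaling)
  dec <- .orient_decisions(.decision_values(model$svm_core, Xs),
                           model$class_levels)
  k <- length(model$class_levels)
  scores <- matrix(NA_real_, nrow(Xs), k,
                   dimnames = list(rownames(Xs), model$class_levels))
  pairs <- .canonical_pairs(model$class_levels)
  for (s in seq_len(nrow(Xs))) {
    r <- matrix(0.5, k, k)
    for (i in seq_along(pairs)) {
      a <- match(pairs[[i]][1], model$class_levels)
      b <- match(pairs[[i]][2], model$class_levels)
      pr <- .platt_apply(model$sigmoids[[i]], dec[s, i])
      pr <- min(max(pr, 1e-7), 1 - 1e-7)
      r[a, b] <- pr
      r[b, a] <- 1 - pr
    }
    scores[s, ] <- .couple_probabilities(r)
  }
  top <- apply(scores, 1, which.max)
  data.frame(sample_id = rownames(Xs),
             score_patient = unname(scores[, "patient"]),
             score_carrier = unname(scores[, "carrier"]),
             score_control = unname(scores[, "control"]),
             predicted_class = model$class_levels[top],
             ambiguous = unname(scores[cbind(seq_len(nrow(scores)), top)] < 0.5),
             stringsAsFactors = FALSE)
}

#' Specificity of a signature model on an external cohort
#'
#' Scores an external cohort (unaffected controls and/or samples from other
#' disorders) and reports the fraction predicted as control, together with a
#' group-by-prediction confusion table and per-group mean scores.
#'
#' @param model a `signature_model`.
#' @param beta external [beta_matrix()].
#' @param sheet the matching sample sheet.
#' @return list with `specificity` (fraction predicted control), `n`,
#'   `confusion` and `scores` (the [predict_scores()] table with groups).
#' @export
evaluate_specificity <- function(model, beta, sheet) {
  stopifnot(inherits(beta, "beta_matrix"))
  sheet <- validate_sample_sheet(sheet)
  if (ncol(beta$values) == 0) .stopf("external cohort is empty")
  preds <- predict_scores(model, beta)
  preds$group <- sheet$group[match(preds$sample_id, sheet$sample_id)]
  list(specificity = mean(preds$predicted_class == "control"),
       n = nrow(preds),
       confusion = table(group = preds$group, predicted = preds$predicted_class),
       scores = preds)
}
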