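# Synthetic methylation-array cohorts with a planted epi-signature.
#
# The generator emulates the structure the downstream stages rely on: bimodal
# beta distributions, CpGs clustered into island-like groups with mixed
# inter-probe gaps, blood cell-type mixtures at dedicated marker probes,
# per-probe and regional planted effects expressed fully in patients and at a
# configurable fraction (default one half) in heterozygous carriers.

#' Default blood cell-type reference profiles (synthetic)
#'
#' Builds a synthetic reference of `K` blood cell types, each with
#' `markers_per_type` marker CpGs that are highly methylated in the owning
#' type and lowly methylated elsewhere. This object is a stand-in built for
#' testing; it is not derived from any measured leukocyte reference data.
#'
#' @param K number of cell types (default 6: granulocytes, CD4 T, CD8 T,
#'   B cells, NK, monocytes).
#' @param markers_per_type marker CpGs per cell type.
#' @param seed RNG seed for the small jitter on the reference betas.
#' @return a `cell_type_reference`.
#' @export
synthetic_cell_reference <- function(K = 6, markers_per_type = 10, seed = 7) {
  types <- c("Gran", "CD4T", "CD8T", "Bcell", "NK", "Mono", "Eos", "Baso")
  if (K < 2 || K > length(types)) .stopf("K must be between 2 and %d", length(types))
  types <- types[seq_len(K)]
  n <- K * markers_per_type
  .with_seed(seed, {
    prof <- matrix(runif(n * K, 0.05, 0.18), nrow = n)
    for (k in seq_len(K)) {
      rows <- (k - 1) * markers_per_type + seq_len(markers_per_type)
      prof[rows, k] <- runif(markers_per_type, 0.80, 0.95)
    }
    rownames(prof) <- sprintf("ct_marker_%03d", seq_len(n))
    colnames(prof) <- types
    cell_type_reference(prof)
  })
}

#' Published region geometry for the planted differentially methylated regions
#'
#' Nine regions mirroring the published Claes-Jensen DMR geometry: the printed
#' chromosome spans, signed regional mean differences (one hypermethylated
#' region on chr15, the rest hypomethylated), and probe counts in the printed
#' 3-8 range assigned by region width. The chr13 analogue sits on a CpG-island
#' shore with the nearest island probe 221 bp away.
#'
#' @return data frame with columns `chrom`, `start`, `end`, `n_probes`,
#'   `delta`, `island_relation`, `island_offset_bp`.
#' @export
claes_jensen_regions <- function() {
  data.frame(
    chrom   = c("chr15", "chr17", "chr6", "chr13", "chr2", "chr5", "chr2", "chr1", "chr16"),
    start   = c(89919993L, 7486551L, 164092410L, 113242878L, 25383404L,
                176559334L, 232348334L, 7887199L, 2801793L),
    end     = c(89921182L, 7486874L, 164093099L, 113243141L, 25384809L,
                176559563L, 232348794L, 7887560L, 2801952L),
    n_probes = c(8L, 3L, 4L, 3L, 6L, 3L, 3L, 3L, 3L),
    delta   = c(0.288, -0.297, -0.326, -0.333, -0.267, -0.333, -0.284, -0.245, -0.313),
    island_relation = c("island", "island", "island", "shore", "island",
                        "island", "island", "island", "island"),
    island_offset_bp = c(NA, NA, NA, 221L, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. Effects are planted
#' on the beta scale: the patient group mean at a planted probe is the control
#' mean shifted by `delta`, the carrier mean by `carrier_factor * delta`, both
#' clipped to `(0.001, 0.999)`. Per-sample betas are logit-normal around the
#' group mean with standard deviation `noise_sd` on the natural-logit scale.
#'
#' @param n_background_probes number of null background CpGs.
#' @param planted_probe_effects `NULL` or a data frame with columns `index`
#'   (position among eligible background probes, in manifest order; see
#'   [sample_probe_effects()]) and `delta` (signed beta difference).
#' @param planted_regions `NULL` or a data frame as [claes_jensen_regions()].
#' @param n_patients,n_carriers,n_controls group sizes
#'   (defaults 7 / 6 / 56, the published training cohort).
#' @param carrier_factor fraction of the patient effect expressed in carriers
#'   (lambda, default 0.5).
#' @param noise_sd per-sample noise s.d. on the natural-logit scale
#'   (default 0.35).
#' @param cell_reference a `cell_type_reference` for the blood mixture, or
#'   `NULL` to use [synthetic_cell_reference()].
#' @param concentration Dirichlet concentration for the cell fractions;
#'   larger means less between-sample variability.
#' @param confounded if `TRUE`, patient cell fractions are drawn with a
#'   granulocyte-shifted mean so that composition is correlated with case
#'   status (exercises the regression adjustment).
#' @param n_chrx_probes chrX probes used by the sex-concordance check.
#' @param detection_failure_rate per-entry probability of a failing
#'   detection p-value (default 1e-4, giving a realistic sub-percent
#'   probe-level removal under the any-sample rule).
#' @param seed integer seed governing all draws (stage sub-seeds are derived
#'   from it deterministically).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_background_probes = 20000,
                       planted_probe_effects = NULL,
                       planted_regions = NULL,
                       n_patients = 7, n_carriers = 6, n_controls = 56,
                       carrier_factor = 0.5,
                       noise_sd = 0.35,
                       cell_reference = NULL,
                       concentration = 80,
                       confounded = FALSE,
                       n_chrx_probes = 100,
                       detection_failure_rate = 1e-4,
                       seed = 1) {
  .assert_scalar_prob(carrier_factor, "carrier_factor")
  .assert_scalar_prob(detection_failure_rate, "detection_failure_rate")
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  if (n_background_probes < 1) .stopf("need at least one background probe")
  if (!is.null(planted_probe_effects)) {
    stopifnot(all(c("index", "delta") %in% names(planted_probe_effects)))
    if (any(abs(planted_probe_effects$delta) > 1))
      .stopf("planted probe |delta| must be <= 1")
  }
  if (!is.null(planted_regions)) {
    stopifnot(all(c("chrom", "start", "end", "n_probes", "delta") %in%
                    names(planted_regions)))
    if (any(planted_regions$n_probes < 1))
      .stopf("each planted region needs at least one probe")
    if (any(abs(planted_regions$delta) > 1))
      .stopf("planted region |delta| must be <= 1")
    if (is.null(planted_regions$island_relation))
      planted_regions$island_relation <- "island"
    if (is.null(planted_regions$island_offset_bp))
      planted_regions$island_offset_bp <- NA_integer_
  }
  cell_reference <- cell_reference %||% synthetic_cell_reference()
  stopifnot(inherits(cell_reference, "cell_type_reference"))
  structure(list(
    n_background_probes = as.integer(n_background_probes),
    planted_probe_effects = planted_probe_effects,
    planted_regions = planted_regions,
    n_patients = as.integer(n_patients),
    n_carriers = as.integer(n_carriers),
    n_controls = as.integer(n_controls),
    carrier_factor = carrier_factor,
    noise_sd = noise_sd,
    cell_reference = cell_reference,
    concentration = concentration,
    confounded = isTRUE(confounded),
    n_chrx_probes = as.integer(n_chrx_probes),
    detection_failure_rate = detection_failure_rate,
    seed = as.integer(seed)), class = "sim_config")
}

.AUTOSOMES <- paste0("chr", 1:22)

#' Generate a synthetic probe manifest
#'
#' Background probes are laid out left to right per autosome in island-like
#' clusters: most inter-probe gaps are below 500 bp, a fraction exceeds it so
#' that the 500-bp clustering rule is exercised in both directions. Planted
#' regions are realized as runs of `n_probes` evenly spaced probes spanning
#' exactly `[start, end]`, with consecutive gaps below 500 bp (an error is
#' raised if the requested probe count cannot achieve that). Region probes are
#' annotated as CpG island (or the configured relation, in which case a
#' nearby island probe can be planted at `island_offset_bp` past the region
#' end). Cell-type marker probes and flagged chrX probes are appended so the
#' QC stage has material to act on.
#'
#' @param config a [sim_config()].
#' @return a validated, coordinate-sorted probe manifest data frame.
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 11L, {
    n <- config$n_background_probes
    chrom_of <- sample(.AUTOSOMES, n, replace = TRUE)
    pieces <- list()
    for (ch in .AUTOSOMES) {
      k <- sum(chrom_of == ch)
      if (k == 0) next
      wide <- runif(k) < 0.25
      gaps <- ifelse(wide, sample(600:5000, k, replace = TRUE),
                     sample(30:480, k, replace = TRUE))
      pos <- 100000L + cumsum(gaps)
      cl <- cumsum(c(TRUE, gaps[-1] > 500))
      rel <- sample(.ISLAND_RELATIONS, max(cl), replace = TRUE,
                    prob = c(0.25, 0.2, 0.1, 0.45))[cl]
      pieces[[ch]] <- data.frame(chrom = ch, pos = as.integer(pos),
                                 island_relation = rel,
                                 stringsAsFactors = FALSE)
    }
    bg <- do.call(rbind, pieces)
    bg$probe_id <- sprintf("sim_cg%06d", seq_len(nrow(bg)))
    bg$flag_xy <- FALSE
    bg$flag_snp <- runif(nrow(bg)) < 0.01
    bg$flag_crossreactive <- runif(nrow(bg)) < 0.01

    extra <- list()
    regs <- config$planted_regions
    if (!is.null(regs)) {
      for (r in seq_len(nrow(regs))) {
        np <- regs$n_probes[r]
        pos <- if (np == 1) regs$start[r] else
          as.integer(round(seq(regs$start[r], regs$end[r], length.out = np)))
        if (np > 1 && max(diff(pos)) > 500)
          .stopf("region %s:%d-%d cannot hold %d probes with gaps < 500 bp",
                 regs$chrom[r], regs$start[r], regs$end[r], np)
        extra[[length(extra) + 1L]] <- data.frame(
          chrom = regs$chrom[r], pos = pos,
          island_relation = regs$island_relation[r],
          probe_id = sprintf("sim_dmr%02d_%02d", r, seq_len(np)),
          flag_xy = FALSE, flag_snp = FALSE, flag_crossreactive = FALSE,
          stringsAsFactors = FALSE)
        off <- regs$island_offset_bp[r]
        if (!is.na(off) && regs$island_relation[r] != "island") {
          extra[[length(extra) + 1L]] <- data.frame(
            chrom = regs$chrom[r], pos = as.integer(regs$end[r] + off),
            island_relation = "island",
            probe_id = sprintf("sim_dmr%02d_isl", r),
            flag_xy = FALSE, flag_snp = FALSE, flag_crossreactive = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
    ref <- config$cell_reference
    extra[[length(extra) + 1L]] <- data.frame(
      chrom = "chr22",
      pos = as.integer(5e6 + 2000L * seq_along(ref$probe_ids)),
      island_relation = "open_sea", probe_id = ref$probe_ids,
      flag_xy = FALSE, flag_snp = FALSE, flag_crossreactive = FALSE,
      stringsAsFactors = FALSE)
    if (config$n_chrx_probes > 0) {
      extra[[length(extra) + 1L]] <- data.frame(
        chrom = "chrX",
        pos = as.integer(100000L + cumsum(sample(100:2000, config$n_chrx_probes,
                                                 replace = TRUE))),
        island_relation = "open_sea",
        probe_id = sprintf("sim_x%04d", seq_len(config$n_chrx_probes)),
        flag_xy = TRUE, flag_snp = FALSE, flag_crossreactive = FALSE,
        stringsAsFactors = FALSE)
    }
    manifest <- rbind(bg, do.call(rbind, extra))
    validate_manifest(manifest)
  })
}

# Background probes eligible to carry a planted single-probe effect:
# autosomal, unflagged, not cell-type markers, not planted-region members.
.eligible_background <- function(config, manifest) {
  in_region <- rep(FALSE, nrow(manifest))
  regs <- config$planted_regions
  if (!is.null(regs)) {
    for (r in seq_len(nrow(regs)))
      in_region <- in_region | (manifest$chrom == regs$chrom[r] &
                                  manifest$pos >= regs$start[r] &
                                  manifest$pos <= regs$end[r])
  }
  which(!manifest$flag_xy & !manifest$flag_snp & !manifest$flag_crossreactive &
          manifest$chrom %in% .AUTOSOMES &
          !(manifest$probe_id %in% config$cell_reference$probe_ids) &
          !grepl("^sim_dmr", manifest$probe_id) & !in_region)
}

#' Draw planted single-probe effects for a configuration
#'
#' Chooses `n` eligible background probes (autosomal, unflagged, outside
#' planted regions and marker sets) and assigns signed beta differences with
#' magnitudes uniform on `[delta_min, delta_max]`; a fraction `prop_hyper`
#' is hypermethylated (positive delta), the rest hypomethylated.
#'
#' @param config a [sim_config()].
#' @param manifest the manifest from [generate_manifest()].
#' @param n number of probes to plant.
#' @param delta_min,delta_max magnitude range of the planted beta difference.
#' @param n_hyper number of hypermethylated probes (overrides `prop_hyper`).
#' @param prop_hyper fraction of positive effects (default 498/1769, the
#'   published direction split).
#' @param seed RNG seed.
#' @return data frame with `index` (into the eligible-probe enumeration),
#'   `probe_id` and `delta`; pass it as `planted_probe_effects`.
#' @export
sample_probe_effects <- function(config, manifest, n,
                                 delta_min = 0.12, delta_max = 0.35,
                                 n_hyper = NULL, prop_hyper = 498 / 1769,
                                 seed = config$seed + 23L) {
  elig <- .eligible_background(config, manifest)
  if (n > length(elig))
    .stopf("requested %d planted probes but only %d eligible background probes",
           n, length(elig))
  .with_seed(seed, {
    idx <- sort(sample(length(elig), n))
    mag <- runif(n, delta_min, delta_max)
    n_hyper <- n_hyper %||% round(prop_hyper * n)
    sgn <- rep(-1, n)
    sgn[sample(n, n_hyper)] <- 1
    data.frame(index = idx, probe_id = manifest$probe_id[elig[idx]],
               delta = sgn * mag, stringsAsFactors = FALSE)
  })
}

# Per-probe true control means and patient deltas, aligned to manifest rows.
.build_truth_means <- function(config, manifest) {
  p <- nrow(manifest)
  comp <- sample(c("low", "mid", "high"), p, replace = TRUE,
                 prob = c(0.46, 0.08, 0.46))
  cm <- numeric(p)
  cm[comp == "low"] <- rbeta(sum(comp == "low"), 6, 54)
  cm[comp == "mid"] <- rbeta(sum(comp == "mid"), 10, 10)
  cm[comp == "high"] <- rbeta(sum(comp == "high"), 54, 6)
  cm <- .clip(cm, 0.001, 0.999)
  # chrX baselines strictly bimodal so the male sex call is unambiguous
  x <- manifest$chrom == "chrX"
  if (any(x)) {
    lowx <- runif(sum(x)) < 0.5
    cmx <- ifelse(lowx, rbeta(sum(x), 6, 54), rbeta(sum(x), 54, 6))
    cm[x] <- .clip(cmx, 0.001, 0.999)
  }
  delta <- numeric(p)
  pe <- config$planted_probe_effects
  if (!is.null(pe)) {
    elig <- .eligible_background(config, manifest)
    if (any(pe$index < 1 | pe$index > length(elig)))
      .stopf("planted probe index out of range (1..%d eligible probes)", length(elig))
    rows <- elig[pe$index]
    delta[rows] <- pe$delta
    # keep the shifted mean inside (0.02, 0.98): hypomethylated probes start
    # high, hypermethylated probes start low (island-like baselines)
    d <- pe$delta
    lo <- ifelse(d < 0, pmax(0.70, -d + 0.07), 0.05)
    hi <- ifelse(d < 0, 0.95, pmin(0.30, 0.93 - d))
    cm[rows] <- runif(length(rows), lo, hi)
  }
  regs <- config$planted_regions
  region_rows <- vector("list", if (is.null(regs)) 0 else nrow(regs))
  if (!is.null(regs)) {
    for (r in seq_len(nrow(regs))) {
      rows <- which(manifest$chrom == regs$chrom[r] &
                      manifest$pos >= regs$start[r] &
                      manifest$pos <= regs$end[r] & !manifest$flag_xy)
      d <- regs$delta[r]
      delta[rows] <- d
      lo <- if (d < 0) max(0.70, -d + 0.07) else 0.05
      hi <- if (d < 0) 0.95 else min(0.30, 0.93 - d)
      cm[rows] <- runif(length(rows), lo, hi)
      region_rows[[r]] <- rows
    }
  }
  list(control_mean = cm, patient_delta = delta, region_rows = region_rows)
}

# Draw per-sample betas for arbitrary group labels given truth means.
.draw_betas <- function(config, manifest, truth, groups, sexes, sample_ids,
                        extra_delta = NULL) {
  p <- nrow(manifest); n <- length(groups)
  lambda <- config$carrier_factor
  eff <- outer(truth$patient_delta,
               c(patient = 1, carrier = lambda, control = 0, unknown = 0)[groups])
  if (!is.null(extra_delta)) eff <- eff + extra_delta
  mu <- .clip(truth$control_mean + eff, 0.001, 0.999)
  if (config$noise_sd == 0) {
    vals <- mu
  } else {
    vals <- plogis(qlogis(mu) + matrix(rnorm(p * n, 0, config$noise_sd), p, n))
  }
  # female chrX: X-inactivation mosaic, intermediate methylation near 0.5
  x <- manifest$chrom == "chrX"
  if (any(x) && any(sexes == "F")) {
    fcols <- which(sexes == "F")
    mid <- matrix(qlogis(runif(sum(x) * length(fcols), 0.40, 0.60)),
                  sum(x), length(fcols))
    noise <- if (config$noise_sd == 0) 0 else
      matrix(rnorm(sum(x) * length(fcols), 0, config$noise_sd),
             sum(x), length(fcols))
    vals[x, fcols] <- plogis(mid + noise)
  }
  # cell-type marker probes: mixture of reference profiles
  ref <- config$cell_reference
  mrows <- match(ref$probe_ids, manifest$probe_id)
  K <- length(ref$cell_types)
  base_props <- c(0.50, 0.15, 0.09, 0.08, 0.06, 0.12, 0.05, 0.02)[seq_len(K)]
  base_props <- base_props / sum(base_props)
  alpha <- config$concentration * base_props
  frac <- .rdirichlet(n, alpha)
  if (config$confounded) {
    shift <- base_props * c(1.6, rep(0.6, K - 1))
    shift <- shift / sum(shift)
    pat <- which(groups == "patient")
    if (length(pat))
      frac[pat, ] <- .rdirichlet(length(pat), config$concentration * shift)
  }
  mix <- ref$profiles %*% t(frac)
  vals[mrows, ] <- .clip(mix + matrix(rnorm(length(mix), 0, 0.01),
                                      nrow(mix), ncol(mix)), 0.001, 0.999)
  dimnames(vals) <- list(manifest$probe_id, sample_ids)
  det <- matrix(rbeta(p * n, 1, 2000), p, n, dimnames = dimnames(vals))
  if (config$detection_failure_rate > 0) {
    fail <- runif(p * n) < config$detection_failure_rate
    det[fail] <- runif(sum(fail), 0.02, 0.5)
  }
  rownames(frac) <- sample_ids
  colnames(frac) <- ref$cell_types
  list(values = vals, detection_p = det, fractions = frac)
}

#' Simulate a study cohort with a planted epi-signature
#'
#' Draws control probe means from a bimodal mixture, applies the planted
#' per-probe and regional effects (full in patients, `carrier_factor` of it in
#' carriers), adds logit-normal per-sample noise, overlays blood cell-type
#' mixtures at the marker probes and X-inactivation-style intermediate
#' methylation on chrX in females, and attaches a detection p-value matrix.
#' Deterministic under a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param manifest the manifest from [generate_manifest()] for this config.
#' @return list with `beta` (a [beta_matrix()]), `sheet` (sample sheet) and
#'   `truth` (control means, patient deltas, region membership, true cell
#'   fractions).
#' @export
simulate_cohort <- function(config, manifest) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 13L, {
    truth <- .build_truth_means(config, manifest)
    groups <- rep(c("patient", "carrier", "control"),
                  c(config$n_patients, config$n_carriers, config$n_controls))
    sexes <- ifelse(groups == "carrier", "F", "M")
    ids <- c(sprintf("pat%02d", seq_len(config$n_patients)),
             sprintf("car%02d", seq_len(config$n_carriers)),
             sprintf("ctl%02d", seq_len(config$n_controls)))
    ages <- round(runif(length(ids), 5, 60))
    drawn <- .draw_betas(config, manifest, truth, groups, sexes, ids)
    sheet <- validate_sample_sheet(data.frame(
      sample_id = ids, labeled_sex = sexes, group = groups,
      age = ages, role = "discovery", stringsAsFactors = FALSE))
    regions <- config$planted_regions
    if (!is.null(regions))
      regions$probe_ids <- vapply(truth$region_rows, function(r)
        paste(manifest$probe_id[r], collapse = ","), character(1))
    list(beta = beta_matrix(drawn$values, drawn$detection_p),
         sheet = sheet,
         truth = list(control_mean = stats::setNames(truth$control_mean,
                                                     manifest$probe_id),
                      patient_delta = stats::setNames(truth$patient_delta,
                                                      manifest$probe_id),
                      regions = regions,
                      cell_fractions = drawn$fractions,
                      carrier_factor = config$carrier_factor))
  })
}

#' Simulate external validation cohorts (specificity analogue)
#'
#' Generates unaffected controls plus "other-disorder" samples carrying a
#' planted signature on probes disjoint from the trained signature, emulating
#' a specificity cohort of unrelated intellectual-disability conditions. The
#' other-disorder effect magnitudes are comparable to the patient signature
#' but placed on different probes; requesting an overlap is an error.
#'
#' @param config the [sim_config()] the training cohort was generated from.
#' @param manifest the matching manifest.
#' @param avoid_probes character vector of probe ids the other-disorder
#'   signature must not touch (typically the trained signature probes).
#' @param n_controls,n_other cohort sizes (defaults 500 / 587).
#' @param n_other_probes size of the other-disorder signature.
#' @param delta_min,delta_max magnitude range of its effects.
#' @param other_probes optional explicit probe ids for the other-disorder
#'   signature; must be disjoint from `avoid_probes`.
#' @param seed RNG seed.
#' @return list with `beta`, `sheet` (role `external`; other-disorder samples
#'   have group `unknown`) and `truth` (other-disorder probe ids and deltas).
#' @export
simulate_external_cohorts <- function(config, manifest, avoid_probes,
                                      n_controls = 500, n_other = 587,
                                      n_other_probes = 200,
                                      delta_min = 0.15, delta_max = 0.35,
                                      other_probes = NULL,
                                      seed = config$seed + 31L) {
  stopifnot(inherits(config, "sim_config"))
  planted_ids <- character(0)
  if (!is.null(config$planted_probe_effects)) {
    elig <- .eligible_background(config, manifest)
    planted_ids <- manifest$probe_id[elig[config$planted_probe_effects$index]]
  }
  if (!is.null(other_probes) && length(intersect(other_probes, avoid_probes)))
    .stopf("other-disorder probes overlap the signature probes: %s",
           paste(utils::head(intersect(other_probes, avoid_probes), 3), collapse = ", "))
  # rebuild the same per-probe truth the training cohort was drawn from, so
  # external controls share its baselines at every signature probe
  truth <- .with_seed(config$seed + 13L, .build_truth_means(config, manifest))
  .with_seed(seed, {
    if (is.null(other_probes)) {
      elig <- .eligible_background(config, manifest)
      pool <- setdiff(manifest$probe_id[elig], c(avoid_probes, planted_ids))
      if (n_other_probes > length(pool))
        .stopf("not enough eligible probes for a disjoint other-disorder signature")
      other_probes <- sort(sample(pool, n_other_probes))
    }
    rows <- match(other_probes, manifest$probe_id)
    if (anyNA(rows)) .stopf("other-disorder probes missing from manifest")
    mag <- runif(length(rows), delta_min, delta_max)
    sgn <- ifelse(runif(length(rows)) < 0.72, -1, 1)
    odelta <- sgn * mag
    # other-disorder baselines adjusted the same way as planted probes
    lo <- ifelse(odelta < 0, pmax(0.70, -odelta + 0.07), 0.05)
    hi <- ifelse(odelta < 0, 0.95, pmin(0.30, 0.93 - odelta))
    truth$control_mean[rows] <- runif(length(rows), lo, hi)
    groups <- rep(c("control", "unknown"), c(n_controls, n_other))
    ids <- c(sprintf("extctl%04d", seq_len(n_controls)),
             sprintf("extoth%04d", seq_len(n_other)))
    sexes <- rep("M", length(ids))
    extra <- matrix(0, nrow(manifest), length(ids))
    extra[rows, groups == "unknown"] <- odelta
    drawn <- .draw_betas(config, manifest, truth, groups, sexes, ids,
                         extra_delta = extra)
    sheet <- validate_sample_sheet(data.frame(
      sample_id = ids, labeled_sex = sexes, group = groups,
      age = round(runif(length(ids), 5, 60)), role = "external",
      stringsAsFactors = FALSE))
    list(beta = beta_matrix(drawn$values, drawn$detection_p), sheet = sheet,
         truth = list(other_probes = other_probes,
                      other_delta = stats::setNames(odelta, other_probes)))
  })
}
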