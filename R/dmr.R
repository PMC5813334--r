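# Bump-hunting detection of differentially methylated regions with bootstrap
# family-wise error rates: cluster CpGs by genomic gaps, threshold the
# per-probe beta-scale effect within clusters, and assess region areas
# against a residual-bootstrap null distribution of the genome-wide maximum.

#' Cluster probes by inter-probe genomic gaps
#'
#' Greedy left-to-right clustering per chromosome: a new cluster starts
#' whenever the gap to the previous probe exceeds `max_gap`. A gap of exactly
#' `max_gap` stays inside the cluster ("gaps no more than 500 bp").
#'
#' @param manifest a validated (coordinate-sorted) probe manifest.
#' @param max_gap maximum intra-cluster gap in bp (default 500).
#' @return integer vector of cluster ids aligned to the manifest rows, named
#'   by probe id.
#' @export
cluster_probes <- function(manifest, max_gap = 500) {
  n <- nrow(manifest)
  if (n == 0) return(integer(0))
  new_cl <- c(TRUE, manifest$chrom[-1] != manifest$chrom[-n] |
                diff(manifest$pos) > max_gap)
  stats::setNames(cumsum(new_cl), manifest$probe_id)
}

# Fast scan shared by the candidate finder and the bootstrap: runs of
# consecutive probes within a cluster, same effect sign, |delta| above cut.
.region_runs <- function(delta, clusters, effect_cut, min_probes) {
  n <- length(delta)
  pass <- !is.na(delta) & abs(delta) > effect_cut
  sgn <- sign(delta)
  sgn[!pass] <- 0
  brk <- c(TRUE, clusters[-1] != clusters[-n] | sgn[-1] != sgn[-n])
  rid <- cumsum(brk)
  first <- which(brk)
  len <- diff(c(first, n + 1L))
  ok <- sgn[first] != 0 & len >= min_probes
  list(from = first[ok], len = len[ok], rid = rid, ok_rid = which(ok))
}

#' Find candidate differentially methylated regions
#'
#' Within each probe cluster, maximal runs of consecutive probes whose
#' beta-scale differences share a sign and exceed `effect_cut` in magnitude;
#' runs with at least `min_probes` probes become candidate regions. Region
#' coordinates are the min/max member positions (1-based inclusive);
#' `mean_diff` is the mean signed difference over member probes and `area`
#' the sum of their absolute differences.
#'
#' @param delta_beta per-probe beta differences (patients minus controls)
#'   aligned to the manifest rows.
#' @param manifest a validated probe manifest.
#' @param clusters optional precomputed [cluster_probes()] output.
#' @param effect_cut per-probe absolute difference cutoff (default 0.10).
#' @param min_probes minimum run length (default 3).
#' @return data frame with `chrom`, `start`, `end`, `width`, `probe_count`,
#'   `mean_diff`, `area`, `row_from`, `row_to` (manifest row span).
#' @export
find_candidate_regions <- function(delta_beta, manifest, clusters = NULL,
                                   effect_cut = 0.10, min_probes = 3) {
  if (length(delta_beta) != nrow(manifest))
    .stopf("delta_beta length (%d) does not match manifest rows (%d)",
           length(delta_beta), nrow(manifest))
  clusters <- clusters %||% cluster_probes(manifest)
  runs <- .region_runs(delta_beta, clusters, effect_cut, min_probes)
  if (!length(runs$from)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), width = integer(0),
                      probe_count = integer(0), mean_diff = numeric(0),
                      area = numeric(0), row_from = integer(0),
                      row_to = integer(0), stringsAsFactors = FALSE))
  }
  from <- runs$from
  to <- from + runs$len - 1L
  mean_diff <- mapply(function(a, b) mean(delta_beta[a:b]), from, to)
  area <- mapply(function(a, b) sum(abs(delta_beta[a:b])), from, to)
  data.frame(chrom = manifest$chrom[from],
             start = manifest$pos[from],
             end = manifest$pos[to],
             width = manifest$pos[to] - manifest$pos[from] + 1L,
             probe_count = runs$len,
             mean_diff = unname(mean_diff),
             area = unname(area),
             row_from = from, row_to = to,
             stringsAsFactors = FALSE)
}

# Maximum qualifying region area for one (bootstrap) delta vector; 0 if none.
.max_region_area <- function(delta, clusters, effect_cut, min_probes) {
  runs <- .region_runs(delta, clusters, effect_cut, min_probes)
  if (!length(runs$from)) return(0)
  max(vapply(seq_along(runs$from), function(i) {
    a <- runs$from[i]
    sum(abs(delta[a:(a + runs$len[i] - 1L)]))
  }, numeric(1)))
}

#' Bootstrap family-wise error rates for candidate regions
#'
#' Residual bootstrap under the null of no group effect: per probe, null
#' fitted values come from the design without the group column while the
#' resampled residuals come from the full design (so they carry no group
#' signal); each bootstrap iteration adds a common resampling (with
#' replacement, over samples) of the residual columns to the null fitted
#' values, back-transforms to betas, recomputes per-probe group differences
#' and records the maximum qualifying region area in the genome. The FWER of an observed region is
#' `(#iterations with max null area >= observed area + 1) / (B + 1)`, so the
#' smallest attainable value at `B = 1000` is 1/1001 (about 0.001). Retained
#' regions satisfy `fwer < fwer_cut`, `|mean_diff| > effect_cut` and
#' `probe_count >= min_probes`.
#'
#' @param beta a QC-filtered [beta_matrix()].
#' @param manifest a validated probe manifest covering the beta probes,
#'   restricted and aligned internally.
#' @param sheet a validated sample sheet (patients and controls are used).
#' @param fractions optional cell-fraction matrix entering the null design.
#' @param B number of bootstrap iterations (default 1000; below 100 a warning
#'   about FWER resolution is emitted).
#' @param effect_cut per-probe absolute difference cutoff (default 0.10).
#' @param min_probes minimum probes per region (default 3).
#' @param fwer_cut FWER cutoff for retention (default 0.01).
#' @param max_gap clustering gap in bp (default 500).
#' @param seed RNG seed for the bootstrap resampling.
#' @param keep_candidates if `TRUE`, return all candidates with their FWERs
#'   instead of only the retained regions.
#' @return DMR table: `chrom`, `start`, `end` (1-based inclusive), `width`,
#'   `probe_count`, `mean_diff`, `area`, `fwer`, ordered by decreasing area.
#' @export
bootstrap_fwer <- function(beta, manifest, sheet, fractions = NULL, B = 1000,
                           effect_cut = 0.10, min_probes = 3, fwer_cut = 0.01,
                           max_gap = 500, seed = 1, keep_candidates = FALSE) {
  stopifnot(inherits(beta, "beta_matrix"))
  sheet <- validate_sample_sheet(sheet)
  if (B < 100) warning("B < 100 gives coarse FWER resolution (minimum 1/(B+1))",
                       call. = FALSE)
  rows <- match(rownames(beta$values), manifest$probe_id)
  if (anyNA(rows)) .stopf("probe(s) in beta matrix absent from manifest")
  man <- manifest[rows, , drop = FALSE]
  ord <- .order_by_position(man$chrom, man$pos)
  man <- man[ord, , drop = FALSE]
  vals <- beta$values[ord, , drop = FALSE]
  ids <- colnames(vals)
  grp <- sheet$group[match(ids, sheet$sample_id)]
  use <- !is.na(grp) & grp %in% c("patient", "control")
  vals <- vals[, use, drop = FALSE]
  grp <- grp[use]
  is_pat <- grp == "patient"
  if (!any(is_pat) || all(is_pat))
    .stopf("need both patient and control samples")
  clusters <- cluster_probes(man, max_gap = max_gap)
  obs_delta <- rowMeans(vals[, is_pat, drop = FALSE]) -
    rowMeans(vals[, !is_pat, drop = FALSE])
  cand <- find_candidate_regions(obs_delta, man, clusters,
                                 effect_cut = effect_cut,
                                 min_probes = min_probes)
  if (nrow(cand) == 0) {
    cand$fwer <- numeric(0)
    return(cand[, c("chrom", "start", "end", "width", "probe_count",
                    "mean_diff", "area", "fwer")])
  }
  # fitted values from the null design (no group column); residuals from the
  # full design (with it), so the resampled noise is free of the group signal
  X0 <- cbind(intercept = rep(1, ncol(vals)))
  if (!is.null(fractions)) {
    fr <- fractions[match(colnames(vals), rownames(fractions)), , drop = FALSE]
    if (anyNA(fr)) .stopf("cell fractions missing for some samples")
    X0 <- cbind(X0, fr[, -ncol(fr), drop = FALSE])
  }
  X1 <- cbind(X0, group = as.numeric(is_pat))
  M <- beta_to_m(vals)
  H0 <- X0 %*% solve(crossprod(X0), t(X0))      # hat matrices, n x n
  H1 <- X1 %*% solve(crossprod(X1), t(X1))
  fitted0 <- M %*% H0
  R <- M - M %*% H1
  n <- ncol(M)
  max_null <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      bb <- m_to_beta(fitted0 + R[, idx])
      d <- rowMeans(bb[, is_pat, drop = FALSE]) -
        rowMeans(bb[, !is_pat, drop = FALSE])
      .max_region_area(d, clusters, effect_cut, min_probes)
    }, numeric(1))
  })
  cand$fwer <- vapply(cand$area, function(a) (sum(max_null >= a) + 1) / (B + 1),
                      numeric(1))
  keep <- if (keep_candidates) rep(TRUE, nrow(cand)) else
    cand$fwer < fwer_cut & abs(cand$mean_diff) > effect_cut &
    cand$probe_count >= min_probes
  out <- cand[keep, c("chrom", "start", "end", "width", "probe_count",
                      "mean_diff", "area", "fwer"), drop = FALSE]
  out <- out[order(-out$area), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate regions with overlapping genes and CpG-island distance
#'
#' `overlapping_gene` is the name of any supplied gene interval intersecting
#' the region; when none overlaps but a gene start (TSS) lies within 2 kb of
#' the region, the gene is reported as `"name (d)"` with `d` the distance in
#' bp from the TSS. `dist_to_island` is 0 when any member probe is annotated
#' as CpG island, otherwise the minimum distance in bp from the region to an
#' island probe on the same chromosome (`NA` if there is none).
#'
#' @param dmrs a DMR table from [bootstrap_fwer()].
#' @param manifest a validated probe manifest.
#' @param gene_bed optional gene intervals: a path to a BED file or a data
#'   frame from [read_gene_bed()].
#' @param tss_window distance window for near-TSS annotation (default 2000).
#' @return the DMR table with `overlapping_gene` and `dist_to_island` added.
#' @export
annotate_dmrs <- function(dmrs, manifest, gene_bed = NULL, tss_window = 2000) {
  genes <- NULL
  if (!is.null(gene_bed))
    genes <- if (is.character(gene_bed)) read_gene_bed(gene_bed) else gene_bed
  ov <- character(nrow(dmrs))
  isl <- rep(NA_real_, nrow(dmrs))
  island_pos <- split(manifest$pos[manifest$island_relation == "island"],
                      manifest$chrom[manifest$island_relation == "island"])
  for (i in seq_len(nrow(dmrs))) {
    s <- dmrs$start[i]; e <- dmrs$end[i]; ch <- dmrs$chrom[i]
    members <- manifest$chrom == ch & manifest$pos >= s & manifest$pos <= e
    if (any(members & manifest$island_relation == "island")) {
      isl[i] <- 0
    } else {
      ip <- island_pos[[ch]]
      if (length(ip)) isl[i] <- min(pmax(0, pmax(s - ip, ip - e)))
    }
    ov[i] <- ""
    if (!is.null(genes)) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      hit <- which(g$start <= e & g$end >= s)
      if (length(hit)) {
        ov[i] <- g$name[hit[1]]
      } else if (nrow(g)) {
        dtss <- pmax(g$start - e, s - g$start, 0)
        j <- which.min(dtss)
        if (dtss[j] > 0 && dtss[j] <= tss_window)
          ov[i] <- sprintf("%s (%d)", g$name[j], as.integer(dtss[j]))
      }
    }
  }
  dmrs$overlapping_gene <- ov
  dmrs$dist_to_island <- isl
  dmrs
}
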