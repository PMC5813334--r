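#' @importFrom stats cor cutree dist hclust pt qlogis plogis rnorm runif rbeta sd var
#' @importFrom utils read.delim read.csv write.table combn packageVersion
NULL

.ISLAND_RELATIONS <- c("island", "shore", "shelf", "open_sea")
.GROUPS <- c("patient", "carrier", "control", "unknown")
.SEXES <- c("M", "F")
.ROLES <- c("discovery", "training", "testing", "external")
.MODEL_FORMAT <- "episig_model_1"

#' Construct a beta-value matrix container
#'
#' A `beta_matrix` bundles a probes-by-samples matrix of methylation fractions
#' (beta values in `[0, 1]`) with an optional detection p-value matrix of the
#' same shape. Probe and sample identifiers are carried as dimnames and must
#' be unique.
#'
#' @param values numeric matrix, probes in rows, samples in columns, entries
#'   in `[0, 1]` or `NA`.
#' @param detection_p optional numeric matrix of detection p-values with the
#'   same dimensions and dimnames as `values`.
#' @return an object of class `beta_matrix`: a list with elements `values`
#'   and `detection_p`.
#' @export
beta_matrix <- function(values, detection_p = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("beta values must be a numeric matrix")
  if (is.null(rownames(values)) || (ncol(values) > 0 && is.null(colnames(values))))
    .stopf("beta matrix needs probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    .stopf("duplicated probe ids in beta matrix")
  if (anyDuplicated(colnames(values)))
    .stopf("duplicated sample ids in beta matrix")
  if (length(values) && !all(is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      .stopf("beta values must lie in [0, 1]; found range [%g, %g]", rng[1], rng[2])
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(values)))
      .stopf("detection p-value matrix does not match beta matrix shape (%d x %d vs %d x %d)",
             NROW(detection_p), NCOL(detection_p), nrow(values), ncol(values))
    if (!identical(rownames(detection_p), rownames(values)) ||
        !identical(colnames(detection_p), colnames(values)))
      .stopf("detection p-value matrix ids do not match beta matrix ids")
    if (min(detection_p, na.rm = TRUE) < 0 || max(detection_p, na.rm = TRUE) > 1)
      .stopf("detection p-values must lie in [0, 1]")
  }
  structure(list(values = values, detection_p = detection_p),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detection_p)) "" else " (with detection p-values)"))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

.read_numeric_tsv <- function(path, what) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stopf("%s file '%s' has no sample columns", what, path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    .stopf("%s file '%s' has non-numeric values in column(s): %s",
           what, path, paste(names(df)[-1][bad], collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' Read a beta-value matrix from TSV
#'
#' The TSV must have a header row of sample ids and probe ids in the first
#' column. An optional detection p-value TSV of identical shape and ids can be
#' attached. Missing betas are encoded as `NA`.
#'
#' @param path path to the beta TSV.
#' @param detection_path optional path to a detection p-value TSV.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path, detection_path = NULL) {
  values <- .read_numeric_tsv(path, "beta")
  det <- if (!is.null(detection_path)) .read_numeric_tsv(detection_path, "detection p-value")
  beta_matrix(values, det)
}

#' Write a beta-value matrix to TSV
#'
#' @param beta a [beta_matrix()].
#' @param path output path for the beta TSV.
#' @param detection_path optional output path for the detection p-value TSV.
#' @return invisibly, `path`.
#' @export
write_beta_matrix <- function(beta, path, detection_path = NULL) {
  stopifnot(inherits(beta, "beta_matrix"))
  .write_id_matrix(beta$values, path)
  if (!is.null(detection_path)) {
    if (is.null(beta$detection_p))
      .stopf("no detection p-value matrix to write")
    .write_id_matrix(beta$detection_p, detection_path)
  }
  invisible(path)
}

.write_id_matrix <- function(m, path, id_col = "probe_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Validate a probe manifest
#'
#' Checks the column set, coordinate sanity, identifier uniqueness and the
#' island-relation vocabulary, and returns the manifest sorted by
#' `(chrom, pos)`.
#'
#' @param manifest data frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based), `island_relation`, `flag_xy`, `flag_snp`, `flag_crossreactive`.
#' @return the validated, coordinate-sorted manifest.
#' @export
validate_manifest <- function(manifest) {
  need <- c("probe_id", "chrom", "pos", "island_relation",
            "flag_xy", "flag_snp", "flag_crossreactive")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    .stopf("manifest is missing required column(s): %s", paste(miss, collapse = ", "))
  manifest$probe_id <- as.character(manifest$probe_id)
  manifest$chrom <- as.character(manifest$chrom)
  manifest$pos <- as.integer(manifest$pos)
  for (fl in c("flag_xy", "flag_snp", "flag_crossreactive"))
    manifest[[fl]] <- as.logical(manifest[[fl]])
  if (anyDuplicated(manifest$probe_id))
    .stopf("duplicated probe id(s) in manifest: %s",
           paste(unique(manifest$probe_id[duplicated(manifest$probe_id)])[1:3], collapse = ", "))
  if (any(is.na(manifest$pos)) || any(manifest$pos < 1))
    .stopf("manifest positions must be integers >= 1")
  bad <- setdiff(unique(manifest$island_relation), .ISLAND_RELATIONS)
  if (length(bad))
    .stopf("unknown island_relation value(s) %s; allowed: %s",
           paste(bad, collapse = ", "), paste(.ISLAND_RELATIONS, collapse = ", "))
  key <- paste(manifest$chrom, manifest$pos)
  if (anyDuplicated(key))
    .stopf("duplicated (chrom, pos) in manifest at %s",
           key[duplicated(key)][1])
  manifest <- manifest[.order_by_position(manifest$chrom, manifest$pos), , drop = FALSE]
  rownames(manifest) <- NULL
  manifest
}

#' Read a probe manifest from TSV
#'
#' @param path path to a manifest TSV (see [validate_manifest()] for columns).
#' @return the validated, coordinate-sorted manifest data frame.
#' @export
read_manifest <- function(path) {
  validate_manifest(read.delim(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

#' Write a probe manifest to TSV
#' @param manifest a validated manifest data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  write.table(validate_manifest(manifest), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#'
#' @param sheet data frame with columns `sample_id`, `labeled_sex` (`M`/`F`),
#'   `group` (`patient`/`carrier`/`control`/`unknown`), `role`
#'   (`discovery`/`training`/`testing`/`external`) and optionally `age`.
#' @return the validated sheet.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "labeled_sex", "group", "role")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    .stopf("sample sheet is missing required column(s): %s",
           paste(miss, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id))
    .stopf("duplicated sample id(s): %s",
           sheet$sample_id[duplicated(sheet$sample_id)][1])
  vocab <- list(labeled_sex = .SEXES, group = .GROUPS, role = .ROLES)
  for (col in names(vocab)) {
    bad <- setdiff(unique(as.character(sheet[[col]])), vocab[[col]])
    if (length(bad))
      .stopf("unknown %s value(s) %s; allowed: %s", col,
             paste(bad, collapse = ", "), paste(vocab[[col]], collapse = ", "))
    sheet[[col]] <- as.character(sheet[[col]])
  }
  if (!"age" %in% names(sheet)) sheet$age <- NA_real_
  sheet
}

#' Read a sample sheet from CSV
#' @param path path to the CSV.
#' @return the validated sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a sample sheet to CSV
#' @param sheet a validated sample sheet.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(validate_sample_sheet(sheet), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a blood cell-type reference profile from TSV
#'
#' The TSV has marker probe ids in the first column and one column of
#' reference beta values per cell type.
#'
#' @param path path to the reference TSV.
#' @return a `cell_type_reference`: list with `probe_ids`, `profiles`
#'   (markers x cell types matrix) and `cell_types`.
#' @export
read_cell_reference <- function(path) {
  m <- .read_numeric_tsv(path, "cell-type reference")
  cell_type_reference(m)
}

#' Construct a cell-type reference object
#' @param profiles markers x cell-types matrix of reference betas in `[0, 1]`,
#'   with marker probe ids as row names and cell-type names as column names.
#' @return a `cell_type_reference` object.
#' @export
cell_type_reference <- function(profiles) {
  if (!is.matrix(profiles) || ncol(profiles) < 2)
    .stopf("cell-type reference needs at least 2 cell types")
  if (anyDuplicated(rownames(profiles)))
    .stopf("duplicated marker probe ids in cell-type reference")
  if (min(profiles) < 0 || max(profiles) > 1)
    .stopf("reference betas must lie in [0, 1]")
  structure(list(probe_ids = rownames(profiles), profiles = profiles,
                 cell_types = colnames(profiles)),
            class = "cell_type_reference")
}

#' Write a cell-type reference to TSV
#' @param reference a `cell_type_reference`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cell_reference <- function(reference, path) {
  stopifnot(inherits(reference, "cell_type_reference"))
  .write_id_matrix(reference$profiles, path)
  invisible(path)
}

#' Write differentially methylated regions as BED
#'
#' Regions are stored internally with 1-based inclusive coordinates (so that
#' `width = end - start + 1`); on output they are converted to the BED
#' convention of 0-based half-open intervals. The BED name field carries the
#' overlapping gene (or `"."`), the score field is `round(1000 * |mean_diff|)`,
#' and four extra columns carry `probe_count`, `mean_diff`, `area` and `fwer`.
#'
#' @param dmrs a DMR table (see [bootstrap_fwer()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gene <- if ("overlapping_gene" %in% names(dmrs)) dmrs$overlapping_gene else NA
  gene <- ifelse(is.na(gene) | gene == "", ".", gene)
  bed <- data.frame(
    chrom = dmrs$chrom,
    start = dmrs$start - 1L,          # 1-based inclusive -> 0-based half-open
    end = dmrs$end,
    name = gene,
    score = round(1000 * abs(dmrs$mean_diff)),
    strand = ".",
    probe_count = dmrs$probe_count,
    mean_diff = dmrs$mean_diff,
    area = dmrs$area,
    fwer = dmrs$fwer,
    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene interval BED file
#'
#' Expects at least four columns (chrom, 0-based start, end, name); intervals
#' are converted to 1-based inclusive coordinates on load.
#'
#' @param path path to the BED file.
#' @return data frame with `chrom`, `start`, `end` (1-based inclusive), `name`.
#' @export
read_gene_bed <- function(path) {
  df <- tryCatch(
    read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) .stopf("malformed BED file '%s': %s", path, conditionMessage(e)))
  if (ncol(df) < 4)
    .stopf("malformed BED file '%s': need at least 4 columns (chrom, start, end, name)", path)
  start0 <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  if (any(is.na(start0)) || any(is.na(end)) || any(end <= start0))
    .stopf("malformed BED file '%s': non-numeric or inverted intervals", path)
  data.frame(chrom = as.character(df[[1]]), start = as.integer(start0) + 1L,
             end = as.integer(end), name = as.character(df[[4]]),
             stringsAsFactors = FALSE)
}

#' Save a trained signature model as JSON
#'
#' The serialization is plain JSON (support vectors, dual coefficients,
#' sigmoid calibration, feature scaling, probe list), written at full double
#' precision so that [load_model()] reproduces identical predictions.
#'
#' @param model a `signature_model` from [train_svm()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  obj <- unclass(model)
  obj$format <- .MODEL_FORMAT
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Load a signature model saved by [save_model()]
#' @param path path to the model JSON.
#' @return a `signature_model`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) .stopf("cannot parse model file '%s': %s",
                                             path, conditionMessage(e)))
  if (is.null(obj$format) || !identical(obj$format, .MODEL_FORMAT))
    .stopf("model file '%s' has format '%s'; this version reads '%s'",
           path, obj$format %||% "<missing>", .MODEL_FORMAT)
  obj$format <- NULL
  obj$probes <- as.character(obj$probes)
  obj$class_levels <- as.character(obj$class_levels)
  obj$scaling$center <- as.numeric(obj$scaling$center)
  obj$scaling$scale <- as.numeric(obj$scaling$scale)
  core <- obj$svm_core
  core$SV <- matrix(as.numeric(core$SV), nrow = length(core$SV) / length(obj$probes),
                    byrow = FALSE)
  # jsonlite returns matrices as parsed; rebuild defensively
  core$SV <- .as_num_matrix(obj$svm_core$SV)
  core$coefs <- .as_num_matrix(obj$svm_core$coefs)
  core$rho <- as.numeric(core$rho)
  core$nSV <- as.integer(core$nSV)
  core$gamma <- as.numeric(core$gamma)
  obj$svm_core <- core
  obj$sigmoids <- lapply(seq_len(nrow(obj$sigmoids)), function(i) {
    as.list(obj$sigmoids[i, , drop = FALSE])
  })
  obj$sigmoids <- lapply(obj$sigmoids, function(s)
    list(first = as.character(s$first), second = as.character(s$second),
         a = as.numeric(s$a), b = as.numeric(s$b)))
  structure(obj, class = "signature_model")
}

.as_num_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  m <- do.call(rbind, lapply(x, as.numeric))
  storage.mode(m) <- "double"
  m
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf(paste0("signature_model: %d probes, RBF SVM (cost = %g, gamma = %g), ",
                     "CV accuracy %.1f%%\n"),
              length(x$probes), x$cost, x$svm_core$gamma, 100 * x$cv_accuracy))
  invisible(x)
}
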