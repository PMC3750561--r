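## Expression matrix IO and QC: loading TSV log-ratio matrices with sample
## metadata, quantile normalization, PCA screening, duplicate detection.
##
## The expression container is deliberately plain: a numeric matrix with
## gene symbols as rownames and sample ids as colnames (genes x samples,
## log2 ratios against a common reference; NA marks a missing measurement),
## plus a metadata data.frame with columns sample_id, patient_id,
## cancer_label and optional survival_days, event, prior_subtype.

validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_ps("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_ps("expression matrix needs gene symbols as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop_ps("duplicate gene symbol row(s): ",
            paste(unique(rownames(values)[duplicated(rownames(values))]),
                  collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_ps("duplicate sample id column(s)")
  invisible(values)
}

#' Load an expression log-ratio matrix and its sample metadata
#'
#' The matrix TSV has gene symbols in the first column and one column per
#' sample (header row = sample ids); `na_token` marks missing measurements.
#' The metadata TSV needs at least `sample_id`, `patient_id` and
#' `cancer_label`; `survival_days`, `event` and `prior_subtype` are optional.
#' Matrix and metadata are joined on sample id; matrix columns without a
#' metadata record are dropped with a warning.
#'
#' @param path path to the expression TSV.
#' @param metadata_path path to the metadata TSV.
#' @param na_token string encoding a missing value (default `"NA"`).
#' @return a list with `values` (genes x samples numeric matrix) and
#'   `metadata` (data frame, one row per retained sample, in column order).
#' @export
load_expression <- function(path, metadata_path, na_token = "NA") {
  if (!file.exists(path)) stop_ps("expression file not found: ", path)
  if (!file.exists(metadata_path))
    stop_ps("metadata file not found: ", metadata_path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = na_token, check.names = FALSE,
                           colClasses = "character")
  genes <- toupper(trimws(raw[[1]]))
  values <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  if (nrow(raw) == 1) values <- matrix(values, nrow = 1,
                                       dimnames = list(NULL, names(raw)[-1]))
  bad <- which(is.na(values) & !is.na(as.matrix(raw[-1])) &
                 as.matrix(raw[-1]) != na_token, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_ps("non-numeric expression value at row ", bad[1, 1],
            ", sample '", colnames(values)[bad[1, 2]], "'")
  rownames(values) <- genes
  validate_expression_matrix(values)

  metadata <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "patient_id", "cancer_label")
  if (!all(req %in% names(metadata)))
    stop_ps("metadata must contain columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop_ps("duplicate sample_id in metadata")
  if ("event" %in% names(metadata)) metadata$event <- as.logical(metadata$event)

  keep <- colnames(values) %in% metadata$sample_id
  if (any(!keep))
    warning(sum(!keep), " sample(s) absent from metadata dropped: ",
            paste(colnames(values)[!keep], collapse = ", "), call. = FALSE)
  values <- values[, keep, drop = FALSE]
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  list(values = values, metadata = metadata)
}

#' Quantile normalize an expression matrix across samples
#'
#' Forces every sample (column) onto the common distribution given by the
#' across-sample mean of order statistics; tied values within a column
#' receive the mean of the reference values at their tied ranks. Missing
#' entries stay missing. Used for PCA/QC only — the rank-based aberration
#' scores are invariant to any within-sample monotone transform, so scoring
#' consumes the raw log ratios.
#'
#' @param values genes x samples numeric matrix (>= 2 samples).
#' @return the normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(values) {
  validate_expression_matrix(values)
  if (ncol(values) < 2)
    stop_ps("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Project samples onto their top principal components
#'
#' Samples are points in gene space; the data are sample-centred and
#' projected onto the top-`k` principal axes. Genes with missing values are
#' mean-imputed (per gene) for this embedding only.
#'
#' @param values genes x samples numeric matrix.
#' @param k number of components (1 <= k <= min(genes, samples)).
#' @return a list with `coords` (samples x k) and `variance_fraction`
#'   (length-k, non-increasing, each in `[0, 1]`).
#' @export
pca_embed <- function(values, k = 2L) {
  validate_expression_matrix(values)
  if (k <= 0) stop_ps("k must be positive")
  if (k > min(dim(values))) stop_ps("k exceeds min(genes, samples)")
  x <- t(values)                                   # samples x genes
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(fit$sdev^2)
  vf <- if (total > 0) fit$sdev^2 / total else rep(0, length(fit$sdev))
  k_avail <- min(k, ncol(fit$x))
  coords <- fit$x[, seq_len(k_avail), drop = FALSE]
  if (k_avail < k)   # degenerate data with fewer distinct directions than k
    coords <- cbind(coords, matrix(0, nrow(coords), k - k_avail))
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords,
       variance_fraction = c(vf, rep(0, k))[seq_len(k)])
}

#' Detect duplicate and blacklisted samples
#'
#' Three screens: (i) samples sharing a `patient_id` are collapsed to one
#' representative per patient (lexicographically first `sample_id` —
#' deterministic); (ii) cross-patient pairs with Pearson correlation at or
#' above `corr_threshold` are reported for manual review (not removed);
#' (iii) samples of blacklisted patients are removed unconditionally.
#'
#' @param values genes x samples numeric matrix.
#' @param metadata data frame with `sample_id` and `patient_id`.
#' @param corr_threshold correlation at or above which a cross-patient pair
#'   is flagged (default 0.99, in (0, 1]).
#' @param blacklist character vector of patient ids to remove outright.
#' @return list with `retained` (character vector of sample ids), `flagged`
#'   (data frame sample_id/reason) and `suspect_pairs` (data frame of
#'   correlated cross-patient pairs).
#' @export
detect_duplicates <- function(values, metadata, corr_threshold = 0.99,
                              blacklist = character(0)) {
  validate_expression_matrix(values)
  stopifnot(corr_threshold > 0, corr_threshold <= 1)
  meta <- metadata[match(colnames(values), metadata$sample_id), ]
  flagged <- data.frame(sample_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)

  black <- meta$sample_id[meta$patient_id %in% blacklist]
  if (length(black))
    flagged <- rbind(flagged, data.frame(sample_id = black,
                                         reason = "blacklisted-patient"))
  meta2 <- meta[!meta$sample_id %in% black, ]

  dup <- unlist(lapply(split(meta2$sample_id, meta2$patient_id), function(ids) {
    sort(ids)[-1]                     # keep the lexicographically first
  }), use.names = FALSE)
  if (length(dup))
    flagged <- rbind(flagged, data.frame(sample_id = dup,
                                         reason = "duplicate-patient"))
  retained <- setdiff(colnames(values), flagged$sample_id)

  suspect <- data.frame(sample_a = character(0), sample_b = character(0),
                        correlation = numeric(0), stringsAsFactors = FALSE)
  if (length(retained) >= 2) {
    cc <- stats::cor(values[, retained, drop = FALSE],
                     use = "pairwise.complete.obs")
    pat <- meta$patient_id[match(retained, meta$sample_id)]
    hit <- which(upper.tri(cc) & cc >= corr_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      cross <- pat[hit[, 1]] != pat[hit[, 2]]
      hit <- hit[cross, , drop = FALSE]
      if (nrow(hit))
        suspect <- data.frame(sample_a = retained[hit[, 1]],
                              sample_b = retained[hit[, 2]],
                              correlation = cc[hit],
                              stringsAsFactors = FALSE)
    }
  }
  list(retained = retained, flagged = flagged, suspect_pairs = suspect)
}
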