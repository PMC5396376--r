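# High-throughput RT-qPCR processing: detection filtering, outlier-sample
# removal, quantile normalization with replicate imputation, and
# limit-of-detection (LOD) expression scoring.

ct_to_matrix <- function(ct) {
  assert_cols(ct, c("assay_id", "sample_id", "ct"), "ct")
  wide <- tidyr::pivot_wider(ct[c("assay_id", "sample_id", "ct")],
                             names_from = "sample_id", values_from = "ct")
  mat <- as.matrix(wide[setdiff(names(wide), "assay_id")])
  rownames(mat) <- wide$assay_id
  mat
}

#' Remove assays with insufficient detection
#'
#' Wells whose quality score falls below `quality_floor` are treated as
#' undetected first; an assay is retained when its detection fraction across
#' samples is at least `min_detection`.
#'
#' @param ct Long Ct tibble (`assay_id`, `sample_id`, `ct`, `detected`,
#'   `quality`).
#' @param min_detection Minimum detection fraction, inclusive (default 0.5).
#' @param quality_floor Wells below this quality count as undetected
#'   (default 0.5).
#' @return The input restricted to retained assays (with low-quality wells
#'   re-flagged undetected); removed assay ids in attribute
#'   `removed_assays`.
#' @export
filter_assays <- function(ct, min_detection = 0.5, quality_floor = 0.5) {
  assert_cols(ct, c("assay_id", "sample_id", "ct", "detected", "quality"),
              "ct")
  assert_scalar_number(min_detection, "min_detection", 0, 1)
  ct <- mutate(ct,
               detected = .data$detected & .data$quality >= quality_floor,
               ct = ifelse(.data$detected, .data$ct, NA_real_))
  frac <- ct |>
    group_by(.data$assay_id) |>
    summarise(detection = mean(.data$detected), .groups = "drop")
  keep <- frac$assay_id[frac$detection >= min_detection]
  out <- filter(ct, .data$assay_id %in% keep)
  attr(out, "removed_assays") <- setdiff(frac$assay_id, keep)
  out
}

#' Detect and remove low-quality (outlier) samples
#'
#' Each sample gets an aggregation score: the mean, over assays, of its
#' detection probability (the detected flag weighted by the well quality
#' score). Samples scoring below `median - k * MAD` are outliers and removed.
#'
#' @param ct Long Ct tibble (post [filter_assays()]).
#' @param k MAD multiplier (default 3); `Inf` disables removal.
#' @return The input restricted to retained samples, with attributes
#'   `outlier_samples` (removed ids) and `scores` (per-sample score tibble).
#' @export
remove_outlier_samples <- function(ct, k = 3) {
  assert_cols(ct, c("assay_id", "sample_id", "detected", "quality"), "ct")
  n_samples <- dplyr::n_distinct(ct$sample_id)
  if (n_samples < 4) abort("at least 4 samples are required")
  scores <- ct |>
    group_by(.data$sample_id) |>
    summarise(score = mean(.data$detected * .data$quality), .groups = "drop")
  cut <- median(scores$score) - k * mad(scores$score)
  out_ids <- scores$sample_id[scores$score < cut]
  if (length(out_ids) == n_samples) {
    abort("all samples flagged as outliers; degenerate panel")
  }
  out <- filter(ct, !(.data$sample_id %in% out_ids))
  attr(out, "outlier_samples") <- out_ids
  attr(out, "scores") <- scores
  out
}

#' Quantile normalization with replicate imputation
#'
#' Classical quantile normalization of the assay x sample Ct matrix: per
#' sample, observed values sorted and replaced by cross-sample rank means;
#' tied raw values receive the mean of the implicated rank means. Samples
#' with missing wells are normalized against the reference distribution
#' interpolated at their reduced rank grid. Each missing cell is then imputed
#' as the mean of its assay's normalized values within the sample's replicate
#' group; cells missing in all replicates stay `NA` and are mapped to the LOD
#' (zero log2 expression) by [lod_and_express()].
#'
#' @param ct Long Ct tibble or wide numeric matrix (assays x samples).
#' @param replicate_groups Named character vector: sample id -> group label,
#'   covering every sample.
#' @return List: `normalized` (assay x sample matrix, imputed), `imputed`
#'   (logical matrix of imputed cells), `unresolved` (logical matrix of cells
#'   missing in all replicates).
#' @export
quantile_normalize_impute <- function(ct, replicate_groups) {
  mat <- if (is.matrix(ct)) ct else ct_to_matrix(ct)
  missing_groups <- setdiff(colnames(mat), names(replicate_groups))
  if (length(missing_groups) > 0) {
    abort(sprintf("replicate group missing for sample(s): %s",
                  paste(missing_groups, collapse = ", ")))
  }
  norm <- quantile_normalize(mat)
  was_na <- is.na(norm)
  groups <- replicate_groups[colnames(norm)]
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    sub <- norm[, cols, drop = FALSE]
    row_mean <- rowMeans(sub, na.rm = TRUE)
    for (j in seq_along(cols)) {
      nas <- is.na(sub[, j]) & !is.nan(row_mean)
      norm[nas, cols[j]] <- row_mean[nas]
    }
  }
  unresolved <- is.na(norm)
  list(normalized = norm, imputed = was_na & !unresolved,
       unresolved = unresolved)
}

# classical quantile normalization; NA-tolerant via rank-grid interpolation
quantile_normalize <- function(mat) {
  n <- nrow(mat)
  # reference distribution: mean of per-sample sorted values, each stretched
  # to the full n-point grid
  stretched <- apply(mat, 2, function(x) {
    xs <- sort(x, na.last = NA)
    if (length(xs) == 0) return(rep(NA_real_, n))
    if (length(xs) == 1) return(rep(xs, n))
    if (length(xs) == n) return(xs)
    approx(seq(0, 1, length.out = length(xs)), xs,
           xout = seq(0, 1, length.out = n))$y
  })
  ref <- rowMeans(stretched, na.rm = TRUE)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    obs <- which(!is.na(x))
    n_obs <- length(obs)
    if (n_obs == 0) next
    grid_ref <- if (n_obs == n) ref else if (n_obs == 1) median(ref) else {
      approx(seq(0, 1, length.out = n), ref,
             xout = seq(0, 1, length.out = n_obs))$y
    }
    vals <- numeric(n_obs)
    vals[order(x[obs])] <- grid_ref
    # ties share the mean of their implicated rank means
    vals <- stats::ave(vals, factor(x[obs]), FUN = mean)
    out[obs, j] <- vals
  }
  out
}

#' Limit-of-detection scoring and expression estimates
#'
#' The overall LOD is the 75% quantile (type 7) of all normalized Ct values,
#' pooled across the matrix, plus a constant. Log2 expression is
#' `LOD - ct_norm` and the rough absolute expression `2^log2_expr`; cells
#' left `NA` by imputation are set to the LOD (zero log2 expression).
#'
#' @param normalized Normalized Ct matrix from [quantile_normalize_impute()].
#' @param constant Additive LOD constant in cycles (default 10).
#' @param per_assay Compute a per-assay LOD instead of the pooled one
#'   (default `FALSE`).
#' @return List: `lod` (scalar, or per-assay vector) and `expression` (tibble
#'   `assay_id`, `sample_id`, `ct_norm`, `log2_expr`, `abs_expr`).
#' @export
lod_and_express <- function(normalized, constant = 10, per_assay = FALSE) {
  if (length(normalized) == 0) abort("empty matrix")
  if (per_assay) {
    lod <- apply(normalized, 1, quantile, probs = 0.75, na.rm = TRUE,
                 type = 7, names = FALSE) + constant
    lod_cell <- matrix(lod, nrow(normalized), ncol(normalized))
  } else {
    lod <- quantile(as.vector(normalized), 0.75, na.rm = TRUE, type = 7,
                    names = FALSE) + constant
    lod_cell <- matrix(lod, nrow(normalized), ncol(normalized))
  }
  ct_norm <- ifelse(is.na(normalized), lod_cell, normalized)
  log2_expr <- lod_cell - ct_norm
  expression <- tibble(
    assay_id = rep(rownames(normalized), times = ncol(normalized)),
    sample_id = rep(colnames(normalized), each = nrow(normalized)),
    ct_norm = as.vector(ct_norm),
    log2_expr = as.vector(log2_expr),
    abs_expr = 2^as.vector(log2_expr)
  )
  list(lod = lod, expression = expression)
}

#' Full qPCR pipeline
#'
#' Chains [filter_assays()], [remove_outlier_samples()],
#' [quantile_normalize_impute()] and [lod_and_express()] with their defaults.
#'
#' @inheritParams filter_assays
#' @inheritParams remove_outlier_samples
#' @inheritParams quantile_normalize_impute
#' @inheritParams lod_and_express
#' @return List: `expression`, `lod`, `normalized`, `outlier_samples`,
#'   `removed_assays`.
#' @export
qpcr_pipeline <- function(ct, replicate_groups, min_detection = 0.5,
                          quality_floor = 0.5, k = 3, constant = 10) {
  filtered <- filter_assays(ct, min_detection, quality_floor)
  kept <- remove_outlier_samples(filtered, k)
  qn <- quantile_normalize_impute(kept, replicate_groups)
  scored <- lod_and_express(qn$normalized, constant)
  list(expression = scored$expression, lod = scored$lod,
       normalized = qn$normalized,
       outlier_samples = attr(kept, "outlier_samples"),
       removed_assays = attr(filtered, "removed_assays"))
}
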