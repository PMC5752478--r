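#' Quantile-normalize an omics matrix
#'
#' Forces every sample column onto the same empirical distribution (the
#' row-wise mean of the sorted columns) while preserving within-column ranks;
#' the standard between-array normalization for single-channel intensity data.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param x An [omics_matrix()] without missing values.
#' @return The normalized [omics_matrix()].
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (anyNA(x$values))
    stop("matrix contains missing values; impute first (see preprocess())")
  out <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(out) <- dimnames(x$values)
  omics_matrix(out, layer = x$layer)
}

# column indices of the two contrast groups, in metadata order
contrast_cols <- function(x, meta, ctr) {
  idx_a <- match(samples_of(meta, ctr$a), colnames(x$values))
  idx_b <- match(samples_of(meta, ctr$b), colnames(x$values))
  if (anyNA(idx_a) || anyNA(idx_b))
    stop("metadata samples missing from the matrix: ",
         paste(c(samples_of(meta, ctr$a), samples_of(meta, ctr$b))[
           is.na(c(idx_a, idx_b))], collapse = ", "))
  list(a = idx_a, b = idx_b)
}

#' Per-feature log2 fold change
#'
#' Mean over the comparison group minus mean over the reference group; since
#' matrices are log2-scale this is the log2 fold change. Missing values are
#' dropped per feature and group.
#'
#' @param x An [omics_matrix()] (log2 scale).
#' @param meta Sample metadata.
#' @param ctr A [contrast()]; positive values mean higher in `ctr$b`.
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(x, meta, ctr) {
  cols <- contrast_cols(x, meta, ctr)
  rowMeans(x$values[, cols$b, drop = FALSE], na.rm = TRUE) -
    rowMeans(x$values[, cols$a, drop = FALSE], na.rm = TRUE)
}

# row-wise means, variances and counts with NA handling
row_stats <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  v <- rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
  v[n < 2] <- NA_real_
  list(n = n, mean = mu, var = v)
}

#' Vectorized Welch two-sample t-test
#'
#' Two-sided Welch t-test per feature with Welch-Satterthwaite degrees of
#' freedom, computed by direct vector arithmetic over all features at once.
#' Degenerate features (zero variance in both groups) yield t = 0, p = 1 when
#' the means agree, and p = 0 with a warning when they differ.
#'
#' @inheritParams log2_fold_change
#' @return A list with numeric vectors `t`, `df` and `p` (named by feature).
#' @export
welch_t <- function(x, meta, ctr) {
  cols <- contrast_cols(x, meta, ctr)
  a <- row_stats(x$values[, cols$a, drop = FALSE])
  b <- row_stats(x$values[, cols$b, drop = FALSE])
  if (any(a$n < 2) || any(b$n < 2))
    stop("each contrast group needs >= 2 non-missing values per feature")
  se2a <- a$var / a$n
  se2b <- b$var / b$n
  se <- sqrt(se2a + se2b)
  tt <- (b$mean - a$mean) / se
  df <- (se2a + se2b)^2 /
    (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- which(se == 0)
  if (length(zero)) {
    same <- abs(b$mean[zero] - a$mean[zero]) < .Machine$double.eps^0.5
    tt[zero[same]] <- 0; p[zero[same]] <- 1; df[zero[same]] <- a$n[zero[same]] + b$n[zero[same]] - 2
    if (any(!same)) {
      warning(sum(!same), " feature(s) with zero variance in both groups but ",
              "unequal means; p set to 0")
      p[zero[!same]] <- 0
      df[zero[!same]] <- a$n[zero[!same]] + b$n[zero[!same]] - 2
    }
  }
  names(tt) <- names(df) <- names(p) <- rownames(x$values)
  list(t = tt, df = df, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_(j>=i) ( m * p_(j) / j )` capped at 1; wraps
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Classify features as up / down / not significant
#'
#' A feature is `up` when `log2fc >= lfc_min` and the (adjusted) p-value is at
#' most `p_de`; `down` symmetric; otherwise `ns`. Results come back sorted by
#' p ascending, ties broken by |log2fc| descending then feature id.
#'
#' @param feature_id Character vector of feature ids.
#' @param log2fc,t_stat,df,p,q Aligned per-feature vectors (`q` defaults to
#'   `p`, the "raw" multiple-testing mode).
#' @param p_de Significance threshold, applied to `q`.
#' @param lfc_min Minimum |log2 fold change| (use 0 to disable).
#' @return A `data.frame` (one row per feature) with a `direction` column.
#' @export
classify_de <- function(feature_id, log2fc, t_stat = NA_real_, df = NA_real_,
                        p, q = p, p_de = 0.05, lfc_min = 1.0) {
  stopifnot(length(log2fc) == length(feature_id), length(p) == length(feature_id))
  direction <- rep("ns", length(feature_id))
  direction[log2fc >= lfc_min & q <= p_de] <- "up"
  direction[log2fc <= -lfc_min & q <= p_de] <- "down"
  out <- data.frame(feature_id = as.character(feature_id), log2fc = log2fc,
                    t_stat = t_stat, df = df, p = p, q = q,
                    direction = direction, stringsAsFactors = FALSE)
  out <- out[order(out$p, -abs(out$log2fc), out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the univariate differential-expression stage for one layer
#'
#' Normalizes (quantile for the miRNA layer, per-sample median-centering for
#' the protein layer, nothing for others unless requested), computes log2 fold
#' changes and Welch t-tests for the contrast, optionally applies
#' Benjamini-Hochberg, and classifies features.
#'
#' @param x An [omics_matrix()].
#' @param meta Sample metadata.
#' @param ctr A [contrast()].
#' @param p_de,lfc_min Thresholds passed to [classify_de()]. `lfc_min`
#'   defaults to 1 for the miRNA layer and 0 for the protein layer (the
#'   emulated study screened proteins on p alone).
#' @param mt_mode `"raw"` (q = p) or `"bh"`.
#' @param normalize `"auto"` (layer-dependent default described above),
#'   `"quantile"`, `"median"`, or `"none"`.
#' @return A `data.frame` of per-feature results (see [classify_de()]).
#' @export
run_de <- function(x, meta, ctr, p_de = 0.05,
                   lfc_min = if (x$layer == "mirna") 1.0 else 0.0,
                   mt_mode = c("raw", "bh"),
                   normalize = c("auto", "quantile", "median", "none")) {
  mt_mode <- match.arg(mt_mode)
  normalize <- match.arg(normalize)
  if (normalize == "auto")
    normalize <- switch(x$layer, mirna = "quantile", protein = "median", "none")
  x <- switch(normalize,
              quantile = quantile_normalize(x),
              median = {
                med <- apply(x$values, 2, stats::median, na.rm = TRUE)
                omics_matrix(sweep(x$values, 2, med - mean(med)),
                             layer = x$layer)
              },
              none = x)
  lfc <- log2_fold_change(x, meta, ctr)
  wt <- welch_t(x, meta, ctr)
  q <- if (mt_mode == "bh") bh_adjust(wt$p) else wt$p
  classify_de(rownames(x$values), lfc, wt$t, wt$df, wt$p, q,
              p_de = p_de, lfc_min = lfc_min)
}

#' Volcano table for plotting
#'
#' @param de Result of [run_de()] / [classify_de()].
#' @return `data.frame` with `feature_id`, `log2fc`, `neg_log10_p`,
#'   `direction`.
#' @export
de_volcano <- function(de) {
  data.frame(feature_id = de$feature_id, log2fc = de$log2fc,
             neg_log10_p = -log10(pmax(de$p, .Machine$double.xmin)),
             direction = de$direction, stringsAsFactors = FALSE)
}
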