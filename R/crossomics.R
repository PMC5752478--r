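#' Pearson correlation of two vectors with pairwise-complete handling
#'
#' Missing entries are removed pairwise (the effective `n` is reported). A
#' constant vector makes the correlation undefined; rather than propagating
#' `NaN`, the result is flagged not computable.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs required).
#' @return List with `r`, `n` (complete pairs used) and `computable`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = n, computable = FALSE))
  list(r = stats::cor(x, y), n = n, computable = TRUE)
}

#' Two-sided p-value for a Pearson correlation
#'
#' From `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the t distribution with
#' `n - 2` degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @param r Correlation in \[-1, 1\] (NA allowed, propagated).
#' @param n Number of pairs used (>= 3).
#' @return p-value(s), vectorized over `r` and `n`.
#' @export
pearson_p <- function(r, n) {
  stopifnot(all(n >= 3))
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1")
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r * sqrt(n - 2) / sqrt(1 - r^2)), n - 2))
  p
}

# canonical cross-layer pair order: lexicographic on layer names
layer_pairs <- function(layers) {
  layers <- sort(unique(layers))
  if (length(layers) < 2) return(NULL)
  pairs <- utils::combn(layers, 2)
  lapply(seq_len(ncol(pairs)), function(i) pairs[, i])
}

#' Cross-layer Pearson correlation edges among significant features
#'
#' Computes a correlation edge for every cross-layer pair of significant
#' features (all three layer pairs when three layers are given), across the
#' pooled samples of the requested groups. Layer pairs are canonicalized
#' lexicographically and edges are ordered deterministically (layer pair,
#' then feature ids), so repeated runs are identical. Pairs with missing
#' metabolite values use pairwise-complete samples; pairs whose effective n
#' falls below 3 or that involve a constant vector are dropped.
#'
#' @param sig Named list (by layer) of significant feature-id vectors; at
#'   least two layers must be nonempty.
#' @param matrices Named list (by layer) of [omics_matrix()] objects with
#'   matched sample ids.
#' @param meta Sample metadata.
#' @param scope_groups Groups whose samples are pooled for the correlation
#'   (default `c("model", "treated")`, the compared groups).
#' @return `data.frame` of edges: `feat_a`, `layer_a`, `feat_b`, `layer_b`,
#'   `r`, `p`, `n`.
#' @export
correlate_layers <- function(sig, matrices, meta,
                             scope_groups = c("model", "treated")) {
  layers <- intersect(names(matrices), names(sig))
  layers <- layers[vapply(sig[layers], length, integer(1)) > 0]
  if (length(layers) < 2)
    stop("need nonempty significant-feature lists for at least two layers")
  samples <- samples_of(meta, scope_groups)
  if (length(samples) < 3) stop("fewer than 3 samples in scope")
  for (ly in layers) {
    missing <- setdiff(samples, colnames(matrices[[ly]]$values))
    if (length(missing))
      stop(sprintf("layer '%s' lacks sample(s): %s", ly,
                   paste(missing, collapse = ", ")))
    bad <- setdiff(sig[[ly]], rownames(matrices[[ly]]$values))
    if (length(bad))
      stop(sprintf("significant feature(s) not in layer '%s': %s", ly,
                   paste(bad, collapse = ", ")))
  }
  out <- list()
  for (pair in layer_pairs(layers)) {
    la <- pair[1]; lb <- pair[2]
    A <- t(matrices[[la]]$values[sort(sig[[la]]), samples, drop = FALSE])
    B <- t(matrices[[lb]]$values[sort(sig[[lb]]), samples, drop = FALSE])
    R <- suppressWarnings(stats::cor(A, B, use = "pairwise.complete.obs"))
    N <- crossprod(!is.na(A), !is.na(B))
    grid <- expand.grid(ia = seq_len(ncol(A)), ib = seq_len(ncol(B)))
    grid <- grid[order(grid$ia, grid$ib), , drop = FALSE]
    edges <- data.frame(
      feat_a = colnames(A)[grid$ia], layer_a = la,
      feat_b = colnames(B)[grid$ib], layer_b = lb,
      r = R[cbind(grid$ia, grid$ib)],
      n = as.integer(N[cbind(grid$ia, grid$ib)]),
      stringsAsFactors = FALSE)
    edges <- edges[edges$n >= 3 & !is.na(edges$r), , drop = FALSE]
    edges$p <- pearson_p(edges$r, edges$n)
    out[[paste(pair, collapse = "|")]] <-
      edges[, c("feat_a", "layer_a", "feat_b", "layer_b", "r", "p", "n")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter correlation edges on |r| and p
#'
#' Keeps edges with `|r| >= r_min` and `p <= p_max`. The absolute value is
#' used for thresholding but the signed correlation is retained on the edge
#' (negative associations are reported with their sign).
#'
#' @param edges Edge table from [correlate_layers()].
#' @param r_min,p_max Thresholds (defaults 0.9 and 0.05).
#' @return Filtered edge table.
#' @export
filter_edges <- function(edges, r_min = 0.9, p_max = 0.05) {
  keep <- !is.na(edges$r) & abs(edges$r) >= r_min & edges$p <= p_max
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank hub miRNAs in a cross-layer correlation network
#'
#' miRNA-side features are ranked by degree (number of retained cross-layer
#' edges) descending, then by mean |r| descending, then by id. Partner lists
#' are sorted alphabetically.
#'
#' @param edges Filtered edge table (see [filter_edges()]).
#' @return `data.frame` with `mirna_id`, `degree`, `mean_abs_r`, `partners`
#'   (semicolon-separated).
#' @export
rank_hubs <- function(edges) {
  is_a <- edges$layer_a == "mirna"
  is_b <- edges$layer_b == "mirna"
  mir <- c(edges$feat_a[is_a], edges$feat_b[is_b & !is_a])
  partner <- c(edges$feat_b[is_a], edges$feat_a[is_b & !is_a])
  absr <- abs(c(edges$r[is_a], edges$r[is_b & !is_a]))
  if (length(mir) == 0)
    return(data.frame(mirna_id = character(0), degree = integer(0),
                      mean_abs_r = numeric(0), partners = character(0),
                      stringsAsFactors = FALSE))
  sp <- split(seq_along(mir), mir)
  out <- data.frame(
    mirna_id = names(sp),
    degree = vapply(sp, length, integer(1)),
    mean_abs_r = vapply(sp, function(i) mean(absr[i]), numeric(1)),
    partners = vapply(sp, function(i)
      paste(sort(partner[i]), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, -out$mean_abs_r, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
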