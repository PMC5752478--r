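#' Metabolomics preprocessing specification
#'
#' @param imputation `"halfmin"` (each missing cell becomes half the
#'   feature's observed minimum, the usual left-censoring surrogate) or
#'   `"none"`.
#' @param normalization `"sum"` (total-intensity normalization of each sample
#'   on the linear scale, then back to log2) or `"none"`.
#' @param scaling Feature-wise `"uv"` (unit variance), `"pareto"` (divide by
#'   the square root of the standard deviation, the metabolomics convention)
#'   or `"none"`.
#' @param centering Subtract feature means (default `TRUE`).
#' @return A list of class `preprocess_spec`.
#' @export
preprocess_spec <- function(imputation = c("halfmin", "none"),
                            normalization = c("none", "sum"),
                            scaling = c("pareto", "uv", "none"),
                            centering = TRUE) {
  structure(list(imputation = match.arg(imputation),
                 normalization = match.arg(normalization),
                 scaling = match.arg(scaling),
                 centering = isTRUE(centering)), class = "preprocess_spec")
}

#' Preprocess a metabolite matrix for multivariate modelling
#'
#' Applies, in order: half-minimum imputation, total-sum normalization
#' (computed on the linear scale, i.e. after de-logging, then re-logged),
#' feature-wise centering, and feature-wise scaling.
#'
#' @param x An [omics_matrix()] (missing values allowed).
#' @param spec A [preprocess_spec()].
#' @return The processed [omics_matrix()].
#' @export
preprocess <- function(x, spec = preprocess_spec()) {
  stopifnot(inherits(x, "omics_matrix"), inherits(spec, "preprocess_spec"))
  v <- x$values
  if (spec$imputation == "halfmin" && anyNA(v)) {
    all_na <- rowSums(!is.na(v)) == 0
    if (any(all_na))
      stop("feature(s) with no observed values: ",
           paste(rownames(v)[all_na], collapse = ", "))
    halfmin <- apply(v, 1, min, na.rm = TRUE) / 2
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- halfmin[idx[, 1]]
  }
  if (anyNA(v))
    stop("missing values remain; use imputation = 'halfmin'")
  if (spec$normalization == "sum") {
    lin <- 2^v
    totals <- colSums(lin)
    lin <- sweep(lin, 2, mean(totals) / totals, `*`)
    v <- log2(lin)
  }
  if (spec$centering) v <- v - rowMeans(v)
  if (spec$scaling != "none") {
    s <- apply(v, 1, stats::sd)
    s[s == 0] <- 1
    div <- if (spec$scaling == "uv") s else sqrt(s)
    v <- v / div
  }
  omics_matrix(v, layer = x$layer)
}

# flip a component's sign so its reference vector's largest-|element| is
# positive; returns +1/-1
sign_flip <- function(ref) {
  i <- which.max(abs(ref))
  if (ref[i] < 0) -1 else 1
}

#' Principal component analysis by SVD
#'
#' @param X Numeric matrix, observations in rows, variables in columns.
#' @param n_comp Number of components (default: full rank).
#' @param center Center columns first (default `TRUE`).
#' @return A list of class `pca_model` with `scores` (n x k), `loadings`
#'   (J x k, orthonormal, each column's largest-magnitude element positive),
#'   `explained` (variance fractions) and `center`.
#' @export
pca_fit <- function(X, n_comp = min(dim(X)) , center = TRUE) {
  X <- as.matrix(X)
  stopifnot(n_comp >= 1, n_comp <= min(dim(X)))
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  k <- n_comp
  flip <- vapply(seq_len(k), function(a) sign_flip(sv$v[, a]), numeric(1))
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, `*`)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k, k), 2, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 center = mu), class = "pca_model")
}

# single NIPALS PLS1 component on centered data; returns unit-norm weight,
# score, x-loading, y-loading and the explained y sum of squares
pls1_component <- function(Xc, yc) {
  w <- drop(crossprod(Xc, yc))
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps) stop("X carries no covariance with y")
  w <- w / nw
  flip <- sign_flip(w)
  w <- w * flip
  t <- drop(Xc %*% w)
  tt <- sum(t^2)
  p <- drop(crossprod(Xc, t)) / tt
  q <- sum(yc * t) / tt
  list(w = w, t = t, p = p, q = q, ssy = q^2 * tt)
}

#' NIPALS PLS1 regression
#'
#' Sequential one-component partial least squares with X and y deflation:
#' per component `w = X'y/||X'y||`, `t = Xw`, `p = X't/(t't)`,
#' `q = y't/(t't)`, then `X <- X - t p'`, `y <- y - t q`. Components carry a
#' deterministic sign (largest-|element| of each weight positive).
#'
#' @param X Matrix, observations x variables.
#' @param y Numeric response (class membership coded -1/+1 for
#'   discriminant use); centered internally.
#' @param n_comp Number of components.
#' @return A list of class `pls_model` with `W`, `T`, `P` (matrices with one
#'   column per component), `q`, `ssy` (explained y sum of squares per
#'   component), `fitted`, `R2Y`, `R2X`, and the training centers.
#' @export
pls1_fit <- function(X, y, n_comp = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), n_comp >= 1)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  ssx_tot <- sum(Xc^2); ssy_tot <- sum(yc^2)
  J <- ncol(X)
  W <- T <- P <- NULL; q <- ssy <- numeric(0)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_comp)) {
    comp <- pls1_component(Xd, yd)
    W <- cbind(W, comp$w); T <- cbind(T, comp$t); P <- cbind(P, comp$p)
    q <- c(q, comp$q); ssy <- c(ssy, comp$ssy)
    Xd <- Xd - tcrossprod(comp$t, comp$p)
    yd <- yd - comp$t * comp$q
  }
  fitted <- y_mean + drop(T %*% q)
  structure(list(W = W, T = T, P = P, q = q, ssy = ssy, fitted = fitted,
                 R2Y = sum(ssy) / ssy_tot,
                 R2X = sum(vapply(seq_len(ncol(T)), function(a)
                   sum(T[, a]^2) * sum(P[, a]^2), numeric(1))) / ssx_tot,
                 x_mean = x_mean, y_mean = y_mean, n_comp = n_comp,
                 J = J), class = "pls_model")
}

#' Orthogonal projections to latent structures (O-PLS / OPLS-DA)
#'
#' Removes up to `n_ortho` y-orthogonal components from X before fitting a
#' single predictive PLS component: per round, with `w = X'y/||X'y||`,
#' `t = Xw`, `p = X't/(t't)`, the orthogonal weight is
#' `w_o = p - (w'p) w` (normalized), `t_o = X w_o`, `p_o = X't_o/(t_o't_o)`,
#' and X is deflated by `t_o p_o'`. When `||w_o||` falls below 1e-12 there is
#' no y-orthogonal variation left and the loop stops early (with a message).
#' With `n_ortho = 0` the model reproduces one-component PLS1 exactly.
#'
#' @inheritParams pls1_fit
#' @param n_ortho Maximum number of orthogonal components (>= 0).
#' @return A list of class `opls_model` with the predictive part (`w_p`,
#'   `t_p`, `p_p`, `q`, `ssy`), the orthogonal part (`W_o`, `T_o`, `P_o`,
#'   `n_ortho` actually kept), `fitted`, `R2X`, `R2Y`, and training centers.
#' @export
opls_fit <- function(X, y, n_ortho = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), n_ortho >= 0)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  ssx_tot <- sum(Xc^2); ssy_tot <- sum(yc^2)
  W_o <- T_o <- P_o <- NULL
  Xd <- Xc
  kept <- 0L
  for (i in seq_len(n_ortho)) {
    w <- drop(crossprod(Xd, yc))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    w_o <- p - sum(w * p) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) {
      message(sprintf(
        "opls_fit: no y-orthogonal variation left after %d component(s); stopping early",
        kept))
      break
    }
    w_o <- w_o / nw
    w_o <- w_o * sign_flip(w_o)
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
    Xd <- Xd - tcrossprod(t_o, p_o)
    kept <- kept + 1L
  }
  comp <- pls1_component(Xd, yc)
  fitted <- y_mean + comp$t * comp$q
  r2x_pred <- sum(comp$t^2) * sum(comp$p^2) / ssx_tot
  r2x_orth <- if (kept > 0)
    sum(vapply(seq_len(kept), function(a)
      sum(T_o[, a]^2) * sum(P_o[, a]^2), numeric(1))) / ssx_tot else 0
  structure(list(w_p = comp$w, t_p = comp$t, p_p = comp$p, q = comp$q,
                 ssy = comp$ssy, W_o = W_o, T_o = T_o, P_o = P_o,
                 n_ortho = kept, fitted = fitted,
                 R2Y = comp$ssy / ssy_tot, R2X = r2x_pred + r2x_orth,
                 R2X_pred = r2x_pred, R2X_ortho = r2x_orth,
                 x_mean = x_mean, y_mean = y_mean, J = ncol(X)),
            class = "opls_model")
}

#' Predict the response for new observations from an O-PLS model
#'
#' @param object An `opls_model`.
#' @param newdata Matrix with the same variables as the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xc <- sweep(as.matrix(newdata), 2, object$x_mean)
  if (object$n_ortho > 0)
    for (a in seq_len(object$n_ortho)) {
      t_o <- drop(Xc %*% object$W_o[, a])
      Xc <- Xc - tcrossprod(t_o, object$P_o[, a])
    }
  object$y_mean + drop(Xc %*% object$w_p) * object$q
}

#' Variable importance in the projection (VIP)
#'
#' `VIP_j = sqrt( J * sum_a [ SSY_a * (w_ja / ||w_a||)^2 ] / sum_a SSY_a )`
#' over the predictive components only (the classic formula; orthogonal
#' components are excluded by construction for O-PLS models). The
#' normalization forces `sum_j VIP_j^2 = J`.
#'
#' @param model A `pls_model` or `opls_model`.
#' @return Numeric vector of VIP scores, named when the training data carried
#'   column names.
#' @export
vip_scores <- function(model) {
  if (inherits(model, "opls_model")) {
    W <- matrix(model$w_p, ncol = 1); ssy <- model$ssy
  } else if (inherits(model, "pls_model")) {
    W <- model$W; ssy <- model$ssy
  } else stop("need a pls_model or opls_model")
  J <- nrow(W)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  vip <- sqrt(J * drop(wn^2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(W)
  if (is.null(names(vip)) && !is.null(names(model$x_mean)))
    names(vip) <- names(model$x_mean)
  vip
}

#' Cross-validated Q2 for an O-PLS discriminant model
#'
#' Stratified k-fold cross-validation: fold membership is assigned within
#' each class after a seeded shuffle, each held-out fold is predicted from a
#' model refit on the remaining samples, and
#' `Q2 = 1 - PRESS / SS_y(total)`.
#'
#' @inheritParams opls_fit
#' @param folds Number of folds (>= 2).
#' @param seed RNG seed for the fold assignment.
#' @return Scalar Q2.
#' @export
q2_cv <- function(X, y, n_ortho = 1L, folds = 7L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(folds >= 2, nrow(X) == length(y))
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(length(idx))]
    }
  })
  press <- 0
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    if (all(test) || !any(test)) next
    fit <- suppressMessages(opls_fit(X[!test, , drop = FALSE], y[!test],
                                     n_ortho = n_ortho))
    press <- press + sum((y[test] - predict(fit, X[test, , drop = FALSE]))^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Select features exceeding a VIP threshold
#'
#' @param vip Named VIP vector (see [vip_scores()]).
#' @param threshold Strict lower bound (> 0).
#' @return `data.frame` with `feature_id` and `vip`, sorted by VIP descending,
#'   ties broken by id.
#' @export
select_by_vip <- function(vip, threshold) {
  stopifnot(threshold > 0, !is.null(names(vip)))
  keep <- vip > threshold
  out <- data.frame(feature_id = names(vip)[keep], vip = unname(vip[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$vip, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit OPLS-DA for a two-group contrast of an omics matrix
#'
#' Convenience wrapper: subsets the matrix to the contrast samples, applies
#' [preprocess()], codes the groups as -1 (reference) / +1 (comparison), fits
#' [opls_fit()], and computes VIP scores and cross-validated Q2.
#'
#' @param x An [omics_matrix()].
#' @param meta Sample metadata.
#' @param ctr A [contrast()].
#' @param spec A [preprocess_spec()] (default: half-minimum imputation plus
#'   Pareto scaling, the MarkerLynx/EZinfo-style convention).
#' @param n_ortho,cv_folds,seed Passed to [opls_fit()] and [q2_cv()].
#' @return List with `model`, `vip`, `q2`, `y`, and the processed sample-by-
#'   feature matrix `X`.
#' @export
run_opls <- function(x, meta, ctr, spec = preprocess_spec(), n_ortho = 1L,
                     cv_folds = 7L, seed = 1L) {
  samples <- c(samples_of(meta, ctr$a), samples_of(meta, ctr$b))
  sub <- omics_matrix(x$values[, samples, drop = FALSE], layer = x$layer)
  proc <- preprocess(sub, spec)
  X <- t(proc$values)
  y <- ifelse(colnames(proc$values) %in% samples_of(meta, ctr$b), 1, -1)
  model <- opls_fit(X, y, n_ortho = n_ortho)
  list(model = model, vip = vip_scores(model),
       q2 = q2_cv(X, y, n_ortho = n_ortho, folds = cv_folds, seed = seed),
       y = y, X = X)
}
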