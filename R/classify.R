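#' @title Discriminant signatures by (multi-block) PLS-DA
#' @name classify
#' @description
#' Supervised dimension reduction used to extract class-discriminant
#' signatures from the activity and co-depletion layers: NIPALS PLS2
#' against a one-hot class matrix, with per-component hard top-k weight
#' truncation ("keepX" semantics), VIP variable ranking, an sGCCA-style
#' multi-block extension, and five-fold cross-validated tuning with
#' centroid-distance prediction.
NULL

.scale_block <- function(X, scale = TRUE) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  scl[!is.finite(scl) | scl == 0] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

.one_hot <- function(y) {
  y <- factor(y)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  attr(Y, "assign") <- NULL
  Y
}

.truncate_keep <- function(w, keep) {
  if (keep < length(w)) {
    drop <- order(abs(w), decreasing = TRUE)[-seq_len(keep)]
    w[drop] <- 0
  }
  n <- sqrt(sum(w^2))
  if (n > 0) w <- w / n
  w
}

.fix_sign <- function(w) if (w[which.max(abs(w))] < 0) -w else w

#' Fit a PLS-DA model
#'
#' NIPALS PLS2 of autoscaled features against the centered one-hot class
#' matrix. The number of components defaults to one fewer than the number
#' of classes. Sparsity is per-component hard truncation: after
#' convergence only the `keep_per_component` largest-magnitude entries of
#' the weight vector survive. Deflation is classic PLS2 regression
#' deflation, so component scores are mutually orthogonal.
#'
#' @param X sample x feature matrix, no missing cells (impute first).
#' @param y class labels, at least two classes.
#' @param n_components number of latent components
#'   (default `nlevels(y) - 1`).
#' @param keep_per_component variables retained per component (scalar or
#'   vector per component); values above `ncol(X)` keep everything.
#' @param scale autoscale features to unit variance (default). Activity
#'   (RADDi) matrices are conventionally fit unscaled
#'   (`scale = FALSE`) since they already live on the \[0, 1\] scale.
#' @param max_iter,tol NIPALS convergence controls.
#' @return object of class `"plsda_model"`: weights `W`, loadings `P`,
#'   scores `T`, class-indicator weights `C`, per-component explained
#'   class variance `ss`, scaling parameters, class centroids in score
#'   space.
#' @export
fit_plsda <- function(X, y, n_components = NULL, keep_per_component = NULL,
                      scale = TRUE, max_iter = 500, tol = 1e-10) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (anyNA(X)) stop("X contains missing cells; impute first")
  if (is.null(n_components)) n_components <- nlevels(y) - 1L
  sc <- .scale_block(X, scale)
  Xc <- sc$X
  Y <- base::scale(.one_hot(y), center = TRUE, scale = FALSE)
  p <- ncol(Xc)
  keep <- rep_len(if (is.null(keep_per_component)) p else keep_per_component,
                  n_components)
  keep <- pmin(keep, p)

  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(Xc), n_components)
  C <- matrix(0, ncol(Y), n_components)
  ss <- numeric(n_components)
  for (h in seq_len(n_components)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    w <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w_new <- drop(crossprod(Xc, u))
      nw <- sqrt(sum(w_new^2))
      if (nw < .Machine$double.eps) break
      w_new <- w_new / nw
      tt <- drop(Xc %*% w_new)
      q <- drop(crossprod(Y, tt))
      q <- q / sqrt(sum(q^2))
      u <- drop(Y %*% q)
      if (sum((w_new - w)^2) < tol) {
        w <- w_new
        break
      }
      w <- w_new
    }
    w <- .truncate_keep(w, keep[h])
    w <- .fix_sign(w)
    tt <- drop(Xc %*% w)
    tss <- sum(tt^2)
    if (tss < .Machine$double.eps) break
    pl <- drop(crossprod(Xc, tt)) / tss
    cl <- drop(crossprod(Y, tt)) / tss
    Xc <- Xc - tcrossprod(tt, pl)
    Y <- Y - tcrossprod(tt, cl)
    W[, h] <- w
    P[, h] <- pl
    Tm[, h] <- tt
    C[, h] <- cl
    ss[h] <- sum(cl^2) * tss  # class variance explained by component h
  }
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("comp", 1:n_components))
  dimnames(Tm) <- list(rownames(X), colnames(W))
  centroids <- apply(Tm, 2, function(s) tapply(s, y, mean))
  structure(list(W = W, P = P, T = Tm, C = C, ss = ss, keep = keep,
                 center = sc$center, scale = sc$scale, y = y,
                 levels = levels(y), centroids = centroids,
                 n_components = n_components),
            class = "plsda_model")
}

.rotation <- function(W, P) {
  M <- crossprod(P, W)
  W %*% solve(M)
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("PLS-DA model:", length(x$levels), "classes,", x$n_components,
      "component(s),", nrow(x$W), "features\n")
  cat("  kept per component:", paste(x$keep, collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes from a PLS-DA model
#'
#' Projects new samples into the latent space and assigns the nearest
#' class centroid (Euclidean by default, Mahalanobis on request).
#'
#' @param object a `"plsda_model"`.
#' @param newdata sample x feature matrix with the training columns.
#' @param distance `"centroid"` (Euclidean) or `"mahalanobis"`.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.plsda_model <- function(object, newdata,
                                distance = c("centroid", "mahalanobis"),
                                ...) {
  distance <- match.arg(distance)
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale,
              "/")
  S <- Xs %*% .rotation(object$W, object$P)
  .nearest_centroid(S, object$centroids, object$T, distance,
                    object$levels)
}

.nearest_centroid <- function(S, centroids, train_scores, distance, levels) {
  Sigma_inv <- NULL
  if (distance == "mahalanobis") {
    Sigma <- stats::cov(train_scores)
    Sigma_inv <- solve(Sigma + diag(1e-8, ncol(Sigma)))
  }
  pred <- apply(S, 1, function(s) {
    d <- apply(centroids, 1, function(ct) {
      v <- s - ct
      if (is.null(Sigma_inv)) sum(v^2) else drop(v %*% Sigma_inv %*% v)
    })
    rownames(centroids)[which.min(d)]
  })
  factor(pred, levels = levels)
}

#' Variable importance in projection
#'
#' Standard VIP: per feature, the weighted sum of squared normalized
#' weights over components, weights = per-component explained class
#' variance; by construction the mean of squared VIP over features is 1.
#'
#' @param model a `"plsda_model"`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  W <- model$W
  used <- model$ss > 0
  wn <- sweep(W[, used, drop = FALSE], 2,
              sqrt(colSums(W[, used, drop = FALSE]^2)), "/")
  v <- sqrt(nrow(W) * drop(wn^2 %*% model$ss[used]) / sum(model$ss[used]))
  stats::setNames(v, rownames(W))
}

#' Fit a multi-block (sGCCA-style) PLS-DA
#'
#' Alternating optimization maximizing the design-weighted sum of
#' covariances between block scores and the class-block score, with
#' per-block hard top-k weight truncation. Each block is deflated by its
#' own score; the class block by the consensus (average) score. With one
#' block this reduces to [fit_plsda].
#'
#' @param blocks named list of sample x feature matrices sharing rows.
#' @param y class labels.
#' @param design_connectivity weight in \[0, 1\] linking every pair of
#'   feature blocks (the class block is always fully linked, weight 1).
#' @param keep named list: per block, variables kept per component
#'   (scalar or vector); `NULL` keeps everything.
#' @param n_components default `nlevels(y) - 1`.
#' @param scale per-block autoscaling flag (scalar or named vector).
#' @param max_iter,tol convergence controls.
#' @return object of class `"block_plsda_model"` with per-block weights,
#'   loadings and scores, consensus scores/centroids, and the per-pair
#'   component-space correlation machinery used for latent-variable
#'   enzyme-protein pairing ([pairwise_association]).
#' @export
fit_block_plsda <- function(blocks, y, design_connectivity = 1, keep = NULL,
                            n_components = NULL, scale = TRUE,
                            max_iter = 500, tol = 1e-10) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(n) != 1) stop("blocks must share the sample axis")
  y <- factor(y)
  if (length(y) != n) stop("labels do not match the sample axis")
  if (is.null(n_components)) n_components <- nlevels(y) - 1L
  B <- length(blocks)
  scale <- rep_len(scale, B)
  sc <- mapply(.scale_block, blocks, scale, SIMPLIFY = FALSE)
  Xb <- lapply(sc, `[[`, "X")
  Y <- base::scale(.one_hot(y), center = TRUE, scale = FALSE)
  pb <- vapply(Xb, ncol, integer(1))
  keepm <- vapply(seq_len(B), function(b) {
    k <- if (is.null(keep) || is.null(keep[[names(blocks)[b]]])) pb[b]
    else keep[[names(blocks)[b]]]
    as.numeric(pmin(rep_len(k, n_components), pb[b]))
  }, numeric(n_components))
  if (is.null(dim(keepm))) keepm <- matrix(keepm, nrow = n_components)
  Xb0 <- Xb  # scaled, undeflated copies kept for association extraction

  W <- lapply(pb, function(p) matrix(0, p, n_components))
  P <- lapply(pb, function(p) matrix(0, p, n_components))
  Tb <- lapply(seq_len(B), function(b) matrix(0, n, n_components))
  Cm <- matrix(0, ncol(Y), n_components)
  for (h in seq_len(n_components)) {
    a <- lapply(seq_len(B), function(b) {
      v <- drop(crossprod(Xb[[b]], Y[, which.max(apply(Y, 2, stats::var))]))
      nv <- sqrt(sum(v^2))
      if (nv > 0) v / nv else v
    })
    tb <- lapply(seq_len(B), function(b) drop(Xb[[b]] %*% a[[b]]))
    for (it in seq_len(max_iter)) {
      a_old <- a
      cl <- drop(crossprod(Y, Reduce(`+`, tb)))
      ncl <- sqrt(sum(cl^2))
      if (ncl > 0) cl <- cl / ncl
      u <- drop(Y %*% cl)
      for (b in seq_len(B)) {
        s <- u
        if (B > 1 && design_connectivity > 0)
          for (b2 in setdiff(seq_len(B), b))
            s <- s + design_connectivity * tb[[b2]]
        v <- drop(crossprod(Xb[[b]], s))
        nv <- sqrt(sum(v^2))
        if (nv > 0) v <- v / nv
        v <- .truncate_keep(v, keepm[h, b])
        a[[b]] <- v
        tb[[b]] <- drop(Xb[[b]] %*% v)
      }
      if (sum(vapply(seq_len(B), function(b)
        sum((a[[b]] - a_old[[b]])^2), numeric(1))) < tol) break
    }
    for (b in seq_len(B)) {
      a[[b]] <- .fix_sign(a[[b]])
      tb[[b]] <- drop(Xb[[b]] %*% a[[b]])
    }
    tcons <- Reduce(`+`, tb) / B
    cl <- drop(crossprod(Y, tcons)) / sum(tcons^2)
    Y <- Y - tcrossprod(tcons, cl)
    Cm[, h] <- cl
    for (b in seq_len(B)) {
      tss <- sum(tb[[b]]^2)
      if (tss < .Machine$double.eps) next
      pl <- drop(crossprod(Xb[[b]], tb[[b]])) / tss
      Xb[[b]] <- Xb[[b]] - tcrossprod(tb[[b]], pl)
      W[[b]][, h] <- a[[b]]
      P[[b]][, h] <- pl
      Tb[[b]][, h] <- tb[[b]]
    }
  }
  for (b in seq_len(B)) {
    dimnames(W[[b]]) <- dimnames(P[[b]]) <-
      list(colnames(blocks[[b]]), paste0("comp", seq_len(n_components)))
    dimnames(Tb[[b]]) <- list(rownames(blocks[[b]]), colnames(W[[b]]))
  }
  names(W) <- names(P) <- names(Tb) <- names(blocks)
  consensus <- Reduce(`+`, Tb) / B
  centroids <- apply(consensus, 2, function(s) tapply(s, y, mean))
  structure(list(W = W, P = P, scores = Tb, consensus = consensus,
                 data = Xb0,
                 C = Cm, centers = lapply(sc, `[[`, "center"),
                 scales = lapply(sc, `[[`, "scale"), y = y,
                 levels = levels(y), centroids = centroids,
                 n_components = n_components, keep = keepm,
                 design_connectivity = design_connectivity),
            class = "block_plsda_model")
}

#' @export
print.block_plsda_model <- function(x, ...) {
  cat("multi-block PLS-DA:", length(x$W), "block(s),", x$n_components,
      "component(s),", length(x$levels), "classes\n")
  invisible(x)
}

#' Predict classes from a multi-block model
#'
#' @param object a `"block_plsda_model"`.
#' @param newblocks named list of matrices matching the training blocks.
#' @param distance `"centroid"` or `"mahalanobis"`.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.block_plsda_model <- function(object, newblocks,
                                      distance = c("centroid",
                                                   "mahalanobis"), ...) {
  distance <- match.arg(distance)
  S <- 0
  for (b in names(object$W)) {
    Xs <- sweep(sweep(as.matrix(newblocks[[b]]), 2, object$centers[[b]]), 2,
                object$scales[[b]], "/")
    S <- S + Xs %*% .rotation(object$W[[b]], object$P[[b]])
  }
  S <- S / length(object$W)
  .nearest_centroid(S, object$centroids, object$consensus, distance,
                    object$levels)
}

#' Component-space feature associations between two blocks
#'
#' The latent-variable pairing used for enzyme-protein signatures: for
#' features i (block a) and j (block b),
#' `M_ij = sum_h cor(x_i, t_h) * cor(z_j, t_h)` over the consensus
#' component scores -- the relevance-network similarity extracted from the
#' fitted multi-block model.
#'
#' @param model a `"block_plsda_model"`.
#' @param block_a,block_b block names (defaults: first two blocks).
#' @return feature-by-feature association matrix in \[-1, 1\].
#' @export
pairwise_association <- function(model, block_a = NULL, block_b = NULL) {
  nb <- names(model$W)
  if (is.null(block_a)) block_a <- nb[1]
  if (is.null(block_b)) block_b <- nb[min(2, length(nb))]
  sa <- model$scores[[block_a]]
  used <- colSums(abs(sa)) > 0
  tcons <- model$consensus[, used, drop = FALSE]
  ca <- suppressWarnings(stats::cor(model$data[[block_a]], tcons))
  cb <- suppressWarnings(stats::cor(model$data[[block_b]], tcons))
  ca[is.na(ca)] <- 0
  cb[is.na(cb)] <- 0
  tcrossprod(ca, cb)
}

#' Cross-validated tuning of a multi-block consensus model
#'
#' Grid search over per-block keep values and component counts, scored by
#' stratified k-fold cross-validation with centroid-distance prediction;
#' returns the consensus model refit on all samples at the best cell.
#'
#' @param blocks named list of sample x feature matrices.
#' @param y class labels.
#' @param candidate_keeps named list: per block, a vector of candidate
#'   keep values (default: all features, i.e. no sparsity grid).
#' @param folds number of CV folds (default 5); must not exceed the
#'   smallest class.
#' @param ncomp_max maximum components tried (default `nlevels(y) - 1`).
#' @param distance prediction distance (see
#'   [predict.block_plsda_model]).
#' @param seed fold-assignment seed; the same seed reproduces the same
#'   folds and the same selected model.
#' @param design_connectivity,scale passed to [fit_block_plsda].
#' @return object of class `"ddabpp_consensus"`: `model` (the refit
#'   [fit_block_plsda]), `cv_error`, `folds`, `keep`, `n_components`,
#'   `selected` (features with non-zero weight, per block), `cv_table`.
#' @export
tune_cv <- function(blocks, y, candidate_keeps = NULL, folds = 5,
                    ncomp_max = NULL, distance = "centroid", seed = 1L,
                    design_connectivity = 1, scale = TRUE) {
  y <- factor(y)
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  if (is.null(ncomp_max)) ncomp_max <- nlevels(y) - 1L
  if (folds > min(table(y)))
    stop("folds exceed the smallest class size; stratification impossible")
  if (is.null(candidate_keeps))
    candidate_keeps <- lapply(blocks, ncol)
  grid <- expand.grid(c(candidate_keeps, list(ncomp = seq_len(ncomp_max))),
                      KEEP.OUT.ATTRS = FALSE)

  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  grid$cv_error <- NA_real_
  for (g in seq_len(nrow(grid))) {
    keep <- as.list(grid[g, names(blocks), drop = FALSE])
    nc <- grid$ncomp[g]
    wrong <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_block_plsda(lapply(blocks, function(X) X[tr, , drop = FALSE]),
                             y[tr], design_connectivity, keep,
                             n_components = nc, scale = scale)
      pred <- predict(fit, lapply(blocks, function(X) X[!tr, , drop = FALSE]),
                      distance = distance)
      wrong <- wrong + sum(pred != y[!tr])
    }
    grid$cv_error[g] <- wrong / length(y)
  }
  total_feats <- rowSums(as.matrix(grid[, names(blocks), drop = FALSE]))
  best <- order(grid$cv_error, total_feats, grid$ncomp)[1L]
  keep <- as.list(grid[best, names(blocks), drop = FALSE])
  model <- fit_block_plsda(blocks, y, design_connectivity, keep,
                           n_components = grid$ncomp[best], scale = scale)
  selected <- lapply(model$W, function(w)
    rownames(w)[rowSums(abs(w)) > 0])
  structure(list(model = model, cv_error = grid$cv_error[best],
                 folds = folds, keep = keep,
                 n_components = grid$ncomp[best], selected = selected,
                 cv_table = grid, fold_id = fold_id, seed = seed),
            class = "ddabpp_consensus")
}

#' @export
print.ddabpp_consensus <- function(x, ...) {
  cat("consensus multi-block PLS-DA model\n")
  cat("  components:", x$n_components, " folds:", x$folds, "\n")
  cat("  CV error:", format(x$cv_error, digits = 3), "\n")
  cat("  classifiers:",
      paste(vapply(x$selected, length, integer(1)), collapse = " + "),
      "features across blocks\n")
  invisible(x)
}

#' @export
predict.ddabpp_consensus <- function(object, newblocks, ...) {
  predict(object$model, newblocks, ...)
}
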