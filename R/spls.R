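#' Sparse PLS configuration
#'
#' Defaults: 2 components with 300 genes retained per component, the first
#' component read against the AUC + area-2h pair and the second against
#' circularity; both blocks standardized. These defaults reflect a
#' 300-gene-per-signature analysis and are fully overridable.
#'
#' @param n_components number of latent components.
#' @param keep_x genes retained (nonzero loadings) per component; scalar or
#'   one value per component.
#' @param scale standardize columns of both blocks (mean 0, SD 1).
#' @param max_iter,tol inner-loop convergence controls.
#' @return An `spls_config` list.
#' @export
spls_config <- function(n_components = 2, keep_x = 300, scale = TRUE,
                        max_iter = 500, tol = 1e-9) {
  if (n_components < 1) stop("'n_components' must be >= 1")
  structure(list(n_components = as.integer(n_components),
                 keep_x = rep_len(as.integer(keep_x), n_components),
                 scale = isTRUE(scale), max_iter = max_iter, tol = tol),
            class = "spls_config")
}

# Keep exactly `keep` entries of z: order by |z| (descending), then by name
# (ascending) for ties; soft-threshold at the largest excluded magnitude.
# An exact tie at the boundary shrinks the threshold infinitesimally so the
# kept weights stay nonzero; selection is deterministic either way.
.soft_keep <- function(z, keep) {
  p <- length(z)
  if (keep >= p) return(z)
  ord <- order(abs(z), seq_len(p), decreasing = c(TRUE, FALSE), method = "radix")
  kept <- ord[seq_len(keep)]
  lambda <- abs(z[ord[keep + 1L]])
  if (abs(z[ord[keep]]) <= lambda) lambda <- lambda * (1 - 1e-9)
  w <- numeric(p)
  w[kept] <- sign(z[kept]) * (abs(z[kept]) - lambda)
  w
}

#' Fit a sparse PLS (regression mode) of parameters on expression
#'
#' Iterative NIPALS-style algorithm: per component, the X weight vector is
#' the cross-covariance direction `X'u` soft-thresholded so that exactly
#' `keep_x` genes survive (LASSO-type penalty calibrated per iteration);
#' alternation with the Y weights continues until the X weights change by
#' less than `tol`. After each component both blocks are deflated by the
#' regression of the block on the X scores (regression-mode deflation). With
#' `keep_x = p` the first component equals dense PLS: the weight vector is
#' the leading singular direction of the X-Y cross-covariance.
#'
#' @param X expression matrix, genes x lines (the CCLE export orientation);
#'   transposed internally to lines x genes.
#' @param Y lines x parameters matrix or data frame (e.g. area_2h, auc,
#'   circularity).
#' @param config an [spls_config()].
#' @return An `spls_fit`: `x_loadings` (genes x components, sparse),
#'   `y_loadings` (parameters x components), `scores_x`, `scores_y`
#'   (lines x components), `explained_cov` per component, plus dimnames and
#'   the configuration.
#' @export
fit_spls <- function(X, Y, config = spls_config()) {
  Y <- as.matrix(Y)
  X <- t(as.matrix(X))                       # lines x genes
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y disagree on the number of cell lines")
  if (n < 3) stop("need at least 3 cell lines")
  if (anyNA(X) || anyNA(Y))
    stop("missing values must be imputed before fitting")
  const <- which(apply(X, 2, sd) == 0)
  if (length(const)) {
    warning(sprintf("dropping %d constant gene column(s)", length(const)))
    X <- X[, -const, drop = FALSE]
  }
  if (any(apply(Y, 2, sd) == 0))
    stop("a parameter column is constant; cannot fit")
  gene_ids <- colnames(X); if (is.null(gene_ids))
    gene_ids <- sprintf("X%d", seq_len(ncol(X)))
  par_ids <- colnames(Y); if (is.null(par_ids))
    par_ids <- sprintf("Y%d", seq_len(ncol(Y)))
  if (config$scale) { X <- scale(X); Y <- scale(Y) }
  else { X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE) }
  p <- ncol(X); q <- ncol(Y)
  ncomp <- min(config$n_components, n - 1L, p)
  W <- matrix(0, p, ncomp); C <- matrix(0, q, ncomp)
  Tx <- matrix(0, n, ncomp); Uy <- matrix(0, n, ncomp)
  expl <- numeric(ncomp)
  Xd <- X; Yd <- Y
  for (h in seq_len(ncomp)) {
    keep <- min(config$keep_x[h], p)
    u <- Yd[, which.max(apply(Yd, 2, function(v) sum(v^2)))]
    w_old <- rep(0, p)
    converged <- FALSE
    for (it in seq_len(config$max_iter)) {
      z <- drop(crossprod(Xd, u))            # p x 1 cross-covariance
      w <- .soft_keep(z, keep)
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("component ", h, " collapsed to zero loadings ",
                        "(degenerate response?)")
      w <- w / nw
      t_sc <- drop(Xd %*% w)
      c_vec <- drop(crossprod(Yd, t_sc))
      nc <- sqrt(sum(c_vec^2))
      if (nc == 0) stop("degenerate response block in component ", h)
      c_vec <- c_vec / nc
      u <- drop(Yd %*% c_vec)
      if (sqrt(sum((w - w_old)^2)) < config$tol) { converged <- TRUE; break }
      w_old <- w
    }
    if (!converged)
      stop(sprintf(
        "sPLS component %d did not converge in %d iterations (last delta %.3g)",
        h, config$max_iter, sqrt(sum((w - w_old)^2))))
    # deterministic sign: largest-|loading| gene has positive weight
    flip <- sign(w[which.max(abs(w))])
    if (flip < 0) { w <- -w; t_sc <- -t_sc; c_vec <- -c_vec; u <- -u }
    W[, h] <- w; C[, h] <- c_vec; Tx[, h] <- t_sc; Uy[, h] <- u
    expl[h] <- abs(cov(t_sc, u))
    # regression-mode deflation of both blocks on the X scores
    tt <- sum(t_sc^2)
    Xd <- Xd - t_sc %*% t(crossprod(Xd, t_sc) / tt)
    Yd <- Yd - t_sc %*% t(crossprod(Yd, t_sc) / tt)
  }
  dimnames(W) <- list(gene_ids, paste0("comp", seq_len(ncomp)))
  dimnames(C) <- list(par_ids, colnames(W))
  structure(list(x_loadings = W, y_loadings = C, scores_x = Tx, scores_y = Uy,
                 explained_cov = expl, gene_ids = gene_ids, par_ids = par_ids,
                 config = config, n_components = ncomp),
            class = "spls_fit")
}

#' @export
print.spls_fit <- function(x, ...) {
  cat(sprintf("spls_fit: %d component(s), %d genes, parameters: %s\n",
              x$n_components, length(x$gene_ids),
              paste(x$par_ids, collapse = ", ")))
  invisible(x)
}

#' Split a component's nonzero loadings into signed gene lists
#'
#' The component sign is anchored so that the component's Y loadings sum
#' positively over the named parameter group: a fit returned with all signs
#' flipped yields the identical selection.
#'
#' @param fit an [fit_spls()] result.
#' @param component component index.
#' @param group character vector of parameter names the component is read
#'   against (e.g. `c("auc", "area_2h")` or `"circularity"`).
#' @param group_label label stored on the selection.
#' @return A `gene_selection`: `positive` and `negative` gene id vectors
#'   (disjoint; together all nonzero loadings), `loadings` (named, signed),
#'   `group_label`.
#' @export
select_genes <- function(fit, component = 1L, group = fit$par_ids,
                         group_label = paste(group, collapse = "+")) {
  stopifnot(inherits(fit, "spls_fit"))
  if (component < 1 || component > fit$n_components)
    stop("component not fitted")
  miss <- setdiff(group, fit$par_ids)
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  w <- fit$x_loadings[, component]
  cvec <- fit$y_loadings[, component]
  if (all(w == 0)) stop("component has all-zero loadings")
  anchor <- sum(cvec[group])
  if (anchor < 0) w <- -w
  structure(list(group_label = group_label,
                 positive = names(w)[w > 0], negative = names(w)[w < 0],
                 loadings = w[w != 0], component = component),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("gene_selection '%s': positive = %d; negative = %d\n",
              x$group_label, length(x$positive), length(x$negative)))
  invisible(x)
}

#' Turn a signed gene selection into an up/down query signature
#'
#' Positively associated genes become the up set, negatively associated
#' genes the down set (duplicates removed).
#'
#' @param selection a [select_genes()] result.
#' @return A `query_signature`: list with `up` and `down` gene id sets.
#' @export
build_query_signature <- function(selection) {
  up <- unique(selection$positive); down <- unique(selection$negative)
  if (length(up) == 0 || length(down) == 0)
    stop("both the positive and negative lists must be non-empty")
  if (length(intersect(up, down)))
    stop("up and down sets overlap")
  structure(list(up = up, down = down, group_label = selection$group_label),
            class = "query_signature")
}
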