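# L1-penalized linear support-vector classifier used for feature selection.
#
# Objective (squared hinge, the LinearSVC parameterization):
#
#     min_{w, b}  ||w||_1  +  C * sum_i max(0, 1 - y_i (x_i'w + b))^2
#
# solved by accelerated proximal gradient (FISTA) with soft-thresholding of
# w; the intercept b is unpenalized. The smooth part is differentiable
# (squared hinge), so the iteration is deterministic and solver-seed-free.
# Larger C weighs the data term more, keeping more nonzero weights; as
# C -> 0 the penalty dominates and the kept set empties.

l1_svc_fit <- function(X, y, C = 2, max_iter = 5000, tol = 1e-8) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  y <- as.numeric(y)
  stopifnot(all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2) {
    abort("feature selection needs both classes present")
  }
  n <- nrow(X); p <- ncol(X)
  Xb <- cbind(X, 1)            # intercept column, unpenalized
  # Lipschitz constant of the smooth part: 2C * sigma_max(Xb)^2,
  # via deterministic power iteration.
  v <- rep(1 / sqrt(p + 1), p + 1)
  for (i in 1:60) {
    v2 <- crossprod(Xb, Xb %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) break
    v <- as.numeric(v2) / nv
  }
  smax2 <- as.numeric(crossprod(Xb %*% v)) / max(sum(v^2), 1e-12)
  L <- max(2 * C * smax2, 1e-8)

  grad <- function(wb) {
    f <- as.numeric(Xb %*% wb)
    slack <- 1 - y * f
    active <- slack > 0
    g <- -2 * C * crossprod(Xb[active, , drop = FALSE],
                            (y * slack)[active])
    as.numeric(g)
  }
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

  wb <- rep(0, p + 1)
  z <- wb
  tk <- 1
  for (iter in seq_len(max_iter)) {
    g <- grad(z)
    wb_new <- z - g / L
    wb_new[seq_len(p)] <- soft(wb_new[seq_len(p)], 1 / L)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- wb_new + ((tk - 1) / tk_new) * (wb_new - wb)
    delta <- max(abs(wb_new - wb))
    wb <- wb_new
    tk <- tk_new
    if (delta < tol) break
  }
  list(w = stats::setNames(wb[seq_len(p)], colnames(X)), b = wb[p + 1])
}

#' L1-based feature selection
#'
#' Fits an L1-penalized linear support-vector classifier (squared hinge
#' loss, penalty weight traded off by `C`) and keeps the features with
#' nonzero weight. The sparsity of the L1 norm prunes the tens of
#' thousands of generated n-gram features down to the informative core;
#' the kept set is then handed to the final classifier, fit separately.
#' Selection must be run on training folds only and frozen before any
#' validation or test data is touched.
#'
#' @param X Numeric feature matrix (rows = instances, named columns).
#' @param y Labels: factor/character with `"related"` positive, or a
#'   numeric vector in -1/1.
#' @param C Trade-off constant (default 2): larger keeps more features.
#' @param weight_tol Weights with absolute value at or below this are
#'   treated as zero.
#' @return An object of class `lx_l1_selection`: `kept` (character vector
#'   of feature names), `weights` (named numeric over kept features),
#'   `bias`, `C`.
#' @export
select_features_l1 <- function(X, y, C = 2, weight_tol = 1e-6) {
  y <- as_pm1(y)
  fit <- l1_svc_fit(X, y, C = C)
  keep <- abs(fit$w) > weight_tol
  structure(list(kept = names(fit$w)[keep],
                 weights = fit$w[keep],
                 bias = fit$b, C = C),
            class = "lx_l1_selection")
}

#' @export
print.lx_l1_selection <- function(x, ...) {
  cat(sprintf("<lx_l1_selection> kept %d feature(s) at C=%g\n",
              length(x$kept), x$C))
  invisible(x)
}

as_pm1 <- function(y) {
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(-1, 1)))
    return(y)
  }
  y <- as.character(y)
  stopifnot(all(y %in% c("related", "unrelated")))
  ifelse(y == "related", 1, -1)
}
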