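# Multivariable MR: several exposures instrumented jointly.

#' Construct a multivariable-MR instrument set
#'
#' @param b_x,s_x Numeric matrices instruments x exposures of exposure
#'   betas and SEs.
#' @param b_y,s_y Outcome beta and SE vectors (one per instrument).
#' @param exposure_labels Character vector naming the exposures; defaults
#'   to `b_x` column names.
#' @param variant_ids Optional instrument ids.
#' @return An object of class `mvmr_set`.
#' @export
mvmr_set <- function(b_x, s_x, b_y, s_y,
                     exposure_labels = colnames(b_x),
                     variant_ids = NULL) {
  b_x <- as.matrix(b_x); s_x <- as.matrix(s_x)
  J <- nrow(b_x); K <- ncol(b_x)
  stopifnot(nrow(s_x) == J, ncol(s_x) == K, length(b_y) == J,
            length(s_y) == J)
  if (J < K + 1)
    stop2("mvmr_set: need at least exposures + 1 instruments")
  if (any(s_x <= 0) || any(s_y <= 0))
    stop2("mvmr_set: standard errors must be positive")
  if (is.null(exposure_labels))
    exposure_labels <- paste0("exposure", seq_len(K))
  colnames(b_x) <- colnames(s_x) <- exposure_labels
  structure(list(b_x = b_x, s_x = s_x, b_y = as.numeric(b_y),
                 s_y = as.numeric(s_y), exposure_labels = exposure_labels,
                 variant_ids = variant_ids %||%
                   paste0("iv", seq_len(J))),
            class = "mvmr_set")
}

# weighted least squares of b_y on columns of X (optionally + intercept)
mvmr_wls <- function(X, y, w, df_resid, labels, method) {
  XtWX <- crossprod(X, w * X)
  qrX <- qr(XtWX)
  if (qrX$rank < ncol(X)) {
    bad <- labels[abs(diag(qr.R(qr(sqrt(w) * X)))) < 1e-10]
    stop2("mvmr: singular design; collinear exposures: ",
          paste(if (length(bad)) bad else labels, collapse = ", "))
  }
  co <- drop(solve(XtWX, crossprod(X, w * y)))
  Q <- sum(w * (y - drop(X %*% co))^2)
  scale <- max(1, sqrt(Q / max(df_resid, 1)))
  ses <- sqrt(diag(solve(XtWX))) * scale
  list(coef = co, se = ses, Q = Q, df = df_resid)
}

#' Multivariable MR fit
#'
#' Jointly estimates the direct causal effect of each exposure:
#' * `ivw` — weighted multiple regression of outcome betas on the
#'   exposure-beta columns through the origin, weights `1 / s_y^2`,
#'   multiplicative overdispersion scale floored at 1;
#' * `egger` — adds an intercept after orienting every instrument so its
#'   beta on the first exposure is non-negative;
#' * `lasso` — augments the IVW model with one L1-penalised intercept
#'   `alpha_j` per instrument (the exposure effects stay unpenalised);
#'   lambda is the largest grid value whose post-selection IVW
#'   heterogeneity Q (on instruments with `alpha_j = 0`) is at or below
#'   the chi-squared 95th percentile of its degrees of freedom, followed
#'   by a post-LASSO IVW on those instruments.
#'
#' @param mv An `mvmr_set`.
#' @param method `"ivw"`, `"egger"` or `"lasso"`.
#' @param lambda_grid Optional decreasing lambda sequence for the lasso.
#' @return Named list of `mr_estimate`, one per exposure. For `lasso`,
#'   attribute `lasso` records lambda and the retained instruments.
#' @export
mvmr_fit <- function(mv, method = c("ivw", "egger", "lasso"),
                     lambda_grid = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(mv, "mvmr_set"))
  J <- nrow(mv$b_x); K <- ncol(mv$b_x)
  w <- 1 / mv$s_y^2
  labels <- mv$exposure_labels

  if (method == "ivw") {
    fit <- mvmr_wls(mv$b_x, mv$b_y, w, J - K, labels, method)
    co <- unname(fit$coef); ses <- unname(fit$se)
    out <- lapply(seq_len(K), function(k)
      mr_estimate(paste0("mvmr_ivw:", labels[k]), J, co[k], ses[k]))
    names(out) <- labels
    attr(out, "heterogeneity") <- heterogeneity_stats(fit$Q, fit$df)
    return(out)
  }

  if (method == "egger") {
    if (J < K + 2) stop2("mvmr_fit: egger needs at least exposures + 2 instruments")
    flip <- sign(mv$b_x[, 1]); flip[flip == 0] <- 1
    X <- cbind(intercept = 1, mv$b_x * flip)
    y <- mv$b_y * flip
    fit <- mvmr_wls(X, y, w, J - K - 1, c("intercept", labels), method)
    co <- unname(fit$coef); ses <- unname(fit$se)
    tp <- function(e, s) 2 * pt(-abs(e / s), df = J - K - 1)
    out <- lapply(seq_len(K), function(k)
      mr_estimate(paste0("mvmr_egger:", labels[k]), J, co[k + 1],
                  ses[k + 1], pval = tp(co[k + 1], ses[k + 1]),
                  intercept = co[1], intercept_se = ses[1],
                  intercept_pval = tp(co[1], ses[1])))
    names(out) <- labels
    attr(out, "heterogeneity") <- heterogeneity_stats(fit$Q, fit$df)
    return(out)
  }

  # lasso: per-instrument intercepts, exposures unpenalised
  sw <- sqrt(w)
  Xstar <- cbind(mv$b_x * sw, diag(sw))
  ystar <- mv$b_y * sw
  pf <- c(rep(0, K), rep(1, J))
  gfit <- glmnet::glmnet(Xstar, ystar, intercept = FALSE,
                         standardize = FALSE, penalty.factor = pf,
                         lambda = lambda_grid)
  lam <- gfit$lambda
  chosen <- NULL
  for (i in seq_along(lam)) {
    alpha <- as.numeric(gfit$beta[K + seq_len(J), i])
    valid <- which(alpha == 0)
    dfq <- length(valid) - K
    if (dfq < 1) next
    sub_fit <- try(mvmr_wls(mv$b_x[valid, , drop = FALSE], mv$b_y[valid],
                            w[valid], dfq, labels, "ivw"), silent = TRUE)
    if (inherits(sub_fit, "try-error")) next
    if (sub_fit$Q <= qchisq(0.95, dfq)) { chosen <- list(i = i, valid = valid, fit = sub_fit); break }
  }
  if (is.null(chosen)) {
    # no lambda achieves homogeneity: keep the sparsest feasible model
    for (i in seq_along(lam)) {
      alpha <- as.numeric(gfit$beta[K + seq_len(J), i])
      valid <- which(alpha == 0)
      if (length(valid) - K >= 1) {
        sub_fit <- try(mvmr_wls(mv$b_x[valid, , drop = FALSE],
                                mv$b_y[valid], w[valid],
                                length(valid) - K, labels, "ivw"),
                       silent = TRUE)
        if (!inherits(sub_fit, "try-error")) chosen <- list(i = i, valid = valid, fit = sub_fit)
      }
    }
    if (is.null(chosen)) stop2("mvmr_fit: lasso found no feasible instrument subset")
  }
  fit <- chosen$fit
  out <- lapply(seq_len(K), function(k)
    mr_estimate(paste0("mvmr_lasso:", labels[k]), length(chosen$valid),
                unname(fit$coef[k]), unname(fit$se[k])))
  names(out) <- labels
  attr(out, "lasso") <- list(lambda = lam[chosen$i],
                             valid_instruments = mv$variant_ids[chosen$valid])
  attr(out, "heterogeneity") <- heterogeneity_stats(fit$Q, fit$df)
  out
}
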