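# mr_core: the two-sample MR estimator battery. All estimators consume a
# harmonised_set; case-control outcome betas are treated as log-ORs
# throughout and reported as ORs by exponentiation downstream.

#' Construct an MR estimate record
#'
#' @param method Estimator label.
#' @param n_snps Number of instruments used.
#' @param beta,se Causal estimate and standard error (log-OR scale for
#'   case-control outcomes).
#' @param ci_low,ci_high Confidence bounds (default normal 95%).
#' @param pval P-value.
#' @param intercept,intercept_se,intercept_pval Optional Egger intercept.
#' @param notes Free-text notes.
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, n_snps, beta, se,
                        ci_low = beta - qnorm(0.975) * se,
                        ci_high = beta + qnorm(0.975) * se,
                        pval = 2 * pnorm(-abs(beta / se)),
                        intercept = NULL, intercept_se = NULL,
                        intercept_pval = NULL, notes = "") {
  stopifnot(se > 0, ci_low <= beta, beta <= ci_high)
  structure(list(method = method, n_snps = n_snps, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_pval = intercept_pval, notes = notes),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta %.4f (SE %.4f, 95%% CI %.4f to %.4f), p = %.3g, %d SNPs\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval,
              x$n_snps))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept %.5f (SE %.5f), p = %.3g\n", x$intercept,
                x$intercept_se, x$intercept_pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             pval = x$pval,
             or = exp(x$beta), or_low = exp(x$ci_low),
             or_high = exp(x$ci_high),
             intercept = x$intercept %||% NA_real_,
             intercept_pval = x$intercept_pval %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' Construct heterogeneity statistics
#'
#' Cochran's Q with its degrees of freedom and p-value, the I-squared
#' inconsistency fraction, and the DerSimonian-Laird between-instrument
#' variance tau-squared computed on Wald-ratio scale.
#'
#' @param Q,df Cochran statistic and degrees of freedom.
#' @param tau2 Between-instrument variance (>= 0).
#' @return An object of class `heterogeneity_stats`.
#' @export
heterogeneity_stats <- function(Q, df, tau2 = 0) {
  stopifnot(Q >= -1e-12, tau2 >= 0)
  Q <- max(Q, 0)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) else 0
  structure(list(Q = Q, df = df, p_Q = pchisq(Q, df, lower.tail = FALSE),
                 I2 = I2, tau2 = tau2),
            class = "heterogeneity_stats")
}

# DerSimonian-Laird tau^2 on per-instrument estimates y with variances v
dl_tau2 <- function(y, v) {
  w <- 1 / v
  yb <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yb)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (length(y) - 1)) / denom)
}

wald_ratios <- function(hs) {
  if (any(hs$b_x == 0)) stop2("wald ratios undefined: some b_x are zero")
  list(ratio = hs$b_y / hs$b_x, se = abs(hs$s_y / hs$b_x))
}

#' Per-variant Wald ratio estimate
#'
#' `beta = b_y / b_x` with first-order delta-method
#' `se = |s_y / b_x|`; setting `second_order = TRUE` adds the exposure
#' uncertainty term `b_y^2 s_x^2 / b_x^4` under the radical.
#'
#' @param b_x,s_x Exposure beta and SE (`b_x` must be nonzero).
#' @param b_y,s_y Outcome beta and SE.
#' @param second_order Use the second-order delta-method SE.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(b_x, s_x, b_y, s_y, second_order = FALSE) {
  if (b_x == 0) stop2("wald_ratio: b_x must be nonzero")
  beta <- b_y / b_x
  se <- if (second_order)
    sqrt(s_y^2 / b_x^2 + b_y^2 * s_x^2 / b_x^4)
  else abs(s_y / b_x)
  mr_estimate("wald_ratio", 1L, beta, se)
}

#' Inverse-variance-weighted MR with multiplicative random effects
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1 / s_y^2`. The standard error is the fixed-effect
#' SE inflated by `max(1, sqrt(Q / (J - 1)))` (multiplicative
#' random-effects overdispersion, floored at 1 so the random-effects SE is
#' never smaller than the fixed-effect one). Heterogeneity is summarised
#' by Cochran's Q, I-squared and a DerSimonian-Laird tau-squared on the
#' Wald ratios.
#'
#' @param hs A `harmonised_set` with at least 2 instruments.
#' @return List with elements `estimate` (`mr_estimate`) and
#'   `heterogeneity` (`heterogeneity_stats`).
#' @export
ivw_mre <- function(hs) {
  J <- length(hs$b_x)
  if (J < 2)
    stop2("ivw_mre: needs >= 2 instruments; use wald_ratio for one")
  w <- 1 / hs$s_y^2
  sxx <- sum(w * hs$b_x^2)
  beta <- sum(w * hs$b_x * hs$b_y) / sxx
  Q <- sum(w * (hs$b_y - beta * hs$b_x)^2)
  scale <- max(1, sqrt(Q / (J - 1)))
  se <- sqrt(1 / sxx) * scale
  wr <- wald_ratios(hs)
  het <- heterogeneity_stats(Q, J - 1L, dl_tau2(wr$ratio, wr$se^2))
  list(estimate = mr_estimate("ivw_mre", J, beta, se,
                              notes = "multiplicative random effects; tau2 by DL on Wald ratios"),
       heterogeneity = het)
}

#' MR-Egger regression
#'
#' Instruments are first oriented so every exposure beta is non-negative,
#' then outcome betas are regressed on exposure betas with an intercept,
#' weights `1 / s_y^2`. The intercept estimates the mean directional
#' pleiotropy (its test is the directional-pleiotropy test); the slope is
#' the pleiotropy-corrected causal effect under the InSIDE assumption.
#' Standard errors use a multiplicative overdispersion scale floored at 1
#' and t(J - 2) reference distributions.
#'
#' @param hs A `harmonised_set` with at least 3 instruments.
#' @return List with `estimate` (slope, with intercept fields filled) and
#'   `heterogeneity` (Rucker's Q about the Egger fit).
#' @export
mr_egger <- function(hs) {
  J <- length(hs$b_x)
  if (J < 3) stop2("mr_egger: needs >= 3 instruments")
  flip <- sign(hs$b_x)
  flip[flip == 0] <- 1
  bx <- hs$b_x * flip
  by <- hs$b_y * flip
  w <- 1 / hs$s_y^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, w * X)
  if (abs(det(XtWX)) < 1e-300 || qr(XtWX)$rank < 2)
    stop2("mr_egger: design is singular (no spread in instrument strength)")
  co <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% co
  Q <- sum(w * resid^2)
  scale <- max(1, sqrt(Q / (J - 2)))
  se_unit <- sqrt(diag(solve(XtWX)))
  se <- se_unit * scale
  tq <- function(est, s) 2 * pt(-abs(est / s), df = J - 2)
  wr <- wald_ratios(hs)
  het <- heterogeneity_stats(Q, J - 2L, dl_tau2(wr$ratio, wr$se^2))
  list(estimate = mr_estimate("mr_egger", J, co[2], se[2],
                              pval = tq(co[2], se[2]),
                              intercept = co[1], intercept_se = se[1],
                              intercept_pval = tq(co[1], se[1]),
                              notes = "instruments oriented to b_x >= 0; t reference"),
       heterogeneity = het)
}

# cumulative-weight interpolation estimator of the weighted median
weighted_median_est <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  below <- max(which(cw < 0.5))
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

#' Weighted-median MR estimate
#'
#' Inverse-variance-weighted median of the per-instrument Wald ratios via
#' the cumulative-weight interpolation estimator; consistent when
#' instruments contributing at least half the weight are valid. The SE is
#' a seeded parametric bootstrap: exposure and outcome betas are
#' resampled from their standard errors and the estimator recomputed.
#'
#' @param hs A `harmonised_set` with at least 3 instruments.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap (mandatory; no hidden state).
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(hs, n_boot = 1000, seed = 1) {
  J <- length(hs$b_x)
  if (J < 3) stop2("weighted_median: needs >= 3 instruments")
  wr <- wald_ratios(hs)
  w <- 1 / wr$se^2
  est <- weighted_median_est(wr$ratio, w)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(J, hs$b_x, hs$s_x)
      by <- rnorm(J, hs$b_y, hs$s_y)
      bx[bx == 0] <- 1e-12
      rb <- by / bx
      wb <- bx^2 / hs$s_y^2
      weighted_median_est(rb, wb)
    }, 0)
  })
  se <- sd(boot)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  mr_estimate("weighted_median", J, est, se,
              notes = sprintf("parametric bootstrap SE (%d resamples, seed %d)",
                              n_boot, seed))
}

# evaluate an expression under a local, restored RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Contamination-mixture MR estimate
#'
#' Profile likelihood over a grid of candidate causal effects: at each
#' grid value every instrument's Wald ratio is classified valid
#' (`N(theta, se_j^2)`) or invalid (`N(0, se_j^2 + psi^2)`) by whichever
#' has the larger likelihood, and the profile log-likelihood is the sum of
#' the winning terms. The estimate is the grid argmax; the 95% confidence
#' set is `{theta : 2 (llmax - ll(theta)) < 3.84}` and may be disjoint, in
#' which case the envelope is reported with a flag.
#'
#' @param hs A `harmonised_set` with at least 3 instruments.
#' @param psi Invalid-component dispersion; default 1.5 x SD of the Wald
#'   ratios (a common heuristic). Note that because the ratio SD
#'   includes pure sampling noise, weak instruments near the invalid
#'   component's centre can be misclassified, giving the estimator a
#'   small away-from-zero bias when instruments are genuinely
#'   homogeneous; supply a smaller psi when instrument strength is low.
#' @param grid_size Number of grid points (default 512).
#' @return An `mr_estimate`; attribute `conmix` carries the grid, profile
#'   log-likelihood, the valid-instrument classification at the optimum
#'   and the disjoint-CI flag.
#' @export
contamination_mixture <- function(hs, psi = NULL, grid_size = 512) {
  J <- length(hs$b_x)
  if (J < 3) stop2("contamination_mixture: needs >= 3 instruments")
  wr <- wald_ratios(hs)
  if (is.null(psi)) psi <- 1.5 * sd(wr$ratio)
  if (!is.finite(psi) || psi <= 0) psi <- 1
  lo <- min(wr$ratio - wr$se)
  hi <- max(wr$ratio + wr$se)
  grid <- seq(lo, hi, length.out = grid_size)
  # valid: N(theta, se^2); invalid: N(0, se^2 + psi^2)
  ll_inval <- dnorm(wr$ratio, 0, sqrt(wr$se^2 + psi^2), log = TRUE)
  llmat <- vapply(grid, function(th) {
    lv <- dnorm(wr$ratio, th, wr$se, log = TRUE)
    pmax(lv, ll_inval)
  }, numeric(J))
  prof <- colSums(llmat)
  if (max(prof) - min(prof) < 1e-12)
    stop2("contamination_mixture: flat profile likelihood; psi too large or instruments uninformative")
  imax <- which.max(prof)
  est <- grid[imax]
  # quadratic interpolation of the profile peak removes the grid-step
  # discretisation bias
  if (imax > 1 && imax < length(grid)) {
    pm <- prof[imax - 1]; p0 <- prof[imax]; pp <- prof[imax + 1]
    denom <- pm - 2 * p0 + pp
    if (denom < -1e-12) {
      step <- grid[2] - grid[1]
      est <- grid[imax] + 0.5 * step * (pm - pp) / denom
    }
  }
  inset <- 2 * (max(prof) - prof) < qchisq(0.95, 1)
  ci_low <- min(grid[inset], est); ci_high <- max(grid[inset], est)
  runs <- rle(inset)
  disjoint <- sum(runs$values) > 1
  se <- max((ci_high - ci_low) / (2 * qnorm(0.975)), .Machine$double.eps)
  valid_at_opt <- dnorm(wr$ratio, est, wr$se, log = TRUE) >= ll_inval
  out <- mr_estimate("contamination_mixture", J, est, se,
                     ci_low = ci_low, ci_high = ci_high,
                     notes = if (disjoint)
                       "confidence set disjoint; envelope reported" else "")
  attr(out, "conmix") <- list(grid = grid, profile = prof, psi = psi,
                              valid = valid_at_opt, disjoint_ci = disjoint)
  out
}

#' Leave-one-out MR sensitivity analysis
#'
#' Re-estimates the causal effect (IVW multiplicative random effects by
#' default) dropping each instrument in turn and flags instruments whose
#' removal changes the estimate by more than `flag_thresh` (default 10%,
#' the conventional outlier rule).
#'
#' @param hs A `harmonised_set` with at least 3 instruments.
#' @param estimator Function of a `harmonised_set` returning a list with
#'   an `estimate` element (default [ivw_mre()]).
#' @param flag_thresh Relative-change threshold (default 0.10).
#' @return data.frame with one row per instrument: `variant_id`, `beta`
#'   (estimate without it), `rel_change`, `abs_change`, `flagged`.
#' @export
leave_one_out <- function(hs, estimator = ivw_mre, flag_thresh = 0.10) {
  J <- length(hs$b_x)
  if (J < 3) stop2("leave_one_out: needs >= 3 instruments")
  full <- estimator(hs)$estimate$beta
  drop_one <- function(j) {
    harmonised_set(hs$variant_ids[-j], hs$b_x[-j], hs$s_x[-j],
                   hs$b_y[-j], hs$s_y[-j], hs$exposure_label,
                   hs$outcome_label, outcome_type = hs$outcome_type)
  }
  betas <- vapply(seq_len(J), function(j) estimator(drop_one(j))$estimate$beta, 0)
  abs_change <- abs(betas - full)
  if (full == 0) {
    rel <- rep(NA_real_, J)
    flagged <- rep(TRUE, J) & abs_change > 0
    note <- "full estimate is 0; relative change undefined, absolute reported"
  } else {
    rel <- abs_change / abs(full)
    flagged <- rel > flag_thresh
    note <- ""
  }
  out <- data.frame(variant_id = hs$variant_ids, beta_without = betas,
                    beta_full = full, abs_change = abs_change,
                    rel_change = rel, flagged = flagged,
                    stringsAsFactors = FALSE)
  attr(out, "note") <- note
  out
}
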