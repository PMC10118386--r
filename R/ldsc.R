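# ldsc: cross-trait LD-score regression. Heritability from the
# regression of z^2 on N*l_j/M, genetic covariance from the regression of
# z1*z2 on sqrt(N1*N2)*l_j/M; uncertainty by delete-a-block jackknife
# over contiguous blocks. Observed scale only; HLA-region variants are
# assumed excluded upstream.

#' Construct an LD-score table
#'
#' @param variant_ids Character vector.
#' @param ld_scores Per-variant LD scores, all >= 1 (self-correlation)
#'   and finite.
#' @param chrom,pos Optional coordinates used to order variants into
#'   contiguous jackknife blocks.
#' @return An object of class `ld_score_table`.
#' @export
ld_score_table <- function(variant_ids, ld_scores, chrom = NULL,
                           pos = NULL) {
  stopifnot(length(variant_ids) == length(ld_scores))
  if (any(!is.finite(ld_scores)) || any(ld_scores < 1))
    stop2("ld_score_table: ld_scores must be finite and >= 1")
  ord <- if (!is.null(chrom) && !is.null(pos)) order(chrom, pos)
         else seq_along(variant_ids)
  structure(list(variant_ids = as.character(variant_ids)[ord],
                 ld_scores = as.numeric(ld_scores)[ord],
                 chrom = chrom[ord], pos = pos[ord]),
            class = "ld_score_table")
}

# leave-block-out WLS with intercept: returns full coefficients and the
# per-block deletions, from accumulated 2x2 crossproducts
block_wls <- function(x, y, w, blocks, n_blocks) {
  if (sd(x) < 1e-12) {
    # degenerate design (constant regressor): slope 0, intercept = mean
    del <- vapply(seq_len(n_blocks), function(b)
      weighted.mean(y[blocks != b], w[blocks != b]), 0)
    return(list(coef = c(weighted.mean(y, w), 0),
                deletions = cbind(del, 0)))
  }
  X <- cbind(1, x)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  full <- solve(XtWX, XtWy)
  del <- matrix(0, n_blocks, 2)
  for (b in seq_len(n_blocks)) {
    i <- blocks == b
    Xb <- X[i, , drop = FALSE]
    co <- solve(XtWX - crossprod(Xb, w[i] * Xb),
                XtWy - crossprod(Xb, w[i] * y[i]))
    del[b, ] <- co
  }
  list(coef = drop(full), deletions = del) # columns: intercept, slope
}

assign_blocks <- function(m_obs, n_blocks) {
  if (m_obs < 2 * n_blocks)
    stop2("ldsc: need at least 2 variants per jackknife block (",
          m_obs, " variants, ", n_blocks, " blocks)")
  sort(rep_len(seq_len(n_blocks), m_obs))
}

jackknife_se <- function(theta_del) {
  g <- length(theta_del)
  sqrt((g - 1) / g * sum((theta_del - mean(theta_del))^2))
}

#' SNP heritability by LD-score regression
#'
#' Weighted regression of chi-squared statistics `z^2` on `N * l_j / M`
#' with a free intercept (absorbing confounding inflation). Weights are
#' the reciprocal of `2 * (intercept0 + h2_0 * N * l_j / M)^2 * l_j`,
#' updated once from an initial unweighted pass. Standard errors by
#' delete-a-block jackknife over `n_blocks` contiguous blocks.
#'
#' @param z Per-variant z-scores, aligned to `ld`.
#' @param n GWAS sample size (scalar or per-variant).
#' @param ld An `ld_score_table`.
#' @param m Reference SNP count M (default: number of variants in `ld`).
#' @param n_blocks Jackknife blocks (default 200).
#' @return List with `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `n_blocks`, `m`.
#' @export
ldsc_h2 <- function(z, n, ld, m = NULL, n_blocks = 200) {
  stopifnot(inherits(ld, "ld_score_table"))
  l <- ld$ld_scores
  if (length(z) != length(l))
    stop2("ldsc_h2: z not aligned to LD-score table")
  m <- m %||% length(l)
  x <- n * l / m
  y <- z^2
  blocks <- assign_blocks(length(l), n_blocks)
  # pass 1: unweighted
  c0 <- coef(lm(y ~ x))
  if (anyNA(c0)) c0 <- c(mean(y), 0)
  # predicted chi-square can never fall below its null expectation of 1
  pred <- pmax(c0[1] + c0[2] * x, 1)
  w <- 1 / (2 * pred^2 * pmax(l, 1))
  fit <- block_wls(x, y, w, blocks, n_blocks)
  list(h2 = unname(fit$coef[2]), h2_se = jackknife_se(fit$deletions[, 2]),
       intercept = unname(fit$coef[1]),
       intercept_se = jackknife_se(fit$deletions[, 1]),
       n_blocks = n_blocks, m = m)
}

#' Genetic correlation by cross-trait LD-score regression
#'
#' Estimates each trait's heritability via [ldsc_h2()], then regresses
#' the z-score products `z1 * z2` on `sqrt(N1 * N2) * l_j / M`. The slope
#' estimates the genetic covariance `rho_g`; the free intercept absorbs
#' sample overlap. `rg = rho_g / sqrt(h2_1 * h2_2)`, with its SE and
#' p-value from a delete-a-block jackknife applied to the full ratio
#' (all three regressions recomputed per deleted block). The reported rg
#' is clamped to \[-1.25, 1.25\] with an out-of-bounds flag.
#'
#' @param z1,z2 Per-variant z-scores for the two traits, aligned to `ld`.
#' @param n1,n2 Sample sizes.
#' @param n_overlap Number of overlapping samples (informational; overlap
#'   is absorbed by the cross-trait intercept).
#' @param ld An `ld_score_table`.
#' @param m Reference SNP count (default: variants in `ld`).
#' @param n_blocks Jackknife blocks (default 200).
#' @return An object of class `ldsc_result`: heritabilities, intercepts,
#'   `rg`, `rg_se`, `rg_p`, `rho_g`, `cross_intercept`, flags.
#' @export
ldsc_rg <- function(z1, z2, n1, n2, n_overlap = 0, ld, m = NULL,
                    n_blocks = 200) {
  stopifnot(inherits(ld, "ld_score_table"))
  l <- ld$ld_scores
  if (length(z1) != length(l) || length(z2) != length(l))
    stop2("ldsc_rg: z-scores not aligned to LD-score table")
  m <- m %||% length(l)
  blocks <- assign_blocks(length(l), n_blocks)

  h1 <- ldsc_h2(z1, n1, ld, m, n_blocks)
  h2 <- ldsc_h2(z2, n2, ld, m, n_blocks)

  x12 <- sqrt(n1 * n2) * l / m
  y12 <- z1 * z2
  # one-step weights from unweighted passes of all three regressions
  x1 <- n1 * l / m; x2 <- n2 * l / m
  c1 <- coef(lm(z1^2 ~ x1)); c2 <- coef(lm(z2^2 ~ x2))
  c12 <- coef(lm(y12 ~ x12))
  if (anyNA(c1)) c1 <- c(mean(z1^2), 0)
  if (anyNA(c2)) c2 <- c(mean(z2^2), 0)
  if (anyNA(c12)) c12 <- c(mean(y12), 0)
  v1 <- pmax(c1[1] + c1[2] * x1, 1)
  v2 <- pmax(c2[1] + c2[2] * x2, 1)
  v12 <- c12[1] + c12[2] * x12
  w <- 1 / (pmax(l, 1) * (v1 * v2 + v12^2))
  fit12 <- block_wls(x12, y12, w, blocks, n_blocks)
  rho_g <- unname(fit12$coef[2])

  flags <- character()
  if (h1$h2 <= 0 || h2$h2 <= 0) {
    rg <- NA_real_; rg_se <- NA_real_; rg_p <- NA_real_
    flags <- c(flags, "h2_nonpositive")
  } else {
    rg <- rho_g / sqrt(h1$h2 * h2$h2)
    # jackknife the ratio: h2_1, h2_2 and rho_g recomputed per block
    w1 <- 1 / (2 * v1^2 * pmax(l, 1))
    w2 <- 1 / (2 * v2^2 * pmax(l, 1))
    d1 <- block_wls(x1, z1^2, w1, blocks, n_blocks)$deletions[, 2]
    d2 <- block_wls(x2, z2^2, w2, blocks, n_blocks)$deletions[, 2]
    d12 <- fit12$deletions[, 2]
    ok <- d1 > 0 & d2 > 0
    rg_del <- ifelse(ok, d12 / sqrt(pmax(d1, 1e-12) * pmax(d2, 1e-12)),
                     rg)
    rg_se <- jackknife_se(rg_del)
    if (rg_se <= 0) rg_se <- .Machine$double.eps
    rg_p <- 2 * pnorm(-abs(rg / rg_se))
    if (abs(rg) > 1.25) {
      flags <- c(flags, "rg_out_of_bounds")
      rg <- max(min(rg, 1.25), -1.25)
    }
  }
  structure(list(h2_1 = h1$h2, h2_1_se = h1$h2_se,
                 h2_2 = h2$h2, h2_2_se = h2$h2_se,
                 intercept_1 = h1$intercept,
                 intercept_1_se = h1$intercept_se,
                 intercept_2 = h2$intercept,
                 intercept_2_se = h2$intercept_se,
                 cross_intercept = unname(fit12$coef[1]),
                 rho_g = rho_g, rg = rg, rg_se = rg_se, rg_p = rg_p,
                 n_blocks = n_blocks, m = m, n_overlap = n_overlap,
                 flags = flags),
            class = "ldsc_result")
}

#' @export
print.ldsc_result <- function(x, ...) {
  cat(sprintf("<ldsc_result> h2_1 %.3f (%.3f), h2_2 %.3f (%.3f)\n",
              x$h2_1, x$h2_1_se, x$h2_2, x$h2_2_se))
  cat(sprintf("  rg %.3f (SE %.3f, p %.3g); cross intercept %.3f\n",
              x$rg, x$rg_se, x$rg_p, x$cross_intercept))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
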