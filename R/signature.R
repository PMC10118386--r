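# signature: the tumour-transcriptome arm. Count normalisation (binned-
# median GC/length correction within sample, upper-quartile depth scaling
# between samples), expression PCA with outlier exclusion, PRS-component
# association, orthogonal Procrustes alignment of train/validation
# embeddings, LASSO signature fitting with bootstrap lambda selection,
# cross-cohort application, and feature association models.

#' Construct an expression count matrix
#'
#' @param counts Non-negative integer matrix genes x samples with row and
#'   column names.
#' @param gene_meta Optional data.frame with `gene_id`, `length` (bp) and
#'   `gc` (fraction); required for GC/length correction.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("expression_matrix: counts need gene and sample names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop2("expression_matrix: duplicate gene or sample ids")
  if (any(counts < 0)) stop2("expression_matrix: counts must be >= 0")
  if (!is.null(gene_meta)) {
    stopifnot(all(c("gene_id", "length", "gc") %in% names(gene_meta)))
    gene_meta <- gene_meta[match(rownames(counts), gene_meta$gene_id), ]
    if (anyNA(gene_meta$gene_id))
      stop2("expression_matrix: gene_meta does not cover all genes")
  }
  structure(list(counts = counts, gene_ids = rownames(counts),
                 sample_ids = colnames(counts), gene_meta = gene_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

# per-sample binned-median correction of log2 counts against a covariate
# (GC or log length); returns the multiplicative offset per gene.
# Computed on expressed genes only so the correction commutes exactly
# with depth rescaling.
binned_offset <- function(logc, covar, n_bins = 10) {
  off <- numeric(length(logc))
  expressed <- is.finite(logc)
  if (sum(expressed) < 2 * n_bins) return(off)
  br <- unique(quantile(covar[expressed], probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) return(off) # covariate essentially constant
  bins <- cut(covar, br, include.lowest = TRUE)
  gmed <- median(logc[expressed])
  bmed <- tapply(logc[expressed], bins[expressed], median)
  delta <- bmed[as.character(bins)] - gmed
  delta[is.na(delta)] <- 0
  off[expressed] <- delta[expressed]
  off
}

#' Normalise RNA-seq read counts
#'
#' Three stages: (1) drop genes with fewer than `min_count` reads in
#' fewer than `min_frac` of samples; (2) within-sample correction of GC
#' and gene-length trends by binned-median regression on log counts
#' (expressed genes only, so the step is exactly invariant to sequencing
#' depth); (3) between-sample upper-quartile scaling of expressed-gene
#' counts to a common depth. Output is `log2(normalised + 1)`.
#'
#' @param em An `expression_matrix`.
#' @param min_count,min_frac Low-count filter: keep genes with
#'   `counts >= min_count` in at least `min_frac` of samples (defaults 5
#'   and 0.2).
#' @param gc_correct Apply GC/length correction (requires `gene_meta`;
#'   default `TRUE` when metadata are present).
#' @param n_bins Bins for the binned-median fit (default 10).
#' @param target_uq Common upper-quartile depth after scaling (default
#'   1000).
#' @return Numeric matrix genes x samples of log2 normalised expression;
#'   attribute `dropped_genes` lists filtered genes.
#' @export
normalise_counts <- function(em, min_count = 5, min_frac = 0.2,
                             gc_correct = !is.null(em$gene_meta),
                             n_bins = 10, target_uq = 1000) {
  stopifnot(inherits(em, "expression_matrix"))
  counts <- em$counts
  keep <- rowMeans(counts >= min_count) >= min_frac
  if (!any(keep)) stop2("normalise_counts: all genes filtered out")
  dropped <- rownames(counts)[!keep]
  counts <- counts[keep, , drop = FALSE]
  meta <- if (!is.null(em$gene_meta)) em$gene_meta[keep, ] else NULL
  if (gc_correct && is.null(meta))
    stop2("normalise_counts: GC correction requested but gene_meta absent")

  corrected <- counts
  if (gc_correct) {
    gc <- meta$gc
    loglen <- log(meta$length)
    for (s in seq_len(ncol(counts))) {
      lc <- ifelse(counts[, s] > 0, log2(counts[, s]), NA_real_)
      off <- binned_offset(lc, gc, n_bins) +
        binned_offset(lc, loglen, n_bins)
      corrected[, s] <- counts[, s] / 2^off
    }
  }
  # upper quartile of expressed (nonzero) corrected counts per sample
  uq <- apply(corrected, 2, function(v) {
    nz <- v[v > 0]
    if (length(nz) == 0) stop2("normalise_counts: sample with no reads")
    quantile(nz, 0.75)
  })
  scaled <- sweep(corrected, 2, uq / target_uq, "/")
  out <- log2(scaled + 1)
  attr(out, "dropped_genes") <- dropped
  out
}

#' Construct a principal-component model
#'
#' @param loadings Genes x k orthonormal loading matrix.
#' @param scores Samples x k score matrix.
#' @param explained_var Non-increasing fractions of variance explained.
#' @param center,scale Per-gene centring/scaling vectors.
#' @param excluded_samples Samples dropped as outliers.
#' @return An object of class `pc_model`.
#' @export
pc_model <- function(loadings, scores, explained_var, center, scale,
                     excluded_samples = character()) {
  k <- ncol(loadings)
  ortho <- crossprod(loadings)
  if (max(abs(ortho - diag(k))) > 1e-8)
    stop2("pc_model: loading columns not orthonormal")
  if (any(diff(explained_var) > 1e-12))
    stop2("pc_model: explained_var must be non-increasing")
  structure(list(loadings = loadings, scores = scores,
                 explained_var = explained_var, center = center,
                 scale = scale, excluded_samples = excluded_samples,
                 k = k),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d genes, %d samples, k = %d; top-%d var %.1f%%; %d outliers excluded\n",
              nrow(x$loadings), nrow(x$scores), x$k, x$k,
              100 * sum(x$explained_var[seq_len(x$k)]), length(x$excluded_samples)))
  invisible(x)
}

svd_fit <- function(mat_gs, k, scale_genes) {
  ctr <- rowMeans(mat_gs)
  scl <- if (scale_genes) apply(mat_gs, 1, sd) else rep(1, nrow(mat_gs))
  if (any(scl == 0)) scl[scl == 0] <- 1
  X <- t((mat_gs - ctr) / scl) # samples x genes
  sv <- svd(X, nu = k, nv = k)
  list(sv = sv, center = ctr, scale = scl, X = X)
}

#' Expression PCA by singular value decomposition
#'
#' Genes are centred (and unit-scaled by default); a provisional SVD
#' flags samples whose score on either of the first two components
#' exceeds `outlier_sd` standard deviations; the decomposition is refit
#' without them. Loading signs are fixed so each column's largest-
#' magnitude entry is positive (reproducible across SVD
#' implementations).
#'
#' @param logmat Log-normalised matrix genes x samples (from
#'   [normalise_counts()]).
#' @param k Number of components to retain (default 5).
#' @param outlier_sd Outlier threshold in score SDs (default 6).
#' @param scale_genes Unit-scale genes before SVD (default `TRUE`).
#' @return A `pc_model`.
#' @export
fit_expression_pca <- function(logmat, k = 5, outlier_sd = 6,
                               scale_genes = TRUE) {
  if (k > min(dim(logmat)))
    stop2("fit_expression_pca: k exceeds matrix rank bound")
  if (ncol(logmat) < k + 2)
    stop2("fit_expression_pca: need at least k + 2 samples")
  f0 <- svd_fit(logmat, k, scale_genes)
  sc0 <- f0$sv$u %*% diag(f0$sv$d[seq_len(k)], k)
  out <- rep(FALSE, ncol(logmat))
  for (j in 1:2) {
    sj <- sc0[, j]
    out <- out | abs(sj - mean(sj)) > outlier_sd * sd(sj)
  }
  excluded <- colnames(logmat)[out] %||% which(out)
  mat <- logmat[, !out, drop = FALSE]
  f <- svd_fit(mat, k, scale_genes)
  d <- f$sv$d
  loadings <- f$sv$v
  scores <- f$sv$u %*% diag(d[seq_len(k)], k)
  # sign convention
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- rownames(logmat)
  rownames(scores) <- colnames(mat)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  ev <- d^2 / sum(d^2)
  pc_model(loadings, scores, ev[seq_len(k)], f$center, f$scale,
           as.character(excluded))
}

#' Top positively and negatively correlated genes per component
#'
#' Correlates each gene's (scaled) expression with a component score,
#' Bonferroni-adjusts over `genes x components` tests, and returns up to
#' `n_top` genes per direction with adjusted p < `alpha`. Intended for
#' export to external enrichment tools.
#'
#' @param pc A `pc_model`.
#' @param logmat The matrix the model was fit on (genes x samples).
#' @param component Component index (<= k).
#' @param n_top Per-direction cap (default 500).
#' @param alpha Adjusted significance level (default 0.05).
#' @return List with `positive` and `negative` character vectors, ordered
#'   by |correlation|; attribute `n_tests` records the Bonferroni
#'   denominator.
#' @export
top_loading_genes <- function(pc, logmat, component, n_top = 500,
                              alpha = 0.05) {
  stopifnot(inherits(pc, "pc_model"), component <= pc$k)
  samp <- rownames(pc$scores)
  mat <- logmat[, samp, drop = FALSE]
  sc <- pc$scores[, component]
  n <- length(sc)
  r <- as.numeric(cor(t(mat), sc))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  n_tests <- nrow(mat) * pc$k
  padj <- bonferroni_adjust(p, n_tests)
  sig <- which(padj < alpha & !is.na(r))
  pos <- sig[r[sig] > 0][order(-r[sig[r[sig] > 0]])]
  neg <- sig[r[sig] < 0][order(r[sig[r[sig] < 0]])]
  out <- list(positive = rownames(mat)[head(pos, n_top)],
              negative = rownames(mat)[head(neg, n_top)])
  attr(out, "n_tests") <- n_tests
  out
}

#' Association between a PRS and expression components
#'
#' For each retained component, least-squares regression of the component
#' score on the standardised PRS plus covariates; reports the effect per
#' SD of PRS with normal 95% CI and p-value.
#'
#' @param pc A `pc_model`.
#' @param prs A `prs_vector` (its `std_score` is used).
#' @param covariates Optional data.frame of per-sample covariates with
#'   rownames matching sample ids (e.g. sex, age, smoking status and
#'   genetic-ancestry PCs).
#' @return data.frame with one row per component: `component`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pval`, `n`.
#' @export
associate_prs_pcs <- function(pc, prs, covariates = NULL) {
  stopifnot(inherits(pc, "pc_model"), inherits(prs, "prs_vector"))
  samp <- intersect(rownames(pc$scores), prs$sample_ids)
  if (!is.null(covariates)) samp <- intersect(samp, rownames(covariates))
  p_cov <- if (is.null(covariates)) 0 else ncol(covariates)
  if (length(samp) < p_cov + 5)
    stop2("associate_prs_pcs: too few shared samples")
  x <- prs$std_score[match(samp, prs$sample_ids)]
  X <- cbind(`(Intercept)` = 1, prs = x)
  if (!is.null(covariates)) {
    cv <- covariates[samp, , drop = FALSE]
    cv <- as.matrix(data.frame(lapply(cv, as.numeric),
                               check.names = FALSE))
    X <- cbind(X, cv)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop2("associate_prs_pcs: rank-deficient design; aliased: ",
          paste(aliased, collapse = ", "))
  }
  out <- lapply(seq_len(pc$k), function(kk) {
    y <- pc$scores[samp, kk]
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    dfr <- length(y) - ncol(X)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(diag(XtXinv) * rss / dfr)
    b <- fit$coefficients["prs"]; s <- se[2]
    data.frame(component = paste0("PC", kk), beta = unname(b),
               se = unname(s),
               ci_low = unname(b - qnorm(0.975) * s),
               ci_high = unname(b + qnorm(0.975) * s),
               pval = unname(2 * pt(-abs(b / s), dfr)),
               n = length(y))
  })
  do.call(rbind, out)
}

#' Align two PC embeddings by orthogonal Procrustes rotation
#'
#' Finds the orthogonal matrix R minimising
#' `||L_val R - L_train||_F` via the SVD of `t(L_val) L_train`, and
#' applies it to the validation loadings and scores. Centring performed
#' during PCA absorbs the translation component of a rigid
#' transformation, so only the rotation/reflection is estimated here.
#'
#' @param pc_train,pc_val `pc_model`s over an identical, identically
#'   ordered gene universe.
#' @return List with `rotation` (k x k orthogonal), `aligned_scores`,
#'   `aligned_loadings` and the Frobenius `alignment_error`.
#' @export
align_pcs_rigid <- function(pc_train, pc_val) {
  stopifnot(inherits(pc_train, "pc_model"), inherits(pc_val, "pc_model"))
  g1 <- rownames(pc_train$loadings); g2 <- rownames(pc_val$loadings)
  if (!identical(g1, g2)) {
    d <- union(setdiff(g1, g2), setdiff(g2, g1))
    stop2("align_pcs_rigid: gene sets differ",
          if (length(d)) paste0("; asymmetric difference: ",
                                paste(head(d, 10), collapse = ", ")) else
            " (ordering mismatch)")
  }
  M <- crossprod(pc_val$loadings, pc_train$loadings)
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  aligned_scores <- pc_val$scores %*% R
  aligned_loadings <- pc_val$loadings %*% R
  dimnames(aligned_scores) <- dimnames(pc_val$scores)
  dimnames(aligned_loadings) <- dimnames(pc_val$loadings)
  list(rotation = R,
       aligned_scores = aligned_scores,
       aligned_loadings = aligned_loadings,
       alignment_error = norm(pc_val$loadings %*% R - pc_train$loadings,
                              "F"))
}

#' Construct a portable gene-expression signature
#'
#' @param gene_ids Signature genes.
#' @param coefficients Per-gene weights (finite, not all zero).
#' @param train_mean,train_sd Training-cohort per-gene scaling of the
#'   log-normalised counts.
#' @param rotation Alignment rotation applied upstream (or identity).
#' @param component Which expression component the signature infers.
#' @return An object of class `signature_model`.
#' @export
signature_model <- function(gene_ids, coefficients, train_mean, train_sd,
                            rotation = NULL, component = 2L) {
  stopifnot(length(gene_ids) == length(coefficients),
            all(is.finite(coefficients)))
  if (all(coefficients == 0))
    stop2("signature_model: coefficients must not all be zero")
  structure(list(gene_ids = as.character(gene_ids),
                 coefficients = setNames(as.numeric(coefficients),
                                         gene_ids),
                 train_mean = setNames(as.numeric(train_mean), gene_ids),
                 train_sd = setNames(as.numeric(train_sd), gene_ids),
                 rotation = rotation, component = component),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> PC%d signature, %d genes\n", x$component,
              length(x$gene_ids)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit a sparse gene signature for an expression component
#'
#' Screens genes by Benjamini-Hochberg FDR < `fdr_q` on their correlation
#' with the component score, z-scales the screened genes, and fits a
#' LASSO of the component score on them. Lambda is chosen to minimise the
#' mean out-of-bag RMSE over `n_boot` seeded bootstrap resamples of
#' samples, then the model is refit on the full data at that lambda;
#' genes with nonzero coefficients form the signature.
#'
#' @param logmat_train Log-normalised matrix genes x samples.
#' @param pc_train A `pc_model` fit on (a superset of) these samples.
#' @param component Component to model (default 2).
#' @param fdr_q BH screening threshold (default 0.05).
#' @param n_boot Bootstrap resamples for lambda selection (default 1000).
#' @param seed RNG seed (mandatory).
#' @param nlambda Length of the lambda path (default 60).
#' @return A `signature_model`; attributes `lambda`, `r2_train` and
#'   `n_screened` document the fit.
#' @export
fit_lasso_signature <- function(logmat_train, pc_train, component = 2,
                                fdr_q = 0.05, n_boot = 1000, seed = 1,
                                nlambda = 60) {
  stopifnot(inherits(pc_train, "pc_model"), component <= pc_train$k)
  samp <- intersect(colnames(logmat_train), rownames(pc_train$scores))
  mat <- logmat_train[, samp, drop = FALSE]
  y <- pc_train$scores[samp, component]
  n <- length(y)
  r <- as.numeric(cor(t(mat), y))
  r[is.na(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  padj <- p.adjust(p, "BH")
  screened <- which(padj < fdr_q)
  if (length(screened) == 0)
    stop2("fit_lasso_signature: no genes pass the FDR screen")
  Xg <- t(mat[screened, , drop = FALSE])
  mu <- colMeans(Xg); sdv <- apply(Xg, 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- scale(Xg, mu, sdv)

  if (length(screened) == 1) {
    # single-predictor limit: plain least squares, no penalty needed
    co1 <- drop(crossprod(Xs[, 1], y - mean(y)) / crossprod(Xs[, 1]))
    fitted <- mean(y) + Xs[, 1] * co1
    sig <- signature_model(colnames(Xs), co1, mu, sdv,
                           component = component)
    attr(sig, "lambda") <- 0
    attr(sig, "r2_train") <- cor(fitted, y)^2
    attr(sig, "n_screened") <- 1L
    return(sig)
  }

  base <- glmnet::glmnet(Xs, y, standardize = FALSE, nlambda = nlambda)
  lam <- base$lambda
  rmse <- matrix(NA_real_, n_boot, length(lam))
  withr_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) < 2) next
      fb <- glmnet::glmnet(Xs[idx, , drop = FALSE], y[idx],
                           standardize = FALSE, lambda = lam)
      pred <- predict(fb, Xs[oob, , drop = FALSE])
      got <- min(ncol(pred), length(lam))
      rmse[b, seq_len(got)] <-
        sqrt(colMeans((pred[, seq_len(got), drop = FALSE] - y[oob])^2))
    }
  })
  mean_rmse <- colMeans(rmse, na.rm = TRUE)
  lam_best <- lam[which.min(mean_rmse)]
  co <- coef(base, s = lam_best)[-1, 1] # drop intercept
  nz <- which(co != 0)
  if (length(nz) == 0)
    stop2("fit_lasso_signature: all coefficients zero at selected lambda; supply a smaller lambda path")
  genes <- colnames(Xs)[nz]
  fitted <- drop(Xs[, nz, drop = FALSE] %*% co[nz]) +
    coef(base, s = lam_best)[1, 1]
  r2 <- cor(fitted, y)^2
  sig <- signature_model(genes, co[nz], mu[nz], sdv[nz],
                         component = component)
  attr(sig, "lambda") <- lam_best
  attr(sig, "r2_train") <- r2
  attr(sig, "n_screened") <- length(screened)
  attr(sig, "boot_rmse") <- min(mean_rmse)
  sig
}

#' Apply a gene signature to a target cohort
#'
#' Each signature gene is z-scaled *within the target cohort* (supporting
#' cross-cohort comparison on a common internal scale; pass
#' `scaling = "training"` to reuse the frozen training mean/SD instead),
#' then `score_s = sum_g coef_g * scaled_gs`. Zero-variance signature
#' genes in the target are dropped with a warning and the score
#' recomputed from the remainder.
#'
#' @param sig A `signature_model`.
#' @param logmat_target Log-normalised matrix genes x samples; must
#'   contain every signature gene (missing genes are a hard error).
#' @param scaling `"target"` (default) or `"training"`.
#' @return Numeric vector of per-sample scores (named); attributes
#'   `scale_mean`, `scale_sd` and `dropped_genes` document the scaling.
#' @export
apply_signature <- function(sig, logmat_target,
                            scaling = c("target", "training")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(sig, "signature_model"))
  missing_g <- setdiff(sig$gene_ids, rownames(logmat_target))
  if (length(missing_g) > 0)
    stop2("apply_signature: target lacks signature gene(s): ",
          paste(missing_g, collapse = ", "))
  X <- t(logmat_target[sig$gene_ids, , drop = FALSE])
  if (scaling == "target") {
    mu <- colMeans(X); sdv <- apply(X, 2, sd)
  } else {
    mu <- sig$train_mean; sdv <- sig$train_sd
  }
  flat <- sdv == 0 | !is.finite(sdv)
  dropped <- sig$gene_ids[flat]
  if (all(flat))
    stop2("apply_signature: every signature gene has zero variance in target")
  if (any(flat))
    warning("apply_signature: dropping zero-variance gene(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  use <- !flat
  Xs <- scale(X[, use, drop = FALSE], mu[use], sdv[use])
  score <- drop(Xs %*% sig$coefficients[use])
  names(score) <- rownames(X)
  attr(score, "scale_mean") <- mu[use]
  attr(score, "scale_sd") <- sdv[use]
  attr(score, "dropped_genes") <- dropped
  score
}

#' Univariate and multivariate feature association models
#'
#' Least-squares models of a per-sample outcome score on clinical and
#' genomic features: each feature alone (`univariate`; a feature named in
#' `adjust_for_ancestry` is additionally adjusted for the ancestry
#' covariates, matching common PRS practice) or all jointly
#' (`multivariate`). The outcome and continuous predictors are
#' standardised to unit SD; binary predictors are left 0/1.
#'
#' @param outcome Named numeric vector of per-sample outcome scores.
#' @param features data.frame of predictors, rownames matching the
#'   outcome names; columns with exactly two distinct values are treated
#'   as binary, others standardised.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param ancestry Optional data.frame of ancestry covariates (e.g. the
#'   first five genetic PCs).
#' @param adjust_for_ancestry Feature names to adjust for ancestry in the
#'   univariate mode (default `"prs"` when present).
#' @return data.frame with `feature`, `beta`, `se`, `pval`, `n`, `mode`.
#' @export
feature_association <- function(outcome, features,
                                mode = c("univariate", "multivariate"),
                                ancestry = NULL,
                                adjust_for_ancestry = intersect("prs", names(features))) {
  mode <- match.arg(mode)
  samp <- intersect(names(outcome), rownames(features))
  if (!is.null(ancestry)) samp <- intersect(samp, rownames(ancestry))
  y <- outcome[samp]
  y <- (y - mean(y)) / sd(y)
  std_col <- function(v) {
    v <- as.numeric(v)
    if (length(unique(v[!is.na(v)])) == 2) return(v)
    (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
  }
  Xf <- as.data.frame(lapply(features[samp, , drop = FALSE], std_col))
  names(Xf) <- names(features)
  anc <- if (!is.null(ancestry))
    as.matrix(data.frame(lapply(ancestry[samp, , drop = FALSE],
                                as.numeric))) else NULL
  one_fit <- function(X, label) {
    ok <- complete.cases(X) & !is.na(y)
    Xm <- cbind(1, as.matrix(X[ok, , drop = FALSE]))
    fit <- lm.fit(Xm, y[ok])
    dfr <- sum(ok) - ncol(Xm)
    rss <- sum(fit$residuals^2)
    XtXinv <- chol2inv(chol(crossprod(Xm)))
    se <- sqrt(diag(XtXinv) * rss / dfr)
    idx <- 1 + seq_along(label)
    data.frame(feature = label, beta = unname(fit$coefficients[idx]),
               se = unname(se[idx]),
               pval = unname(2 * pt(-abs(fit$coefficients[idx] / se[idx]),
                                    dfr)),
               n = sum(ok), mode = mode, stringsAsFactors = FALSE)
  }
  if (mode == "multivariate") {
    qrx <- qr(as.matrix(Xf[complete.cases(Xf), , drop = FALSE]))
    if (qrx$rank < ncol(Xf))
      stop2("feature_association: rank-deficient multivariate design; aliased: ",
            paste(names(Xf)[qrx$pivot[(qrx$rank + 1):ncol(Xf)]],
                  collapse = ", "))
    return(one_fit(Xf, names(Xf)))
  }
  out <- lapply(names(Xf), function(f) {
    X <- Xf[, f, drop = FALSE]
    if (f %in% adjust_for_ancestry && !is.null(anc))
      X <- cbind(X, anc)
    one_fit(X, f)[1, , drop = FALSE]
  })
  do.call(rbind, out)
}
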