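# signature: normalisation, PCA, alignment, LASSO signature, feature
# models.

small_cohort <- function(seed = 1, n_samples = 120, n_genes = 600) {
  simulate_tumour_cohort(n_samples = n_samples, n_genes = n_genes,
                         n_variants = 40, seed = seed)
}

test_that("normalise_counts filters low-count genes and is depth-invariant", {
  withr_local_seed(3)
  counts <- matrix(rnbinom(200 * 20, mu = 60, size = 3), 200, 20,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("s%02d", 1:20)))
  # one gene expressed in only 10% of samples at >= 5 reads
  counts["g001", ] <- c(rep(10, 2), rep(0, 18))
  meta <- data.frame(gene_id = rownames(counts),
                     length = sample(500:5000, 200), gc = runif(200, 0.3, 0.7))
  em <- expression_matrix(counts, meta)
  lmat <- normalise_counts(em, min_count = 5, min_frac = 0.2)
  expect_true("g001" %in% attr(lmat, "dropped_genes"))

  # doubling one sample's depth leaves the whole output unchanged
  counts2 <- counts
  counts2[, 3] <- counts[, 3] * 2L
  lmat2 <- normalise_counts(expression_matrix(counts2, meta),
                            min_count = 5, min_frac = 0.2)
  # the doubled sample maps back onto the original column...
  expect_equal(lmat2[, 3], lmat[, 3], tolerance = 1e-6)
  # ...and all other columns are untouched (fixed common depth target)
  expect_equal(lmat2[, -3], lmat[, -3], tolerance = 1e-12)

  # GC-flat genes: correction is a no-op within tolerance
  meta_flat <- meta; meta_flat$gc <- 0.5; meta_flat$length <- 1000
  em_flat <- expression_matrix(counts, meta_flat)
  with_gc <- normalise_counts(em_flat, min_count = 5, min_frac = 0.2)
  without <- normalise_counts(em_flat, min_count = 5, min_frac = 0.2,
                              gc_correct = FALSE)
  expect_equal(with_gc, without, tolerance = 1e-10)

  expect_error(normalise_counts(em, min_count = 1e6, min_frac = 1),
               "filtered")
})

test_that("fit_expression_pca: planted rank-1 structure, outliers, Eckart-Young", {
  withr_local_seed(13)
  n_g <- 150; n_s <- 60
  f <- rnorm(n_s)
  load <- rnorm(n_g)
  mat <- outer(load, f) + matrix(rnorm(n_g * n_s, 0, 0.01), n_g, n_s)
  dimnames(mat) <- list(sprintf("g%03d", 1:n_g), sprintf("s%02d", 1:n_s))
  pc <- fit_expression_pca(mat, k = 3, scale_genes = FALSE)
  expect_gt(pc$explained_var[1], 0.99)
  # loadings orthonormal, explained variance non-increasing
  expect_equal(crossprod(pc$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$explained_var) <= 1e-12))

  # Eckart-Young: reconstruction error equals trailing singular values
  ctr <- mat - rowMeans(mat)
  d <- svd(t(ctr))$d
  recon_err <- norm(t(ctr) - pc$scores %*% t(pc$loadings), "F")
  expect_equal(recon_err, sqrt(sum(d[4:length(d)]^2)), tolerance = 1e-6)

  # a sample displaced 10 SDs on PC1 is excluded
  mat_out <- mat
  mat_out[, 5] <- mat[, 5] + load * 10 * sd(f)
  pc_out <- fit_expression_pca(mat_out, k = 3, outlier_sd = 6,
                               scale_genes = FALSE)
  expect_true("s05" %in% pc_out$excluded_samples)
  expect_false("s05" %in% rownames(pc_out$scores))

  expect_error(fit_expression_pca(mat, k = 100), "k exceeds")
})

test_that("top_loading_genes recovers planted modules and ignores noise", {
  withr_local_seed(23)
  n_s <- 80
  f <- rnorm(n_s)
  module <- sprintf("mod%02d", 1:20)
  noise <- sprintf("n%03d", 1:180)
  mat <- rbind(
    outer(rep(1, 20), f) + matrix(rnorm(20 * n_s, 0, 0.2), 20),
    matrix(rnorm(180 * n_s), 180))
  dimnames(mat) <- list(c(module, noise), sprintf("s%02d", 1:n_s))
  pc <- fit_expression_pca(mat, k = 2, scale_genes = FALSE)
  tl <- top_loading_genes(pc, mat, 1, n_top = 500)
  strong <- if (length(tl$positive) >= length(tl$negative))
    tl$positive else tl$negative
  expect_true(all(module %in% strong))
  expect_identical(attr(tl, "n_tests"), nrow(mat) * 2L)
  # a pure-noise component yields (almost) no significant genes
  tl2 <- top_loading_genes(pc, mat, 2, n_top = 500)
  expect_lt(length(tl2$positive) + length(tl2$negative), 5)
})

test_that("associate_prs_pcs: orthogonal PRS gives a null beta; permutation p-values are uniform", {
  sim <- small_cohort(seed = 33)
  lmat <- normalise_counts(sim$em)
  pc <- fit_expression_pca(lmat, k = 3)
  prs <- compute_prs(sim$genotypes, sim$weights)
  # orthogonalise the PRS against component 1 -> beta exactly 0
  s1 <- pc$scores[, 1]
  x <- prs$std_score[match(rownames(pc$scores), prs$sample_ids)]
  resid <- lm(x ~ s1)$residuals
  prs_orth <- structure(list(sample_ids = rownames(pc$scores),
                             raw_score = resid,
                             std_score = (resid - mean(resid)) /
                               sqrt(mean((resid - mean(resid))^2)),
                             n_variants = prs$n_variants),
                        class = "prs_vector")
  a <- associate_prs_pcs(pc, prs_orth)
  expect_lt(abs(a$beta[1]), 1e-8)

  # permutation null: p-values uniform (KS) over 200 permutations
  withr_local_seed(34)
  pvals <- replicate(200, {
    perm <- structure(list(sample_ids = sample(prs$sample_ids),
                           raw_score = prs$raw_score,
                           std_score = prs$std_score,
                           n_variants = prs$n_variants),
                      class = "prs_vector")
    associate_prs_pcs(pc, perm)$pval[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)

  # rank-deficient design names the aliased covariate
  cov_bad <- data.frame(a = rep(1, nrow(pc$scores)),
                        row.names = rownames(pc$scores))
  expect_error(associate_prs_pcs(pc, prs, cov_bad), "aliased")
})

test_that("align_pcs_rigid: identity, reflection, and random-rotation recovery", {
  sim <- small_cohort(seed = 43)
  lmat <- normalise_counts(sim$em)
  pc <- fit_expression_pca(lmat, k = 5)
  # identity
  al <- align_pcs_rigid(pc, pc)
  expect_equal(al$rotation, diag(5), tolerance = 1e-10, ignore_attr = TRUE)

  # reflection of components 1-2
  flip <- diag(c(-1, -1, 1, 1, 1))
  pc_f <- pc_model(pc$loadings %*% flip, pc$scores %*% flip,
                   pc$explained_var, pc$center, pc$scale)
  rownames(pc_f$loadings) <- rownames(pc$loadings)
  al_f <- align_pcs_rigid(pc, pc_f)
  expect_equal(al_f$rotation, flip, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(al_f$aligned_loadings, pc$loadings, tolerance = 1e-10,
               ignore_attr = TRUE)

  # random small rotation: recovered within 1e-6 Frobenius; the 2x2
  # subcase agrees with a grid-search oracle over angles
  withr_local_seed(44)
  A <- matrix(rnorm(25, 0, 0.1), 5, 5)
  rot <- expm_skew <- diag(5) + (A - t(A)) / 2
  rot <- qr.Q(qr(rot))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  pc_r <- pc_model(pc$loadings %*% rot, pc$scores %*% rot,
                   pc$explained_var, pc$center, pc$scale)
  rownames(pc_r$loadings) <- rownames(pc$loadings)
  al_r <- align_pcs_rigid(pc, pc_r)
  expect_lt(norm(al_r$rotation - t(rot), "F"), 1e-6)
  expect_lt(al_r$alignment_error, 1e-8)
  # orthogonality and round-trip identity
  expect_equal(crossprod(al_r$rotation), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  back <- align_pcs_rigid(pc_r, pc)
  expect_equal(al_r$rotation %*% back$rotation, diag(5),
               tolerance = 1e-8, ignore_attr = TRUE)

  # differing gene sets are a hard error listing the difference
  pc_bad <- pc_model(pc$loadings, pc$scores, pc$explained_var,
                     pc$center, pc$scale)
  rownames(pc_bad$loadings) <- c("WEIRD",
                                 rownames(pc$loadings)[-1])
  expect_error(align_pcs_rigid(pc, pc_bad), "WEIRD")
})

test_that("fit_lasso_signature: single perfect predictor and planted modules", {
  withr_local_seed(53)
  n_s <- 90
  y <- rnorm(n_s)
  mat <- matrix(rnorm(40 * n_s), 40, n_s,
                dimnames = list(sprintf("g%03d", 1:40),
                                sprintf("s%02d", 1:n_s)))
  mat["g001", ] <- y + rnorm(n_s, 0, 0.005)
  # hand-built pc_model carrier for the score
  pcs <- cbind(PC1 = rnorm(n_s), PC2 = y)
  rownames(pcs) <- colnames(mat)
  L <- qr.Q(qr(matrix(rnorm(80), 40, 2)))
  rownames(L) <- rownames(mat)
  pc <- pc_model(L, pcs, c(0.6, 0.4), rowMeans(mat), rep(1, 40))
  sig <- fit_lasso_signature(mat, pc, component = 2, n_boot = 30,
                             seed = 7)
  expect_true("g001" %in% sig$gene_ids)
  expect_gt(attr(sig, "r2_train"), 0.99)

  # planted 10-gene module driving the factor: selection is nearly pure
  # (12 replicates, scaled down from the design-scale 50; >= 9 must pass)
  pure <- vapply(1:12, function(s) {
    withr_local_seed(6000 + s)
    n_s2 <- 120
    f <- rnorm(n_s2)
    mod_mat <- outer(runif(10, 0.8, 1.2), f) +
      matrix(rnorm(10 * n_s2, 0, 0.15), 10)
    noise_mat <- matrix(rnorm(200 * n_s2), 200)
    m2 <- rbind(mod_mat, noise_mat)
    dimnames(m2) <- list(sprintf("g%03d", 1:210),
                         sprintf("s%03d", 1:n_s2))
    pcs2 <- cbind(PC1 = rnorm(n_s2), PC2 = f)
    rownames(pcs2) <- colnames(m2)
    L2 <- qr.Q(qr(matrix(rnorm(420), 210, 2)))
    rownames(L2) <- rownames(m2)
    pc2 <- pc_model(L2, pcs2, c(0.6, 0.4), rowMeans(m2), rep(1, 210))
    sg <- fit_lasso_signature(m2, pc2, component = 2, n_boot = 25,
                              seed = s)
    false_pos <- setdiff(sg$gene_ids, sprintf("g%03d", 1:10))
    length(false_pos) <= 2
  }, TRUE)
  expect_gte(sum(pure), 9)

  # single-predictor limit: the perfectly correlated gene alone survives
  # an extreme screen and is fit without a penalty
  sig1 <- fit_lasso_signature(mat, pc, component = 2, fdr_q = 1e-12,
                              n_boot = 5, seed = 1)
  expect_identical(sig1$gene_ids, "g001")
  expect_gt(attr(sig1, "r2_train"), 0.99)

  # a score unrelated to every gene leaves the screen empty
  pcs_noise <- cbind(PC1 = rnorm(n_s), PC2 = rnorm(n_s))
  rownames(pcs_noise) <- colnames(mat)
  pc_noise <- pc_model(L, pcs_noise, c(0.6, 0.4), rowMeans(mat),
                       rep(1, 40))
  expect_error(fit_lasso_signature(mat, pc_noise, component = 2,
                                   fdr_q = 1e-6, n_boot = 5, seed = 1),
               "FDR screen")
})

test_that("apply_signature: self-application, invariances, degenerate targets", {
  sim <- small_cohort(seed = 63)
  lmat <- normalise_counts(sim$em)
  pc <- fit_expression_pca(lmat, k = 3)
  sig <- fit_lasso_signature(lmat, pc, component = 2, n_boot = 20,
                             seed = 9)
  sc <- apply_signature(sig, lmat)
  expect_gt(cor(sc[rownames(pc$scores)], pc$scores[, 2]), 0.99)

  # invariant to gene order and to rescaling a non-signature gene
  perm <- sample(nrow(lmat))
  sc_perm <- apply_signature(sig, lmat[perm, ])
  expect_equal(sc_perm, sc)
  other <- setdiff(rownames(lmat), sig$gene_ids)[1]
  lmat2 <- lmat
  lmat2[other, ] <- lmat2[other, ] * 3 + 1
  expect_equal(apply_signature(sig, lmat2), sc)

  # missing signature genes are a hard error listing them
  expect_error(apply_signature(sig, lmat[setdiff(rownames(lmat),
                                                 sig$gene_ids[1]), ]),
               sig$gene_ids[1])
  # all-identical target: zero variance everywhere -> error
  flatmat <- lmat
  flatmat[] <- rep(flatmat[, 1], ncol(lmat))
  expect_error(apply_signature(sig, flatmat), "zero variance")
  # single flat gene: dropped with a warning, flag recorded
  lmat3 <- lmat
  lmat3[sig$gene_ids[1], ] <- 5
  expect_warning(sc3 <- apply_signature(sig, lmat3),
                 sig$gene_ids[1])
  expect_identical(attr(sc3, "dropped_genes"), sig$gene_ids[1])
})

test_that("feature_association recovers planted structure in both modes", {
  withr_local_seed(73)
  n <- 400
  feats <- data.frame(
    age = rnorm(n, 65, 9),
    sex = rbinom(n, 1, 0.5),
    smoking = rbinom(n, 1, 0.7),
    prs = rnorm(n),
    proliferation = rnorm(n),
    row.names = sprintf("s%03d", 1:n))
  beta_true <- c(age = 0.15, sex = 0.2, smoking = -0.2, prs = 0.1,
                 proliferation = -0.4)
  Xs <- scale(data.matrix(feats))
  Xs[, "sex"] <- feats$sex; Xs[, "smoking"] <- feats$smoking
  y_raw <- drop(Xs %*% beta_true) + rnorm(n, 0, 0.6)
  shrink <- 1 / sd(y_raw)            # outcome standardisation factor
  y <- setNames(y_raw * shrink, rownames(feats))

  multi <- feature_association(y, feats, "multivariate")
  # coefficients recovered within ~3 SEs (outcome-standardised scale)
  for (f in names(beta_true)) {
    row <- multi[multi$feature == f, ]
    expect_lt(abs(row$beta - beta_true[f] * shrink), 3.5 * row$se)
  }

  uni <- feature_association(y, feats, "univariate")
  expect_identical(nrow(uni), 5L)
  # a feature uncorrelated with the outcome has beta within 3 SEs of 0
  feats2 <- cbind(feats, unrelated = rnorm(n))
  uni2 <- feature_association(y, feats2, "univariate")
  row <- uni2[uni2$feature == "unrelated", ]
  expect_lt(abs(row$beta), 3 * row$se)

  # univariate PRS row is ancestry-adjusted when ancestry PCs supplied
  anc <- data.frame(matrix(rnorm(n * 5), n), row.names = rownames(feats))
  uni3 <- feature_association(y, feats, "univariate", ancestry = anc)
  expect_identical(nrow(uni3), 5L)
})
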