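# mr_core: estimator battery, diagnostics, invariants.

make_hs <- function(b_x, b_y, s_x = 0.01, s_y = 0.05) {
  J <- length(b_x)
  harmonised_set(sprintf("iv%02d", seq_len(J)), b_x,
                 rep_len(s_x, J), b_y, rep_len(s_y, J))
}

test_that("wald_ratio closed forms and second-order SE against simulation", {
  w <- wald_ratio(0.5, 0.05, 0.25, 0.1)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(wald_ratio(0.5, 0.05, 0, 0.1)$beta, 0)
  expect_error(wald_ratio(0, 0.05, 0.1, 0.1), "nonzero")

  # Monte-Carlo oracle (1e6 draws): the SD of the ratio matches the
  # second-order delta-method SE within 5%
  withr_local_seed(99)
  bx <- 0.5; sx <- 0.03; by <- 0.25; sy <- 0.05
  ratio_draws <- rnorm(1e6, by, sy) / rnorm(1e6, bx, sx)
  se2 <- wald_ratio(bx, sx, by, sy, second_order = TRUE)$se
  expect_equal(sd(ratio_draws), se2, tolerance = 0.05)
})

test_that("ivw_mre reproduces a noiseless linear relation and floors the scale", {
  b_x <- c(0.2, 0.3, 0.4, 0.5)
  hs <- make_hs(b_x, 0.3 * b_x, s_y = 0.05)
  fit <- ivw_mre(hs)
  expect_equal(fit$estimate$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$heterogeneity$Q, 0, tolerance = 1e-20)
  # scale floored at 1: the MRE se equals the fixed-effect se
  w <- 1 / hs$s_y^2
  expect_equal(fit$estimate$se, sqrt(1 / sum(w * hs$b_x^2)))
  expect_error(ivw_mre(make_hs(0.3, 0.1)), "wald_ratio")
})

test_that("ivw_mre agrees with a weighted regression through the origin", {
  withr_local_seed(5)
  hs <- make_hs(runif(20, 0.1, 0.5), rnorm(20, 0.1, 0.05),
                s_y = runif(20, 0.02, 0.1))
  fit <- ivw_mre(hs)
  ref <- lm(hs$b_y ~ 0 + hs$b_x, weights = 1 / hs$s_y^2)
  expect_equal(fit$estimate$beta, unname(coef(ref)), tolerance = 1e-10)
  # multiplicative random-effects SE >= fixed-effect SE
  w <- 1 / hs$s_y^2
  expect_gte(fit$estimate$se, sqrt(1 / sum(w * hs$b_x^2)) - 1e-15)
})

test_that("mr_egger recovers exact intercept/slope and tests pleiotropy", {
  b_x <- seq(0.1, 0.5, length.out = 6)
  hs <- make_hs(b_x, 0.02 + 0.4 * b_x)
  fit <- mr_egger(hs)
  expect_equal(fit$estimate$beta, 0.4, tolerance = 1e-10)
  expect_equal(fit$estimate$intercept, 0.02, tolerance = 1e-10)
  expect_error(mr_egger(make_hs(c(0.1, 0.2), c(0.1, 0.2))), ">= 3")
})

test_that("weighted_median handles degenerate and textbook cases", {
  b_x <- c(0.2, 0.3, 0.4)
  expect_equal(weighted_median(make_hs(b_x, 0.7 * b_x),
                               n_boot = 50, seed = 1)$beta, 0.7)
  # equal weights, ratios (0.1, 0.2, 0.9) -> plain median 0.2
  hs <- make_hs(c(1, 1, 1), c(0.1, 0.2, 0.9), s_y = 0.05)
  expect_equal(weighted_median(hs, n_boot = 50, seed = 1)$beta, 0.2)
  # estimate lies inside the range of Wald ratios
  withr_local_seed(21)
  hs2 <- make_hs(runif(15, 0.1, 0.5), rnorm(15, 0.05, 0.1),
                 s_y = runif(15, 0.02, 0.2))
  est <- weighted_median(hs2, n_boot = 50, seed = 2)$beta
  ratios <- hs2$b_y / hs2$b_x
  expect_gte(est, min(ratios)); expect_lte(est, max(ratios))
  # bootstrap SE is reproducible under the same seed
  expect_identical(weighted_median(hs2, n_boot = 100, seed = 3)$se,
                   weighted_median(hs2, n_boot = 100, seed = 3)$se)
})

test_that("weighted_median stays consistent with 49% invalid instruments", {
  # scaled-down consistency check (design scale: 1000 sims); 40 sims here.
  # 25 of 51 equal-weight instruments carry large one-directional
  # pleiotropy; the valid half of the weight keeps the median consistent
  # as the outcome SEs shrink.
  withr_local_seed(31)
  ests <- replicate(40, {
    J <- 51
    bx <- rep(0.3, J)
    alpha <- c(rep(0, 26), rep(0.3, 25))
    sy <- rep(5e-4, J)
    by <- rnorm(J, 0.5 * bx + alpha, sy)
    weighted_median(make_hs(bx, by, s_y = 5e-4), n_boot = 2,
                    seed = 1)$beta
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.5), 3 * mc_se + 0.01)
})

test_that("contamination_mixture matches IVW when clean and an enumeration oracle", {
  b_x <- seq(0.2, 0.6, length.out = 10)
  hs <- make_hs(b_x, 0.45 * b_x, s_y = 0.002)
  cm <- contamination_mixture(hs)
  ivw <- ivw_mre(hs)$estimate$beta
  step <- diff(attr(cm, "conmix")$grid[1:2])
  expect_lt(abs(cm$beta - ivw), step + 1e-12)

  # enumeration oracle, J = 8: maximise the classified likelihood over
  # all 2^8 valid/invalid assignments; profile maximum must agree
  withr_local_seed(41)
  J <- 8
  bx <- runif(J, 0.2, 0.5)
  by <- c(3 * bx[1:5], 3 * bx[6:8] - 2)   # 3 contaminated, away from 0
  hs2 <- make_hs(bx, by, s_y = 0.05)
  psi <- 1
  cm2 <- contamination_mixture(hs2, psi = psi, grid_size = 4001)
  r <- hs2$b_y / hs2$b_x; se <- hs2$s_y / abs(hs2$b_x)
  best <- -Inf; best_theta <- NA
  for (mask in 0:(2^J - 1)) {
    valid <- as.logical(bitwAnd(mask, 2^(0:(J - 1))))
    th <- if (any(valid))
      sum(r[valid] / se[valid]^2) / sum(1 / se[valid]^2) else 0
    ll <- sum(dnorm(r[valid], th, se[valid], log = TRUE)) +
      sum(dnorm(r[!valid], 0, sqrt(se[!valid]^2 + psi^2), log = TRUE))
    if (ll > best) { best <- ll; best_theta <- th }
  }
  expect_equal(max(attr(cm2, "conmix")$profile), best, tolerance = 1e-4)
  expect_equal(cm2$beta, best_theta, tolerance = 2 * diff(attr(cm2, "conmix")$grid[1:2]))
  # the shifted half is classified invalid at the optimum
  expect_identical(unname(attr(cm2, "conmix")$valid), rep(c(TRUE, FALSE), c(5, 3)))

  # psi -> infinity: the invalid density vanishes, all classified valid
  cm3 <- contamination_mixture(hs2, psi = 1e300)
  expect_true(all(attr(cm3, "conmix")$valid))
})

test_that("leave_one_out flags only influential instruments at the 10% rule", {
  b_x <- seq(0.2, 0.6, length.out = 6)
  hs <- make_hs(b_x, 0.3 * b_x)
  expect_false(any(leave_one_out(hs)$flagged))

  # inject one outlying instrument among 12 clean ones; verify the flag
  # by direct recomputation of the IVW fit without it
  bxl <- seq(0.2, 0.75, length.out = 12)
  bx2 <- c(bxl, 0.5)
  by2 <- c(0.3 * bxl, 0.9 * 0.5 + 0.45)
  hs2 <- make_hs(bx2, by2)
  loo <- leave_one_out(hs2)
  full <- ivw_mre(hs2)$estimate$beta
  without <- ivw_mre(make_hs(bxl, 0.3 * bxl))$estimate$beta
  expect_true(loo$flagged[13])
  expect_gt(abs(without - full) / abs(full), 0.10)
  expect_equal(loo$beta_without[13], without)
  expect_false(any(loo$flagged[1:12]))
})

test_that("estimators are invariant to jointly flipping any instrument's signs", {
  withr_local_seed(61)
  J <- 12
  hs <- make_hs(runif(J, 0.1, 0.5), rnorm(J, 0.08, 0.05),
                s_y = runif(J, 0.02, 0.08))
  flip <- rep(1, J); flip[c(2, 5, 9)] <- -1
  hsf <- harmonised_set(hs$variant_ids, hs$b_x * flip, hs$s_x,
                        hs$b_y * flip, hs$s_y)
  expect_equal(ivw_mre(hsf)$estimate$beta, ivw_mre(hs)$estimate$beta)
  expect_equal(mr_egger(hsf)$estimate$beta, mr_egger(hs)$estimate$beta)
  expect_equal(mr_egger(hsf)$estimate$intercept,
               mr_egger(hs)$estimate$intercept)
  expect_equal(weighted_median(hsf, n_boot = 40, seed = 4)$beta,
               weighted_median(hs, n_boot = 40, seed = 4)$beta)
  expect_equal(contamination_mixture(hsf)$beta,
               contamination_mixture(hs)$beta)
})

test_that("type-I error is controlled under the null with balanced pleiotropy", {
  # scaled down from the design-scale 2000 sims to 400 (noted); J = 50
  withr_local_seed(71)
  n_sim <- 400
  rej <- matrix(FALSE, n_sim, 3,
                dimnames = list(NULL, c("ivw", "egger", "median")))
  for (i in seq_len(n_sim)) {
    J <- 50
    bx_true <- abs(rnorm(J, 0.03, 0.01))
    sx <- rep(0.002, J); sy <- rep(0.01, J)
    alpha <- rnorm(J, 0, 0.005)      # balanced pleiotropy
    hs <- harmonised_set(paste0("v", 1:J), rnorm(J, bx_true, sx), sx,
                         rnorm(J, alpha, sy), sy)
    rej[i, "ivw"] <- ivw_mre(hs)$estimate$pval < 0.05
    rej[i, "egger"] <- mr_egger(hs)$estimate$pval < 0.05
    wm <- weighted_median(hs, n_boot = 40, seed = i)
    rej[i, "median"] <- wm$pval < 0.05
  }
  # allow Monte-Carlo slack around the design 0.07 ceiling at 400 sims
  for (m in colnames(rej))
    expect_lte(mean(rej[, m]), 0.07 + 2 * sqrt(0.07 * 0.93 / n_sim))
})
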