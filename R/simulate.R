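# simulate: ground-truth generators. Every generator is a pure function
# of its parameters and seed (bit-reproducible) and returns both the
# dataset and a sim_truth record sufficient to regenerate it.

new_sim_truth <- function(scenario, params) {
  structure(c(list(scenario = scenario), params), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> scenario '%s' (seed %s)\n", x$scenario,
              format(x$seed)))
  invisible(x)
}

#' Simulate a harmonised two-sample MR instrument set
#'
#' Linear causal model with optional directional pleiotropy. True
#' exposure effects are `|N(0.03, 0.01^2)|` (a realistic per-variant
#' effect scale for a standardised polygenic exposure); observed exposure
#' betas add sampling noise `s_X = 1/sqrt(n_exp)`; per-instrument
#' pleiotropic effects `alpha_j ~ N(pleio_mean, pleio_sd^2)` are drawn
#' independently of instrument strength (InSIDE holds); outcome betas are
#' `N(theta * b_X_true + alpha_j, s_Y^2)` with `s_Y = 1/sqrt(n_out)`.
#'
#' @param j Number of instruments (>= 2); default 144, the size of a
#'   well-powered telomere-length instrument.
#' @param theta True causal effect (default 0.5).
#' @param pleio_mean,pleio_sd Directional-pleiotropy mean and SD
#'   (defaults 0).
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes (defaults
#'   464716 and 85689, typical biobank/consortium lung-cancer scales).
#' @param case_fraction Outcome case fraction; the outcome SE uses the
#'   binary-trait form `1 / sqrt(N * phi * (1 - phi))` (default 0.3413,
#'   a 29k-case / 56k-control consortium GWAS).
#' @param seed RNG seed.
#' @return List with `hs` (a `harmonised_set`) and `truth`
#'   (a `sim_truth`).
#' @export
simulate_mr_instruments <- function(j = 144, theta = 0.5, pleio_mean = 0,
                                    pleio_sd = 0, n_exp = 464716,
                                    n_out = 85689,
                                    case_fraction = 29239 / 85689,
                                    seed = 1) {
  stopifnot(j >= 2)
  withr_seed(seed, {
    bx_true <- abs(rnorm(j, 0.03, 0.01))
    s_x <- rep(1 / sqrt(n_exp), j)
    s_y <- rep(1 / sqrt(n_out * case_fraction * (1 - case_fraction)), j)
    b_x <- rnorm(j, bx_true, s_x)
    alpha <- if (pleio_sd > 0 || pleio_mean != 0)
      rnorm(j, pleio_mean, pleio_sd) else rep(pleio_mean, j)
    b_y <- rnorm(j, theta * bx_true + alpha, s_y)
    hs <- harmonised_set(sprintf("iv%03d", seq_len(j)), b_x, s_x, b_y,
                         s_y, exposure_label = "sim_exposure",
                         outcome_label = "sim_outcome",
                         outcome_type = "case-control")
    truth <- new_sim_truth("mr_instruments",
                           list(theta = theta, pleio_mean = pleio_mean,
                                pleio_sd = pleio_sd, bx_true = bx_true,
                                alpha = alpha, n_exp = n_exp,
                                n_out = n_out, seed = seed))
    list(hs = hs, truth = truth)
  })
}

#' Simulate regional multi-trait summary statistics under AR(1) LD
#'
#' LD follows `r_ij = rho^|i-j|`; the marginal z-score means are the
#' causal (joint) noncentralities propagated through LD
#' (`mu = R %*% z_causal` with `z_causal = beta * sqrt(n)` at the causal
#' indices), and observed z-scores are a single MVN(mu, R) draw per
#' trait. Betas and SEs are back-computed as `z / sqrt(n)` and
#' `1 / sqrt(n)`.
#'
#' @param n_snps Variants in the window (default 50).
#' @param rho AR(1) LD decay parameter in \[0, 1).
#' @param causal_config Named list (one element per trait), each a list
#'   with `causal` (integer indices, possibly empty) and `beta`
#'   (per-causal standardised effects).
#' @param n_per_trait Per-trait sample sizes (scalar recycled).
#' @param trait_types Per-trait types (recycled; default quantitative).
#' @param seed RNG seed.
#' @return List with `region` (a `regional_dataset`) and `truth`.
#' @export
simulate_coloc_region <- function(n_snps = 50, rho = 0.9,
                                  causal_config = list(
                                    t1 = list(causal = 25, beta = 0.05),
                                    t2 = list(causal = 25, beta = 0.05)),
                                  n_per_trait = 10000,
                                  trait_types = "quantitative",
                                  seed = 1) {
  stopifnot(rho >= 0, rho < 1)
  k <- length(causal_config)
  n_per_trait <- rep_len(n_per_trait, k)
  trait_types <- rep_len(trait_types, k)
  R <- rho^abs(outer(seq_len(n_snps), seq_len(n_snps), "-"))
  ids <- sprintf("snp%03d", seq_len(n_snps))
  cholR <- chol(R + diag(1e-10, n_snps))
  withr_seed(seed, {
    traits <- list()
    for (t in seq_len(k)) {
      cfg <- causal_config[[t]]
      if (any(cfg$causal > n_snps))
        stop2("simulate_coloc_region: causal index exceeds n_snps")
      zc <- numeric(n_snps)
      if (length(cfg$causal) > 0)
        zc[cfg$causal] <- cfg$beta * sqrt(n_per_trait[t])
      mu <- drop(R %*% zc)
      z <- mu + drop(crossprod(cholR, rnorm(n_snps)))
      se <- rep(1 / sqrt(n_per_trait[t]), n_snps)
      traits[[names(causal_config)[t] %||% paste0("t", t)]] <-
        list(beta = z * se, se = se, z = z, trait_type = trait_types[t],
             scale_param = if (trait_types[t] == "case-control") 0.34 else 1)
    }
    region <- regional_dataset(list(chrom = "1", start = 1,
                                    end = n_snps * 2000),
                               ld_matrix(R, ids), traits,
                               positions = seq_len(n_snps) * 2000L)
    truth <- new_sim_truth("coloc_region",
                           list(rho = rho, causal_config = causal_config,
                                n_per_trait = n_per_trait, seed = seed))
    list(region = region, truth = truth)
  })
}

#' Simulate paired genome-wide z-scores under the LDSC polygenic model
#'
#' Per-SNP z-score pairs are drawn from the bivariate normal implied by
#' the LD-score regression model:
#' `var(z_t) = 1 + N_t h2_t l_j / M`,
#' `cov(z_1, z_2) = rg sqrt(h2_1 h2_2 N_1 N_2) l_j / M + overlap`, where
#' the overlap term is `(n_overlap / sqrt(N_1 N_2)) * rho_pheno` with the
#' phenotypic correlation of overlapping samples approximated by the
#' genetic covariance `rg sqrt(h2_1 h2_2)`.
#'
#' @param m Number of SNPs (default 20000).
#' @param ld_scores Optional per-SNP LD scores (>= 1); generated as
#'   `1 + Exp(mean 50)` when `NULL`.
#' @param h2_1,h2_2 True heritabilities in \[0, 1\].
#' @param rg True genetic correlation in \[-1, 1\].
#' @param n1,n2 Sample sizes.
#' @param n_overlap Overlapping samples (default 0).
#' @param seed RNG seed.
#' @return List with `z1`, `z2`, `ld` (an `ld_score_table`) and `truth`.
#' @export
simulate_ldsc_traits <- function(m = 20000, ld_scores = NULL, h2_1 = 0.1,
                                 h2_2 = 0.1, rg = 0, n1 = 50000,
                                 n2 = 50000, n_overlap = 0, seed = 1) {
  stopifnot(abs(rg) <= 1, h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1)
  withr_seed(seed, {
    l <- ld_scores %||% (1 + stats::rexp(m, rate = 1 / 50))
    m <- length(l)
    v1 <- 1 + n1 * h2_1 * l / m
    v2 <- 1 + n2 * h2_2 * l / m
    rho_pheno <- rg * sqrt(h2_1 * h2_2)
    cv <- rg * sqrt(h2_1 * h2_2 * n1 * n2) * l / m +
      n_overlap / sqrt(n1 * n2) * rho_pheno
    cv <- sign(cv) * pmin(abs(cv), sqrt(v1 * v2) * 0.999)
    e1 <- rnorm(m); e2 <- rnorm(m)
    z1 <- sqrt(v1) * e1
    z2 <- cv / sqrt(v1) * e1 + sqrt(pmax(v2 - cv^2 / v1, 1e-12)) * e2
    ld <- ld_score_table(sprintf("snp%06d", seq_len(m)), l,
                         chrom = rep("1", m), pos = seq_len(m))
    truth <- new_sim_truth("ldsc_traits",
                           list(h2_1 = h2_1, h2_2 = h2_2, rg = rg,
                                n1 = n1, n2 = n2, n_overlap = n_overlap,
                                m = m, seed = seed))
    list(z1 = z1, z2 = z2, ld = ld, truth = truth)
  })
}

#' Simulate a tumour cohort with a genotype-driven expression factor
#'
#' Generates allele dosages, a latent genetic telomere-length score, five
#' latent expression factors (the second carrying the planted PRS effect
#' plus demographic covariate effects, all scaled so the factor has
#' approximately unit variance), and negative-binomial gene counts
#' `NB(exp(baseline_g + Lambda_g . F_s + log depth_s), 1/dispersion)`.
#' Factors load on disjoint gene modules with decreasing loading
#' magnitude so an expression PCA recovers them in order. Covariates:
#' sex ~ Bernoulli(0.5), age ~ N(65, 9^2), smoking ~ Bernoulli(0.75),
#' stage ~ {1..4} with decreasing frequency.
#'
#' @param n_samples Cohort size (default 343, a realistic adenocarcinoma
#'   cohort).
#' @param n_genes Genes (default 2000).
#' @param n_variants PRS variants (default 144).
#' @param prs_effect Planted effect of the standardised genetic score on
#'   factor 2, per SD (default 0.17).
#' @param n_factors Latent factors (default 5, max 5).
#' @param covariate_effects Named vector of effects of (standardised)
#'   sex/age/smoking/stage on factor 2; defaults
#'   `c(sex = 0.15, age = 0.10, smoking = -0.15, stage = -0.10)`.
#' @param nb_dispersion Negative-binomial dispersion (default 0.3).
#' @param loading_scale Base loading magnitude (default 0.55).
#' @param seed RNG seed.
#' @return List with `genotypes` (samples x variants dosage matrix),
#'   `weights` (per-variant PRS weights), `covariates` (data.frame),
#'   `em` (an `expression_matrix`) and `truth` (factors, loadings,
#'   module assignments, planted effects).
#' @export
simulate_tumour_cohort <- function(n_samples = 343, n_genes = 2000,
                                   n_variants = 144, prs_effect = 0.17,
                                   n_factors = 5,
                                   covariate_effects = c(sex = 0.15,
                                                         age = 0.10,
                                                         smoking = -0.15,
                                                         stage = -0.10),
                                   nb_dispersion = 0.3,
                                   loading_scale = 0.7, seed = 1) {
  stopifnot(n_factors <= 5, n_factors >= 2)
  withr_seed(seed, {
    sample_ids <- sprintf("S%04d", seq_len(n_samples))
    variant_ids <- sprintf("rs%05d", seq_len(n_variants))
    freq <- runif(n_variants, 0.1, 0.9)
    G <- vapply(freq, function(f) rbinom(n_samples, 2, f),
                numeric(n_samples))
    dimnames(G) <- list(sample_ids, variant_ids)
    w <- rnorm(n_variants, 0, 0.05)
    names(w) <- variant_ids
    gscore <- drop(G %*% w)
    gscore_std <- (gscore - mean(gscore)) / sd(gscore)

    sex <- rbinom(n_samples, 1, 0.5)
    age <- rnorm(n_samples, 65, 9)
    smoking <- rbinom(n_samples, 1, 0.75)
    stage <- sample(1:4, n_samples, replace = TRUE,
                    prob = c(0.5, 0.25, 0.15, 0.1))
    covs_std <- cbind(sex = (sex - mean(sex)) / sd(sex),
                      age = (age - mean(age)) / sd(age),
                      smoking = (smoking - mean(smoking)) / sd(smoking),
                      stage = (stage - mean(stage)) / sd(stage))
    ce <- covariate_effects[colnames(covs_std)]
    ce[is.na(ce)] <- 0
    lin2 <- prs_effect * gscore_std + drop(covs_std %*% ce)
    resid_var <- max(0.1, 1 - prs_effect^2 - sum(ce^2))
    FF <- matrix(rnorm(n_samples * n_factors), n_samples, n_factors)
    FF[, 2] <- lin2 + sqrt(resid_var) * rnorm(n_samples)

    # disjoint gene modules, decreasing loading magnitude by factor
    module <- sample(rep_len(c(seq_len(n_factors), 0), n_genes))
    mag <- loading_scale * c(1.5, 1.25, 1.0, 0.85, 0.7)[seq_len(n_factors)]
    Lambda <- matrix(0, n_genes, n_factors)
    for (f in seq_len(n_factors)) {
      g <- which(module == f)
      Lambda[g, f] <- rnorm(length(g), mag[f], 0.15 * mag[f]) *
        sample(c(-1, 1), length(g), replace = TRUE, prob = c(0.3, 0.7))
    }
    baseline <- rnorm(n_genes, log(250), 1.2)
    depth <- exp(rnorm(n_samples, 0, 0.25))
    eta <- outer(baseline, log(depth), "+") + Lambda %*% t(FF)
    mu <- exp(eta)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                     n_genes, n_samples)
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    dimnames(counts) <- list(gene_ids, sample_ids)
    meta <- data.frame(gene_id = gene_ids,
                       length = round(exp(rnorm(n_genes, 7.5, 0.6))),
                       gc = runif(n_genes, 0.35, 0.65))
    em <- expression_matrix(counts, meta)
    covariates <- data.frame(sex = sex, age = age, smoking = smoking,
                             stage = stage, row.names = sample_ids)
    truth <- new_sim_truth("tumour_cohort",
                           list(prs_effect = prs_effect,
                                covariate_effects = ce,
                                factors = FF, loadings = Lambda,
                                module = module,
                                gscore_std = gscore_std,
                                weights = w, freq = freq,
                                nb_dispersion = nb_dispersion,
                                seed = seed))
    list(genotypes = G, weights = w, covariates = covariates, em = em,
         truth = truth)
  })
}
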