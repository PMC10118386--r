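# Shared fixture builders. Everything is generated in code; no binary or
# bundled data.

toy_records <- function(n = 5, chrom = "5", start_pos = 1e6, step = 1000,
                        beta = NULL, se = NULL, pval = NULL, eaf = NULL,
                        effect_allele = "A", other_allele = "G") {
  data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)),
    chrom = chrom,
    pos = start_pos + (seq_len(n) - 1) * step,
    effect_allele = rep_len(effect_allele, n),
    other_allele = rep_len(other_allele, n),
    eaf = eaf %||% rep(0.3, n),
    beta = beta %||% seq(0.1, by = 0.05, length.out = n),
    se = se %||% rep(0.02, n),
    pval = pval %||% rep(1e-10, n),
    n = 10000,
    stringsAsFactors = FALSE
  )
}

toy_sumstats <- function(n = 5, trait_label = "toy", ...) {
  summary_stats(toy_records(n, ...), trait_label = trait_label)
}

identity_ld <- function(ids) ld_matrix(diag(length(ids)), ids)

ar1_ld <- function(ids, rho = 0.8) {
  n <- length(ids)
  ld_matrix(rho^abs(outer(seq_len(n), seq_len(n), "-")), ids)
}

write_tsv_tmp <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent brute-force enumeration of the coloc posteriors: loops over
# every (causal SNP for trait 1) x (causal SNP for trait 2) configuration
enum_coloc_oracle <- function(labf1, labf2, p1, p2, p12) {
  n <- length(labf1)
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  s0 <- 1
  s1 <- sum(p1 * bf1)
  s2 <- sum(p2 * bf2)
  s3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) s3 <- s3 + p1 * bf1[i] * p2 * bf2[j]
  s4 <- sum(p12 * bf1 * bf2)
  tot <- s0 + s1 + s2 + s3 + s4
  c(PP0 = s0, PP1 = s1, PP2 = s2, PP3 = s3, PP4 = s4) / tot
}

# random small region for property tests (quantitative traits, sdY = 1)
random_small_region <- function(n_snps, seed) {
  withr_local_seed(seed)
  ids <- sprintf("s%02d", seq_len(n_snps))
  rho <- runif(1, 0, 0.9)
  R <- rho^abs(outer(seq_len(n_snps), seq_len(n_snps), "-"))
  mk_trait <- function() {
    se <- runif(n_snps, 0.01, 0.2)
    beta <- rnorm(n_snps, 0, 0.1)
    list(beta = beta, se = se, trait_type = "quantitative",
         scale_param = 1)
  }
  regional_dataset(list("1", 1, n_snps * 1000),
                   ld_matrix(R, ids),
                   list(t1 = mk_trait(), t2 = mk_trait()),
                   positions = seq_len(n_snps) * 1000L)
}

withr_local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
}
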