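# instruments: instrument selection by p-value clumping, exposure/outcome
# harmonisation with proxy substitution, polygenic risk scoring, and
# asymptotic MR power for binary outcomes.

#' Construct a harmonised exposure/outcome instrument set
#'
#' The working object of every two-sample MR estimator: exposure and
#' outcome effects aligned to a common effect allele per instrument.
#'
#' @param variant_ids Character vector of instrument ids.
#' @param b_x,s_x Exposure betas and standard errors.
#' @param b_y,s_y Outcome betas and standard errors (log-OR scale for
#'   case-control outcomes).
#' @param exposure_label,outcome_label Trait labels.
#' @param proxy_map Named character vector recording proxy substitutions
#'   (target id -> proxy id used).
#' @param outcome_type `"quantitative"` or `"case-control"`; when
#'   case-control, causal estimates are reported as ORs by exponentiation.
#' @return An object of class `harmonised_set`.
#' @export
harmonised_set <- function(variant_ids, b_x, s_x, b_y, s_y,
                           exposure_label = "exposure",
                           outcome_label = "outcome",
                           proxy_map = character(),
                           outcome_type = "case-control") {
  n <- length(variant_ids)
  stopifnot(n >= 1, length(b_x) == n, length(s_x) == n, length(b_y) == n,
            length(s_y) == n)
  if (any(s_x <= 0) || any(s_y <= 0))
    stop2("harmonised_set: standard errors must be positive")
  structure(list(variant_ids = as.character(variant_ids),
                 b_x = as.numeric(b_x), s_x = as.numeric(s_x),
                 b_y = as.numeric(b_y), s_y = as.numeric(s_y),
                 exposure_label = exposure_label,
                 outcome_label = outcome_label,
                 proxy_map = proxy_map,
                 outcome_type = outcome_type),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("<harmonised_set> %s -> %s: %d instruments (%d proxied)\n",
              x$exposure_label, x$outcome_label, length(x$variant_ids),
              length(x$proxy_map)))
  invisible(x)
}

#' Select independent genetic instruments by greedy clumping
#'
#' Candidates are variants with `pval < p_thresh` and minor allele
#' frequency `min(eaf, 1 - eaf) >= maf_min`. Candidates are visited in
#' ascending p-value order (ties broken lexicographically by variant id
#' for determinism) and accepted iff their squared LD correlation with
#' every already-accepted variant is below `r2_thresh`. Defaults mirror
#' standard practice for a telomere-length instrument: genome-wide
#' significance, r-squared < 0.01, MAF > 1%.
#'
#' @param ss A `summary_stats` for the exposure; `eaf` must be present for
#'   all candidates.
#' @param ld An `ld_matrix` with signed correlations covering every
#'   candidate pair.
#' @param p_thresh P-value threshold (default 5e-8).
#' @param r2_thresh Squared-correlation independence threshold (default
#'   0.01).
#' @param maf_min Minor-allele-frequency floor (default 0.01).
#' @return Character vector of selected variant ids, in acceptance order.
#' @export
select_instruments <- function(ss, ld, p_thresh = 5e-8, r2_thresh = 0.01,
                               maf_min = 0.01) {
  stopifnot(inherits(ss, "summary_stats"), inherits(ld, "ld_matrix"))
  rec <- ss$records
  if (anyNA(rec$eaf))
    stop2("select_instruments: eaf required for all candidate variants")
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  cand <- rec[rec$pval < p_thresh & maf >= maf_min, , drop = FALSE]
  if (nrow(cand) == 0) return(character())
  cand <- cand[order(cand$pval, cand$variant_id), , drop = FALSE]
  missing_ld <- setdiff(cand$variant_id, ld$variant_ids)
  if (length(missing_ld) > 0)
    stop2("select_instruments: LD matrix lacks candidate variant(s): ",
          paste(head(missing_ld, 5), collapse = ", "))
  accepted <- character()
  for (v in cand$variant_id) {
    if (length(accepted) == 0 ||
        all(ld$r[v, accepted]^2 < r2_thresh))
      accepted <- c(accepted, v)
  }
  accepted
}

#' Harmonise exposure and outcome effects for a set of instruments
#'
#' Aligns outcome betas to the exposure effect allele: sign flip (and EAF
#' complement) when the outcome lists the allele pair swapped.
#' Strand-ambiguous palindromic variants (A/T or C/G) are dropped when MAF
#' exceeds `palindrome_maf` in either trait, otherwise aligned by
#' frequency. Instruments absent from the outcome are replaced by their
#' highest-r-squared LD proxy above `proxy_r2` when an LD matrix is
#' supplied; the signed correlation orients the proxy's effect. All drops
#' are itemised in the attached report.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param variants Instrument ids selected from the exposure.
#' @param ld Optional `ld_matrix` (signed r) used for proxy lookup.
#' @param proxy_r2 Minimum squared correlation for a proxy (default 0.8).
#' @param palindrome_maf MAF above which palindromic variants are deemed
#'   unresolvable (default 0.3).
#' @return A `harmonised_set`; attribute `report` details drops and
#'   proxies.
#' @export
harmonise_pair <- function(exposure, outcome, variants, ld = NULL,
                           proxy_r2 = 0.8, palindrome_maf = 0.3) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  exp_rec <- exposure$records
  out_rec <- outcome$records
  variants <- intersect(variants, exp_rec$variant_id)
  if (length(variants) == 0) stop2("harmonise_pair: no instruments found")

  is_palin <- function(a1, a2) {
    p <- paste0(a1, a2)
    p %in% c("AT", "TA", "CG", "GC")
  }
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  flip_strand <- function(a) unname(comp[a])

  ids <- character(); bx <- sx <- by <- sy <- numeric()
  proxy_map <- character()
  dropped <- list(palindromic = character(), allele_mismatch = character(),
                  missing_no_proxy = character())

  for (v in variants) {
    ei <- match(v, exp_rec$variant_id)
    e_ea <- exp_rec$effect_allele[ei]; e_oa <- exp_rec$other_allele[ei]
    target <- v
    oi <- match(v, out_rec$variant_id)
    used_proxy <- NA_character_
    proxy_sign <- 1
    if (is.na(oi) && !is.null(ld) && v %in% ld$variant_ids) {
      # proxy lookup: best-correlated outcome variant above the threshold
      cand <- intersect(ld$variant_ids, out_rec$variant_id)
      cand <- setdiff(cand, v)
      if (length(cand) > 0) {
        rr <- ld$r[v, cand]
        best <- cand[which.max(rr^2)]
        if (max(rr^2) > proxy_r2) {
          used_proxy <- best
          proxy_sign <- sign(ld$r[v, best])
          oi <- match(best, out_rec$variant_id)
          target <- best
        }
      }
    }
    if (is.na(oi)) {
      dropped$missing_no_proxy <- c(dropped$missing_no_proxy, v)
      next
    }
    o_ea <- out_rec$effect_allele[oi]; o_oa <- out_rec$other_allele[oi]
    b_out <- out_rec$beta[oi]

    if (!is.na(used_proxy)) {
      # proxy alleles are oriented through the signed LD correlation:
      # positive r means the proxy effect allele tags the target effect
      # allele (frequency-matched coding assumed for the panel)
      b_al <- proxy_sign * b_out
    } else if (is_palin(e_ea, e_oa)) {
      maf_e <- min(exp_rec$eaf[ei], 1 - exp_rec$eaf[ei])
      maf_o <- if (is.na(out_rec$eaf[oi])) NA
               else min(out_rec$eaf[oi], 1 - out_rec$eaf[oi])
      if (is.na(maf_e) || is.na(maf_o) || maf_e > palindrome_maf ||
          maf_o > palindrome_maf) {
        dropped$palindromic <- c(dropped$palindromic, v)
        next
      }
      # align by frequency: minor allele tags minor allele
      e_minor_is_ea <- exp_rec$eaf[ei] < 0.5
      o_minor_is_ea <- out_rec$eaf[oi] < 0.5
      b_al <- if (e_minor_is_ea == o_minor_is_ea) b_out else -b_out
    } else if (o_ea == e_ea && o_oa == e_oa) {
      b_al <- b_out
    } else if (o_ea == e_oa && o_oa == e_ea) {
      b_al <- -b_out
    } else if (o_ea == flip_strand(e_ea) && o_oa == flip_strand(e_oa)) {
      b_al <- b_out
    } else if (o_ea == flip_strand(e_oa) && o_oa == flip_strand(e_ea)) {
      b_al <- -b_out
    } else {
      dropped$allele_mismatch <- c(dropped$allele_mismatch, v)
      next
    }
    ids <- c(ids, v)
    bx <- c(bx, exp_rec$beta[ei]); sx <- c(sx, exp_rec$se[ei])
    by <- c(by, b_al); sy <- c(sy, out_rec$se[oi])
    if (!is.na(used_proxy)) proxy_map[v] <- used_proxy
  }
  if (length(ids) == 0)
    stop2("harmonise_pair: no instruments survive harmonisation")
  hs <- harmonised_set(ids, bx, sx, by, sy,
                       exposure_label = exposure$trait_label,
                       outcome_label = outcome$trait_label,
                       proxy_map = proxy_map,
                       outcome_type = outcome$trait_type)
  attr(hs, "report") <- dropped
  hs
}

#' Polygenic risk score from dosages and per-variant weights
#'
#' `raw_score_i = sum_j w_j g_ij` over the overlap of weight and genotype
#' variants, with missing dosages mean-imputed per variant (standard PRS
#' software behaviour). The standardised score is centred and scaled to
#' unit SD over the cohort.
#'
#' @param genotypes Numeric matrix samples x variants of allele dosages in
#'   \[0, 2\], with variant ids as column names and sample ids as row
#'   names.
#' @param weights Named numeric vector of betas keyed by variant id (each
#'   beta expressed per copy of its effect allele, matching the dosage
#'   coding).
#' @return An object of class `prs_vector` with `sample_ids`, `raw_score`
#'   and `std_score`.
#' @export
compute_prs <- function(genotypes, weights) {
  stopifnot(is.matrix(genotypes), !is.null(colnames(genotypes)))
  shared <- intersect(names(weights), colnames(genotypes))
  if (length(shared) == 0)
    stop2("compute_prs: no overlap between weight and genotype variants")
  g <- genotypes[, shared, drop = FALSE]
  rng <- range(g, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop2("compute_prs: dosages must lie in [0, 2]")
  for (j in seq_len(ncol(g))) {
    mj <- is.na(g[, j])
    if (any(mj)) g[mj, j] <- mean(g[, j], na.rm = TRUE)
  }
  raw <- drop(g %*% weights[shared])
  # population-SD standardisation (denominator n), the PRS convention
  s <- sqrt(mean((raw - mean(raw))^2))
  if (!is.finite(s) || s == 0)
    stop2("compute_prs: raw scores have zero variance; cannot standardise")
  std <- (raw - mean(raw)) / s
  structure(list(sample_ids = rownames(genotypes) %||%
                   as.character(seq_len(nrow(genotypes))),
                 raw_score = unname(raw), std_score = unname(std),
                 n_variants = length(shared)),
            class = "prs_vector")
}

#' @export
print.prs_vector <- function(x, ...) {
  cat(sprintf("<prs_vector> %d samples, %d variants\n",
              length(x$raw_score), x$n_variants))
  invisible(x)
}

#' Asymptotic power of a two-sample MR test with a binary outcome
#'
#' Two-sided Wald-test power
#' `Phi(sqrt(N * r2_x * phi * (1 - phi)) * |log OR| - z_(1 - alpha/2))`
#' where `phi` is the case fraction, `N = n_cases + n_controls` and `r2_x`
#' the variance in the exposure explained by the instrument. At OR = 1
#' this returns approximately `alpha / 2` (one tail of the false-positive
#' rate); the full two-sided rejection rate adds the symmetric tail, which
#' is negligible away from the null.
#'
#' @param n_cases,n_controls Outcome GWAS counts.
#' @param r2_x Fraction of exposure variance explained by the instrument,
#'   in (0, 1).
#' @param odds_ratio Causal OR per SD of exposure (> 0).
#' @param alpha Two-sided type-1 error rate (default 0.05).
#' @return Power as a fraction in (0, 1).
#' @export
mr_power <- function(n_cases, n_controls, r2_x, odds_ratio, alpha = 0.05) {
  stopifnot(r2_x > 0, r2_x < 1, odds_ratio > 0, alpha > 0, alpha < 1)
  n <- n_cases + n_controls
  phi <- n_cases / n
  ncp <- sqrt(n * r2_x * phi * (1 - phi)) * abs(log(odds_ratio))
  zc <- qnorm(1 - alpha / 2)
  # both rejection tails of the two-sided Wald test
  pnorm(ncp - zc) + pnorm(-ncp - zc)
}
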