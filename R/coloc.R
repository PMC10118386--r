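# coloc: approximate-Bayes-factor colocalisation under the single-causal-
# variant assumption, approximate conditioning/masking for secondary
# signals, PP4 averaging across method runs, and a simplified divisive
# multi-trait clustering.

#' Wakefield log approximate Bayes factor
#'
#' For a variant with estimate `beta`, standard error `se` and a
#' `N(0, W)` effect prior with `sqrt(W) = prior_sd`: with
#' `r = W / (W + se^2)` and `z = beta / se`,
#' `lABF = 0.5 log(1 - r) + 0.5 r z^2`. Vectorised over variants.
#'
#' @param beta,se Effect estimates and positive SEs.
#' @param prior_sd Prior standard deviation of a true effect (default
#'   0.15, the conventional choice for a standardised quantitative trait;
#'   use 0.2 on the log-OR scale for case-control traits).
#' @return Numeric vector of log approximate Bayes factors.
#' @export
wakefield_labf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop2("wakefield_labf: se must be positive")
  W <- prior_sd^2
  r <- W / (W + se^2)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * r * z^2
}

# per-trait lABF vector using the trait's type/scale to pick prior_sd
trait_labf <- function(trait) {
  prior_sd <- if (trait$trait_type == "case-control") 0.2
              else 0.15 * (trait$scale_param %||% 1)
  wakefield_labf(trait$beta, trait$se, prior_sd)
}

#' Construct a colocalisation result
#'
#' @param pp Named numeric vector `PP0..PP4`, non-negative, summing to 1
#'   within 1e-8.
#' @param method Run label (e.g. `"single"`, `"cond:rs123|single"`).
#' @param lead_pair Character pair: top-ABF variant per trait.
#' @param n_snps Number of shared variants used.
#' @param priors Named vector `(p1, p2, p12)`.
#' @return An object of class `coloc_result`.
#' @export
coloc_result <- function(pp, method, lead_pair, n_snps, priors) {
  stopifnot(length(pp) == 5, all(pp >= -1e-12),
            abs(sum(pp) - 1) <= 1e-8)
  pp <- pmax(pp, 0)
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, method = method, lead_pair = lead_pair,
                 n_snps = n_snps, priors = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s (%d SNPs): %s\n", x$method, x$n_snps,
              paste(sprintf("%s=%.3f", names(x$pp), x$pp),
                    collapse = " ")))
  invisible(x)
}

#' Pairwise colocalisation by approximate Bayes factors
#'
#' Standard single-causal-variant enumeration over the five hypotheses
#' (H0 no association, H1/H2 one trait only, H3 two distinct causal
#' variants, H4 one shared causal variant), with per-SNP priors `p1`,
#' `p2`, `p12`. Defaults are the conventional conservative choice
#' (1e-3, 1e-4, 1e-5). All sums are taken in log space.
#'
#' @param region A `regional_dataset` with at least 2 variants.
#' @param trait1,trait2 Names of the two traits in `region$traits`.
#' @param p1,p2,p12 Per-SNP priors for association with trait 1 only,
#'   trait 2 only, and both.
#' @return A `coloc_result`.
#' @export
coloc_abf <- function(region, trait1, trait2,
                      p1 = 1e-3, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(inherits(region, "regional_dataset"))
  t1 <- region$traits[[trait1]]; t2 <- region$traits[[trait2]]
  if (is.null(t1) || is.null(t2))
    stop2("coloc_abf: trait not found in region")
  if (anyNA(t1$se) || anyNA(t2$se))
    stop2("coloc_abf: missing standard errors")
  n <- length(t1$beta)
  if (n < 2) stop2("coloc_abf: needs >= 2 shared variants")
  l1 <- trait_labf(t1)
  l2 <- trait_labf(t2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)          # same SNP causal for both
  # sum over ordered pairs i != j = (sum_i)(sum_j) - sum_i both
  scross <- if (s1 + s2 > s12) logdiffexp(s1 + s2, s12) else -Inf
  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + scross,
          H4 = log(p12) + s12)
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  ids <- region$ld$variant_ids
  coloc_result(pp, method = "single",
               lead_pair = c(ids[which.max(l1)], ids[which.max(l2)]),
               n_snps = n, priors = c(p1 = p1, p2 = p2, p12 = p12))
}

#' Approximate conditional summary statistics within a region
#'
#' Adjusts one trait's z-scores for a conditioning variant using the
#' signed LD correlation `r_c`:
#' `z_cond = (z - r_c z_c) / sqrt(1 - r_c^2)`, with the conditioning
#' variant's own conditional z set to 0 and betas rescaled as
#' `z_cond * se`. Variants in near-perfect LD with the conditioning
#' variant (|r_c| >= 0.99, other than itself) cannot be separated from it
#' and are removed from the returned dataset (all traits), itemised in
#' the `masked` attribute.
#'
#' @param region A `regional_dataset`.
#' @param trait Name of the trait to condition.
#' @param condition_on variant_id of the conditioning variant.
#' @param ridge Ridge added to the LD diagonal for the conditioning
#'   check (default 1e-4).
#' @return A `regional_dataset` with the trait's statistics replaced by
#'   conditional ones.
#' @export
conditional_sumstats <- function(region, trait, condition_on,
                                 ridge = 1e-4) {
  stopifnot(inherits(region, "regional_dataset"))
  ids <- region$ld$variant_ids
  if (!condition_on %in% ids)
    stop2("conditional_sumstats: ", condition_on, " not in region")
  if (is.null(region$traits[[trait]]))
    stop2("conditional_sumstats: trait not found")
  R <- region$ld$r + diag(ridge, length(ids))
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-6)
    stop2("conditional_sumstats: LD matrix ill-conditioned (min eigenvalue ",
          format(ev_min), ")")
  rc <- unname(region$ld$r[, condition_on])
  ci <- match(condition_on, ids)
  masked <- ids[abs(rc) >= 0.99 & seq_along(ids) != ci]
  keep <- !(ids %in% masked)

  tr <- region$traits[[trait]]
  zc <- tr$z[ci]
  z_new <- (tr$z - rc * zc) / sqrt(pmax(1 - rc^2, .Machine$double.eps))
  z_new[ci] <- 0
  tr$z <- z_new
  tr$beta <- z_new * tr$se
  traits <- region$traits
  traits[[trait]] <- tr

  ids_k <- ids[keep]
  traits_k <- lapply(traits, function(t)
    list(beta = t$beta[keep], se = t$se[keep], z = t$z[keep],
         trait_type = t$trait_type, scale_param = t$scale_param))
  out <- regional_dataset(region$window,
                          ld_matrix(region$ld$r[ids_k, ids_k, drop = FALSE],
                                    ids_k),
                          traits_k,
                          positions = region$positions[keep])
  attr(out, "masked") <- masked
  attr(out, "conditioned_on") <- c(attr(region, "conditioned_on"),
                                   condition_on)
  out
}

# stepwise signal detection for one trait: lead |z|, condition, repeat
# while the conditional lead stays below p_thresh, up to max_signals
detect_signals <- function(region, trait, p_thresh = 1e-5,
                           max_signals = 3) {
  leads <- character()
  cur <- region
  for (i in seq_len(max_signals)) {
    tr <- cur$traits[[trait]]
    j <- which.max(abs(tr$z))
    p <- 2 * pnorm(-abs(tr$z[j]))
    if (p >= p_thresh) break
    lead <- cur$ld$variant_ids[j]
    leads <- c(leads, lead)
    cur <- conditional_sumstats(cur, trait, lead)
  }
  leads
}

# build per-trait analysis views: unadjusted, conditioned to isolate each
# signal, and masked versions removing LD partners of the other signals
trait_views <- function(region, trait, signals, r2_mask) {
  views <- list(list(region = region, label = "single"))
  if (length(signals) < 2) return(views)
  ids <- region$ld$variant_ids
  for (i in seq_along(signals)) {
    others <- signals[-i]
    # conditioning view: adjust for every other signal
    reg_c <- region
    ok <- TRUE
    for (s in others) {
      if (!s %in% reg_c$ld$variant_ids) { ok <- FALSE; break }
      reg_c <- tryCatch(conditional_sumstats(reg_c, trait, s),
                        error = function(e) NULL)
      if (is.null(reg_c)) { ok <- FALSE; break }
    }
    if (ok)
      views[[length(views) + 1]] <-
        list(region = reg_c,
             label = paste0("cond[", trait, ":", signals[i], "]"))
    # masking view: drop variants tagging the other signals
    r2o <- apply(region$ld$r[, others, drop = FALSE]^2, 1, max)
    keep <- r2o <= r2_mask | ids %in% signals[i]
    if (sum(keep) >= 2) {
      ids_k <- ids[keep]
      traits_k <- lapply(region$traits, function(t)
        list(beta = t$beta[keep], se = t$se[keep], z = t$z[keep],
             trait_type = t$trait_type, scale_param = t$scale_param))
      reg_m <- regional_dataset(region$window,
                                ld_matrix(region$ld$r[ids_k, ids_k,
                                                      drop = FALSE], ids_k),
                                traits_k,
                                positions = region$positions[keep])
      views[[length(views) + 1]] <-
        list(region = reg_m,
             label = paste0("mask[", trait, ":", signals[i], "]"))
    }
  }
  views
}

#' Colocalisation averaged over conditioning/masking runs
#'
#' Detects up to `max_signals` independent signals per trait by stepwise
#' conditioning (a signal is declared while the conditional lead p-value
#' stays below `signal_p`), builds per-trait views (unadjusted;
#' conditioned to isolate each signal; masked of LD partners of the other
#' signals at r-squared > `r2_mask`), runs [coloc_abf()] on every pair of
#' views, and reports the unweighted mean PP4 over all runs as the
#' posterior belief in colocalisation. Single-signal regions degenerate
#' to a plain [coloc_abf()] run.
#'
#' @param region A `regional_dataset`.
#' @param trait1,trait2 Trait names.
#' @param max_signals Maximum signals per trait (default 3).
#' @param r2_mask Masking r-squared threshold (default 0.01).
#' @param p1,p2,p12 Colocalisation priors.
#' @param signal_p Conditional p-value below which a signal is declared
#'   (default 1e-5).
#' @return List with `avg_pp4`, `runs` (list of `coloc_result`), and the
#'   detected `signals` per trait.
#' @export
coloc_condmask_average <- function(region, trait1, trait2,
                                   max_signals = 3, r2_mask = 0.01,
                                   p1 = 1e-3, p2 = 1e-4, p12 = 1e-5,
                                   signal_p = 1e-5) {
  stopifnot(max_signals >= 1)
  sig1 <- detect_signals(region, trait1, signal_p, max_signals)
  sig2 <- detect_signals(region, trait2, signal_p, max_signals)
  v1 <- trait_views(region, trait1, sig1, r2_mask)
  v2 <- trait_views(region, trait2, sig2, r2_mask)
  runs <- list()
  for (a in v1) for (b in v2) {
    # when both views modify the region, intersect their variant sets
    reg <- a$region
    if (!identical(b$label, "single")) {
      if (identical(a$label, "single")) {
        reg <- b$region
      } else {
        shared <- intersect(a$region$ld$variant_ids,
                            b$region$ld$variant_ids)
        if (length(shared) < 2) next
        ai <- match(shared, a$region$ld$variant_ids)
        bi <- match(shared, b$region$ld$variant_ids)
        traits <- a$region$traits
        traits[[trait2]] <- lapply(b$region$traits[[trait2]],
                                   function(x) x)
        traits <- list()
        traits[[trait1]] <- subset_trait(a$region$traits[[trait1]], ai)
        traits[[trait2]] <- subset_trait(b$region$traits[[trait2]], bi)
        reg <- regional_dataset(region$window,
                                ld_matrix(region$ld$r[shared, shared,
                                                      drop = FALSE],
                                          shared),
                                traits,
                                positions = NULL)
      }
    } else if (identical(a$label, "single")) {
      reg <- region
    }
    res <- tryCatch(coloc_abf(reg, trait1, trait2, p1, p2, p12),
                    error = function(e) NULL)
    if (is.null(res)) next
    res$method <- paste(a$label, b$label, sep = " | ")
    runs[[length(runs) + 1]] <- res
  }
  avg_pp4 <- mean(vapply(runs, function(r) r$pp["PP4"], 0))
  avg_pp <- Reduce(`+`, lapply(runs, function(r) r$pp)) / length(runs)
  list(avg_pp4 = unname(avg_pp4), avg_pp = avg_pp, runs = runs,
       signals = list(sig1, sig2) |> setNames(c(trait1, trait2)))
}

subset_trait <- function(t, idx) {
  list(beta = t$beta[idx], se = t$se[idx], z = t$z[idx],
       trait_type = t$trait_type, scale_param = t$scale_param)
}

#' Simplified multi-trait colocalisation by divisive clustering
#'
#' Computes the posterior that ALL traits in the current set share one
#' causal variant: the shared hypothesis (per SNP, the product of the
#' traits' approximate Bayes factors, summed over SNPs with per-SNP
#' prior `prior_shared`) is weighed against the independence alternative
#' in which each trait is separately null or associated with its own
#' variant at per-SNP prior `prior_single`. While the posterior is below
#' `drop_thresh`, the trait whose removal maximises the posterior is
#' removed greedily; the removed set is then re-clustered the same way.
#' This is a deliberate simplification of full multi-trait clustering
#' algorithms (no regional/alignment factorisation); results carry a
#' `method = "divisive-abf"` marker.
#'
#' @param region A `regional_dataset`.
#' @param traits Trait names (default all in `region`).
#' @param prior_shared Per-SNP prior that one variant is causal for all
#'   traits in the set (default 1e-5, the pairwise p12 convention).
#' @param prior_single Per-SNP prior that a variant is causal for one
#'   trait alone (default 3e-4, the geometric mean of the pairwise
#'   p1/p2 convention, keeping two-trait behaviour close to
#'   [coloc_abf()]).
#' @param drop_thresh Posterior below which the set is split (default
#'   0.7, the conventional evidence cutoff).
#' @return An object of class `multi_coloc_result` with `clusters` (each
#'   a list of `traits`, `posterior`, `candidate_snp`) and
#'   `dropped_traits`.
#' @export
multitrait_coloc <- function(region, traits = names(region$traits),
                             prior_shared = 1e-5, prior_single = 3e-4,
                             drop_thresh = 0.7) {
  stopifnot(length(traits) >= 2)
  labfs <- vapply(traits, function(nm) trait_labf(region$traits[[nm]]),
                  numeric(length(region$ld$variant_ids)))
  colnames(labfs) <- traits
  ids <- region$ld$variant_ids

  lone <- function(t)
    logsumexp(c(0, log(prior_single) + logsumexp(labfs[, t])))
  post_shared <- function(set) {
    tot <- rowSums(labfs[, set, drop = FALSE])
    num <- log(prior_shared) + logsumexp(tot)
    # alternatives: full independence, and every leave-one-out partial
    # sharing (the excluded trait null or on its own variant)
    alts <- sum(vapply(set, lone, 0))
    if (length(set) > 2) {
      alts <- c(alts, vapply(set, function(t) {
        sub <- setdiff(set, t)
        log(prior_shared) +
          logsumexp(rowSums(labfs[, sub, drop = FALSE])) + lone(t)
      }, 0))
    }
    list(post = exp(num - logsumexp(c(num, alts))),
         snp = ids[which.max(tot)])
  }

  clusters <- list()
  dropped <- character()
  carve <- function(set) {
    while (length(set) >= 2) {
      ps <- post_shared(set)
      if (ps$post >= drop_thresh) {
        clusters[[length(clusters) + 1]] <<-
          list(traits = set, posterior = ps$post,
               candidate_snp = ps$snp)
        return(invisible())
      }
      cand_posts <- vapply(set, function(t)
        post_shared(setdiff(set, t))$post, 0)
      worst <- set[which.max(cand_posts)]
      dropped <<- c(dropped, worst)
      set <- setdiff(set, worst)
    }
    if (length(set) == 1) dropped <<- c(dropped, set)
  }
  carve(traits)
  # re-cluster removed traits until no progress is possible
  repeat {
    pool <- setdiff(dropped, unlist(lapply(clusters, `[[`, "traits")))
    if (length(pool) < 2) break
    n_before <- length(clusters)
    dropped <- setdiff(dropped, pool)
    carve(pool)
    if (length(clusters) == n_before) { dropped <- c(dropped, pool); break }
    dropped <- unique(dropped)
  }
  structure(list(clusters = clusters,
                 dropped_traits = setdiff(dropped,
                                          unlist(lapply(clusters, `[[`,
                                                        "traits"))),
                 method = "divisive-abf",
                 prior_shared = prior_shared,
                 drop_thresh = drop_thresh),
            class = "multi_coloc_result")
}

#' @export
print.multi_coloc_result <- function(x, ...) {
  cat("<multi_coloc_result> (divisive-abf)\n")
  for (cl in x$clusters)
    cat(sprintf("  cluster {%s}: posterior %.3f at %s\n",
                paste(cl$traits, collapse = ", "), cl$posterior,
                cl$candidate_snp))
  if (length(x$dropped_traits))
    cat("  dropped:", paste(x$dropped_traits, collapse = ", "), "\n")
  invisible(x)
}
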