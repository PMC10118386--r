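# io_core: tabular/matrix readers and writers plus the shared containers
# (summary statistics, LD matrices, regional datasets) every downstream
# module consumes. Variant identity is by variant_id string throughout;
# coordinates are 1-based inclusive and the genome build is carried as an
# opaque label, never converted.

.SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "pval", "n",
                    "n_cases", "n_controls")
.MANDATORY_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "beta", "se", "pval")

#' Construct a summary-statistics object
#'
#' Container for one trait's per-variant GWAS associations. Records must
#' already satisfy the field invariants (positive SEs, p-values in (0, 1],
#' distinct alleles, unique variant ids); use [read_sumstats()] to filter
#' raw tables.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and optionally
#'   `eaf`, `n`, `n_cases`, `n_controls`.
#' @param trait_label Character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"case-control"`. Case-control
#'   traits must carry `n_cases` and `n_controls`.
#' @param genome_build Opaque build label (e.g. `"GRCh37"`); carried
#'   through, never converted.
#' @param sd_y For quantitative traits, the phenotype standard deviation on
#'   which betas are expressed (used as the colocalisation scale
#'   parameter). Default 1.
#' @return An object of class `summary_stats`.
#' @export
summary_stats <- function(records, trait_label, trait_type = "quantitative",
                          genome_build = "GRCh37", sd_y = 1) {
  trait_type <- match.arg(trait_type, c("quantitative", "case-control"))
  stopifnot(is.data.frame(records))
  miss <- setdiff(.MANDATORY_COLS, names(records))
  if (length(miss) > 0)
    stop2("summary_stats: missing mandatory column(s): ",
          paste(miss, collapse = ", "))
  for (cc in setdiff(.SUMSTATS_COLS, names(records))) records[[cc]] <- NA
  records <- records[, .SUMSTATS_COLS]
  if (anyDuplicated(records$variant_id))
    stop2("summary_stats: duplicate variant_id values")
  if (any(records$se <= 0, na.rm = TRUE) || anyNA(records$se))
    stop2("summary_stats: se must be > 0 for all records")
  if (any(records$pval <= 0 | records$pval > 1))
    stop2("summary_stats: pval must lie in (0, 1]")
  if (any(records$effect_allele == records$other_allele))
    stop2("summary_stats: effect_allele must differ from other_allele")
  if (any(records$pos < 1))
    stop2("summary_stats: pos must be >= 1")
  if (trait_type == "case-control" &&
      (anyNA(records$n_cases) || anyNA(records$n_controls)))
    stop2("summary_stats: case-control traits need n_cases and n_controls")
  records$effect_allele <- toupper(records$effect_allele)
  records$other_allele <- toupper(records$other_allele)
  rownames(records) <- NULL
  structure(list(trait_label = trait_label, trait_type = trait_type,
                 genome_build = genome_build, sd_y = sd_y,
                 records = records),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s' (%s, build %s): %d variants\n",
              x$trait_label, x$trait_type, x$genome_build,
              nrow(x$records)))
  invisible(x)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited table with a header, renames columns
#' through `column_map`, validates every row against the record invariants
#' and drops (with counts) rows that fail. Underflowing p-values (below
#' 1e-300, including literal zeros) are clamped to 1e-300 and flagged
#' rather than dropped.
#'
#' @param path Path to a delimited text file with header.
#' @param column_map Named character vector mapping semantic names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pval`, `n`, `n_cases`, `n_controls`) to the
#'   file's column names. Identity mapping by default.
#' @param trait_label,trait_type,genome_build,sd_y Passed to
#'   [summary_stats()].
#' @param sep Field separator; `NULL` (default) tries tab then comma.
#' @return A `summary_stats` object; the attached `report` attribute lists
#'   input rows, kept rows, per-reason drop counts and the number of
#'   clamped p-values.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = "trait",
                          trait_type = "quantitative",
                          genome_build = "GRCh37", sd_y = 1, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    miss_src <- setdiff(unname(column_map), names(raw))
    if (length(miss_src) > 0)
      stop2("read_sumstats: file lacks mapped column(s): ",
            paste(miss_src, collapse = ", "))
    idx <- match(unname(column_map), names(raw))
    names(raw)[idx] <- names(column_map)
  }
  miss <- setdiff(.MANDATORY_COLS, names(raw))
  if (length(miss) > 0)
    stop2("read_sumstats: missing mandatory column(s): ",
          paste(miss, collapse = ", "))
  for (cc in setdiff(.SUMSTATS_COLS, names(raw))) raw[[cc]] <- NA
  raw <- raw[, .SUMSTATS_COLS]
  num_cols <- c("pos", "eaf", "beta", "se", "pval", "n", "n_cases",
                "n_controls")
  for (cc in num_cols) raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  raw$variant_id <- as.character(raw$variant_id)
  raw$chrom <- as.character(raw$chrom)
  raw$effect_allele <- toupper(as.character(raw$effect_allele))
  raw$other_allele <- toupper(as.character(raw$other_allele))

  n_in <- nrow(raw)
  # p-value underflow policy: clamp, do not drop
  under <- !is.na(raw$pval) & raw$pval >= 0 & raw$pval < .P_FLOOR
  raw$pval[under] <- .P_FLOOR

  drops <- c(bad_se = 0, bad_pval = 0, same_alleles = 0, bad_pos = 0,
             bad_eaf = 0, incomplete = 0, duplicate_id = 0)
  ok_core <- !is.na(raw$variant_id) & !is.na(raw$beta) & !is.na(raw$se) &
    !is.na(raw$pval) & !is.na(raw$pos) & nzchar(raw$effect_allele) &
    nzchar(raw$other_allele)
  drops["incomplete"] <- sum(!ok_core)
  keep <- ok_core
  bad <- keep & raw$se <= 0
  drops["bad_se"] <- sum(bad); keep <- keep & !bad
  bad <- keep & (raw$pval <= 0 | raw$pval > 1)
  drops["bad_pval"] <- sum(bad); keep <- keep & !bad
  bad <- keep & raw$effect_allele == raw$other_allele
  drops["same_alleles"] <- sum(bad); keep <- keep & !bad
  bad <- keep & raw$pos < 1
  drops["bad_pos"] <- sum(bad); keep <- keep & !bad
  bad <- keep & !is.na(raw$eaf) & (raw$eaf <= 0 | raw$eaf >= 1)
  drops["bad_eaf"] <- sum(bad); keep <- keep & !bad
  dup <- duplicated(raw$variant_id) & keep
  drops["duplicate_id"] <- sum(dup & keep); keep <- keep & !dup

  out <- raw[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop2("read_sumstats: zero valid rows in ", path)
  ss <- summary_stats(out, trait_label, trait_type, genome_build, sd_y)
  attr(ss, "report") <- list(n_in = n_in, n_kept = nrow(out),
                             drops = drops,
                             n_pval_underflow = sum(under & keep))
  ss
}

#' Write summary statistics to a delimited file
#'
#' Numeric fields are serialised with 17 significant digits so a
#' write/read round trip preserves every double exactly.
#'
#' @param ss A `summary_stats` object.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path, sep = "\t") {
  stopifnot(inherits(ss, "summary_stats"))
  df <- ss$records
  for (cc in names(df)) {
    if (is.numeric(df[[cc]]))
      df[[cc]] <- ifelse(is.na(df[[cc]]), "NA",
                         formatC(df[[cc]], digits = 17, format = "g"))
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an LD matrix
#'
#' Signed pairwise correlations between variants. Stored signed so proxy
#' substitution can orient alleles; r-squared values are derived.
#'
#' @param r Square numeric matrix of correlations, symmetric within 1e-8,
#'   unit diagonal, entries in \[-1, 1\].
#' @param variant_ids Character vector matching the matrix dimension.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop2("ld_matrix: matrix must be square")
  if (is.null(variant_ids) || length(variant_ids) != nrow(r))
    stop2("ld_matrix: variant_ids must match matrix dimension")
  if (max(abs(r - t(r))) > 1e-8) stop2("ld_matrix: matrix not symmetric")
  if (any(abs(diag(r) - 1) > 1e-8)) stop2("ld_matrix: diagonal must be 1")
  if (any(abs(r) > 1 + 1e-8)) stop2("ld_matrix: entries must lie in [-1, 1]")
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r = r),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d x %d variants\n", nrow(x$r), ncol(x$r)))
  invisible(x)
}

#' Read an LD correlation matrix from a delimited file
#'
#' Expects a square numeric matrix with variant ids as both header row and
#' first column. Asymmetries up to 1e-6 are repaired by averaging; the
#' diagonal is forced to 1 when within 1e-6 of it. Larger violations, and
#' any entry beyond 1 + 1e-6 in magnitude, are hard errors.
#'
#' @param path Path to the delimited matrix.
#' @param sep Field separator; `NULL` auto-detects tab vs comma.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE)
  r <- as.matrix(df)
  if (nrow(r) != ncol(r))
    stop2("read_ld_matrix: matrix is not square (", nrow(r), " x ",
          ncol(r), ")")
  if (any(abs(r) > 1 + 1e-6))
    stop2("read_ld_matrix: correlation entries exceed 1 in magnitude")
  asym <- max(abs(r - t(r)))
  if (asym > 1e-6)
    stop2("read_ld_matrix: asymmetry ", format(asym), " exceeds 1e-6")
  r <- (r + t(r)) / 2
  if (any(abs(diag(r) - 1) > 1e-6))
    stop2("read_ld_matrix: diagonal departs from 1 by more than 1e-6")
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  ld_matrix(r, rownames(r))
}

#' Write an LD matrix to a delimited file
#'
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path, sep = "\t") {
  stopifnot(inherits(ld, "ld_matrix"))
  m <- format(ld$r, digits = 17, trim = TRUE, scientific = FALSE)
  df <- data.frame(variant_id = ld$variant_ids, m, check.names = FALSE)
  names(df) <- c("variant_id", ld$variant_ids)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a regional multi-trait dataset
#'
#' A genomic window's aligned per-trait association vectors tied to one LD
#' matrix; the colocalisation working object.
#'
#' @param window List or vector `(chrom, start, end)`, 1-based inclusive.
#' @param ld An `ld_matrix` over the region's variants.
#' @param traits Named list; each element a list with `beta`, `se`, `z`
#'   (optional, recomputed as beta/se), `trait_type` and `scale_param`
#'   (sdY for quantitative traits, case fraction for case-control).
#' @param positions Optional integer vector of variant positions (same
#'   order as `ld$variant_ids`).
#' @return An object of class `regional_dataset`.
#' @export
regional_dataset <- function(window, ld, traits, positions = NULL) {
  stopifnot(inherits(ld, "ld_matrix"), is.list(traits), length(traits) >= 1)
  p <- length(ld$variant_ids)
  for (nm in names(traits)) {
    tr <- traits[[nm]]
    if (length(tr$beta) != p || length(tr$se) != p)
      stop2("regional_dataset: trait '", nm,
            "' vectors do not match LD dimension")
    if (any(tr$se <= 0)) stop2("regional_dataset: trait '", nm,
                               "' has non-positive SEs")
    z <- tr$beta / tr$se
    if (!is.null(tr$z) && max(abs(tr$z - z)) > 1e-8)
      stop2("regional_dataset: trait '", nm, "' z != beta/se")
    tr$z <- z
    tr$trait_type <- match.arg(tr$trait_type %||% "quantitative",
                               c("quantitative", "case-control"))
    tr$scale_param <- tr$scale_param %||% 1
    traits[[nm]] <- tr
  }
  if (!is.null(positions) && length(positions) != p)
    stop2("regional_dataset: positions must match LD dimension")
  structure(list(window = window, ld = ld, traits = traits,
                 positions = positions),
            class = "regional_dataset")
}

#' @export
print.regional_dataset <- function(x, ...) {
  cat(sprintf("<regional_dataset> %s:%s-%s, %d variants, traits: %s\n",
              x$window[[1]], x$window[[2]], x$window[[3]],
              length(x$ld$variant_ids),
              paste(names(x$traits), collapse = ", ")))
  invisible(x)
}

#' Extract an aligned multi-trait region around a centre variant
#'
#' Keeps variants within half the window of the centre's position that are
#' present in every trait and in the LD matrix, and harmonises each
#' trait's effects to the first trait's effect allele (sign flip when the
#' allele pair is swapped; variants whose allele pairs cannot be matched
#' are dropped). The default 150 kb window is read as a total width
#' centred on the lead variant (+/- 75 kb).
#'
#' @param ss_list List of `summary_stats` (first trait fixes the allele
#'   reference). Names default to each trait's label.
#' @param ld An `ld_matrix` covering the region.
#' @param center variant_id of the centre (lead) variant.
#' @param window_kb Total window width in kb (default 150).
#' @return A `regional_dataset`, variants ordered by position then id.
#' @export
extract_region <- function(ss_list, ld, center, window_kb = 150) {
  stopifnot(length(ss_list) >= 1)
  if (is.null(names(ss_list)) || any(!nzchar(names(ss_list))))
    names(ss_list) <- vapply(ss_list, function(s) s$trait_label, "")
  for (s in ss_list) {
    if (!center %in% s$records$variant_id)
      stop2("extract_region: centre variant ", center, " absent from trait ",
            s$trait_label)
  }
  if (!center %in% ld$variant_ids)
    stop2("extract_region: centre variant ", center, " absent from LD matrix")

  ref <- ss_list[[1]]$records
  cpos <- ref$pos[match(center, ref$variant_id)]
  half <- window_kb * 1000 / 2
  lo <- cpos - half + 1
  hi <- cpos + half

  in_win <- ref$variant_id[ref$pos >= lo & ref$pos <= hi]
  common <- intersect(in_win, ld$variant_ids)
  for (s in ss_list) common <- intersect(common, s$records$variant_id)

  # align each trait to the first trait's effect allele
  ridx <- match(common, ref$variant_id)
  ea <- ref$effect_allele[ridx]; oa <- ref$other_allele[ridx]
  traits <- list()
  keep <- rep(TRUE, length(common))
  aligned <- list()
  for (nm in names(ss_list)) {
    rec <- ss_list[[nm]]$records
    i <- match(common, rec$variant_id)
    same <- rec$effect_allele[i] == ea & rec$other_allele[i] == oa
    swap <- rec$effect_allele[i] == oa & rec$other_allele[i] == ea
    keep <- keep & (same | swap)
    b <- ifelse(swap, -rec$beta[i], rec$beta[i])
    aligned[[nm]] <- list(beta = b, se = rec$se[i])
  }
  common <- common[keep]
  if (length(common) < 2)
    stop2("extract_region: fewer than 2 variants survive in the window")
  ord <- order(ref$pos[match(common, ref$variant_id)], common)
  common <- common[ord]
  sub_r <- ld$r[common, common, drop = FALSE]
  for (nm in names(ss_list)) {
    s <- ss_list[[nm]]
    scale_param <- if (s$trait_type == "case-control") {
      rec1 <- s$records[1, ]
      rec1$n_cases / (rec1$n_cases + rec1$n_controls)
    } else s$sd_y
    b <- aligned[[nm]]$beta[keep][ord]
    se <- aligned[[nm]]$se[keep][ord]
    traits[[nm]] <- list(beta = b, se = se, z = b / se,
                         trait_type = s$trait_type,
                         scale_param = scale_param)
  }
  pos <- ref$pos[match(common, ref$variant_id)]
  regional_dataset(window = list(chrom = ref$chrom[ridx][1], start = lo,
                                 end = hi),
                   ld = ld_matrix(sub_r, common),
                   traits = traits, positions = pos)
}
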