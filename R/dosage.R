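#' Pair Sc/Se orthologues from a gene table
#'
#' One pair per orthologue-group id having exactly one `Sc` and one `Se`
#' member; genes without a partner are returned separately (whole
#' sub-genome chromosome losses leave many such singletons).
#'
#' @param genes Gene tibble with `gene_id`, `base_id`, `subgenome` and,
#'   optionally, a `cn` column (carried into `cn_sc`/`cn_se`).
#' @return List with `pairs` (tibble `base_id`, `sc_id`, `se_id`, and
#'   `cn_sc`/`cn_se` when available) and `unmatched` (the leftover gene
#'   rows).
#' @export
pair_orthologs <- function(genes) {
  dup <- genes |>
    dplyr::count(.data$base_id, .data$subgenome) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort(paste0("duplicate members within a sub-genome for base id(s): ",
                 paste(unique(dup$base_id), collapse = ", ")))
  has_cn <- "cn" %in% names(genes)
  wide <- genes |>
    dplyr::select("base_id", "subgenome", "gene_id",
                  dplyr::any_of("cn")) |>
    tidyr::pivot_wider(names_from = "subgenome",
                       values_from = dplyr::all_of(if (has_cn)
                         c("gene_id", "cn") else "gene_id"))
  if (has_cn) {
    wide <- dplyr::rename(wide, sc_id = "gene_id_Sc", se_id = "gene_id_Se",
                          cn_sc = "cn_Sc", cn_se = "cn_Se")
  } else {
    wide <- dplyr::rename(wide, sc_id = "Sc", se_id = "Se")
  }
  paired <- dplyr::filter(wide, !is.na(.data$sc_id), !is.na(.data$se_id))
  unmatched <- genes |>
    dplyr::filter(!.data$gene_id %in% c(paired$sc_id, paired$se_id))
  list(pairs = paired, unmatched = unmatched)
}

#' Canonical copy-number ratio category
#'
#' Reduces `(cn_sc, cn_se)` by their greatest common divisor and formats
#' `"sc:se"`; `(0, 0)` maps to `"0:0"`. Vectorised.
#'
#' @param cn_sc,cn_se Non-negative integer copy numbers.
#' @return Character vector of categories such as `"3:1"`.
#' @export
#' @examples
#' ratio_category(c(2, 3, 0), c(4, 1, 2))
ratio_category <- function(cn_sc, cn_se) {
  if (any(cn_sc < 0 | cn_se < 0)) abort("copy numbers must be non-negative")
  g <- gcd2(cn_sc, cn_se)
  g[g == 0] <- 1L
  paste0(as.integer(cn_sc) %/% g, ":", as.integer(cn_se) %/% g)
}

#' Within-strain allele differential expression for orthologue pairs
#'
#' For one strain and condition, the `Sc` and `Se` allele counts of each
#' pair across the same replicate samples are contrasted with the
#' negative-binomial Wald machinery (alleles as the two groups, replicate
#' samples unpaired); `log2fc > 0` means the `Sc` allele is higher.
#' Size factors come from the full strain-condition count matrix so that
#' allele contrasts share the sample normalisation.
#'
#' @param counts Counts tibble covering both alleles' genes.
#' @param sample_info Sample sheet (`sample`, `strain`, `condition`, ...).
#' @param pairs Pair tibble from [pair_orthologs()].
#' @param strain,condition The cell to analyse (>= 2 replicates).
#' @return `pairs` with `log2fc`, `lfc_se`, `pvalue`, `padj` columns; pairs
#'   with both alleles all-zero carry `NA`.
#' @export
allele_log2fc <- function(counts, sample_info, pairs, strain, condition) {
  samp <- sample_info$sample[sample_info$strain == strain &
                               sample_info$condition == condition]
  if (length(samp) < 2) abort("need >= 2 replicates for the strain/condition")
  m <- counts_matrix(counts[, c(names(counts)[1], samp), drop = FALSE])
  missing <- setdiff(c(pairs$sc_id, pairs$se_id), rownames(m))
  if (length(missing) > 0)
    abort(paste0("pair gene(s) absent from counts: ",
                 paste(head(missing, 5), collapse = ", ")))
  sf_tbl <- size_factors(counts[, c(names(counts)[1], samp), drop = FALSE])
  sf <- sf_tbl$size_factor[match(samp, sf_tbl$sample)]

  # pairs x (sc reps, se reps) pseudo-matrix; alleles are the two groups
  y <- cbind(m[pairs$sc_id, samp, drop = FALSE],
             m[pairs$se_id, samp, drop = FALSE])
  rownames(y) <- pairs$base_id
  colnames(y) <- c(paste0(samp, ".Sc"), paste0(samp, ".Se"))
  x <- rep(c(1L, 0L), each = length(samp))       # 1 = Sc allele
  offs <- log(rep(sf, 2))
  grp <- rep(c("Sc", "Se"), each = length(samp))
  disp <- estimate_dispersion(matrix_to_counts(y), grp,
                              size_factors = tibble::tibble(
                                sample = colnames(y),
                                size_factor = rep(sf, 2)))
  alpha <- disp$dispersion[match(pairs$base_id, disp$gene_id)]
  fit <- nb_two_group_fit(y, x, offs, alpha)
  log2fc <- fit$beta1 / log(2)
  p <- 2 * pnorm(-abs(fit$beta1 / fit$se1))
  p[!fit$converged] <- NA_real_
  zero <- rowSums(y) == 0
  log2fc[zero] <- NA_real_; p[zero] <- NA_real_
  dplyr::mutate(pairs, log2fc = unname(log2fc),
                lfc_se = unname(fit$se1) / log(2),
                pvalue = unname(p), padj = bh_adjust(unname(p)))
}

#' Summarise allele log2 fold changes per copy-number-ratio category
#'
#' @param pairs Pair tibble with `cn_sc`, `cn_se`, `log2fc`.
#' @return Tibble per non-empty category: `category`, `log2_ratio`
#'   (`log2(cn_sc/cn_se)`, `NA` for zero-copy categories), `n`, `mean`,
#'   `sem`, `n_up` (`log2fc >= 1`), `n_down` (`log2fc <= -1`), ordered by
#'   log ratio.
#' @export
category_summary <- function(pairs) {
  pairs |>
    dplyr::filter(!is.na(.data$log2fc)) |>
    dplyr::mutate(category = ratio_category(.data$cn_sc, .data$cn_se),
                  log2_ratio = ifelse(.data$cn_sc > 0 & .data$cn_se > 0,
                                      log2(.data$cn_sc / .data$cn_se), NA)) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      log2_ratio = .data$log2_ratio[1],
      n = dplyr::n(),
      mean = mean(.data$log2fc),
      sem = sd(.data$log2fc) / sqrt(dplyr::n()),
      n_up = sum(.data$log2fc >= 1),
      n_down = sum(.data$log2fc <= -1),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$log2_ratio)
}

# Shared regression core for dosage analyses: weighted OLS of per-category
# mean response on log2 copy-number ratio, plus an unbinned per-observation
# fit. `data` needs cn_a, cn_b, log2fc.
dosage_fit <- function(data, min_categories = 3L) {
  usable <- data |>
    dplyr::filter(.data$cn_a > 0, .data$cn_b > 0, !is.na(.data$log2fc)) |>
    dplyr::mutate(category = ratio_category(.data$cn_a, .data$cn_b),
                  log2_ratio = log2(.data$cn_a / .data$cn_b))
  excluded <- dplyr::filter(data, .data$cn_a == 0 | .data$cn_b == 0)
  cats <- usable |>
    dplyr::group_by(.data$category, .data$log2_ratio) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$log2fc),
                     sem = sd(.data$log2fc) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::arrange(.data$log2_ratio)
  if (nrow(cats) < min_categories || dplyr::n_distinct(cats$log2_ratio) < 2)
    abort(paste0("need >= ", min_categories,
                 " copy-number-ratio categories with finite ratios"))
  binned <- lm(mean ~ log2_ratio, data = cats, weights = cats$n)
  unbinned <- lm(log2fc ~ log2_ratio, data = usable)
  sb <- summary(binned)
  structure(list(
    slope = unname(coef(binned)[2]),
    intercept = unname(coef(binned)[1]),
    r_squared = sb$r.squared,
    p_value = sb$coefficients[2, 4],
    n_pairs = nrow(usable),
    n_excluded_zero_cn = nrow(excluded),
    categories = cats,
    binned_fit = binned,
    unbinned = list(slope = unname(coef(unbinned)[2]),
                    intercept = unname(coef(unbinned)[1]),
                    r_squared = summary(unbinned)$r.squared,
                    p_value = summary(unbinned)$coefficients[2, 4])
  ), class = "dosage_regression")
}

#' Dosage-expression regression across orthologue pairs
#'
#' Quantifies how the allele expression ratio follows the allele copy-number
#' ratio: ordinary least squares of per-category mean allele `log2fc`
#' (Sc over Se) on `log2(cn_sc/cn_se)`, weighted by category size (the
#' primary, binned fit), with an unbinned per-pair fit reported alongside.
#' Pairs with a zero copy number on either side have an undefined log ratio
#' and are excluded (their count is reported).
#'
#' @param pairs Pair tibble with `cn_sc`, `cn_se` and `log2fc` (e.g. from
#'   [allele_log2fc()]).
#' @return A `"dosage_regression"` object: `slope`, `intercept`,
#'   `r_squared`, `p_value` (slope t-test), `n_pairs`, `categories`,
#'   `unbinned`. Under a pure dosage response the slope is 1 and the
#'   intercept `-log2(allele bias)`.
#' @export
#' @examples
#' pairs <- tibble::tibble(cn_sc = rep(1:3, each = 20), cn_se = 1,
#'                         log2fc = log2(rep(1:3, each = 20)) + rnorm(60, 0, .1))
#' dosage_correlation(pairs)
dosage_correlation <- function(pairs) {
  dosage_fit(dplyr::rename(pairs, cn_a = "cn_sc", cn_b = "cn_se"))
}

#' @export
print.dosage_regression <- function(x, ...) {
  cat("Dosage-expression regression (binned, weighted by category size)\n")
  cat(sprintf("  slope = %.3f, intercept = %.3f, R^2 = %.3f, p = %.3g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  cat(sprintf("  %d pairs in %d categories (%d excluded for zero copy number)\n",
              x$n_pairs, nrow(x$categories), x$n_excluded_zero_cn))
  invisible(x)
}
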