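#' Counts per million, with an optional log2 transform
#'
#' `cpm_ij = counts_ij / libsize_j * 1e6`. The log variant adds
#' `prior_count` on the count scale before scaling (the convention used for
#' clustering and plotting transforms), `log2((count + prior) / libsize *
#' 1e6)`. When `prior_count = 0` and a count is 0 the log value is floored
#' at -30 rather than returning `-Inf`.
#'
#' @param counts Counts tibble (gene id first column, samples after).
#' @param log Return `log2` CPM?
#' @param prior_count Pseudocount added on the count scale for the log
#'   transform; ignored when `log = FALSE`.
#' @return Tibble of the same shape as `counts`.
#' @export
#' @examples
#' cts <- tibble::tibble(gene_id = "g1", s1 = 5L)
#' cpm(cts)  # 5 / 5 * 1e6
cpm <- function(counts, log = FALSE, prior_count = 4) {
  m <- counts_matrix(counts)
  libs <- colSums(m)
  if (any(libs <= 0)) {
    bad <- colnames(m)[libs <= 0]
    abort(paste0("zero-library sample(s): ", paste(bad, collapse = ", ")))
  }
  if (log) {
    v <- log2(sweep(m + prior_count, 2, libs, "/") * 1e6)
    v[!is.finite(v)] <- -30
  } else {
    v <- sweep(m, 2, libs, "/") * 1e6
  }
  rownames(v) <- rownames(m)
  matrix_to_counts(v, id_name = names(counts)[1])
}

#' Filter genes by detection
#'
#' Keeps a gene iff its CPM is at least `min_cpm` in at least
#' `min_libraries` samples (boundaries inclusive); row order is preserved.
#'
#' @inheritParams cpm
#' @param min_cpm Detection threshold in CPM.
#' @param min_libraries Minimum number of samples reaching it.
#' @return Filtered counts tibble.
#' @export
filter_detected <- function(counts, min_cpm = 0.5, min_libraries = 1) {
  v <- counts_matrix(cpm(counts))
  keep <- rowSums(v >= min_cpm) >= min_libraries
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of that
#' sample's count divided by the gene's geometric mean across samples,
#' computed over genes with nonzero counts in every sample.
#'
#' @inheritParams cpm
#' @return Tibble `sample`, `size_factor`.
#' @export
#' @examples
#' cts <- tibble::tibble(g = c("a", "b", "c"),
#'                       s1 = c(10, 100, 4), s2 = c(20, 200, 8))
#' size_factors(cts)
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok))
    abort("no gene has nonzero counts in every sample; cannot normalise")
  lgm <- rowMeans(log(m[ok, , drop = FALSE]))
  sf <- apply(m[ok, , drop = FALSE], 2, function(col) exp(median(log(col) - lgm)))
  tibble::tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' On size-factor-normalised counts, the raw gene-wise dispersion is
#' \eqn{\hat\alpha_g = \max((v_g - m_g)/m_g^2, 10^{-8})} with \eqn{v_g}
#' the replicate-pooled within-group variance and \eqn{m_g} the mean.
#' Raw values are then shrunk 50/50 toward a mean-dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu} fitted across genes, stabilising
#' estimates at the small replicate numbers typical of RNA-seq designs.
#'
#' @inheritParams cpm
#' @param groups Factor/character vector, one group label per sample column.
#' @param size_factors Optional tibble from [size_factors()]; computed if
#'   missing.
#' @param alpha_min Dispersion floor.
#' @return Tibble `gene_id`, `mean_norm`, `dispersion_raw`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, groups, size_factors = NULL,
                                alpha_min = 1e-8) {
  m <- counts_matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(m))
    abort("groups must have one label per sample column")
  reps <- table(groups)
  if (!any(reps >= 2))
    abort("dispersion estimation needs >= 2 replicates in at least one group")
  if (is.null(size_factors)) size_factors <- size_factors(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample)]
  q <- sweep(m, 2, sf, "/")

  mu <- rowMeans(q)
  use <- names(reps)[reps >= 2]
  ssq <- matrix(0, nrow(q), 1); dof <- 0
  vsum <- rep(0, nrow(q))
  for (g in use) {
    idx <- which(groups == g)
    gm <- rowMeans(q[, idx, drop = FALSE])
    vsum <- vsum + rowSums((q[, idx, drop = FALSE] - gm)^2)
    dof <- dof + length(idx) - 1L
  }
  v <- vsum / dof
  a_raw <- pmax((v - mu) / mu^2, alpha_min)
  a_raw[!is.finite(a_raw)] <- alpha_min

  fit_ok <- mu > 0 & a_raw > alpha_min
  if (sum(fit_ok) >= 10) {
    cf <- tryCatch(coef(lm(a_raw[fit_ok] ~ I(1 / mu[fit_ok]))),
                   error = function(e) c(median(a_raw[fit_ok]), 0))
    a0 <- max(cf[1], 0); a1 <- max(cf[2], 0)
  } else {
    a0 <- median(a_raw); a1 <- 0
  }
  a_trend <- a0 + a1 / pmax(mu, 1e-8)
  a_final <- pmax(0.5 * a_raw + 0.5 * a_trend, alpha_min)

  tibble::tibble(gene_id = rownames(m), mean_norm = unname(mu),
                 dispersion_raw = unname(a_raw), dispersion = unname(a_final))
}

# Vectorised two-group NB GLM fit with log link and per-sample offsets.
# y: genes x samples matrix; x: 0/1 group indicator per sample;
# offset: log size factors; alpha: per-gene dispersion.
# Returns per-gene beta0, beta1 (natural log), se1, converged.
nb_two_group_fit <- function(y, x, offset, alpha, max_iter = 50L,
                             tol = 1e-8, beta_cap = 30) {
  g0 <- which(x == 0); g1 <- which(x == 1)
  sf <- exp(offset)
  m0 <- rowSums(y[, g0, drop = FALSE]) / sum(sf[g0])
  m1 <- rowSums(y[, g1, drop = FALSE]) / sum(sf[g1])
  eps <- 1e-8
  b0 <- log(pmax(m0, eps)); b1 <- log(pmax(m1, eps)) - b0
  conv <- rep(FALSE, nrow(y))
  for (it in seq_len(max_iter)) {
    eta <- outer(b0, rep(1, length(x))) + outer(b1, x) +
      matrix(offset, nrow(y), length(x), byrow = TRUE)
    mu <- exp(pmin(eta, 700))
    w <- mu / (1 + alpha * mu)
    z <- eta - matrix(offset, nrow(y), length(x), byrow = TRUE) + (y - mu) / mu
    sw0 <- rowSums(w[, g0, drop = FALSE]); sw1 <- rowSums(w[, g1, drop = FALSE])
    nb0 <- rowSums((w * z)[, g0, drop = FALSE]) / pmax(sw0, eps)
    nb1g <- rowSums((w * z)[, g1, drop = FALSE]) / pmax(sw1, eps)
    nb1 <- nb1g - nb0
    nb0 <- pmin(pmax(nb0, -beta_cap), beta_cap)
    nb1 <- pmin(pmax(nb1, -beta_cap), beta_cap)
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    b0 <- nb0; b1 <- nb1
    conv <- conv | delta < tol
    if (all(conv)) break
  }
  eta <- outer(b0, rep(1, length(x))) + outer(b1, x) +
    matrix(offset, nrow(y), length(x), byrow = TRUE)
  mu <- exp(pmin(eta, 700))
  w <- mu / (1 + alpha * mu)
  sw0 <- rowSums(w[, g0, drop = FALSE]); sw1 <- rowSums(w[, g1, drop = FALSE])
  se1 <- sqrt(1 / pmax(sw0, eps) + 1 / pmax(sw1, eps))
  list(beta0 = b0, beta1 = b1, se1 = se1,
       converged = conv & abs(b1) < beta_cap)
}

#' Negative-binomial Wald test between two groups
#'
#' Fits, per gene, a negative-binomial GLM with log link, a two-level group
#' factor and `log(size factor)` offsets by iteratively reweighted least
#' squares, and tests the group coefficient with a Wald statistic against
#' the standard normal. Positive `log2fc` means higher expression in the
#' second contrast level.
#'
#' @inheritParams cpm
#' @param sample_info Tibble with a `sample` column matching the count
#'   columns plus the contrast variable.
#' @param contrast Length-3 character vector `c(variable, level_test,
#'   level_reference)`; `log2fc > 0` means higher at `level_test`.
#' @param size_factors Optional [size_factors()] tibble (computed on the
#'   contrast samples if missing).
#' @param dispersions Optional [estimate_dispersion()] tibble (computed on
#'   the contrast samples if missing).
#' @return Tibble `gene_id`, `base_mean`, `log2fc`, `lfc_se`, `stat`,
#'   `pvalue`, `converged`. Non-converged genes carry `NA` p-values.
#' @export
nb_wald <- function(counts, sample_info, contrast, size_factors = NULL,
                    dispersions = NULL) {
  stopifnot(length(contrast) == 3)
  var <- contrast[1]
  if (!var %in% names(sample_info))
    abort(paste0("contrast variable '", var, "' not in sample_info"))
  keep <- sample_info$sample[sample_info[[var]] %in% contrast[2:3]]
  if (!all(sample_info[[var]][sample_info$sample %in% keep] %in% contrast[2:3]))
    abort("internal contrast selection error")
  sub <- counts[, c(names(counts)[1], keep), drop = FALSE]
  m <- counts_matrix(sub)
  grp <- sample_info[[var]][match(colnames(m), sample_info$sample)]
  if (!all(contrast[2:3] %in% grp)) abort("both contrast groups must be non-empty")
  x <- as.integer(grp == contrast[2])  # 1 = test level

  if (is.null(size_factors)) size_factors <- size_factors(sub)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample)]
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(sub, grp, size_factors = size_factors)
  alpha <- dispersions$dispersion[match(rownames(m), dispersions$gene_id)]

  fit <- nb_two_group_fit(m, x, log(sf), alpha)
  log2fc <- fit$beta1 / log(2)
  se <- fit$se1 / log(2)
  stat <- fit$beta1 / fit$se1
  p <- 2 * pnorm(-abs(stat))
  p[!fit$converged] <- NA_real_
  allzero <- rowSums(m) == 0
  log2fc[allzero] <- 0; p[allzero] <- NA_real_
  tibble::tibble(
    gene_id = rownames(m),
    base_mean = unname(rowMeans(sweep(m, 2, sf, "/"))),
    log2fc = unname(log2fc), lfc_se = unname(se), stat = unname(stat),
    pvalue = unname(p), converged = unname(fit$converged & !allzero)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; `NA` p-values are propagated and excluded from the
#' effective number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Classify differential-expression status
#'
#' `up` iff `log2fc >= lfc_min` and `padj < fdr`; `down` iff
#' `log2fc <= -lfc_min` and `padj < fdr`; otherwise `ns`. The fold-change
#' boundary is inclusive and the FDR boundary strict, so
#' `(log2fc = 1, padj = 0.05)` is `ns` but `(1, 0.049)` is `up`.
#'
#' @param results Tibble with `log2fc` and `padj` columns.
#' @param lfc_min Minimum absolute log2 fold change (inclusive).
#' @param fdr FDR cutoff (exclusive).
#' @return `results` with a `status` column in `{"up", "down", "ns"}`.
#' @export
classify_deg <- function(results, lfc_min = 1, fdr = 0.05) {
  dplyr::mutate(results, status = dplyr::case_when(
    !is.na(.data$padj) & .data$padj < fdr & .data$log2fc >= lfc_min ~ "up",
    !is.na(.data$padj) & .data$padj < fdr & .data$log2fc <= -lfc_min ~ "down",
    TRUE ~ "ns"
  ))
}

#' One-call differential expression pipeline
#'
#' Detection filter, median-of-ratios normalisation, dispersion estimation,
#' NB Wald test, BH adjustment and status classification for one contrast.
#'
#' @inheritParams nb_wald
#' @inheritParams filter_detected
#' @inheritParams classify_deg
#' @return [nb_wald()] tibble plus `padj` and `status`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 3, n_chromosomes_per_subgenome = 2,
#'                   genes_per_chromosome = 10)
#' sim <- simulate_hybrid_genome(cfg)
#' des <- sim_design(strains = "S", conditions = c("minimal", "day2"))
#' cts <- simulate_counts(sim$genes, sim$truth, des, cfg)
#' de <- run_de(cts, des, contrast = c("condition", "day2", "minimal"))
#' dplyr::count(de, status)
run_de <- function(counts, sample_info, contrast, min_cpm = 0.5,
                   min_libraries = 1, lfc_min = 1, fdr = 0.05) {
  filtered <- filter_detected(counts, min_cpm = min_cpm,
                              min_libraries = min_libraries)
  res <- nb_wald(filtered, sample_info, contrast)
  res$padj <- bh_adjust(res$pvalue)
  classify_deg(res, lfc_min = lfc_min, fdr = fdr)
}
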