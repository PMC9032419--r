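#' Build the orthologue-summed consolidated transcriptome
#'
#' Collapses each orthologue pair to one row by summing the `Sc` and `Se`
#' allele counts per sample; unmatched genes pass through under their own
#' orthologue-group id; genes with zero reads in all samples are removed.
#' Column sums are conserved before the zero-row removal.
#'
#' @param counts Counts tibble (gene id first column).
#' @param pairs Pair tibble from [pair_orthologs()] (`base_id`, `sc_id`,
#'   `se_id`).
#' @return Consolidated counts tibble with `base_id` first.
#' @export
consolidate_counts <- function(counts, pairs) {
  m <- counts_matrix(counts)
  missing <- setdiff(c(pairs$sc_id, pairs$se_id), rownames(m))
  if (length(missing) > 0)
    abort(paste0("pair gene(s) absent from counts: ",
                 paste(head(missing, 5), collapse = ", ")))
  summed <- m[pairs$sc_id, , drop = FALSE] + m[pairs$se_id, , drop = FALSE]
  rownames(summed) <- pairs$base_id
  rest <- m[!rownames(m) %in% c(pairs$sc_id, pairs$se_id), , drop = FALSE]
  rownames(rest) <- sub("_(Sc|Se)$", "", rownames(rest))
  if (anyDuplicated(c(rownames(summed), rownames(rest))))
    abort("duplicate base ids after consolidation")
  out <- rbind(summed, rest)
  out <- out[rowSums(out) > 0, , drop = FALSE]
  matrix_to_counts(out, id_name = "base_id")
}

#' Total gene copy number per orthologue group
#'
#' The strain-level dosage of a gene product: `cn_sc + cn_se` for paired
#' orthologues, the single allele's copy number for unmatched genes.
#'
#' @param pairs Pair tibble with `cn_sc`, `cn_se`.
#' @param unmatched Optional unmatched-gene tibble with `base_id`, `cn`.
#' @return Tibble `base_id`, `cn_total`.
#' @export
total_gene_cn <- function(pairs, unmatched = NULL) {
  out <- tibble::tibble(base_id = pairs$base_id,
                        cn_total = pairs$cn_sc + pairs$cn_se)
  if (!is.null(unmatched) && nrow(unmatched) > 0)
    out <- dplyr::bind_rows(out, tibble::tibble(base_id = unmatched$base_id,
                                                cn_total = unmatched$cn))
  out
}

#' Cross-strain differential expression on consolidated counts
#'
#' Joins two strains' consolidated matrices on shared orthologue-group ids
#' and contrasts the strains within one condition using the NB Wald test;
#' size factors are computed jointly across both strains' samples.
#' `log2fc > 0` means higher in strain A.
#'
#' @param cons_a,cons_b Consolidated counts tibbles for strains A and B.
#' @param sample_info Combined sample sheet covering both strains' samples.
#' @param condition Condition to compare (>= 2 replicates per strain).
#' @param strain_a,strain_b Strain labels in `sample_info`; default = the
#'   two strains present, in order of appearance.
#' @return List with `de` (the [nb_wald()] result plus `padj`, `status`)
#'   and `exclusive` (tibble of base ids present in only one matrix).
#' @export
cross_strain_de <- function(cons_a, cons_b, sample_info, condition,
                            strain_a = NULL, strain_b = NULL) {
  strains <- unique(sample_info$strain)
  if (is.null(strain_a)) strain_a <- strains[1]
  if (is.null(strain_b)) strain_b <- strains[2]
  shared <- intersect(cons_a[[1]], cons_b[[1]])
  if (length(shared) == 0) abort("no shared base ids between strains")
  exclusive <- tibble::tibble(
    base_id = c(setdiff(cons_a[[1]], shared), setdiff(cons_b[[1]], shared)),
    strain = rep(c(strain_a, strain_b),
                 c(length(setdiff(cons_a[[1]], shared)),
                   length(setdiff(cons_b[[1]], shared)))))
  samp <- sample_info$sample[sample_info$condition == condition]
  a_cols <- intersect(names(cons_a), samp)
  b_cols <- intersect(names(cons_b), samp)
  if (length(a_cols) < 2 || length(b_cols) < 2)
    abort("need >= 2 replicates per strain in the chosen condition")
  ma <- counts_matrix(cons_a)[shared, a_cols, drop = FALSE]
  mb <- counts_matrix(cons_b)[shared, b_cols, drop = FALSE]
  combined <- matrix_to_counts(cbind(ma, mb), id_name = "base_id")
  info <- sample_info[sample_info$sample %in% c(a_cols, b_cols), ]
  res <- nb_wald(combined, info, contrast = c("strain", strain_a, strain_b))
  res$padj <- bh_adjust(res$pvalue)
  list(de = classify_deg(res), exclusive = exclusive)
}

#' Correlate cross-strain expression change with copy-number ratio
#'
#' Regression of cross-strain `log2fc` on `log2(cn_total_A / cn_total_B)`,
#' binned by canonical copy-number-ratio category (weighted by category
#' size) with an unbinned fit alongside, exactly as in
#' [dosage_correlation()]. Genes with zero total copy number in either
#' strain are excluded and counted separately.
#'
#' @param de Cross-strain DE tibble with `gene_id` (base id) and `log2fc`.
#' @param cn_a,cn_b [total_gene_cn()] tibbles for strains A and B.
#' @return A `"dosage_regression"` object.
#' @export
cn_ratio_correlation <- function(de, cn_a, cn_b) {
  dat <- de |>
    dplyr::inner_join(dplyr::rename(cn_a, cn_a = "cn_total"),
                      by = c(gene_id = "base_id")) |>
    dplyr::inner_join(dplyr::rename(cn_b, cn_b = "cn_total"),
                      by = c(gene_id = "base_id"))
  if (nrow(dat) == 0) abort("no genes shared between DE table and CN tables")
  dosage_fit(dat)
}
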