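#' Simulate an RNA-seq count matrix under the gene-dosage model
#'
#' Counts for gene allele \eqn{g} in sample \eqn{j} are negative-binomial
#' with mean
#' \deqn{\mu_{gj} = s_j \, b_g \, \mathrm{CN}_g \, \beta_g \, f_{g,c(j)}}
#' where \eqn{s_j} is a per-sample scaling, \eqn{b_g} the baseline
#' expression per copy shared by both alleles of an orthologue pair,
#' \eqn{\mathrm{CN}_g} the allele's true copy number, \eqn{\beta_g} the
#' `allele_bias` factor (applied to `Se` alleles), and \eqn{f_{g,c}} a
#' per-gene condition effect \eqn{2^{N(0,\sigma)}}. Variance is
#' \eqn{\mu + \alpha\mu^2}; `nb_dispersion = 0` draws Poisson counts.
#'
#' @param genes Gene tibble from [simulate_hybrid_genome()].
#' @param truth Matching truth list.
#' @param design Sample sheet tibble with columns `sample`, `strain`,
#'   `condition`, `replicate`. Conditions must come from `conditions`.
#' @param config The same [sim_config()].
#' @param conditions Allowed condition labels.
#' @param condition_effects Optional pre-drawn per-gene condition-effect
#'   matrix (base ids x conditions), e.g. the `condition_effects` attribute
#'   of another strain's count matrix. Supplying it models two strains that
#'   share gene-by-condition responses while differing in karyotype; the
#'   matrix replaces the freshly drawn effects (the random stream is
#'   advanced identically either way, so count noise stays reproducible).
#' @return A counts tibble (`gene_id` plus one column per sample) with
#'   attributes `design`, `sample_scaling` and `condition_effects`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes_per_subgenome = 2,
#'                   genes_per_chromosome = 8)
#' sim <- simulate_hybrid_genome(cfg)
#' des <- sim_design(strains = "S1", conditions = "minimal", n_replicates = 3)
#' cts <- simulate_counts(sim$genes, sim$truth, des, cfg)
#' dim(cts)
simulate_counts <- function(genes, truth, design, config,
                            conditions = c("minimal", "day2", "day4"),
                            condition_effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  req <- c("sample", "strain", "condition", "replicate")
  if (!all(req %in% names(design)))
    abort("design must have columns sample, strain, condition, replicate")
  if (nrow(design) < 1L) abort("design must contain at least one sample")
  bad <- setdiff(unique(design$condition), conditions)
  if (length(bad) > 0)
    abort(paste0("unknown condition label(s): ", paste(bad, collapse = ", ")))

  set.seed(substream_seed(config$seed, "counts"))
  n_samp <- nrow(design)
  s_j <- rlnorm(n_samp, meanlog = 0, sdlog = config$sample_scaling_sd)

  base_ids <- truth$expression$base_id
  f <- matrix(2 ^ rnorm(length(base_ids) * length(conditions),
                        sd = config$condition_effect_sd),
              nrow = length(base_ids),
              dimnames = list(base_ids, conditions))
  if (!is.null(condition_effects)) {
    if (!all(base_ids %in% rownames(condition_effects)) ||
        !all(conditions %in% colnames(condition_effects)))
      abort("condition_effects must cover all base ids and conditions")
    f <- condition_effects[base_ids, conditions, drop = FALSE]
  }

  gtab <- dplyr::left_join(genes, truth$gene_cn[, c("gene_id", "cn_true")],
                           by = "gene_id") |>
    dplyr::left_join(truth$expression, by = "base_id")
  if (anyNA(gtab$cn_true)) abort("every gene needs a true copy number in truth")

  bias <- ifelse(gtab$subgenome == "Se", config$allele_bias, 1)
  per_copy <- gtab$base_expression * gtab$cn_true * bias

  counts <- matrix(0, nrow = nrow(gtab), ncol = n_samp,
                   dimnames = list(gtab$gene_id, design$sample))
  for (j in seq_len(n_samp)) {
    mu <- s_j[j] * per_copy * f[gtab$base_id, design$condition[j]]
    counts[, j] <- if (config$nb_dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  }

  out <- matrix_to_counts(counts)
  attr(out, "design") <- design
  attr(out, "sample_scaling") <- tibble::tibble(sample = design$sample,
                                               scaling = s_j)
  attr(out, "condition_effects") <- f
  out
}

#' Build a factorial sample sheet for the simulator
#'
#' @param strains Strain labels.
#' @param conditions Condition labels.
#' @param n_replicates Replicates per strain-condition cell.
#' @return A tibble with `sample`, `strain`, `condition`, `replicate`.
#' @export
sim_design <- function(strains = c("strainA"),
                       conditions = c("minimal", "day2", "day4"),
                       n_replicates = 3) {
  tidyr::crossing(strain = strains, condition = conditions,
                  replicate = seq_len(n_replicates)) |>
    dplyr::mutate(sample = paste(.data$strain, .data$condition,
                                 .data$replicate, sep = "_"),
                  .before = 1)
}
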