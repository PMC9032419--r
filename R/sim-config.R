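#' Configuration for the synthetic hybrid-genome simulator
#'
#' Bundles and validates every knob of the generative model used throughout
#' the package's validation suite: an interspecies hybrid with two divergent
#' sub-genomes (`Sc`, `Se`), aneuploid integer chromosome copy numbers,
#' optional hybrid chromosomes carrying a single intragenic recombination
#' breakpoint, Poisson binned sequencing coverage proportional to copy
#' number, and negative-binomial RNA-seq counts whose expectation is
#' proportional to allele copy number times condition-dependent expression.
#'
#' The defaults emulate a lager-yeast-like genome: 16 chromosomes per
#' sub-genome, copy numbers between 1 and 6, two hybrid chromosomes, 500-bp
#' coverage bins, and moderately overdispersed counts
#' (\eqn{Var = \mu + \alpha \mu^2}, \eqn{\alpha = 0.1}).
#'
#' @param n_chromosomes_per_subgenome Chromosomes per parental sub-genome.
#' @param genes_per_chromosome Genes placed evenly along each chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param bin_width Coverage bin width in bp.
#' @param cn_range Integer interval (length-2 vector) for per-chromosome
#'   parental copy numbers; must lie within `[0, 8]`.
#' @param n_hybrid_chromosomes Number of chromosomes carrying a recombinant
#'   (hybrid) molecule with one breakpoint inside a gene body.
#' @param depth_per_copy Expected sequencing reads per bin contributed by one
#'   chromosome copy.
#' @param base_expression_log_mean,base_expression_log_sd Log-normal
#'   parameters of per-gene baseline expression per copy.
#' @param condition_effect_sd Standard deviation (log2 scale) of per-gene
#'   condition effects; 0 means expression identical across conditions.
#' @param nb_dispersion Negative-binomial dispersion \eqn{\alpha}
#'   (variance \eqn{\mu + \alpha\mu^2}); 0 degenerates to Poisson.
#' @param allele_bias Multiplicative expression factor applied to the `Se`
#'   allele of every orthologue pair (1 = no bias).
#' @param sample_scaling_sd Log-scale standard deviation of the per-sample
#'   scaling \eqn{s_j} (sequencing-depth variation); 0 gives equal depths.
#' @param seed Master seed. Stage-specific substreams are derived from it so
#'   genome, coverage and count draws are independently reproducible.
#'
#' @return A named list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$cn_range
sim_config <- function(n_chromosomes_per_subgenome = 16,
                       genes_per_chromosome = 32,
                       chrom_length = 2e5,
                       bin_width = 500,
                       cn_range = c(1L, 6L),
                       n_hybrid_chromosomes = 2,
                       depth_per_copy = 50,
                       base_expression_log_mean = log(100),
                       base_expression_log_sd = 1,
                       condition_effect_sd = 1,
                       nb_dispersion = 0.1,
                       allele_bias = 1,
                       sample_scaling_sd = 0.2,
                       seed = 1L) {
  chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != floor(x))
      abort(paste0("invalid sim_config field '", nm, "': must be an integer >= ",
                   min))
  }
  chk_count(n_chromosomes_per_subgenome, "n_chromosomes_per_subgenome")
  chk_count(genes_per_chromosome, "genes_per_chromosome")
  chk_count(chrom_length, "chrom_length", min = 1000)
  chk_count(bin_width, "bin_width")
  chk_count(n_hybrid_chromosomes, "n_hybrid_chromosomes", min = 0)
  if (n_hybrid_chromosomes > n_chromosomes_per_subgenome)
    abort("invalid sim_config field 'n_hybrid_chromosomes': exceeds chromosome count")
  if (length(cn_range) != 2 || any(cn_range != floor(cn_range)) ||
      cn_range[1] > cn_range[2] || cn_range[1] < 0 || cn_range[2] > 8)
    abort("invalid sim_config field 'cn_range': need integer interval within [0, 8]")
  if (!is.numeric(depth_per_copy) || depth_per_copy < 0)
    abort("invalid sim_config field 'depth_per_copy': must be >= 0")
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0)
    abort("invalid sim_config field 'nb_dispersion': must be >= 0")
  if (!is.numeric(allele_bias) || allele_bias <= 0)
    abort("invalid sim_config field 'allele_bias': must be > 0")
  if (!is.numeric(condition_effect_sd) || condition_effect_sd < 0)
    abort("invalid sim_config field 'condition_effect_sd': must be >= 0")
  if (!is.numeric(sample_scaling_sd) || sample_scaling_sd < 0)
    abort("invalid sim_config field 'sample_scaling_sd': must be >= 0")
  chk_count(seed, "seed", min = 0)

  structure(list(
    n_chromosomes_per_subgenome = as.integer(n_chromosomes_per_subgenome),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    chrom_length = as.integer(chrom_length),
    bin_width = as.integer(bin_width),
    cn_range = as.integer(cn_range),
    n_hybrid_chromosomes = as.integer(n_hybrid_chromosomes),
    depth_per_copy = depth_per_copy,
    base_expression_log_mean = base_expression_log_mean,
    base_expression_log_sd = base_expression_log_sd,
    condition_effect_sd = condition_effect_sd,
    nb_dispersion = nb_dispersion,
    allele_bias = allele_bias,
    sample_scaling_sd = sample_scaling_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}
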