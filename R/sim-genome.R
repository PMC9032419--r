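#' Simulate an aneuploid hybrid genome
#'
#' Draws per-chromosome parental copy numbers for both sub-genomes, selects
#' hybrid chromosomes and places one recombination breakpoint inside a gene
#' body on each (uniformly within the middle 80% of the chromosome, then
#' snapped inside the nearest gene), lays out orthologous gene pairs, and
#' records the complete generative truth.
#'
#' Chromosomes are represented on parental reference coordinates, mirroring
#' read mapping against a combined two-species reference: a hybrid molecule
#' whose left arm derives from sub-genome `Sc` adds one copy to the `Sc`
#' reference chromosome left of the breakpoint and one copy to the `Se`
#' reference right of it, producing the within-chromosome copy-number step
#' that karyotyping detects.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{genes}{tibble of gene annotations: `gene_id`, `base_id`
#'       (orthologue-group id shared by the `Sc` and `Se` alleles),
#'       `subgenome`, `chrom`, `start`, `end` (0-based half-open bp).}
#'     \item{truth}{list with `chromosomes` (per reference chromosome:
#'       parental copy number, modal copy number), `hybrids` (breakpoint
#'       position, left-arm sub-genome, breakpoint gene), `segments`
#'       (true per-segment copy number on reference coordinates), `gene_cn`
#'       (true per-allele copy number), and `expression` (per-base-id
#'       log-normal baseline expression per copy).}
#'   }
#' @export
#' @examples
#' sim <- simulate_hybrid_genome(sim_config(seed = 1))
#' dplyr::count(sim$genes, subgenome)
simulate_hybrid_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genome"))
  nc <- config$n_chromosomes_per_subgenome
  ng <- config$genes_per_chromosome
  L  <- config$chrom_length

  chrom_idx <- seq_len(nc)
  cn_vals <- seq(config$cn_range[1], config$cn_range[2])
  base_cn <- tibble::tibble(
    index = rep(chrom_idx, 2L),
    subgenome = rep(c("Sc", "Se"), each = nc),
    chrom = paste0(.data$subgenome, "_chr", sprintf("%02d", .data$index)),
    # sample() treats a scalar as 1:x, so guard the degenerate range
    base_cn = if (length(cn_vals) == 1L) rep(cn_vals, 2L * nc)
      else sample(cn_vals, 2L * nc, replace = TRUE)
  )

  # gene layout: ng equal slots per chromosome, gene occupies middle 60%
  slot <- L / ng
  g_start <- as.integer(round((seq_len(ng) - 1) * slot + 0.2 * slot))
  g_end   <- as.integer(round((seq_len(ng) - 1) * slot + 0.8 * slot))
  layout <- tibble::tibble(
    gene_index = seq_len(ng), start = g_start, end = g_end,
    mid = (g_start + g_end) / 2
  )

  hyb_idx <- if (config$n_hybrid_chromosomes > 0)
    sort(sample(chrom_idx, config$n_hybrid_chromosomes)) else integer(0)
  empty_hybrids <- tibble::tibble(
    index = integer(0), left_subgenome = character(0),
    right_subgenome = character(0), breakpoint_pos = integer(0),
    breakpoint_gene = character(0), hybrid_copies = integer(0))
  hybrids <- purrr::map_dfr(hyb_idx, function(ci) {
    left <- sample(c("Sc", "Se"), 1L)
    target <- runif(1, 0.1 * L, 0.9 * L)
    gi <- layout$gene_index[which.min(abs(layout$mid - target))]
    g <- layout[layout$gene_index == gi, ]
    bp <- sample(seq(g$start + 1L, g$end - 1L), 1L)  # strictly inside gene
    tibble::tibble(
      index = ci, left_subgenome = left,
      right_subgenome = setdiff(c("Sc", "Se"), left),
      breakpoint_pos = bp,
      breakpoint_gene = sprintf("g%02d_%03d", ci, gi),
      hybrid_copies = 1L
    )
  })
  if (nrow(hybrids) == 0L) hybrids <- empty_hybrids

  # true copy-number segments on each parental reference chromosome
  segments <- purrr::pmap_dfr(base_cn, function(index, subgenome, chrom, base_cn) {
    h <- hybrids[hybrids$index == index, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(tibble::tibble(chrom = chrom, start = 0L, end = L, cn = base_cn))
    }
    extra_left <- as.integer(h$left_subgenome == subgenome) * h$hybrid_copies
    extra_right <- as.integer(h$right_subgenome == subgenome) * h$hybrid_copies
    tibble::tibble(
      chrom = chrom,
      start = c(0L, h$breakpoint_pos),
      end = c(h$breakpoint_pos, L),
      cn = c(base_cn + extra_left, base_cn + extra_right)
    )
  })

  genes <- tidyr::crossing(
    base_cn[, c("index", "subgenome", "chrom")],
    layout
  ) |>
    dplyr::mutate(
      base_id = sprintf("g%02d_%03d", .data$index, .data$gene_index),
      gene_id = paste0(.data$base_id, "_", .data$subgenome)
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("gene_id", "base_id", "subgenome", "chrom", "start", "end")

  gene_cn <- genes |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2) |>
    dplyr::left_join(segments, by = "chrom", suffix = c("", "_seg"),
                     relationship = "many-to-many") |>
    dplyr::filter(.data$mid >= .data$start_seg, .data$mid < .data$end_seg) |>
    dplyr::select("gene_id", "base_id", "subgenome", "chrom", cn_true = "cn")

  expression <- tibble::tibble(
    base_id = sprintf("g%02d_%03d",
                      rep(chrom_idx, each = ng), rep(seq_len(ng), nc)),
    base_expression = rlnorm(nc * ng,
                             meanlog = config$base_expression_log_mean,
                             sdlog = config$base_expression_log_sd)
  )

  modal <- segments |>
    dplyr::group_by(.data$chrom, .data$cn) |>
    dplyr::summarise(len = sum(.data$end - .data$start), .groups = "drop_last") |>
    dplyr::slice_max(.data$len, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", modal_cn = "cn")

  chromosomes <- dplyr::left_join(base_cn, modal, by = "chrom") |>
    dplyr::mutate(is_hybrid = .data$index %in% hyb_idx)

  list(
    genes = genes,
    truth = list(
      chromosomes = chromosomes,
      hybrids = hybrids,
      segments = segments,
      gene_cn = gene_cn,
      expression = expression,
      chrom_length = L
    )
  )
}
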