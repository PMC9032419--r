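#' Simulate binned sequencing coverage from a karyotype truth
#'
#' Each reference chromosome is tiled with fixed-width bins; the read count
#' of a bin is Poisson with mean `segment copy number x depth_per_copy`,
#' where the relevant segment is the one containing the bin midpoint. This
#' is the generative inverse of coverage-based karyotyping from reads per
#' 500-bp bin normalised by library size.
#'
#' @param truth Truth list from [simulate_hybrid_genome()].
#' @param config The same [sim_config()].
#' @return A coverage tibble: `chrom`, `start`, `end` (bp, 0-based
#'   half-open), `count`, and `library_size` (total simulated reads,
#'   identical in every row).
#' @export
#' @examples
#' sim <- simulate_hybrid_genome(sim_config(seed = 1))
#' cov <- simulate_coverage(sim$truth, sim_config(seed = 1))
#' head(cov)
simulate_coverage <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "coverage"))
  bw <- config$bin_width
  L <- truth$chrom_length
  n_bins <- ceiling(L / bw)
  starts <- (seq_len(n_bins) - 1L) * bw
  bins <- tidyr::crossing(
    chrom = sort(unique(truth$segments$chrom)),
    tibble::tibble(start = starts, end = pmin(starts + bw, L))
  ) |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2)

  cov <- bins |>
    dplyr::left_join(truth$segments, by = "chrom", suffix = c("", "_seg"),
                     relationship = "many-to-many") |>
    dplyr::filter(.data$mid >= .data$start_seg, .data$mid < .data$end_seg) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(count = rpois(dplyr::n(), .data$cn * config$depth_per_copy)) |>
    dplyr::select("chrom", "start", "end", "count")

  cov$library_size <- sum(cov$count)
  cov
}
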