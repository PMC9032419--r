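#' Normalise binned coverage by library size
#'
#' Converts raw reads per bin into reads per bin per million mapped reads,
#' the scale on which chromosome copy number is estimated.
#'
#' @param coverage Coverage tibble (`chrom`, `start`, `end`, `count`,
#'   `library_size`), e.g. from [read_coverage_bedgraph()] or
#'   [simulate_coverage()].
#' @return The same tibble with a `norm` column
#'   (`count / library_size * 1e6`).
#' @export
normalize_coverage <- function(coverage) {
  if (!all(c("chrom", "start", "count", "library_size") %in% names(coverage)))
    abort("coverage needs columns chrom, start, count, library_size")
  if (any(coverage$library_size <= 0))
    abort("library_size must be > 0")
  dplyr::mutate(coverage, norm = .data$count / .data$library_size * 1e6)
}

# Best single change-point of a numeric vector by SSE reduction.
# Returns list(split, gain): `split` is the size of the left part, and
# `gain` the reduction in total within-segment SSE relative to no split.
# Both children are required to contain >= min_size points.
best_split <- function(x, min_size = 1L) {
  n <- length(x)
  if (n < 2L * min_size) return(list(split = NA_integer_, gain = 0))
  cs <- cumsum(x)
  k <- seq(min_size, n - min_size)  # candidate left sizes
  s1 <- cs[k]; s2 <- cs[n] - s1
  gain <- s1^2 / k + s2^2 / (n - k) - cs[n]^2 / n
  i <- which.max(gain)
  list(split = k[i], gain = gain[i])
}

#' Segment a coverage profile by recursive binary segmentation
#'
#' Recursively splits the per-bin values at the change-point that maximises
#' the reduction in within-segment sum of squared errors; a split is kept if
#' the reduction exceeds `penalty * log(n_bins) * sigma2`, a BIC-style
#' threshold, where `sigma2` is a robust noise-variance estimate from
#' first differences of the profile (robust against the mean shifts being
#' sought). Children shorter than `min_seg_bins` are never created.
#'
#' @param values Numeric vector of per-bin (normalised) coverage for one
#'   chromosome, in positional order.
#' @param min_seg_bins Minimum segment length in bins (default 20, i.e.
#'   10 kb at 500-bp bins, suppressing noise splits).
#' @param penalty Multiplier of the `log(n) * sigma2` split threshold.
#' @return Tibble of segments: `start_bin`, `end_bin` (0-based half-open
#'   bin indices), `n_bins`, `mean`.
#' @export
#' @examples
#' segment_bins(c(rpois(100, 100), rpois(100, 300)))
segment_bins <- function(values, min_seg_bins = 20L, penalty = 3) {
  n <- length(values)
  if (n < min_seg_bins) {
    warn("fewer bins than min_seg_bins; returning a single segment")
    return(tibble::tibble(start_bin = 0L, end_bin = n, n_bins = n,
                          mean = mean(values)))
  }
  d <- diff(values)
  sigma2 <- if (length(d) > 1) (median(abs(d)) / (0.6744898 * sqrt(2)))^2 else 0
  if (sigma2 == 0) sigma2 <- max(var(values), .Machine$double.eps)
  threshold <- penalty * log(n) * sigma2

  bounds <- integer(0)
  recurse <- function(lo, hi) {  # half-open [lo, hi)
    bs <- best_split(values[(lo + 1L):hi], min_size = min_seg_bins)
    if (is.na(bs$split) || bs$gain <= threshold) return()
    cut <- lo + bs$split
    bounds[[length(bounds) + 1L]] <<- cut
    recurse(lo, cut)
    recurse(cut, hi)
  }
  recurse(0L, n)

  edges <- c(0L, sort(bounds), n)
  tibble::tibble(
    start_bin = edges[-length(edges)],
    end_bin = edges[-1]
  ) |>
    dplyr::mutate(
      n_bins = .data$end_bin - .data$start_bin,
      mean = purrr::map2_dbl(.data$start_bin, .data$end_bin,
                             ~ mean(values[(.x + 1L):.y]))
    )
}

#' Estimate the haploid coverage unit
#'
#' Finds the normalised-coverage value `u` contributed by a single
#' chromosome copy, by grid search over candidate units minimising the
#' length-weighted squared distance of `mean/u` from the nearest integer:
#' \deqn{J(u) = \sum_s n_s\,(m_s/u - \mathrm{round}(m_s/u))^2}
#' subject to every implied copy number being at most `max_cn` and the
#' largest segment receiving at least one copy. Among candidates within 1%
#' of the optimum the largest `u` is returned, which resolves the
#' scale ambiguity (any u/k fits equally well) in favour of the smallest
#' copy numbers.
#'
#' @param segments Segment tibble with columns `mean` and `n_bins`
#'   (e.g. [segment_bins()] output, pooled across chromosomes).
#' @param max_cn Largest admissible copy number.
#' @param grid_points Extra uniformly spaced candidate units evaluated in
#'   addition to the exact `mean/k` candidates.
#' @return The haploid unit `u` (scalar).
#' @export
#' @examples
#' estimate_haploid_unit(tibble::tibble(mean = c(100, 200, 300),
#'                                      n_bins = c(50, 50, 50)))
estimate_haploid_unit <- function(segments, max_cn = 8L, grid_points = 400L) {
  m <- segments$mean
  w <- segments$n_bins
  keep <- m > 0
  if (!any(keep)) abort("no coverage signal: all segment means are zero")
  mx <- max(m)
  cand <- sort(unique(c(
    as.vector(outer(m[keep], seq_len(max_cn), `/`)),
    seq(mx / (max_cn + 0.49), mx, length.out = grid_points)
  )))
  cand <- cand[cand >= mx / (max_cn + 0.49) & cand <= mx * 1.0001]

  obj <- vapply(cand, function(u) {
    r <- m / u
    sum(w * (r - round_half_away(r))^2)
  }, numeric(1))
  jmin <- min(obj)
  tol <- jmin * 1.01 + 1e-12 * sum(w * m^2)
  max(cand[obj <= tol])
}

#' Call integer copy numbers for segments
#'
#' Divides each segment mean by the haploid unit and rounds half away from
#' zero (calls near x.5 under noise must not alternate with round-half-even),
#' clipping into `[0, max_cn]` with a warning.
#'
#' @param segments Segment tibble with a `mean` column.
#' @param u Haploid coverage unit from [estimate_haploid_unit()].
#' @param max_cn Clip ceiling.
#' @return `segments` with an integer `cn` column.
#' @export
call_integer_cn <- function(segments, u, max_cn = 8L) {
  if (u <= 0) abort("haploid unit must be > 0")
  cn_raw <- round_half_away(segments$mean / u)
  if (any(cn_raw > max_cn))
    warn(paste0(sum(cn_raw > max_cn), " segment(s) clipped to max_cn = ", max_cn))
  dplyr::mutate(segments, cn = as.integer(pmin(pmax(cn_raw, 0), max_cn)))
}

#' Estimate a karyotype from binned coverage
#'
#' End-to-end wrapper: normalises coverage, segments every chromosome,
#' estimates the haploid unit jointly across chromosomes, and calls integer
#' copy numbers.
#'
#' @inheritParams normalize_coverage
#' @inheritParams segment_bins
#' @inheritParams call_integer_cn
#' @param bin_width Bin width in bp, used to convert bin indices to
#'   coordinates.
#' @return An object of class `"karyotype"`: list with `segments`
#'   (chromosome, `start`/`end` in bp, `start_bin`/`end_bin`, `mean`
#'   normalised coverage, `cn`), `chromosomes` (modal copy number per
#'   chromosome, see [chromosome_copy_table()]), `unit` (haploid unit) and
#'   `bin_width`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 2, n_chromosomes_per_subgenome = 2,
#'                   genes_per_chromosome = 8, depth_per_copy = 100)
#' sim <- simulate_hybrid_genome(cfg)
#' kt <- call_karyotype(simulate_coverage(sim$truth, cfg))
#' kt$chromosomes
call_karyotype <- function(coverage, min_seg_bins = 20L, penalty = 3,
                           max_cn = 8L, bin_width = NULL) {
  nc <- normalize_coverage(coverage)
  if (is.null(bin_width)) bin_width <- max(nc$end - nc$start)
  segs <- nc |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(~ segment_bins(.x$norm, min_seg_bins = min_seg_bins,
                                       penalty = penalty)) |>
    dplyr::ungroup()
  u <- estimate_haploid_unit(segs, max_cn = max_cn)
  segs <- call_integer_cn(segs, u, max_cn = max_cn) |>
    dplyr::mutate(start = .data$start_bin * bin_width,
                  end = .data$end_bin * bin_width)
  kt <- structure(list(segments = segs, unit = u, bin_width = bin_width),
                  class = "karyotype")
  kt$chromosomes <- chromosome_copy_table(kt)
  kt
}

#' Per-chromosome modal copy numbers and genome total
#'
#' The copy number of a chromosome is defined as the length-weighted mode of
#' its segment copy numbers, so a hybrid chromosome whose arms differ in
#' copy number still contributes a single well-defined count; the genome
#' total is the sum of modal copy numbers over chromosomes. Ties between
#' equally long copy-number states break toward the lower state.
#'
#' @param karyotype A `"karyotype"` object with called segments.
#' @return Tibble `chrom`, `modal_cn`, `n_segments`, with the genome total
#'   in attribute `total_cn`.
#' @export
chromosome_copy_table <- function(karyotype) {
  segs <- if (inherits(karyotype, "karyotype")) karyotype$segments else karyotype
  if (!"cn" %in% names(segs)) abort("segments must carry called cn")
  out <- segs |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(n_segments = dplyr::n()) |>
    dplyr::group_by(.data$chrom, .data$n_segments, .data$cn) |>
    dplyr::summarise(len = sum(.data$n_bins), .groups = "drop") |>
    dplyr::group_by(.data$chrom, .data$n_segments) |>
    dplyr::arrange(dplyr::desc(.data$len), .data$cn, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", modal_cn = "cn", "n_segments")
  attr(out, "total_cn") <- sum(out$modal_cn)
  out
}

#' Detect copy-number breakpoints and their genes
#'
#' Every internal segment boundary where the called copy number changes is
#' reported as a breakpoint and attributed to the gene whose body contains
#' the boundary position; when no gene contains it, the gene with the
#' nearest midpoint is reported, ties resolved toward the lower coordinate.
#'
#' @param karyotype A `"karyotype"` object.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`), sorted or
#'   not.
#' @return Tibble `chrom`, `position` (bp), `left_cn`, `right_cn`,
#'   `gene_id`, `contained` (logical: breakpoint inside the gene body).
#' @export
detect_breakpoints <- function(karyotype, genes) {
  segs <- karyotype$segments |>
    dplyr::arrange(.data$chrom, .data$start_bin)
  bps <- segs |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(right_cn = dplyr::lead(.data$cn),
                  position = .data$end) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$right_cn), .data$right_cn != .data$cn) |>
    dplyr::select("chrom", "position", left_cn = "cn", "right_cn")
  if (nrow(bps) == 0L)
    return(dplyr::mutate(bps, gene_id = character(0), contained = logical(0)))

  g <- dplyr::arrange(genes, .data$chrom, .data$start)
  annotate <- function(chrom, position) {
    gc <- g[g$chrom == chrom, ]
    if (nrow(gc) == 0L)
      return(tibble::tibble(gene_id = NA_character_, contained = FALSE))
    hit <- which(gc$start <= position & position < gc$end)
    if (length(hit) > 0)
      return(tibble::tibble(gene_id = gc$gene_id[hit[1]], contained = TRUE))
    mid <- (gc$start + gc$end) / 2
    i <- which(abs(mid - position) == min(abs(mid - position)))[1]  # lower coord wins ties
    tibble::tibble(gene_id = gc$gene_id[i], contained = FALSE)
  }
  dplyr::bind_cols(bps, purrr::map2_dfr(bps$chrom, bps$position, annotate))
}

#' Assign per-gene copy number from a karyotype
#'
#' A gene's copy number is the called copy number of the segment containing
#' its midpoint on its reference chromosome. Because coverage is mapped to
#' parental reference coordinates, this automatically sums parental copies
#' and the matching arm of any hybrid chromosome copies. Genes on
#' chromosomes absent from the karyotype get copy number 0 with a warning.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, ...).
#' @param karyotype A `"karyotype"` object.
#' @return `genes` with an integer `cn` column.
#' @export
assign_gene_cn <- function(genes, karyotype) {
  segs <- karyotype$segments
  matched <- genes |>
    dplyr::mutate(.mid = (.data$start + .data$end) / 2) |>
    dplyr::inner_join(
      dplyr::select(segs, "chrom", seg_start = "start", seg_end = "end", "cn"),
      by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(.data$.mid >= .data$seg_start, .data$.mid < .data$seg_end) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select(-".mid", -"seg_start", -"seg_end")
  missing <- dplyr::anti_join(genes, matched, by = "gene_id")
  if (nrow(missing) > 0) {
    warn(paste0(nrow(missing), " gene(s) on chromosomes absent from the ",
                "karyotype; copy number set to 0"))
    missing$cn <- 0L
  }
  dplyr::bind_rows(matched, missing) |>
    dplyr::mutate(cn = as.integer(.data$cn)) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Label genes on a hybrid chromosome by breakpoint side
#'
#' Genes entirely on one side of the recombination breakpoint inherit that
#' side's sub-genome; the gene spanning the breakpoint is labelled by the
#' side containing the larger fraction of its length.
#'
#' @param genes Gene tibble for one chromosome (`gene_id`, `start`, `end`).
#' @param breakpoint_pos Breakpoint position (bp).
#' @param left_subgenome,right_subgenome Sub-genome labels of the two arms.
#' @return `genes` with a `subgenome_assigned` column.
#' @export
assign_subgenome_hybrid <- function(genes, breakpoint_pos,
                                    left_subgenome = "Sc",
                                    right_subgenome = "Se") {
  frac_left <- pmin(pmax(breakpoint_pos - genes$start, 0), genes$end - genes$start) /
    (genes$end - genes$start)
  dplyr::mutate(genes, subgenome_assigned =
                  ifelse(frac_left > 0.5, left_subgenome, right_subgenome))
}
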