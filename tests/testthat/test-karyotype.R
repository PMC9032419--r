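test_that("coverage normalisation is the library-size scaling it claims", {
  cov <- tibble::tibble(chrom = "c", start = c(0, 500), end = c(500, 1000),
                        count = c(100, 200), library_size = 1e6)
  expect_equal(normalize_coverage(cov)$norm, c(100, 200))
  cov2 <- dplyr::mutate(cov, library_size = 2e6)
  expect_equal(normalize_coverage(cov2)$norm, c(50, 100))
  cov0 <- dplyr::mutate(cov, count = 0)
  expect_equal(normalize_coverage(cov0)$norm, c(0, 0))
  expect_error(normalize_coverage(dplyr::mutate(cov, library_size = 0)),
               "library_size")
  # linearity / positive homogeneity in the raw counts
  k <- 3.7
  expect_equal(normalize_coverage(dplyr::mutate(cov, count = count * k))$norm,
               normalize_coverage(cov)$norm * k)
})

test_that("segmentation recovers planted change-points", {
  withr::local_seed(21)
  flat <- rpois(400, 200)
  expect_equal(nrow(segment_bins(flat)), 1)

  one <- c(rpois(200, 300), rpois(200, 100))
  s1 <- segment_bins(one)
  expect_equal(nrow(s1), 2)
  expect_lte(abs(s1$end_bin[1] - 200), 2)

  two <- c(rpois(150, 100), rpois(150, 300), rpois(100, 200))
  s2 <- segment_bins(two)
  expect_equal(nrow(s2), 3)
  expect_lte(abs(s2$end_bin[1] - 150), 2)
  expect_lte(abs(s2$end_bin[2] - 300), 2)

  expect_warning(short <- segment_bins(rpois(5, 10), min_seg_bins = 20),
                 "single segment")
  expect_equal(nrow(short), 1)
})

test_that("best split agrees with exhaustive single change-point search", {
  # independent oracle: enumerate every split position, minimise total SSE
  exhaustive <- function(x) {
    n <- length(x)
    sse <- function(v) sum((v - mean(v))^2)
    gains <- vapply(1:(n - 1), function(k)
      sse(x) - sse(x[1:k]) - sse(x[(k + 1):n]), numeric(1))
    list(split = which.max(gains), gain = max(gains))
  }
  withr::local_seed(33)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1), mean = rep(c(0, sample(0:3, 1)),
                                           times = c(10, 20))[1:30])
    x <- x[!is.na(x)]
    ours <- karyodose:::best_split(x, min_size = 1L)
    orac <- exhaustive(x)
    expect_equal(ours$split, orac$split)
    expect_equal(ours$gain, orac$gain, tolerance = 1e-10)
  }
})

test_that("haploid unit estimation inverts the copy-number scale", {
  segs <- tibble::tibble(mean = c(100, 200, 300), n_bins = c(50, 50, 50))
  expect_equal(estimate_haploid_unit(segs), 100)

  # noisy means: compare against an independent dense-grid oracle
  noisy <- tibble::tibble(mean = c(95, 210, 298), n_bins = c(60, 40, 80))
  u <- estimate_haploid_unit(noisy)
  grid <- seq(30, 300, by = 0.01)
  obj <- vapply(grid, function(g) {
    r <- noisy$mean / g
    if (any(round(r) > 8)) return(Inf)
    sum(noisy$n_bins * (r - round(r))^2)
  }, numeric(1))
  u_oracle <- grid[which.min(obj)]
  expect_lt(abs(u - u_oracle), 2)
  expect_equal(round(noisy$mean / u), c(1, 2, 3))

  # unidentifiable single segment resolves to the largest unit (CN 1)
  expect_equal(estimate_haploid_unit(tibble::tibble(mean = 240, n_bins = 10)),
               240)
  expect_error(estimate_haploid_unit(tibble::tibble(mean = 0, n_bins = 5)),
               "no coverage signal")
})

test_that("integer calls round half away from zero and clip", {
  segs <- tibble::tibble(mean = c(2.49, 2.51, 0), n_bins = 1)
  expect_equal(call_integer_cn(segs, u = 1)$cn, c(2L, 3L, 0L))
  expect_warning(clipped <- call_integer_cn(
    tibble::tibble(mean = 20, n_bins = 1), u = 1, max_cn = 8), "clip")
  expect_equal(clipped$cn, 8L)
})

test_that("chromosome table uses length-weighted modal copy number", {
  segs <- tibble::tibble(
    chrom = c("a", "a", "b"),
    start_bin = c(0L, 60L, 0L), end_bin = c(60L, 100L, 50L),
    n_bins = c(60L, 40L, 50L), mean = c(3, 2, 1), cn = c(3L, 2L, 1L))
  kt <- structure(list(segments = segs), class = "karyotype")
  tab <- chromosome_copy_table(kt)
  expect_equal(tab$modal_cn[tab$chrom == "a"], 3L)  # longer state wins
  expect_equal(attr(tab, "total_cn"), 4L)
  # synthetic truth recovery: called totals equal simulated modal totals
  s <- small_sim()
  kt2 <- call_karyotype(simulate_coverage(s$sim$truth, s$cfg))
  expect_equal(attr(kt2$chromosomes, "total_cn"),
               sum(s$sim$truth$chromosomes$modal_cn))
})

test_that("chromosome totals are invariant to bin order within chromosomes", {
  cfg <- sim_config(n_chromosomes_per_subgenome = 4, genes_per_chromosome = 12,
                    chrom_length = 6e4, depth_per_copy = 100,
                    n_hybrid_chromosomes = 0, seed = 13)
  sim <- simulate_hybrid_genome(cfg)
  cov <- simulate_coverage(sim$truth, cfg)
  kt_a <- call_karyotype(cov)
  withr::local_seed(1)
  shuffled <- cov |>
    dplyr::group_by(chrom) |>
    dplyr::mutate(count = sample(count)) |>
    dplyr::ungroup()
  kt_b <- call_karyotype(shuffled)
  expect_equal(attr(kt_b$chromosomes, "total_cn"),
               attr(kt_a$chromosomes, "total_cn"))
})

test_that("breakpoints map to their genes with the stated tie rule", {
  s <- small_sim()
  kt <- call_karyotype(simulate_coverage(s$sim$truth, s$cfg))
  bps <- detect_breakpoints(kt, s$sim$genes)
  hy <- s$sim$truth$hybrids
  expect_gt(nrow(bps), 0)
  # every detected breakpoint names the planted gene (per sub-genome allele)
  expect_true(all(sub("_(Sc|Se)$", "", bps$gene_id) %in% hy$breakpoint_gene))

  # uniform chromosome: no breakpoints
  kt_flat <- structure(list(segments = tibble::tibble(
    chrom = "c", start_bin = 0L, end_bin = 100L, n_bins = 100L,
    mean = 2, cn = 2L, start = 0, end = 50000)), class = "karyotype")
  expect_equal(nrow(detect_breakpoints(kt_flat, s$sim$genes)), 0)

  # boundary exactly between two genes -> lower-coordinate gene
  kt_tie <- structure(list(segments = tibble::tibble(
    chrom = "c", start_bin = c(0L, 10L), end_bin = c(10L, 20L),
    n_bins = 10L, mean = c(1, 2), cn = c(1L, 2L),
    start = c(0, 5000), end = c(5000, 10000))), class = "karyotype")
  genes_tie <- tibble::tibble(
    gene_id = c("left", "right"), chrom = "c",
    start = c(3000, 6000), end = c(4000, 7000))  # midpoints 3500 / 6500
  bp_tie <- detect_breakpoints(kt_tie, genes_tie)
  expect_equal(bp_tie$gene_id, "left")
  expect_false(bp_tie$contained)
})

test_that("gene copy-number assignment reproduces the hybrid chrX pattern", {
  # 2 Sc + 1 Se parental copies + 1 hybrid (Sc left / Se right) recombining
  # at 50 kb: Sc:Se is 3:1 left of the breakpoint and 1:1 right of it
  kt <- structure(list(segments = tibble::tibble(
    chrom = c("Sc_chrX", "Sc_chrX", "Se_chrX", "Se_chrX"),
    start = c(0, 50000, 0, 50000), end = c(50000, 1e5, 50000, 1e5),
    start_bin = c(0L, 100L, 0L, 100L), end_bin = c(100L, 200L, 100L, 200L),
    n_bins = 100L, mean = c(3, 2, 1, 2), cn = c(3L, 2L, 1L, 2L))),
    class = "karyotype")
  genes <- tidyr::crossing(
    sub = c("Sc", "Se"),
    tibble::tibble(start = c(10000, 80000), end = c(12000, 82000))) |>
    dplyr::mutate(chrom = paste0(sub, "_chrX"),
                  gene_id = paste0(ifelse(start < 50000, "gL", "gR"), "_", sub))
  out <- assign_gene_cn(genes, kt)
  cn <- setNames(out$cn, out$gene_id)
  expect_equal(unname(cn[c("gL_Sc", "gL_Se")]), c(3L, 1L))   # 3:1 left
  expect_equal(unname(cn[c("gR_Sc", "gR_Se")]), c(2L, 2L))   # 1:1 right
  expect_equal(ratio_category(cn["gL_Sc"], cn["gL_Se"]), "3:1")
  expect_equal(ratio_category(cn["gR_Sc"], cn["gR_Se"]), "1:1")

  # genes on a chromosome missing from the karyotype get CN 0 with warning
  lost <- tibble::tibble(gene_id = "z_Sc", chrom = "Sc_lost",
                         start = 0, end = 100)
  expect_warning(out2 <- assign_gene_cn(lost, kt), "absent")
  expect_equal(out2$cn, 0L)
})

test_that("simulated genomes are recovered gene by gene", {
  s <- small_sim()
  kt <- call_karyotype(simulate_coverage(s$sim$truth, s$cfg))
  assigned <- assign_gene_cn(s$sim$genes, kt)
  cmp <- dplyr::inner_join(assigned, s$sim$truth$gene_cn[, c("gene_id", "cn_true")],
                           by = "gene_id")
  expect_gte(mean(cmp$cn == cmp$cn_true), 0.99)
})

test_that("hybrid-chromosome gene labels follow the breakpoint side", {
  genes <- tibble::tibble(gene_id = c("a", "b", "c"),
                          start = c(0, 900, 2000), end = c(500, 2000, 2500))
  lab <- assign_subgenome_hybrid(genes, breakpoint_pos = 1230,
                                 left_subgenome = "Sc", right_subgenome = "Se")
  expect_equal(lab$subgenome_assigned, c("Sc", "Se", "Se"))
  # spanning gene b: 330/1100 = 30% left -> majority Se side
})
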