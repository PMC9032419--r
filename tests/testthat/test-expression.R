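test_that("cpm matches its definition and invariances", {
  cts <- tibble::tibble(g = c("a", "b"), s1 = c(5L, 9999995L))
  expect_equal(cpm(cts)$s1[1], 0.5)   # 5 reads in a 1e7 library
  # doubling all counts (and thus the library) leaves CPM unchanged
  cts2 <- dplyr::mutate(cts, s1 = s1 * 2L)
  expect_equal(cpm(cts2)$s1, cpm(cts)$s1)
  # log variant with prior 4 uses the count scale before scaling
  lg <- cpm(cts, log = TRUE, prior_count = 4)
  expect_equal(lg$s1[1], log2((5 + 4) / 1e7 * 1e6))
  # zero count with zero prior is floored, not -Inf
  z <- cpm(tibble::tibble(g = c("a", "b"), s1 = c(0L, 10L)),
           log = TRUE, prior_count = 0)
  expect_true(all(is.finite(z$s1)))
  expect_error(cpm(tibble::tibble(g = "a", s1 = 0L)), "s1")
})

test_that("detection filter boundaries are inclusive", {
  # 0.6 CPM in exactly one sample is kept; all-zero genes are dropped
  cts <- tibble::tibble(g = c("kept", "zero", "boundary"),
                        s1 = c(6L, 0L, 5L), s2 = c(0L, 0L, 0L))
  cts <- dplyr::bind_rows(cts,
    tibble::tibble(g = "filler", s1 = 9999989L, s2 = 1e6L))
  v <- cpm(cts)
  expect_equal(v$s1[3], 0.5)
  f <- filter_detected(cts, min_cpm = 0.5, min_libraries = 1)
  expect_setequal(f$g, c("kept", "boundary", "filler"))
  expect_equal(filter_detected(cts, min_cpm = 0)$g, cts$g)  # identity
})

test_that("size factors follow median-of-ratios", {
  # hand-computed oracle: geometric means (sqrt(200), sqrt(20000), sqrt(32)),
  # per-column ratios are all 1/sqrt(2) and sqrt(2)
  cts <- tibble::tibble(g = c("a", "b", "c"),
                        s1 = c(10, 100, 4), s2 = c(20, 200, 8))
  sf <- size_factors(cts)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)))
  expect_equal(sf$size_factor[2] / sf$size_factor[1], 2)
  # identical columns -> equal factors
  same <- tibble::tibble(g = c("a", "b"), s1 = c(3, 7), s2 = c(3, 7))
  expect_equal(size_factors(same)$size_factor, c(1, 1))
  # scale equivariance: factors are identified up to a common scale, so
  # multiplying one column by c multiplies its factor *ratio* to any other
  # sample by exactly c
  k <- 3.5
  sc <- size_factors(dplyr::mutate(cts, s2 = s2 * k))$size_factor
  expect_equal(sc[2] / sc[1], k * sf$size_factor[2] / sf$size_factor[1],
               tolerance = 1e-12)
  expect_error(size_factors(tibble::tibble(g = c("a", "b"),
                                           s1 = c(0, 1), s2 = c(1, 0))),
               "nonzero")
})

test_that("size factors agree with DESeq2 on a simulated matrix", {
  skip_if_not_installed("DESeq2")
  s <- small_sim()
  sf <- size_factors(s$cts)
  m <- as.matrix(s$cts[, -1])
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # same up to a common scale (conventions differ by geometric-mean centring)
  expect_equal(sf$size_factor / exp(mean(log(sf$size_factor))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-6)
})

test_that("dispersion estimation recovers the generative dispersion", {
  withr::local_seed(5)
  G <- 2000
  mu <- rlnorm(G, log(100), 1)
  mk <- function(alpha, n) {
    y <- matrix(if (alpha == 0) rpois(G * n, rep(mu, n)) else
      rnbinom(G * n, mu = rep(mu, n), size = 1 / alpha), nrow = G,
      dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
    karyodose:::matrix_to_counts(y)
  }
  # Poisson data: median estimate near zero
  d0 <- estimate_dispersion(mk(0, 6), rep(c("A", "B"), each = 3))
  expect_lte(median(d0$dispersion), 0.01)
  # alpha = 0.2, 6 per group: median within [0.1, 0.4]
  d2 <- estimate_dispersion(mk(0.2, 12), rep(c("A", "B"), each = 6))
  expect_gte(median(d2$dispersion), 0.1)
  expect_lte(median(d2$dispersion), 0.4)
  # constant gene: raw moment estimate hits the floor
  cst <- tibble::tibble(g = "const", s1 = 5L, s2 = 5L, s3 = 5L)
  dc <- estimate_dispersion(cst, c("A", "A", "A"),
                            size_factors = tibble::tibble(
                              sample = c("s1", "s2", "s3"), size_factor = 1))
  expect_equal(dc$dispersion_raw, 1e-8)
  expect_error(estimate_dispersion(cst, c("A", "B", "C")), "replicates")
})

test_that("the NB Wald test is exact on degenerate contrasts", {
  # identical per-gene counts in both groups -> log2FC exactly 0
  cts <- tibble::tibble(g = c("a", "b"),
                        s1 = c(10L, 50L), s2 = c(10L, 50L),
                        s3 = c(10L, 50L), s4 = c(10L, 50L))
  info <- tibble::tibble(sample = paste0("s", 1:4),
                         condition = rep(c("minimal", "day2"), each = 2),
                         strain = "X", replicate = c(1, 2, 1, 2))
  res <- nb_wald(cts, info, c("condition", "day2", "minimal"))
  expect_equal(res$log2fc, c(0, 0))
  # constant 2x ratio with equal library scaling -> log2FC exactly 1
  cts2 <- tibble::tibble(g = c("a", "b"),
                         s1 = c(10L, 100L), s2 = c(10L, 100L),
                         s3 = c(20L, 200L), s4 = c(20L, 200L))
  sf1 <- tibble::tibble(sample = paste0("s", 1:4), size_factor = 1)
  res2 <- nb_wald(cts2, info, c("condition", "day2", "minimal"),
                  size_factors = sf1)
  expect_equal(res2$log2fc, c(1, 1), tolerance = 1e-6)
})

test_that("NB Wald agrees with DESeq2 on simulated data", {
  skip_if_not_installed("DESeq2")
  withr::local_seed(9)
  G <- 300
  mu <- rlnorm(G, log(100), 1)
  fc <- 2 ^ rnorm(G, 0, 0.8)
  y <- cbind(
    matrix(rnbinom(G * 3, mu = rep(mu, 3), size = 10), nrow = G),
    matrix(rnbinom(G * 3, mu = rep(mu * fc, 3), size = 10), nrow = G))
  rownames(y) <- paste0("g", 1:G); colnames(y) <- paste0("s", 1:6)
  info <- tibble::tibble(sample = paste0("s", 1:6), strain = "X",
                         condition = rep(c("minimal", "day2"), each = 3),
                         replicate = rep(1:3, 2))
  ours <- nb_wald(karyodose:::matrix_to_counts(y), info,
                  c("condition", "day2", "minimal"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    y, S4Vectors::DataFrame(condition = factor(info$condition,
                                               c("minimal", "day2"))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  keep <- !is.na(ref$log2FoldChange) & !is.na(ours$log2fc)
  expect_gt(cor(ours$log2fc[keep], ref$log2FoldChange[keep]), 0.98)
})

test_that("BH adjustment matches the step-up definition", {
  # brute-force step-up oracle
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p)
    adj <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      r <- which(o == i)  # rank of p[i]
      adj[i] <- min(vapply(r:n, function(j) n * p[o[j]] / j, numeric(1)), 1)
    }
    adj
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::local_seed(8)
  for (n in c(3, 17, 100, 1000)) {
    p <- runif(n) ^ 2
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # NA propagation and validation
  p <- c(0.01, NA, 0.5)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bh_oracle(c(0.01, 0.5)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing in sorted p, and padj >= p
  sp <- sort(runif(50))
  expect_true(all(diff(bh_adjust(sp)) >= -1e-14))
  expect_true(all(bh_adjust(sp) >= sp))
})

test_that("DEG classification applies the documented boundaries", {
  res <- tibble::tibble(
    log2fc = c(1.0, -0.99, 3, -1.0, 0.2, 1.5),
    padj = c(0.049, 0.001, 0.05, 0.0499, 0.01, NA))
  st <- classify_deg(res)$status
  expect_equal(st, c("up",   # lfc boundary inclusive
                     "ns",   # below lfc threshold despite tiny padj
                     "ns",   # FDR boundary strict
                     "down", "ns", "ns"))
  expect_true(all(st %in% c("up", "down", "ns")))  # exact partition
})
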