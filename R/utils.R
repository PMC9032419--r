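#' @importFrom rlang abort warn .data :=
#' @importFrom stats rpois rnbinom rnorm runif median var sd lm coef pchisq
#'   phyper pnorm p.adjust setNames rlnorm quantile
#' @importFrom utils head tail
NULL

# Derive a reproducible substream seed for one simulation stage from the
# master seed, so adding a stage never perturbs draws in earlier stages.
# Constants are arbitrary coprime multipliers; result stays inside the
# 32-bit integer range set.seed() accepts.
substream_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  offs <- c(genome = 11L, coverage = 23L, counts = 37L, misc = 53L)
  if (!stage %in% names(offs)) abort(paste0("unknown seed stage: ", stage))
  as.integer((abs(as.numeric(master)) * 7919 + 104729 * offs[[stage]]) %%
               2147483647)
}

# Round half away from zero. base::round() rounds half to even, which is the
# wrong convention for copy-number calls hovering around x.5.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Greatest common divisor, vectorised over pairs of non-negative integers.
gcd2 <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (any(b != 0L)) {
    r <- ifelse(b != 0L, a %% b, 0L)
    a <- ifelse(b != 0L, b, a)
    b <- r
  }
  a
}

# Extract a counts tibble (gene id first column, sample columns after) into a
# base matrix with gene ids as rownames. The single internal bridge between
# the tidy surface and numeric code.
counts_matrix <- function(counts, id_col = 1L) {
  stopifnot(is.data.frame(counts), ncol(counts) >= 2L)
  ids <- as.character(counts[[id_col]])
  if (anyDuplicated(ids)) abort("duplicate gene ids in count table")
  m <- as.matrix(counts[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_counts <- function(m, id_name = "gene_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id_name := rownames(m)), out)
}
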