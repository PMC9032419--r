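#' Load gene sets from a GMT file
#'
#' GMT: one tab-separated line per term — term id, description, then member
#' gene ids. Duplicate members within a term are removed with a warning.
#'
#' @param path GMT file path.
#' @return Tibble `term_id`, `term_name`, `members` (list-column of unique
#'   gene ids).
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file")
  parsed <- purrr::imap(lines, function(l, i) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      abort(paste0("malformed GMT line ", i, ": need term, description and ",
                   ">= 1 member"))
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warn(paste0("duplicate members in term '", f[1], "'; deduplicated"))
      members <- unique(members)
    }
    tibble::tibble(term_id = f[1], term_name = f[2], members = list(members))
  })
  dplyr::bind_rows(parsed)
}

#' Hypergeometric gene-set enrichment with pathway-level filters
#'
#' Upper-tail hypergeometric test of the overlap between a regulated gene
#' list and each set (members intersected with the universe). All tested
#' terms enter the BH adjustment; a term is then kept iff the overlap has
#' at least `min_genes` genes, covers more than `min_frac` of the set, and
#' the unadjusted p is below `alpha`.
#'
#' @param gene_list Character vector of regulated gene ids (subset of
#'   `universe`).
#' @param universe Character vector of detected gene ids.
#' @param sets [load_gene_sets()] tibble.
#' @param min_genes Minimum overlap size (inclusive).
#' @param min_frac Minimum overlap fraction of the set (inclusive).
#' @param alpha p-value cutoff (exclusive).
#' @return Tibble per tested term: `term_id`, `term_name`, `k` (overlap),
#'   `K` (set size in universe), `n` (list size), `N` (universe size),
#'   `fraction` (`k/K`), `p_value`, `padj`, `kept`, `overlap`
#'   (list-column).
#' @export
hypergeom_enrich <- function(gene_list, universe, sets, min_genes = 4,
                             min_frac = 0.25, alpha = 0.05) {
  gene_list <- unique(gene_list); universe <- unique(universe)
  if (length(gene_list) == 0 || length(universe) == 0)
    abort("gene list and universe must be non-empty")
  if (!all(gene_list %in% universe))
    abort("gene list must be a subset of the universe")
  N <- length(universe); n <- length(gene_list)
  out <- sets |>
    dplyr::mutate(
      set_in_universe = purrr::map(.data$members, intersect, universe),
      K = lengths(.data$set_in_universe),
      overlap = purrr::map(.data$set_in_universe, intersect, gene_list),
      k = lengths(.data$overlap)
    ) |>
    dplyr::filter(.data$K > 0) |>
    dplyr::mutate(
      N = N, n = n,
      fraction = .data$k / .data$K,
      p_value = phyper(.data$k - 1L, .data$K, N - .data$K, n,
                       lower.tail = FALSE),
      padj = bh_adjust(.data$p_value),
      kept = .data$k >= min_genes & .data$fraction >= min_frac &
        .data$p_value < alpha
    ) |>
    dplyr::select("term_id", "term_name", "k", "K", "n", "N", "fraction",
                  "p_value", "padj", "kept", "overlap")
  out
}

#' Sub-genome composition deviation of enrichment overlaps
#'
#' For each term, the observed fraction of `Sc` alleles among the
#' (allele-level) overlap genes minus the expected `Sc` fraction in the
#' strain: positive scores mean Sc-skewed terms, negative Se-skewed, zero
#' the genomic expectation. Terms whose overlap is exclusively `Se` score
#' `-p_sc` and are flagged.
#'
#' @param enrichment [hypergeom_enrich()] result (needs the `overlap`
#'   list-column).
#' @param gene_subgenomes Tibble `gene_id`, `subgenome` mapping overlap
#'   members to sub-genome labels.
#' @param p_sc Expected Sc fraction among detected transcripts.
#' @return `enrichment` plus `sc_fraction`, `composition_score`
#'   (in `[-p_sc, 1 - p_sc]`) and `exclusive_se`.
#' @export
subgenome_composition <- function(enrichment, gene_subgenomes, p_sc) {
  stopifnot(p_sc >= 0, p_sc <= 1)
  lab <- setNames(gene_subgenomes$subgenome, gene_subgenomes$gene_id)
  stats <- purrr::map_dfr(enrichment$overlap, function(ids) {
    sg <- lab[ids]
    n_sc <- sum(sg == "Sc", na.rm = TRUE)
    n_se <- sum(sg == "Se", na.rm = TRUE)
    tot <- n_sc + n_se
    frac <- if (tot > 0) n_sc / tot else NA_real_
    tibble::tibble(sc_fraction = frac,
                   composition_score = if (tot > 0) frac - p_sc else NA_real_,
                   exclusive_se = tot > 0 && n_sc == 0)
  })
  dplyr::bind_cols(enrichment, stats)
}
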