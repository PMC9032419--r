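#' Expected sub-genome proportions from detected genes
#'
#' The genome-wide expectation against which DEG pools are tested: the
#' proportions of detected `Sc` and `Se` transcripts in a strain.
#'
#' @param genes Tibble of detected genes with a `subgenome` column
#'   (`"Sc"`/`"Se"`).
#' @return Tibble `p_sc`, `p_se`, `n_sc`, `n_se`. If one sub-genome is
#'   absent entirely a warning is raised and the proportions are `NA`
#'   (no meaningful test exists).
#' @export
#' @examples
#' expected_subgenome_ratio(tibble::tibble(subgenome = rep(c("Sc", "Se"),
#'                                                         c(6252, 5083))))
expected_subgenome_ratio <- function(genes) {
  n_sc <- sum(genes$subgenome == "Sc")
  n_se <- sum(genes$subgenome == "Se")
  if (n_sc == 0 || n_se == 0) {
    warn("one sub-genome has no detected genes; representation test degenerate")
    return(tibble::tibble(p_sc = NA_real_, p_se = NA_real_,
                          n_sc = n_sc, n_se = n_se))
  }
  tibble::tibble(p_sc = n_sc / (n_sc + n_se), p_se = n_se / (n_sc + n_se),
                 n_sc = n_sc, n_se = n_se)
}

#' Chi-squared test of sub-genome representation
#'
#' Goodness-of-fit test of the observed `Sc`/`Se` split in a gene pool
#' against expected proportions: \eqn{\chi^2 = \sum (O-E)^2/E} with
#' \eqn{E = N p}, one degree of freedom, no continuity correction (pools
#' are large). Significance stars use inclusive thresholds: `"**"` for
#' `p <= 0.001`, `"*"` for `p <= 0.05`.
#'
#' @param n_sc,n_se Observed counts in the pool.
#' @param expected Length-2 vector `c(p_sc, p_se)` summing to 1.
#' @param pool Optional pool label carried into the output.
#' @return One-row tibble: `pool`, `n_sc`, `n_se`, `p_sc_expected`,
#'   `chi2`, `df`, `p_value`, `stars`, `small_expected` (any expected cell
#'   < 1).
#' @export
#' @examples
#' subgenome_chi2(60, 40)          # chi2 = 4, p ~ 0.0455
#' subgenome_chi2(80, 20)          # chi2 = 36
subgenome_chi2 <- function(n_sc, n_se, expected = c(0.5, 0.5), pool = "") {
  if (length(expected) != 2 || any(expected < 0) ||
      abs(sum(expected) - 1) > 1e-8)
    abort("expected must be two proportions summing to 1")
  n <- n_sc + n_se
  if (n < 1) abort("pool must contain at least one gene")
  e <- n * expected
  small <- any(e < 1)
  if (small) warn("expected cell below 1; chi-squared approximation is weak")
  chi2 <- sum((c(n_sc, n_se) - e)^2 / e)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  stars <- if (p <= 0.001) "**" else if (p <= 0.05) "*" else ""
  tibble::tibble(pool = pool, n_sc = n_sc, n_se = n_se,
                 p_sc_expected = expected[1], chi2 = chi2, df = 1L,
                 p_value = p, stars = stars, small_expected = small)
}

#' Region counts and membership for up to three gene lists
#'
#' Computes all exclusive Venn regions (2^k - 1 for k lists) with counts
#' and member ids, the numeric companion of a Venn diagram of DEG pools.
#'
#' @param lists Named list of 1-3 character vectors of gene ids.
#' @return Tibble `region` (e.g. `"A&B"`), `in_sets` (list-column of set
#'   names), `n`, `members` (list-column).
#' @export
#' @examples
#' deg_set_ops(list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = "c"))
deg_set_ops <- function(lists) {
  k <- length(lists)
  if (k < 1 || k > 3) abort("deg_set_ops supports 1 to 3 lists")
  if (is.null(names(lists)) || any(names(lists) == ""))
    names(lists) <- LETTERS[seq_len(k)]
  lists <- purrr::map(lists, unique)
  universe <- unique(unlist(lists))
  member <- vapply(lists, function(l) universe %in% l,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(lists)))
  combos <- rev(expand.grid(rep(list(c(TRUE, FALSE)), k)))[-(2^k), , drop = FALSE]
  names(combos) <- names(lists)
  purrr::pmap_dfr(combos, function(...) {
    inc <- c(...)
    sel <- rep(TRUE, length(universe))
    for (j in seq_len(k)) sel <- sel & (member[, j] == inc[j])
    tibble::tibble(
      region = paste(names(lists)[inc], collapse = "&"),
      in_sets = list(names(lists)[inc]),
      n = sum(sel),
      members = list(universe[sel])
    )
  })
}
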