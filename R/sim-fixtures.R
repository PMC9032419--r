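#' Write a simulated dataset as plain-text fixtures
#'
#' Emits the standard on-disk representation used by the readers in this
#' package: genes as 6-column BED (0-based half-open), the orthologue map as
#' TSV, coverage as 4-column bedGraph plus a JSON sidecar holding the
#' library size, counts as TSV with the sample sheet as a sidecar, and the
#' generative truth as JSON. All files round-trip losslessly through
#' [read_gene_bed()], [read_ortholog_map()], [read_coverage_bedgraph()],
#' [read_counts_tsv()] and [read_truth_json()].
#'
#' @param outdir Output directory (created if absent).
#' @param genes,truth Gene tibble and truth list from
#'   [simulate_hybrid_genome()].
#' @param coverage Coverage tibble from [simulate_coverage()].
#' @param counts Counts tibble from [simulate_counts()].
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(outdir, genes, truth, coverage, counts) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, mode = 2) != 0)
    abort(paste0("cannot write to directory: ", outdir))
  p <- function(f) file.path(outdir, f)

  bed <- genes |>
    dplyr::transmute(.data$chrom, .data$start, .data$end, name = .data$gene_id,
                     score = 0L, strand = "+")
  readr::write_tsv(bed, p("genes.bed"), col_names = FALSE)

  orth <- genes |>
    dplyr::select("base_id", "subgenome", "gene_id") |>
    tidyr::pivot_wider(names_from = "subgenome", values_from = "gene_id")
  for (col in c("Sc", "Se")) if (!col %in% names(orth))
    orth[[col]] <- NA_character_
  orth <- dplyr::rename(orth, sc_id = "Sc", se_id = "Se")
  readr::write_tsv(orth, p("orthologs.tsv"))

  readr::write_tsv(coverage[, c("chrom", "start", "end", "count")],
                   p("coverage.bedGraph"), col_names = FALSE)
  jsonlite::write_json(list(library_size = coverage$library_size[1]),
                       p("coverage_meta.json"), auto_unbox = TRUE)

  readr::write_tsv(counts, p("counts.tsv"))
  design <- attr(counts, "design")
  if (!is.null(design)) readr::write_tsv(design, p("samples.tsv"))

  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)

  invisible(c(genes = p("genes.bed"), orthologs = p("orthologs.tsv"),
              coverage = p("coverage.bedGraph"),
              coverage_meta = p("coverage_meta.json"),
              counts = p("counts.tsv"), samples = p("samples.tsv"),
              truth = p("truth.json")))
}

#' Read gene annotations from BED
#'
#' Expects 4+ columns (chrom, start, end, name). Gene ids of the form
#' `<base>_Sc` / `<base>_Se` are split back into orthologue-group id and
#' sub-genome label.
#'
#' @param path BED file path.
#' @return Gene tibble: `gene_id`, `base_id`, `subgenome`, `chrom`,
#'   `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(bed) < 4) abort("BED file needs at least 4 columns")
  tibble::tibble(
    gene_id = as.character(bed[[4]]),
    base_id = sub("_(Sc|Se)$", "", as.character(bed[[4]])),
    subgenome = ifelse(grepl("_Se$", bed[[4]]), "Se",
                       ifelse(grepl("_Sc$", bed[[4]]), "Sc", NA_character_)),
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]])
  ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Read an orthologue-mapping table
#' @param path TSV with header columns `base_id`, `sc_id`, `se_id`.
#' @return A tibble with those columns.
#' @export
read_ortholog_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read binned coverage from bedGraph
#'
#' @param path 4-column bedGraph (chrom, start, end, count).
#' @param library_size Total mapped reads. Defaults to the value in a
#'   `coverage_meta.json` sidecar next to `path`, else to the sum of counts.
#' @return Coverage tibble: `chrom`, `start`, `end`, `count`, `library_size`.
#' @export
read_coverage_bedgraph <- function(path, library_size = NULL) {
  bg <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "count"),
                        show_col_types = FALSE)
  if (is.null(library_size)) {
    meta <- file.path(dirname(path), "coverage_meta.json")
    library_size <- if (file.exists(meta))
      jsonlite::read_json(meta)$library_size else sum(bg$count)
  }
  bg$library_size <- library_size
  dplyr::arrange(bg, .data$chrom, .data$start)
}

#' Read a counts TSV and optional sample sheet
#' @param path Counts TSV (header row, gene id first column).
#' @param samples_path Optional sample-sheet TSV; attached as the `design`
#'   attribute.
#' @return Counts tibble.
#' @export
read_counts_tsv <- function(path, samples_path = NULL) {
  cts <- readr::read_tsv(path, show_col_types = FALSE)
  cts[[1]] <- as.character(cts[[1]])
  if (!is.null(samples_path))
    attr(cts, "design") <- readr::read_tsv(samples_path, show_col_types = FALSE)
  cts
}

#' Read a simulation truth JSON back into tibbles
#' @param path `truth.json` written by [write_fixture()].
#' @return Truth list with tibble components.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("chromosomes", "hybrids", "segments", "gene_cn", "expression"))
    x[[nm]] <- tibble::as_tibble(x[[nm]])
  x
}
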