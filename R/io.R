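#' Read a gene-by-tissue expression matrix from TSV
#'
#' Expects a UTF-8 tab-separated file with a header row whose first column
#' is `gene`; the remaining columns are tissue (or sample) names holding
#' non-negative transcripts-per-million values.
#'
#' @param path File path.
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per tissue.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  # parsing problems are surfaced as our own error below, not as warnings
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  )))
  if (!nrow(raw) || ncol(raw) < 2) abort(paste0("empty or header-only expression table: ", path))
  if (names(raw)[1] != "gene") abort("first column of an expression TSV must be 'gene'")
  prob <- readr::problems(raw)
  if (nrow(prob)) {
    abort(paste0("non-numeric cell at row ", prob$row[1], ", column ", prob$col[1],
                 " of ", path))
  }
  validate_expression_table(raw)
  raw
}

validate_expression_table <- function(tbl, what = "expression table") {
  if (anyDuplicated(tbl$gene)) {
    abort(paste0("duplicate gene rows in ", what, ": ",
                 paste(unique(tbl$gene[duplicated(tbl$gene)]), collapse = ", ")))
  }
  if (anyDuplicated(names(tbl))) abort(paste0("duplicate tissue columns in ", what))
  vals <- as.matrix(tbl[-1])
  if (any(vals < 0, na.rm = TRUE)) abort(paste0("negative values in ", what))
  invisible(tbl)
}

#' Write a gene-by-tissue table to TSV
#'
#' @param tbl Tibble with a `gene` column (expression values or call tokens).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a trichotomous call matrix from TSV
#'
#' Reads a symbol matrix in the style of the packaged tissue table: first
#' column `gene`, remaining columns tissues, cells holding the call tokens
#' (by default `-`, `+`, `++`).
#'
#' @param path File path.
#' @param tokens Named character vector with entries `none`, `expressed`,
#'   `high`.
#' @return A long tibble of class `th_calls` with columns `gene`, `tissue`,
#'   `call` (ordered factor over the three tokens).
#' @examples
#' calls <- read_call_matrix(thprof_example("tissue_calls_human.tsv"))
#' dplyr::count(calls, call)
#' @export
read_call_matrix <- function(path, tokens = th_call_tokens) {
  check_tokens(tokens)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  wide <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (names(wide)[1] != "gene") abort("first column of a call matrix must be 'gene'")
  if (anyDuplicated(wide$gene)) abort("duplicate gene rows in call matrix")
  long <- tidyr::pivot_longer(wide, -"gene", names_to = "tissue", values_to = "call")
  bad <- setdiff(unique(long$call), unname(tokens))
  if (length(bad)) {
    abort(paste0("unknown call tokens in ", path, ": ",
                 paste(bad, collapse = ", ")))
  }
  long$call <- call_factor(long$call, tokens)
  new_th_calls(long, tokens = tokens, provenance = list(source = path))
}

#' Write calls as a Table-style symbol matrix
#'
#' Inverse of [read_call_matrix()]: pivots a long call table to the wide
#' `gene` x tissue token matrix and writes it as TSV.
#'
#' @param calls A `th_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_matrix <- function(calls, path) {
  wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(calls), "gene", "tissue", "call"),
    names_from = "tissue", values_from = "call"
  )
  wide <- dplyr::mutate(wide, dplyr::across(-"gene", as.character))
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name`, `description`, then the member symbols. Duplicate members within
#' a set are dropped with a warning.
#'
#' @param path File path.
#' @return A list of `th_geneset` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("empty GMT file: ", path))
  purrr::map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(paste0("malformed GMT line (need name, description, >=1 member): ",
                   substr(l, 1, 60)))
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) abort(paste0("GMT set '", f[1], "' has an empty member list"))
    if (anyDuplicated(genes)) {
      warn(paste0("GMT set '", f[1], "': duplicate members dropped"))
    }
    new_geneset(f[1], f[2], genes)
  })
}

#' Write gene sets to a GMT file
#'
#' @param sets A `th_geneset` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "th_geneset")) sets <- list(sets)
  lines <- purrr::map_chr(sets, function(s) {
    paste(c(s$name, s$description %||% "", s$genes), collapse = "\t")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
thprof_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "thprof")))
  }
  extdata_path(file)
}
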