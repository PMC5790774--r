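#' Load the packaged Th-subset regulator catalog
#'
#' Returns the curated panel of 61 CD4+ T-helper subset regulators
#' (transcription factors, activators, a repressor, signal transducers,
#' cytokines, lineage-inducing factors and receptors), each annotated with
#' the subset(s) it regulates. Genes that regulate several subsets (for
#' example IL2, which maps to Th1, Th2, Th9 and Treg) appear as a single row
#' whose `subsets` list-column holds all memberships.
#'
#' Symbols are cased per species convention: upper-case for human
#' (`FOXP3`), title-case for mouse (`Foxp3`). The printed spellings of the
#' source table are preserved verbatim; [load_gene_aliases()] maps them to
#' standard symbols but is never applied silently.
#'
#' @param species `"human"` or `"mouse"`.
#' @return A tibble of class `th_catalog` with columns `symbol`,
#'   `common_name`, `unigene` (the species' database identifier, `NA` when
#'   none is printed), `category` (one of the eight regulator categories)
#'   and `subsets` (list-column of subset codes).
#' @examples
#' cat_h <- load_regulator_catalog("human")
#' nrow(cat_h) # 61
#' dplyr::count(cat_h, category)
#' @export
load_regulator_catalog <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  raw <- readr::read_tsv(
    extdata_path("th_regulators.tsv"),
    col_types = readr::cols(.default = readr::col_character())
  )
  need <- c("symbol", "common_name", "unigene_human", "unigene_mouse",
            "category", "subsets")
  if (!all(need %in% names(raw))) {
    abort("regulator catalog fixture is corrupt: missing columns")
  }
  out <- tibble(
    symbol = if (species == "human") toupper(raw$symbol) else mouse_case(raw$symbol),
    common_name = raw$common_name,
    unigene = if (species == "human") raw$unigene_human else raw$unigene_mouse,
    category = raw$category,
    subsets = strsplit(raw$subsets, ";", fixed = TRUE)
  )
  validate_catalog(out)
  structure(out, species = species, class = c("th_catalog", class(out)))
}

validate_catalog <- function(x) {
  if (anyDuplicated(x$symbol)) {
    abort(paste0("duplicate catalog symbols: ",
                 paste(unique(x$symbol[duplicated(x$symbol)]), collapse = ", ")))
  }
  bad_cat <- setdiff(unique(x$category), th_category_codes)
  if (length(bad_cat)) {
    abort(paste0("unknown regulator categories in fixture: ",
                 paste(bad_cat, collapse = ", ")))
  }
  subs <- unique(unlist(x$subsets))
  if (any(lengths(x$subsets) == 0) || !all(subs %in% th_subset_codes)) {
    abort("every regulator must carry at least one valid Th-subset code")
  }
  invisible(x)
}

# Mouse gene-symbol convention: first letter capitalized, rest lower-case.
mouse_case <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
}

#' @export
print.th_catalog <- function(x, ...) {
  cat("Th-subset regulator catalog (", attr(x, "species"), "), ",
      nrow(x), " genes\n", sep = "")
  NextMethod()
}

#' Regulators mapped to one Th subset
#'
#' Inverse index over the catalog: all regulators whose subset memberships
#' include `subset`, in fixture order.
#'
#' @param catalog A catalog from [load_regulator_catalog()].
#' @param subset One of `"Th1"`, `"Th2"`, `"Th9"`, `"Tfh"`, `"Th17"`,
#'   `"Treg"`, `"Th22"`, `"Th25"`.
#' @return A tibble with the same columns as the catalog.
#' @examples
#' regulators_for_subset(load_regulator_catalog("human"), "Th1")$symbol
#' @export
regulators_for_subset <- function(catalog, subset) {
  if (!is.character(subset) || length(subset) != 1 ||
      !subset %in% th_subset_codes) {
    abort(paste0("'subset' must be one of: ",
                 paste(th_subset_codes, collapse = ", ")))
  }
  dplyr::filter(catalog, purrr::map_lgl(.data$subsets, ~ subset %in% .x))
}

#' Load a packaged gene set
#'
#' Serves the curated gene panels used by the analysis:
#' * `mhc2_mouse` — the 14 mouse MHC class II molecules;
#' * `cosignal_partial` — the partial co-stimulation/co-inhibition receptor
#'   panel named in the source text. This list is **incomplete** (the full
#'   28-gene panel is not machine-readable) and must not be treated as the
#'   complete co-signaling receptor complement;
#' * `housekeeping_human` — PRS27A, GADPH, ARHGDIA (printed spellings);
#' * `housekeeping_mouse` — Ldha, Nono, Rpl32.
#'
#' @param name Set name, see above.
#' @return A `th_geneset`: list with `name`, `description` and `genes`.
#' @examples
#' length(load_gene_set("mhc2_mouse")$genes) # 14
#' @export
load_gene_set <- function(name) {
  sets <- read_gmt(extdata_path("gene_sets.gmt"))
  idx <- match(name, purrr::map_chr(sets, "name"))
  if (is.na(idx)) {
    abort(paste0("unknown gene set '", name, "'; available: ",
                 paste(purrr::map_chr(sets, "name"), collapse = ", ")))
  }
  sets[[idx]]
}

new_geneset <- function(name, description, genes) {
  if (!length(genes)) abort("a gene set must contain at least one gene")
  structure(list(name = name, description = description,
                 genes = unique(genes)),
            class = "th_geneset")
}

#' @export
print.th_geneset <- function(x, ...) {
  cat("Gene set '", x$name, "' (", length(x$genes), " genes)\n", sep = "")
  if (nzchar(x$description %||% "")) cat("  ", x$description, "\n", sep = "")
  cat("  ", paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Printed-symbol alias map
#'
#' The source tables contain non-standard spellings (e.g. `GADPH`,
#' `PRS27A`) and synonym-style names for co-signaling receptors (`B7-1`,
#' `LIGHT`). This map relates each printed symbol to its standard gene
#' symbol. It is provided for auditing and explicit joins only; no package
#' function applies it implicitly.
#'
#' @return A tibble with columns `printed`, `canonical`, `note`.
#' @export
load_gene_aliases <- function() {
  readr::read_tsv(extdata_path("gene_aliases.tsv"),
                  col_types = readr::cols(.default = readr::col_character()))
}
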