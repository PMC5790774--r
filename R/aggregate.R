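#' Per-tissue Th-subset expression summaries
#'
#' Tallies the trichotomous calls of the catalog regulators per
#' (tissue, subset) pair. A regulator mapped to several subsets contributes
#' to every subset it carries. Only regulators actually present in the call
#' table are counted (`n_regulators` is the measured panel size).
#'
#' @param calls A `th_calls` tibble (from [profile_pipeline()] or
#'   [read_call_matrix()]).
#' @param catalog A `th_catalog` from [load_regulator_catalog()].
#' @return A tibble of class `th_subset_summary`: `tissue`, `subset`,
#'   `n_regulators`, `n_expressed` (expressed or high), `n_high`,
#'   `fraction_high`.
#' @examples
#' calls <- read_call_matrix(thprof_example("tissue_calls_human.tsv"))
#' summarize_subsets(calls, load_regulator_catalog("human"))
#' @export
summarize_subsets <- function(calls, catalog) {
  map <- tidyr::unnest(
    dplyr::select(as_tibble(catalog), gene = "symbol", "subsets"),
    "subsets"
  )
  map <- dplyr::rename(map, subset = "subsets")
  flags <- call_flags(calls)
  calls2 <- dplyr::mutate(as_tibble(calls),
                          .expressed = flags$expressed, .high = flags$high)
  measured <- dplyr::inner_join(calls2, map, by = "gene",
                                relationship = "many-to-many")
  if (!nrow(measured)) {
    warn("no catalog regulators found in the call table; empty summary")
  }
  out <- dplyr::summarise(
    dplyr::group_by(measured, .data$tissue, .data$subset),
    n_regulators = dplyr::n_distinct(.data$gene),
    n_expressed = sum(.data$.expressed),
    n_high = sum(.data$.high),
    .groups = "drop"
  )
  out <- dplyr::mutate(out, fraction_high = ifelse(
    .data$n_regulators > 0, .data$n_high / .data$n_regulators, 0
  ))
  structure(out, class = c("th_subset_summary", class(tibble())))
}

#' Count tissues where genes are expressed / highly expressed
#'
#' The per-gene tissue counts quoted in tissue-atlas analyses: for each
#' requested gene, the number of tissues called expressed-or-high and the
#' number called high.
#'
#' @param calls A `th_calls` tibble.
#' @param genes Character vector of gene symbols present in `calls`.
#' @return A tibble: `gene`, `n_expressed`, `n_high`.
#' @examples
#' calls <- read_call_matrix(thprof_example("tissue_calls_human.tsv"))
#' count_expression(calls, c("GATA3", "SPI1"))
#' @export
count_expression <- function(calls, genes) {
  missing <- setdiff(genes, unique(calls$gene))
  if (length(missing)) {
    abort(paste0("genes not in call table: ", paste(missing, collapse = ", ")))
  }
  flags <- call_flags(calls)
  df <- dplyr::mutate(as_tibble(calls),
                      .expressed = flags$expressed, .high = flags$high)
  df <- dplyr::filter(df, .data$gene %in% genes)
  out <- dplyr::summarise(dplyr::group_by(df, .data$gene),
                          n_expressed = sum(.data$.expressed),
                          n_high = sum(.data$.high), .groups = "drop")
  out[match(genes, out$gene), ]
}

#' Tissue pyramid: rank tissues by Th-subset variety
#'
#' Ranks tissues by the number of distinct Th subsets with at least one
#' highly expressed regulator, breaking ties by the number of subsets with
#' at least one expressed regulator, then by tissue name. Tissues at the
#' top of the pyramid host the widest variety of Th-subset activity.
#'
#' @param summaries A `th_subset_summary` from [summarize_subsets()].
#' @return A tibble of class `th_pyramid`, ordered top-down: `tissue`,
#'   `n_subsets_high`, `n_subsets_expressed`.
#' @export
tissue_pyramid <- function(summaries) {
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(summaries), .data$tissue),
    n_subsets_high = sum(.data$n_high >= 1),
    n_subsets_expressed = sum(.data$n_expressed >= 1),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$n_subsets_high),
                        dplyr::desc(.data$n_subsets_expressed), .data$tissue)
  structure(out, class = c("th_pyramid", class(tibble())))
}

#' Dominant Th subsets of a tissue
#'
#' Scores each subset in a tissue and reports which subset(s) attain the
#' maximal score. The default score is size-normalized — the fraction of
#' the subset's measured regulators called highly expressed — because the
#' subset panels differ greatly in size (1 to 20 genes). Raw high counts
#' are available via `score = "n_high"`.
#'
#' When every score is zero, no subset is marked dominant.
#'
#' @param summaries A `th_subset_summary`.
#' @param tissue Tissue name present in `summaries`.
#' @param score `"fraction_high"` (default) or `"n_high"`.
#' @return A tibble: `subset`, `score`, `dominant` (logical); the tissue is
#'   attached as attribute `tissue`.
#' @export
dominant_subsets <- function(summaries, tissue,
                             score = c("fraction_high", "n_high")) {
  score <- match.arg(score)
  df <- dplyr::filter(as_tibble(summaries), .data$tissue == !!tissue)
  if (!nrow(df)) abort(paste0("unknown tissue: ", tissue))
  out <- tibble(subset = df$subset, score = df[[score]])
  top <- max(out$score)
  out$dominant <- out$score == top & top > 0
  structure(dplyr::arrange(out, dplyr::desc(.data$score), .data$subset),
            tissue = tissue, class = class(tibble()))
}

#' Flag candidate immune-privileged tissues
#'
#' Tissues with no (or nearly no) resident Th-subset activity: total high
#' calls across all subsets at most `min_high` and overall expressed
#' fraction below `max_expressed_fraction`. The defaults (`min_high = 0`,
#' no expressed-fraction constraint) flag exactly the tissues in which not
#' a single regulator reaches the high-expression threshold.
#'
#' @param summaries A `th_subset_summary`.
#' @param min_high Maximum tolerated number of high calls (summed over
#'   subsets); default 0.
#' @param max_expressed_fraction Strict upper bound on the tissue's
#'   expressed fraction; default `Inf` (inactive).
#' @return A tibble of flagged tissues: `tissue`, `n_high_total`,
#'   `expressed_fraction`.
#' @export
immune_privilege_flags <- function(summaries, min_high = 0,
                                   max_expressed_fraction = Inf) {
  per_tissue <- dplyr::summarise(
    dplyr::group_by(as_tibble(summaries), .data$tissue),
    n_high_total = sum(.data$n_high),
    expressed_fraction = sum(.data$n_expressed) / sum(.data$n_regulators),
    .groups = "drop"
  )
  dplyr::filter(per_tissue,
                .data$n_high_total <= min_high,
                .data$expressed_fraction < max_expressed_fraction)
}

#' @exportS3Method generics::glance
glance.th_subset_summary <- function(x, ...) {
  tibble(
    n_tissues = dplyr::n_distinct(x$tissue),
    n_subsets = dplyr::n_distinct(x$subset),
    total_high = sum(x$n_high),
    total_expressed = sum(x$n_expressed)
  )
}
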