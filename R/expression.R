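#' Normalize expression to beta-actin arbitrary units
#'
#' Divides every gene's transcripts-per-million (TPM) by the reference
#' gene's TPM in the same tissue, yielding dimensionless arbitrary units
#' (AU). The reference row itself becomes 1 in every tissue.
#'
#' Tissues where the reference gene has zero TPM cannot be normalized; they
#' raise an error naming the offending tissues rather than imputing.
#'
#' @param tbl Expression tibble: `gene` column plus numeric tissue columns
#'   (TPM). `NA` cells are treated as TPM 0 (absence in the source library
#'   is indistinguishable from non-expression).
#' @param ref_gene Reference gene symbol; default `"ACTB"` (beta-actin).
#' @return A tibble of the same shape holding AU values, with attributes
#'   `ref_gene` and `n_missing` (count of `NA` cells treated as 0).
#' @examples
#' tpm <- tibble::tibble(gene = c("ACTB", "FOXP3"), liver = c(100, 50))
#' normalize_arbitrary_units(tpm)$liver # 1.0, 0.5
#' @export
normalize_arbitrary_units <- function(tbl, ref_gene = "ACTB") {
  validate_expression_table(tbl)
  if (!ref_gene %in% tbl$gene) {
    abort(paste0("reference gene '", ref_gene, "' is not in the table"))
  }
  vals <- as.matrix(tbl[-1])
  n_missing <- sum(is.na(vals))
  vals[is.na(vals)] <- 0
  ref <- vals[match(ref_gene, tbl$gene), ]
  zero <- names(ref)[ref <= 0]
  if (length(zero)) {
    abort(paste0("reference gene '", ref_gene, "' has zero TPM in: ",
                 paste(zero, collapse = ", "), "; cannot form arbitrary units"))
  }
  au <- sweep(vals, 2, ref, "/")
  out <- dplyr::bind_cols(tbl[1], as_tibble(au))
  attr(out, "ref_gene") <- ref_gene
  attr(out, "n_missing") <- n_missing
  out
}

#' Housekeeping mean + 2 SD significance threshold
#'
#' Computes the upper limit of the housekeeping expression band:
#' `mean + 2 * SD` of the arbitrary-unit values of a fixed housekeeping
#' panel, using the sample standard deviation (n - 1 denominator). An AU
#' value above this limit is considered significantly high expression.
#'
#' With `scope = "pooled"` (default) all housekeeping AU values across all
#' tissues form one sample and a single limit applies everywhere; with
#' `scope = "per_tissue"` each tissue gets its own limit from that tissue's
#' housekeeping values.
#'
#' @param au Arbitrary-unit tibble from [normalize_arbitrary_units()].
#' @param hk_genes Character vector of housekeeping gene symbols present in
#'   `au` (the packaged panels have three genes each, see
#'   [load_gene_set()]).
#' @param scope `"pooled"` or `"per_tissue"`.
#' @return An object of class `hk_threshold`: list with `scope`,
#'   `hk_genes`, and a `stats` tibble (`tissue`, `mean`, `sd`, `upper`;
#'   `tissue` is `NA` for the pooled scope).
#' @examples
#' au <- tibble::tibble(gene = c("ACTB", "HK1", "HK2"),
#'                      t1 = c(1, 0.2, 0.4), t2 = c(1, 0.6, 0.4))
#' housekeeping_threshold(au, c("HK1", "HK2"))$stats$upper
#' @export
housekeeping_threshold <- function(au, hk_genes,
                                   scope = c("pooled", "per_tissue")) {
  scope <- match.arg(scope)
  missing <- setdiff(hk_genes, au$gene)
  if (length(missing)) {
    abort(paste0("housekeeping genes not in table: ",
                 paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(au[match(hk_genes, au$gene), -1, drop = FALSE])
  if (scope == "pooled") {
    v <- vals[is.finite(vals)]
    if (length(v) < 2) abort("degenerate threshold: fewer than 2 usable housekeeping AU values")
    stats <- tibble(tissue = NA_character_, mean = mean(v), sd = sd(v),
                    upper = mean(v) + 2 * sd(v))
  } else {
    if (length(hk_genes) < 2) {
      abort("per-tissue scope needs at least 2 housekeeping genes")
    }
    stats <- purrr::map_dfr(colnames(vals), function(t) {
      v <- vals[, t]
      v <- v[is.finite(v)]
      if (length(v) < 2) {
        abort(paste0("degenerate threshold in tissue '", t,
                     "': fewer than 2 usable housekeeping AU values"))
      }
      tibble(tissue = t, mean = mean(v), sd = sd(v),
             upper = mean(v) + 2 * sd(v))
    })
  }
  structure(list(scope = scope, hk_genes = hk_genes, stats = stats),
            class = "hk_threshold")
}

#' @export
print.hk_threshold <- function(x, ...) {
  cat("Housekeeping threshold (mean + 2*SD), scope = ", x$scope,
      ", panel: ", paste(x$hk_genes, collapse = ", "), "\n", sep = "")
  print(x$stats, ...)
  invisible(x)
}

#' Trichotomous expression calling
#'
#' Applies the two calling rules per gene-tissue cell:
#' * TPM below 1 per million: not expressed (`-`);
#' * otherwise, AU strictly above the housekeeping upper limit: highly
#'   expressed (`++`);
#' * otherwise: low expressed (`+`).
#'
#' Ties fall to the lower category (a TPM of exactly 1 is expressed; an AU
#' exactly at the limit is not high).
#'
#' @param tbl TPM tibble (`gene` + tissue columns).
#' @param au Matching arbitrary-unit tibble.
#' @param threshold An `hk_threshold` from [housekeeping_threshold()].
#' @param tokens Call tokens, see [read_call_matrix()].
#' @return A `th_calls` tibble: columns `gene`, `tissue`, `tpm`, `au`,
#'   `call`, with the threshold and reference recorded as attributes.
#' @export
call_expression <- function(tbl, au, threshold, tokens = th_call_tokens) {
  check_tokens(tokens)
  if (!identical(tbl$gene, au$gene) || !identical(names(tbl), names(au))) {
    abort("TPM and AU tables must share identical gene and tissue axes")
  }
  if (!inherits(threshold, "hk_threshold")) {
    abort("'threshold' must be an hk_threshold object")
  }
  long_tpm <- tidyr::pivot_longer(tbl, -"gene", names_to = "tissue",
                                  values_to = "tpm")
  long_au <- tidyr::pivot_longer(au, -"gene", names_to = "tissue",
                                 values_to = "au")
  long <- dplyr::left_join(long_tpm, long_au, by = c("gene", "tissue"))
  long$tpm[is.na(long$tpm)] <- 0
  if (threshold$scope == "pooled") {
    long$upper <- threshold$stats$upper
  } else {
    long <- dplyr::left_join(long,
                             dplyr::select(threshold$stats, "tissue", "upper"),
                             by = "tissue")
    if (anyNA(long$upper)) {
      abort("per-tissue threshold does not cover all tissues in the table")
    }
  }
  long$call <- call_factor(dplyr::case_when(
    long$tpm < 1 ~ tokens[["none"]],
    long$au > long$upper ~ tokens[["high"]],
    TRUE ~ tokens[["expressed"]]
  ), tokens)
  long$upper <- NULL
  new_th_calls(long, tokens = tokens,
               ref_gene = attr(au, "ref_gene"),
               threshold = threshold,
               provenance = list(
                 n_missing = attr(au, "n_missing") %||% 0L,
                 rules = "tpm<1 -> none; au>upper -> high; else expressed"
               ))
}

#' Full expression-profiling pipeline
#'
#' Composes [normalize_arbitrary_units()], [housekeeping_threshold()] and
#' [call_expression()]: TPM table in, trichotomous call table out.
#'
#' @inheritParams normalize_arbitrary_units
#' @param hk_genes Housekeeping panel symbols; defaults to the packaged
#'   panel for `hk_panel`.
#' @param hk_panel `"human"` or `"mouse"`; ignored when `hk_genes` is given.
#' @param scope Threshold scope, see [housekeeping_threshold()].
#' @param tokens Call tokens.
#' @return A `th_calls` tibble (see [call_expression()]).
#' @examples
#' sim <- simulate_tissue_panel(n_genes = 20, n_tissues = 4, seed = 1)
#' calls <- profile_pipeline(sim$expression, hk_genes = sim$hk_genes)
#' dplyr::count(calls, call)
#' @export
profile_pipeline <- function(tbl, ref_gene = "ACTB", hk_genes = NULL,
                             hk_panel = c("human", "mouse"),
                             scope = c("pooled", "per_tissue"),
                             tokens = th_call_tokens) {
  scope <- match.arg(scope)
  if (is.null(hk_genes)) {
    hk_panel <- match.arg(hk_panel)
    hk_genes <- load_gene_set(paste0("housekeeping_", hk_panel))$genes
  }
  au <- normalize_arbitrary_units(tbl, ref_gene = ref_gene)
  thr <- housekeeping_threshold(au, hk_genes = hk_genes, scope = scope)
  call_expression(tbl, au, thr, tokens = tokens)
}

new_th_calls <- function(long, tokens, ref_gene = NULL, threshold = NULL,
                         provenance = list()) {
  structure(long,
            tokens = tokens, ref_gene = ref_gene, threshold = threshold,
            provenance = provenance,
            class = c("th_calls", class(tibble())))
}

check_tokens <- function(tokens) {
  if (!all(c("none", "expressed", "high") %in% names(tokens)) ||
      anyDuplicated(tokens)) {
    abort("'tokens' must be distinct values named none, expressed, high")
  }
  invisible(tokens)
}

# Map a call column to logical expressed / high indicators using the
# tokens attached to the calls object.
call_flags <- function(calls) {
  tokens <- attr(calls, "tokens") %||% th_call_tokens
  list(
    expressed = calls$call %in% tokens[c("expressed", "high")],
    high = calls$call == tokens[["high"]]
  )
}

#' @exportS3Method generics::tidy
tidy.hk_threshold <- function(x, ...) {
  dplyr::mutate(x$stats, scope = x$scope, .before = 1)
}

#' @exportS3Method generics::glance
glance.hk_threshold <- function(x, ...) {
  tibble(scope = x$scope, n_hk_genes = length(x$hk_genes),
         min_upper = min(x$stats$upper), max_upper = max(x$stats$upper))
}
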