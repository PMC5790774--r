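#' Signed fold change
#'
#' The signed convention used in knockout/disease expression tables: the
#' ratio `r = mean_case / mean_control` is reported as `r` when `r >= 1`
#' and as `-1/r` when `r < 1`, so a value of -1.28 means 1.28-fold down.
#' The magnitude is therefore always at least 1.
#'
#' @param mean_case,mean_control Non-negative group means (vectorized).
#' @param epsilon Pseudo-count added to both means; default 0. A small
#'   positive value (e.g. 0.5) permits genes absent in one group; with
#'   `epsilon = 0` a zero/zero pair is an error, never a silent 1.
#' @return Numeric vector of signed fold changes.
#' @examples
#' signed_fold_change(20, 10)    # +2
#' signed_fold_change(10, 12.8)  # -1.28
#' @export
signed_fold_change <- function(mean_case, mean_control, epsilon = 0) {
  if (any(mean_case < 0, na.rm = TRUE) || any(mean_control < 0, na.rm = TRUE)) {
    abort("group means must be non-negative")
  }
  if (epsilon < 0) abort("'epsilon' must be non-negative")
  a <- mean_case + epsilon
  b <- mean_control + epsilon
  if (any(a == 0 & b == 0)) {
    abort("both means zero after pseudo-count; use epsilon > 0 or drop the gene")
  }
  r <- a / b
  ifelse(r >= 1, r, -1 / r)
}

#' Two-group location test
#'
#' Two-sided unequal-variance (Welch) two-sample t-test on replicate
#' values; the significance gate for regulation calls. When both groups
#' have zero variance the p-value is 1 for equal means and 0 otherwise.
#'
#' @param case_values,control_values Numeric replicate vectors (length >= 2
#'   each).
#' @return The p-value.
#' @export
test_two_groups <- function(case_values, control_values) {
  if (length(case_values) < 2 || length(control_values) < 2) {
    abort("need at least 2 replicates per group")
  }
  if (sd(case_values) == 0 && sd(control_values) == 0) {
    return(if (mean(case_values) == mean(control_values)) 1 else 0)
  }
  t.test(case_values, control_values, var.equal = FALSE)$p.value
}

#' Classify regulation from a signed fold change and p-value
#'
#' A gene is called `UP` when its signed fold change is at least `+fc_min`
#' and the significance gate passes, `DOWN` when it is at most `-fc_min`
#' under the same gate, and `UNCHANGED` otherwise. The gate passes when the
#' p-value is below `alpha`, or when no p-value is available (pre-gated
#' tables). Sub-2-fold changes therefore still count as regulation whenever
#' they are statistically significant.
#'
#' @param sfc Signed fold change(s), `|sfc| >= 1`.
#' @param p_value P-value(s) or `NA` for pre-gated input.
#' @param fc_min Minimum fold-change magnitude, >= 1; default 1.2.
#' @param alpha Significance level; default 0.05.
#' @return Factor with levels `UP`, `DOWN`, `UNCHANGED`.
#' @examples
#' classify_regulation(1.33, 0.01)  # UP
#' classify_regulation(3, 0.2)      # UNCHANGED
#' @export
classify_regulation <- function(sfc, p_value = NA_real_, fc_min = 1.2,
                                alpha = 0.05) {
  if (fc_min < 1) abort("'fc_min' must be >= 1")
  if (alpha <= 0 || alpha > 1) abort("'alpha' must be in (0, 1]")
  n <- max(length(sfc), length(p_value))
  sfc <- rep_len(sfc, n)
  p_value <- rep_len(p_value, n)
  gate <- is.na(p_value) | p_value < alpha
  factor(dplyr::case_when(
    gate & !is.na(sfc) & sfc >= fc_min ~ "UP",
    gate & !is.na(sfc) & sfc <= -fc_min ~ "DOWN",
    TRUE ~ "UNCHANGED"
  ), levels = c("UP", "DOWN", "UNCHANGED"))
}

#' Case-versus-control differential table
#'
#' Per shared gene: group means, signed fold change, Welch p-value and the
#' regulation call. Replicate matrices must be on the linear scale
#' (`scale = "linear"`); log2 input is exponentiated first — the scale is
#' never guessed from the data.
#'
#' @param case,control Tibbles with a `gene` column and one numeric column
#'   per replicate. Gene sets must coincide (order may differ).
#' @param fc_min,alpha Classification thresholds, see
#'   [classify_regulation()].
#' @param epsilon Pseudo-count for [signed_fold_change()].
#' @param scale `"linear"` or `"log2"`; mandatory knowledge about the
#'   input, no autodetection.
#' @param p_adjust `"none"` (default; the classical mining analysis uses
#'   raw p-values) or `"BH"` for Benjamini-Hochberg.
#' @param contrast Optional label stored with the result.
#' @return A tibble of class `th_diff`: `gene`, `mean_case`,
#'   `mean_control`, `sfc`, `p`, `call`; thresholds in the attribute
#'   `thresholds`.
#' @examples
#' sim <- simulate_case_control(n_genes = 50, seed = 1)
#' diff <- diff_table(sim$case, sim$control)
#' dplyr::count(diff, call)
#' @export
diff_table <- function(case, control, fc_min = 1.2, alpha = 0.05,
                       epsilon = 0, scale = c("linear", "log2"),
                       p_adjust = c("none", "BH"), contrast = NULL) {
  scale <- match.arg(scale)
  p_adjust <- match.arg(p_adjust)
  validate_expression_table(case, "case matrix")
  validate_expression_table(control, "control matrix")
  if (!setequal(case$gene, control$gene)) {
    abort("case and control matrices must share the same gene set")
  }
  if (ncol(case) < 3 || ncol(control) < 3) {
    abort("need at least 2 replicate columns per group")
  }
  control <- control[match(case$gene, control$gene), ]
  a <- as.matrix(case[-1])
  b <- as.matrix(control[-1])
  if (scale == "log2") {
    a <- 2^a
    b <- 2^b
  }
  p <- vapply(seq_len(nrow(a)), function(i) test_two_groups(a[i, ], b[i, ]),
              numeric(1))
  if (p_adjust == "BH") p <- p.adjust(p, method = "BH")
  sfc <- signed_fold_change(rowMeans(a), rowMeans(b), epsilon = epsilon)
  out <- tibble(
    gene = case$gene,
    mean_case = rowMeans(a),
    mean_control = rowMeans(b),
    sfc = sfc,
    p = p,
    call = classify_regulation(sfc, p, fc_min = fc_min, alpha = alpha)
  )
  structure(out,
            thresholds = list(fc_min = fc_min, alpha = alpha,
                              epsilon = epsilon, scale = scale,
                              p_adjust = p_adjust),
            contrast = contrast,
            class = c("th_diff", class(tibble())))
}

#' Load a printed signed fold-change table
#'
#' Reads a pre-gated differential table in the layout of the published
#' MHC class II table: first column `gene`, optional annotation columns,
#' then one column per contrast holding signed fold changes or blanks.
#' Blank cells mean "not significantly changed" in the source and become
#' `UNCHANGED`; signed values become `UP`/`DOWN` by sign. No p-value
#' re-testing is performed (replicate data are not printed).
#'
#' @param path TSV path, or a data frame already in that layout.
#' @param contrasts Names of the contrast columns; defaults to every
#'   column after `gene` except `gene_id`.
#' @return A long tibble of class `th_diff`: `gene`, `contrast`, `sfc`
#'   (`NA` for blanks), `call`.
#' @examples
#' diff <- load_signed_table(thprof_example("mhc2_diff_mouse.tsv"))
#' dplyr::count(diff, contrast, call)
#' @export
load_signed_table <- function(path, contrasts = NULL) {
  tbl <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(
      gene = readr::col_character(), .default = readr::col_guess()
    ))
  }
  if (!"gene" %in% names(tbl)) abort("signed table needs a 'gene' column")
  if (is.null(contrasts)) {
    contrasts <- setdiff(names(tbl), c("gene", "gene_id"))
  }
  if (!length(contrasts)) abort("no contrast columns found")
  long <- tidyr::pivot_longer(tbl[c("gene", contrasts)], -"gene",
                              names_to = "contrast", values_to = "sfc")
  long$sfc <- suppressWarnings(as.numeric(long$sfc))
  bad <- !is.na(long$sfc) & abs(long$sfc) < 1
  if (any(bad)) {
    abort(paste0("signed fold changes must have magnitude >= 1; offending gene(s): ",
                 paste(unique(long$gene[bad]), collapse = ", ")))
  }
  long$call <- factor(dplyr::case_when(
    is.na(long$sfc) ~ "UNCHANGED",
    long$sfc > 0 ~ "UP",
    TRUE ~ "DOWN"
  ), levels = c("UP", "DOWN", "UNCHANGED"))
  structure(long,
            thresholds = list(pre_gated = TRUE),
            class = c("th_diff", class(tibble())))
}

#' Tally regulation calls over a gene set
#'
#' Counts how many members of a gene set are up-, down- or unregulated in
#' a differential table (per contrast, when the table carries several).
#' Set members absent from the table are reported as unmeasured, so the
#' four counts always sum to the set size.
#'
#' @param diff A `th_diff` tibble from [diff_table()] or
#'   [load_signed_table()].
#' @param gene_set A `th_geneset` (see [load_gene_set()]) or a character
#'   vector of symbols.
#' @return A tibble with one row per contrast: `set`, `contrast` (`NA`
#'   when the table has none), `n_up`, `n_down`, `n_unchanged`,
#'   `n_unmeasured`, and `members` (list-column with the member-level
#'   calls).
#' @examples
#' diff <- load_signed_table(thprof_example("mhc2_diff_mouse.tsv"))
#' geneset_regulation_counts(diff, load_gene_set("mhc2_mouse"))
#' @export
geneset_regulation_counts <- function(diff, gene_set) {
  if (inherits(gene_set, "th_geneset")) {
    set_name <- gene_set$name
    genes <- gene_set$genes
  } else {
    set_name <- "gene_set"
    genes <- unique(as.character(gene_set))
  }
  if (!length(genes)) abort("empty gene set")
  df <- as_tibble(diff)
  if (!"contrast" %in% names(df)) df$contrast <- NA_character_
  purrr::map_dfr(unique(df$contrast), function(ct) {
    keep <- if (is.na(ct)) is.na(df$contrast) else !is.na(df$contrast) & df$contrast == ct
    sub <- df[keep, ]
    members <- tibble(gene = genes)
    members <- dplyr::left_join(members, sub[c("gene", "sfc", "call")],
                                by = "gene")
    measured <- !is.na(members$call)
    tibble(
      set = set_name,
      contrast = ct,
      n_up = sum(members$call[measured] == "UP"),
      n_down = sum(members$call[measured] == "DOWN"),
      n_unchanged = sum(members$call[measured] == "UNCHANGED"),
      n_unmeasured = sum(!measured),
      members = list(members)
    )
  })
}

#' @exportS3Method generics::glance
glance.th_diff <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble(
    n_genes = dplyr::n_distinct(x$gene),
    n_up = sum(x$call == "UP"),
    n_down = sum(x$call == "DOWN"),
    n_unchanged = sum(x$call == "UNCHANGED"),
    fc_min = thr$fc_min %||% NA_real_,
    alpha = thr$alpha %||% NA_real_,
    pre_gated = isTRUE(thr$pre_gated)
  )
}

#' @exportS3Method generics::tidy
tidy.th_diff <- function(x, ...) as_tibble(x)
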