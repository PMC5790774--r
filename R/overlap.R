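#' Exact Venn partition of named sets
#'
#' Partitions the union of 2-8 named item sets into exclusive Venn
#' regions: every item is assigned to exactly one region, the region of
#' the sets (and only the sets) that contain it. Region counts therefore
#' sum to the union size.
#'
#' Items are normalized before comparison — trimmed and, by default,
#' case-folded to upper case (gene and pathway labels exported from
#' different tools differ in case and stray whitespace). The applied
#' normalization map is attached as attribute `normalization`.
#'
#' @param named_sets Named list of character vectors. Names must be unique.
#' @param case_fold Fold items to upper case before comparison? Default
#'   `TRUE`; use `FALSE` for case-sensitive (e.g. mixed-species) labels.
#' @return A tibble of class `th_venn` with one row per non-empty
#'   combination of set names: `region` (e.g. `"A&B"`), `sets`
#'   (list-column), `degree`, `items` (sorted list-column), `n`.
#' @examples
#' venn <- set_overlap(list(A = c("x", "y"), B = c("y", "z"), C = "y"))
#' venn[venn$n > 0, c("region", "n")]
#' @export
set_overlap <- function(named_sets, case_fold = TRUE) {
  nm <- names(named_sets)
  if (is.null(nm) || any(!nzchar(nm))) abort("all sets must be named")
  if (anyDuplicated(nm)) abort("duplicate set names")
  if (length(named_sets) < 2 || length(named_sets) > 8) {
    abort("set_overlap handles 2 to 8 sets")
  }
  norm_map <- list()
  sets <- purrr::imap(named_sets, function(v, n) {
    v <- as.character(v)
    w <- trimws(v)
    if (case_fold) w <- toupper(w)
    changed <- w != v
    if (any(changed)) {
      norm_map[[n]] <<- tibble(set = n, original = v[changed],
                               normalized = w[changed])
    }
    unique(w)
  })
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, nm))
  # all non-empty subsets of set names, ordered by degree then name order
  combos <- unlist(lapply(seq_along(nm), function(k) {
    asplit(utils::combn(nm, k), 2)
  }), recursive = FALSE)
  rows <- purrr::map_dfr(combos, function(cmb) {
    inside <- rowSums(membership[, cmb, drop = FALSE]) == length(cmb)
    outside <- if (length(cmb) == length(nm)) {
      rep(TRUE, length(universe))
    } else {
      rowSums(membership[, setdiff(nm, cmb), drop = FALSE]) == 0
    }
    items <- universe[inside & outside]
    n_items <- length(items)
    tibble(region = paste(cmb, collapse = "&"),
           sets = list(as.character(cmb)), degree = length(cmb),
           items = list(items), n = n_items)
  })
  structure(rows,
            set_names = nm,
            set_sizes = lengths(sets),
            n_union = length(universe),
            normalization = dplyr::bind_rows(norm_map),
            class = c("th_venn", class(tibble())))
}

#' Set-specific versus shared items of one set
#'
#' Splits a focus set into the items exclusive to it (its private Venn
#' region) and the items it shares with at least one other set. The two
#' parts partition the focus set.
#'
#' @param venn A `th_venn` from [set_overlap()].
#' @param focus Name of one input set.
#' @return A list with sorted character vectors `specific` and `shared`.
#' @examples
#' venn <- set_overlap(list(A = c("x", "y"), B = c("y", "z")))
#' shared_specific(venn, "A")
#' @export
shared_specific <- function(venn, focus) {
  nm <- attr(venn, "set_names")
  if (!focus %in% nm) {
    abort(paste0("unknown focus set '", focus, "'; sets: ",
                 paste(nm, collapse = ", ")))
  }
  has_focus <- purrr::map_lgl(venn$sets, ~ focus %in% .x)
  specific <- unlist(venn$items[has_focus & venn$degree == 1])
  shared <- unlist(venn$items[has_focus & venn$degree > 1])
  list(specific = sort(as.character(specific %||% character())),
       shared = sort(as.character(shared %||% character())))
}

#' @exportS3Method generics::tidy
tidy.th_venn <- function(x, ...) {
  dplyr::select(as_tibble(x), "region", "degree", "n")
}

#' @exportS3Method generics::glance
glance.th_venn <- function(x, ...) {
  tibble(n_sets = length(attr(x, "set_names")),
         n_union = attr(x, "n_union"),
         n_regions_nonempty = sum(x$n > 0))
}
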