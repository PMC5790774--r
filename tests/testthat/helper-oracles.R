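# Independent straight-line oracles used to cross-check the vectorized
# implementations. These deliberately re-derive every quantity with plain
# loops and base R so they share no code path with the package.

# Per-cell re-implementation of the two calling rules: TPM below one per
# million -> "-"; AU strictly above the housekeeping upper limit -> "++";
# otherwise "+". `upper` is a single pooled limit or a per-tissue vector
# named by tissue.
oracle_calls <- function(tpm_mat, au_mat, upper) {
  out <- matrix(NA_character_, nrow(tpm_mat), ncol(tpm_mat),
                dimnames = dimnames(tpm_mat))
  for (g in rownames(tpm_mat)) {
    for (t in colnames(tpm_mat)) {
      u <- if (length(upper) == 1) upper else upper[[t]]
      out[g, t] <- if (tpm_mat[g, t] < 1) {
        "-"
      } else if (au_mat[g, t] > u) {
        "++"
      } else {
        "+"
      }
    }
  }
  out
}

# Random TPM table containing a reference gene and a housekeeping trio,
# with values straddling the 1-TPM boundary and the housekeeping band.
random_tpm_table <- function(n_genes, n_tissues) {
  stopifnot(n_genes >= 5)
  genes <- c("ACTB", paste0("HK", 1:3), paste0("G", seq_len(n_genes - 4)))
  tissues <- paste0("t", seq_len(n_tissues))
  vals <- matrix(0, n_genes, n_tissues, dimnames = list(genes, tissues))
  vals["ACTB", ] <- runif(n_tissues, 50, 500)
  for (h in paste0("HK", 1:3)) {
    vals[h, ] <- vals["ACTB", ] * runif(n_tissues, 0.2, 0.8)
  }
  for (g in genes[-(1:4)]) {
    mode <- sample(c("low", "mid", "high"), n_tissues, replace = TRUE)
    vals[g, ] <- ifelse(mode == "low", runif(n_tissues, 0, 2),
                        ifelse(mode == "mid",
                               vals["ACTB", ] * runif(n_tissues, 0.1, 0.9),
                               vals["ACTB", ] * runif(n_tissues, 0.9, 3)))
  }
  tibble::as_tibble(cbind(tibble::tibble(gene = genes),
                          tibble::as_tibble(vals)))
}

# Long-form calls from the package, reshaped to a gene x tissue matrix of
# tokens for comparison against oracle_calls().
calls_as_matrix <- function(calls) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(calls), gene, tissue, call),
    names_from = tissue, values_from = call
  )
  m <- as.matrix(wide[-1])
  m[] <- as.character(as.matrix(wide[-1]))
  rownames(m) <- wide$gene
  m
}

# Brute-force Venn: classify every item of the union by its full
# membership pattern and tally patterns.
oracle_venn <- function(sets) {
  sets <- lapply(sets, function(s) unique(toupper(trimws(s))))
  universe <- sort(unique(unlist(sets)))
  patterns <- vapply(universe, function(it) {
    paste(names(sets)[vapply(sets, function(s) it %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  split(universe, patterns)
}

# Manual subset tally for a toy call table: counts per (tissue, subset)
# with nested loops over an explicit gene->subsets map.
oracle_subset_tally <- function(call_df, gene_subsets) {
  out <- list()
  for (t in unique(call_df$tissue)) {
    for (s in unique(unlist(gene_subsets))) {
      genes <- names(gene_subsets)[vapply(gene_subsets,
                                          function(x) s %in% x, logical(1))]
      genes <- intersect(genes, unique(call_df$gene))
      sub <- call_df[call_df$tissue == t & call_df$gene %in% genes, ]
      out[[paste(t, s)]] <- data.frame(
        tissue = t, subset = s, n_regulators = length(genes),
        n_expressed = sum(sub$call %in% c("+", "++")),
        n_high = sum(sub$call == "++")
      )
    }
  }
  do.call(rbind, out)
}
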