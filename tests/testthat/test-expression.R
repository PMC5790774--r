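toy_tpm <- tibble::tibble(
  gene = c("ACTB", "HK1", "G1"),
  t1 = c(100, 40, 50),
  t2 = c(200, 60, 30)
)

test_that("arbitrary units are per-tissue ratios to the reference", {
  au <- normalize_arbitrary_units(toy_tpm, "ACTB")
  # hand-normalized cell by cell
  expect_equal(au$t1, c(1, 0.4, 0.5))
  expect_equal(au$t2, c(1, 0.3, 0.15))
  expect_equal(attr(au, "ref_gene"), "ACTB")
})

test_that("normalization refuses absent or silent reference genes", {
  expect_error(normalize_arbitrary_units(toy_tpm, "GAPDH"), "not in the table")
  broken <- toy_tpm
  broken$t2[1] <- 0
  expect_error(normalize_arbitrary_units(broken, "ACTB"), "t2")
})

test_that("missing cells are treated as zero TPM and counted", {
  holey <- toy_tpm
  holey$t1[3] <- NA
  au <- normalize_arbitrary_units(holey, "ACTB")
  expect_equal(au$t1[3], 0)
  expect_equal(attr(au, "n_missing"), 1L)
})

test_that("housekeeping threshold is mean + 2 sample SD", {
  au <- tibble::tibble(gene = c("A", "B", "C"),
                       t1 = c(1, 0.2, 0.6), t2 = c(1, 0.4, 0.9))
  thr <- housekeeping_threshold(au, c("B", "C"))
  vals <- c(0.2, 0.6, 0.4, 0.9)
  expect_equal(thr$stats$upper, mean(vals) + 2 * sd(vals))
  # the worked {0.2, 0.4, 0.6} example: mean 0.4, sample SD 0.2, upper 0.8
  au3 <- tibble::tibble(gene = c("R", "H"), t1 = c(1, 0.2),
                        t2 = c(1, 0.4), t3 = c(1, 0.6))
  thr3 <- housekeeping_threshold(au3, "H")
  expect_equal(thr3$stats$mean, 0.4)
  expect_equal(thr3$stats$sd, 0.2)
  expect_equal(thr3$stats$upper, 0.8)
})

test_that("zero-variance housekeeping collapses the band to its mean", {
  au <- tibble::tibble(gene = c("R", "H1", "H2"),
                       t1 = c(1, 0.5, 0.5), t2 = c(1, 0.5, 0.5))
  thr <- housekeeping_threshold(au, c("H1", "H2"))
  expect_equal(thr$stats$sd, 0)
  expect_equal(thr$stats$upper, 0.5)
})

test_that("pooled threshold is invariant to tissue order", {
  au <- normalize_arbitrary_units(toy_tpm, "ACTB")
  thr1 <- housekeeping_threshold(au, "HK1")
  au_perm <- au[c("gene", "t2", "t1")]
  thr2 <- housekeeping_threshold(au_perm, "HK1")
  expect_equal(thr1$stats$upper, thr2$stats$upper)
})

test_that("per-tissue scope yields one limit per tissue and needs >= 2 genes", {
  au <- tibble::tibble(gene = c("R", "H1", "H2"),
                       t1 = c(1, 0.2, 0.4), t2 = c(1, 0.6, 0.8))
  thr <- housekeeping_threshold(au, c("H1", "H2"), scope = "per_tissue")
  expect_equal(thr$stats$tissue, c("t1", "t2"))
  expect_equal(thr$stats$upper[1], 0.3 + 2 * sd(c(0.2, 0.4)))
  expect_error(housekeeping_threshold(au, "H1", scope = "per_tissue"),
               "at least 2 housekeeping genes")
})

test_that("degenerate thresholds are refused", {
  au <- tibble::tibble(gene = c("R", "H1"), t1 = c(1, 0.5))
  expect_error(housekeeping_threshold(au, "H1"), "degenerate")
})

test_that("calling applies the 1-TPM and mean+2SD rules with strict ties", {
  tpm <- tibble::tibble(gene = c("A", "B", "C", "D"),
                        t1 = c(0.5, 10, 10, 10))
  au <- tibble::tibble(gene = c("A", "B", "C", "D"),
                       t1 = c(0.01, 0.9, 0.4, 0.8))
  thr <- structure(list(scope = "pooled", hk_genes = "HK",
                        stats = tibble::tibble(tissue = NA_character_,
                                               mean = 0.4, sd = 0.2,
                                               upper = 0.8)),
                   class = "hk_threshold")
  calls <- call_expression(tpm, au, thr)
  got <- as.character(calls$call)
  expect_equal(got[calls$gene == "A"], "-")   # below one per million
  expect_equal(got[calls$gene == "B"], "++")  # 0.9 > 0.8
  expect_equal(got[calls$gene == "C"], "+")
  expect_equal(got[calls$gene == "D"], "+")   # exactly at the limit: not high
})

test_that("call_expression rejects mismatched axes", {
  au <- normalize_arbitrary_units(toy_tpm, "ACTB")
  thr <- housekeeping_threshold(au, "HK1")
  expect_error(call_expression(toy_tpm[c(1, 3, 2), ], au, thr),
               "identical gene and tissue axes")
})

test_that("every cell receives exactly one of the three calls", {
  withr::with_seed(11, {
    for (i in 1:5) {
      tbl <- random_tpm_table(sample(6:15, 1), sample(2:6, 1))
      calls <- profile_pipeline(tbl, hk_genes = paste0("HK", 1:3))
      expect_equal(nrow(calls), (ncol(tbl) - 1) * nrow(tbl))
      expect_false(anyNA(calls$call))
      counts <- table(calls$gene)
      expect_true(all(counts == ncol(tbl) - 1))
    }
  })
})

test_that("calls agree with the straight-line oracle on random tables", {
  withr::with_seed(21, {
    for (i in 1:20) {
      tbl <- random_tpm_table(sample(5:20, 1), sample(2:10, 1))
      au <- normalize_arbitrary_units(tbl, "ACTB")
      thr <- housekeeping_threshold(au, paste0("HK", 1:3))
      calls <- call_expression(tbl, au, thr)
      tpm_mat <- as.matrix(tibble::column_to_rownames(tbl, "gene"))
      au_mat <- as.matrix(tibble::column_to_rownames(tibble::as_tibble(au), "gene"))
      expect_identical(calls_as_matrix(calls),
                       oracle_calls(tpm_mat, au_mat, thr$stats$upper))
    }
  })
})

test_that("scaling a tissue's TPM leaves AU, threshold and calls unchanged", {
  withr::with_seed(31, {
    tbl <- random_tpm_table(12, 4)
    # guard: scaling must not push any cell across the 1-TPM boundary
    tbl[-1] <- lapply(tbl[-1], function(x) ifelse(x < 1, x / 10, x * 10))
    base <- profile_pipeline(tbl, hk_genes = paste0("HK", 1:3))
    scaled <- tbl
    scaled$t2 <- scaled$t2 * 7
    again <- profile_pipeline(scaled, hk_genes = paste0("HK", 1:3))
    expect_equal(as.character(base$call), as.character(again$call))
  })
})

test_that("raising a gene's TPM never demotes its call", {
  withr::with_seed(41, {
    tbl <- random_tpm_table(10, 3)
    hk <- paste0("HK", 1:3)
    rank_of <- function(calls, g, t) {
      match(as.character(calls$call[calls$gene == g & calls$tissue == t]),
            c("-", "+", "++"))
    }
    for (i in 1:10) {
      g <- sample(setdiff(tbl$gene, c("ACTB", hk)), 1)
      t <- sample(names(tbl)[-1], 1)
      before <- rank_of(profile_pipeline(tbl, hk_genes = hk), g, t)
      bumped <- tbl
      bumped[bumped$gene == g, t] <- bumped[bumped$gene == g, t][[1]] * 5 + 2
      after <- rank_of(profile_pipeline(bumped, hk_genes = hk), g, t)
      expect_gte(after, before)
    }
  })
})

test_that("duplicate tissue profiles get identical call columns", {
  tbl <- toy_tpm
  tbl$t3 <- tbl$t1
  calls <- profile_pipeline(tbl, hk_genes = "HK1")
  wide <- calls_as_matrix(calls)
  expect_identical(wide[, "t1"], wide[, "t3"])
})

test_that("a panel of only reference and housekeeping genes has no silent calls", {
  tbl <- tibble::tibble(gene = c("ACTB", "HK1", "HK2", "HK3"),
                        t1 = c(100, 30, 40, 50), t2 = c(80, 20, 35, 45))
  calls <- profile_pipeline(tbl, hk_genes = paste0("HK", 1:3))
  expect_true(all(as.character(calls$call) %in% c("+", "++")))
})

test_that("threshold tidiers expose the band", {
  au <- normalize_arbitrary_units(toy_tpm, "ACTB")
  thr <- housekeeping_threshold(au, "HK1")
  td <- tidy(thr)
  expect_true(all(c("scope", "mean", "sd", "upper") %in% names(td)))
  expect_equal(glance(thr)$n_hk_genes, 1)
})
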