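# Seeded simulators that emulate the statistical structure of the mined
# inputs: EST-derived TPM panels with a beta-actin reference and a
# low-variance housekeeping panel, and case/control replicate matrices
# with planted multiplicative effects. Each simulator returns the planted
# truth alongside the data so recovery can be measured.

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed_ <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Negative-binomial draw; an infinite size means "no noise" for that gene.
nb_draw <- function(mu, size) {
  out <- mu
  stoch <- is.finite(size)
  if (any(stoch)) {
    out[stoch] <- rnbinom(sum(stoch), mu = mu[stoch], size = size[stoch])
  }
  out
}

#' Simulate a gene-by-tissue TPM panel with planted calls
#'
#' Generates an EST-style expression panel: negative-binomial read counts
#' per gene per tissue, column-normalized to transcripts per million. The
#' panel contains a beta-actin-like reference gene, a low-variance
#' housekeeping trio, genes planted to exceed the housekeeping
#' mean + 2 SD threshold by a configured multiple (expected call `++`),
#' genes planted below 1 TPM (expected call `-`), background genes well
#' inside the housekeeping band (`+`), and one bulk row absorbing the rest
#' of the transcriptome so that column sums are meaningful.
#'
#' @param n_genes Total gene rows excluding the bulk remainder; default 50.
#' @param n_tissues Number of tissue columns; default 10.
#' @param ref_gene Reference symbol; default `"ACTB"`.
#' @param ref_tpm Target TPM of the reference gene; default 20000.
#' @param n_hk,hk_mean_au,hk_cv Housekeeping panel: gene count (default 3),
#'   mean arbitrary units (0.5), coefficient of variation (0.1).
#' @param n_high,high_multiple Planted high genes: count (5) and multiple
#'   of the expected threshold (3; must exceed 1).
#' @param n_none,none_tpm Planted silent genes: count (5) and target TPM
#'   (0.5; must be below 1).
#' @param cv Count-noise coefficient of variation for non-housekeeping
#'   genes; default 0.1. `cv = 0` gives the deterministic noiseless limit.
#' @param depth Simulated reads per tissue library; default 1e8 (deep
#'   enough that sub-1-TPM genes stay sub-1 under count noise).
#' @param seed Required RNG seed.
#' @return A list: `expression` (TPM tibble, `gene` + tissue columns),
#'   `truth` (tibble `gene`, `tissue`, `call`), `hk_genes`, `ref_gene`,
#'   `config`.
#' @examples
#' sim <- simulate_tissue_panel(n_genes = 20, n_tissues = 4, seed = 42)
#' head(sim$truth)
#' @export
simulate_tissue_panel <- function(n_genes = 50, n_tissues = 10,
                                  ref_gene = "ACTB", ref_tpm = 20000,
                                  n_hk = 3, hk_mean_au = 0.5, hk_cv = 0.1,
                                  n_high = 5, high_multiple = 3,
                                  n_none = 5, none_tpm = 0.5,
                                  cv = 0.1, depth = 1e8, seed) {
  if (high_multiple <= 1) abort("'high_multiple' must exceed 1")
  if (none_tpm >= 1) abort("'none_tpm' must be below 1 TPM")
  if (cv < 0 || hk_cv < 0) abort("coefficients of variation must be >= 0")
  n_bg <- n_genes - 1 - n_hk - n_high - n_none
  if (n_bg < 1) {
    abort("infeasible config: n_genes too small for the planted groups")
  }
  expected_upper <- hk_mean_au * (1 + 2 * hk_cv)
  with_seed_(seed, {
    genes <- c(ref_gene,
               paste0("HK", seq_len(n_hk)),
               paste0("HIGH", seq_len(n_high)),
               paste0("NONE", seq_len(n_none)),
               paste0("BG", seq_len(n_bg)))
    au_target <- c(1,
                   rep(hk_mean_au, n_hk),
                   rep(high_multiple * expected_upper, n_high),
                   rep(NA_real_, n_none),  # defined in TPM, not AU
                   runif(n_bg, 0.1, 0.6) * hk_mean_au)
    tpm_target <- ifelse(is.na(au_target), none_tpm, au_target * ref_tpm)
    bulk <- 1e6 - sum(tpm_target)
    if (bulk <= 0) {
      abort("infeasible config: planted TPM targets exceed one million")
    }
    genes <- c(genes, "BULK_REMAINDER")
    tpm_target <- c(tpm_target, bulk)
    size_cv <- if (cv > 0) 1 / cv^2 else Inf
    size_hk <- if (hk_cv > 0) 1 / hk_cv^2 else Inf
    size <- c(size_cv, rep(size_hk, n_hk),
              rep(size_cv, n_high + n_none + n_bg), size_cv)
    if (any(tpm_target[tpm_target >= 1] < 2)) {
      abort("infeasible config: an expressed gene's target TPM is too close to the 1-TPM rule")
    }
    mu <- tpm_target * depth / 1e6
    counts <- vapply(seq_len(n_tissues), function(t) {
      nb_draw(mu, size)
    }, numeric(length(mu)))
    tpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
    tissues <- paste0("tissue_", seq_len(n_tissues))
    colnames(tpm) <- tissues
    expr <- dplyr::bind_cols(tibble(gene = genes), as_tibble(tpm))
    truth_call <- c(if (1 > expected_upper) "++" else "+",
                    rep("+", n_hk),
                    rep("++", n_high),
                    rep("-", n_none),
                    rep("+", n_bg),
                    "++")
    truth <- tidyr::expand_grid(gene = genes, tissue = tissues)
    truth$call <- rep(truth_call, each = n_tissues)
    list(expression = expr,
         truth = truth,
         hk_genes = paste0("HK", seq_len(n_hk)),
         ref_gene = ref_gene,
         config = list(n_genes = n_genes, n_tissues = n_tissues,
                       ref_tpm = ref_tpm, hk_mean_au = hk_mean_au,
                       hk_cv = hk_cv, high_multiple = high_multiple,
                       none_tpm = none_tpm, cv = cv, depth = depth,
                       expected_upper = expected_upper, seed = seed))
  })
}

#' Simulate case/control replicate matrices with planted effects
#'
#' Gene-level baseline means are drawn log-normally; a configured fraction
#' of genes receives a multiplicative up or down effect in the case group;
#' replicate values are gamma-distributed around the group mean with the
#' configured within-group coefficient of variation (so mean and CV match
#' the configuration exactly in expectation).
#'
#' @param n_genes Number of genes; default 1000.
#' @param n_rep Replicates per group (>= 2); default 5.
#' @param frac_up,frac_down Fractions of genes planted up/down; defaults
#'   0.1 each.
#' @param effect_size Fold effect (>= 1) applied to planted genes;
#'   default 2.
#' @param cv Within-group coefficient of variation; default 0.1.
#' @param base_meanlog,base_sdlog Log-normal parameters of the baseline
#'   means; defaults `log(100)` and 1.
#' @param seed Required RNG seed.
#' @return A list: `case`, `control` (tibbles, `gene` + replicate
#'   columns), `truth` (tibble `gene`, `call`, `base_mean`), `config`.
#' @examples
#' sim <- simulate_case_control(n_genes = 100, seed = 7)
#' dplyr::count(sim$truth, call)
#' @export
simulate_case_control <- function(n_genes = 1000, n_rep = 5,
                                  frac_up = 0.1, frac_down = 0.1,
                                  effect_size = 2, cv = 0.1,
                                  base_meanlog = log(100), base_sdlog = 1,
                                  seed) {
  if (n_rep < 2) abort("'n_rep' must be at least 2")
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1) {
    abort("'frac_up' and 'frac_down' must be non-negative and sum to <= 1")
  }
  if (effect_size < 1) abort("'effect_size' must be >= 1")
  if (cv < 0) abort("'cv' must be >= 0")
  with_seed_(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    base <- rlnorm(n_genes, base_meanlog, base_sdlog)
    n_up <- round(frac_up * n_genes)
    n_down <- round(frac_down * n_genes)
    status <- sample(c(rep("UP", n_up), rep("DOWN", n_down),
                       rep("UNCHANGED", n_genes - n_up - n_down)))
    case_mean <- base * ifelse(status == "UP", effect_size,
                               ifelse(status == "DOWN", 1 / effect_size, 1))
    draw <- function(means) {
      m <- vapply(seq_len(n_rep), function(i) {
        if (cv == 0) means else {
          shape <- 1 / cv^2
          rgamma(n_genes, shape = shape, scale = means / shape)
        }
      }, numeric(n_genes))
      m
    }
    case_m <- draw(case_mean)
    ctrl_m <- draw(base)
    colnames(case_m) <- paste0("case_", seq_len(n_rep))
    colnames(ctrl_m) <- paste0("control_", seq_len(n_rep))
    list(
      case = dplyr::bind_cols(tibble(gene = genes), as_tibble(case_m)),
      control = dplyr::bind_cols(tibble(gene = genes), as_tibble(ctrl_m)),
      truth = tibble(gene = genes,
                     call = factor(status,
                                   levels = c("UP", "DOWN", "UNCHANGED")),
                     base_mean = base),
      config = list(n_genes = n_genes, n_rep = n_rep, frac_up = frac_up,
                    frac_down = frac_down, effect_size = effect_size,
                    cv = cv, seed = seed)
    )
  })
}
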