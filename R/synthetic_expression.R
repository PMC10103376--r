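#' Specification of a synthetic expression cohort
#'
#' Emulates a metastatic-breast-cancer expression cohort: `n_samples`
#' samples (default 184) measured on a fixed gene panel (default 771
#' genes), with two gene-set axes - cell fate commitment and cell
#' population proliferation - whose coordinate regulation encodes a latent
#' compartment signature per sample:
#' \itemize{
#'   \item qSC: both axes depressed
#'   \item pSC: fate depressed, proliferation elevated
#'   \item TA: both elevated
#'   \item TD: fate elevated, proliferation depressed
#' }
#' which mirrors the quartile logic used to call signatures, so the
#' classifier can recover the latent labels.
#'
#' Latent label proportions default to (qSC 0.10, pSC 0.15, TA 0.60,
#' TD 0.15): each axis is depressed in exactly 25% of samples, matching
#' the quartile geometry, with the TA-dominant composition the signature
#' analysis expects. Label counts are assigned deterministically by
#' rounding and shuffled under the seed.
#'
#' @param n_samples number of samples, >= 8 (so quartile bins are
#'   nonempty).
#' @param gene_sets named list of two character vectors (fate axis first);
#'   default 40 genes each, disjoint.
#' @param label_probs latent label proportions over (qSC, pSC, TA, TD).
#' @param effect_size shift (in units of the per-gene noise SD) applied to
#'   in-set genes; sign per the label pattern above. Default 2.
#' @param n_genes total panel size including background genes.
#' @param seed integer RNG seed.
#' @return An object of class `expression_cohort_spec`.
#' @export
expression_cohort_spec <- function(n_samples = 184L,
                                   gene_sets = NULL,
                                   label_probs = c(qSC = 0.10, pSC = 0.15,
                                                   TA = 0.60, TD = 0.15),
                                   effect_size = 2,
                                   n_genes = 771L,
                                   seed = 20230413L) {
  if (is.null(gene_sets))
    gene_sets <- list(
      CELL_FATE_COMMITMENT = sprintf("FATE%03d", 1:40),
      CELL_POPULATION_PROLIFERATION = sprintf("PROL%03d", 1:40)
    )
  stopifnot(n_samples >= 8L, length(gene_sets) == 2L,
            !is.null(names(gene_sets)),
            abs(sum(label_probs) - 1) < 1e-8, all(label_probs >= 0),
            effect_size >= 0)
  if (any(lengths(gene_sets) == 0L))
    stop("expression_cohort_spec: empty gene set")
  overlap <- intersect(gene_sets[[1]], gene_sets[[2]])
  if (length(overlap) > 0L)
    message("expression_cohort_spec: gene sets overlap on ",
            length(overlap), " genes")
  if (n_genes < sum(lengths(gene_sets)))
    stop("expression_cohort_spec: n_genes smaller than the gene sets")
  structure(
    list(n_samples = as.integer(n_samples), gene_sets = gene_sets,
         label_probs = label_probs, effect_size = effect_size,
         n_genes = as.integer(n_genes), seed = as.integer(seed)),
    class = "expression_cohort_spec"
  )
}

#' Generate a synthetic expression cohort
#'
#' Draws a genes x samples matrix of standard-Gaussian log-expression
#' noise and shifts each sample's in-set genes by `+effect_size/2` or
#' `-effect_size/2` according to its latent compartment label (see
#' [expression_cohort_spec]). With `effect_size = 0` the labels leave no
#' trace in the data. Reproducible under the spec seed.
#'
#' @param spec an [expression_cohort_spec].
#' @return list with `expression` (matrix, genes x samples), `truth`
#'   (data frame: `sample_id`, `label`), `gene_sets`.
#' @export
generate_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "expression_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  sets <- spec$gene_sets
  set_genes <- unique(unlist(sets))
  n_bg <- spec$n_genes - length(set_genes)
  genes <- c(set_genes, sprintf("BG%04d", seq_len(n_bg)))

  # deterministic label counts (largest-remainder rounding), shuffled
  counts <- floor(spec$label_probs * n)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- spec$label_probs * n - counts
    counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  }
  labels <- sample(rep(names(spec$label_probs), counts))

  expr <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, sprintf("S%03d", seq_len(n))))
  half <- spec$effect_size / 2
  fate_dir <- c(qSC = -1, pSC = -1, TA = 1, TD = 1)
  prolif_dir <- c(qSC = -1, pSC = 1, TA = 1, TD = -1)
  fate_idx <- rownames(expr) %in% sets[[1]]
  prolif_idx <- rownames(expr) %in% sets[[2]]
  for (j in seq_len(n)) {
    expr[fate_idx, j] <- expr[fate_idx, j] + half * fate_dir[labels[j]]
    expr[prolif_idx, j] <- expr[prolif_idx, j] + half * prolif_dir[labels[j]]
  }
  list(expression = expr,
       truth = data.frame(sample_id = colnames(expr),
                          label = factor(labels,
                                         levels = compartment_levels)),
       gene_sets = sets)
}
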