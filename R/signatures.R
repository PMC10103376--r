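#' Single-sample gene-set enrichment score (rank normalized)
#'
#' Scores one sample's coordinate up-/down-regulation of a gene set.
#' Expression values are replaced by ranks (midranks for ties - the rank
#' normalization), genes are ordered from highest to lowest rank, and the
#' score is the sum over the ordered list of the difference between the
#' weighted in-set cumulative distribution (weights `rank^exponent`) and
#' the uniform out-of-set cumulative distribution. Both cumulative curves
#' are evaluated inclusively through the end of each tie group, so the
#' score is invariant under strictly monotone transforms of the expression
#' values and is exactly 0 when all values are tied.
#'
#' @param expression named numeric vector: one sample's gene -> value map.
#' @param gene_set character vector of gene names.
#' @param weight_exponent rank weight exponent; default 0.25.
#' @return scalar enrichment score, or `NA` (with a warning) when the set
#'   and the measured genes do not overlap.
#' @examples
#' expr <- setNames(10:1, paste0("g", 1:10))
#' ssgsea_score(expr, c("g1", "g2"))
#' @export
ssgsea_score <- function(expression, gene_set, weight_exponent = 0.25) {
  stopifnot(is.numeric(expression), !is.null(names(expression)))
  in_set <- names(expression) %in% gene_set
  if (!any(in_set)) {
    warning("ssgsea_score: no overlap between gene set and measured genes")
    return(NA_real_)
  }
  r <- rank(expression, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  r <- r[ord]; in_set <- in_set[ord]
  n <- length(r)
  n_out <- n - sum(in_set)
  w <- r^weight_exponent
  w[!in_set] <- 0
  cum_in <- cumsum(w) / sum(w)
  cum_out <- if (n_out > 0) cumsum(!in_set) / n_out else rep(1, n)
  # evaluate each position at the end of its tie group
  grp <- cumsum(c(TRUE, diff(r) != 0))
  grp_end <- cumsum(tabulate(grp))[grp]
  sum(cum_in[grp_end] - cum_out[grp_end])
}

#' Quartile bins of per-sample scores
#'
#' Samples are divided by the empirical 25/50/75 percentiles of their
#' scores into Q1 (lowest) to Q4 (highest). A score exactly on a boundary
#' goes to the lower bin, so the binning is a deterministic function of
#' the score values (stable under sample reordering).
#'
#' @param scores numeric vector, `n >= 4`, not all tied.
#' @return ordered factor with levels `Q1 < Q2 < Q3 < Q4`.
#' @examples
#' table(quartile_bin(1:8))  # 2 per bin
#' @export
quartile_bin <- function(scores) {
  stopifnot(length(scores) >= 4L, all(is.finite(scores)))
  if (max(scores) == min(scores))
    stop("quartile_bin: all scores tied; quartiles undefined")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  bin <- 1L + (scores > q[1]) + (scores > q[2]) + (scores > q[3])
  factor(paste0("Q", bin), levels = paste0("Q", 1:4), ordered = TRUE)
}

#' Compartment-mimicking signature from a quartile pair
#'
#' The quartile-logic mapping from (cell fate commitment quartile,
#' cell population proliferation quartile) to a tissue-compartment
#' signature: (Q1, Q1) is qSC-like, (Q1, Q2-Q4) pSC-like, (Q2-Q4, Q2-Q4)
#' TA-like, (Q2-Q4, Q1) TD-like. The mapping is total on the 16 quartile
#' pairs: 1 maps to qSC, 3 to pSC, 9 to TA and 3 to TD.
#'
#' @param q_fate,q_prolif quartile assignments (factors from
#'   [quartile_bin], or strings "Q1".."Q4"); vectorized.
#' @return factor over `qSC`, `pSC`, `TA`, `TD`.
#' @examples
#' compartment_signature("Q1", "Q1")  # qSC
#' compartment_signature("Q3", "Q4")  # TA
#' @export
compartment_signature <- function(q_fate, q_prolif) {
  fate_low <- as.character(q_fate) == "Q1"
  prolif_low <- as.character(q_prolif) == "Q1"
  lab <- ifelse(fate_low & prolif_low, "qSC",
         ifelse(fate_low & !prolif_low, "pSC",
         ifelse(!fate_low & !prolif_low, "TA", "TD")))
  factor(lab, levels = compartment_levels)
}

#' Stratify an expression cohort by compartment-mimicking signatures
#'
#' End-to-end signature pipeline: score every sample against the two
#' gene-set axes with [ssgsea_score], bin each axis into quartiles across
#' samples, and map the quartile pair to a compartment signature. The
#' result partitions the cohort, ready for stratified survival analysis.
#'
#' @param expression numeric matrix, genes x samples, with dimnames.
#' @param gene_sets named list of two character vectors; the first is the
#'   cell-fate-commitment axis, the second the proliferation axis.
#' @param weight_exponent passed to [ssgsea_score].
#' @return An object of class `signature_calls`: a data frame with
#'   `sample_id`, `score_fate`, `score_prolif`, `q_fate`, `q_prolif`,
#'   `label`, plus a `counts` attribute (label table).
#' @export
stratify_cohort <- function(expression, gene_sets, weight_exponent = 0.25) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  if (ncol(expression) < 4L)
    stop("stratify_cohort: need at least 4 samples for quartiles")
  stopifnot(is.list(gene_sets), length(gene_sets) == 2L)
  score_axis <- function(set)
    apply(expression, 2, ssgsea_score, gene_set = set,
          weight_exponent = weight_exponent)
  s_fate <- score_axis(gene_sets[[1]])
  s_prolif <- score_axis(gene_sets[[2]])
  q_fate <- quartile_bin(s_fate)
  q_prolif <- quartile_bin(s_prolif)
  label <- compartment_signature(q_fate, q_prolif)
  calls <- data.frame(sample_id = colnames(expression),
                      score_fate = unname(s_fate),
                      score_prolif = unname(s_prolif),
                      q_fate = q_fate, q_prolif = q_prolif, label = label)
  structure(calls, class = c("signature_calls", "data.frame"),
            counts = table(label))
}

#' Read / write GMT gene-set files
#'
#' GMT: one gene set per line, tab separated: name, description, genes.
#'
#' @param path file path.
#' @param sets named list of character vectors (`write_gmt`).
#' @param descriptions optional character vector matching `sets`.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write GCT 1.2 expression matrices
#'
#' GCT 1.2: `#1.2` header, dimensions line, then a tab-separated table
#' with `Name`, `Description` and one column per sample.
#'
#' @param path file path.
#' @param expression genes x samples numeric matrix with dimnames
#'   (`write_gct`).
#' @return `read_gct` returns a genes x samples matrix.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#1.2"))
    stop("read_gct: not a GCT 1.2 file")
  tab <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE)
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(m) <- tab$Name
  m
}

#' @rdname read_gct
#' @export
write_gct <- function(expression, path) {
  stopifnot(is.matrix(expression))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(sprintf("%d\t%d", nrow(expression), ncol(expression)), con)
  tab <- data.frame(Name = rownames(expression),
                    Description = "na",
                    expression, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
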