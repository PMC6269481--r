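#' Rank genes by Pearson correlation with a signature score
#'
#' For every gene in the (coding-gene) expression matrix, computes the
#' Pearson correlation between its expression vector and the per-sample
#' signature score over the samples common to both, and returns the genes
#' sorted by descending correlation.  Genes with zero variance across the
#' used samples have no defined correlation; they are excluded and listed
#' in the `excluded` attribute.  Ties in the statistic are broken
#' lexicographically by gene id (C locale), so the ranking is deterministic.
#'
#' @param mat Expression matrix (genes x samples).
#' @param scores A `score_vector` (from [signature_score()]) or named
#'   numeric vector of per-sample scores.
#' @return A `data.frame` of class `ranked_gene_list` with columns
#'   `gene_id` and `statistic` (Pearson r, non-increasing), attributes
#'   `n_samples_used` and `excluded`.
#' @export
correlate_genes_with_score <- function(mat, scores) {
  validate_expression_matrix(mat)
  s <- if (inherits(scores, "score_vector")) scores$score else scores
  if (is.null(names(s))) stop("scores must carry sample names")
  common <- intersect(colnames(mat), names(s))
  if (length(common) < 3L)
    stop("need at least 3 samples common to matrix and scores, got ",
         length(common))
  x <- mat[, common, drop = FALSE]
  sv <- s[common]
  if (stats::sd(sv) == 0) stop("score vector is constant over the common samples")
  gene_sd <- apply(x, 1L, stats::sd)
  excluded <- rownames(x)[gene_sd == 0]
  keep <- gene_sd > 0
  if (!any(keep)) stop("all genes have zero variance over the common samples")
  r <- as.vector(stats::cor(t(x[keep, , drop = FALSE]), sv))
  ids <- rownames(x)[keep]
  ord <- order(-r, ids, method = "radix")
  out <- data.frame(gene_id = ids[ord], statistic = r[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  attr(out, "n_samples_used") <- length(common)
  attr(out, "excluded") <- excluded
  out
}

#' Construct a ranked gene list from ids and statistics
#'
#' For externally produced rankings (e.g. a differential-expression t
#' statistic): sorts by descending statistic with lexicographic id
#' tie-break and wraps them in the container [correlate_genes_with_score()]
#' returns.
#'
#' @param gene_ids Character vector of unique gene ids.
#' @param statistic Numeric ranking statistic, one per gene.
#' @param n_samples_used Optional sample count to record.
#' @return A `ranked_gene_list`.
#' @export
ranked_gene_list <- function(gene_ids, statistic, n_samples_used = NA_integer_) {
  gene_ids <- as.character(gene_ids)
  .check_unique(gene_ids, "gene id")
  if (length(gene_ids) != length(statistic))
    stop("gene_ids and statistic lengths differ")
  if (!all(is.finite(statistic))) stop("ranking statistic must be finite")
  ord <- order(-statistic, gene_ids, method = "radix")
  out <- data.frame(gene_id = gene_ids[ord], statistic = statistic[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  attr(out, "n_samples_used") <- n_samples_used
  attr(out, "excluded") <- character()
  out
}

#' Take the top-N positively correlated genes as a derived signature
#'
#' The derived mRNA signature is the first `n` genes of the correlation
#' ranking, all required to have strictly positive correlation with the
#' score; the result is an all-"up" directional signature (the derived
#' signature marks genes co-expressed with the stemness score, so there is
#' no down set).
#'
#' @param ranked A `ranked_gene_list`.
#' @param n Signature size (default 500).
#' @param name Name for the derived signature.
#' @return A [directional_signature()] with `n` up members and no down
#'   members.
#' @export
derive_top_signature <- function(ranked, n = 500L, name = "derived_signature") {
  stopifnot(inherits(ranked, "ranked_gene_list") ||
            (is.data.frame(ranked) && all(c("gene_id", "statistic") %in% names(ranked))))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (n > nrow(ranked))
    stop("requested top ", n, " genes but the ranked list has only ",
         nrow(ranked))
  if (ranked$statistic[n] <= 0) {
    n_pos <- sum(ranked$statistic > 0)
    stop("only ", n_pos, " genes with positive correlation; cannot take top ", n)
  }
  directional_signature(up = ranked$gene_id[seq_len(n)], name = name)
}

#' Pairwise Pearson correlation among selected genes
#'
#' Symmetric correlation table for a set of genes across all samples,
#' used to inspect tight co-regulation within a signature (e.g. cell-cycle
#' regulators correlating above 0.9 with their transcription-factor
#' driver).  Zero-variance genes are dropped with a report.
#'
#' @param mat Expression matrix.
#' @param genes Character vector of feature ids, all present in `mat`.
#' @return Symmetric numeric matrix of Pearson r with unit diagonal and
#'   attribute `excluded` (zero-variance genes dropped).
#' @export
pairwise_gene_correlation <- function(mat, genes) {
  validate_expression_matrix(mat)
  genes <- unique(as.character(genes))
  absent <- setdiff(genes, rownames(mat))
  if (length(absent))
    stop("gene(s) not in matrix: ", paste(absent, collapse = ", "))
  if (ncol(mat) < 3L) stop("need at least 3 samples for pairwise correlation")
  x <- mat[genes, , drop = FALSE]
  gene_sd <- apply(x, 1L, stats::sd)
  excluded <- genes[gene_sd == 0]
  keep <- genes[gene_sd > 0]
  if (length(keep) < 2L)
    stop("fewer than 2 genes with nonzero variance")
  out <- stats::cor(t(x[keep, , drop = FALSE]))
  attr(out, "excluded") <- excluded
  out
}
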