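#' Within-sample rank transform
#'
#' Transforms one sample's expression values to ranks, with rank 1 for the
#' lowest-expressed feature.  Ties receive midranks (the mean of the tied
#' rank positions), so the rank sum is always G(G+1)/2 for G features.
#'
#' @param values Finite numeric vector.
#' @return Numeric vector of (mid)ranks.
#' @examples
#' rank_transform(c(10, 5, 1, 7))  # 4 2 1 3
#' @export
rank_transform <- function(values) {
  if (!length(values)) stop("cannot rank an empty vector")
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("rank_transform requires finite numeric values")
  rank(values, ties.method = "average")
}

#' Directional rank-sum signature score
#'
#' The central per-sample statistic: each sample's expression values are
#' rank-transformed across all G matrix features (rank 1 = lowest), and the
#' score is the difference of mean normalized ranks between the signature's
#' up and down members present in the matrix:
#' \deqn{S_j = \frac{1}{G}\,\mathrm{mean}_{f \in up} r(f,j)
#'       \;-\; \frac{1}{G}\,\mathrm{mean}_{f \in down} r(f,j)}
#' A direction with no members contributes 0.  Scores lie in (-1, 1); a
#' sample expressing the up members highest and the down members lowest
#' attains the maximum achievable score for that matrix.  Because only
#' within-sample ranks enter, the score is invariant to any strictly
#' increasing transform applied to a sample's expression column, and each
#' sample's score is independent of every other sample.
#'
#' @param mat Expression matrix (features x samples), validated.
#' @param sig A [directional_signature()].
#' @param min_coverage Minimum fraction of each nonempty direction that
#'   must be present among the matrix features (default 0.5); below it the
#'   score is considered unreliable and an error names the missing members.
#' @return An object of class `score_vector`: list with `sample_ids`,
#'   `score` (named numeric), `n_up_used`, `n_down_used`.
#' @examples
#' m <- matrix(c(4, 2, 1, 3), nrow = 4,
#'             dimnames = list(paste0("f", 1:4), "s1"))
#' sig <- directional_signature(up = "f1", down = "f2")
#' signature_score(m, sig)$score  # (4 - 2) / 4 = 0.5
#' @export
signature_score <- function(mat, sig, min_coverage = 0.5) {
  validate_expression_matrix(mat)
  stopifnot(inherits(sig, "directional_signature"))
  if (!length(sig$up) && !length(sig$down)) stop("signature is empty")
  stopifnot(is.numeric(min_coverage), length(min_coverage) == 1L,
            min_coverage >= 0, min_coverage <= 1)
  cov <- signature_coverage(sig, mat)
  for (dir in c("up", "down")) {
    members <- sig[[dir]]
    if (!length(members)) next
    frac <- if (dir == "up") cov$up_fraction else cov$down_fraction
    if (frac < min_coverage) {
      missing <- if (dir == "up") cov$missing_up else cov$missing_down
      stop(sprintf(
        "only %.0f%% of '%s' members of signature '%s' found in the matrix (min_coverage %.0f%%); missing: %s",
        100 * frac, dir, sig$name, 100 * min_coverage,
        paste(missing, collapse = ", ")))
    }
  }
  up_present <- intersect(sig$up, rownames(mat))
  down_present <- intersect(sig$down, rownames(mat))
  G <- nrow(mat)
  ranks <- apply(mat, 2L, rank, ties.method = "average")
  dir_mean <- function(members) {
    if (!length(members)) return(rep(0, ncol(mat)))
    colMeans(ranks[members, , drop = FALSE]) / G
  }
  score <- dir_mean(up_present) - dir_mean(down_present)
  names(score) <- colnames(mat)
  structure(list(sample_ids = colnames(mat),
                 score = score,
                 n_up_used = length(up_present),
                 n_down_used = length(down_present)),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("Signature scores for %d samples (%d up / %d down members used)\n",
              length(x$score), x$n_up_used, x$n_down_used))
  print(utils::head(x$score))
  invisible(x)
}

#' @export
as.data.frame.score_vector <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, score = unname(x$score),
             stringsAsFactors = FALSE)
}

#' Split samples into high/low score groups at the median
#'
#' Labels each sample `high` when its score is strictly above the median
#' score and `low` otherwise, the dichotomization used for the
#' Kaplan-Meier / log-rank comparisons.  Samples exactly at the median go
#' to the low group (a deterministic tie-break: an exactly equal split is
#' impossible for odd n or tied medians).
#'
#' @param scores A `score_vector` or named numeric vector of scores.
#' @return An object of class `group_labels`: list with `sample_ids`,
#'   `label` (factor, levels low/high) and `cutoff_value` (the median).
#' @export
dichotomize_by_median <- function(scores) {
  s <- if (inherits(scores, "score_vector")) scores$score else scores
  if (!is.numeric(s) || length(s) < 2L)
    stop("need at least 2 numeric scores to dichotomize")
  if (is.null(names(s))) names(s) <- paste0("sample", seq_along(s))
  if (diff(range(s)) == 0)
    stop("all scores identical; median split is uninformative")
  cutoff <- stats::median(s)
  label <- factor(ifelse(s > cutoff, "high", "low"), levels = c("low", "high"))
  names(label) <- names(s)
  structure(list(sample_ids = names(s), label = label, cutoff_value = cutoff),
            class = "group_labels")
}

#' @export
print.group_labels <- function(x, ...) {
  cat(sprintf("Median split at %.4g: %d low, %d high\n", x$cutoff_value,
              sum(x$label == "low"), sum(x$label == "high")))
  invisible(x)
}
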