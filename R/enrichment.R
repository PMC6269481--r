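# Weighted-KS enrichment score for hit positions in a ranked list.
# The running sum increases by |stat|^w (normalized over the set) at hits
# and decreases by 1/(N - nh) at misses; its extremum is only ever attained
# immediately after a hit (maximum candidates) or immediately before a hit
# or at the list end (minimum candidates), so only O(nh) positions need
# evaluation rather than the full cumulative sum.
.es_core <- function(abs_stat_w, hit_pos, N) {
  nh <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  w <- abs_stat_w[hit_pos]
  total <- sum(w)
  inc <- if (total > 0) w / total else rep(1 / nh, nh)
  dec <- 1 / (N - nh)
  cum_inc <- cumsum(inc)
  miss_before <- hit_pos - seq_len(nh)      # misses preceding each hit
  after_hit <- cum_inc - miss_before * dec  # running sum just after hit i
  before_hit <- c(0, cum_inc[-nh]) - miss_before * dec
  hi <- max(after_hit)
  lo <- min(before_hit, 0)
  es <- if (hi >= -lo) hi else lo
  peak <- if (hi >= -lo) hit_pos[which.max(after_hit)]
          else hit_pos[which.min(before_hit)]
  list(es = es, peak = peak, after_hit = after_hit)
}

#' Pre-ranked gene-set enrichment with a permutation null
#'
#' GSEA-style enrichment of gene sets against a ranked gene list: a
#' weighted Kolmogorov-Smirnov running sum walks down the list, stepping up
#' by \eqn{|s_g|^w / \sum_{set} |s_g|^w} at set members ("hits") and down
#' by \eqn{1/(N - n_{hit})} otherwise; the enrichment score ES is the
#' running sum's maximum deviation from zero.  The null distribution is
#' built by drawing `n_perm` random gene sets of the same size from the
#' list (gene-permutation null, the appropriate null for externally ranked
#' lists).  NES is ES divided by the mean |null ES| of matching sign, the
#' permutation p-value counts the same-sign null ES at least as extreme
#' with the add-one convention (`(k+1)/(m+1)`, exactly uniform under the
#' null and never below `1/(n_perm+1)`), and FDR q-values come
#' from the sign-stratified NES-ratio procedure (fraction of pooled null
#' NES at least as extreme over fraction of observed NES at least as
#' extreme, within each sign).
#'
#' Sets with fewer than 2 members in the ranked list are skipped and
#' reported via the `skipped` attribute; a set covering the entire list
#' has no miss denominator and is an error.
#'
#' @param ranked A `ranked_gene_list` (columns `gene_id`, `statistic`,
#'   already in authoritative order; ties keep list position).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param weight_exponent Weight on the ranking statistic (default 1, the
#'   published GSEA default; 0 gives the classic unweighted KS statistic).
#' @param n_perm Number of null permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @return A `data.frame` of class `enrichment_result` with columns
#'   `set_name`, `size`, `ES`, `NES`, `p_perm`, `fdr_q` and
#'   `leading_edge` (list column), plus attribute `skipped`.
#' @export
preranked_enrichment <- function(ranked, sets, weight_exponent = 1,
                                 n_perm = 1000L, seed = 1L) {
  stopifnot(is.data.frame(ranked), all(c("gene_id", "statistic") %in% names(ranked)))
  stopifnot(is.list(sets), !is.null(names(sets)), length(sets) >= 1L)
  .check_unique(names(sets), "gene-set name")
  n_perm <- as.integer(n_perm)
  stopifnot(n_perm >= 1L, is.numeric(weight_exponent), weight_exponent >= 0)
  genes <- ranked$gene_id
  N <- length(genes)
  abs_w <- abs(ranked$statistic)^weight_exponent
  pos_of <- seq_len(N)
  names(pos_of) <- genes

  in_list <- lapply(sets, function(s) unname(pos_of[intersect(unique(s), genes)]))
  sizes <- vapply(in_list, length, 1L)
  if (any(sizes >= N))
    stop("gene set covering the entire ranked list: ",
         paste(names(sets)[sizes >= N], collapse = ", "))
  skipped <- names(sets)[sizes < 2L]
  keep <- names(sets)[sizes >= 2L]
  if (!length(keep)) stop("no gene set has at least 2 members in the ranked list")

  results <- withr::with_seed(seed, lapply(keep, function(nm) {
    hp <- in_list[[nm]]
    nh <- length(hp)
    obs <- .es_core(abs_w, hp, N)
    null_es <- vapply(seq_len(n_perm), function(b) {
      .es_core(abs_w, sample.int(N, nh), N)$es
    }, 0)
    same <- null_es[sign(null_es) == sign(obs$es)]
    denom <- if (length(same)) mean(abs(same)) else mean(abs(null_es))
    nes <- if (denom > 0) obs$es / denom else 0
    # permutation p with the add-one convention: exactly rank-uniform under
    # the null and never zero (so never below 1/(n_perm+1))
    p <- if (length(same)) (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
         else 1 / (n_perm + 1)
    # normalize each null ES by the mean |null ES| of its own sign, giving
    # the pooled null NES distribution the FDR step compares against
    m_pos <- if (any(null_es > 0)) mean(null_es[null_es > 0]) else 1
    m_neg <- if (any(null_es < 0)) mean(abs(null_es[null_es < 0])) else 1
    null_nes <- ifelse(null_es >= 0, null_es / m_pos, null_es / m_neg)
    le <- if (obs$es >= 0) genes[intersect(hp, seq_len(obs$peak))]
          else genes[intersect(hp, obs$peak:N)]
    list(set_name = nm, size = nh, ES = obs$es, NES = nes, p_perm = p,
         leading_edge = le, null_nes = null_nes)
  }))

  ES <- vapply(results, `[[`, 0, "ES")
  NES <- vapply(results, `[[`, 0, "NES")
  pooled_null <- unlist(lapply(results, `[[`, "null_nes"))
  fdr_q <- vapply(seq_along(results), function(i) {
    s <- sign(NES[i])
    if (s == 0) return(1)
    null_same <- pooled_null[sign(pooled_null) == s]
    obs_same <- NES[sign(NES) == s]
    num <- if (length(null_same)) mean(abs(null_same) >= abs(NES[i])) else 0
    den <- mean(abs(obs_same) >= abs(NES[i]))
    min(1, max(num / den, 1 / (length(pooled_null) + 1)))
  }, 0)

  out <- data.frame(set_name = vapply(results, `[[`, "", "set_name"),
                    size = vapply(results, `[[`, 1L, "size"),
                    ES = ES, NES = NES,
                    p_perm = vapply(results, `[[`, 0, "p_perm"),
                    fdr_q = fdr_q,
                    stringsAsFactors = FALSE)
  out$leading_edge <- lapply(results, `[[`, "leading_edge")
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "skipped") <- skipped
  attr(out, "n_perm") <- n_perm
  out
}

#' Fisher's exact overlap of two gene lists
#'
#' Tests whether two gene sets overlap more than expected by chance within
#' a stated universe, via the one-sided (enrichment) hypergeometric tail
#' \eqn{P(X \ge |A \cap B|)}.  The odds ratio is taken directly from the
#' 2x2 table as \eqn{ad/bc}; when any cell is zero the Haldane 0.5
#' continuity correction is applied to the odds ratio only, and flagged.
#'
#' @param set_a,set_b Nonempty character vectors, both subsets of
#'   `universe`.
#' @param universe Character vector of all eligible genes.
#' @return An object of class `overlap_result`: list with `table` (2x2
#'   matrix), `odds_ratio`, `p`, `universe_size`, `haldane`.
#' @examples
#' fisher_overlap(letters[1:5], letters[1:5], letters[1:10])$p  # 1/252
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (!length(set_a) || !length(set_b)) stop("empty gene set")
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("set members outside the universe: ",
         paste(c(out_a, out_b), collapse = ", "))
  U <- length(universe)
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  c_ <- length(set_b) - a
  d <- U - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("in_A", "not_A"), c("in_B", "not_B")))
  p <- stats::phyper(a - 1, length(set_a), U - length(set_a), length(set_b),
                     lower.tail = FALSE)
  haldane <- any(tab == 0)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  structure(list(table = tab, odds_ratio = or, p = p, universe_size = U,
                 haldane = haldane),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap %d of |A|=%d, |B|=%d in universe %d: OR = %.3g%s, p = %.4g\n",
              x$table[1, 1], sum(x$table[1, ]), sum(x$table[, 1]),
              x$universe_size, x$odds_ratio,
              if (x$haldane) " (Haldane-corrected)" else "", x$p))
  invisible(x)
}

#' Two-group comparison of scores or expression
#'
#' Compares a numeric quantity between two groups with either the Welch
#' two-sample t-test or the Mann-Whitney rank-sum test (normal
#' approximation with tie correction), both two-sided.
#'
#' @param values Numeric vector.
#' @param labels Two-level grouping of the same length.
#' @param method `"t"` (Welch) or `"mannwhitney"`.
#' @return List with `statistic` (t, or the Mann-Whitney U of the first
#'   group level), `p`, and `method`.
#' @export
two_group_test <- function(values, labels, method = c("t", "mannwhitney")) {
  method <- match.arg(method)
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("labels must have exactly 2 levels")
  if (length(values) != length(g)) stop("values and labels lengths differ")
  x <- values[g == levels(g)[1L]]
  y <- values[g == levels(g)[2L]]
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need at least 2 values")
  if (method == "t") {
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      stop("zero variance in both groups; t-test undefined")
    ht <- stats::t.test(x, y)
  } else {
    ht <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  }
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       method = method)
}
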