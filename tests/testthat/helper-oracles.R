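# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and rank()): midranks by counting, running sums by full
# cumulative evaluation, hypergeometric tails by explicit choose() sums.

# midrank of x[i] = (# strictly smaller) + (# tied + 1) / 2
oracle_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, 0)
}

# directional rank-sum score, evaluated sample by sample from first principles
oracle_signature_score <- function(mat, up, down) {
  G <- nrow(mat)
  vapply(seq_len(ncol(mat)), function(j) {
    r <- oracle_midranks(mat[, j])
    names(r) <- rownames(mat)
    up_term <- if (length(up)) mean(r[up]) / G else 0
    down_term <- if (length(down)) mean(r[down]) / G else 0
    up_term - down_term
  }, 0)
}

# weighted-KS enrichment score by full cumulative running sum
oracle_es <- function(stats, hit, weight = 1) {
  N <- length(stats)
  nh <- sum(hit)
  w <- abs(stats)^weight
  total <- sum(w[hit])
  inc <- if (total > 0) w / total else rep(1 / nh, N)
  step <- ifelse(hit, inc, -1 / (N - nh))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

# one-sided hypergeometric enrichment tail P(X >= a) by explicit summation
oracle_hyper_tail <- function(a, size_a, size_b, universe) {
  ks <- a:min(size_a, size_b)
  sum(choose(size_a, ks) * choose(universe - size_a, size_b - ks)) /
    choose(universe, size_b)
}

# log-rank chi-square by explicit 2x2 tables at each distinct event time
oracle_logrank_chi2 <- function(times, events, groups) {
  g <- as.integer(factor(groups)) == 1L
  oe <- 0
  v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & g)
    oe <- oe + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

# random expression matrix with distinct-ish values and named axes
random_matrix <- function(G, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(G * n), nrow = G,
         dimnames = list(sprintf("f%03d", seq_len(G)),
                         sprintf("s%03d", seq_len(n))))
}

# small synthetic cohort: full-size miRNA compartment, reduced mRNA block
# (used where the mRNA matrix plays no role in the quantity under test)
small_cohort <- function(seed, n_samples = 100, hazard_log_ratio = 0.7,
                         effect_size = 1.0) {
  simulate_cohort(simulation_config(
    n_samples = n_samples, n_mrna = 10L, n_driver_genes = 2L,
    hazard_log_ratio = hazard_log_ratio, effect_size = effect_size,
    seed = seed))
}
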