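test_that("enrichment score matches the worked 5-gene running sum", {
  rk <- ranked_gene_list(paste0("g", 1:5), c(5, 4, 3, 2, 1))
  res <- preranked_enrichment(rk, list(top2 = c("g1", "g2")),
                              n_perm = 50, seed = 1)
  # running sum reaches 5/9 + 4/9 = 1 before any miss is taken
  expect_equal(res$ES, 1)
  expect_setequal(res$leading_edge[[1]], c("g1", "g2"))
})

test_that("top and bottom sets mirror each other for equal statistics", {
  rk <- ranked_gene_list(sprintf("g%02d", 1:10), rep(1, 10))
  res <- preranked_enrichment(rk, list(top = c("g01", "g02"),
                                       bottom = c("g09", "g10")),
                              n_perm = 50, seed = 2)
  expect_equal(res$ES[res$set_name == "top"], 1)
  expect_equal(res$ES[res$set_name == "top"],
               -res$ES[res$set_name == "bottom"])
})

test_that("enrichment scores agree with brute-force running sums and fgsea", {
  set.seed(99)
  for (i in 1:60) {
    N <- sample(10:120, 1)
    stats <- sort(rnorm(N), decreasing = TRUE)
    rk <- ranked_gene_list(sprintf("g%04d", 1:N), stats)
    nh <- sample(2:min(10, N - 1), 1)
    members <- sample(rk$gene_id, nh)
    w <- sample(c(0, 1, 1.5), 1)
    res <- preranked_enrichment(rk, list(S = members), weight_exponent = w,
                                n_perm = 1, seed = i)
    hit <- rk$gene_id %in% members
    expect_equal(res$ES, oracle_es(rk$statistic, hit, weight = w),
                 tolerance = 1e-12)
  }
  # independent implementation check on the published algorithm
  stats <- setNames(sort(rnorm(80), decreasing = TRUE), sprintf("g%03d", 1:80))
  rk <- ranked_gene_list(names(stats), unname(stats))
  members <- sample(names(stats), 12)
  mine <- preranked_enrichment(rk, list(S = members), n_perm = 1, seed = 3)$ES
  ref <- fgsea::calcGseaStat(stats, which(names(stats) %in% members),
                             gseaParam = 1)
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("degenerate gene sets are skipped or rejected", {
  rk <- ranked_gene_list(paste0("g", 1:8), 8:1)
  res <- preranked_enrichment(rk, list(ok = c("g1", "g2"), tiny = "g3",
                                       alien = c("x", "y")),
                              n_perm = 20, seed = 4)
  expect_identical(res$set_name, "ok")
  expect_setequal(attr(res, "skipped"), c("tiny", "alien"))
  expect_error(
    preranked_enrichment(rk, list(all = paste0("g", 1:8)), n_perm = 20, seed = 4),
    "entire ranked list")
})

test_that("permutation p-values respect the attainable lower bound and seed determinism", {
  rk <- ranked_gene_list(sprintf("g%03d", 1:100), 100:1)
  sets <- list(strong = sprintf("g%03d", 1:10))
  a <- preranked_enrichment(rk, sets, n_perm = 200, seed = 11)
  b <- preranked_enrichment(rk, sets, n_perm = 200, seed = 11)
  expect_identical(a$NES, b$NES)
  expect_identical(a$p_perm, b$p_perm)
  expect_gte(a$p_perm, 1 / 201)
  expect_lte(a$fdr_q, 0.05)  # top-decile block of a clean ranking is enriched
})

test_that("fisher overlap reproduces closed-form hypergeometric values", {
  # overlap 5 of |A|=|B|=5 in universe 10: point mass 1/choose(10,5)
  u <- sprintf("u%02d", 1:10)
  res <- fisher_overlap(u[1:5], u[1:5], u)
  expect_equal(res$p, 1 / choose(10, 5))
  expect_true(res$haldane)  # off-diagonal cells are zero

  # the balanced 2x2 table with one of everything: no association
  res2 <- fisher_overlap(c("a", "b"), c("a", "c"), c("a", "b", "c", "d"))
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p, oracle_hyper_tail(1, 2, 2, 4))

  # disjoint halves: least-enriched configuration, p = 1
  res3 <- fisher_overlap(u[1:5], u[6:10], u)
  expect_equal(res3$p, 1)

  expect_error(fisher_overlap(character(), u[1:2], u), "empty")
  expect_error(fisher_overlap(c("zz", u[1]), u[1:2], u), "zz")
})

test_that("fisher overlap agrees with fisher.test's one-sided tail", {
  set.seed(55)
  u <- sprintf("u%02d", 1:25)
  for (i in 1:20) {
    A <- sample(u, sample(2:12, 1))
    B <- sample(u, sample(2:12, 1))
    mine <- fisher_overlap(A, B, u)
    ref <- fisher.test(matrix(c(
      length(intersect(A, B)), length(setdiff(A, B)),
      length(setdiff(B, A)),
      25 - length(union(A, B))), 2, byrow = TRUE), alternative = "greater")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("two-group tests behave symmetrically and flag degenerate input", {
  x <- c(1.2, 3.1, 2.0, 4.5, 0.7, 2.2)
  g <- rep(c("a", "b"), each = 3)
  tt <- two_group_test(x, g, "t")
  tt_swap <- two_group_test(x, ifelse(g == "a", "b", "a"), "t")
  expect_equal(tt$statistic, -tt_swap$statistic)
  expect_equal(tt$p, tt_swap$p)

  same <- two_group_test(rep(c(1, 2, 3), 2), g, "mannwhitney")
  expect_equal(same$p, 1)
  expect_equal(two_group_test(rep(c(1, 2, 3), 2), g, "t")$statistic, 0)

  # fully separated groups attain the extreme U of 0 for the low group
  sep <- two_group_test(c(1, 2, 3, 4, 5, 6), g, "mannwhitney")
  expect_equal(sep$statistic, 0)
  expect_lt(sep$p, 0.1)

  expect_error(two_group_test(c(1, 2, 3), c("a", "a", "b"), "t"),
               "at least 2")
  expect_error(two_group_test(rep(1, 6), g, "t"), "zero variance")
})
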