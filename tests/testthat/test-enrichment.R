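test_that("Fisher enrichment matches the enumeration oracle", {
  universe <- sprintf("g%03d", 1:50)
  ann <- data.frame(gene = universe[1:5], term = "T1", stringsAsFactors = FALSE)
  gene_set <- universe[1:5]
  res <- fisher_enrichment(gene_set, universe, ann)
  # k=5, n=5, K=5, N=50
  expect_equal(res$p, enum_fisher_p(5, 5, 50, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)

  # every universe gene carries the term: no enrichment is possible
  ann_all <- data.frame(gene = universe, term = "T1", stringsAsFactors = FALSE)
  expect_equal(fisher_enrichment(gene_set, universe, ann_all)$p, 1.0)

  # random tables against the oracle and stats::fisher.test
  set.seed(7)
  for (i in 1:20) {
    N <- sample(20:60, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    u <- sprintf("u%03d", 1:N)
    a <- data.frame(gene = u[seq_len(K)], term = "T", stringsAsFactors = FALSE)
    gs <- sample(u, n)
    r <- fisher_enrichment(gs, u, a)
    k <- sum(gs %in% u[seq_len(K)])
    expect_equal(r$p, enum_fisher_p(k, K, N, n), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2),
                             alternative = "greater")
    expect_equal(r$p, ft$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_enrichment(character(0), universe, ann), "empty")
  expect_error(fisher_enrichment("zzz", universe, ann), "subset")
})

test_that("BH adjustment reproduces the step-up definition", {
  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-14)
  }
  # q is monotone in p-rank and never below p
  u <- sprintf("u%03d", 1:100)
  ann <- data.frame(gene = sample(u, 300, replace = TRUE),
                    term = sample(sprintf("T%d", 1:20), 300, replace = TRUE))
  res <- fisher_enrichment(sample(u, 30), u, ann)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(diff(res$q) >= -1e-15))
})

test_that("printed fractions round half-up at the cited precision", {
  x <- data.frame(label = c("core_genes", "busco", "self"),
                  numerator = c(14135, 1402, 77),
                  denominator = c(51533, 1440, 77),
                  decimals = c(1, 2, 1), stringsAsFactors = FALSE)
  out <- printed_fraction_report(x)
  expect_equal(out$pct, c(27.4, 97.36, 100.0))
  expect_error(printed_fraction_report(
    data.frame(label = "bad", numerator = 1, denominator = 0, decimals = 1)),
    "undefined")
  # half-up, not half-even
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(2.5, 0), 3)
})
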