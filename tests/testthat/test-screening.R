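test_that("exact Mann-Whitney p matches the textbook worked case", {
  # cancer (1,2,3) vs normal (4,5,6): U = 0; of the C(6,3) = 20 label
  # assignments, 2 are as extreme -> two-sided p = 0.1
  vals <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  colnames(vals) <- paste0("s", 1:6)
  de <- mann_whitney_de(make_study(vals, n_cancer = 3))
  expect_equal(de$table$statistic, 0)
  expect_equal(de$table$p_value, 0.1)
})

test_that("degenerate and symmetric inputs behave", {
  vals <- rbind(
    flat = rep(2.5, 8),
    up = c(5, 6, 7, 8, 1, 2, 3, 4)
  )
  colnames(vals) <- paste0("s", 1:8)
  study <- make_study(vals, n_cancer = 4)
  de <- mann_whitney_de(study)
  expect_equal(de$table$p_value[de$table$gene_id == "flat"], 1)

  # swapping group labels leaves every two-sided p unchanged
  swapped <- expression_study(
    vals,
    stats::setNames(rev(sample_groups(study)), colnames(vals)),
    name = "swapped")
  expect_equal(mann_whitney_de(swapped)$table$p_value, de$table$p_value)

  tiny <- vals[, 1:3]
  expect_error(mann_whitney_de(make_study(tiny, n_cancer = 2)), "2 samples")
})

test_that("exact enumeration agrees with implementation across random draws", {
  # tie-free inputs with n1 = n2 <= 7: package p vs full enumeration
  withr::local_seed(101)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    x <- rnorm(n)
    y <- rnorm(n, mean = sample(c(0, 1), 1))
    vals <- matrix(c(x, y), nrow = 1,
      dimnames = list("g", paste0("s", seq_len(2 * n))))
    de <- mann_whitney_de(make_study(vals, n_cancer = n))
    expect_equal(de$table$p_value, enumerate_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact test at the cutover", {
  # min(n1, n2) = 8, tie-free: approximate and exact p within 0.01
  withr::local_seed(202)
  diffs <- replicate(200, {
    n2 <- sample(12:20, 1)
    x <- rnorm(8)
    y <- rnorm(n2, mean = runif(1, 0, 1.5))
    exact <- mann_whitney_de(make_study(
      matrix(c(x, y), 1,
        dimnames = list("g", paste0("s", seq_len(8 + n2)))),
      n_cancer = 8))$table$p_value
    r <- rank(c(x, y))
    u <- sum(r[1:8]) - 8 * 9 / 2
    z <- u - 8 * n2 / 2
    z <- z - sign(z) * 0.5
    approx <- min(2 * pnorm(-abs(z / sqrt(8 * n2 * (8 + n2 + 1) / 12))), 1)
    abs(exact - approx)
  })
  expect_lt(max(diffs), 0.01)
})

test_that("screening is monotone in alpha", {
  sim <- simulate_pair(sim_config(n_genes = 120, module_sizes = c(40),
    seed = 7))
  sig_at <- function(a) significant_genes(mann_whitney_de(sim$study_a,
    alpha = a))
  s01 <- sig_at(0.01)
  s05 <- sig_at(0.05)
  s20 <- sig_at(0.20)
  expect_true(all(s01 %in% s05))
  expect_true(all(s05 %in% s20))
})

test_that("common gene intersection and rates follow the contract", {
  mk_de <- function(genes, sig, name) {
    structure(list(
      table = tibble::tibble(gene_id = genes, statistic = 0,
        p_value = ifelse(genes %in% sig, 0.01, 0.5),
        significant = genes %in% sig),
      alpha = 0.05, adjust = "none", name = name), class = "de_result")
  }
  genes <- paste0("g", 1:6)
  res <- common_de_genes(
    mk_de(genes, c("g1", "g2", "g3"), "A"),
    mk_de(genes, c("g2", "g3", "g4"), "B"))
  expect_equal(res$genes, c("g2", "g3"))
  expect_equal(res$summary$rate_a, 2 / 3)
  expect_equal(res$summary$rate_b, 2 / 3)
  expect_lte(res$summary$n_common,
    min(res$summary$n_sig_a, res$summary$n_sig_b))

  # empty cohort-B significant set: rate 0 with a warning
  expect_warning(
    res0 <- common_de_genes(mk_de(genes, c("g1"), "A"),
      mk_de(genes, character(0), "B")),
    "cohort B")
  expect_equal(res0$genes, character(0))
  expect_equal(res0$summary$rate_b, 0)

  # identical significant sets: both rates 1
  res1 <- common_de_genes(mk_de(genes, c("g1", "g5"), "A"),
    mk_de(genes, c("g1", "g5"), "B"))
  expect_equal(res1$summary$rate_a, 1)
  expect_equal(res1$summary$rate_b, 1)

  expect_error(common_de_genes(mk_de(paste0("a", 1:3), "a1", "A"),
    mk_de(paste0("b", 1:3), "b1", "B")), "disjoint")
})

test_that("connectivity filter keeps the planted hub genes", {
  # 3 perfectly correlated genes + 3 independent noise genes
  withr::local_seed(33)
  base <- rnorm(20)
  vals <- rbind(
    h1 = base, h2 = 2 * base + 5, h3 = -base,
    n1 = rnorm(20), n2 = rnorm(20), n3 = rnorm(20))
  colnames(vals) <- paste0("s", 1:20)
  sa <- make_study(vals, n_cancer = 10, name = "A")
  sb <- make_study(vals[, sample(20)], n_cancer = 10, name = "B")
  keep <- consensus_connectivity_filter(sa, sb, rownames(vals), n_keep = 3)
  expect_setequal(keep, c("h1", "h2", "h3"))
  # n_keep = all genes returns all genes
  expect_setequal(
    consensus_connectivity_filter(sa, sb, rownames(vals), n_keep = 6),
    rownames(vals))
  expect_error(
    consensus_connectivity_filter(sa, sb, rownames(vals), n_keep = 7),
    "n_keep")
})

test_that("connectivity filter equals brute-force min-connectivity ranking", {
  sim <- simulate_pair(sim_config(n_genes = 30, module_sizes = c(10, 10),
    seed = 8))
  genes <- gene_ids(sim$study_a)
  keep <- consensus_connectivity_filter(sim$study_a, sim$study_b, genes,
    n_keep = 10, beta = 6)
  # oracle: recompute connectivities from scratch
  k_study <- function(study) {
    cc <- stats::cor(t(study$values[genes, ]))
    a <- abs(cc)^6
    diag(a) <- 1
    rowSums(a) - 1
  }
  k <- pmin(k_study(sim$study_a), k_study(sim$study_b))
  oracle <- names(sort(k, decreasing = TRUE))[1:10]
  expect_setequal(keep, oracle)
  # invariant to gene input order
  keep_shuffled <- consensus_connectivity_filter(sim$study_a, sim$study_b,
    rev(genes), n_keep = 10, beta = 6)
  expect_equal(keep, keep_shuffled)
})
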