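test_that("identical member genes give variance explained 1", {
  base <- rnorm(12)
  vals <- rbind(g1 = base, g2 = base, g3 = base)
  colnames(vals) <- paste0("s", 1:12)
  eg <- module_eigengene(make_study(vals, n_cancer = 6), rownames(vals))
  expect_equal(eg$var_explained, 1)
  # E proportional to the common standardized profile, unit norm, sign +
  prof <- (base - mean(base)) / sd(base)
  expect_equal(abs(cor(eg$eigengene, prof)), 1, tolerance = 1e-12)
  expect_gt(cor(eg$eigengene, prof), 0)
  expect_equal(sum(eg$eigengene^2), 1)
})

test_that("two independent genes split variance roughly evenly", {
  withr::local_seed(14)
  vals <- rbind(g1 = rnorm(1000), g2 = rnorm(1000))
  colnames(vals) <- paste0("s", 1:1000)
  eg <- module_eigengene(make_study(vals, n_cancer = 500), c("g1", "g2"))
  expect_equal(eg$var_explained, 0.5, tolerance = 0.1)
})

test_that("SVD route matches an independent eigendecomposition", {
  withr::local_seed(15)
  vals <- matrix(rnorm(10 * 20), 10, 20,
    dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  study <- make_study(vals, n_cancer = 10)
  eg <- module_eigengene(study, rownames(vals))
  # oracle: eigendecomposition of the gene-gene correlation matrix
  cc <- cor(t(vals))
  ev <- eigen(cc, symmetric = TRUE)
  expect_equal(eg$var_explained, ev$values[1] / sum(ev$values),
    tolerance = 1e-10)
  # eigengene spans the same direction as the loading-weighted profile
  xs <- t(scale(t(vals)))
  e_oracle <- as.numeric(t(xs) %*% ev$vectors[, 1])
  e_oracle <- e_oracle / sqrt(sum(e_oracle^2))
  expect_equal(abs(sum(eg$eigengene * e_oracle)), 1, tolerance = 1e-10)
  # loadings reproduce the eigengene as a weighted gene combination
  e_from_loadings <- as.numeric(t(xs) %*% eg$loadings)
  e_from_loadings <- e_from_loadings / sqrt(sum(e_from_loadings^2))
  expect_equal(unname(e_from_loadings), unname(eg$eigengene),
    tolerance = 1e-10)
})

test_that("eigengene is invariant to gene order and global sign flips", {
  withr::local_seed(16)
  sim <- simulate_pair(sim_config(n_genes = 30, module_sizes = c(20),
    seed = 19))
  genes <- sim$truth$gene_id[sim$truth$module == "M1"]
  eg <- module_eigengene(sim$study_a, genes)
  eg_rev <- module_eigengene(sim$study_a, rev(genes))
  expect_equal(eg$eigengene, eg_rev$eigengene, tolerance = 1e-12)
  expect_equal(eg$loadings[genes], eg_rev$loadings[genes],
    tolerance = 1e-12)
  # flipping every member gene's values flips E deterministically (the
  # orientation rule tracks the member genes) and changes nothing
  # downstream: variance explained and eigengene-network correlations are
  # untouched
  flipped_vals <- -sim$study_a$values
  flipped <- expression_study(flipped_vals, sample_groups(sim$study_a),
    name = "flip")
  eg_flip <- module_eigengene(flipped, genes)
  expect_equal(eg$eigengene, -eg_flip$eigengene, tolerance = 1e-12)
  expect_equal(eg$var_explained, eg_flip$var_explained, tolerance = 1e-12)
  mem <- stats::setNames(
    ifelse(sim$truth$module == "background", "grey", sim$truth$module),
    sim$truth$gene_id)
  mem[sim$truth$module == "background"] <- "m2"  # second module from noise
  asn <- assign_colors(mem)
  net <- eigengene_network(module_eigengenes(sim$study_a, asn))
  net_flip <- eigengene_network(module_eigengenes(flipped, asn))
  expect_equal(net$cor, net_flip$cor, tolerance = 1e-12)
})

test_that("appending noise genes does not increase variance explained", {
  # in expectation across seeds
  withr::local_seed(23)
  deltas <- replicate(10, {
    base <- rnorm(40)
    vals <- rbind(
      t(sapply(1:6, function(i) 0.9 * base + 0.45 * rnorm(40))),
      t(sapply(1:4, function(i) rnorm(40))))
    rownames(vals) <- paste0("g", 1:10)
    colnames(vals) <- paste0("s", 1:40)
    study <- make_study(vals, n_cancer = 20)
    module_eigengene(study, paste0("g", 1:6))$var_explained -
      module_eigengene(study, paste0("g", 1:10))$var_explained
  })
  expect_gt(mean(deltas), 0)
})

test_that("constant member genes error unless dropped", {
  vals <- rbind(g1 = rnorm(10), g2 = rnorm(10), g3 = rep(4, 10))
  colnames(vals) <- paste0("s", 1:10)
  study <- make_study(vals, n_cancer = 5)
  expect_error(module_eigengene(study, rownames(vals)), "g3")
  expect_warning(
    eg <- module_eigengene(study, rownames(vals), drop_constant = TRUE),
    "g3")
  expect_setequal(eg$genes, c("g1", "g2"))
})

test_that("duplicated modules have perfectly correlated eigengenes", {
  sim <- simulate_pair(sim_config(n_genes = 30, module_sizes = c(20),
    seed = 25))
  genes <- sim$truth$gene_id[sim$truth$module == "M1"]
  mem <- stats::setNames(rep("grey", 30), gene_ids(sim$study_a))
  mem[genes[1:10]] <- "m1"
  mem[genes[11:20]] <- "m2"
  # two colors over the same underlying factor
  asn <- assign_colors(mem)
  eigs <- module_eigengenes(sim$study_a, asn)
  expect_gt(cor(eigs$E[, 1], eigs$E[, 2]), 0.5)
  # literally duplicated gene content -> correlation 1
  vals2 <- sim$study_a$values[c(genes, genes), ]
  rownames(vals2) <- c(paste0("a", seq_along(genes)),
    paste0("b", seq_along(genes)))
  study2 <- expression_study(vals2, sample_groups(sim$study_a), "dup")
  mem2 <- stats::setNames(rep(c("m1", "m2"), each = length(genes)),
    rownames(vals2))
  eigs2 <- module_eigengenes(study2, assign_colors(mem2))
  expect_equal(unname(cor(eigs2$E[, 1], eigs2$E[, 2])), 1,
    tolerance = 1e-12)
})

test_that("designed meta-branches reappear in the eigengene dendrogram", {
  # 8 planted modules in two branches with factor correlation 0.8 within
  # branch and 0 across; the eigengene tree should split into the branches
  cfg <- sim_config(n_genes = 340, module_sizes = rep(40L, 8),
    branches = rep(1:2, each = 4), branch_cor = 0.8, seed = 31)
  sim <- simulate_pair(cfg)
  mem <- stats::setNames(
    ifelse(sim$truth$module == "background", "grey", sim$truth$module),
    sim$truth$gene_id)
  asn <- assign_colors(mem)
  planted_branch <- stats::setNames(
    rep(1:2, each = 4)[as.integer(sub("M", "", unique(
      sim$truth$module[sim$truth$module != "background"])))],
    unique(sim$truth$module[sim$truth$module != "background"]))
  for (study in list(sim$study_a, sim$study_b)) {
    net <- eigengene_network(module_eigengenes(study, asn))
    cut2 <- stats::cutree(net$tree, k = 2)
    # recover which planted module each color carries
    color_of <- stats::setNames(asn$assignment$module, asn$assignment$gene_id)
    module_of_color <- tapply(
      sim$truth$module[sim$truth$module != "background"],
      color_of[sim$truth$gene_id[sim$truth$module != "background"]],
      function(x) x[1])
    got <- cut2[names(module_of_color)]
    want <- planted_branch[module_of_color[names(got)]]
    expect_equal(length(unique(paste(got, want))), 2)
  }
  # an eigengene network needs at least two modules
  one_mod <- assign_colors(stats::setNames(
    ifelse(sim$truth$module == "M1", "m", "grey"), sim$truth$gene_id))
  expect_error(
    eigengene_network(module_eigengenes(sim$study_a, one_mod)),
    ">= 2 modules")
})
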