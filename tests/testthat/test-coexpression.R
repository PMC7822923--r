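# Topological overlap, module detection, eigengenes, trait correlation,
# the inverse-sign module rule, and split-cohort conservation.

test_that("TOM matches hand-computed values and its invariants", {
  a <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  a["a", "b"] <- a["b", "a"] <- 0.5
  a["a", "c"] <- a["c", "a"] <- 0.2
  a["b", "c"] <- a["c", "b"] <- 0.4
  tom <- tom_similarity(a)
  # TOM_ab = (a_ac * a_cb + a_ab) / (min(k_a, k_b) + 1 - a_ab)
  expect_equal(tom["a", "b"], (0.2 * 0.4 + 0.5) / (0.7 + 1 - 0.5),
               tolerance = 1e-12)
  expect_equal(tom["a", "c"], (0.5 * 0.4 + 0.2) / (0.6 + 1 - 0.2),
               tolerance = 1e-12)
  expect_equal(tom["b", "c"], (0.5 * 0.2 + 0.4) / (0.6 + 1 - 0.4),
               tolerance = 1e-12)

  set.seed(11)
  r <- abs(cor(matrix(rnorm(40 * 30), 40)))^6
  diag(r) <- 0
  tr <- tom_similarity(r)
  expect_equal(tr, t(tr), tolerance = 1e-12)
  expect_true(all(diag(tr) == 1))
  expect_true(all(tr >= 0 & tr <= 1 + 1e-12))
})

test_that("planted correlation blocks are recovered as two modules", {
  set.seed(12)
  n <- 300
  make_block <- function(m, r) {
    f <- rnorm(n)
    t(replicate(m, sqrt(r) * f + sqrt(1 - r) * rnorm(n)))
  }
  expr <- rbind(make_block(60, 0.7), make_block(40, 0.7))
  rownames(expr) <- paste0("g", 1:100)
  colnames(expr) <- paste0("s", 1:n)
  ms <- detect_modules(expr, power = 6)
  expect_length(ms$modules, 2)
  a <- unname(ms$assignment)
  agree <- max(
    mean(c(a[1:60] == "M1", a[61:100] == "M2")),
    mean(c(a[1:60] == "M2", a[61:100] == "M1")))
  expect_gte(agree, 0.95)
})

test_that("i.i.d. noise genes are left unassigned", {
  set.seed(13)
  expr <- matrix(rnorm(100 * 300), nrow = 100,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:300)))
  ms <- detect_modules(expr, power = 6)
  expect_gte(mean(ms$assignment == "grey"), 0.9)
})

test_that("module assignment is invariant to gene and sample order", {
  sh <- shared_cohort()
  expr <- sh$norm$matrix
  ms1 <- detect_modules(expr, power = 5)
  set.seed(14)
  gperm <- sample(nrow(expr)); sperm <- sample(ncol(expr))
  ms2 <- detect_modules(expr[gperm, sperm], power = 5)
  # same partition up to label names: compare co-membership of module genes
  for (m in ms1$modules) {
    genes <- names(ms1$assignment)[ms1$assignment == m]
    labs <- unique(ms2$assignment[genes])
    expect_length(labs, 1)
    expect_false(labs == "grey")
  }
  expect_identical(sort(names(ms1$assignment)[ms1$assignment == "grey"]),
                   sort(names(ms2$assignment)[ms2$assignment == "grey"]))
})

test_that("eigengene contracts hold", {
  set.seed(15)
  base <- rnorm(100)
  same <- matrix(rep(base, 5), nrow = 5, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:100)))
  e <- module_eigengene(same, rownames(same))
  expect_equal(e$variance_explained, 1, tolerance = 1e-12)

  # flipping every gene leaves the oriented eigengene unchanged
  set.seed(16)
  expr <- matrix(rnorm(10 * 80), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:80)))
  expr <- expr + rep(rnorm(80, sd = 2), each = 10)  # shared factor
  e1 <- module_eigengene(expr, rownames(expr))
  e2 <- module_eigengene(-expr, rownames(expr))
  expect_equal(abs(cor(e1$score, e2$score)), 1, tolerance = 1e-9)

  # one-factor module with loading 0.7: VE ~ 0.49 + 0.51 / m
  set.seed(17)
  n <- 500; m <- 60
  f <- rnorm(n)
  mod <- t(replicate(m, 0.7 * f + sqrt(1 - 0.49) * rnorm(n)))
  rownames(mod) <- paste0("g", 1:m); colnames(mod) <- paste0("s", 1:n)
  ve <- module_eigengene(mod, rownames(mod))$variance_explained
  expect_lt(abs(ve - (0.49 + 0.51 / m)), 0.05)
  # eigengene tracks the module mean on one-factor data
  expect_gt(abs(cor(module_eigengene(mod, rownames(mod))$score,
                    colMeans(mod))), 0.9)
  expect_error(module_eigengene(mod, "g1"), ">= 2")
})

test_that("module-trait correlations and the sign rule work end to end", {
  sh <- shared_cohort()
  co <- sh$cohort; norm <- sh$norm
  ms <- detect_modules(norm$matrix, power = 5)
  met <- znormalize_metabolites(co$metabolites[, norm$kept_samples,
                                               drop = FALSE])
  tc <- correlate_modules_with_traits(ms, co$traits[norm$kept_samples, ],
                                      met)
  expect_true(all(c("trait", "metabolite") %in% tc$family))
  # eigengene against itself
  m1 <- ms$modules[1]
  self <- cor(ms$eigengenes[[m1]], ms$eigengenes[[m1]])
  expect_equal(self, 1)

  gld <- find_gld_modules(tc)
  expect_equal(nrow(gld), 1)
  genes <- names(ms$assignment)[ms$assignment == gld$module[1]]
  truth_gld <- names(co$truth$module_labels)[co$truth$module_labels ==
                                               co$truth$gld_module]
  expect_gt(length(intersect(genes, truth_gld)) /
              length(union(genes, truth_gld)), 0.9)

  # sign pattern at FDR for the flagged module (orientation-aware)
  sub <- tc[tc$module == gld$module[1] & tc$family == "trait" &
              tc$q <= 0.05, ]
  flip <- if (gld$flipped[1]) -1 else 1
  expect_true(all(flip * sub$r[sub$variable %in% c("LDL", "TotalChol")] < 0))
  expect_true(all(flip * sub$r[sub$variable %in% c("HbA1c", "Glucose")] > 0))

  # degenerate thresholds give an empty list
  expect_equal(nrow(find_gld_modules(tc, fdr = 0)), 0)
  # all-positive correlations cannot satisfy the inverse rule
  fake <- tc[tc$family == "trait", ]
  fake$r <- abs(fake$r); fake$q <- 0
  expect_equal(nrow(find_gld_modules(fake)), 0)
})

test_that("permuted traits are not called significant", {
  sh <- shared_cohort()
  ms <- detect_modules(sh$norm$matrix, power = 5)
  set.seed(18)
  hits <- replicate(100, {
    fake <- data.frame(LDL = sample(rnorm(length(sh$norm$kept_samples))))
    rownames(fake) <- sh$norm$kept_samples
    tc <- correlate_modules_with_traits(ms, fake)
    any(tc$q <= 0.05)
  })
  expect_gte(mean(!hits), 0.95)
})

test_that("module overlap matches the exact hypergeometric computation", {
  # toy: reference module of 60, candidate of 58 sharing 54, universe 7000
  universe <- paste0("g", 1:7000)
  ref <- setNames(rep("grey", 7000), universe)
  ref[universe[1:60]] <- "ref1"
  cand <- setNames(rep("grey", 7000), universe)
  cand[universe[c(1:54, 100:103)]] <- "c1"
  ov <- module_overlap(cand, ref, universe)
  row <- ov$table[ov$table$ref_module == "ref1" & ov$table$module == "c1", ]
  expect_equal(row$overlap, 54)
  expect_equal(row$p, hyper_tail_oracle(54, 58, 60, 7000), tolerance = 1e-12)
  expect_lte(row$overlap, min(row$ref_size, row$mod_size))

  # a module set best-matches itself with the capped odds ratio
  self <- module_overlap(ref, ref, universe)
  expect_equal(self$best_match$module, self$best_match$ref_module)
  expect_equal(self$best_match$odds_ratio, 1e6)
})

test_that("the module survives a random cohort split", {
  sh <- shared_cohort()
  ms <- detect_modules(sh$norm$matrix, power = 5)
  set.seed(19)
  flip <- sample(c("h1", "h2"), ncol(sh$norm$matrix), replace = TRUE)
  res <- split_and_conserve(sh$norm$matrix, flip, ms, min_group = 30,
                            power = 5)
  for (g in names(res)) {
    bm <- res[[g]]$overlap$best_match
    for (m in ms$modules) {
      row <- bm[bm$ref_module == m, ]
      expect_gte(row$overlap / row$ref_size, 0.8)
    }
  }
  expect_error(split_and_conserve(sh$norm$matrix,
                                  rep(c("a", "b"), c(5, ncol(sh$norm$matrix) - 5)),
                                  ms, min_group = 30), "floor")
})

test_that("soft power selection finds a power on scale-free data", {
  # one-factor model with uniform loadings: connectivity k ~ l^p follows
  # an exact power law, so a low power should reach the fit target
  set.seed(61)
  n <- 400; m <- 150
  l <- runif(m, 0.05, 0.95)
  f <- rnorm(n)
  expr <- t(sapply(l, function(li) li * f + sqrt(1 - li^2) * rnorm(n)))
  rownames(expr) <- paste0("g", seq_len(m))
  colnames(expr) <- paste0("s", seq_len(n))
  sel <- suppressMessages(pick_soft_power(expr))
  expect_false(sel$fallback)
  expect_gte(sel$fit_table$rsq[sel$fit_table$power == sel$power], 0.8)
  # power 1 does not reach the target on this fixture
  expect_lt(sel$fit_table$rsq[1], 0.8)
  expect_gt(sel$power, 1)
})

test_that("the module is conserved under the statin split", {
  sh <- shared_cohort()
  co <- sh$cohort; norm <- sh$norm
  ms <- detect_modules(norm$matrix, power = 5)
  statin <- factor(ifelse(co$traits[norm$kept_samples, "Statin"] == 1,
                          "statin", "no_statin"))
  res <- split_and_conserve(norm$matrix, statin, ms, min_group = 30,
                            power = 5)
  gld <- find_gld_modules(correlate_modules_with_traits(
    ms, co$traits[norm$kept_samples, ]))
  ref_mod <- gld$module[1]
  for (g in names(res)) {
    bm <- res[[g]]$overlap$best_match
    row <- bm[bm$ref_module == ref_mod, ]
    expect_gte(row$overlap / row$ref_size, 0.8)
    expect_lt(row$q, 0.05)
  }
})

test_that("soft power selection falls back and rejects degenerate input", {
  set.seed(20)
  noise <- matrix(rnorm(60 * 100), nrow = 60,
                  dimnames = list(paste0("g", 1:60), paste0("s", 1:100)))
  sel <- suppressMessages(pick_soft_power(noise))
  # power 1 on uncorrelated data cannot satisfy the fit target
  expect_false(sel$fit_table$rsq[1] >= 0.8 &&
                 identical(sel$power, 1))
  if (sel$fallback) expect_equal(sel$power, 5)
  expect_error(pick_soft_power(noise[1:2, ]), ">= 3")
  expect_warning(pick_soft_power(noise[, 1:10]), "20 samples")
})
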