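test_that("newick parsing yields the path-length covariance matrix", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "C"], 0)

  star <- read_newick(text = "(A:1,B:1,C:1);")
  expect_equal(unname(phylo_vcv(star)), diag(3))

  expect_silent(read_newick(text = "((A:1,B:1)anc:1,C:2);"))  # inner labels ok
  expect_error(read_newick(text = "((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(read_newick(text = "((A,B),C);"), "branch lengths")
})

test_that("spearman_cor matches brute-force permutation enumeration at n = 7", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(30, 20, 10))$rho, -1)

  set.seed(11)
  for (rep in 1:3) {
    x <- rnorm(7); y <- rnorm(7)
    got <- spearman_cor(x, y)
    expect_equal(got$p_value, spearman_perm_p(x, y), tolerance = 1e-8)
  }

  # invariance under monotone transforms of either variable
  x <- rexp(9); y <- rnorm(9)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
  expect_equal(spearman_cor(x, y^3)$rho, base$rho)
  expect_equal(spearman_cor(log(x), y)$p_value, base$p_value)
})

test_that("wilcoxon_signed_rank matches exact sign-assignment enumeration", {
  w <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
  expect_equal(w$statistic, 6)
  expect_equal(w$p_value, 0.25)

  set.seed(13)
  for (n in c(6, 9)) {
    x <- rnorm(n, 0.3); y <- rnorm(n)
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$p_value, wilcoxon_enum_p(x - y), tolerance = 1e-10)
    # antisymmetry: reversing the pairing gives the identical p
    expect_equal(wilcoxon_signed_rank(y, x)$p_value, got$p_value)
  }
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "nonzero")
})

test_that("pgls reduces to OLS at lambda = 0 and to contrasts at lambda = 1", {
  cl <- generate_clade(seed = 4)
  tr <- cl$phylogeny
  set.seed(5)
  x <- rnorm(15); y <- 1 + 0.5 * x + rnorm(15, 0, 0.3)
  names(x) <- names(y) <- tr$tip.label

  f0 <- pgls(y, x, tr, "fixed0")
  ols <- stats::lm(y[tr$tip.label] ~ x[tr$tip.label])
  expect_equal(unname(f0$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(f0$slope_p, summary(ols)$coefficients[2, 4], tolerance = 1e-8)

  f1 <- pgls(y, x, tr, "fixed1")
  ic <- stats::lm(ape::pic(y, tr) ~ ape::pic(x, tr) - 1)
  expect_equal(f1$slope, unname(coef(ic)[1]), tolerance = 1e-8)

  # star tree: no covariance, ML fit coincides with OLS
  star <- star_tree(12)
  set.seed(6)
  xs <- rnorm(12); ys <- 2 * xs + rnorm(12)
  names(xs) <- names(ys) <- star$tip.label
  fs <- pgls(ys, xs, star, "ml")
  ols_s <- stats::lm(ys[star$tip.label] ~ xs[star$tip.label])
  expect_equal(fs$slope, unname(coef(ols_s)[2]), tolerance = 1e-6)
})

test_that("lambda bound tests behave at and away from the boundary", {
  cl <- generate_clade(seed = 8)
  tr <- cl$phylogeny
  set.seed(9)
  y <- rnorm(15)          # white noise: lambda-hat should hit 0
  names(y) <- tr$tip.label
  fit <- pgls(y, NULL, tr, "ml")
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
  if (fit$lambda < 1e-6) expect_equal(unname(fit$lambda_bounds["vs0"]), 1)
  # adjusted R2 definition is consistent with its R2
  x <- rnorm(15); names(x) <- tr$tip.label
  f <- pgls(y, x, tr, "fixed1")
  expect_equal(f$adjusted_R2, 1 - (1 - f$R2) * 14 / 13, tolerance = 1e-12)
})

test_that("ML lambda agrees with an independent phylogenetic-signal estimator", {
  skip_if_not_installed("phytools")
  tr <- ape::rphylo(80, 1, 0)
  y <- bm_simulate(tr, 0.5, seed = 21)[, 1]
  ours <- pgls(y, NULL, tr, "ml")$lambda
  ref <- phytools::phylosig(tr, y, method = "lambda")$lambda
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("the phylogenetic paired t-test collapses to the ordinary t-test on a star", {
  star <- star_tree(14)
  set.seed(10)
  a <- rnorm(14, 0.5); b <- rnorm(14)
  names(a) <- names(b) <- star$tip.label
  got <- phyl_paired_ttest(a, b, star)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-6)

  expect_error(phyl_paired_ttest(a, a + 3, star), "degenerate")
})

test_that("bm_simulate is seeded, handles zero rates, and spans traits", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_equal(unname(bm_simulate(tr, 0, root = 5)[, 1]), rep(5, 3))
  s1 <- bm_simulate(tr, 0.3, seed = 2)
  s2 <- bm_simulate(tr, 0.3, seed = 2)
  expect_identical(s1, s2)
  s3 <- bm_simulate(tr, matrix(c(1, 0.9, 0.9, 1), 2), root = c(0, 10), seed = 3)
  expect_equal(dim(s3), c(3, 2))
  expect_equal(rownames(s3), tr$tip.label)
})

test_that("run_correlation_suite reports 5 pairs x 3 lambda treatments", {
  cl <- generate_clade(n_species = 8, split = c(4, 4), seed = 12)
  tr <- cl$phylogeny
  n <- 8
  # constructed anti-monotone performance: impact ranks reverse torsion ranks
  imp <- seq(2e5, 9e5, length.out = n)
  tab <- data.frame(peak_vm_impact = imp,
                    peak_vm_torsion = rev(imp) * 0.5,
                    sigma_cr = 1e8 / imp,
                    tau_max = rev(imp) * 0.3,
                    body_length = seq(10, 30, length.out = n),
                    row.names = tr$tip.label)
  suite <- run_correlation_suite(tab, tr)
  expect_equal(nrow(suite), 15)
  expect_equal(sort(unique(suite$lambda_mode)), c("fixed0", "fixed1", "ml"))
  first <- suite[suite$predictor == "peak_vm_torsion", ]
  expect_equal(unique(first$spearman_rho), -1)

  bad <- tab
  rownames(bad) <- paste0("X", seq_len(n))
  expect_error(run_correlation_suite(bad, tr), "labels")
  expect_error(run_correlation_suite(tab[, -1], tr), "missing columns")
})
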