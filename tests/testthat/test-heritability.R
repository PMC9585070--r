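# small genotype fixture shared across the regression tests
herit_fixture <- function(m = 1200, n = 150, seed = 31) {
  gp <- generate_genotypes(n = n, m = m, block_size = 30, rho = 0.8,
                           spacing_bp = 500, seed = seed)
  ann <- binary_annotation(as.integer(seq_len(m) <= m / 10), name = "cas")
  ls <- compute_ld_scores(gp$genotypes, gp$panel, list(ann), window_cm = 0.2)
  list(gp = gp, ann = ann, ls = ls)
}

test_that("LD scores reduce to the own-SNP term at window zero", {
  gp <- generate_genotypes(n = 100, m = 50, rho = 0.5, seed = 1)
  ann <- binary_annotation(rep(c(1L, 0L), 25), name = "half")
  ls0 <- compute_ld_scores(gp$genotypes, gp$panel, list(ann), window_cm = 0)
  expect_equal(unname(ls0$ell[, "base"]), rep(1, 50))  # adjusted own r2 = 1
  expect_equal(unname(ls0$ell[, "half"]), rep(c(1, 0), 25))
})

test_that("perfectly correlated SNP pairs give raw ell = 2", {
  x <- rbinom(80, 2, 0.4)
  G <- cbind(x, x)
  panel <- snp_panel(c("a", "b"), "1", c(100, 200), cm = c(1e-4, 2e-4))
  ann <- binary_annotation(c(1L, 1L), name = "all")
  ls <- compute_ld_scores(G, panel, list(ann), adjusted = FALSE)
  expect_equal(unname(ls$ell[, 1]), c(2, 2))
})

test_that("adjusted ell is about 1 per SNP under independence", {
  # adjusted r2 has mean 0 for independent pairs, so ell ~ own term = 1
  set.seed(77)
  means <- replicate(25, {
    gp <- generate_genotypes(n = 250, m = 80, rho = 0, block_size = 1,
                             seed = sample.int(1e6, 1))
    ls <- compute_ld_scores(gp$genotypes, gp$panel,
                            list(binary_annotation(rep(1L, 80), "all")),
                            window_cm = 10)
    mean(ls$ell[, 1])
  })
  expect_lt(abs(mean(means) - 1), 0.05)
})

test_that("monomorphic SNPs are excluded with a warning", {
  G <- cbind(rbinom(50, 2, 0.3), rep(0L, 50), rbinom(50, 2, 0.4))
  panel <- snp_panel(c("a", "b", "c"), "1", c(1, 2, 3) * 100,
                     cm = c(1, 2, 3) * 1e-4)
  expect_warning(
    ls <- compute_ld_scores(G, panel,
                            list(binary_annotation(rep(1L, 3), "all"))),
    "monomorphic")
  expect_equal(ls$snp, c("a", "c"))
})

test_that("noiseless chi-square identifies tau exactly", {
  fx <- herit_fixture()
  tau_true <- c(base = 2e-5, cas = 8e-5)
  N <- 5e4
  chi2 <- 1 + N * drop(fx$ls$ell %*% tau_true)
  ss <- sumstats(fx$ls$snp, sqrt(chi2), N)
  fit <- stratified_regression(ss, fx$ls, weights = "none")
  expect_equal(unname(fit$tau), unname(tau_true), tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  # weighted fit recovers the same noiseless solution
  fitw <- stratified_regression(ss, fx$ls)
  expect_equal(unname(fitw$tau), unname(tau_true), tolerance = 1e-8)
  # and the jackknife sees no variation: SE 0, Wald p for tau=0 at null is 1
  jk <- jackknife_se(fit, n_blocks = 24)
  expect_equal(jk$table$tau_se, c(0, 0), tolerance = 1e-10)
})

test_that("null simulation gives intercept near 1 and tau near 0", {
  fx <- herit_fixture()
  set.seed(99)
  z <- rnorm(nrow(fx$ls$ell))
  ss <- sumstats(fx$ls$snp, z, 5e4)
  fit <- stratified_regression(ss, fx$ls)
  expect_lt(abs(fit$intercept - 1), 0.15)
  expect_lt(max(abs(fit$tau)) * 5e4 * max(fx$ls$ell), 1)  # tiny on chi2 scale
})

test_that("duplicated annotation columns are rejected by name", {
  fx <- herit_fixture(m = 400)
  dup <- binary_annotation(as.integer(fx$ann), name = "cas2")
  ls2 <- compute_ld_scores(fx$gp$genotypes, fx$gp$panel,
                           list(fx$ann, dup), window_cm = 0.2)
  ss <- sumstats(ls2$snp, rnorm(nrow(ls2$ell)), 1e4)
  expect_error(stratified_regression(ss, ls2), "cas")
})

test_that("enrichment is the h2 share over the SNP share", {
  # all-SNPs annotation: shares cancel, enrichment 1
  A <- cbind(base = rep(1L, 100), cas = rep(c(1L, 0L), c(10, 90)))
  tau <- c(base = 0.001, cas = 0.0025)
  pe <- partition_and_enrich(tau, annot = A)
  # hand arithmetic: h2_cas = 10*(0.001+0.0025) = 0.035; h2_tot = 0.1+0.025
  expect_equal(pe$enrichment[1], 1)
  expect_equal(pe$prop_h2[2], 0.035 / 0.125)
  expect_equal(pe$enrichment[2], (0.035 / 0.125) / 0.1)
  # printed-definition arithmetic: share 0.35 over share 0.10 is 3.5
  expect_equal(0.35 / 0.10, 3.5)
  expect_error(partition_and_enrich(tau, annot = cbind(A, empty = 0L)),
               "empty")
})

test_that("enrichment telescopes: shares of a partition sum to one", {
  A <- cbind(base = rep(1L, 60),
             left = rep(c(1L, 0L), c(20, 40)),
             right = rep(c(0L, 1L), c(20, 40)))
  tau <- c(base = 1e-3, left = 4e-3, right = 2e-4)
  pe <- partition_and_enrich(tau, annot = A)
  parts <- pe[pe$annotation != "base", ]
  expect_equal(sum(parts$prop_snps * parts$enrichment), 1)
})

test_that("block jackknife matches a brute-force delete-block refit", {
  fx <- herit_fixture(m = 600)
  set.seed(5)
  ss <- simulate_sumstats(fx$gp$panel, list(fx$ann), target_enrichment = 2,
                          N = 2e4, ldscores = fx$ls, seed = 12)
  fit <- stratified_regression(ss, fx$ls)
  B <- 12
  jk <- jackknife_se(fit, n_blocks = B)
  # oracle: refit WLS directly on the retained SNPs for each block
  D <- cbind(1, fit$n_gwas * fit$ell)
  block <- ceiling(seq_len(fit$n_snps) / (fit$n_snps / B))
  for (b in c(1, 5, B)) {
    keep <- block != b
    beta <- solve(crossprod(D[keep, ] * sqrt(fit$w[keep])),
                  crossprod(D[keep, ], fit$w[keep] * fit$chi2[keep]))
    expect_equal(jk$blocks$coefficients[b, ], unname(drop(beta)),
                 tolerance = 1e-8)
  }
  expect_error(jackknife_se(fit, n_blocks = 1), "at least 2")
  expect_error(jackknife_se(fit, n_blocks = 1e5), "more blocks")
})

test_that("BH step-up matches the hand oracle and its stated examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 6))))
  expect_true(bh_fdr(0.04))
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p, 0.05), oracle_bh_flags(p, 0.05))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("sumstats files round-trip in the LDSC dialect", {
  ss <- sumstats(c("rs1", "rs2"), c(1.5, -0.3), c(1e4, 1e4), "A", "G")
  path <- tempfile(fileext = ".sumstats.gz")
  write_sumstats(ss, path)
  back <- read_sumstats(path)
  expect_equal(back$z, ss$z)
  expect_equal(back$n, ss$n)
  fx <- herit_fixture(m = 300)
  lpath <- tempfile(fileext = ".l2.ldscore.gz")
  write_ldscores(fx$ls, fx$gp$panel, lpath)
  tab <- crisprable:::read_table_any(lpath)
  expect_equal(names(tab), c("CHR", "SNP", "BP", "baseL2", "casL2"))
  expect_equal(tab$baseL2, unname(fx$ls$ell[, "base"]))
})
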