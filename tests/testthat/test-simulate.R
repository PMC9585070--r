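test_that("generated genomes honour GC blocks, N runs and determinism", {
  spec <- genome_spec(c(c1 = 60000L),
                      gc_blocks = data.frame(chrom = "c1", start = 1,
                                             end = 50000, gc = 0.8),
                      seed = 13)
  g <- generate_genome(spec)
  block <- Biostrings::subseq(g[[1]], 1, 50000)
  gc <- sum(Biostrings::letterFrequency(block, c("C", "G"))) / 50000
  expect_true(gc >= 0.78 && gc <= 0.82)  # binomial concentration at 50 kb
  expect_identical(as.character(generate_genome(spec)),
                   as.character(g))  # same seed, same bytes
  spec2 <- spec; spec2$seed <- 14
  expect_false(identical(as.character(generate_genome(spec2)[[1]]),
                         as.character(g[[1]])))
  # FASTA writing round-trips through the standard reader
  fa <- tempfile(fileext = ".fa")
  generate_genome(spec, fasta = fa)
  expect_identical(as.character(Biostrings::readDNAStringSet(fa)[[1]]),
                   as.character(g[[1]]))
  expect_error(genome_spec(c(c1 = 100L),
                           gc_blocks = data.frame(chrom = "c1", start = 1,
                                                  end = 200, gc = 0.5)))
})

test_that("planted motifs appear at the requested density", {
  spec <- genome_spec(c(c1 = 20000L), default_gc = 0,  # A/T background
                      motifs = data.frame(chrom = "c1", start = 1,
                                          end = 20000, motif = "ACGCGT",
                                          count = 40), seed = 2)
  g <- generate_genome(spec)
  hits <- match_positions(as.character(g[[1]]), "ACGCGT",
                          strands = "forward")
  # overwrites can collide, so slightly fewer than 40 is possible
  expect_gt(nrow(hits), 30)
  # N-run overwriting a motif interval warns and leaves Ns in place
  spec_n <- genome_spec(c(c1 = 1000L),
                        n_runs = data.frame(chrom = "c1", start = 1,
                                            end = 1000),
                        motifs = data.frame(chrom = "c1", start = 1,
                                            end = 1000, motif = "ACGT",
                                            count = 3), seed = 3)
  expect_warning(gn <- generate_genome(spec_n), "N wins")
  expect_equal(as.character(Biostrings::subseq(gn[[1]], 1, 4)), "NNNN")
})

test_that("genotype panels have the requested LD block structure", {
  gp <- generate_genotypes(n = 300, m = 200, block_size = 20, rho = 0.9,
                           seed = 6)
  X <- scale(gp$genotypes)
  r2 <- (crossprod(X) / (nrow(X) - 1))^2
  block <- ceiling(seq_len(200) / 20)
  same <- outer(block, block, `==`) & upper.tri(r2)
  diff <- (!outer(block, block, `==`)) & upper.tri(r2)
  expect_gt(mean(r2[same]), 10 * mean(r2[diff]))
  # independence: mean off-diagonal r2 is about 1/n (known small-sample bias)
  gp0 <- generate_genotypes(n = 150, m = 150, block_size = 1, rho = 0,
                            seed = 16)
  X0 <- scale(gp0$genotypes)
  r20 <- (crossprod(X0) / (nrow(X0) - 1))^2
  expect_lt(abs(mean(r20[upper.tri(r20)]) - 1 / 150), 0.004)
  # determinism and validation
  gp2 <- generate_genotypes(n = 300, m = 200, block_size = 20, rho = 0.9,
                            seed = 6)
  expect_identical(gp$genotypes, gp2$genotypes)
  expect_error(generate_genotypes(10, 10, rho = 1), "rho")
  expect_error(generate_genotypes(10, 10, maf_range = c(0, 0.6)), "MAF")
  expect_false(is.unsorted(gp$panel$cm))
})

test_that("target enrichment converts to per-SNP variances exactly", {
  # E = 3.5 on a 10% annotation with h2 = 0.5: h2 share must be 0.35
  tau <- crisprable:::enrichment_to_tau(3.5, M = 1000, M_c = 100, h2 = 0.5)
  h2_annot <- 100 * (tau["base"] + tau["annot"])
  h2_tot <- 1000 * tau["base"] + 100 * tau["annot"]
  expect_equal(unname(h2_tot), 0.5)
  expect_equal(unname(h2_annot / h2_tot), 0.35)
  expect_error(crisprable:::enrichment_to_tau(11, 1000, 100, 0.5),
               "infeasible")
})

test_that("model-level sumstats follow the stratified chi-square model", {
  gp <- generate_genotypes(n = 150, m = 2000, block_size = 25, rho = 0.8,
                           seed = 42)
  ann <- binary_annotation(as.integer(seq_len(2000) <= 200), name = "cas")
  ls <- compute_ld_scores(gp$genotypes, gp$panel, list(ann),
                          window_cm = 0.2)
  # null: tau = 0 everywhere gives mean chi2 about 1
  ss0 <- simulate_sumstats(gp$panel, list(ann),
                           tau = c(base = 0, cas = 0), N = 1e4,
                           ldscores = ls, seed = 1)
  expect_lt(abs(mean(ss0$z^2) - 1), 0.1)
  # planted signal: mean chi2 matches the model prediction
  ss1 <- simulate_sumstats(gp$panel, list(ann), target_enrichment = 3.5,
                           h2 = 0.5, N = 1e4, ldscores = ls, seed = 2)
  tau <- attr(ss1, "tau")
  pred <- mean(1 + 1e4 * drop(ls$ell %*% tau[colnames(ls$ell)]))
  expect_lt(abs(mean(ss1$z^2) - pred) / pred, 0.1)
  # determinism and argument validation
  ss1b <- simulate_sumstats(gp$panel, list(ann), target_enrichment = 3.5,
                            h2 = 0.5, N = 1e4, ldscores = ls, seed = 2)
  expect_identical(ss1$z, ss1b$z)
  expect_error(simulate_sumstats(gp$panel, list(ann), tau = c(0, 0),
                                 target_enrichment = 2, ldscores = ls),
               "not both")
})

test_that("genotype-level sumstats carry the planted signal", {
  gp <- generate_genotypes(n = 400, m = 1000, block_size = 20, rho = 0.7,
                           seed = 9)
  ann <- binary_annotation(as.integer(seq_len(1000) <= 100), name = "cas")
  ss <- simulate_sumstats(gp$panel, list(ann), target_enrichment = 5,
                          h2 = 0.5, mode = "genotype",
                          genotypes = gp$genotypes, seed = 4)
  expect_equal(ss$n[1], 400)
  # annotated SNPs carry larger chi2 on average than background
  chi2 <- ss$z^2
  expect_gt(mean(chi2[1:100]), mean(chi2[101:1000]))
  expect_error(simulate_sumstats(gp$panel, list(ann),
                                 tau = c(base = 1e-4, cas = -1e-4),
                                 mode = "genotype",
                                 genotypes = gp$genotypes),
               "tau >= 0")
})

test_that("functional annotations track segment GC when coupled", {
  seg <- tiny_segments(10)
  g <- attr(seg, "genome")
  set.seed(12)
  pos0 <- sort(sample(g$total_length, 5000)) - 1
  bounds <- c(g$offsets, g$total_length)
  ci <- findInterval(pos0, bounds)
  panel <- snp_panel(sprintf("rs%d", 1:5000), g$chrom[ci],
                     pos0 - g$offsets[ci] + 1)
  gc_top <- top_k_segments(ifelse(seg$all_n, NA, seg$gc_adjusted), k = 2,
                           label = "GC")
  gc_ann <- annotate_snps(panel, gc_top, seg)
  coupled <- generate_functional_annotations(panel, seg, gc_coupling = 3,
                                             seed = 1)[[1]]
  flat <- generate_functional_annotations(panel, seg, gc_coupling = 0,
                                          seed = 1)[[1]]
  expect_gt(fisher_or(coupled, gc_ann)$log_or, log(1.5))
  expect_lt(abs(fisher_or(flat, gc_ann)$log_or), log(1.5))
  # determinism
  again <- generate_functional_annotations(panel, seg, gc_coupling = 3,
                                           seed = 1)[[1]]
  expect_identical(as.integer(coupled), as.integer(again))
})

test_that("off-target generator couples counts to PAM density on demand", {
  seg <- tiny_segments(10)
  ngg <- count_pam_per_segment(seg, "NGG")
  s1 <- generate_offtarget_sites(seg, ngg, coupling = 1, n_sites = 500,
                                 seed = 3)
  s1b <- generate_offtarget_sites(seg, ngg, coupling = 1, n_sites = 500,
                                  seed = 3)
  expect_identical(s1, s1b)
  expect_true(all(s1$frequency >= 0 & s1$frequency <= 1))
  # coupling 0: sites spread uniformly over eligible segments
  s0 <- generate_offtarget_sites(seg, ngg, coupling = 0, n_sites = 900,
                                 seed = 5)
  tab <- table(factor(s0$segment, levels = seg$segment[!is.na(ngg)]))
  expect_lt(max(tab) / min(tab), 2)
  expect_warning(generate_offtarget_sites(seg, ifelse(is.na(ngg), NA, 0),
                                          n_sites = 10, seed = 1),
                 "uniformly")
  expect_error(generate_offtarget_sites(seg, ngg, n_sites = 0), "n_sites")
})
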