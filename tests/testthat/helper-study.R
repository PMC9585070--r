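# End-to-end study fixture for the enrichment-recovery checks: a 5-Mb
# synthetic genome with spatially structured GC and one assembly gap,
# segmented into 100 pieces; a 20,000-SNP LD-structured panel (n = 200
# individuals, 50-SNP blocks, 1 cM/Mb); the NGG-top-10% Cas annotation; and
# stratified LD scores over a 1-cM window. Built once per test run.
build_recovery_study <- function(seed = 2026L) {
  gc_blocks <- data.frame(chrom = "1",
                          start = seq(1, 5e6, by = 250000),
                          end = seq(250000, 5e6, by = 250000),
                          gc = rep(c(0.35, 0.55), 10))
  gspec <- genome_spec(c("1" = 5000000L), gc_blocks = gc_blocks,
                       n_runs = data.frame(chrom = "1", start = 2000001,
                                           end = 2050000),
                       seed = seed)
  genome <- concatenate_autosomes(generate_genome(gspec))
  segments <- segment_genome(genome, 100L)
  ngg <- count_pam_per_segment(segments, "NGG")
  regions <- top_k_segments(ngg, k = 10L, label = "NGG-Cas")
  gp <- generate_genotypes(n = 200L, m = 20000L, block_size = 50L,
                           rho = 0.8, spacing_bp = 250L, chrom = "1",
                           seed = seed + 1L)
  cas <- annotate_snps(gp$panel, regions, segments, name = "cas")
  ls <- compute_ld_scores(gp$genotypes, gp$panel, list(cas), window_cm = 1)
  list(genome = genome, segments = segments, ngg = ngg, regions = regions,
       panel = gp$panel, genotypes = gp$genotypes, cas = cas, ldscores = ls)
}

# one simulated trait + S-LDSC fit; returns the candidate row
recovery_replicate <- function(study, tau = NULL, target_enrichment = NULL,
                               seed, n_gwas = 20000) {
  ss <- simulate_sumstats(study$panel, list(study$cas), tau = tau,
                          target_enrichment = target_enrichment, h2 = 0.5,
                          N = n_gwas, ldscores = study$ldscores, seed = seed)
  res <- sldsc(ss, study$ldscores, n_blocks = 200L)
  res$table[res$table$annotation == "cas", ]
}
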