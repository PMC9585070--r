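# Generators for desk-scale synthetic inputs: a genome with spatially
# structured GC and N-runs, LD-structured genotype panels, GWAS summary
# statistics following the stratified chi-square model, GC-coupled
# functional annotations and off-target site tables. Every generator is a
# pure function of its arguments + seed.

# evaluate code under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic genome
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param default_gc GC fraction outside explicit GC blocks (0.41 mimics the
#'   human genome-wide average).
#' @param gc_blocks Optional data.frame `chrom`, `start`, `end` (1-based
#'   closed), `gc`: intervals with their own target GC.
#' @param n_runs Optional data.frame `chrom`, `start`, `end`: intervals
#'   overwritten with N (assembly gaps).
#' @param motifs Optional data.frame `chrom`, `start`, `end`, `motif`,
#'   `count`: plant `count` copies of a concrete motif uniformly in the
#'   interval.
#' @param seed RNG seed; the spec + seed fully determine the FASTA bytes.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(chrom_lengths, default_gc = 0.41, gc_blocks = NULL,
                        n_runs = NULL, motifs = NULL, seed = 1L) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1))
  check_iv <- function(iv) {
    if (is.null(iv)) return(invisible())
    stopifnot(all(iv$start >= 1),
              all(iv$end <= chrom_lengths[as.character(iv$chrom)]),
              all(iv$start <= iv$end))
  }
  check_iv(gc_blocks); check_iv(n_runs); check_iv(motifs)
  if (!is.null(gc_blocks)) stopifnot(all(gc_blocks$gc >= 0 & gc_blocks$gc <= 1))
  structure(list(chrom_lengths = chrom_lengths, default_gc = default_gc,
                 gc_blocks = gc_blocks, n_runs = n_runs, motifs = motifs,
                 seed = seed),
            class = "genome_spec")
}

#' Generate a synthetic genome
#'
#' Bases are drawn independently with per-block GC probability (G/C and A/T
#' split evenly), planted motifs are written over the background, and
#' N-runs are written last — an N-run overlapping a planted motif wins, with
#' a warning. For blocks >= 10 kb the empirical GC is within about 0.02 of
#' target (binomial concentration).
#'
#' @param spec A [genome_spec()].
#' @param fasta Optional path; when given, the genome is also written as
#'   FASTA.
#' @return A `Biostrings::DNAStringSet`, one sequence per chromosome.
#' @export
generate_genome <- function(spec, fasta = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    seqs <- lapply(names(spec$chrom_lengths), function(ch) {
      len <- spec$chrom_lengths[[ch]]
      gc <- rep(spec$default_gc, len)
      gb <- spec$gc_blocks
      if (!is.null(gb)) {
        for (i in which(gb$chrom == ch)) {
          gc[gb$start[i]:gb$end[i]] <- gb$gc[i]
        }
      }
      is_gc <- stats::runif(len) < gc
      half <- stats::runif(len) < 0.5
      base <- ifelse(is_gc, ifelse(half, "G", "C"),
                     ifelse(half, "A", "T"))
      mo <- spec$motifs
      if (!is.null(mo)) {
        for (i in which(mo$chrom == ch)) {
          w <- nchar(mo$motif[i])
          lo <- mo$start[i]; hi <- mo$end[i] - w + 1L
          if (hi < lo) stop("motif interval shorter than the motif")
          at <- sample(lo:hi, mo$count[i], replace = TRUE)
          mchars <- strsplit(mo$motif[i], "")[[1]]
          for (s in at) base[s:(s + w - 1L)] <- mchars
        }
      }
      nr <- spec$n_runs
      if (!is.null(nr)) {
        for (i in which(nr$chrom == ch)) {
          idx <- nr$start[i]:nr$end[i]
          if (!is.null(mo) && any(mo$chrom == ch)) {
            warning("N-run may overwrite planted motifs on ", ch,
                    "; N wins")
          }
          base[idx] <- "N"
        }
      }
      paste0(base, collapse = "")
    })
    dss <- Biostrings::DNAStringSet(unlist(seqs))
    names(dss) <- names(spec$chrom_lengths)
    if (!is.null(fasta)) Biostrings::writeXStringSet(dss, fasta)
    dss
  })
}

#' Generate an LD-structured genotype panel
#'
#' Haplotypes are drawn from a blockwise latent-Gaussian model: within an LD
#' block every SNP's latent value shares a block factor with loading
#' `sqrt(rho)`, so within-block haplotype correlation is about `rho` on the
#' latent scale and zero between blocks. Alleles are obtained by
#' thresholding at the SNP's MAF quantile; genotypes are the sum of two
#' independent haplotypes. The genetic map is uniform `cm_per_mb`.
#'
#' @param n Individuals.
#' @param m SNPs.
#' @param block_size SNPs per LD block.
#' @param rho Within-block latent correlation in `[0, 1)`.
#' @param maf_range MAFs drawn uniformly from this range (both in (0, 0.5]).
#' @param positions Optional 1-based bp positions (length m, increasing);
#'   default: evenly spaced at `spacing_bp`.
#' @param spacing_bp Spacing when `positions` is NULL.
#' @param chrom Chromosome name for the panel.
#' @param cm_per_mb Uniform genetic-map density (default 1 cM/Mb).
#' @param seed RNG seed.
#' @return List: `genotypes` (n x m), `panel` (a [snp_panel()] with MAF set
#'   to the drawn allele frequencies and cM from the uniform map).
#' @export
generate_genotypes <- function(n, m, block_size = 50L, rho = 0.9,
                               maf_range = c(0.05, 0.5), positions = NULL,
                               spacing_bp = 250L, chrom = "1",
                               cm_per_mb = 1, seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop("MAF range must lie in (0, 0.5]")
  }
  if (is.null(positions)) positions <- seq_len(m) * spacing_bp
  stopifnot(length(positions) == m, !is.unsorted(positions))
  with_seed(seed, {
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    thr <- stats::qnorm(maf)
    block <- ceiling(seq_len(m) / block_size)
    hap <- function() {
      u <- stats::rnorm(n * max(block))
      dim(u) <- c(n, max(block))
      z <- sqrt(rho) * u[, block, drop = FALSE] +
        sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
      (z < rep(thr, each = n)) + 0L
    }
    G <- hap() + hap()
    panel <- snp_panel(sprintf("rs%d", seq_len(m)), chrom, positions,
                       a1 = "A", a2 = "G", maf = maf,
                       cm = positions * cm_per_mb / 1e6)
    list(genotypes = G, panel = panel)
  })
}

# convert a target enrichment E for one annotation (SNP share p) into
# per-SNP variances (tau_base, tau_annot) under total heritability h2:
#   tau_base  = h2 (1 - pE) / (M (1 - p));  tau_annot = h2 (E - 1) / (M (1 - p))
enrichment_to_tau <- function(target_enrichment, M, M_c, h2) {
  p <- M_c / M
  if (p <= 0 || p >= 1) stop("annotation must be a proper subset of SNPs")
  if (target_enrichment * p >= 1) {
    stop("infeasible enrichment: annotation would exceed total h2")
  }
  tau_base <- h2 * (1 - p * target_enrichment) / (M * (1 - p))
  tau_annot <- h2 * (target_enrichment - 1) / (M * (1 - p))
  c(base = tau_base, annot = tau_annot)
}

#' Simulate GWAS summary statistics under the stratified model
#'
#' Model-level mode draws `Z_j ~ Normal(0, sqrt(1 + N * sum_c tau_c *
#' ell(j,c)))`, so `E[chi2]` follows the stratified regression model exactly
#' — fast enough for replicate studies. Genotype-level mode draws per-SNP
#' effects `beta_j ~ Normal(0, sum_c tau_c a_jc)` on standardised genotypes,
#' builds a phenotype `y = X beta + e` with environmental variance
#' `1 - h2`, and computes marginal-regression Z scores — the full causal
#' chain at the panel's own sample size.
#'
#' @param panel A [snp_panel()].
#' @param annotations List of `binary_annotation`s (a base annotation is
#'   added if none covers all SNPs).
#' @param tau Named per-SNP variance vector aligned to
#'   `c(base, annotations)`; give either `tau` or `target_enrichment`, not
#'   both.
#' @param target_enrichment Target enrichment for the *first* supplied
#'   annotation; converted to `tau` under total heritability `h2`.
#' @param h2 Total SNP heritability used with `target_enrichment` (and as
#'   the genetic variance in genotype-level mode).
#' @param N GWAS sample size (model-level mode).
#' @param mode `"model"` or `"genotype"`.
#' @param ldscores Precomputed [compute_ld_scores()] for model-level mode
#'   (required there; its annotation columns define the tau order).
#' @param genotypes n x m genotype matrix for genotype-level mode.
#' @param seed RNG seed.
#' @return A [sumstats()] table; `attr(, "tau")` records the generating tau.
#' @export
simulate_sumstats <- function(panel, annotations, tau = NULL,
                              target_enrichment = NULL, h2 = 0.5,
                              N = 10000, mode = c("model", "genotype"),
                              ldscores = NULL, genotypes = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.null(tau) && !is.null(target_enrichment)) {
    stop("give either tau or target_enrichment, not both")
  }
  if (inherits(annotations, "binary_annotation")) {
    annotations <- list(annotations)
  }
  A <- do.call(cbind, lapply(annotations, as.integer))
  colnames(A) <- vapply(annotations, attr, character(1), "name")
  if (!any(colSums(A) == nrow(panel))) A <- cbind(base = 1L, A)
  if (is.null(tau)) {
    if (is.null(target_enrichment)) stop("tau or target_enrichment required")
    cand <- which(colSums(A) < nrow(A))[1]
    t2 <- enrichment_to_tau(target_enrichment, nrow(A), sum(A[, cand]), h2)
    tau <- stats::setNames(rep(0, ncol(A)), colnames(A))
    tau[colSums(A) == nrow(A)][1] <- t2["base"]
    tau[cand] <- t2["annot"]
  }
  if (length(tau) != ncol(A)) {
    stop("tau must have one entry per annotation (incl. the base)")
  }
  with_seed(seed, {
    if (mode == "model") {
      if (is.null(ldscores)) {
        stop("model-level simulation needs precomputed LD scores")
      }
      stopifnot(inherits(ldscores, "ld_scores"))
      tau_l <- tau[colnames(ldscores$ell)]
      if (anyNA(tau_l)) stop("tau names must match the LD score columns")
      s2 <- pmax(1 + N * drop(ldscores$ell %*% tau_l), 0.05)
      i <- match(ldscores$snp, panel$snp)
      z <- stats::rnorm(length(s2), 0, sqrt(s2))
      out <- sumstats(ldscores$snp, z, N, panel$a1[i], panel$a2[i])
    } else {
      if (is.null(genotypes)) stop("genotype-level simulation needs genotypes")
      if (any(tau < 0)) stop("genotype-level mode needs tau >= 0")
      stopifnot(ncol(genotypes) == nrow(panel))
      sds <- apply(genotypes, 2L, stats::sd)
      X <- genotypes
      poly <- sds > 0
      X[, poly] <- scale(genotypes[, poly, drop = FALSE])
      X[, !poly] <- 0
      var_j <- drop(A %*% tau)
      beta <- stats::rnorm(ncol(X), 0, sqrt(var_j))
      g <- drop(X %*% beta)
      h2_true <- sum(var_j)
      y <- g + stats::rnorm(nrow(X), 0, sqrt(max(1 - h2_true, 0.05)))
      n <- nrow(X)
      z <- sqrt(n) * drop(crossprod(X, y - mean(y))) / (n - 1) / stats::sd(y)
      out <- sumstats(panel$snp, z, n, panel$a1, panel$a2)
    }
    attr(out, "tau") <- tau
    out
  })
}

#' Generate functional annotations coupled to segment GC content
#'
#' Each SNP's membership probability is logistic in its segment's
#' (standardised) GC content: `plogis(qlogis(base_rate) + gc_coupling *
#' gc_std)`. Slope 0 gives annotations independent of GC.
#'
#' @param panel A [snp_panel()].
#' @param segments A [segment_genome()] table over the panel's genome.
#' @param n_annot Number of annotations to draw.
#' @param gc_coupling Log-odds slope per SD of segment GC.
#' @param base_rate Marginal membership probability at average GC.
#' @param seed RNG seed.
#' @return Named list of `binary_annotation`s (`func1`, `func2`, ...).
#' @export
generate_functional_annotations <- function(panel, segments, n_annot = 1L,
                                            gc_coupling = 0,
                                            base_rate = 0.1, seed = 1L) {
  stopifnot(is.finite(gc_coupling))
  g <- attr(segments, "genome")
  pos0 <- concat_coord(g, panel$chrom, panel$pos)
  idx <- findInterval(pos0, segments$start)
  gc <- segments$gc_adjusted[idx]
  gc_std <- rep(0, length(gc))
  ok <- !is.na(gc)
  if (stats::sd(gc[ok]) > 0) {
    gc_std[ok] <- (gc[ok] - mean(gc[ok])) / stats::sd(gc[ok])
  }
  p <- stats::plogis(stats::qlogis(base_rate) + gc_coupling * gc_std)
  with_seed(seed, {
    out <- lapply(seq_len(n_annot), function(i) {
      binary_annotation(stats::rbinom(length(p), 1L, p),
                        name = sprintf("func%d", i))
    })
    names(out) <- sprintf("func%d", seq_len(n_annot))
    out
  })
}

# map 0-based concatenated positions back to (chrom, 1-based pos)
chrom_coord <- function(genome, pos0) {
  bounds <- c(genome$offsets, genome$total_length)
  ci <- findInterval(pos0, bounds)
  data.frame(chrom = genome$chrom[ci],
             pos = pos0 - genome$offsets[ci] + 1,
             row.names = NULL)
}

#' Generate off-target sites preferentially in PAM-dense segments
#'
#' Each site's segment is drawn with probability proportional to
#' `ngg_count ^ coupling` (coupling 0 = uniform over eligible segments;
#' all-zero counts fall back to uniform with a warning); its position is
#' uniform within the segment and its cleavage frequency is uniform on
#' `[0, 1]`, independent of PAM count.
#'
#' @param segments A [segment_genome()] table.
#' @param ngg_counts Per-segment PAM counts (`NA` = ineligible).
#' @param coupling Exponent tying site density to PAM count.
#' @param n_sites Number of sites (>= 1).
#' @param seed RNG seed.
#' @return data.frame `chrom`, `pos`, `frequency`, `segment`.
#' @export
generate_offtarget_sites <- function(segments, ngg_counts, coupling = 1,
                                     n_sites = 100L, seed = 1L) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  stopifnot(length(ngg_counts) == nrow(segments))
  elig <- which(!is.na(ngg_counts))
  wgt <- ngg_counts[elig]^coupling
  if (all(wgt == 0)) {
    warning("all PAM counts zero: sampling segments uniformly")
    wgt <- rep(1, length(elig))
  }
  with_seed(seed, {
    seg <- sample(elig, n_sites, replace = TRUE, prob = wgt)
    pos0 <- segments$start[seg] +
      floor(stats::runif(n_sites) * (segments$end[seg] - segments$start[seg]))
    cc <- chrom_coord(attr(segments, "genome"), pos0)
    data.frame(chrom = cc$chrom, pos = cc$pos,
               frequency = stats::runif(n_sites),
               segment = segments$segment[seg], row.names = NULL)
  })
}
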