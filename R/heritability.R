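# Stratified LD score regression at desk scale.
#
# Model: E[chi2_j] = intercept + N * sum_c tau_c * ell(j, c), with
# ell(j, c) = sum over SNPs k of annotation c within a genetic-distance
# window of the (small-sample adjusted) squared correlation r2(j, k).
# tau_c is the per-SNP heritability contributed by membership in c;
# enrichment of c is (share of h2 in c) / (share of SNPs in c).

#' Compute stratified LD scores from a genotype panel
#'
#' For each SNP j and annotation c, `ell(j, c)` sums `r2` between j and every
#' SNP of c within `window_cm` centiMorgans (the LDSC convention is a 1-cM
#' window), using by default the small-sample adjusted estimator
#' `r2_adj = r2 - (1 - r2) / (n - 2)`, which is unbiased under independence.
#' The SNP's own term is included (r2 = 1, adjusted value 1).
#'
#' @param genotypes n x m matrix of allele counts (0/1/2), columns aligned
#'   to `panel` rows. Monomorphic SNPs are excluded with a warning.
#' @param panel A [snp_panel()] with non-decreasing `cm` positions.
#' @param annotations List of `binary_annotation`s aligned to the panel. An
#'   all-ones base annotation named `"base"` is prepended unless one of the
#'   supplied annotations already covers every SNP.
#' @param window_cm Window radius in cM (default 1).
#' @param adjusted Use the small-sample adjusted r2 estimator (default TRUE).
#' @param chunk_size SNPs per block in the chunked computation.
#' @return An `ld_scores` object: list with `ell` (m_kept x C matrix),
#'   `annot` (0/1 matrix over kept SNPs), `snp`, `cm`, `M` (panel-wide SNP
#'   counts per annotation, monomorphic SNPs included), `M_total`, `n_ind`,
#'   `base` (index of the all-SNPs column).
#' @export
compute_ld_scores <- function(genotypes, panel, annotations, window_cm = 1,
                              adjusted = TRUE, chunk_size = 512L) {
  stopifnot(ncol(genotypes) == nrow(panel))
  if (anyNA(panel$cm)) stop("panel needs cM positions for windowing")
  if (is.unsorted(panel$cm)) stop("panel must be sorted by cM position")
  if (inherits(annotations, "binary_annotation")) {
    annotations <- list(annotations)
  }
  stopifnot(all(lengths(annotations) == nrow(panel)))
  A <- do.call(cbind, lapply(annotations, as.integer))
  colnames(A) <- vapply(annotations, attr, character(1), "name")
  if (!any(colSums(A) == nrow(panel))) {
    A <- cbind(base = 1L, A)
  }
  base <- which(colSums(A) == nrow(panel))[1]

  n <- nrow(genotypes)
  if (n < 3) stop("need at least 3 individuals for the adjusted estimator")
  sds <- apply(genotypes, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " monomorphic SNP(s) excluded from LD scores")
  }
  X <- scale(genotypes[, keep, drop = FALSE])  # columns: mean 0, sd 1
  cm <- panel$cm[keep]
  Ak <- A[keep, , drop = FALSE]
  m <- ncol(X)
  ell <- matrix(0, m, ncol(A), dimnames = list(NULL, colnames(A)))
  for (j1 in seq(1L, m, by = chunk_size)) {
    j2 <- min(j1 + chunk_size - 1L, m)
    lo <- findInterval(cm[j1] - window_cm, cm, left.open = TRUE) + 1L
    hi <- findInterval(cm[j2] + window_cm, cm)
    K <- lo:hi
    r <- crossprod(X[, j1:j2, drop = FALSE], X[, K, drop = FALSE]) / (n - 1)
    r2 <- r * r
    if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
    inwin <- abs(outer(cm[j1:j2], cm[K], `-`)) <= window_cm
    ell[j1:j2, ] <- (r2 * inwin) %*% Ak[K, , drop = FALSE]
  }
  structure(
    list(ell = ell, annot = Ak, snp = panel$snp[keep], cm = cm,
         M = colSums(A), M_total = nrow(panel), n_ind = n, base = base),
    class = "ld_scores")
}

#' @export
print.ld_scores <- function(x, ...) {
  cat(sprintf("LD scores: %d SNPs x %d annotations (base: '%s')\n",
              nrow(x$ell), ncol(x$ell), colnames(x$ell)[x$base]))
  invisible(x)
}

#' Build a summary-statistics table
#'
#' @param snp SNP identifiers.
#' @param z Association Z statistics (`chi2 = z^2`).
#' @param n Per-SNP GWAS sample size (positive).
#' @param a1,a2 Alleles (optional, kept for the sumstats file dialect).
#' @return A `sumstats` data.frame.
#' @export
sumstats <- function(snp, z, n, a1 = NA, a2 = NA) {
  if (any(!is.finite(z))) stop("Z statistics must be finite")
  if (any(n <= 0)) stop("sample size must be positive")
  out <- data.frame(snp = as.character(snp), a1 = a1, a2 = a2,
                    n = as.numeric(n), z = as.numeric(z),
                    stringsAsFactors = FALSE)
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Read / write the LDSC sumstats dialect (SNP A1 A2 N Z)
#'
#' @param path File path (plain or gz).
#' @return [read_sumstats()] returns a [sumstats()] table.
#' @export
read_sumstats <- function(path) {
  t <- read_table_any(path)
  names(t) <- toupper(names(t))
  need <- c("SNP", "N", "Z")
  if (!all(need %in% names(t))) {
    stop("sumstats file must have columns SNP, N, Z")
  }
  grab <- function(col) if (col %in% names(t)) t[[col]] else NA
  sumstats(t$SNP, t$Z, t$N, grab("A1"), grab("A2"))
}

#' @rdname read_sumstats
#' @param ss A [sumstats()] table.
#' @export
write_sumstats <- function(ss, path) {
  data.table::fwrite(
    data.frame(SNP = ss$snp, A1 = ss$a1, A2 = ss$a2, N = ss$n, Z = ss$z),
    path, sep = "\t",
    compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Write LD scores in the LDSC l2.ldscore dialect
#'
#' Columns CHR, SNP, BP, then one `<name>L2` column per annotation.
#'
#' @param ldscores An [compute_ld_scores()] object.
#' @param panel The [snp_panel()] (for CHR/BP lookup by SNP id).
#' @param path Output path (`.gz` compresses).
#' @export
write_ldscores <- function(ldscores, panel, path) {
  i <- match(ldscores$snp, panel$snp)
  out <- data.frame(CHR = panel$chrom[i], SNP = ldscores$snp,
                    BP = panel$pos[i])
  l2 <- as.data.frame(ldscores$ell)
  names(l2) <- paste0(colnames(ldscores$ell), "L2")
  data.table::fwrite(cbind(out, l2), path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Stratified regression of GWAS chi-square on annotation LD scores
#'
#' Weighted least squares fit of
#' `chi2_j = intercept + N_j * sum_c tau_c * ell(j, c)`. Default weights are
#' the heteroskedasticity proxy `1 / (2 * (1 + N * ell_base * h2/M)^2)` with
#' `h2` taken from a preliminary unweighted fit; `weights = "none"` gives
#' ordinary least squares.
#'
#' @param ss A [sumstats()] table (joined to the LD scores on SNP id).
#' @param ldscores An [compute_ld_scores()] object.
#' @param weights `"ldsc"` (default) or `"none"`.
#' @return An `sldsc_fit`: list with `tau` (named vector), `intercept`,
#'   the joined design pieces (`ell`, `annot`, `chi2`, `n_gwas`, `w`),
#'   annotation totals `M`, `M_total`, `base`, and `n_snps`.
#' @export
stratified_regression <- function(ss, ldscores, weights = c("ldsc", "none")) {
  weights <- match.arg(weights)
  stopifnot(inherits(ldscores, "ld_scores"))
  i <- match(ldscores$snp, ss$snp)
  if (all(is.na(i))) stop("no SNP ids shared between sumstats and LD scores")
  keep <- !is.na(i)
  ell <- ldscores$ell[keep, , drop = FALSE]
  if (ncol(ell) < 2L) stop("need >= 2 annotations including the base")
  if (anyDuplicated(t(ell)) > 0) {
    dup <- which(duplicated(t(ell)) | duplicated(t(ell), fromLast = TRUE))
    stop("collinear (duplicated) annotation columns: ",
         paste(colnames(ell)[dup], collapse = ", "))
  }
  chi2 <- ss$z[i[keep]]^2
  n_gwas <- ss$n[i[keep]]
  D <- cbind(intercept = 1, n_gwas * ell)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    stop("rank-deficient design; collinear annotations: ",
         paste(colnames(D)[qrD$pivot[-seq_len(qrD$rank)]], collapse = ", "))
  }
  solve_wls <- function(w) {
    ch <- chol(crossprod(D * sqrt(w)))
    drop(backsolve(ch, backsolve(ch, crossprod(D, w * chi2),
                                 transpose = TRUE)))
  }
  if (weights == "ldsc") {
    beta0 <- solve_wls(rep(1, nrow(D)))
    h2bar <- min(max(sum(beta0[-1] * ldscores$M), 1e-3), 1)
    w <- 1 / (2 * (1 + n_gwas * ell[, ldscores$base] *
                     h2bar / ldscores$M_total)^2)
  } else {
    w <- rep(1, nrow(D))
  }
  beta <- solve_wls(w)
  names(beta) <- colnames(D)
  structure(
    list(tau = beta[-1], intercept = unname(beta[1]), ell = ell,
         annot = ldscores$annot[keep, , drop = FALSE], chi2 = chi2,
         n_gwas = n_gwas, w = w, M = ldscores$M,
         M_total = ldscores$M_total, base = ldscores$base,
         n_snps = nrow(ell)),
    class = "sldsc_fit")
}

#' @export
print.sldsc_fit <- function(x, ...) {
  cat(sprintf("S-LDSC fit: %d SNPs, %d annotations, intercept %.3f\n",
              x$n_snps, length(x$tau), x$intercept))
  print(x$tau)
  invisible(x)
}

# h2 per annotation from tau: h2_c = sum_j a_jc * (sum_c' tau_c' a_jc'),
# aggregated over the reference annotation matrix A (rows = SNPs).
.partition_h2 <- function(tau, A) {
  drop(crossprod(A, drop(A %*% tau)))
}

#' Partition heritability and compute enrichment
#'
#' Per-annotation heritability is `h2_c = sum_j a_jc var_j` with
#' `var_j = sum_c' tau_c' a_jc'`; enrichment is the annotation's share of
#' total h2 divided by its share of SNPs. Negative per-annotation h2 (from a
#' negative tau) is reported as-is, not truncated.
#'
#' @param fit An [stratified_regression()] fit (or a named tau vector, in
#'   which case `annot` must be supplied).
#' @param annot Optional 0/1 annotation matrix overriding the fit's.
#' @return data.frame: `annotation`, `M_c`, `prop_snps`, `tau`, `h2`,
#'   `prop_h2`, `enrichment`.
#' @export
partition_and_enrich <- function(fit, annot = NULL) {
  if (inherits(fit, "sldsc_fit")) {
    tau <- fit$tau
    if (is.null(annot)) annot <- fit$annot
  } else {
    tau <- fit
    if (is.null(annot)) stop("supply the annotation matrix with a raw tau")
  }
  M_c <- colSums(annot)
  if (any(M_c == 0)) {
    stop("empty annotation(s): ",
         paste(colnames(annot)[M_c == 0], collapse = ", "))
  }
  h2_c <- .partition_h2(tau, annot)
  h2_tot <- sum(drop(annot %*% tau))
  prop_snps <- M_c / nrow(annot)
  prop_h2 <- h2_c / h2_tot
  data.frame(annotation = colnames(annot), M_c = M_c,
             prop_snps = prop_snps, tau = unname(tau), h2 = h2_c,
             prop_h2 = prop_h2, enrichment = prop_h2 / prop_snps,
             row.names = NULL)
}

#' Block-jackknife standard errors for an S-LDSC fit
#'
#' Delete-one-block jackknife over `n_blocks` contiguous SNP blocks (SNPs
#' are already in genome order): the WLS fit is recomputed with each block
#' removed, and the SE of every reported quantity (tau, intercept, h2
#' shares, enrichment) is `sqrt((B-1)/B * sum((q_b - mean(q_b))^2))`. Wald
#' p-values test tau = 0 and enrichment = 1 against a normal reference.
#'
#' @param fit An [stratified_regression()] fit.
#' @param n_blocks Number of jackknife blocks (LDSC convention: 200).
#' @return List with `table` (the [partition_and_enrich()] frame plus
#'   `tau_se`, `tau_p`, `enrichment_se`, `enrichment_p`), `intercept`,
#'   `intercept_se`, and the per-block estimates in `blocks`.
#' @export
jackknife_se <- function(fit, n_blocks = 200L) {
  stopifnot(inherits(fit, "sldsc_fit"))
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop("need at least 2 jackknife blocks")
  if (n_blocks > fit$n_snps) stop("more blocks than SNPs")
  D <- cbind(intercept = 1, fit$n_gwas * fit$ell)
  w <- fit$w
  y <- fit$chi2
  block <- ceiling(seq_len(fit$n_snps) / (fit$n_snps / n_blocks))
  XtWX <- crossprod(D * sqrt(w))
  XtWy <- crossprod(D, w * y)
  p <- ncol(D)
  est <- matrix(NA_real_, n_blocks, p)
  enr <- matrix(NA_real_, n_blocks, length(fit$tau))
  for (b in seq_len(n_blocks)) {
    ib <- which(block == b)
    Db <- D[ib, , drop = FALSE]
    wb <- w[ib]
    A_b <- XtWX - crossprod(Db * sqrt(wb))
    c_b <- XtWy - crossprod(Db, wb * y[ib])
    beta_b <- drop(solve(A_b, c_b))
    est[b, ] <- beta_b
    pe <- partition_and_enrich(stats::setNames(beta_b[-1], names(fit$tau)),
                               annot = fit$annot)
    enr[b, ] <- pe$enrichment
  }
  jse <- function(v) {
    B <- length(v)
    sqrt((B - 1) / B * sum((v - mean(v))^2))
  }
  tau_se <- apply(est[, -1, drop = FALSE], 2L, jse)
  enr_se <- apply(enr, 2L, jse)
  tab <- partition_and_enrich(fit)
  tab$tau_se <- tau_se
  tab$tau_p <- 2 * stats::pnorm(-abs(tab$tau) / tau_se)
  tab$enrichment_se <- enr_se
  tab$enrichment_p <- ifelse(enr_se == 0 & tab$enrichment == 1, 1,
                             2 * stats::pnorm(-abs(tab$enrichment - 1) /
                                                enr_se))
  list(table = tab, intercept = fit$intercept,
       intercept_se = jse(est[, 1]),
       blocks = list(coefficients = est, enrichment = enr))
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up BH over all supplied p-values jointly (the default pooling:
#' one grid of annotation x trait tests, one FDR).
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical vector: TRUE where the test is significant at FDR `q`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' One-call heritability enrichment analysis
#'
#' Runs [stratified_regression()], [jackknife_se()] and BH flagging for one
#' trait's summary statistics.
#'
#' @inheritParams stratified_regression
#' @param n_blocks Jackknife blocks.
#' @param q FDR level for the per-call BH flags (pool p-values across traits
#'   yourself for a global FDR).
#' @return The [jackknife_se()] result with an `fdr_significant` column
#'   added to `table`.
#' @export
sldsc <- function(ss, ldscores, weights = "ldsc", n_blocks = 200L, q = 0.05) {
  fit <- stratified_regression(ss, ldscores, weights = weights)
  jk <- jackknife_se(fit, n_blocks = n_blocks)
  jk$table$fdr_significant <- bh_fdr(jk$table$enrichment_p, q = q)
  jk
}
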