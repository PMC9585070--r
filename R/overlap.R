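#' Fisher exact odds ratio between two binary annotations
#'
#' The 2x2 table counts joint SNP membership: `a` = both 1, `b` = A only,
#' `c` = B only, `d` = neither. The reported OR is the sample cross-product
#' `(a*d)/(b*c)` (the quantity whose log is plotted in annotation-overlap
#' heatmaps); `estimate = "cmle"` returns the conditional MLE instead. The
#' two-sided p-value is the exact hypergeometric tail (sum over tables with
#' probability <= observed). A zero off-diagonal cell yields OR `Inf` (or
#' 0), flagged; no continuity correction is applied.
#'
#' @param annotA,annotB 0/1 vectors aligned to one SNP panel.
#' @param estimate `"cross-product"` (default) or `"cmle"`.
#' @return List: `or`, `log_or`, `p`, `table` (2x2), `degenerate` (TRUE when
#'   a zero cell makes the cross-product 0 or infinite).
#' @export
fisher_or <- function(annotA, annotB, estimate = c("cross-product", "cmle")) {
  estimate <- match.arg(estimate)
  if (length(annotA) != length(annotB)) {
    stop("annotations must be aligned to the same panel")
  }
  A <- as.integer(annotA); B <- as.integer(annotB)
  a <- sum(A == 1L & B == 1L)
  b <- sum(A == 1L & B == 0L)
  c_ <- sum(A == 0L & B == 1L)
  d <- sum(A == 0L & B == 0L)
  tab <- matrix(c(a, c_, b, d), 2L,
                dimnames = list(A = c("1", "0"), B = c("1", "0")))
  ft <- stats::fisher.test(tab)
  or <- if (estimate == "cmle") unname(ft$estimate) else
    (a / b) * (d / c_)  # a*d/(b*c) without integer overflow
  list(or = or, log_or = log(or), p = ft$p.value, table = tab,
       degenerate = !is.finite(or) || or == 0)
}

#' Odds-ratio matrix between Cas annotations and functional annotations
#'
#' One [fisher_or()] per (Cas, functional) pair, the computation behind the
#' annotation-overlap heatmaps (rows: Cas annotations, columns: functional
#' annotations; blue cells are log OR > 0).
#'
#' @param cas_annots,functional_annots Named lists of 0/1 annotations on a
#'   shared panel.
#' @return List of matrices `log_or` and `p` (rows = Cas, columns =
#'   functional).
#' @export
or_matrix <- function(cas_annots, functional_annots) {
  nm_r <- names(cas_annots)
  nm_c <- names(functional_annots)
  log_or <- matrix(NA_real_, length(cas_annots), length(functional_annots),
                   dimnames = list(nm_r, nm_c))
  p <- log_or
  for (i in seq_along(cas_annots)) {
    for (j in seq_along(functional_annots)) {
      f <- fisher_or(cas_annots[[i]], functional_annots[[j]])
      log_or[i, j] <- f$log_or
      p[i, j] <- f$p
    }
  }
  list(log_or = log_or, p = p)
}

#' Pearson correlation with a Fisher-Z p-value
#'
#' `r` is the ordinary Pearson coefficient; significance comes from the
#' Fisher Z transform, `z = atanh(r) * sqrt(n - 3)`, compared two-sided to a
#' standard normal. `|r| = 1` makes z infinite; p is reported as 0 with
#' `underflow = TRUE`.
#'
#' @param x,y Numeric vectors, length >= 4, non-constant.
#' @return List: `r`, `z`, `p`, `n`, `underflow`.
#' @export
pearson_fisher_z <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need n >= 4 for the Fisher-Z test")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  r <- stats::cor(x, y)
  if (1 - abs(r) < 1e-12) r <- sign(r)  # numerically collinear
  z <- atanh(r) * sqrt(n - 3)
  p <- 2 * stats::pnorm(-abs(z))
  list(r = r, z = z, p = p, n = n,
       underflow = !is.finite(z) || p < .Machine$double.xmin)
}

#' Read an off-target site table
#'
#' TSV with columns `chrom`, `pos` (1-based), `frequency` (cleavage
#' frequency in `[0, 1]`) and optionally `study`.
#'
#' @param path TSV file path.
#' @return data.frame of sites.
#' @export
read_offtargets <- function(path) {
  t <- as.data.frame(data.table::fread(path))
  need <- c("chrom", "pos", "frequency")
  if (!all(need %in% names(t))) {
    stop("off-target TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(t$frequency < 0 | t$frequency > 1, na.rm = TRUE)) {
    stop("cleavage frequency must lie in [0, 1]")
  }
  t
}

#' Match off-target sites to genome segments
#'
#' Assigns each site to the half-open segment containing its position and
#' reports per-segment site counts and mean cleavage frequency — the inputs
#' for asking whether PAM-dense segments attract more off-target sites and
#' whether cleavage frequency tracks PAM count (pair the columns with an NGG
#' count vector via [pearson_fisher_z()]).
#'
#' @param sites Off-target table (`chrom`, `pos`, `frequency`); sites on
#'   chromosomes absent from the segmentation are dropped and counted.
#' @param segments A [segment_genome()] table.
#' @return List: `per_segment` data.frame (`segment`, `n_sites`,
#'   `mean_frequency`) covering all segments, and `n_dropped`.
#' @export
offtargets_to_segments <- function(sites, segments) {
  g <- attr(segments, "genome")
  known <- sites$chrom %in% g$chrom
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    warning(n_dropped, " off-target site(s) on unknown chromosomes dropped")
  }
  s <- sites[known, , drop = FALSE]
  pos0 <- concat_coord(g, s$chrom, s$pos)
  idx <- findInterval(pos0, segments$start) - 1L
  idx[pos0 >= segments$end[nrow(segments)]] <- NA_integer_
  bad <- is.na(idx)
  if (any(bad)) {
    warning(sum(bad), " site(s) beyond the segmented coordinate dropped")
    n_dropped <- n_dropped + sum(bad)
    idx <- idx[!bad]; s <- s[!bad, , drop = FALSE]
  }
  n_sites <- tabulate(idx + 1L, nbins = nrow(segments))
  fsum <- rep(0, nrow(segments))
  agg <- tapply(s$frequency, idx, sum)
  fsum[as.integer(names(agg)) + 1L] <- agg
  list(per_segment = data.frame(
         segment = segments$segment, n_sites = n_sites,
         mean_frequency = ifelse(n_sites > 0, fsum / n_sites, NA_real_)),
       n_dropped = n_dropped)
}
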