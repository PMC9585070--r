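#' Build a SNP panel
#'
#' @param snp SNP identifiers.
#' @param chrom Chromosome names.
#' @param pos 1-based positions (VCF/BIM convention).
#' @param a1,a2 Alleles (optional).
#' @param maf Minor allele frequencies in `[0, 0.5]` (optional).
#' @param cm Genetic-map positions in centiMorgans (optional).
#' @return A `snp_panel` data.frame.
#' @export
snp_panel <- function(snp, chrom, pos, a1 = NA, a2 = NA, maf = NA, cm = NA) {
  if (!all(is.na(maf)) && any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    stop("MAF must lie in [0, 0.5]")
  }
  out <- data.frame(snp = as.character(snp), chrom = as.character(chrom),
                    pos = as.numeric(pos), a1 = a1, a2 = a2,
                    maf = as.numeric(maf), cm = as.numeric(cm),
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Read a PLINK BIM file as a SNP panel
#'
#' BIM columns: chrom, snp, cm, pos, a1, a2 (no header, no MAF).
#'
#' @param path BIM file path.
#' @return A [snp_panel()] with `maf = NA`.
#' @export
read_bim <- function(path) {
  b <- data.table::fread(path, header = FALSE,
                         col.names = c("chrom", "snp", "cm", "pos",
                                       "a1", "a2"))
  snp_panel(b$snp, b$chrom, b$pos, b$a1, b$a2, maf = NA, cm = b$cm)
}

#' Read a sites-only VCF as a SNP panel
#'
#' Parses CHROM/POS/ID/REF/ALT and, when present, an `AF=` INFO field
#' (folded to minor allele frequency). Plain or bgzipped VCF.
#'
#' @param path VCF file path.
#' @return A [snp_panel()].
#' @export
read_vcf_panel <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[!startsWith(lines, "##")]
  v <- data.table::fread(text = sub("^#", "", lines), header = TRUE)
  af <- rep(NA_real_, nrow(v))
  if ("INFO" %in% names(v)) {
    m <- regmatches(v$INFO, regexpr("(?<=^AF=|;AF=)[0-9.eE+-]+", v$INFO,
                                    perl = TRUE))
    has <- grepl("(^|;)AF=", v$INFO)
    af[has] <- as.numeric(m)
  }
  maf <- pmin(af, 1 - af)
  snp_panel(v$ID, v$CHROM, v$POS, v$REF, v$ALT, maf = maf, cm = NA)
}

#' Read a plain TSV SNP panel
#'
#' Requires columns `snp`, `chrom`, `pos`; `a1`, `a2`, `maf`, `cm` are
#' optional.
#'
#' @param path TSV file path.
#' @return A [snp_panel()].
#' @export
read_snp_panel <- function(path) {
  t <- data.table::fread(path)
  need <- c("snp", "chrom", "pos")
  if (!all(need %in% names(t))) {
    stop("panel TSV must have columns: ", paste(need, collapse = ", "))
  }
  grab <- function(col) if (col %in% names(t)) t[[col]] else NA
  snp_panel(t$snp, t$chrom, t$pos, grab("a1"), grab("a2"),
            grab("maf"), grab("cm"))
}

#' Annotate SNPs by membership in a Cas-enriched region set
#'
#' A SNP is annotated 1 iff its position falls inside a selected segment's
#' half-open interval `[start, end)` in concatenated coordinates (a SNP
#' exactly at a segment's end coordinate belongs to the next segment);
#' all other SNPs are 0.
#'
#' @param panel A [snp_panel()].
#' @param regions A [top_k_segments()] region set.
#' @param segments The [segment_genome()] table the regions come from.
#' @param on_missing_chrom `"error"` (default) or `"drop"`: what to do with
#'   SNPs on chromosomes absent from the segmentation's genome. Dropped SNPs
#'   get membership 0 and a warning reports how many.
#' @param name Annotation name.
#' @return A `binary_annotation`: integer 0/1 vector aligned to the panel,
#'   with attributes `name` and `n_segments`.
#' @export
annotate_snps <- function(panel, regions, segments,
                          on_missing_chrom = c("error", "drop"),
                          name = regions$label) {
  on_missing_chrom <- match.arg(on_missing_chrom)
  stopifnot(inherits(regions, "region_set"))
  if (regions$n_segments != nrow(segments)) {
    stop("region set and segment table disagree on segment count")
  }
  g <- attr(segments, "genome")
  known <- panel$chrom %in% g$chrom
  if (!all(known)) {
    if (on_missing_chrom == "error") {
      stop("SNPs on chromosomes absent from segmentation: ",
           paste(unique(panel$chrom[!known]), collapse = ", "))
    }
    warning(sum(!known), " SNP(s) on unknown chromosomes annotated 0")
  }
  memb <- integer(nrow(panel))
  pos0 <- concat_coord(g, panel$chrom[known], panel$pos[known])
  # segment index of each SNP: segments are consecutive half-open intervals
  idx <- findInterval(pos0, segments$start) - 1L
  idx[pos0 >= segments$end[nrow(segments)]] <- NA_integer_
  memb[known] <- as.integer(idx %in% regions$segments)
  binary_annotation(memb, name = name, n_segments = regions$n_segments)
}

#' Construct a binary annotation
#'
#' @param membership 0/1 vector, one entry per panel SNP.
#' @param name Annotation name.
#' @param n_segments Optional segmentation size carried for sanity checks.
#' @return A `binary_annotation` integer vector.
#' @export
binary_annotation <- function(membership, name = "annot", n_segments = NA) {
  m <- as.integer(membership)
  if (any(is.na(m)) || !all(m %in% c(0L, 1L))) {
    stop("membership must be 0/1 with no NA")
  }
  structure(m, class = "binary_annotation", name = name,
            n_segments = n_segments)
}

#' @export
print.binary_annotation <- function(x, ...) {
  cat(sprintf("Annotation '%s': %d of %d SNPs (%.1f%%)\n", attr(x, "name"),
              sum(x), length(x), 100 * mean(x)))
  invisible(x)
}

#' Filter a SNP panel the way the heritability analysis expects
#'
#' Keeps SNPs with MAF strictly above `maf_min` (a SNP at exactly 5% is
#' removed), removes SNPs inside excluded regions (default: the GRCh37 MHC,
#' chr6:25,000,000-34,000,000, excluded for its atypical LD), and, when a
#' keep list is given (e.g. HapMap3 identifiers), intersects with it.
#'
#' @param panel A [snp_panel()].
#' @param maf_min Strict lower MAF bound; `NULL` skips the MAF filter
#'   (as does an all-NA `maf` column).
#' @param exclude data.frame of 1-based closed intervals (`chrom`, `start`,
#'   `end`) to remove; `NULL` for none.
#' @param keep_list Optional character vector of SNP ids to retain.
#' @return The filtered [snp_panel()].
#' @export
apply_snp_filters <- function(panel, maf_min = 0.05, exclude = mhc_grch37(),
                              keep_list = NULL) {
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(maf_min) && !all(is.na(panel$maf))) {
    keep <- keep & !is.na(panel$maf) & panel$maf > maf_min
  }
  if (!is.null(exclude)) {
    for (i in seq_len(nrow(exclude))) {
      inside <- panel$chrom == exclude$chrom[i] &
        panel$pos >= exclude$start[i] & panel$pos <= exclude$end[i]
      keep <- keep & !inside
    }
  }
  if (!is.null(keep_list)) {
    keep <- keep & panel$snp %in% keep_list
    if (length(keep_list) == 0L) warning("empty keep_list: no SNPs retained")
  }
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default MHC exclusion interval (GRCh37)
#'
#' @param chrom Chromosome name as spelled in the panel (default `"6"`).
#' @return One-row data.frame (`chrom`, `start`, `end`), 1-based closed.
#' @export
mhc_grch37 <- function(chrom = "6") {
  data.frame(chrom = chrom, start = 25e6, end = 34e6)
}

#' Write binary annotations in LDSC annot, BED or TSV format
#'
#' The ldsc-annot dialect has one row per SNP with columns CHR, BP, SNP, CM,
#' then one 0/1 column per annotation; a `.gz` path gzip-compresses. BED
#' exports the distinct annotated segments' chromosome intervals; TSV writes
#' `snp` plus the 0/1 columns.
#'
#' @param annotations A `binary_annotation` or list of them (all aligned to
#'   `panel`).
#' @param panel The [snp_panel()] the annotations are aligned to.
#' @param path Output path (`.gz` suffix triggers compression).
#' @param format `"ldsc-annot"`, `"bed"` or `"tsv"`.
#' @param segments Required for `"bed"`: the [segment_genome()] table.
#' @export
write_annotation <- function(annotations, panel, path,
                             format = c("ldsc-annot", "bed", "tsv"),
                             segments = NULL) {
  format <- match.arg(format)
  if (inherits(annotations, "binary_annotation")) {
    annotations <- list(annotations)
  }
  nm <- vapply(annotations, attr, character(1), "name")
  stopifnot(all(lengths(annotations) == nrow(panel)))
  cols <- stats::setNames(lapply(annotations, as.integer), nm)
  if (format == "ldsc-annot") {
    out <- data.frame(CHR = panel$chrom, BP = panel$pos, SNP = panel$snp,
                      CM = ifelse(is.na(panel$cm), 0, panel$cm))
    out <- cbind(out, cols)
    data.table::fwrite(out, path, sep = "\t",
                       compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  } else if (format == "tsv") {
    data.table::fwrite(cbind(data.frame(snp = panel$snp), cols), path,
                       sep = "\t")
  } else {
    if (is.null(segments)) stop("BED export needs the segment table")
    bed <- segments_to_bed(segments)
    for (i in seq_along(annotations)) {
      snp1 <- panel[annotations[[i]] == 1L, , drop = FALSE]
      g <- attr(segments, "genome")
      pos0 <- concat_coord(g, snp1$chrom, snp1$pos)
      segs <- sort(unique(findInterval(pos0, segments$start) - 1L))
      sel <- bed[bed$name %in% sprintf("segment_%d", segs), , drop = FALSE]
      sel$name <- paste0(nm[i], ":", sel$name)
      data.table::fwrite(sel, path, sep = "\t", col.names = FALSE,
                         append = i > 1L)
    }
  }
  invisible(path)
}

#' Read an ldsc-annot file back into binary annotations
#'
#' @param path Annot file written by [write_annotation()] (plain or gz).
#' @return List with `panel` (a [snp_panel()], MAF unknown) and
#'   `annotations` (list of `binary_annotation`).
#' @export
read_annotation <- function(path) {
  t <- read_table_any(path)
  need <- c("CHR", "BP", "SNP", "CM")
  if (!all(need %in% names(t))) stop("not an ldsc-annot file")
  panel <- snp_panel(t$SNP, t$CHR, t$BP, cm = t$CM)
  acols <- setdiff(names(t), need)
  ann <- lapply(acols, function(a) binary_annotation(t[[a]], name = a))
  names(ann) <- acols
  list(panel = panel, annotations = ann)
}
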