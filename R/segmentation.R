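#' Concatenate chromosomes end to end
#'
#' Joins the requested sequences of a FASTA file (or an in-memory
#' `DNAStringSet`) into one piece with a chromosome -> offset map, the
#' coordinate system in which fixed-width segmentation is done. For the
#' GRCh37 primary-assembly autosomes chr1..chr22 the concatenated length is
#' 2,881,033,286 bases.
#'
#' @param fasta Path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @param chromosomes Ordered character vector of sequence names to include;
#'   `NULL` takes all sequences in file order. FASTA headers are matched on
#'   their first whitespace-separated token.
#' @return A `genome_concat`: list with `seq` (one `DNAString`), `chrom`,
#'   `lengths`, `offsets` (0-based start of each chromosome in the
#'   concatenated coordinate), `total_length` and `source`.
#' @export
concatenate_autosomes <- function(fasta, chromosomes = NULL) {
  if (inherits(fasta, "DNAStringSet")) {
    dss <- fasta
    src <- "DNAStringSet"
  } else {
    dss <- Biostrings::readDNAStringSet(fasta)
    src <- as.character(fasta)
  }
  names(dss) <- vapply(strsplit(names(dss), "\\s+"), `[`, character(1), 1L)
  if (is.null(chromosomes)) chromosomes <- names(dss)
  if (length(chromosomes) == 0L) stop("no chromosomes requested")
  missing <- setdiff(chromosomes, names(dss))
  if (length(missing)) {
    stop("chromosome(s) not found in FASTA: ",
         paste(missing, collapse = ", "))
  }
  dss <- dss[chromosomes]
  lens <- Biostrings::width(dss)
  offsets <- cumsum(c(0, lens[-length(lens)]))
  names(offsets) <- chromosomes
  seq <- Biostrings::DNAString(
    toupper(as.character(unlist(Biostrings::DNAStringSet(dss)))))
  structure(
    list(seq = seq, chrom = chromosomes,
         lengths = stats::setNames(lens, chromosomes),
         offsets = offsets, total_length = sum(lens), source = src),
    class = "genome_concat")
}

#' @export
print.genome_concat <- function(x, ...) {
  cat(sprintf("Concatenated genome: %d chromosome(s), %s bases\n",
              length(x$chrom), format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Map chromosome positions to concatenated coordinates
#'
#' @param genome A [concatenate_autosomes()] result.
#' @param chrom,pos Chromosome names and 1-based positions (VCF/BIM
#'   convention).
#' @return 0-based positions in the concatenated coordinate; `NA` for
#'   chromosomes absent from the concatenation.
#' @export
concat_coord <- function(genome, chrom, pos) {
  stopifnot(inherits(genome, "genome_concat"))
  off <- genome$offsets[as.character(chrom)]
  unname(off + pos - 1L)
}

#' Cut a concatenated genome into fixed-count segments
#'
#' Segment length is `ceiling(total_length / n_segments)`; segments are
#' consecutive 0-based half-open intervals and the last one may be shorter.
#' For 2,881,033,286 bases in 20,000 segments this gives 144,052 bp per
#' segment (last segment 137,338 bp). Per-segment base composition is
#' computed, with GC content adjusted for non-N length; fully-N segments are
#' flagged `all_n` and excluded from downstream ranking.
#'
#' @param genome A `genome_concat`.
#' @param n_segments Number of segments (>= 1, <= total length).
#' @return A `segment_table` data.frame with columns `segment` (0-based
#'   index), `start`, `end` (half-open concatenated coordinates), base
#'   counts `A C G T N`, `gc_adjusted` (`NA` for all-N segments) and
#'   `all_n`. The genome is kept in `attr(, "genome")`, the segment length
#'   in `attr(, "segment_length")`.
#' @export
segment_genome <- function(genome, n_segments) {
  stopifnot(inherits(genome, "genome_concat"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("n_segments must be >= 1")
  if (n_segments > genome$total_length) {
    stop("n_segments exceeds genome length")
  }
  L <- as.integer(ceiling(genome$total_length / n_segments))
  starts <- (seq_len(n_segments) - 1) * as.numeric(L)
  ends <- pmin(starts + L, genome$total_length)
  keep <- starts < genome$total_length  # all TRUE by construction of ceil
  starts <- starts[keep]; ends <- ends[keep]
  v <- IRanges::Views(genome$seq, start = starts + 1, end = ends)
  freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
  other <- (ends - starts) - rowSums(freq)
  if (any(other > 0)) {
    stop("genome contains characters outside {A,C,G,T,N}")
  }
  non_n <- (ends - starts) - freq[, "N"]
  gc_adj <- ifelse(non_n > 0, (freq[, "C"] + freq[, "G"]) / non_n, NA_real_)
  out <- data.frame(segment = seq_along(starts) - 1L, start = starts,
                    end = ends, freq, gc_adjusted = gc_adj,
                    all_n = non_n == 0, row.names = NULL)
  attr(out, "genome") <- genome
  attr(out, "segment_length") <- L
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Base composition of a single sequence
#'
#' @param sequence DNA string; lowercase (soft-masked) letters are upper-cased
#'   and counted as their base.
#' @param on_other `"error"` (default) rejects characters outside
#'   `{A,C,G,T,N}`; `"as_n"` counts them as N.
#' @return List with `counts` (named A/C/G/T/N), `gc_adjusted` = (G+C) /
#'   (length - N), and `all_n` (TRUE means the excluded flag: GC undefined).
#' @export
segment_composition <- function(sequence, on_other = c("error", "as_n")) {
  on_other <- match.arg(on_other)
  s <- toupper(as.character(sequence))
  chars <- strsplit(s, "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  bad <- !chars %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    if (on_other == "error") {
      stop(sprintf("invalid character '%s' at position %d",
                   chars[which(bad)[1]], which(bad)[1]))
    }
    chars[bad] <- "N"
  }
  counts <- vapply(c("A", "C", "G", "T", "N"),
                   function(b) sum(chars == b), integer(1))
  non_n <- length(chars) - counts[["N"]]
  list(counts = counts,
       gc_adjusted = if (non_n > 0)
         (counts[["C"]] + counts[["G"]]) / non_n else NA_real_,
       all_n = non_n == 0L)
}

# sequence of one segment (row index i, 1-based) as a Views-backed DNAString
.segment_seq <- function(segments, i) {
  g <- attr(segments, "genome")
  Biostrings::subseq(g$seq, start = segments$start[i] + 1,
                     end = segments$end[i])
}

#' Project concatenated segments back to chromosome intervals (BED)
#'
#' Segments may span chromosome junctions; such segments yield one BED row
#' per chromosome piece. BED is 0-based half-open.
#'
#' @param segments A `segment_table`.
#' @param path Output file; `NULL` returns the data.frame invisibly written.
#' @return Invisibly, a data.frame with `chrom`, `start`, `end`, `name`.
#' @export
segments_to_bed <- function(segments, path = NULL) {
  g <- attr(segments, "genome")
  bounds <- c(g$offsets, total = g$total_length)
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments$start[i]; e <- segments$end[i]
    ci <- findInterval(s, bounds, rightmost.closed = FALSE)
    cj <- findInterval(e - 1, bounds)
    idx <- ci:cj
    data.frame(
      chrom = g$chrom[idx],
      start = pmax(s, bounds[idx]) - bounds[idx],
      end = pmin(e, bounds[idx + 1]) - bounds[idx],
      name = sprintf("segment_%d", segments$segment[i]),
      row.names = NULL)
  })
  bed <- do.call(rbind, rows)
  if (!is.null(path)) {
    data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  }
  invisible(bed)
}

#' Write a segment table as TSV
#'
#' @param segments A `segment_table`.
#' @param path Output TSV path.
#' @export
write_segment_table <- function(segments, path) {
  data.table::fwrite(as.data.frame(segments), path, sep = "\t")
  invisible(path)
}
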