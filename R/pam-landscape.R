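#' Find PAM occurrences in a sequence on one or both strands
#'
#' Forward hits are windows of the sequence matching the IUPAC pattern;
#' reverse hits are windows matching [revcomp_pattern()] of it (scanning
#' `NGG` on both strands means counting `NGG` and `CCN`, as a reverse-strand
#' PAM site reads as the reverse complement on the forward strand).
#' Overlapping windows are all reported; windows containing `N` never match.
#' Offsets are 0-based window starts in forward-strand coordinates.
#'
#' @param sequence DNA string or `DNAString` (case-insensitive).
#' @param pattern A [pam_pattern()] or character scalar.
#' @param strands `"both"` (default) or `"forward"`.
#' @return data.frame with `offset` (0-based) and `strand` (`"+"`/`"-"`),
#'   ordered by offset then strand.
#' @export
match_positions <- function(sequence, pattern, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  p <- as_pam(pattern)
  subj <- if (inherits(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  len <- length(subj)
  # positions of N letters, found once: pattern codes never denote the
  # letter N, so any window containing one must be rejected
  n_at <- which(Biostrings::isMatchingAt(.dna_cache("N"), subj,
                                         at = seq_len(len), fixed = TRUE))
  scan <- function(pat) {
    w <- nchar(pat)
    if (w > len) return(integer(0))
    st <- which(Biostrings::isMatchingAt(
      .dna_cache(unclass(pat)), subj, at = seq_len(len - w + 1L),
      fixed = c(pattern = FALSE, subject = TRUE)))
    if (length(n_at) && length(st)) {
      has_n <- (findInterval(st + w - 1L, n_at) -
                  findInterval(st - 1L, n_at)) > 0
      st <- st[!has_n]
    }
    st - 1L
  }
  fwd <- scan(p)
  rev <- if (strands == "both") scan(.revcomp_cached(unclass(p))) else
    integer(0)
  off <- c(fwd, rev)
  str <- rep(c("+", "-"), c(length(fwd), length(rev)))
  o <- order(off, str)
  data.frame(offset = off[o], strand = str[o], stringsAsFactors = FALSE)
}

#' Count PAM occurrences per genome segment
#'
#' Each segment's sequence is scanned with [match_positions()]; only windows
#' fully inside the segment are counted (occurrences straddling a segment
#' boundary are dropped — at 144-kb segments this loses at most
#' `length(pattern) - 1` sites per boundary). All-N segments get `NA`.
#'
#' @param segments A [segment_genome()] table.
#' @param pattern A [pam_pattern()] or character scalar.
#' @param strands Passed to [match_positions()].
#' @param adjust_non_n If `TRUE`, counts are rescaled by
#'   `segment_length / non-N length`, the non-N adjustment used for
#'   partially-N segments.
#' @return Numeric vector of counts, one per segment row.
#' @export
count_pam_per_segment <- function(segments, pattern,
                                  strands = c("both", "forward"),
                                  adjust_non_n = FALSE) {
  strands <- match.arg(strands)
  p <- as_pam(pattern)
  counts <- vapply(seq_len(nrow(segments)), function(i) {
    if (segments$all_n[i]) return(NA_real_)
    nrow(match_positions(.segment_seq(segments, i), p, strands))
  }, numeric(1))
  if (adjust_non_n) {
    len <- segments$end - segments$start
    counts <- counts * len / (len - segments$N)
  }
  counts
}

#' Count a Cas enzyme's PAM sites per segment, deduplicated across PAMs
#'
#' A Cas with several PAMs counts the *union* of its ranking PAMs' match
#' positions: a window matched by two PAMs of the same enzyme (same offset,
#' same strand) counts once. The same window matching on both strands counts
#' twice — forward and reverse hits are distinct targetable sites. Only the
#' enzyme's `ranking_pams` are used (for xCas9 that is NG alone, since its
#' GAA/GAT sites are contained in the NG sites).
#'
#' @param segments A [segment_genome()] table.
#' @param cas A [cas_enzyme()].
#' @param strands Passed to [match_positions()].
#' @return Numeric vector of deduplicated counts, `NA` for all-N segments.
#' @export
cas_segment_counts <- function(segments, cas, strands = c("both", "forward")) {
  stopifnot(inherits(cas, "cas_enzyme"))
  strands <- match.arg(strands)
  vapply(seq_len(nrow(segments)), function(i) {
    if (segments$all_n[i]) return(NA_real_)
    s <- .segment_seq(segments, i)
    hits <- lapply(cas$ranking_pams, function(p)
      match_positions(s, p, strands))
    hits <- do.call(rbind, hits)
    nrow(unique(hits))
  }, numeric(1))
}

#' Count matrix for every PAM and enzyme of a registry
#'
#' @param segments A [segment_genome()] table.
#' @param registry A [cas_registry()].
#' @param strands Passed to [match_positions()].
#' @return data.frame: `segment`, one column per unique PAM pattern, then one
#'   column per enzyme (position-deduplicated union of its ranking PAMs).
#' @export
registry_segment_counts <- function(segments, registry,
                                    strands = c("both", "forward")) {
  stopifnot(inherits(registry, "cas_registry"))
  strands <- match.arg(strands)
  out <- data.frame(segment = segments$segment)
  for (p in registry$unique_pams) {
    out[[p]] <- count_pam_per_segment(segments, p, strands)
  }
  for (e in registry$enzymes) {
    rk <- vapply(e$ranking_pams, unclass, character(1))
    if (length(rk) == 1L) {
      out[[e$name]] <- out[[rk]]  # single ranking PAM: no dedup needed
    } else {
      out[[e$name]] <- cas_segment_counts(segments, e, strands)
    }
  }
  out
}

#' Select the top-k segments by count
#'
#' The standard convention: the top 10% of segments (2000 of 20,000) with the
#' highest PAM/Cas count form the enriched region set. All-N segments
#' (count `NA`) are excluded; ties at the k-boundary are broken by ascending
#' segment index, so the selection is deterministic.
#'
#' @param counts Numeric count vector aligned to segment indices 0..n-1
#'   (`NA` = ineligible).
#' @param k Number of segments to select; default 10% of eligible segments.
#' @param label Region-set label.
#' @return A `region_set`: list with `segments` (0-based indices), `label`,
#'   `k`, `n_segments`.
#' @export
top_k_segments <- function(counts, k = NULL, label = "top") {
  eligible <- which(!is.na(counts))
  if (is.null(k)) k <- floor(length(eligible) / 10)
  if (k > length(eligible)) {
    stop(sprintf("k = %d exceeds the %d eligible segments", k,
                 length(eligible)))
  }
  ord <- eligible[order(-counts[eligible], eligible)]
  structure(list(segments = sort(ord[seq_len(k)]) - 1L, label = label,
                 k = as.integer(k), n_segments = length(counts)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("Region set '%s': %d of %d segments\n", x$label,
              length(x$segments), x$n_segments))
  invisible(x)
}

#' Overlap of a PAM-enriched region set with a GC-rich region set
#'
#' Reports how many of the top PAM segments are (not) among the top GC-rich
#' segments — the count printed in the landscape comparison figures. In the
#' GRCh37 analysis the PAM GCAA has 1993 of its 2000 top segments outside
#' the top GC-rich segments, GGCG has 666.
#'
#' @param pam_top,gc_top Two [top_k_segments()] region sets over the same
#'   segmentation.
#' @return List with `overlap` and `non_overlap` counts.
#' @export
gc_overlap_analysis <- function(pam_top, gc_top) {
  stopifnot(inherits(pam_top, "region_set"), inherits(gc_top, "region_set"))
  if (pam_top$n_segments != gc_top$n_segments) {
    stop("region sets come from different segmentations")
  }
  ov <- length(intersect(pam_top$segments, gc_top$segments))
  list(overlap = ov, non_overlap = length(pam_top$segments) - ov)
}

#' Paired quantiles of GC content vs PAM count across segments
#'
#' Both vectors are min-max normalised to [0, 1] and sorted, giving the
#' quantile-quantile pairing used to compare the two distributions.
#'
#' @param gc,pam Equal-length vectors over eligible segments (no NA).
#' @return data.frame with monotone columns `gc` and `pam`.
#' @export
qq_pam_vs_gc <- function(gc, pam) {
  if (length(gc) != length(pam)) stop("vectors must have equal length")
  if (anyNA(gc) || anyNA(pam)) stop("drop ineligible (NA) segments first")
  norm <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) stop("constant vector: min-max normalisation degenerate")
    (x - r[1]) / (r[2] - r[1])
  }
  data.frame(gc = sort(norm(gc)), pam = sort(norm(pam)))
}
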