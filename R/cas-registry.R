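# IUPAC nucleotide ambiguity codes -> allowed concrete bases
IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Create a PAM pattern
#'
#' A PAM (protospacer-adjacent motif) is the short sequence a Cas enzyme
#' requires next to its target site. Patterns are written with IUPAC
#' ambiguity codes (e.g. `NGG` for SpCas9, `TTTV` for AsCas12a).
#'
#' @param pattern Character scalar over the IUPAC alphabet
#'   `A C G T R Y S W K M B D H V N`.
#' @param orientation `"downstream"` (Cas9 convention, PAM 3' of the
#'   protospacer) or `"upstream"` (Cas12a convention).
#' @return A `pam_pattern`: the upper-cased pattern string with an
#'   `orientation` attribute.
#' @examples
#' pam_pattern("NGG")
#' pam_pattern("TTTV", orientation = "upstream")
#' @export
pam_pattern <- function(pattern, orientation = c("downstream", "upstream")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0L) stop("PAM pattern must be non-empty")
  chars <- strsplit(pattern, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_BASES))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC code '%s' at position %d of pattern '%s'",
                 chars[bad[1]], bad[1], pattern))
  }
  structure(pattern, class = "pam_pattern", orientation = orientation)
}

as_pam <- function(x) {
  if (inherits(x, "pam_pattern")) x else pam_pattern(x)
}

#' @export
print.pam_pattern <- function(x, ...) {
  cat(sprintf("PAM %s (%s, GC %.0f%%)\n", unclass(x),
              attr(x, "orientation"), 100 * pam_gc_content(x)))
  invisible(x)
}

#' Expand an IUPAC-degenerate pattern to concrete DNA strings
#'
#' @param pattern A [pam_pattern()] or character scalar.
#' @return Character vector of all concrete sequences the pattern denotes;
#'   its length is the product of the per-position code cardinalities
#'   (`expand_iupac("NGG")` has 4 elements).
#' @export
expand_iupac <- function(pattern) {
  p <- as_pam(pattern)
  sets <- IUPAC_BASES[strsplit(unclass(p), "")[[1]]]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste0,
             collapse = ""))
}

#' Reverse complement of an IUPAC pattern
#'
#' Degenerate codes are complemented as sets (N<->N, V<->B, R<->Y, S<->S, ...),
#' so `revcomp_pattern("NGG")` is `"CCN"` — the motif one scans on the forward
#' strand to find reverse-strand PAM sites.
#'
#' @inheritParams expand_iupac
#' @return A `pam_pattern` with the same orientation attribute.
#' @export
revcomp_pattern <- function(pattern) {
  p <- as_pam(pattern)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(unclass(p))))
  structure(rc, class = "pam_pattern", orientation = attr(p, "orientation"))
}

# GC weight of one IUPAC code: fraction of its allowed bases that are G/C.
# N returns NA so callers can exclude it.
.gc_weight <- function(code) {
  if (code == "N") return(NA_real_)
  b <- IUPAC_BASES[[code]]
  mean(b %in% c("G", "C"))
}

#' GC content of a PAM pattern
#'
#' The fraction of G/C among the non-N positions of the pattern. N positions
#' are excluded from both numerator and denominator; other degenerate codes
#' contribute the fraction of G/C among their allowed bases (V -> 2/3,
#' S -> 1, W -> 0, ...), which is the expected GC under a uniform choice of
#' allowed base. `NGG` gives 1 (100%), `NGAG` gives 2/3 (67%).
#'
#' @inheritParams expand_iupac
#' @return Fraction in `[0, 1]`.
#' @export
pam_gc_content <- function(pattern) {
  p <- as_pam(pattern)
  w <- vapply(strsplit(unclass(p), "")[[1]], .gc_weight, numeric(1))
  w <- w[!is.na(w)]
  if (length(w) == 0L) {
    stop(sprintf("GC content of all-N pattern '%s' is undefined", unclass(p)))
  }
  mean(w)
}

#' Create a Cas enzyme
#'
#' @param name Unique enzyme identifier (e.g. `"SpCas9"`).
#' @param cas_type `"Cas9"` or `"Cas12a"`.
#' @param pams List/vector of PAM patterns the enzyme recognises.
#' @param ranking_pams Subset of `pams` used when ranking segments. Defaults
#'   to all of `pams`; xCas9 is the documented exception — its GAA/GAT sites
#'   are a subset of its NG sites, so only NG is counted for ranking.
#' @param orientation Passed to [pam_pattern()] for patterns given as strings.
#' @return A `cas_enzyme` object.
#' @export
cas_enzyme <- function(name, cas_type = c("Cas9", "Cas12a"), pams,
                       ranking_pams = pams,
                       orientation = if (match.arg(cas_type) == "Cas12a")
                         "upstream" else "downstream") {
  cas_type <- match.arg(cas_type)
  if (length(pams) == 0L) stop("a Cas enzyme needs at least one PAM")
  pams <- lapply(pams, function(p)
    if (inherits(p, "pam_pattern")) p else pam_pattern(p, orientation))
  ranking_pams <- lapply(ranking_pams, function(p)
    if (inherits(p, "pam_pattern")) p else pam_pattern(p, orientation))
  pam_str <- vapply(pams, unclass, character(1))
  rank_str <- vapply(ranking_pams, unclass, character(1))
  if (!all(rank_str %in% pam_str)) {
    stop(sprintf("ranking PAMs of %s must be a subset of its PAMs", name))
  }
  structure(
    list(name = name, cas_type = cas_type, pams = pams,
         ranking_pams = ranking_pams, overall_gc = .pooled_gc(pams)),
    class = "cas_enzyme")
}

# Pooled GC over all PAMs of one enzyme: sum of GC weights over all non-N
# positions of all patterns / total non-N positions.
.pooled_gc <- function(pams) {
  w <- unlist(lapply(pams, function(p)
    vapply(strsplit(unclass(p), "")[[1]], .gc_weight, numeric(1))))
  w <- w[!is.na(w)]
  if (length(w) == 0L) stop("all PAMs are all-N; overall GC undefined")
  mean(w)
}

#' Overall GC content of a Cas enzyme
#'
#' GC weights are pooled over the non-N positions of *all* the enzyme's PAMs
#' (not averaged per PAM), so a Cas with PAMs `{NGG, NAA}` has GC
#' `(2 + 0) / (2 + 2) = 0.5`.
#'
#' @param cas A [cas_enzyme()].
#' @return Fraction in `[0, 1]`.
#' @export
cas_overall_gc <- function(cas) {
  stopifnot(inherits(cas, "cas_enzyme"))
  .pooled_gc(cas$pams)
}

#' @export
print.cas_enzyme <- function(x, ...) {
  cat(sprintf("%s (%s): PAMs %s; ranking %s; GC %.0f%%\n", x$name, x$cas_type,
              paste(vapply(x$pams, unclass, character(1)), collapse = ","),
              paste(vapply(x$ranking_pams, unclass, character(1)),
                    collapse = ","),
              100 * x$overall_gc))
  invisible(x)
}

#' Build a Cas registry
#'
#' @param enzymes List of [cas_enzyme()] objects with unique names.
#' @return A `cas_registry`: list with `enzymes` and the deduplicated
#'   `unique_pams` character vector across all enzymes.
#' @export
cas_registry <- function(enzymes) {
  stopifnot(all(vapply(enzymes, inherits, logical(1), "cas_enzyme")))
  nm <- vapply(enzymes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate enzyme names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(enzymes) <- nm
  upams <- sort(unique(unlist(lapply(enzymes, function(e)
    vapply(e$pams, unclass, character(1))))))
  structure(list(enzymes = enzymes, unique_pams = upams),
            class = "cas_registry")
}

#' @export
print.cas_registry <- function(x, ...) {
  tp <- table(vapply(x$enzymes, `[[`, character(1), "cas_type"))
  cat(sprintf("Cas registry: %d enzymes (%s), %d unique PAM patterns\n",
              length(x$enzymes),
              paste(sprintf("%d %s", tp, names(tp)), collapse = ", "),
              length(x$unique_pams)))
  invisible(x)
}

#' Read a Cas/PAM registry from a TSV file
#'
#' Expected columns: `name`, `cas_type`, `pams` (comma-separated),
#' `ranking_pams` (comma-separated; empty means all PAMs). Lines starting
#' with `#` are comments. The shipped default registry
#' (`system.file("extdata", "cas_pam_registry.tsv", package = "crisprable")`)
#' is a curation of 21 enzymes (16 Cas9, 5 Cas12a) from the primary
#' literature; edit or replace it to analyse other enzyme panels.
#'
#' @param path TSV file path.
#' @return A [cas_registry()].
#' @export
read_cas_registry <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "cas_type", "pams", "ranking_pams")
  if (!all(need %in% names(tab))) {
    stop("registry file must have columns: ", paste(need, collapse = ", "))
  }
  split_pams <- function(s) {
    s <- trimws(strsplit(s, ",")[[1]])
    s[nzchar(s)]
  }
  enzymes <- lapply(seq_len(nrow(tab)), function(i) {
    pams <- split_pams(tab$pams[i])
    rk <- split_pams(tab$ranking_pams[i])
    if (length(rk) == 0L) rk <- pams
    cas_enzyme(tab$name[i], tab$cas_type[i], pams, rk)
  })
  cas_registry(enzymes)
}

#' The curated default Cas/PAM registry
#'
#' @return A [cas_registry()] of 21 Cas enzymes (16 Cas9, 5 Cas12a).
#' @export
default_cas_registry <- function() {
  read_cas_registry(system.file("extdata", "cas_pam_registry.tsv",
                                package = "crisprable", mustWork = TRUE))
}
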