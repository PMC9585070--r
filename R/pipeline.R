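#' Full CRISPRable-landscape workflow for one genome
#'
#' Runs the segment pipeline end to end: concatenate the requested
#' chromosomes, cut into `n_segments`, count every registry PAM and enzyme
#' per segment on both strands, select top-k enriched region sets, and
#' compare each PAM's top segments with the top GC-rich segments. On the
#' GRCh37 autosomes with 20,000 segments and k = 2000 this is the full-scale
#' analysis; on a synthetic genome it runs in seconds.
#'
#' @param fasta FASTA path or `DNAStringSet`.
#' @param registry A [cas_registry()]; default the shipped 21-enzyme table.
#' @param chromosomes Ordered chromosome list (`NULL` = all, file order).
#' @param n_segments Segment count (20,000 for the human autosomes).
#' @param k Region-set size; default 10% of eligible segments.
#' @param strands Passed to the counting operations.
#' @return List: `genome`, `segments`, `counts` (segment x PAM/Cas matrix),
#'   `gc_top` (GC-rich region set), `pam_top` / `cas_top` (named lists of
#'   region sets), `gc_overlap` (per-PAM overlap/non-overlap with `gc_top`).
#' @export
cas_landscape <- function(fasta, registry = default_cas_registry(),
                          chromosomes = NULL, n_segments = 20000L, k = NULL,
                          strands = "both") {
  genome <- if (inherits(fasta, "genome_concat")) fasta else
    concatenate_autosomes(fasta, chromosomes)
  segments <- segment_genome(genome, n_segments)
  counts <- registry_segment_counts(segments, registry, strands)
  gc <- ifelse(segments$all_n, NA_real_, segments$gc_adjusted)
  gc_top <- top_k_segments(gc, k, label = "GC-rich")
  pam_top <- lapply(registry$unique_pams, function(p)
    top_k_segments(counts[[p]], k, label = p))
  names(pam_top) <- registry$unique_pams
  cas_top <- lapply(names(registry$enzymes), function(e)
    top_k_segments(counts[[e]], k, label = e))
  names(cas_top) <- names(registry$enzymes)
  gc_overlap <- data.frame(
    pam = registry$unique_pams,
    gc_content = vapply(registry$unique_pams,
                        function(p) pam_gc_content(p), numeric(1)),
    overlap = NA_integer_, non_overlap = NA_integer_, row.names = NULL)
  for (i in seq_len(nrow(gc_overlap))) {
    ov <- gc_overlap_analysis(pam_top[[gc_overlap$pam[i]]], gc_top)
    gc_overlap$overlap[i] <- ov$overlap
    gc_overlap$non_overlap[i] <- ov$non_overlap
  }
  list(genome = genome, segments = segments, counts = counts,
       gc_top = gc_top, pam_top = pam_top, cas_top = cas_top,
       gc_overlap = gc_overlap)
}
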