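# Independent brute-force oracles and small shared fixtures.

# IUPAC code -> regex character class (independent of the package's tables)
oracle_class <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                  S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                  N = "[ACGT]")

oracle_regex <- function(pattern) {
  paste0(oracle_class[strsplit(toupper(pattern), "")[[1]]], collapse = "")
}

# overlapping forward-strand matches, 0-based offsets; windows with N never
# match because the classes only contain ACGT
oracle_forward_hits <- function(sequence, pattern) {
  m <- gregexpr(paste0("(?=", oracle_regex(pattern), ")"), sequence,
                perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# reverse complement of a concrete sequence, done with the oracle's own map
oracle_revcomp_seq <- function(sequence) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(sequence, "")[[1]]]), collapse = "")
}

# both-strand hits: reverse hits found by scanning the reverse-complemented
# sequence with the forward pattern, then mapping offsets back
oracle_match_positions <- function(sequence, pattern) {
  sequence <- toupper(sequence)
  w <- nchar(pattern)
  fwd <- oracle_forward_hits(sequence, pattern)
  rc_hits <- oracle_forward_hits(oracle_revcomp_seq(sequence), pattern)
  rev <- nchar(sequence) - rc_hits - w
  off <- c(fwd, rev)
  str <- c(rep("+", length(fwd)), rep("-", length(rev)))
  o <- order(off, str)
  data.frame(offset = off[o], strand = str[o], stringsAsFactors = FALSE)
}

# two-sided Fisher exact p by full hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by hand
oracle_bh_flags <- function(p, q) {
  n <- length(p)
  o <- order(p)
  below <- p[o] <= q * seq_len(n) / n
  kmax <- if (any(below)) max(which(below)) else 0L
  flags <- logical(n)
  if (kmax > 0) flags[o[seq_len(kmax)]] <- TRUE
  flags
}

# small genome with a GC-rich block, an all-N stretch and planted NGG sites
tiny_genome_spec <- function(seed = 101L) {
  genome_spec(
    c(cA = 30000L, cB = 20000L),
    default_gc = 0.40,
    gc_blocks = data.frame(chrom = "cA", start = 1, end = 10000, gc = 0.75),
    n_runs = data.frame(chrom = "cB", start = 15001, end = 20000),
    motifs = data.frame(chrom = "cA", start = 20001, end = 25000,
                        motif = "TGGTGGAGG", count = 120),
    seed = seed)
}

tiny_segments <- function(n_segments = 10L, seed = 101L) {
  g <- concatenate_autosomes(generate_genome(tiny_genome_spec(seed)))
  segment_genome(g, n_segments)
}

random_dna <- function(len, n_prob = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)), collapse = "")
}
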