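# per-session caches for the motif scanner: DNAString pattern objects and
# reverse-complement strings are reused across millions of segment scans
.pkg_cache <- new.env(parent = emptyenv())

.dna_cache <- function(pattern) {
  key <- paste0("dna:", pattern)
  val <- .pkg_cache[[key]]
  if (is.null(val)) {
    val <- Biostrings::DNAString(pattern)
    assign(key, val, envir = .pkg_cache)
  }
  val
}

.revcomp_cached <- function(pattern) {
  key <- paste0("rc:", pattern)
  val <- .pkg_cache[[key]]
  if (is.null(val)) {
    val <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pattern)))
    assign(key, val, envir = .pkg_cache)
  }
  val
}

# delimited reader that also handles gzipped files
read_table_any <- function(path, header = TRUE) {
  if (grepl("\\.gz$", path)) {
    data.table::as.data.table(
      utils::read.delim(gzfile(path), header = header, check.names = FALSE,
                        stringsAsFactors = FALSE))
  } else {
    data.table::fread(path, header = header)
  }
}
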