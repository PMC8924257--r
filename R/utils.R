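# 0-based half-open substring; end exclusive; vectorised over start/end
.subseq0 <- function(seq, start, end) substring(seq, start + 1L, end)

.check_dna <- function(s, what = "sequence") {
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L)
    stop(sprintf("illegal character '%s' in %s at position %d",
                 substr(s, bad, bad), what, bad), call. = FALSE)
  invisible(s)
}

# Hamming distance between equal-length strings
.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# extract a window of given length from a contig, wrapping around the origin
# when the contig is circular; start may be negative or end may exceed the
# contig length only in circular mode (callers check the linear case)
.extract_window <- function(g, start, len) {
  L <- nchar(g$seq)
  idx <- ((seq.int(start, length.out = len)) %% L) + 1L
  chars <- strsplit(g$seq, "", fixed = TRUE)[[1]]
  paste0(chars[idx], collapse = "")
}
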