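# Genome-wide approximate matching of an N20 spacer.
#
# A 20-mer window is an off-target hit when its Hamming distance to the
# spacer, read on the window's strand, is strictly below the
# mismatch-exclusion threshold (default 2, i.e. 0 or 1 mismatches), and the
# window is not the on-target locus itself (same contig, start and strand
# as the spacer's source site). Substitution-only distance: no bulges or
# gaps. An N in a genomic window always counts as a mismatch (spacers never
# contain N). Scanning is linear on every contig, including contigs flagged
# circular.

# mismatch counts of `pat` (raw vector, length w) against every w-window of
# `bs` (raw vector); returns integer vector of length length(bs) - w + 1
.window_mismatches <- function(bs, pat) {
  w <- length(pat)
  nwin <- length(bs) - w + 1L
  if (nwin < 1L) return(integer())
  m <- integer(nwin)
  for (k in seq_len(w))
    m <- m + (bs[seq.int(k, length.out = nwin)] != pat[k])
  m
}

.n20_seq <- function(n20) {
  if (inherits(n20, "n20")) n20$seq else toupper(as.character(n20))
}

.n20_site <- function(n20) if (inherits(n20, "n20")) n20$site else NULL

# PAM presence immediately 3' of a 20-mer window, on the window's strand.
# `starts` are 0-based forward starts of the windows.
.has_pam_3prime <- function(bs, starts, strand) {
  G <- as.raw(71L); C <- as.raw(67L)
  L <- length(bs)
  if (strand == "+") {
    ok <- starts + 23L <= L
    ok[ok] <- bs[starts[ok] + 22L] == G & bs[starts[ok] + 23L] == G
  } else {
    ok <- starts - 3L >= 0L
    ok[ok] <- bs[starts[ok] - 2L] == C & bs[starts[ok] - 1L] == C
  }
  ok
}

#' Count genome-wide off-targets of a spacer
#'
#' Scans every 20-mer window on both strands of every contig and counts
#' windows within Hamming distance `threshold - 1` of the spacer
#' ("deviating by fewer than `threshold` bases"). When the spacer carries
#' its source site (an [extract_n20] result), the on-target window itself
#' is excluded by coordinates; windows merely overlapping it still count.
#'
#' @param genomes A [genome_seq] or list of them.
#' @param n20 An `n20` object or a plain 20-base string (no on-target
#'   exclusion in the latter case).
#' @param threshold Mismatch-exclusion boundary; a window is a hit when its
#'   distance is strictly less than this (default 2).
#' @param require_pam If `TRUE`, a hit must additionally have an NGG
#'   triplet immediately 3' of the window on its strand. Default `FALSE`,
#'   reproducing a plain fuzzy subsequence search.
#' @return An object of class `guide_candidate`: a list with `n20`, `site`,
#'   `offtarget_count` and `hits` (data frame with columns `contig`,
#'   `start`, `strand`, `mismatches`, `seq`, where `seq` is the window read
#'   on its own strand).
#' @export
count_offtargets <- function(genomes, n20, threshold = 2L,
                             require_pam = FALSE) {
  stopifnot(threshold >= 1L)
  genomes <- .as_genome_list(genomes)
  seq <- .n20_seq(n20)
  if (nchar(seq) != 20L) stop("spacer must be 20 bases", call. = FALSE)
  .check_dna(seq, "spacer")
  if (grepl("N", seq, fixed = TRUE))
    stop("spacer contains N", call. = FALSE)
  site <- .n20_site(n20)

  pat_f <- charToRaw(seq)
  pat_r <- charToRaw(reverse_complement(seq))
  hits <- list()
  for (g in genomes) {
    bs <- charToRaw(g$seq)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_f else pat_r
      m <- .window_mismatches(bs, pat)
      keep <- which(m < threshold)
      if (!length(keep)) next
      starts <- keep - 1L               # 0-based forward window starts
      if (require_pam) {
        ok <- .has_pam_3prime(bs, starts, strand)
        starts <- starts[ok]
        keep <- keep[ok]
      }
      if (!length(keep)) next
      wseq <- .subseq0(g$seq, starts, starts + 20L)
      if (strand == "-") wseq <- reverse_complement(wseq)
      hits[[length(hits) + 1L]] <-
        data.frame(contig = g$name, start = starts, strand = strand,
                   mismatches = m[keep], seq = wseq,
                   stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(contig = character(), start = integer(),
               strand = character(), mismatches = integer(),
               seq = character(), stringsAsFactors = FALSE)
  if (!is.null(site) && nrow(hits)) {
    on_target <- hits$contig == site$contig &
      hits$start == site$proto_start & hits$strand == site$strand
    hits <- hits[!on_target, , drop = FALSE]
  }
  hits <- hits[order(hits$contig, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(n20 = if (inherits(n20, "n20")) n20 else
                   structure(list(seq = seq, site = NULL), class = "n20"),
                 site = site,
                 offtarget_count = nrow(hits),
                 hits = hits),
            class = "guide_candidate")
}

#' @export
print.guide_candidate <- function(x, ...) {
  loc <- if (is.null(x$site)) "unanchored" else
    sprintf("%s:%d %s", x$site$contig, x$site$pam_start, x$site$strand)
  cat(sprintf("<guide_candidate> %s (%s): %d off-target(s)\n",
              x$n20$seq, loc, x$offtarget_count))
  invisible(x)
}

#' Brute-force off-target enumeration (test oracle)
#'
#' Naive O(L * 20) scan implementing the hit definition literally: every
#' window on each strand is extracted as a string (reverse-complemented for
#' the minus strand), compared character by character against the spacer,
#' and the 3-prime PAM triplet is read definitionally on the window's
#' strand. Guarded to genomes of total length <= 1 Mb; intended as ground
#' truth for the production scanner, not for routine use.
#'
#' @inheritParams count_offtargets
#' @return A data frame of hits with the same columns as the `hits` field
#'   of [count_offtargets].
#' @export
brute_force_offtargets <- function(genomes, n20, threshold = 2L,
                                   require_pam = FALSE) {
  genomes <- .as_genome_list(genomes)
  total <- sum(vapply(genomes, function(g) nchar(g$seq), 0))
  if (total > 1e6)
    stop("brute-force oracle is guarded to genomes <= 1 Mb", call. = FALSE)
  seq <- .n20_seq(n20)
  site <- .n20_site(n20)
  pat <- strsplit(seq, "", fixed = TRUE)[[1]]
  rows <- list()
  for (g in genomes) {
    L <- nchar(g$seq)
    if (L < 20L) next
    chars <- strsplit(g$seq, "", fixed = TRUE)[[1]]
    for (s in 0:(L - 20L)) {
      win_f <- chars[(s + 1L):(s + 20L)]
      for (strand in c("+", "-")) {
        win <- if (strand == "+") paste0(win_f, collapse = "") else
          reverse_complement(paste0(win_f, collapse = ""))
        d <- sum(strsplit(win, "", fixed = TRUE)[[1]] != pat)
        if (d >= threshold) next
        if (!is.null(site) && g$name == site$contig &&
            s == site$proto_start && strand == site$strand) next
        if (require_pam) {
          pam <- if (strand == "+") {
            if (s + 23L > L) "" else .subseq0(g$seq, s + 20L, s + 23L)
          } else {
            if (s - 3L < 0L) "" else
              reverse_complement(.subseq0(g$seq, s - 3L, s))
          }
          if (!grepl("^.GG$", pam)) next
        }
        rows[[length(rows) + 1L]] <-
          data.frame(contig = g$name, start = s, strand = strand,
                     mismatches = d, seq = win, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(),
               strand = character(), mismatches = integer(),
               seq = character(), stringsAsFactors = FALSE)
  hits <- hits[order(hits$contig, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write an off-target hit report to TSV
#'
#' @param candidate A `guide_candidate` from [count_offtargets].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(candidate, path) {
  stopifnot(inherits(candidate, "guide_candidate"))
  utils::write.table(candidate$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
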