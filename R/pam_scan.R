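# NGG PAM discovery on both strands and N20 protospacer extraction.
#
# Strand conventions (forward coordinates are always genome coordinates):
#   + strand site: PAM triplet at [pam_start, pam_start+3), reads N-G-G on
#     the forward strand; the 20-base protospacer occupies
#     [pam_start-20, pam_start), immediately 5' of the PAM.
#   - strand site: the forward triplet at [pam_start, pam_start+3) reads
#     C-C-N, so its reverse complement (the minus strand read 5'->3') is
#     N-G-G; the protospacer occupies [pam_start+3, pam_start+23), which on
#     the minus strand is immediately 5' of the PAM.

#' Window around a desired edit
#'
#' Returns the 0-based half-open interval of `window` bases centered on the
#' edit (center = `pos + floor(len(ref)/2)`), clipped to the contig in
#' linear mode. Clipping produces a warning, not an error. For circular
#' contigs the interval may extend past the sequence ends; coordinates are
#' then interpreted modulo the contig length by downstream extraction.
#'
#' @param edit An [edit_spec].
#' @param genomes A [genome_seq] or list of them.
#' @param window Window size in bases (default 80, the repair-template
#'   length, so that candidate PAMs lie within reach of the template).
#' @return Integer vector `c(start, end)` (0-based half-open) with
#'   attribute `clipped` (logical).
#' @export
neighborhood <- function(edit, genomes, window = 80L) {
  stopifnot(window >= 1L)
  g <- .get_contig(genomes, edit$contig)
  L <- nchar(g$seq)
  center <- edit$pos + nchar(edit$ref) %/% 2L
  start <- center - window %/% 2L
  end <- start + as.integer(window)
  clipped <- FALSE
  if (!g$circular) {
    if (start < 0L || end > L) {
      clipped <- TRUE
      start <- max(start, 0L)
      end <- min(end, L)
      warning("window for edit '", edit$label,
              "' clipped to contig bounds [", start, ", ", end, ")",
              call. = FALSE)
    }
  }
  structure(c(start = start, end = end), clipped = clipped)
}

#' Find NGG PAM sites on both strands of a region
#'
#' Reports every position where the 3-mer starting there reads N-G-G on the
#' forward strand (`+` sites) or on the reverse strand (`-` sites; the
#' forward triplet then reads C-C-N). A site qualifies when its PAM triplet
#' lies fully inside `region`; the protospacer may extend beyond the region
#' but not beyond the contig. Sites whose 20-base protospacer would run off
#' the contig are dropped with a warning; sites whose protospacer or PAM
#' contains `N` are dropped silently (a message is emitted). Overlapping
#' sites are all reported.
#'
#' @param genome A [genome_seq].
#' @param region Integer `c(start, end)`, 0-based half-open, within the
#'   contig. Defaults to the whole contig.
#' @return A data frame of class `pam_sites` with columns `contig`,
#'   `pam_start` (0-based forward coordinate of the triplet), `strand`,
#'   `pam_seq` (triplet read 5'->3' on its own strand), `proto_start`,
#'   `proto_end` (0-based half-open forward interval of the protospacer).
#' @export
find_pam_sites <- function(genome, region = NULL) {
  stopifnot(inherits(genome, "genome_seq"))
  L <- nchar(genome$seq)
  if (is.null(region)) region <- c(start = 0L, end = L)
  start <- max(0L, as.integer(region[[1]]))
  end <- min(L, as.integer(region[[2]]))
  empty <- data.frame(contig = character(), pam_start = integer(),
                      strand = character(), pam_seq = character(),
                      proto_start = integer(), proto_end = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("pam_sites", "data.frame")
  if (end - start < 3L) return(empty)

  bs <- charToRaw(genome$seq)
  G <- as.raw(71L); C <- as.raw(67L)
  p0 <- seq.int(start, end - 3L)                 # candidate triplet starts
  plus <- p0[bs[p0 + 2L] == G & bs[p0 + 3L] == G]   # fwd N-G-G
  minus <- p0[bs[p0 + 1L] == C & bs[p0 + 2L] == C]  # fwd C-C-N => rev N-G-G

  sites <- rbind(
    if (length(plus)) data.frame(contig = genome$name, pam_start = plus,
                                 strand = "+",
                                 proto_start = plus - 20L,
                                 proto_end = plus,
                                 stringsAsFactors = FALSE),
    if (length(minus)) data.frame(contig = genome$name, pam_start = minus,
                                  strand = "-",
                                  proto_start = minus + 3L,
                                  proto_end = minus + 23L,
                                  stringsAsFactors = FALSE)
  )
  if (is.null(sites) || nrow(sites) == 0L) return(empty)

  off <- sites$proto_start < 0L | sites$proto_end > L
  if (any(off)) {
    warning(sum(off), " PAM site(s) dropped: protospacer outside contig '",
            genome$name, "'", call. = FALSE)
    sites <- sites[!off, , drop = FALSE]
  }
  if (nrow(sites)) {
    pam_fwd <- .subseq0(genome$seq, sites$pam_start, sites$pam_start + 3L)
    proto_fwd <- .subseq0(genome$seq, sites$proto_start, sites$proto_end)
    hasN <- grepl("N", pam_fwd, fixed = TRUE) |
      grepl("N", proto_fwd, fixed = TRUE)
    if (any(hasN)) {
      message(sum(hasN), " PAM site(s) dropped: N in PAM or protospacer")
      sites <- sites[!hasN, , drop = FALSE]
      pam_fwd <- pam_fwd[!hasN]
    }
    sites$pam_seq <- ifelse(sites$strand == "+", pam_fwd,
                            reverse_complement(pam_fwd))
  } else {
    sites$pam_seq <- character()
  }
  sites <- sites[!duplicated(sites[c("strand", "pam_start")]), , drop = FALSE]
  sites <- sites[order(sites$pam_start, sites$strand), ,
                 drop = FALSE]
  sites <- sites[, c("contig", "pam_start", "strand", "pam_seq",
                     "proto_start", "proto_end")]
  rownames(sites) <- NULL
  class(sites) <- c("pam_sites", "data.frame")
  sites
}

#' Extract the N20 spacer sequence of a PAM site
#'
#' The spacer is written 5'->3' on the protospacer (non-target) strand:
#' the literal forward subsequence for `+` sites, its reverse complement
#' for `-` sites. This matches universal gRNA design practice (the spacer
#' is homologous to the strand complementary to the one Cas9 unwinds).
#'
#' @param genome A [genome_seq].
#' @param site One row of a `pam_sites` data frame (or an equivalent list
#'   with fields `contig`, `pam_start`, `strand`, `proto_start`,
#'   `proto_end`).
#' @return An object of class `n20` with fields `seq` (20-base string) and
#'   `site` (the originating PAM site as a list).
#' @export
extract_n20 <- function(genome, site) {
  site <- as.list(site)
  L <- nchar(genome$seq)
  if (site$proto_start < 0L || site$proto_end > L)
    stop("protospacer interval [", site$proto_start, ", ", site$proto_end,
         ") outside contig '", genome$name, "'", call. = FALSE)
  if (site$proto_end - site$proto_start != 20L)
    stop("protospacer interval must have length 20", call. = FALSE)
  fwd <- .subseq0(genome$seq, site$proto_start, site$proto_end)
  if (grepl("N", fwd, fixed = TRUE))
    stop("protospacer at ", genome$name, ":", site$proto_start + 1L,
         " contains N", call. = FALSE)
  seq <- if (site$strand == "+") fwd else reverse_complement(fwd)
  structure(list(seq = seq, site = site), class = "n20")
}

#' @export
print.n20 <- function(x, ...) {
  cat(sprintf("<n20> %s (%s:%d %s)\n", x$seq, x$site$contig,
              x$site$pam_start, x$site$strand))
  invisible(x)
}
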