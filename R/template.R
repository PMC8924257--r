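# Construction of the single-stranded homology repair oligo, in-silico
# recombineering, and the Cas9 counter-selection escape check.
#
# The template spans the same centered window as the PAM neighborhood
# (default 80 bases) so that "window size == template size" holds
# structurally. Templates are written on the forward strand. On circular
# contigs the interval may wrap the origin; its `start`/`end` fields then
# satisfy end = start + length with end > contig length, and genomic
# positions inside it are taken modulo the contig length.

.template_positions <- function(template, L) {
  (seq.int(template$start, template$end - 1L) %% L)
}

#' Build a repair template carrying a desired edit
#'
#' Constructs the `length`-base homology oligo centered on the edit (same
#' centering rule as [neighborhood]), with the alternate allele substituted
#' for the reference. In linear mode the window must fit the contig; on
#' circular contigs it wraps the origin.
#'
#' @param genome A [genome_seq].
#' @param edit An [edit_spec] (validated against `genome`).
#' @param length Template length in bases (default 80).
#' @return An object of class `repair_template` with fields `seq`,
#'   `contig`, `start`, `end` (0-based half-open; `end` may exceed the
#'   contig length when wrapping), `strand` (always `"+"`), and
#'   `edits_applied`, a data frame with one row per changed base: `pos`
#'   (genomic, 0-based), `ref`, `alt`, `reason` (`"desired"` or
#'   `"pam_escape"`).
#' @export
build_template <- function(genome, edit, length = 80L) {
  stopifnot(inherits(genome, "genome_seq"), inherits(edit, "edit_spec"))
  validate_edit(edit, genome)
  length <- as.integer(length)
  L <- nchar(genome$seq)
  center <- edit$pos + nchar(edit$ref) %/% 2L
  start <- center - length %/% 2L
  end <- start + length
  if (!genome$circular && (start < 0L || end > L)) {
    pad <- max(-start, end - L, 0L)
    stop("template window [", start, ", ", end, ") for edit '", edit$label,
         "' does not fit linear contig '", genome$name, "' (", pad,
         " base(s) of padding required); shorten the template or mark the ",
         "contig circular", call. = FALSE)
  }
  if (genome$circular) start <- ((start %% L) + L) %% L
  end <- start + length
  seq <- .extract_window(genome, start, length)

  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  gpos <- .template_positions(list(start = start, end = end), L)
  erange <- seq.int(edit$pos, length.out = nchar(edit$ref))
  idx <- match(erange, gpos)
  if (anyNA(idx))
    stop("edit '", edit$label, "' not fully inside template window",
         call. = FALSE)
  refc <- strsplit(edit$ref, "", fixed = TRUE)[[1]]
  altc <- strsplit(edit$alt, "", fixed = TRUE)[[1]]
  changed <- which(refc != altc)
  chars[idx[changed]] <- altc[changed]
  edits <- data.frame(pos = erange[changed], ref = refc[changed],
                      alt = altc[changed], reason = "desired",
                      stringsAsFactors = FALSE)
  structure(list(seq = paste0(chars, collapse = ""),
                 contig = genome$name, start = start, end = end,
                 strand = "+", edits_applied = edits),
            class = "repair_template")
}

#' @export
print.repair_template <- function(x, ...) {
  cat(sprintf("<repair_template> %s:[%d, %d) %s, %d base(s), %d edit(s)\n",
              x$contig, x$start, x$end, x$strand, nchar(x$seq),
              nrow(x$edits_applied)))
  for (i in seq_len(nrow(x$edits_applied)))
    cat(sprintf("  %d %s>%s (%s)\n", x$edits_applied$pos[i] + 1L,
                x$edits_applied$ref[i], x$edits_applied$alt[i],
                x$edits_applied$reason[i]))
  invisible(x)
}

#' Recombine a template into the genome in silico
#'
#' Models perfect homologous replacement: returns a genome copy whose
#' subsequence over the template interval equals the template sequence.
#' The genome must agree with the template everywhere except at the
#' recorded edit positions (where it must carry the recorded reference
#' bases); anything else is an interval mismatch error.
#'
#' @param genome A [genome_seq].
#' @param template A `repair_template`.
#' @return A new [genome_seq] carrying the template's edits.
#' @export
apply_template <- function(genome, template) {
  stopifnot(inherits(genome, "genome_seq"),
            inherits(template, "repair_template"))
  if (genome$name != template$contig)
    stop("template targets contig '", template$contig, "', not '",
         genome$name, "'", call. = FALSE)
  L <- nchar(genome$seq)
  len <- template$end - template$start
  if (!genome$circular && template$end > L)
    stop("template interval outside linear contig", call. = FALSE)
  gpos <- .template_positions(template, L)
  chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  tchars <- strsplit(template$seq, "", fixed = TRUE)[[1]]
  diff <- which(chars[gpos + 1L] != tchars)
  recorded <- match(template$edits_applied$pos, gpos)
  if (!setequal(diff, recorded) ||
      !all(chars[gpos[recorded] + 1L] == template$edits_applied$ref))
    stop("interval mismatch: genome and template disagree outside the ",
         "recorded edits", call. = FALSE)
  chars[gpos + 1L] <- tchars
  genome_seq(genome$name, paste0(chars, collapse = ""), genome$circular)
}

# protospacer + PAM of a site, read from a (possibly recombined) genome
.read_site <- function(genome, site) {
  L <- nchar(genome$seq)
  proto_fwd <- .subseq0(genome$seq, site$proto_start, site$proto_end)
  pam_fwd <- .subseq0(genome$seq, site$pam_start, site$pam_start + 3L)
  if (site$strand == "+")
    list(proto = proto_fwd, pam = pam_fwd)
  else
    list(proto = reverse_complement(proto_fwd),
         pam = reverse_complement(pam_fwd))
}

.is_ngg <- function(pam) nchar(pam) == 3L && substr(pam, 2L, 3L) == "GG"

# TRUE when the guide can still cleave its locus in `genome`
.cleavable <- function(genome, guide, escape_min_mismatches = 1L) {
  site <- guide$site
  at <- .read_site(genome, site)
  .hamming(at$proto, guide$n20$seq) < escape_min_mismatches &&
    .is_ngg(at$pam)
}

#' Guarantee the recombined genome escapes Cas9 counter-selection
#'
#' After perfect incorporation of the template, the guide must no longer
#' find a cleavable locus (perfect protospacer match plus NGG PAM) at the
#' target site; otherwise Cas9 would kill the successfully edited cell. If
#' the desired edit already disrupts the protospacer or the PAM, the
#' template is returned unchanged. Otherwise one additional synonymous-
#' where-possible mutation is introduced at one of the PAM's two G
#' positions (preferring the second G, i.e. PAM position 3, G to A),
#' destroying the NGG motif.
#'
#' @param genome A [genome_seq] (reference, pre-edit).
#' @param template A `repair_template` from [build_template].
#' @param guide A `guide_candidate` from [count_offtargets] whose site
#'   overlaps the template interval.
#' @param escape_min_mismatches Number of protospacer mismatches considered
#'   sufficient to escape cleavage (default 1: only a perfect match is
#'   cleavable). Raise for a seed-region safety margin.
#' @param cds Optional data frame of coding regions (columns `contig`,
#'   `start`, `end` 0-based half-open, `strand`), e.g. from
#'   [read_cds_gff]; when supplied, a synonymous PAM substitution is
#'   preferred.
#' @return The template, possibly with one `pam_escape` row appended to
#'   `edits_applied`.
#' @export
ensure_cas9_escape <- function(genome, template, guide,
                               escape_min_mismatches = 1L, cds = NULL) {
  stopifnot(inherits(template, "repair_template"),
            inherits(guide, "guide_candidate"))
  site <- guide$site
  if (is.null(site))
    stop("guide has no source site; score it with count_offtargets on an ",
         "extract_n20 result", call. = FALSE)
  L <- nchar(genome$seq)
  gpos <- .template_positions(template, L)
  span <- c(seq.int(site$proto_start, site$proto_end - 1L),
            seq.int(site$pam_start, site$pam_start + 2L))
  if (!any(span %in% gpos))
    stop("guide's protospacer and PAM do not overlap the template ",
         "interval; escape is impossible within this template",
         call. = FALSE)
  recombined <- apply_template(genome, template)
  if (!.cleavable(recombined, guide, escape_min_mismatches))
    return(template)

  # locus still cleavable: mutate a PAM G inside the template
  pam_g <- if (site$strand == "+")
    c(site$pam_start + 2L, site$pam_start + 1L)   # PAM pos 3, then pos 2
  else
    c(site$pam_start, site$pam_start + 1L)
  pam_g <- pam_g[pam_g %in% gpos]
  pam_g <- pam_g[!(pam_g %in% template$edits_applied$pos)]
  if (!length(pam_g))
    stop("PAM G positions not covered by the template; use a longer ",
         "template or a different guide", call. = FALSE)
  g <- pam_g[1L]
  tidx <- match(g, gpos)
  chars <- strsplit(template$seq, "", fixed = TRUE)[[1]]
  ref_base <- chars[tidx]
  new_base <- .escape_base(recombined, g, site$strand, cds)
  chars[tidx] <- new_base
  template$seq <- paste0(chars, collapse = "")
  template$edits_applied <- rbind(
    template$edits_applied,
    data.frame(pos = g, ref = ref_base, alt = new_base,
               reason = "pam_escape", stringsAsFactors = FALSE))
  # the mutated PAM must no longer read NGG
  stopifnot(!.cleavable(apply_template(genome, template), guide,
                        escape_min_mismatches))
  template
}

# choose the replacement base (forward strand) for the PAM G at genomic
# position g: non-G on the PAM strand; synonymous under the standard code
# when a covering CDS is supplied; fallback G->A on the PAM strand
.escape_base <- function(genome, g, pam_strand, cds = NULL) {
  # candidates on the PAM strand, in preference order
  cand_pam <- c("A", "T", "C")
  to_fwd <- function(b) if (pam_strand == "+") b else
    chartr("ACGT", "TGCA", b)
  if (!is.null(cds)) {
    row <- cds[cds$contig == genome$name & cds$start <= g & g < cds$end, ,
               drop = FALSE]
    if (nrow(row) >= 1L) {
      row <- row[1L, ]
      for (b in cand_pam) {
        fb <- to_fwd(b)
        if (.is_synonymous(genome, row, g, fb)) return(fb)
      }
    }
  }
  to_fwd("A")
}

# does replacing forward base at genomic pos g by fwd_base leave the codon's
# amino acid unchanged, for a CDS row (0-based half-open, phase 0)?
.is_synonymous <- function(genome, cds_row, g, fwd_base) {
  code <- Biostrings::GENETIC_CODE
  if (cds_row$strand == "+") {
    off <- g - cds_row$start
    c0 <- cds_row$start + 3L * (off %/% 3L)
    codon <- .subseq0(genome$seq, c0, c0 + 3L)
    mut <- codon
    substr(mut, off %% 3L + 1L, off %% 3L + 1L) <- fwd_base
  } else {
    off <- (cds_row$end - 1L) - g
    c0 <- cds_row$end - 3L * (off %/% 3L) - 3L
    fwd <- .subseq0(genome$seq, c0, c0 + 3L)
    mutf <- fwd
    substr(mutf, 3L - off %% 3L, 3L - off %% 3L) <- fwd_base
    codon <- reverse_complement(fwd)
    mut <- reverse_complement(mutf)
  }
  if (grepl("N", codon, fixed = TRUE) || grepl("N", mut, fixed = TRUE))
    return(FALSE)
  identical(unname(code[codon]), unname(code[mut]))
}

#' Read CDS intervals from a GFF3 file
#'
#' Extracts `CDS` features as a data frame usable by
#' [ensure_cas9_escape]'s synonymous-substitution preference. Requires the
#' rtracklayer package. Phase is assumed 0 (full codons from the CDS
#' start).
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `contig`, `start`, `end` (0-based
#'   half-open) and `strand`.
#' @export
read_cds_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stop("reading GFF input requires the rtracklayer and GenomicRanges ",
         "packages", call. = FALSE)
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
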