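# Coordinate conventions used throughout the package:
#   * internal coordinates are 0-based, half-open [start, end)
#   * user-facing edit tables (TSV) and VCF are 1-based
#   * BED output is 0-based half-open
# Sequences are stored uppercase over the alphabet {A, C, G, T, N}.

#' DNA contig with topology flag
#'
#' Container for one named DNA sequence. Sequences are uppercased on
#' construction and must contain only `A`, `C`, `G`, `T` or `N`; any other
#' character (including IUPAC ambiguity codes other than `N`) is an error.
#'
#' @param name Contig identifier (single string).
#' @param seq DNA sequence (single string, case-insensitive on input).
#' @param circular Logical topology flag. Circularity affects only window
#'   extraction near the contig ends (wraparound); scans remain linear.
#' @return An object of class `genome_seq` with fields `name`, `seq`
#'   (uppercase) and `circular`.
#' @examples
#' genome_seq("chr", "acgtACGT")
#' @export
genome_seq <- function(name, seq, circular = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(seq), length(seq) == 1L,
            is.logical(circular), length(circular) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L)
    stop("sequence for contig '", name, "' is empty", call. = FALSE)
  .check_dna(seq, sprintf("record '%s'", name))
  structure(list(name = name, seq = seq, circular = circular),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %s bp (%s)\n", x$name,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

# Accept a single genome_seq or a list of them; always return a named list.
.as_genome_list <- function(genome) {
  if (inherits(genome, "genome_seq")) genome <- list(genome)
  if (!is.list(genome) || !all(vapply(genome, inherits, TRUE, "genome_seq")))
    stop("expected a genome_seq or a list of genome_seq objects",
         call. = FALSE)
  names(genome) <- vapply(genome, `[[`, "", "name")
  genome
}

.get_contig <- function(genomes, contig) {
  genomes <- .as_genome_list(genomes)
  g <- genomes[[contig]]
  if (is.null(g))
    stop("contig '", contig, "' not found in genome (have: ",
         paste(names(genomes), collapse = ", "), ")", call. = FALSE)
  g
}

#' Read genome sequences from a FASTA file
#'
#' Parses a (possibly multi-record) FASTA file. Record names are the first
#' whitespace-delimited token of each header; sequences are uppercased and
#' validated against the `{A,C,G,T,N}` alphabet, with an error naming the
#' offending record and position otherwise.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, recycled across records; marks contigs as
#'   circular.
#' @return A list of [genome_seq] objects, named by contig.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  nms <- sub("\\s.*$", "", names(recs))
  circular <- rep_len(circular, length(recs))
  out <- vector("list", length(recs))
  for (i in seq_along(recs))
    out[[i]] <- genome_seq(nms[i], as.character(recs[[i]]), circular[i])
  names(out) <- nms
  out
}

#' Write sequences to a FASTA file
#'
#' @param genomes A [genome_seq] or list of them, or a named character
#'   vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (is.character(genomes)) {
    seqs <- genomes
  } else {
    genomes <- .as_genome_list(genomes)
    seqs <- vapply(genomes, `[[`, "", "seq")
    names(seqs) <- names(genomes)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed. `N` is its own complement. Vectorised
#' over its argument.
#'
#' @param seq Character vector of DNA strings over `{A,C,G,T,N}`
#'   (case-insensitive).
#' @return Character vector of reverse-complemented sequences (uppercase).
#' @examples
#' reverse_complement("ACGT") # "ACGT"
#' reverse_complement("CCN")  # "NGG"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  for (s in seq) .check_dna(s, "sequence")
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

#' Specify one desired point substitution
#'
#' An edit is a same-length substitution (`ref` -> `alt`) at a 0-based
#' position on a contig. Indels are not supported.
#'
#' @param contig Contig identifier.
#' @param pos 0-based index of the first edited base.
#' @param ref Reference allele (length >= 1).
#' @param alt Alternate allele, same length as `ref` and different from it.
#' @param label Free-text name for the edit.
#' @return An object of class `edit_spec`.
#' @export
edit_spec <- function(contig, pos, ref, alt, label = sprintf("%s:%d", contig, pos + 1L)) {
  ref <- toupper(ref); alt <- toupper(alt)
  .check_dna(ref, sprintf("ref allele of '%s'", label))
  .check_dna(alt, sprintf("alt allele of '%s'", label))
  if (nchar(ref) != nchar(alt) || nchar(ref) < 1L)
    stop("edit '", label, "': ref and alt must be the same non-zero length ",
         "(substitutions only)", call. = FALSE)
  if (ref == alt)
    stop("edit '", label, "': ref and alt are identical", call. = FALSE)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 0L)
    stop("edit '", label, "': pos must be a non-negative integer",
         call. = FALSE)
  structure(list(contig = contig, pos = pos, ref = ref, alt = alt,
                 label = label),
            class = "edit_spec")
}

#' @export
print.edit_spec <- function(x, ...) {
  cat(sprintf("<edit_spec> %s: %s:%d %s>%s\n", x$label, x$contig,
              x$pos + 1L, x$ref, x$alt))
  invisible(x)
}

#' Validate an edit against the loaded genome
#'
#' Checks that the genome subsequence at the edit position equals the stated
#' reference allele.
#'
#' @param edit An [edit_spec].
#' @param genomes A [genome_seq] or list of them.
#' @return `edit`, invisibly, on success; otherwise an error naming the edit
#'   and both sequences.
#' @export
validate_edit <- function(edit, genomes) {
  g <- .get_contig(genomes, edit$contig)
  end <- edit$pos + nchar(edit$ref)
  if (end > nchar(g$seq))
    stop("edit '", edit$label, "' extends past the end of contig '",
         g$name, "'", call. = FALSE)
  found <- .subseq0(g$seq, edit$pos, end)
  if (found != edit$ref)
    stop("edit '", edit$label, "': reference allele mismatch at ",
         g$name, ":", edit$pos + 1L, " (edit says '", edit$ref,
         "', genome has '", found, "')", call. = FALSE)
  invisible(edit)
}

#' Read desired edits from a TSV table or VCF
#'
#' TSV input must have header columns `contig`, `pos` (1-based), `ref`,
#' `alt`, `label`. Files ending in `.vcf` or `.vcf.gz` are read as VCF
#' (substitution records only; requires the vcfR package). Every reference
#' allele is verified against the genome before the list is returned.
#'
#' @param path Path to the edit table.
#' @param genomes A [genome_seq] or list of them, used for validation.
#' @return A list of [edit_spec] objects (positions converted to 0-based).
#' @export
read_edits <- function(path, genomes) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    edits <- .read_edits_vcf(path)
  } else {
    edits <- .read_edits_tsv(path)
  }
  for (e in edits) validate_edit(e, genomes)
  edits
}

.read_edits_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("contig", "pos", "ref", "alt", "label")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("edit table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) stop("edit table ", path, " has no rows",
                            call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    if (nchar(tab$ref[i]) != nchar(tab$alt[i]))
      stop("edit '", tab$label[i], "': substitutions only (ref '",
           tab$ref[i], "' vs alt '", tab$alt[i], "')", call. = FALSE)
    edit_spec(tab$contig[i], as.integer(tab$pos[i]) - 1L,
              tab$ref[i], tab$alt[i], tab$label[i])
  })
}

.read_edits_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("no records in VCF ", path, call. = FALSE)
  lapply(seq_len(nrow(fix)), function(i) {
    ref <- unname(fix[i, "REF"]); alt <- unname(fix[i, "ALT"])
    id <- unname(fix[i, "ID"])
    label <- if (is.na(id) || id == ".")
      sprintf("%s:%s", fix[i, "CHROM"], fix[i, "POS"]) else id
    if (grepl(",", alt))
      stop("edit '", label, "': multiallelic VCF records are unsupported",
           call. = FALSE)
    if (nchar(ref) != nchar(alt))
      stop("edit '", label, "': indels unsupported (substitutions only)",
           call. = FALSE)
    edit_spec(unname(fix[i, "CHROM"]), as.integer(fix[i, "POS"]) - 1L,
              ref, alt, label)
  })
}
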