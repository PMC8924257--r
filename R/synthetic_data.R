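# Seeded synthetic genomes with planted protospacers and ground truth.
#
# PRNG stream discipline: generate_fixture() calls set.seed(spec$seed) once
# on entry and then draws, in this fixed order: (1) random guide sequences,
# (2) background bases, (3) per-plant mutation positions/bases, placement
# starts and PAM N bases, in plant-list order, (4) sanitization re-rolls,
# (5) the planted edit's alternate base. Any change to this order is a
# breaking change for stored expectations.

#' Describe a synthetic genome fixture
#'
#' @param seed Integer seed controlling all randomness.
#' @param length Genome length in bases.
#' @param gc GC fraction of the background in `[0, 1]` (default 0.5).
#' @param guides Either the number of random 20-mer guides to draw, or a
#'   character vector of explicit guide sequences.
#' @param plants List of [plant] entries describing the copies to embed.
#' @param edit Optional planted edit: a list with `plant` (index of a
#'   `dist = 0`, `pam = TRUE`, `count = 1` plant entry), `offset` (0-based
#'   position within the protospacer, on the protospacer strand; default
#'   9), optional `alt` base and `label`.
#' @param name Contig name (default `"synthetic_1"`).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, length, gc = 0.5, guides = 1L,
                         plants = list(plant()), edit = NULL,
                         name = "synthetic_1") {
  stopifnot(length >= 30L, gc >= 0, gc <= 1)
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 gc = gc, guides = guides, plants = plants, edit = edit,
                 name = name),
            class = "fixture_spec")
}

#' One planting instruction for [fixture_spec]
#'
#' @param guide Index into the fixture's guide list (or an explicit 20-base
#'   sequence).
#' @param strand `"+"` or `"-"`.
#' @param count Number of copies to plant.
#' @param dist Hamming distance of each copy from the guide (mutations
#'   never re-create the original base).
#' @param pam Plant an NGG PAM immediately 3' of each copy on its strand
#'   (default only for `dist = 0` plants, which serve as on-target loci).
#' @param at Optional fixed 0-based forward start of the 20-mer window
#'   (requires `count = 1`); otherwise placement is random,
#'   non-overlapping.
#' @return A list of class `fixture_plant`.
#' @export
plant <- function(guide = 1L, strand = "+", count = 1L, dist = 0L,
                  pam = (dist == 0L), at = NULL) {
  stopifnot(strand %in% c("+", "-"), count >= 0L, dist >= 0L, dist <= 20L)
  if (!is.null(at)) stopifnot(count == 1L)
  structure(list(guide = guide, strand = strand, count = as.integer(count),
                 dist = as.integer(dist), pam = isTRUE(pam), at = at),
            class = "fixture_plant")
}

.random_dna <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# mutate `guide` at exactly d positions; each mutation avoids the original
# base, so the Hamming distance is exactly d
.mutate_guide <- function(guide, d) {
  chars <- strsplit(guide, "", fixed = TRUE)[[1]]
  if (d == 0L) return(guide)
  pos <- sample(length(chars), d)
  for (p in pos) {
    alts <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- alts[sample.int(3L, 1L)]
  }
  paste0(chars, collapse = "")
}

#' Generate a seeded synthetic genome with planted guide copies
#'
#' Produces i.i.d. background at the requested GC content, embeds each
#' planted copy (the guide mutated at exactly `dist` positions, with an
#' NGG PAM when requested) at non-overlapping positions, and
#' rejection-checks the background: any accidental 20-mer window within
#' Hamming distance < 2 of any guide, on either strand, that is not a
#' planted window has its background bases re-rolled until the genome is
#' clean, so ground-truth off-target counts are exact by construction.
#' Fully deterministic given `spec$seed`.
#'
#' @param spec A [fixture_spec].
#' @return An object of class `crmage_fixture`: a list with `genome` (a
#'   [genome_seq]), `guides` (character vector), `truth` (data frame of
#'   every planted window: `contig`, `start`, `strand`, `dist`, `guide`
#'   index, `pam`, `seq`), `edit` (an [edit_spec] or `NULL`) and `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  L <- spec$length

  # (1) resolve guides
  guides <- if (is.character(spec$guides)) {
    toupper(spec$guides)
  } else {
    vapply(seq_len(spec$guides), function(i)
      paste0(.random_dna(20L, 0.5), collapse = ""), "")
  }
  for (g in guides) {
    .check_dna(g, "guide")
    if (nchar(g) != 20L) stop("guides must be 20 bases", call. = FALSE)
    if (grepl("N", g, fixed = TRUE)) stop("guides must not contain N",
                                          call. = FALSE)
  }

  plant_len <- function(p) 20L + if (p$pam) 3L else 0L
  total_planted <- sum(vapply(spec$plants, function(p)
    p$count * plant_len(p), 0L))
  if (total_planted > 0.5 * L)
    stop("infeasible fixture: planted bases (", total_planted,
         ") exceed half the genome length", call. = FALSE)

  # (2) background
  chars <- .random_dna(L, spec$gc)
  planted_mask <- logical(L)   # TRUE where a base belongs to a plant

  # (3) plants
  truth <- list()
  plant_window_start <- integer(length(spec$plants))
  for (pi in seq_along(spec$plants)) {
    p <- spec$plants[[pi]]
    gidx <- if (is.character(p$guide)) {
      match(toupper(p$guide), guides)
    } else as.integer(p$guide)
    if (is.na(gidx) || gidx < 1L || gidx > length(guides))
      stop("plant ", pi, " references an unknown guide", call. = FALSE)
    guide <- guides[gidx]
    seglen <- plant_len(p)
    for (ci in seq_len(p$count)) {
      variant <- .mutate_guide(guide, p$dist)
      pam_n <- if (p$pam) .random_dna(1L, spec$gc) else character()
      seg <- if (p$strand == "+") {
        paste0(variant, if (p$pam) paste0(pam_n, "GG") else "")
      } else {
        reverse_complement(
          paste0(variant, if (p$pam) paste0(pam_n, "GG") else ""))
      }
      if (!is.null(p$at)) {
        seg_start <- if (p$strand == "+" || !p$pam) p$at else p$at - 3L
        if (seg_start < 0L || seg_start + seglen > L)
          stop("plant ", pi, " at fixed position does not fit the genome",
               call. = FALSE)
        if (any(planted_mask[(seg_start + 1L):(seg_start + seglen)]))
          stop("plant ", pi, " at fixed position overlaps another plant",
               call. = FALSE)
      } else {
        seg_start <- NULL
        for (try in seq_len(10000L)) {
          s <- sample.int(L - seglen + 1L, 1L) - 1L
          if (!any(planted_mask[(s + 1L):(s + seglen)])) {
            seg_start <- s; break
          }
        }
        if (is.null(seg_start))
          stop("could not place plant ", pi,
               " without overlap; genome too short for the requested ",
               "plants", call. = FALSE)
      }
      rng <- (seg_start + 1L):(seg_start + seglen)
      chars[rng] <- strsplit(seg, "", fixed = TRUE)[[1]]
      planted_mask[rng] <- TRUE
      win_start <- if (p$strand == "+" || !p$pam) seg_start else
        seg_start + 3L
      truth[[length(truth) + 1L]] <-
        data.frame(contig = spec$name, start = win_start,
                   strand = p$strand, dist = p$dist, guide = gidx,
                   pam = p$pam, seq = variant, stringsAsFactors = FALSE)
      if (ci == 1L) plant_window_start[pi] <- win_start
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig = character(), start = integer(),
               strand = character(), dist = integer(), guide = integer(),
               pam = logical(), seq = character(), stringsAsFactors = FALSE)

  # (4) sanitize background: no accidental window within distance < 2 of
  # any guide on either strand
  chars <- .sanitize_background(chars, planted_mask, guides, truth,
                                spec$gc)
  genome <- genome_seq(spec$name, paste0(chars, collapse = ""))

  # (5) planted edit
  edit <- NULL
  if (!is.null(spec$edit)) {
    e <- spec$edit
    pi <- e$plant
    p <- spec$plants[[pi]]
    if (p$dist != 0L || !p$pam || p$count != 1L)
      stop("fixture edit must anchor to a dist = 0, pam = TRUE, ",
           "count = 1 plant", call. = FALSE)
    offset <- if (is.null(e$offset)) 9L else as.integer(e$offset)
    stopifnot(offset >= 0L, offset < 20L)
    ws <- plant_window_start[pi]
    pos <- if (p$strand == "+") ws + offset else ws + (19L - offset)
    ref <- chars[pos + 1L]
    alt <- if (!is.null(e$alt)) toupper(e$alt) else {
      alts <- setdiff(c("A", "C", "G", "T"), ref)
      alts[sample.int(3L, 1L)]
    }
    label <- if (is.null(e$label)) sprintf("%s-edit", spec$name) else
      e$label
    edit <- edit_spec(spec$name, pos, ref, alt, label)
  }

  structure(list(genome = genome, guides = guides, truth = truth,
                 edit = edit, spec = spec),
            class = "crmage_fixture")
}

# re-roll background bases of accidental near-match windows until none
# remain; planted windows (any dist, either strand) are exempt
.sanitize_background <- function(chars, planted_mask, guides, truth, gc) {
  L <- length(chars)
  if (L < 20L) return(chars)
  for (iter in seq_len(50L)) {
    offending <- integer()
    seq <- paste0(chars, collapse = "")
    bs <- charToRaw(seq)
    for (gi in seq_along(guides)) {
      expect <- truth[truth$guide == gi & truth$dist < 2L, , drop = FALSE]
      for (strand in c("+", "-")) {
        pat <- charToRaw(if (strand == "+") guides[gi] else
          reverse_complement(guides[gi]))
        m <- .window_mismatches(bs, pat)
        s0 <- which(m < 2L) - 1L
        bad <- s0[!(s0 %in% expect$start[expect$strand == strand])]
        offending <- c(offending, bad)
      }
    }
    offending <- sort(unique(offending))
    if (!length(offending)) return(chars)
    for (s in offending) {
      idx <- (s + 1L):(s + 20L)
      bg <- idx[!planted_mask[idx]]
      if (!length(bg))
        stop("cannot sanitize: an accidental near-match window lies ",
             "entirely within planted sequence", call. = FALSE)
      chars[bg] <- .random_dna(length(bg), gc)
    }
  }
  stop("background sanitization did not converge after 50 rounds; the ",
       "requested composition is degenerate (e.g. extreme GC with a ",
       "matching guide)", call. = FALSE)
}

#' @export
print.crmage_fixture <- function(x, ...) {
  cat(sprintf("<crmage_fixture> %s: %d bp, %d guide(s), %d planted window(s)%s\n",
              x$genome$name, nchar(x$genome$seq), length(x$guides),
              nrow(x$truth),
              if (is.null(x$edit)) "" else
                sprintf(", edit '%s'", x$edit$label)))
  invisible(x)
}

#' Write a fixture's genome and ground truth to disk
#'
#' Emits `<prefix>.fasta` (the genome) and `<prefix>.truth.tsv` (one row
#' per planted window).
#'
#' @param fixture A `crmage_fixture` from [generate_fixture].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_fixture <- function(fixture, prefix) {
  stopifnot(inherits(fixture, "crmage_fixture"))
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".truth.tsv")
  write_fasta(fixture$genome, fa)
  utils::write.table(fixture$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa, tsv))
}
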