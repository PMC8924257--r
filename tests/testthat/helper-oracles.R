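# Independent oracles and small generators used across the suite.
# These re-derive expectations from definitions and never call the
# production scanners they are checking.

# definitional NGG enumerator: slide a 3-window over both strands, keep
# NGG, attach the 20-base protospacer 5' of the PAM on the PAM's strand,
# drop sites whose protospacer leaves the contig or touches an N
oracle_pam_sites <- function(genome, region = NULL) {
  s <- genome$seq
  L <- nchar(s)
  if (is.null(region)) region <- c(0L, L)
  rows <- list()
  for (p in seq.int(region[[1]], region[[2]] - 3L)) {
    if (p < 0L || p + 3L > L) next
    fwd <- substr(s, p + 1L, p + 3L)
    if (substr(fwd, 2L, 3L) == "GG") {
      ps <- p - 20L
      if (ps >= 0L) {
        proto <- substr(s, ps + 1L, p)
        if (!grepl("N", proto) && !grepl("N", fwd))
          rows[[length(rows) + 1L]] <- data.frame(
            contig = genome$name, pam_start = p, strand = "+",
            pam_seq = fwd, proto_start = ps, proto_end = p,
            stringsAsFactors = FALSE)
      }
    }
    rc <- reverse_complement(fwd)
    if (substr(rc, 2L, 3L) == "GG") {
      pe <- p + 23L
      if (pe <= L) {
        proto <- substr(s, p + 4L, pe)
        if (!grepl("N", proto) && !grepl("N", fwd))
          rows[[length(rows) + 1L]] <- data.frame(
            contig = genome$name, pam_start = p, strand = "-",
            pam_seq = rc, proto_start = p + 3L, proto_end = pe,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(), pam_start = integer(),
                      strand = character(), pam_seq = character(),
                      proto_start = integer(), proto_end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$pam_start, out$strand), ]
  rownames(out) <- NULL
  out
}

# plain random genome, independent of the package's fixture generator
random_genome <- function(seed, len, gc = 0.5, name = "rnd") {
  set.seed(seed)
  genome_seq(name, paste0(
    sample(c("A", "C", "G", "T"), len, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

# hand-built guide_candidate for ranking tests (only the fields
# rank_and_select consults)
fake_candidate <- function(count, pam_start, strand = "+",
                           contig = "c1") {
  pam_start <- as.integer(pam_start)
  structure(list(
    n20 = structure(list(seq = strrep("A", 20), site = NULL),
                    class = "n20"),
    site = list(contig = contig, pam_start = pam_start, strand = strand,
                proto_start = if (strand == "+") pam_start - 20L else
                  pam_start + 3L,
                proto_end = if (strand == "+") pam_start else
                  pam_start + 23L),
    offtarget_count = as.integer(count),
    hits = data.frame()),
    class = "guide_candidate")
}

# fixture with three distinct guides whose PAMs sit inside the 80-base
# window around a planted edit, each with a known number of planted
# 1-mismatch copies elsewhere; returns the fixture plus the truth counts
selection_fixture <- function(seed, counts = NULL) {
  set.seed(seed * 13L + 7L)
  if (is.null(counts)) counts <- sample(0:5, 3L)
  plants <- list(plant(1L, "+", 1L, 0L, pam = TRUE, at = 2000L),
                 plant(2L, "+", 1L, 0L, pam = TRUE, at = 1972L),
                 plant(3L, "+", 1L, 0L, pam = TRUE, at = 2024L))
  for (g in 1:3) if (counts[g] > 0L)
    plants[[length(plants) + 1L]] <-
      plant(g, if (g == 2L) "-" else "+", counts[g], 1L, pam = FALSE)
  fx <- generate_fixture(fixture_spec(
    seed = seed, length = 4000L, guides = 3L, plants = plants,
    edit = list(plant = 1L, offset = 9L)))
  list(fixture = fx, counts = counts)
}

# score the three planted on-target sites of a selection_fixture
planted_candidates <- function(fx, threshold = 2L) {
  on <- fx$truth[fx$truth$dist == 0L & fx$truth$pam, , drop = FALSE]
  on <- on[order(on$guide), , drop = FALSE]
  lapply(seq_len(nrow(on)), function(i) {
    site <- list(contig = on$contig[i], pam_start = on$start[i] + 20L,
                 strand = "+", pam_seq = NA_character_,
                 proto_start = on$start[i], proto_end = on$start[i] + 20L)
    count_offtargets(fx$genome, extract_n20(fx$genome, site), threshold)
  })
}

# drop S3 classes and rownames so data-frame comparisons are structural
strip_df <- function(df) {
  df <- as.data.frame(df)
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}
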