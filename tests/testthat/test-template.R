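# shared scaffold: a protospacer at [50, 70) with a TGG PAM at [70, 73)
make_locus <- function(seed = 123, pam = "TGG") {
  set.seed(seed)
  proto <- paste0(sample(c("A", "C", "T"), 20, replace = TRUE),
                  collapse = "")                      # GG-free spacer
  pad <- function(n) paste0(sample(c("A", "C", "T"), n, replace = TRUE),
                            collapse = "")            # GG/CC-free padding
  g <- genome_seq("c", paste0(pad(50), proto, pam, pad(80)))
  site <- list(contig = "c", pam_start = 70L, strand = "+",
               pam_seq = pam, proto_start = 50L, proto_end = 70L)
  guide <- count_offtargets(g, extract_n20(g, site))
  list(g = g, site = site, guide = guide, proto = proto)
}

test_that("build_template centers the window and integrates the edit", {
  g <- genome_seq("c", "AAGAA")
  tpl <- build_template(g, edit_spec("c", 2, "G", "A", "e"), length = 5)
  expect_identical(tpl$seq, "AAAAA")
  expect_identical(c(tpl$start, tpl$end), c(0L, 5L))
  expect_identical(tpl$edits_applied$reason, "desired")

  lc <- make_locus()
  tpl80 <- build_template(lc$g, edit_spec("c", 60,
                                          substr(lc$g$seq, 61, 61), "G",
                                          "mid"))
  expect_identical(nchar(tpl80$seq), 80L)
  ref_win <- substr(lc$g$seq, tpl80$start + 1L, tpl80$end)
  diffs <- which(strsplit(tpl80$seq, "")[[1]] != strsplit(ref_win, "")[[1]])
  expect_identical(diffs, 61L - tpl80$start)   # exactly one difference
})

test_that("multi-base substitutions record one row per changed base", {
  g <- genome_seq("c", "AAGTAAA")
  tpl <- build_template(g, edit_spec("c", 2, "GT", "AC", "mnv"),
                        length = 7)
  expect_identical(nrow(tpl$edits_applied), 2L)
  expect_identical(tpl$edits_applied$pos, c(2L, 3L))
  # positions where ref and alt agree are not recorded
  g2 <- genome_seq("c", "AAGAAAA")
  tpl2 <- build_template(g2, edit_spec("c", 2, "GA", "GC", "half"),
                         length = 7)
  expect_identical(tpl2$edits_applied$pos, 3L)
})

test_that("windows that leave a linear contig error with required padding", {
  g <- genome_seq("c", strrep("ACT", 40))
  expect_error(build_template(g, edit_spec("c", 2, "T", "G", "e"), 80),
               "padding required")
})

test_that("circular contigs wrap the template around the origin", {
  set.seed(9)
  seq <- paste0(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  g <- genome_seq("ori", seq, circular = TRUE)
  ref <- substr(seq, 3, 3)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  tpl <- build_template(g, edit_spec("ori", 2, ref, alt, "wrap"), 80)
  expect_identical(nchar(tpl$seq), 80L)
  expect_true(tpl$end > 100L)          # wraps the origin
  out <- apply_template(g, tpl)
  expect_identical(nchar(out$seq), 100L)
  expect_identical(substr(out$seq, 3, 3), alt)
  # only the edited base changed
  expect_identical(sum(charToRaw(out$seq) != charToRaw(seq)), 1L)
})

test_that("apply_template models perfect replacement and validates input", {
  lc <- make_locus()
  ref <- substr(lc$g$seq, 61, 61)
  edit <- edit_spec("c", 60, ref, "G", "e")
  tpl <- build_template(lc$g, edit)
  out <- apply_template(lc$g, tpl)
  expect_identical(substr(out$seq, tpl$start + 1L, tpl$end), tpl$seq)
  # the inverse edit validates against the recombined genome
  expect_silent(validate_edit(edit_spec("c", 60, "G", ref, "inv"), out))
  # a template altered outside its recorded edits is rejected
  bad <- tpl
  substr(bad$seq, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                   substr(bad$seq, 5, 5))[1]
  expect_error(apply_template(lc$g, bad), "interval mismatch")
  # zero-difference template is the identity
  noop <- tpl
  noop$seq <- substr(lc$g$seq, tpl$start + 1L, tpl$end)
  noop$edits_applied <- tpl$edits_applied[0, ]
  expect_identical(apply_template(lc$g, noop)$seq, lc$g$seq)
})

test_that("an edit that destroys the PAM needs no escape mutation", {
  lc <- make_locus()
  edit <- edit_spec("c", 71, "G", "T", "pam-hit")   # first G of TGG
  tpl <- build_template(lc$g, edit)
  out <- ensure_cas9_escape(lc$g, tpl, lc$guide)
  expect_identical(out$seq, tpl$seq)
  expect_false("pam_escape" %in% out$edits_applied$reason)
})

test_that("a protospacer edit escapes under the strict rule but not with margin", {
  lc <- make_locus()
  ref <- substr(lc$g$seq, 61, 61)
  edit <- edit_spec("c", 60, ref, "G", "proto-hit")
  tpl <- build_template(lc$g, edit)
  # one mismatch already defeats a perfect-match cleavage rule
  out <- ensure_cas9_escape(lc$g, tpl, lc$guide)
  expect_identical(out$seq, tpl$seq)
  # requiring two mismatches forces a PAM mutation on top of the edit
  out2 <- ensure_cas9_escape(lc$g, tpl, lc$guide,
                             escape_min_mismatches = 2)
  esc <- out2$edits_applied[out2$edits_applied$reason == "pam_escape", ]
  expect_identical(nrow(esc), 1L)
  expect_identical(esc$pos, 72L)                    # PAM position 3
  expect_identical(esc$alt, "A")
  pam_after <- substr(apply_template(lc$g, out2)$seq, 71, 73)
  expect_false(substr(pam_after, 2, 3) == "GG")
})

test_that("an edit outside protospacer and PAM gains a PAM-escape mutation", {
  lc <- make_locus()
  ref <- substr(lc$g$seq, 101, 101)
  edit <- edit_spec("c", 100, ref, "G", "outside")
  tpl <- build_template(lc$g, edit)
  out <- ensure_cas9_escape(lc$g, tpl, lc$guide)
  expect_identical(sum(out$edits_applied$reason == "pam_escape"), 1L)
  recombined <- apply_template(lc$g, out)
  # the recombined genome holds no perfect protospacer+NGG for the guide
  # at the locus (exact scan, PAM required, no on-target exclusion)
  scan <- count_offtargets(recombined, lc$guide$n20$seq, threshold = 1,
                           require_pam = TRUE)
  at_locus <- scan$hits$start == 50L & scan$hits$strand == "+"
  expect_false(any(at_locus))
})

test_that("escape fails loudly when the PAM is out of template reach", {
  lc <- make_locus()
  ref <- substr(lc$g$seq, 101, 101)
  edit <- edit_spec("c", 100, ref, "G", "far")
  tpl9 <- build_template(lc$g, edit, length = 9)    # [96, 105): no overlap
  expect_error(ensure_cas9_escape(lc$g, tpl9, lc$guide),
               "escape is impossible")
  ref45 <- substr(lc$g$seq, 46, 46)
  edit45 <- edit_spec("c", 45, ref45, "G", "near")
  tpl30 <- build_template(lc$g, edit45, length = 30) # covers proto, not PAM
  expect_error(ensure_cas9_escape(lc$g, tpl30, lc$guide),
               "not covered by the template")
})

test_that("templates never deviate from the reference beyond edit + escape", {
  for (seed in 1:10) {
    fx <- generate_fixture(fixture_spec(
      seed = seed + 200, length = 3000, guides = 1,
      plants = list(plant(1, "+", 1, 0, pam = TRUE)),
      edit = list(plant = 1)))
    reports <- suppressWarnings(design(fx$genome, fx$edit, k = 2))
    for (r in reports) for (tpl in r$templates) {
      expect_lte(nrow(tpl$edits_applied), nchar(r$edit$ref) + 1L)
      ref_win <- substr(fx$genome$seq, tpl$start + 1L, tpl$end)
      expect_identical(
        which(strsplit(tpl$seq, "")[[1]] != strsplit(ref_win, "")[[1]]),
        sort(match(tpl$edits_applied$pos, tpl$start:(tpl$end - 1L))))
    }
  }
})

test_that("synonymous PAM escapes are preferred when a CDS is supplied", {
  code <- Biostrings::GENETIC_CODE
  # with a CGG PAM, the codon in frame with the CDS below is CGG (Arg);
  # the default escape G->A at PAM position 3 gives CGA, still arginine
  lc <- make_locus(seed = 321, pam = "CGG")
  # a + strand CDS whose reading frame puts 72 at codon position 3
  cds <- data.frame(contig = "c", start = 52L, end = 100L, strand = "+",
                    stringsAsFactors = FALSE)
  stopifnot((72 - 52) %% 3 == 2)
  ref <- substr(lc$g$seq, 101, 101)
  edit <- edit_spec("c", 100, ref, "G", "syn")
  tpl <- build_template(lc$g, edit)
  out <- ensure_cas9_escape(lc$g, tpl, lc$guide, cds = cds)
  esc <- out$edits_applied[out$edits_applied$reason == "pam_escape", ]
  expect_identical(esc$pos, 72L)
  before <- apply_template(lc$g, tpl)
  after <- apply_template(lc$g, out)
  codon_b <- substr(before$seq, 71, 73)
  codon_a <- substr(after$seq, 71, 73)
  expect_identical(unname(code[codon_b]), unname(code[codon_a]))
})

test_that("codon arithmetic holds on both CDS strands", {
  # + strand: CCG codon, third-position G; A is synonymous
  g <- genome_seq("c", paste0(strrep("A", 12), "CCG", strrep("A", 12)))
  cds_p <- data.frame(contig = "c", start = 12L, end = 15L, strand = "+")
  expect_true(crmage:::.is_synonymous(g, cds_p[1, ], 14L, "A"))
  # + strand: ATG codon, third-position G; no substitution is synonymous
  g2 <- genome_seq("c", paste0(strrep("A", 12), "ATG", strrep("A", 12)))
  expect_false(crmage:::.is_synonymous(g2, cds_p[1, ], 14L, "A"))
  expect_false(crmage:::.is_synonymous(g2, cds_p[1, ], 14L, "T"))
  # - strand CDS: forward CGG reads CCG on the minus strand (Pro, read
  # right to left); mutating forward position 12 (codon position 3 on the
  # minus strand) to T gives CCA, synonymous
  g3 <- genome_seq("c", paste0(strrep("A", 12), "CGG", strrep("A", 12)))
  cds_m <- data.frame(contig = "c", start = 12L, end = 15L, strand = "-")
  expect_identical(reverse_complement(substr(g3$seq, 13, 15)), "CCG")
  expect_true(crmage:::.is_synonymous(g3, cds_m[1, ], 12L, "T"))
})

test_that("CDS intervals load from GFF3 with 0-based starts", {
  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c\tsrc\tgene\t10\t60\t.\t+\t.\tID=g1",
               "c\tsrc\tCDS\t13\t45\t.\t+\t0\tID=c1;Parent=g1",
               "c\tsrc\tCDS\t50\t58\t.\t-\t0\tID=c2;Parent=g1"), gff)
  cds <- read_cds_gff(gff)
  expect_identical(nrow(cds), 2L)                  # gene row excluded
  expect_identical(cds$start, c(12L, 49L))         # 1-based -> 0-based
  expect_identical(cds$end, c(45L, 58L))           # half-open
  expect_identical(cds$strand, c("+", "-"))
})
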