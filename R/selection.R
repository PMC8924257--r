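# Candidate ranking and the end-to-end design pipeline.

# gap (bases) between the PAM triplet and the edited interval; 0 if they
# overlap. Used as the second ranking key: cleavage close to the edit
# favours recombineering efficiency.
.pam_edit_distance <- function(site, edit) {
  a1 <- site$pam_start; a2 <- site$pam_start + 3L
  b1 <- edit$pos; b2 <- edit$pos + nchar(edit$ref)
  max(0L, max(a1, b1) - min(a2, b2))
}

#' Rank guide candidates and select the k best
#'
#' Deterministic ordering: off-target count ascending, then PAM-to-edit
#' distance ascending (when an edit is supplied), then PAM start ascending,
#' then `+` strand before `-`.
#'
#' @param candidates List of `guide_candidate` objects (from
#'   [count_offtargets], with source sites).
#' @param k Number of candidates to keep (>= 1).
#' @param edit Optional [edit_spec] used for the distance tie-break.
#' @return Ordered list of at most `k` candidates. An empty candidate list
#'   yields an empty result with a warning, not an error.
#' @export
rank_and_select <- function(candidates, k = 6L, edit = NULL) {
  stopifnot(k >= 1L)
  if (!length(candidates)) {
    warning("no candidates to select from", call. = FALSE)
    return(list())
  }
  counts <- vapply(candidates, function(x) as.numeric(x$offtarget_count), 0)
  starts <- vapply(candidates, function(x) as.numeric(x$site$pam_start), 0)
  strands <- vapply(candidates, function(x) x$site$strand, "")
  dist <- if (is.null(edit)) rep(0, length(candidates)) else
    vapply(candidates, function(x)
      as.numeric(.pam_edit_distance(x$site, edit)), 0)
  ord <- order(counts, dist, starts, match(strands, c("+", "-")))
  if (k > length(candidates))
    warning("only ", length(candidates), " candidate(s) available for k = ",
            k, call. = FALSE)
  candidates[ord][seq_len(min(k, length(candidates)))]
}

#' Design guides and repair templates for a batch of edits
#'
#' Runs the full procedure for each edit: window the neighborhood, find
#' NGG PAM sites on both strands, extract N20 spacers, score each by
#' genome-wide off-target count, select the `k` with the fewest
#' off-targets, build the repair template carrying the edit, and add a
#' PAM-escape mutation whenever the edited locus would remain cleavable.
#' Candidates whose PAM cannot be mutated within the template are dropped
#' with a warning and the next-best candidate fills in. Per-edit failures
#' are recorded in that edit's report; the batch never aborts on one bad
#' edit.
#'
#' @param genomes A [genome_seq] or list of them.
#' @param edits An [edit_spec] or list of them.
#' @param window Neighborhood size in bases for PAM discovery (default 80,
#'   the repair-template size).
#' @param template_length Repair-template length in bases (default 80).
#' @param mismatch_threshold Off-target mismatch-exclusion boundary
#'   (default 2: hits deviate by fewer than 2 bases).
#' @param k Number of guides to select per edit (default 6).
#' @param require_pam_offtargets Require an NGG PAM for off-target hits
#'   (default `FALSE`).
#' @param escape_min_mismatches Passed to [ensure_cas9_escape].
#' @param cds Optional CDS table (see [ensure_cas9_escape]).
#' @return An object of class `design_report_set`: a list of
#'   `design_report` objects, one per edit, each with fields `edit`,
#'   `candidates` (all scored candidates), `selected`, `templates` (one per
#'   selected candidate) and `warnings`.
#' @export
design <- function(genomes, edits, window = 80L, template_length = 80L,
                   mismatch_threshold = 2L, k = 6L,
                   require_pam_offtargets = FALSE,
                   escape_min_mismatches = 1L, cds = NULL) {
  genomes <- .as_genome_list(genomes)
  if (inherits(edits, "edit_spec")) edits <- list(edits)
  reports <- lapply(edits, function(edit) {
    .design_one(genomes, edit, window, template_length, mismatch_threshold,
                k, require_pam_offtargets, escape_min_mismatches, cds)
  })
  structure(reports, class = "design_report_set")
}

.design_one <- function(genomes, edit, window, template_length,
                        mismatch_threshold, k, require_pam_offtargets,
                        escape_min_mismatches, cds) {
  warnings <- character()
  note <- function(w) warnings[[length(warnings) + 1L]] <<- w
  report <- function(candidates = list(), selected = list(),
                     templates = list()) {
    structure(list(edit = edit, candidates = candidates,
                   selected = selected, templates = templates,
                   warnings = warnings),
              class = "design_report")
  }
  g <- tryCatch(.get_contig(genomes, edit$contig), error = function(e) e)
  if (inherits(g, "error")) { note(conditionMessage(g)); return(report()) }
  ok <- tryCatch({ validate_edit(edit, g); TRUE }, error = function(e) {
    note(conditionMessage(e)); FALSE
  })
  if (!ok) return(report())

  region <- withCallingHandlers(
    neighborhood(edit, g, window),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })
  sites <- withCallingHandlers(
    find_pam_sites(g, region),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") },
    message = function(m) { note(trimws(conditionMessage(m)))
      invokeRestart("muffleMessage") })
  if (nrow(sites) == 0L) {
    note(sprintf("no PAM in window for edit '%s'", edit$label))
    return(report())
  }
  candidates <- lapply(seq_len(nrow(sites)), function(i) {
    n20 <- extract_n20(g, sites[i, ])
    count_offtargets(genomes, n20, mismatch_threshold,
                     require_pam_offtargets)
  })
  ranked <- withCallingHandlers(
    rank_and_select(candidates, length(candidates), edit),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })

  base_tpl <- tryCatch(build_template(g, edit, template_length),
                       error = function(e) e)
  if (inherits(base_tpl, "error")) {
    note(conditionMessage(base_tpl))
    return(report(candidates))
  }
  selected <- list(); templates <- list()
  for (cand in ranked) {
    if (length(selected) >= k) break
    tpl <- tryCatch(
      ensure_cas9_escape(g, base_tpl, cand, escape_min_mismatches, cds),
      error = function(e) e)
    if (inherits(tpl, "error")) {
      note(sprintf("candidate at %s:%d %s dropped: %s", edit$contig,
                   cand$site$pam_start, cand$site$strand,
                   conditionMessage(tpl)))
      next
    }
    selected[[length(selected) + 1L]] <- cand
    templates[[length(templates) + 1L]] <- tpl
  }
  if (length(selected) < min(k, length(ranked)))
    note(sprintf("selected %d of %d requested guides for edit '%s'",
                 length(selected), k, edit$label))
  report(candidates, selected, templates)
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> edit '%s' (%s:%d %s>%s)\n", x$edit$label,
              x$edit$contig, x$edit$pos + 1L, x$edit$ref, x$edit$alt))
  cat(sprintf("  candidates: %d, selected: %d\n", length(x$candidates),
              length(x$selected)))
  for (i in seq_along(x$selected)) {
    cand <- x$selected[[i]]
    cat(sprintf("  [%d] %s %s:%d %s  off-targets: %d  template edits: %d\n",
                i, cand$n20$seq, cand$site$contig, cand$site$pam_start,
                cand$site$strand, cand$offtarget_count,
                nrow(x$templates[[i]]$edits_applied)))
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
print.design_report_set <- function(x, ...) {
  cat(sprintf("<design_report_set> %d edit(s)\n", length(x)))
  for (r in x) print(r)
  invisible(x)
}

#' @method summary design_report_set
#' @export
summary.design_report_set <- function(object, ...) {
  as_summary_df(object)
}

#' Tabulate selected guides across a report set
#'
#' @param reports A `design_report_set` from [design].
#' @return Data frame with one row per selected guide: `label`, `contig`,
#'   `pam_start`, `strand`, `n20`, `offtarget_count`, `oligo_name`.
#' @export
as_summary_df <- function(reports) {
  rows <- list()
  for (r in reports) for (i in seq_along(r$selected)) {
    cand <- r$selected[[i]]
    tpl <- r$templates[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      label = r$edit$label, contig = cand$site$contig,
      pam_start = cand$site$pam_start, strand = cand$site$strand,
      n20 = cand$n20$seq, offtarget_count = cand$offtarget_count,
      oligo_name = sprintf("%s|%s|%d-%d|%s|%s", r$edit$label, tpl$contig,
                           tpl$start, tpl$end, tpl$strand,
                           paste(sprintf("%d%s>%s", tpl$edits_applied$pos,
                                         tpl$edits_applied$ref,
                                         tpl$edits_applied$alt),
                                 collapse = ",")),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(label = character(), contig = character(),
                      pam_start = integer(), strand = character(),
                      n20 = character(), offtarget_count = integer(),
                      oligo_name = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a design summary TSV
#'
#' One row per selected guide (see [as_summary_df]).
#'
#' @param reports A `design_report_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(reports, path) {
  utils::write.table(as_summary_df(reports), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the full design report as JSON
#'
#' @param reports A `design_report_set`.
#' @param path Output path.
#' @param max_hits Number of off-target hits retained per candidate in the
#'   report (the count is always exact); default 20.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(reports, path, max_hits = 20L) {
  ser_cand <- function(cand) list(
    n20 = cand$n20$seq,
    site = cand$site[c("contig", "pam_start", "strand", "pam_seq",
                       "proto_start", "proto_end")],
    offtarget_count = cand$offtarget_count,
    hits = utils::head(cand$hits, max_hits))
  out <- lapply(reports, function(r) list(
    edit = unclass(r$edit),
    candidates = lapply(r$candidates, ser_cand),
    selected = lapply(r$selected, ser_cand),
    templates = lapply(r$templates, function(tpl)
      list(seq = tpl$seq, contig = tpl$contig, start = tpl$start,
           end = tpl$end, strand = tpl$strand,
           edits_applied = tpl$edits_applied)),
    warnings = r$warnings))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write selected repair oligos as FASTA
#'
#' Headers follow `label|contig|start-end|strand|edits`.
#'
#' @param reports A `design_report_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oligos_fasta <- function(reports, path) {
  seqs <- character(); nms <- character()
  for (r in reports) for (i in seq_along(r$templates)) {
    tpl <- r$templates[[i]]
    nm <- sprintf("%s|%s|%d-%d|%s|%s", r$edit$label, tpl$contig, tpl$start,
                  tpl$end, tpl$strand,
                  paste(sprintf("%d%s>%s", tpl$edits_applied$pos,
                                tpl$edits_applied$ref,
                                tpl$edits_applied$alt), collapse = ","))
    # one oligo per selected guide; disambiguate duplicated headers
    if (nm %in% nms) nm <- sprintf("%s#%d", nm, i)
    nms <- c(nms, nm); seqs <- c(seqs, tpl$seq)
  }
  names(seqs) <- nms
  write_fasta(seqs, path)
}

#' Write candidate protospacer coordinates as BED6
#'
#' One record per scored candidate: chrom, protospacer start/end (0-based
#' half-open), `name = label:strand:pam_start`, score = off-target count,
#' strand.
#'
#' @param reports A `design_report_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(reports, path) {
  rows <- list()
  for (r in reports) for (cand in r$candidates) {
    s <- cand$site
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = s$contig, start = s$proto_start, end = s$proto_end,
      name = sprintf("%s:%s:%d", r$edit$label, s$strand, s$pam_start),
      score = cand$offtarget_count, strand = s$strand,
      stringsAsFactors = FALSE)
  }
  bed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character())
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
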