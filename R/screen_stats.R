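# Quantification of the two colorimetric screen readouts: colony-count
# killing rates and indigoidine absorbance indices.

#' Killing rate from colony counts
#'
#' The killing rate of a replicate is the proportion of white (edited)
#' colonies among all colonies: `white / (white + red)`. Replicates with
#' zero total colonies are excluded with a warning. The across-replicate
#' spread is the sample standard deviation (n - 1 denominator); it is `NA`
#' for a single replicate.
#'
#' @param counts Data frame with columns `white` and `red` (non-negative
#'   integers), one row per biological replicate; an optional `replicate`
#'   column names them.
#' @return A list of class `killing_rate` with `rates` (per-replicate data
#'   frame), `mean` and `sd`.
#' @export
killing_rate <- function(counts) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("white", "red") %in% names(counts)))
  if (!"replicate" %in% names(counts))
    counts$replicate <- seq_len(nrow(counts))
  if (any(counts$white < 0 | counts$red < 0))
    stop("colony counts must be non-negative", call. = FALSE)
  total <- counts$white + counts$red
  usable <- total >= 1
  if (any(!usable))
    warning(sum(!usable), " replicate(s) with zero total colonies excluded",
            call. = FALSE)
  if (!any(usable))
    stop("no usable replicates (all totals are zero)", call. = FALSE)
  kept <- counts[usable, , drop = FALSE]
  rate <- kept$white / (kept$white + kept$red)
  rates <- data.frame(replicate = kept$replicate, white = kept$white,
                      red = kept$red, rate = rate,
                      stringsAsFactors = FALSE)
  structure(list(rates = rates, mean = mean(rate),
                 sd = if (nrow(rates) > 1L) stats::sd(rate) else NA_real_),
            class = "killing_rate")
}

#' @export
print.killing_rate <- function(x, ...) {
  cat(sprintf("<killing_rate> %d replicate(s): mean %.4f, sd %s\n",
              nrow(x$rates), x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.4f", x$sd)))
  invisible(x)
}

#' Indigoidine production index from absorbance readings
#'
#' The index of a sample is its 615 nm absorbance normalised by its 800 nm
#' absorbance (`A615 / A800`), which cancels background turbidity and
#' volume differences. Samples with non-positive `A800` cannot be
#' normalised and are flagged and excluded with a warning.
#'
#' @param records Data frame with columns `a615` and `a800`; an optional
#'   `sample` column names the samples.
#' @return A list of class `indigoidine_index` with `indices`
#'   (per-sample data frame), `mean`, `sd` and `excluded` (names of
#'   excluded samples).
#' @export
indigoidine_index <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("a615", "a800") %in% names(records)))
  if (!"sample" %in% names(records))
    records$sample <- seq_len(nrow(records))
  usable <- records$a800 > 0
  if (any(!usable))
    warning(sum(!usable), " sample(s) with non-positive A800 excluded",
            call. = FALSE)
  if (!any(usable))
    stop("no usable samples (all A800 non-positive)", call. = FALSE)
  kept <- records[usable, , drop = FALSE]
  index <- kept$a615 / kept$a800
  indices <- data.frame(sample = kept$sample, a615 = kept$a615,
                        a800 = kept$a800, index = index,
                        stringsAsFactors = FALSE)
  structure(list(indices = indices, mean = mean(index),
                 sd = if (nrow(indices) > 1L) stats::sd(index) else
                   NA_real_,
                 excluded = records$sample[!usable]),
            class = "indigoidine_index")
}

#' @export
print.indigoidine_index <- function(x, ...) {
  cat(sprintf("<indigoidine_index> %d sample(s): mean %.4f, sd %s\n",
              nrow(x$indices), x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.4f", x$sd)))
  invisible(x)
}

#' Read a colony-count or absorbance table
#'
#' Reads CSV or TSV by extension (`.csv` vs anything else).
#'
#' @param path Path to the table.
#' @return A data frame.
#' @export
read_screen_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE)
  else
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a screen-statistics summary TSV
#'
#' @param stats A `killing_rate` or `indigoidine_index` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_summary <- function(stats, path) {
  per <- if (inherits(stats, "killing_rate")) stats$rates else
    stats$indices
  utils::write.table(per, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf("# mean\t%.10g\n# sd\t%s\n", stats$mean,
              if (is.na(stats$sd)) "NA" else
                sprintf("%.10g", stats$sd)),
      file = path, append = TRUE)
  invisible(path)
}
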