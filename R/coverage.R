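#' Alignment filter parameters
#'
#' The mapping-stringency contract applied before any coverage or linkage
#' computation: a record is kept when its identity (1 minus edit distance
#' over aligned columns) is at least `min_identity` and its aligned query
#' length is at least `min_aligned_fraction` of the read length. Both
#' thresholds are inclusive. Defaults are the conventional 95% similarity
#' over 70% of the read length.
#'
#' @param min_identity Minimum identity fraction in (0, 1].
#' @param min_aligned_fraction Minimum aligned fraction of the read in (0, 1].
#' @return An object of class `alignment_filter_params`.
#' @export
alignment_filter_params <- function(min_identity = 0.95,
                                    min_aligned_fraction = 0.70) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_aligned_fraction > 0, min_aligned_fraction <= 1)
  structure(list(min_identity = min_identity,
                 min_aligned_fraction = min_aligned_fraction),
            class = "alignment_filter_params")
}

# query bases in the alignment (M/I/=/X), reference span (M/D/=/X), and
# alignment columns (M/I/D/=/X) from CIGAR strings
cigar_widths <- function(cigar) {
  ops <- GenomicAlignments::cigarOpTable(cigar)
  get <- function(cols) rowSums(ops[, intersect(cols, colnames(ops)), drop = FALSE])
  list(query = get(c("M", "I", "=", "X")),
       ref = get(c("M", "D", "=", "X")),
       columns = get(c("M", "I", "D", "=", "X")))
}

#' Filter alignment records by identity and aligned fraction
#'
#' Drops unmapped, secondary and supplementary records, then keeps exactly
#' the records with `identity >= min_identity` and
#' `aligned_length / read_length >= min_aligned_fraction` (both inclusive).
#' Identity is `1 - nm / aligned_columns` with `nm` the edit distance from
#' the standard mismatch-count tag.
#'
#' @param records Alignment record data.frame (see [simulate_alignments()]).
#' @param params An [alignment_filter_params()].
#' @return The retained records, same shape; idempotent.
#' @export
filter_alignments <- function(records, params = alignment_filter_params()) {
  stopifnot(inherits(params, "alignment_filter_params"))
  mapped <- !bitwAnd(records$flag, 4L) & !bitwAnd(records$flag, 256L) &
    !bitwAnd(records$flag, 2048L) & !is.na(records$rname)
  records <- records[mapped, , drop = FALSE]
  if (nrow(records) == 0) return(records)
  if (anyNA(records$nm)) {
    bad <- records$qname[is.na(records$nm)][1]
    stop("record lacks identity information (no mismatch count): ", bad)
  }
  w <- cigar_widths(records$cigar)
  identity <- 1 - records$nm / w$columns
  aligned_fraction <- w$query / records$read_len
  keep <- identity >= params$min_identity &
    aligned_fraction >= params$min_aligned_fraction
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length and GC content of a scaffold sequence
#'
#' @param sequence A single nucleotide string (ACGTN, case-insensitive) or
#'   [Biostrings::DNAString].
#' @return Named numeric `c(length_bp, gc_pct)`. GC percent is
#'   `100 * (G + C) / (A + C + G + T)`: `N` counts toward the length but is
#'   excluded from both numerator and denominator.
#' @export
scaffold_properties <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1 || nchar(s) == 0) stop("empty sequence")
  fr <- Biostrings::letterFrequency(Biostrings::BString(s),
                                    letters = c("A", "C", "G", "T"))
  denom <- sum(fr)
  if (denom == 0) stop("sequence contains no unambiguous bases")
  c(length_bp = nchar(s), gc_pct = 100 * sum(fr[c("C", "G")]) / denom)
}

#' Compute per-scaffold, per-sample coverage profiles
#'
#' Converts filtered alignment records into the coverage table that is the
#' coordinate system of differential-coverage binning. Depth is mean
#' per-base: total aligned reference bases on the scaffold divided by its
#' length. Scaffolds without records get depth 0. The result is
#' order-invariant in the records.
#'
#' @param records Filtered alignment records; the `sample` column defines
#'   the samples (override with `samples`).
#' @param scaffolds Named [Biostrings::DNAStringSet] of all scaffolds.
#' @param samples Optional character vector fixing sample column order.
#' @return A `coverage_profiles` data.frame: `scaffold_id, length_bp,
#'   gc_pct` and one `depth_<sample>` column per sample.
#' @export
compute_coverage <- function(records, scaffolds, samples = NULL) {
  if (length(scaffolds) == 0) stop("empty scaffold set")
  if (is.null(names(scaffolds))) stop("scaffolds must be named")
  if (nrow(records) > 0 &&
      !all(records$rname %in% names(scaffolds))) {
    stop("records reference scaffolds absent from the assembly: ",
         paste(utils::head(setdiff(records$rname, names(scaffolds))), collapse = ", "))
  }
  samples <- samples %||% sort(unique(records$sample))
  if (length(samples) == 0) samples <- "S1"
  gc <- 100 * Biostrings::letterFrequency(scaffolds, "GC") /
    Biostrings::letterFrequency(scaffolds, "ACGT")
  prof <- data.frame(scaffold_id = names(scaffolds),
                     length_bp = Biostrings::width(scaffolds),
                     gc_pct = as.numeric(gc),
                     stringsAsFactors = FALSE)
  for (s in samples) {
    rs <- records[records$sample %in% s, , drop = FALSE]
    col <- paste0("depth_", s)
    if (nrow(rs) == 0) { prof[[col]] <- 0; next }
    ref_bases <- cigar_widths(rs$cigar)$ref
    tot <- tapply(ref_bases, factor(rs$rname, levels = names(scaffolds)),
                  sum, default = 0)
    prof[[col]] <- as.numeric(tot) / prof$length_bp
  }
  class(prof) <- c("coverage_profiles", "data.frame")
  prof
}

#' Filter coverage profiles by scaffold length
#'
#' The analysis default keeps scaffolds of at least 1 kbp (inclusive).
#' Plot-style filtering uses `strict = TRUE` with `min_bp = 5000`, keeping
#' only scaffolds strictly longer than the threshold.
#'
#' @param profiles A `coverage_profiles` data.frame.
#' @param min_bp Length threshold in bp (default 1000).
#' @param strict If `TRUE`, keep `length_bp > min_bp`; else `>=`.
#' @return Filtered profiles.
#' @export
length_filter <- function(profiles, min_bp = 1000, strict = FALSE) {
  keep <- if (strict) profiles$length_bp > min_bp else profiles$length_bp >= min_bp
  out <- profiles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

depth_cols <- function(profiles) {
  grep("^depth_", names(profiles), value = TRUE)
}

#' Write / read a coverage table
#'
#' Tab-separated interchange format: `scaffold_id, length_bp, gc_pct,
#' depth_<sample>...`. [write_plot_data()] appends the per-scaffold marker
#' count and majority taxonomy, the attributes used to colour
#' differential-coverage plots.
#'
#' @param profiles A `coverage_profiles` data.frame.
#' @param path File path.
#' @return Invisibly `path` (writer) or the profiles (reader).
#' @export
write_coverage <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  prof <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(prof) <- c("coverage_profiles", "data.frame")
  prof
}

#' @rdname write_coverage
#' @param hits Marker hit table (see [detect_markers()]).
#' @export
write_plot_data <- function(profiles, hits, path) {
  n_markers <- table(factor(hits$scaffold_id, levels = profiles$scaffold_id))
  tax <- vapply(profiles$scaffold_id, function(s) {
    lab <- hits$taxonomy_label[hits$scaffold_id == s]
    if (length(lab) == 0) NA_character_ else names(sort(table(lab), decreasing = TRUE))[1]
  }, "")
  out <- cbind(profiles, n_markers = as.integer(n_markers), taxonomy = tax)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Differential coverage plot of two samples
#'
#' Scatter of scaffolds in log10-depth space for two samples, point size by
#' scaffold length, coloured by majority marker taxonomy when `hits` is
#' given. Requires ggplot2.
#'
#' @param profiles A `coverage_profiles` data.frame.
#' @param sample_x,sample_y Sample identifiers (names after `depth_`).
#' @param hits Optional marker hits for colouring.
#' @param min_bp Plot length filter, strict (default 5000).
#' @param eps Pseudo-depth added before log10 (default 0.01).
#' @return A ggplot object.
#' @export
plot_coverage <- function(profiles, sample_x, sample_y, hits = NULL,
                          min_bp = 5000, eps = 0.01) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_coverage requires ggplot2")
  }
  d <- length_filter(profiles, min_bp, strict = TRUE)
  d$x <- log10(d[[paste0("depth_", sample_x)]] + eps)
  d$y <- log10(d[[paste0("depth_", sample_y)]] + eps)
  d$taxonomy <- "unclassified"
  if (!is.null(hits)) {
    for (i in seq_len(nrow(d))) {
      lab <- hits$taxonomy_label[hits$scaffold_id == d$scaffold_id[i]]
      if (length(lab)) d$taxonomy[i] <- names(sort(table(lab), decreasing = TRUE))[1]
    }
  }
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = y, size = length_bp,
                                  colour = taxonomy)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = paste0("log10 depth (", sample_x, ")"),
                  y = paste0("log10 depth (", sample_y, ")"),
                  size = "scaffold bp", colour = "markers") +
    ggplot2::theme_minimal()
}
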