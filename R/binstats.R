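#' Split a scaffold into contigs at N-gaps
#'
#' Splits at runs of at least `min_n_run` consecutive `N` (case-insensitive);
#' shorter N-runs stay inside a contig. Empty fragments are dropped.
#' Assembler dialects differ on the run threshold, so it is a parameter.
#'
#' @param scaffold_sequence A nucleotide string or [Biostrings::DNAString].
#' @param min_n_run Minimum N-run length that splits (default 10).
#' @return Character vector of contig sequences.
#' @export
split_contigs <- function(scaffold_sequence, min_n_run = 10) {
  s <- toupper(as.character(scaffold_sequence))
  parts <- strsplit(s, sprintf("N{%d,}", min_n_run))[[1]]
  parts[nzchar(parts)]
}

#' N50 of a set of fragment lengths
#'
#' The largest length L such that fragments of length >= L together cover
#' at least half the total. Ties use the >=-half convention: sort
#' descending and take the length at which the cumulative sum first reaches
#' total/2. Always a member of the input.
#'
#' @param lengths Positive integer vector, non-empty.
#' @return The N50 length.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length set")
  stopifnot(all(lengths > 0))
  l <- sort(lengths, decreasing = TRUE)
  l[which(cumsum(as.numeric(l)) >= sum(as.numeric(l)) / 2)[1]]
}

#' Summarize a genome bin
#'
#' Assembly-table statistics for one bin: total size, scaffold and contig
#' counts, contig N50 and maximum, length-weighted GC, marker completeness
#' and duplication, and the bin's relative abundance per sample as its share
#' of all aligned bases:
#' `100 * sum_bin(depth x length) / sum_all(depth x length)`.
#'
#' @param bin A `genome_bin` or character vector of scaffold ids.
#' @param scaffolds Named [Biostrings::DNAStringSet] of the full assembly.
#' @param profiles Coverage profiles of the full assembly.
#' @param hits Marker hits.
#' @param catalog A [marker_catalog()].
#' @param min_n_run Contig split threshold (see [split_contigs()]).
#' @return An object of class `bin_stats` (a list; printable).
#' @export
summarize_bin <- function(bin, scaffolds, profiles, hits, catalog,
                          min_n_run = 10) {
  ids <- if (inherits(bin, "genome_bin")) bin$scaffold_ids else bin
  missing <- setdiff(ids, names(scaffolds))
  if (length(missing)) {
    stop("bin scaffold(s) missing from assembly: ",
         paste(utils::head(missing), collapse = ", "))
  }
  seqs <- scaffolds[ids]
  lens <- Biostrings::width(seqs)
  contigs <- unlist(lapply(as.character(seqs), split_contigs,
                           min_n_run = min_n_run), use.names = FALSE)
  clen <- nchar(contigs)
  gc_each <- vapply(as.character(seqs),
                    function(s) scaffold_properties(s)["gc_pct"], 0)
  dcols <- depth_cols(profiles)
  pin <- profiles$scaffold_id %in% ids
  rel <- vapply(dcols, function(cn) {
    tot <- sum(profiles[[cn]] * profiles$length_bp)
    if (tot == 0) return(NA_real_)
    100 * sum(profiles[[cn]][pin] * profiles$length_bp[pin]) / tot
  }, 0)
  names(rel) <- sub("^depth_", "", dcols)
  structure(list(
    size_bp = sum(lens),
    n_scaffolds = length(ids),
    n_contigs = length(contigs),
    contig_n50_bp = if (length(clen)) n50(clen) else NA_real_,
    max_contig_bp = if (length(clen)) max(clen) else NA_real_,
    gc_pct = sum(gc_each * lens) / sum(lens),
    completeness_pct = completeness(ids, hits, catalog),
    contamination_pct = duplication(ids, hits, catalog),
    rel_abundance_pct = rel
  ), class = "bin_stats")
}

#' @export
print.bin_stats <- function(x, ...) {
  cat(sprintf("Genome size (Mbp)  %.2f\n", x$size_bp / 1e6))
  cat(sprintf("Scaffolds          %d\n", x$n_scaffolds))
  cat(sprintf("Contigs            %d\n", x$n_contigs))
  cat(sprintf("Contig N50         %d\n", as.integer(x$contig_n50_bp)))
  cat(sprintf("Max contig size    %d\n", as.integer(x$max_contig_bp)))
  cat(sprintf("GC content (%%)     %.1f\n", x$gc_pct))
  cat(sprintf("Completeness (%%)   %.1f\n", x$completeness_pct))
  cat(sprintf("Contamination (%%)  %.1f\n", x$contamination_pct))
  for (s in names(x$rel_abundance_pct)) {
    cat(sprintf("Abundance %s (%%)   %.1f\n", s, x$rel_abundance_pct[s]))
  }
  invisible(x)
}

#' @rdname summarize_bin
#' @param stats A `bin_stats` object.
#' @param path File path for a TSV report.
#' @export
write_bin_stats <- function(stats, path) {
  rows <- data.frame(
    statistic = c("size_bp", "n_scaffolds", "n_contigs", "contig_n50_bp",
                  "max_contig_bp", "gc_pct", "completeness_pct",
                  "contamination_pct",
                  paste0("rel_abundance_pct_", names(stats$rel_abundance_pct))),
    value = c(stats$size_bp, stats$n_scaffolds, stats$n_contigs,
              stats$contig_n50_bp, stats$max_contig_bp, stats$gc_pct,
              stats$completeness_pct, stats$contamination_pct,
              unname(stats$rel_abundance_pct)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
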