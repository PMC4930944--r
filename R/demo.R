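#' Default two-sample demonstration community
#'
#' The stock study-condition community used throughout the package's tests
#' and examples: 10 genomes of 100 kbp, two samples, every genome with a
#' five-fold abundance contrast between the samples (half the genomes up in
#' sample A, half in sample B, on a two-fold ladder of overall abundances so
#' all ten occupy distinct coordinates in differential-coverage space),
#' scaffolds of 5-15 kbp, and the full 107-marker catalog planted per
#' genome.
#'
#' @param seed Integer seed.
#' @return A [community_spec()].
#' @export
demo_community_spec <- function(seed = 1) {
  w_a <- c(10, 2, 20, 4, 40, 8, 80, 16, 160, 32)
  w_b <- c(2, 10, 4, 20, 8, 40, 16, 80, 32, 160)
  ab <- cbind(A = w_a / sum(w_a), B = w_b / sum(w_b))
  community_spec(
    n_genomes = 10,
    genome_length_bp = 1e5,
    gc_target = seq(0.35, 0.65, length.out = 10),
    abundance_matrix = ab,
    n_markers = 107,
    fragment_mean_bp = 10000,
    fragment_min_bp = 5000,
    seed = seed)
}

#' Score candidate bins against community ground truth
#'
#' For every genome in the truth, finds the candidate scaffold set with the
#' highest F1 against the genome's true scaffolds and reports precision,
#' recall and F1 of that assignment.
#'
#' @param candidates List of character vectors of scaffold ids (e.g. from
#'   [cluster_coverage()]) or of `genome_bin` objects.
#' @param truth A `community_truth`.
#' @return Data.frame `genome_id, candidate, precision, recall, f1`.
#' @export
bin_recovery <- function(candidates, truth) {
  sets <- lapply(candidates, function(c) {
    if (inherits(c, "genome_bin")) c$scaffold_ids else c
  })
  gids <- unique(truth$scaffold_map$genome_id)
  rows <- lapply(gids, function(g) {
    tset <- truth$scaffold_map$scaffold_id[truth$scaffold_map$genome_id == g]
    best <- c(cand = NA_integer_, precision = 0, recall = 0, f1 = 0)
    for (i in seq_along(sets)) {
      tp <- length(intersect(sets[[i]], tset))
      if (tp == 0) next
      prec <- tp / length(sets[[i]])
      rec <- tp / length(tset)
      f1 <- 2 * prec * rec / (prec + rec)
      if (f1 > best["f1"]) best <- c(cand = i, precision = prec,
                                     recall = rec, f1 = f1)
    }
    data.frame(genome_id = g, candidate = best["cand"],
               precision = best["precision"], recall = best["recall"],
               f1 = best["f1"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
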