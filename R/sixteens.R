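#' Generate a labelled 16S sequence set with planted probe sites
#'
#' Builds synthetic 16S-like sequences, grouped by taxonomy, each carrying
#' the binding site (reverse complement) of every planned probe at a
#' recorded position with exactly the planned number of substitutions.
#' Background sequence is rejection-checked: a draw containing an
#' accidental site within 1 mismatch of any supplied probe (other than its
#' own planted site) is regenerated, so coverage tables computed from the
#' set equal the plan exactly.
#'
#' @param probes Named list of [probe_spec()] objects.
#' @param group_sizes Named integer vector: taxonomy label -> number of
#'   sequences.
#' @param mismatch_plan Data.frame `taxonomy, probe, mismatches`: which
#'   probes are planted in which group and with how many substitutions.
#'   Probe/taxon combinations absent from the plan are not planted.
#' @param seq_length Sequence length in bp (default 1400, full-length
#'   16S-like).
#' @param seed Integer seed; generation is deterministic.
#' @return List with `sequences` ([Biostrings::DNAStringSet], ids
#'   `<taxon>_<i>`), `taxonomy` (data.frame `sequence_id, taxonomy`) and
#'   `plan` (the plan augmented with `sequence_id` and planted `start`).
#' @export
generate_16s_set <- function(probes, group_sizes, mismatch_plan,
                             seq_length = 1400, seed = 1) {
  stopifnot(is.list(probes), length(names(probes)) == length(probes))
  mismatch_plan <- as.data.frame(mismatch_plan)
  stopifnot(all(c("taxonomy", "probe", "mismatches") %in% names(mismatch_plan)))
  if (!all(mismatch_plan$probe %in% names(probes))) {
    stop("plan references unknown probes: ",
         paste(setdiff(mismatch_plan$probe, names(probes)), collapse = ", "))
  }
  plen <- vapply(probes, function(p) nchar(p$sequence), 0L)
  for (i in seq_len(nrow(mismatch_plan))) {
    if (mismatch_plan$mismatches[i] > plen[mismatch_plan$probe[i]]) {
      stop("planned mismatches exceed probe length for ",
           mismatch_plan$probe[i])
    }
  }
  # fixed, non-overlapping offsets per probe (order of the probes list)
  offsets <- 50 + cumsum(c(0, utils::head(plen, -1) + 40))
  names(offsets) <- names(probes)
  if (any(offsets + plen - 1 > seq_length)) {
    stop("impossible plan: probes do not fit in sequences of ", seq_length, " bp")
  }
  sites <- vapply(probes, function(p) rev_comp(p$sequence), "")

  seqs <- character(0)
  tax_rows <- list(); plan_rows <- list()
  for (tx in names(group_sizes)) {
    planned <- mismatch_plan[mismatch_plan$taxonomy == tx, , drop = FALSE]
    for (i in seq_len(group_sizes[[tx]])) {
      sid <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", tx), i)
      s <- NULL
      for (attempt in 1:25) {
        s <- with_stream(seed, c("16s", tx, i, attempt), {
          bg <- strsplit(random_dna(seq_length, 0.5), "", fixed = TRUE)[[1]]
          for (j in seq_len(nrow(planned))) {
            pn <- planned$probe[j]
            k <- planned$mismatches[j]
            site <- strsplit(sites[[pn]], "", fixed = TRUE)[[1]]
            if (k > 0) {
              pos <- sample.int(length(site), k)
              site[pos] <- vapply(site[pos], function(b) {
                sample(setdiff(c("A", "C", "G", "T"), b), 1)
              }, "")
            }
            o <- offsets[[pn]]
            bg[o:(o + length(site) - 1)] <- site
          }
          paste(bg, collapse = "")
        })
        # reject accidental near-perfect sites for any supplied probe
        clean <- TRUE
        for (pn in names(probes)) {
          hits <- match_probe(probes[[pn]], s, max_mismatch = 1)
          own_k <- planned$mismatches[planned$probe == pn]
          allowed <- if (length(own_k) && own_k <= 1) offsets[[pn]] else integer(0)
          if (!all(hits$start %in% allowed)) { clean <- FALSE; break }
        }
        if (clean) break
        if (attempt == 25) stop("failed to generate clean background for ", sid)
      }
      seqs[sid] <- s
      tax_rows[[length(tax_rows) + 1]] <- data.frame(
        sequence_id = sid, taxonomy = tx, stringsAsFactors = FALSE)
      if (nrow(planned)) {
        plan_rows[[length(plan_rows) + 1]] <- data.frame(
          sequence_id = sid, taxonomy = tx, probe = planned$probe,
          mismatches = planned$mismatches,
          start = unname(offsets[planned$probe]),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(sequences = Biostrings::DNAStringSet(seqs),
       taxonomy = do.call(rbind, tax_rows),
       plan = if (length(plan_rows)) do.call(rbind, plan_rows) else
         data.frame(sequence_id = character(0), taxonomy = character(0),
                    probe = character(0), mismatches = integer(0),
                    start = integer(0)))
}

#' Write a 16S set as FASTA plus taxonomy TSV
#'
#' @param set Result of [generate_16s_set()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_16s_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "sequences_16s.fasta")
  tsv <- file.path(dir, "taxonomy.tsv")
  Biostrings::writeXStringSet(set$sequences, fa)
  utils::write.table(set$taxonomy, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, taxonomy = tsv))
}
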