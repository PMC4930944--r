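# IUPAC nucleotide bitmasks (A=1, C=2, G=4, T/U=8); degenerate codes are
# unions. Used so degenerate bases in targets match when any expansion does.
iupac_mask <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

#' Specify an rRNA-targeted oligonucleotide probe
#'
#' A 5'->3' oligonucleotide with optional 16S reference coordinates
#' (1-based inclusive positions on the E. coli numbering), a target
#' description, the recommended hybridization-buffer formamide
#' concentration (carried as metadata only; hybridization thermodynamics
#' are out of scope) and the names of its unlabeled competitor probes.
#' Probe sequences must be non-degenerate (ACGT); a declared reference span
#' must equal the probe length.
#'
#' @param name Probe name.
#' @param sequence 5'->3' probe sequence (whitespace tolerated).
#' @param ecoli_start,ecoli_end Optional 1-based inclusive reference span.
#' @param target_description Free-text target description.
#' @param formamide_pct Recommended formamide percent (metadata).
#' @param competitors Character vector of competitor probe names.
#' @return Object of class `probe_spec`.
#' @export
probe_spec <- function(name, sequence, ecoli_start = NA, ecoli_end = NA,
                       target_description = "", formamide_pct = NA,
                       competitors = character(0)) {
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  sequence <- chartr("U", "T", sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("probe sequences must be non-degenerate ACGT: ", name)
  }
  if (!is.na(ecoli_start) && !is.na(ecoli_end)) {
    if (ecoli_end - ecoli_start + 1 != nchar(sequence)) {
      stop(sprintf(
        "declared span %d-%d is inconsistent with a %d-mer (%s)",
        ecoli_start, ecoli_end, nchar(sequence), name))
    }
  }
  structure(list(name = name, sequence = sequence,
                 ecoli_start = ecoli_start, ecoli_end = ecoli_end,
                 target_description = target_description,
                 formamide_pct = formamide_pct,
                 competitors = competitors),
            class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  span <- if (is.na(x$ecoli_start)) "" else
    sprintf(" [%d-%d]", x$ecoli_start, x$ecoli_end)
  cat(sprintf("probe %s%s: 5'-%s-3' (%d nt)\n",
              x$name, span, x$sequence, nchar(x$sequence)))
  invisible(x)
}

#' Probe set targeting the Propionivibrio clade within the PAOmix range
#'
#' The two probes (with their unlabeled competitors) designed to resolve
#' Propionivibrio-lineage GAOs from "Ca. Accumulibacter": Prop207
#' (positions 207-230, 35% formamide) with competitor Prop207c, and the
#' broader Prop470 (470-494, high stringency) with competitors
#' Prop470c1-c3. Each competitor differs from its probe at exactly one
#' position, matching the weakly mismatched non-target sequences it blocks.
#'
#' @return Named list of [probe_spec()] objects.
#' @export
prop_probes <- function() {
  list(
    Prop207 = probe_spec("Prop207", "GCT CCA AAA GCG CAA GGT CCG AAG",
                         207, 230, "Ca. Propionivibrio aalborgensis", 35,
                         competitors = "Prop207c"),
    Prop207c = probe_spec("Prop207c", "GCT CCA AAA GCA CAA GGT CCG AAG",
                          207, 230, "Competitor for Prop207"),
    Prop470 = probe_spec("Prop470", "ATG CGG GTA CCG TCA TCT ACT CAG G",
                         470, 494, "Some Propionivibrio spp.", 70,
                         competitors = c("Prop470c1", "Prop470c2", "Prop470c3")),
    Prop470c1 = probe_spec("Prop470c1", "ATT CGG GTA CCG TCA TCT ACT CAG G",
                           470, 494, "Competitor for Prop470"),
    Prop470c2 = probe_spec("Prop470c2", "ATG CTG GTA CCG TCA TCT ACT CAG G",
                           470, 494, "Competitor for Prop470"),
    Prop470c3 = probe_spec("Prop470c3", "ATG CGG GTA CCG TCA TCT ACT CCG G",
                           470, 494, "Competitor for Prop470"))
}

target_masks <- function(target) {
  chars <- strsplit(chartr("uU", "TT", toupper(as.character(target))),
                    "", fixed = TRUE)[[1]]
  m <- unname(iupac_mask[chars])
  bad <- is.na(m)
  if (any(bad)) {
    message(sum(bad), " non-IUPAC character(s) in target treated as universal mismatches")
    m[bad] <- 0L
  }
  m
}

hamming_profile <- function(site_mask, tmask) {
  m <- length(site_mask)
  nw <- length(tmask) - m + 1
  if (nw < 1) return(integer(0))
  mism <- integer(nw)
  for (j in seq_len(m)) {
    mism <- mism + as.integer(bitwAnd(site_mask[j], tmask[j:(j + nw - 1)]) == 0L)
  }
  mism
}

#' Find probe binding sites on a target sequence
#'
#' Slides the reverse complement of the probe along the target and reports
#' every window within `max_mismatch` substitutions (Hamming distance;
#' degenerate IUPAC bases in the target match when any expansion does;
#' non-IUPAC characters are universal mismatches). With
#' `allow_single_indel`, windows matching with one single-base insertion or
#' deletion are additionally reported, the gap counted as one
#' mismatch-equivalent — the situation where a probe still hybridizes a
#' non-target sequence carrying an indel. Matches are sorted by
#' (mismatches, start).
#'
#' @param probe A [probe_spec()] (or plain 5'->3' sequence string).
#' @param target Target nucleotide sequence (sense strand; RNA accepted,
#'   U treated as T).
#' @param max_mismatch Maximum mismatch-equivalents (default 0).
#' @param allow_single_indel Also search 1-base-gapped sites (default FALSE).
#' @return Data.frame `start, mismatches, indel` (1-based target position;
#'   `indel` is `"none"`, `"del@<k>"` or `"ins@<k>"` with k the position in
#'   the probe's binding site).
#' @export
match_probe <- function(probe, target, max_mismatch = 0,
                        allow_single_indel = FALSE) {
  seqp <- if (inherits(probe, "probe_spec")) probe$sequence else
    toupper(gsub("[[:space:]]", "", chartr("uU", "TT", probe)))
  site <- rev_comp(seqp)
  m <- nchar(site)
  tmask <- target_masks(target)
  if (m > length(tmask)) stop("probe longer than target")
  site_mask <- unname(iupac_mask[strsplit(site, "", fixed = TRUE)[[1]]])
  mism <- hamming_profile(site_mask, tmask)
  ok <- which(mism <= max_mismatch)
  res <- data.frame(start = ok, mismatches = mism[ok],
                    indel = rep("none", length(ok)),
                    stringsAsFactors = FALSE)
  if (allow_single_indel && max_mismatch >= 1) {
    gap <- list()
    # deletion: the target lacks one site base (window m-1)
    for (k in seq_len(m)) {
      p <- hamming_profile(site_mask[-k], tmask) + 1L
      ok <- which(p <= max_mismatch)
      if (length(ok)) gap[[length(gap) + 1]] <- data.frame(
        start = ok, mismatches = p[ok], indel = sprintf("del@%d", k))
    }
    # insertion: the target carries one extra base inside the site (window m+1)
    nw <- length(tmask) - m
    if (nw >= 1) {
      for (k in seq_len(m + 1)) {
        idx_keep <- setdiff(seq_len(m + 1), k)
        mm <- integer(nw)
        for (j in seq_len(m)) {
          tj <- idx_keep[j]
          mm <- mm + as.integer(
            bitwAnd(site_mask[j], tmask[tj:(tj + nw - 1)]) == 0L)
        }
        ok <- which(mm + 1L <= max_mismatch)
        if (length(ok)) gap[[length(gap) + 1]] <- data.frame(
          start = ok, mismatches = mm[ok] + 1L, indel = sprintf("ins@%d", k))
      }
    }
    if (length(gap)) {
      gap <- do.call(rbind, gap)
      # keep the best gapped variant per start, and drop gapped hits where an
      # ungapped hit at the same start is at least as good
      gap <- gap[order(gap$start, gap$mismatches), ]
      gap <- gap[!duplicated(gap$start), ]
      plain <- stats::setNames(res$mismatches, res$start)
      worse <- gap$start %in% names(plain) &
        gap$mismatches >= plain[as.character(gap$start)]
      res <- rbind(res, gap[!worse, ])
    }
  }
  res <- res[order(res$mismatches, res$start), ]
  rownames(res) <- NULL
  res
}

#' Hamming distance between a probe and its competitor
#'
#' Competitor probes are designed against weakly mismatched non-target
#' sequences and should differ from the labeled probe at exactly the
#' discriminating position(s).
#'
#' @param probe,competitor [probe_spec()] objects (or sequences) of equal
#'   length.
#' @return List with `distance` and 1-based `positions` of difference.
#' @export
competitor_check <- function(probe, competitor) {
  a <- if (inherits(probe, "probe_spec")) probe$sequence else
    toupper(gsub("[[:space:]]", "", probe))
  b <- if (inherits(competitor, "probe_spec")) competitor$sequence else
    toupper(gsub("[[:space:]]", "", competitor))
  if (nchar(a) != nchar(b)) stop("probe and competitor lengths differ")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  pos <- which(ca != cb)
  list(distance = length(pos), positions = pos)
}

#' Per-taxon probe coverage table
#'
#' For each probe and each listed taxon, the percent of that taxon's
#' sequences containing at least one binding site within `max_mismatch`.
#' Sequences whose taxonomy is not among the listed taxa are tallied in a
#' `total_other_hits` count column. A listed taxon with no sequences is
#' reported as `NA` (not applicable), not 0. Percentages are monotone
#' non-decreasing in `max_mismatch`.
#'
#' @param probes List of [probe_spec()] (or a single one).
#' @param sequences Named character vector or [Biostrings::DNAStringSet].
#' @param taxonomy Data.frame `sequence_id, taxonomy`.
#' @param max_mismatch Mismatch allowance (default 0).
#' @param taxa Taxa forming the table columns (default: those present).
#' @param allow_single_indel Passed to [match_probe()].
#' @return Data.frame: `probe`, one percent column per taxon,
#'   `total_other_hits`.
#' @export
coverage_table <- function(probes, sequences, taxonomy, max_mismatch = 0,
                           taxa = NULL, allow_single_indel = FALSE) {
  if (inherits(probes, "probe_spec")) probes <- list(probes)
  seqs <- as.character(sequences)
  if (is.null(names(seqs))) stop("sequences must be named")
  stopifnot(all(c("sequence_id", "taxonomy") %in% names(taxonomy)))
  if (!all(names(seqs) %in% taxonomy$sequence_id)) {
    stop("every sequence needs a taxonomy label")
  }
  lab <- stats::setNames(taxonomy$taxonomy, taxonomy$sequence_id)[names(seqs)]
  taxa <- taxa %||% sort(unique(lab))
  rows <- lapply(probes, function(p) {
    hit <- vapply(seqs, function(s) {
      nrow(match_probe(p, s, max_mismatch, allow_single_indel)) > 0
    }, TRUE)
    pct <- vapply(taxa, function(tx) {
      members <- lab == tx
      if (!any(members)) return(NA_real_)
      100 * sum(hit[members]) / sum(members)
    }, 0)
    out <- data.frame(probe = if (inherits(p, "probe_spec")) p$name else "probe",
                      stringsAsFactors = FALSE)
    out[paste0("pct_", taxa)] <- as.list(pct)
    out$total_other_hits <- sum(hit[!(lab %in% taxa)])
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Locate a probe on a 16S reference and return its span
#'
#' Finds the probe's binding site on a user-supplied 16S reference sequence
#' (up to `max_mismatch` substitutions; the site must be unique at the best
#' mismatch level) and returns the 1-based inclusive span — the coordinate
#' convention of probe tables. A span declared on the probe is validated
#' against the probe length at construction time.
#'
#' @param probe A [probe_spec()].
#' @param reference Reference 16S sequence (not bundled; supply your own).
#' @param max_mismatch Site search allowance (default 2).
#' @return Named integer vector `c(start, end)`.
#' @export
map_ecoli_positions <- function(probe, reference, max_mismatch = 2) {
  hits <- match_probe(probe, reference, max_mismatch)
  if (nrow(hits) == 0) stop("no binding site found on the reference")
  best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  if (nrow(best) > 1) stop("ambiguous binding site on the reference")
  m <- nchar(if (inherits(probe, "probe_spec")) probe$sequence else probe)
  c(start = best$start[1], end = best$start[1] + m - 1L)
}

#' Write / read a probe table
#'
#' TSV with columns `name, ecoli_start, ecoli_end, target_description,
#' sequence, formamide_pct, competitors` (competitors comma-separated).
#'
#' @param probes Named list of [probe_spec()].
#' @param path File path.
#' @export
write_probes <- function(probes, path) {
  df <- do.call(rbind, lapply(probes, function(p) data.frame(
    name = p$name, ecoli_start = p$ecoli_start, ecoli_end = p$ecoli_end,
    target_description = p$target_description, sequence = p$sequence,
    formamide_pct = p$formamide_pct,
    competitors = paste(p$competitors, collapse = ","),
    stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probes
#' @export
read_probes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    comp <- df$competitors[i]
    probe_spec(df$name[i], df$sequence[i], df$ecoli_start[i],
               df$ecoli_end[i], df$target_description[i],
               df$formamide_pct[i],
               if (is.na(comp) || comp == "") character(0) else
                 strsplit(comp, ",")[[1]])
  })
  stats::setNames(out, df$name)
}
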