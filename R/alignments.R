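#' Simulate multi-sample read alignments against a synthetic community
#'
#' Emulates mapping of paired-end reads back to the community's scaffolds.
#' For each sample, each genome receives read pairs in proportion to its
#' relative abundance: the genome's expected depth is
#' `abundance * n_genomes * depth_per_sample`, so `depth_per_sample` is the
#' community-mean depth. Fragment start positions are uniform over the
#' genome; a read is emitted only if it lies fully within one scaffold, so
#' pairs whose insert spans a scaffold junction surface as cross-scaffold
#' mate pairs — the signal [build_linkage()] consumes. Reads are error-free
#' with the mismatch count (`nm`) set explicitly, so identity/aligned-length
#' filters are exercisable downstream.
#'
#' @param truth A `community_truth` from [generate_community()].
#' @param depth_per_sample Community-mean per-base depth per sample.
#' @param read_bp Read length (default 150, short-insert HiSeq-like).
#' @param insert_bp Insert (outer fragment) size, default 300.
#' @param count_model `"poisson"` (default) or `"nbinom"` pair counts per
#'   genome; `nb_size` is the negative-binomial size (dispersion) parameter.
#' @param nb_size Negative-binomial size when `count_model = "nbinom"`.
#' @param library_type Label recorded on every record: `"pe"` or `"mp"`.
#'
#' @return A data.frame of alignment records with columns `qname, flag,
#'   rname, pos, mapq, cigar, mrnm, mpos, tlen, read_len, nm, sample,
#'   library`. One row per mapped read; SAM flag bits follow the standard
#'   (paired 0x1, mate-unmapped 0x8, first/second 0x40/0x80).
#' @export
simulate_alignments <- function(truth, depth_per_sample = 20,
                                read_bp = 150, insert_bp = 300,
                                count_model = c("poisson", "nbinom"),
                                nb_size = 10, library_type = "pe") {
  stopifnot(inherits(truth, "community_truth"))
  count_model <- match.arg(count_model)
  if (length(truth$scaffolds) == 0) stop("empty truth: no scaffolds")
  if (depth_per_sample <= 0) stop("depth_per_sample must be > 0")
  if (read_bp >= min(Biostrings::width(truth$scaffolds))) {
    stop("read_bp must be shorter than the shortest scaffold")
  }
  spec <- truth$spec
  ab <- spec$abundance_matrix
  samples <- colnames(ab)
  gids <- genome_ids(spec)
  glen <- Biostrings::width(truth$genomes)
  if (any(insert_bp > glen)) stop("insert_bp exceeds a genome length")

  out <- list()
  for (s in seq_along(samples)) {
    for (g in seq_len(spec$n_genomes)) {
      depth_gs <- ab[g, s] * spec$n_genomes * depth_per_sample
      if (depth_gs == 0) next
      G <- glen[g]
      S <- G - insert_bp + 1
      lambda <- depth_gs * G / (2 * read_bp)
      rec <- with_stream(spec$seed, c("aln", s, g), {
        n_pairs <- switch(count_model,
          poisson = stats::rpois(1, lambda),
          nbinom = stats::rnbinom(1, mu = lambda, size = nb_size))
        if (n_pairs == 0) return(NULL)
        f <- sample.int(S, n_pairs, replace = TRUE)
        fmap <- truth$scaffold_map[truth$scaffold_map$genome_id == gids[g], ]
        fmap <- fmap[order(fmap$scaffold_order), ]
        locate <- function(rs, re) {
          idx <- findInterval(rs, fmap$genome_start)
          ok <- re <= fmap$genome_end[idx]
          list(idx = idx, ok = ok, pos = rs - fmap$genome_start[idx] + 1L)
        }
        r1 <- locate(f, f + read_bp - 1L)
        r2 <- locate(f + insert_bp - read_bp, f + insert_bp - 1L)
        qn <- sprintf("%s_%s_%07d", samples[s], gids[g], seq_len(n_pairs))
        mk <- function(self, mate, first) {
          keep <- self$ok
          if (!any(keep)) return(NULL)
          mate_ok <- mate$ok[keep]
          flag <- 1L + ifelse(mate_ok, 0L, 8L) + if (first) 64L else 128L
          flag <- flag + ifelse(mate_ok, 2L + if (first) 32L else 16L,
                                if (first) 0L else 16L)
          same <- mate_ok & fmap$scaffold_id[mate$idx[keep]] ==
            fmap$scaffold_id[self$idx[keep]]
          data.frame(
            qname = qn[keep], flag = flag,
            rname = fmap$scaffold_id[self$idx[keep]],
            pos = self$pos[keep], mapq = 60L,
            cigar = sprintf("%dM", read_bp),
            mrnm = ifelse(mate_ok, fmap$scaffold_id[mate$idx[keep]], "*"),
            mpos = ifelse(mate_ok, mate$pos[keep], 0L),
            tlen = ifelse(same, if (first) insert_bp else -insert_bp, 0L),
            read_len = read_bp, nm = 0L,
            stringsAsFactors = FALSE)
        }
        rbind(mk(r1, r2, TRUE), mk(r2, r1, FALSE))
      })
      if (!is.null(rec)) {
        rec$sample <- samples[s]
        rec$library <- library_type
        out[[length(out) + 1]] <- rec
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Analytic expected per-scaffold depth of the simulator
#'
#' Closed-form expectation of [simulate_alignments()]'s mean per-base depth
#' for every scaffold and sample, accounting for the loss of reads that
#' would cross scaffold junctions.
#'
#' @inheritParams simulate_alignments
#' @return A data.frame `scaffold_id, sample, expected_depth`.
#' @export
expected_depth <- function(truth, depth_per_sample = 20,
                           read_bp = 150, insert_bp = 300) {
  spec <- truth$spec
  ab <- spec$abundance_matrix
  gids <- genome_ids(spec)
  glen <- Biostrings::width(truth$genomes)
  rows <- list()
  for (s in colnames(ab)) {
    for (g in seq_len(spec$n_genomes)) {
      depth_gs <- ab[g, s] * spec$n_genomes * depth_per_sample
      G <- glen[g]
      S <- G - insert_bp + 1
      lambda <- depth_gs * G / (2 * read_bp)
      fmap <- truth$scaffold_map[truth$scaffold_map$genome_id == gids[g], ]
      nstarts <- function(lo, hi) pmax(0, pmin(hi, S) - pmax(lo, 1) + 1)
      c1 <- nstarts(fmap$genome_start, fmap$genome_end - read_bp + 1)
      c2 <- nstarts(fmap$genome_start - insert_bp + read_bp,
                    fmap$genome_end - insert_bp + 1)
      rows[[length(rows) + 1]] <- data.frame(
        scaffold_id = fmap$scaffold_id, sample = s,
        expected_depth = read_bp * (c1 + c2) * lambda / (S * fmap$length_bp),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write alignment records as a SAM file
#'
#' Emits a standards-conformant SAM file (one per call; filter by the
#' `sample` column first for per-sample files) with `@SQ` header lines for
#' every scaffold and the mismatch count as an `NM:i:` tag. Sequence and
#' quality columns are `*`: the simulator's reads are error-free and the
#' pipeline never needs the bases.
#'
#' @param records Alignment record data.frame ([simulate_alignments()] shape).
#' @param scaffolds Named [Biostrings::DNAStringSet] of reference scaffolds.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(records, scaffolds, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(scaffolds),
                      Biostrings::width(scaffolds)))
  rnext <- ifelse(records$mrnm == records$rname & records$mrnm != "*",
                  "=", records$mrnm)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*\tNM:i:%d",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, rnext, records$mpos,
                  records$tlen, records$nm)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read alignment records from a SAM file
#'
#' Converts via [Rsamtools::asBam()] and scans the standard fields plus the
#' `NM` tag, returning the package's alignment record data.frame. The read
#' length is recovered from the CIGAR query width (soft clips included), so
#' files without stored sequences round-trip exactly.
#'
#' @param path SAM file path.
#' @param sample Sample identifier to stamp on the records.
#' @return Alignment record data.frame (see [simulate_alignments()]).
#' @export
read_sam <- function(path, sample = NA_character_) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  cig <- as.character(x$cigar)
  read_len <- rep(NA_integer_, length(cig))
  has <- !is.na(cig)
  read_len[has] <- GenomicAlignments::cigarWidthAlongQuerySpace(cig[has])
  data.frame(
    qname = x$qname, flag = x$flag,
    rname = as.character(x$rname), pos = x$pos, mapq = x$mapq,
    cigar = cig,
    mrnm = ifelse(is.na(as.character(x$mrnm)), "*", as.character(x$mrnm)),
    mpos = ifelse(is.na(x$mpos), 0L, x$mpos),
    tlen = ifelse(is.na(x$isize), 0L, x$isize),
    read_len = read_len,
    nm = if (is.null(x$tag$NM)) NA_integer_ else x$tag$NM,
    sample = sample, library = "pe",
    stringsAsFactors = FALSE)
}
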