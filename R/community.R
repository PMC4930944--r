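#' Specify a synthetic metagenome community
#'
#' A community specification fixes everything the generator needs: the number
#' of genomes, their lengths and GC targets, a genomes-by-samples relative
#' abundance matrix (the premise of differential-coverage binning is that
#' these columns differ), the size of the planted single-copy marker catalog,
#' and how genomes are fragmented into assembly-like scaffolds. Optionally a
#' genome may be declared a perturbed copy of another (a closely related
#' strain), which blurs both its coverage and its marker signatures.
#'
#' @param n_genomes Number of genomes in the community.
#' @param genome_length_bp Genome length(s) in bp; recycled to `n_genomes`.
#' @param gc_target Per-genome GC fraction in (0,1); recycled.
#' @param abundance_matrix Numeric matrix, `n_genomes` rows by one column per
#'   sample; every column must sum to 1 (relative abundances). Column names
#'   become sample identifiers (defaults `S1`, `S2`, ...).
#' @param n_markers Size of the planted single-copy marker catalog
#'   (default 107, the conventional essential-gene catalog size).
#' @param fragment_mean_bp Mean scaffold length for fragmentation. A genome
#'   with `fragment_mean_bp >= genome_length_bp` stays in one scaffold.
#' @param fragment_min_bp Minimum scaffold length (>= 1).
#' @param strain_of Optional `data.frame(genome, parent, rate)` declaring
#'   genome `genome` a copy of `parent` mutated at per-site rate `rate`.
#' @param taxonomy Optional character vector of per-genome taxonomy labels
#'   (e.g. class-level); strains default to their parent's label.
#' @param seed Integer seed; the whole generator is deterministic given it.
#'
#' @return An object of class `community_spec`.
#' @seealso [generate_community()], [simulate_alignments()]
#' @export
community_spec <- function(n_genomes,
                           genome_length_bp = 1e5,
                           gc_target = 0.5,
                           abundance_matrix = NULL,
                           n_markers = 107,
                           fragment_mean_bp = 10000,
                           fragment_min_bp = 1000,
                           strain_of = NULL,
                           taxonomy = NULL,
                           seed = 1) {
  stopifnot(n_genomes >= 1, n_markers >= 1, fragment_min_bp >= 1)
  genome_length_bp <- rep_len(as.numeric(genome_length_bp), n_genomes)
  gc_target <- rep_len(as.numeric(gc_target), n_genomes)
  if (any(genome_length_bp <= 0)) stop("all genome lengths must be > 0")
  if (any(gc_target <= 0 | gc_target >= 1)) stop("gc_target must lie in (0,1)")
  if (any(fragment_min_bp > genome_length_bp)) {
    stop("invalid spec: fragment_min_bp exceeds a genome length")
  }
  if (is.null(abundance_matrix)) {
    abundance_matrix <- matrix(1 / n_genomes, n_genomes, 2)
  }
  abundance_matrix <- as.matrix(abundance_matrix)
  if (nrow(abundance_matrix) != n_genomes) {
    stop("abundance_matrix must have one row per genome")
  }
  if (any(abundance_matrix < 0)) stop("abundances must be non-negative")
  csum <- colSums(abundance_matrix)
  if (any(abs(csum - 1) > 1e-9)) {
    stop("abundance_matrix columns must each sum to 1 (tolerance 1e-9)")
  }
  if (is.null(colnames(abundance_matrix))) {
    colnames(abundance_matrix) <- paste0("S", seq_len(ncol(abundance_matrix)))
  }
  sig_len <- 63L
  spacing <- (genome_length_bp - sig_len) / n_markers
  if (any(spacing < sig_len + 1)) {
    stop("genomes too short to plant ", n_markers,
         " non-overlapping marker signatures")
  }
  if (!is.null(strain_of)) {
    strain_of <- as.data.frame(strain_of)
    stopifnot(all(c("genome", "parent", "rate") %in% names(strain_of)))
    if (any(strain_of$genome == strain_of$parent) ||
        any(strain_of$parent %in% strain_of$genome)) {
      stop("strain parents must themselves be non-strain genomes")
    }
  }
  if (is.null(taxonomy)) {
    taxonomy <- sprintf("Taxon%02d", seq_len(n_genomes))
    if (!is.null(strain_of)) {
      taxonomy[strain_of$genome] <- taxonomy[strain_of$parent]
    }
  }
  structure(list(
    n_genomes = as.integer(n_genomes),
    genome_length_bp = genome_length_bp,
    gc_target = gc_target,
    abundance_matrix = abundance_matrix,
    n_markers = as.integer(n_markers),
    fragment_mean_bp = fragment_mean_bp,
    fragment_min_bp = fragment_min_bp,
    strain_of = strain_of,
    taxonomy = taxonomy,
    signature_length = sig_len,
    seed = as.integer(seed)
  ), class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat("community_spec:", x$n_genomes, "genomes,",
      ncol(x$abundance_matrix), "samples,",
      x$n_markers, "planted markers, seed", x$seed, "\n")
  invisible(x)
}

genome_ids <- function(spec) sprintf("G%02d", seq_len(spec$n_genomes))
marker_ids <- function(n) sprintf("ESCG_%03d", seq_len(n))

# Fragment one genome into scaffold coordinates, never cutting through a
# planted signature. Returns a data.frame of genome-coordinate intervals.
fragment_coords <- function(L, mean_bp, min_bp, sig_starts, sig_len) {
  starts <- integer(0); ends <- integer(0)
  pos <- 1
  while (pos <= L) {
    remaining <- L - pos + 1
    if (remaining <= mean_bp) {
      len <- remaining
    } else {
      len <- round(stats::rnorm(1, mean_bp, 0.2 * mean_bp))
      len <- max(min_bp, min(len, remaining))
      if (remaining - len < min_bp) len <- remaining
    }
    e <- pos + len - 1
    # shift the cut right past any signature it would split
    inside <- which(sig_starts <= e & sig_starts + sig_len - 1 > e)
    if (length(inside)) e <- max(sig_starts[inside]) + sig_len - 1
    if (L - e < min_bp && e < L) e <- L
    starts <- c(starts, pos); ends <- c(ends, e)
    pos <- e + 1
  }
  data.frame(start = starts, end = ends)
}

#' Generate a synthetic community with known ground truth
#'
#' Builds every genome as random DNA at its GC target, plants the full
#' single-copy marker catalog as unique 63-bp signature subsequences at
#' evenly spaced positions, copies and mutates strain genomes, fragments
#' each genome into scaffolds (never through a signature), and records the
#' complete ground truth: scaffold-to-genome mapping, planted marker
#' positions with taxonomy labels, within-genome scaffold adjacency, and the
#' signature registry that [detect_markers()] consumes in signature mode.
#' Re-running with an identical spec is bit-identical.
#'
#' @param spec A [community_spec()].
#' @return An object of class `community_truth`: a list with elements
#'   `genomes` and `scaffolds` ([Biostrings::DNAStringSet]), `scaffold_map`,
#'   `planted_markers`, `adjacency`, `signatures` (data.frames), `catalog`
#'   (a [marker_catalog()]) and the `spec`.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  gids <- genome_ids(spec)
  mids <- marker_ids(spec$n_markers)
  sig_len <- spec$signature_length
  is_strain <- rep(FALSE, spec$n_genomes)
  if (!is.null(spec$strain_of)) is_strain[spec$strain_of$genome] <- TRUE

  genomes <- vector("list", spec$n_genomes)
  sig_rows <- list()
  marker_pos <- vector("list", spec$n_genomes)

  for (g in which(!is_strain)) {
    L <- spec$genome_length_bp[g]
    seqg <- with_stream(spec$seed, c("genome", g),
                        random_dna(L, spec$gc_target[g]))
    pos <- floor((seq_len(spec$n_markers) - 1) * (L - sig_len) / spec$n_markers) + 1
    sigs <- with_stream(spec$seed, c("sig", g),
                        vapply(seq_len(spec$n_markers),
                               function(i) random_dna(sig_len, 0.5), ""))
    chars <- strsplit(seqg, "", fixed = TRUE)[[1]]
    for (i in seq_len(spec$n_markers)) {
      chars[pos[i]:(pos[i] + sig_len - 1)] <- strsplit(sigs[i], "", fixed = TRUE)[[1]]
    }
    genomes[[g]] <- paste(chars, collapse = "")
    marker_pos[[g]] <- pos
    sig_rows[[g]] <- data.frame(
      marker_id = mids, signature = sigs,
      genome_id = gids[g], taxonomy_label = spec$taxonomy[g],
      stringsAsFactors = FALSE)
  }

  if (!is.null(spec$strain_of)) {
    for (k in seq_len(nrow(spec$strain_of))) {
      g <- spec$strain_of$genome[k]
      p <- spec$strain_of$parent[k]
      rate <- spec$strain_of$rate[k]
      chars <- strsplit(genomes[[p]], "", fixed = TRUE)[[1]]
      idx <- with_stream(spec$seed, c("mut", g),
                         which(stats::runif(length(chars)) < rate))
      if (length(idx)) {
        subs <- with_stream(spec$seed, c("mutbase", g), {
          vapply(chars[idx], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, "")
        })
        chars[idx] <- subs
      }
      genomes[[g]] <- paste(chars, collapse = "")
      marker_pos[[g]] <- marker_pos[[p]]
      spec$genome_length_bp[g] <- length(chars)
    }
  }

  # fragment, assemble truth tables
  scaf_seqs <- character(0)
  map_rows <- list(); mk_rows <- list(); adj_rows <- list()
  for (g in seq_len(spec$n_genomes)) {
    L <- nchar(genomes[[g]])
    fr <- with_stream(spec$seed, c("frag", g),
                      fragment_coords(L, spec$fragment_mean_bp,
                                      spec$fragment_min_bp,
                                      marker_pos[[g]], sig_len))
    sids <- sprintf("%s_S%03d", gids[g], seq_len(nrow(fr)))
    pieces <- substring(genomes[[g]], fr$start, fr$end)
    names(pieces) <- sids
    scaf_seqs <- c(scaf_seqs, pieces)
    map_rows[[g]] <- data.frame(
      scaffold_id = sids, genome_id = gids[g],
      scaffold_order = seq_len(nrow(fr)),
      genome_start = fr$start, genome_end = fr$end,
      length_bp = fr$end - fr$start + 1, stringsAsFactors = FALSE)
    if (nrow(fr) > 1) {
      adj_rows[[g]] <- data.frame(
        scaffold_a = sids[-length(sids)], scaffold_b = sids[-1],
        genome_id = gids[g], stringsAsFactors = FALSE)
    }
    scaf_idx <- findInterval(marker_pos[[g]], fr$start)
    mk_rows[[g]] <- data.frame(
      scaffold_id = sids[scaf_idx], marker_id = mids,
      taxonomy_label = spec$taxonomy[g],
      start_bp = marker_pos[[g]] - fr$start[scaf_idx] + 1,
      genome_id = gids[g], stringsAsFactors = FALSE)
  }

  signatures <- do.call(rbind, sig_rows)
  truth <- structure(list(
    genomes = Biostrings::DNAStringSet(structure(unlist(genomes), names = gids)),
    scaffolds = Biostrings::DNAStringSet(scaf_seqs),
    scaffold_map = do.call(rbind, map_rows),
    planted_markers = do.call(rbind, mk_rows),
    adjacency = if (length(adj_rows)) do.call(rbind, adj_rows) else
      data.frame(scaffold_a = character(0), scaffold_b = character(0),
                 genome_id = character(0)),
    signatures = signatures,
    catalog = marker_catalog(mids, signatures = signatures),
    spec = spec
  ), class = "community_truth")
  rownames(truth$scaffold_map) <- NULL
  rownames(truth$planted_markers) <- NULL
  truth
}

#' @export
print.community_truth <- function(x, ...) {
  cat("community_truth:", length(x$genomes), "genomes in",
      length(x$scaffolds), "scaffolds;",
      nrow(x$planted_markers), "planted markers;",
      nrow(x$adjacency), "adjacency junctions\n")
  invisible(x)
}

#' Write a community's FASTA and truth tables to a directory
#'
#' @param truth A `community_truth`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of files written.
#' @export
write_community <- function(truth, dir) {
  stopifnot(inherits(truth, "community_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    scaffolds = file.path(dir, "scaffolds.fasta"),
    genomes = file.path(dir, "genomes.fasta"),
    scaffold_map = file.path(dir, "scaffold_map.tsv"),
    planted_markers = file.path(dir, "planted_markers.tsv"),
    adjacency = file.path(dir, "adjacency.tsv"),
    catalog = file.path(dir, "marker_catalog.tsv"))
  Biostrings::writeXStringSet(truth$scaffolds, files["scaffolds"])
  Biostrings::writeXStringSet(truth$genomes, files["genomes"])
  write_tsv <- function(df, f) utils::write.table(
    df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(truth$scaffold_map, files["scaffold_map"])
  write_tsv(truth$planted_markers[, c("scaffold_id", "marker_id",
                                      "taxonomy_label", "start_bp")],
            files["planted_markers"])
  write_tsv(truth$adjacency, files["adjacency"])
  write_tsv(truth$signatures, files["catalog"])
  invisible(files)
}
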