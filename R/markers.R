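#' A single-copy marker catalog
#'
#' The catalog of essential single-copy genes used for completeness and
#' contamination arithmetic. Each genome is expected to carry each marker
#' exactly once, so distinct markers present measure completeness and
#' repeated markers measure contamination. In synthetic mode the catalog
#' also registers the planted 63-bp signature of every (marker, genome)
#' pair; detection then reduces to exact substring search.
#'
#' @param marker_ids Character vector of unique marker identifiers, or a
#'   single integer n for a default catalog of n markers (default 107).
#' @param signatures Optional data.frame `marker_id, signature, genome_id,
#'   taxonomy_label` (the synthetic registry).
#' @return An object of class `marker_catalog`.
#' @export
marker_catalog <- function(marker_ids = 107, signatures = NULL) {
  if (is.numeric(marker_ids) && length(marker_ids) == 1) {
    marker_ids <- sprintf("ESCG_%03d", seq_len(marker_ids))
  }
  marker_ids <- as.character(marker_ids)
  if (length(marker_ids) == 0) stop("empty catalog")
  if (anyDuplicated(marker_ids)) stop("marker ids must be unique")
  if (!is.null(signatures)) {
    stopifnot(all(signatures$marker_id %in% marker_ids))
  }
  structure(list(marker_ids = marker_ids, signatures = signatures),
            class = "marker_catalog")
}

#' @export
print.marker_catalog <- function(x, ...) {
  cat("marker_catalog:", length(x$marker_ids), "markers",
      if (!is.null(x$signatures)) "(with synthetic signatures)" else "", "\n")
  invisible(x)
}

#' Detect single-copy markers on scaffolds
#'
#' Two detection strategies behind one interface. `"signature"` searches the
#' catalog's registered signature subsequences on both strands by exact
#' match (the synthetic-community route). `"imported"` ingests a hit table
#' from an external HMM/BLAST workflow (`data.frame` or TSV path with
#' columns `scaffold_id, marker_id, taxonomy_label, start_bp`); rows whose
#' marker is not in the catalog are skipped with a warning.
#'
#' @param scaffolds Named [Biostrings::DNAStringSet] (signature mode).
#' @param catalog A [marker_catalog()].
#' @param mode `"signature"` or `"imported"`.
#' @param table Imported hit table or TSV path (imported mode).
#' @return Marker-hit data.frame: `scaffold_id, marker_id, taxonomy_label,
#'   start_bp, strand`.
#' @export
detect_markers <- function(scaffolds = NULL, catalog,
                           mode = c("signature", "imported"), table = NULL) {
  stopifnot(inherits(catalog, "marker_catalog"))
  mode <- match.arg(mode)
  if (mode == "imported") {
    if (is.null(table)) stop("imported mode requires a hit table")
    if (is.character(table)) {
      table <- utils::read.delim(table, stringsAsFactors = FALSE)
    }
    needed <- c("scaffold_id", "marker_id", "taxonomy_label")
    stopifnot(all(needed %in% names(table)))
    if (is.null(table$start_bp)) table$start_bp <- NA_integer_
    bad <- !(table$marker_id %in% catalog$marker_ids)
    if (any(bad)) {
      warning(sum(bad), " imported hit(s) with unknown marker id skipped: ",
              paste(unique(table$marker_id[bad]), collapse = ", "))
      table <- table[!bad, , drop = FALSE]
    }
    table$strand <- table$strand %||% "+"
    out <- table[, c("scaffold_id", "marker_id", "taxonomy_label",
                     "start_bp", "strand")]
    rownames(out) <- NULL
    return(out)
  }
  reg <- catalog$signatures
  if (is.null(reg)) stop("signature mode requires a catalog with a signature registry")
  stopifnot(!is.null(scaffolds), !is.null(names(scaffolds)))
  hits <- list()
  scan <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, scaffolds)
    st <- Biostrings::startIndex(m)
    n <- vapply(st, length, 0L)
    idx <- rep(seq_along(scaffolds), n)
    data.frame(scaffold_id = names(scaffolds)[idx],
               start_bp = unlist(st, use.names = FALSE) %||% integer(0),
               strand = rep(strand, length(idx)), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(reg))) {
    fwd <- scan(reg$signature[i], "+")
    rev <- scan(rev_comp(reg$signature[i]), "-")
    found <- rbind(fwd, rev)
    if (nrow(found)) {
      found$marker_id <- reg$marker_id[i]
      found$taxonomy_label <- reg$taxonomy_label[i]
      hits[[length(hits) + 1]] <- found
    }
  }
  if (!length(hits)) {
    return(data.frame(scaffold_id = character(0), marker_id = character(0),
                      taxonomy_label = character(0), start_bp = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, hits)[, c("scaffold_id", "marker_id",
                                  "taxonomy_label", "start_bp", "strand")]
  out <- out[order(out$scaffold_id, out$marker_id, out$start_bp), ]
  rownames(out) <- NULL
  out
}

bin_hits <- function(bin_scaffolds, hits) {
  if (inherits(bin_scaffolds, "genome_bin")) bin_scaffolds <- bin_scaffolds$scaffold_ids
  hits[hits$scaffold_id %in% bin_scaffolds, , drop = FALSE]
}

#' Completeness of a bin from single-copy markers
#'
#' `100 * distinct markers present / catalog size`.
#'
#' @param bin_scaffolds Character vector of scaffold ids (or a `genome_bin`).
#' @param hits Marker hit table ([detect_markers()]).
#' @param catalog A [marker_catalog()].
#' @return Percent in \[0, 100\].
#' @export
completeness <- function(bin_scaffolds, hits, catalog) {
  stopifnot(inherits(catalog, "marker_catalog"))
  if (length(catalog$marker_ids) == 0) stop("empty catalog")
  h <- bin_hits(bin_scaffolds, hits)
  100 * length(unique(h$marker_id)) / length(catalog$marker_ids)
}

#' Marker duplication (contamination proxy) of a bin
#'
#' `100 * (total hits - distinct markers) / catalog size`. Every extra copy
#' of a single-copy marker counts once; a clean single-genome bin scores 0.
#'
#' @inheritParams completeness
#' @return Percent, >= 0.
#' @export
duplication <- function(bin_scaffolds, hits, catalog) {
  stopifnot(inherits(catalog, "marker_catalog"))
  if (length(catalog$marker_ids) == 0) stop("empty catalog")
  h <- bin_hits(bin_scaffolds, hits)
  100 * (nrow(h) - length(unique(h$marker_id))) / length(catalog$marker_ids)
}

#' Majority taxonomy label of a bin's marker hits
#'
#' @inheritParams completeness
#' @return The most frequent `taxonomy_label` among the bin's hits, or
#'   `NA` when the bin has none.
#' @export
bin_taxonomy <- function(bin_scaffolds, hits) {
  h <- bin_hits(bin_scaffolds, hits)
  if (nrow(h) == 0) return(NA_character_)
  names(sort(table(h$taxonomy_label), decreasing = TRUE))[1]
}

#' Write marker hits as TSV
#'
#' @param hits Marker hit table.
#' @param path File path.
#' @export
write_marker_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
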