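#' Build the scaffold linkage graph from spanning read pairs
#'
#' Counts read pairs whose two mates map to two different scaffolds (both
#' records should already have passed [filter_alignments()]) and keeps every
#' unordered scaffold pair supported by at least `min_links` pairs. One
#' spanning pair is indistinguishable from chimeric or mis-mapping noise, so
#' the default threshold is 2. Secondary and supplementary alignments are
#' excluded; intra-scaffold pairs are ignored.
#'
#' @param records Alignment record data.frame with mate scaffold in `mrnm`.
#' @param min_links Minimum spanning pairs per edge (default 2).
#' @return Edge data.frame `scaffold_a, scaffold_b, n_links, library` with
#'   `scaffold_a < scaffold_b`; `library` is `pe`, `mp` or `mixed`.
#' @export
build_linkage <- function(records, min_links = 2) {
  pri <- !bitwAnd(records$flag, 4L) & !bitwAnd(records$flag, 256L) &
    !bitwAnd(records$flag, 2048L)
  r <- records[pri & records$mrnm != "*" & !is.na(records$mrnm) &
                 records$mrnm != records$rname, , drop = FALSE]
  empty <- data.frame(scaffold_a = character(0), scaffold_b = character(0),
                      n_links = integer(0), library = character(0))
  if (nrow(r) == 0) return(empty)
  a <- pmin(r$rname, r$mrnm)
  b <- pmax(r$rname, r$mrnm)
  lib <- if (is.null(r$library)) rep("pe", nrow(r)) else r$library
  # each spanning pair contributes one record per mate; count unique read ids
  key <- paste(a, b, sep = "\r")
  df <- data.frame(key = key, qname = r$qname, library = lib,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$key, df$qname)), , drop = FALSE]
  n <- tapply(df$qname, df$key, length)
  libs <- tapply(df$library, df$key, function(l) {
    u <- unique(l); if (length(u) == 1) u else "mixed"
  })
  keys <- names(n)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(scaffold_a = vapply(parts, `[`, "", 1),
                    scaffold_b = vapply(parts, `[`, "", 2),
                    n_links = as.integer(n),
                    library = as.character(libs),
                    stringsAsFactors = FALSE)
  out <- out[out$n_links >= min_links, , drop = FALSE]
  out <- out[order(out$scaffold_a, out$scaffold_b), ]
  rownames(out) <- NULL
  out
}

#' Expand a bin along linkage edges
#'
#' Breadth-first growth: each round adds every scaffold connected by an edge
#' to the current set. Monotone; `rounds = 0` is the identity and a fixed
#' point is reached in at most as many rounds as there are scaffolds.
#'
#' @param bin Character vector of seed scaffold ids (or a `genome_bin`).
#' @param edges Edge data.frame from [build_linkage()].
#' @param rounds Number of expansion rounds (default 1).
#' @return List with `scaffolds` (seed plus additions) and `added` (the
#'   additions only, in the order discovered).
#' @export
expand_bin <- function(bin, edges, rounds = 1) {
  if (inherits(bin, "genome_bin")) bin <- bin$scaffold_ids
  current <- unique(bin)
  added <- character(0)
  for (i in seq_len(rounds)) {
    touch <- edges$scaffold_a %in% current | edges$scaffold_b %in% current
    nbr <- setdiff(unique(c(edges$scaffold_a[touch], edges$scaffold_b[touch])),
                   current)
    if (length(nbr) == 0) break
    added <- c(added, sort(nbr))
    current <- c(current, sort(nbr))
  }
  list(scaffolds = current, added = added)
}

#' Extract read ids associated with a bin
#'
#' Ids of all reads with either mate mapped to a bin scaffold — the read set
#' one would pull out for re-assembly. Deduplicated and sorted.
#'
#' @param bin Character vector of scaffold ids (or a `genome_bin`).
#' @param records Alignment record data.frame.
#' @return Sorted character vector of read identifiers.
#' @export
extract_read_ids <- function(bin, records) {
  if (inherits(bin, "genome_bin")) bin <- bin$scaffold_ids
  mapped <- !bitwAnd(records$flag, 4L)
  hit <- (mapped & records$rname %in% bin) | records$mrnm %in% bin
  sort(unique(records$qname[hit]))
}

#' Write linkage edges / read ids
#'
#' @param edges Edge data.frame.
#' @param path File path.
#' @export
write_linkage <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_linkage
#' @param ids Character vector of read ids.
#' @export
write_read_ids <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
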