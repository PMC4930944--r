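# Independent brute-force oracles. Deliberately written with different
# algorithms / primitives than the implementations they check.

# N50 straight from the definition: the largest L whose >=L fragments cover
# at least half the total.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  stop("unreachable")
}

# scalar crossing-number point-in-polygon with explicit boundary test
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  on_boundary <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- vx[i]; y1 <- vy[i]; x2 <- vx[j]; y2 <- vy[j]
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cr) < 1e-12 &&
        px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
        py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12) {
      on_boundary <- TRUE
    }
  }
  if (on_boundary) return(TRUE)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    y1 <- vy[i]; y2 <- vy[j]
    if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
      xint <- vx[i] + (py - y1) / (y2 - y1) * (vx[j] - vx[i])
      if (px < xint) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# all-window Hamming scan of a probe's reverse complement, character by
# character, with IUPAC expansion on the target side
oracle_match_probe <- function(probe_seq, target, max_mismatch) {
  site <- strsplit(ebprbin::rev_comp(probe_seq), "")[[1]]
  tch <- strsplit(chartr("u", "U", toupper(target)), "")[[1]]
  tch[tch == "U"] <- "T"
  m <- length(site)
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  for (s in seq_len(length(tch) - m + 1)) {
    mm <- 0L
    for (k in seq_len(m)) {
      tset <- iupac_sets[[tch[s + k - 1]]]
      if (is.null(tset) || !(site[k] %in% tset)) mm <- mm + 1L
    }
    if (mm <= max_mismatch) {
      hits <- rbind(hits, data.frame(start = s, mismatches = mm))
    }
  }
  hits
}

# spanning-pair counter: walk read ids, look the mates up pairwise
oracle_linkage_counts <- function(records) {
  counts <- list()
  mapped <- records[!bitwAnd(records$flag, 4L) &
                      !bitwAnd(records$flag, 256L) &
                      !bitwAnd(records$flag, 2048L), , drop = FALSE]
  for (q in unique(mapped$qname)) {
    rows <- mapped[mapped$qname == q, , drop = FALSE]
    scafs <- unique(rows$rname[rows$mrnm != "*" & rows$mrnm != rows$rname])
    pairs <- unique(rows[rows$mrnm != "*" & rows$mrnm != rows$rname,
                         c("rname", "mrnm")])
    if (nrow(pairs) == 0) next
    key <- paste(pmin(pairs$rname, pairs$mrnm),
                 pmax(pairs$rname, pairs$mrnm), sep = "|")
    for (k in unique(key)) {
      counts[[k]] <- (counts[[k]] %||% 0) + 1
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run-length based contig splitter
oracle_split_contigs <- function(s, min_n_run) {
  ch <- strsplit(toupper(s), "")[[1]]
  r <- rle(ch == "N")
  out <- character(0)
  pos <- 1
  buf <- ""
  for (i in seq_along(r$lengths)) {
    piece <- substr(s, pos, pos + r$lengths[i] - 1)
    if (r$values[i] && r$lengths[i] >= min_n_run) {
      if (nchar(buf)) out <- c(out, buf)
      buf <- ""
    } else {
      buf <- paste0(buf, piece)
    }
    pos <- pos + r$lengths[i]
  }
  if (nchar(buf)) out <- c(out, buf)
  out
}
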