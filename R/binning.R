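#' A genome bin
#'
#' A named set of scaffold identifiers with the provenance of its selection
#' (which two samples were compared and with what polygon or clustering
#' parameters) and optional per-scaffold flags (`linkage-added`,
#' `duplicate-marker`).
#'
#' @param bin_id Bin identifier.
#' @param scaffold_ids Non-empty character vector of member scaffolds.
#' @param provenance List; should record `sample_x`, `sample_y` and the
#'   selection method/parameters.
#' @param flags Optional data.frame `scaffold_id, flag`.
#' @return An object of class `genome_bin`.
#' @export
genome_bin <- function(bin_id, scaffold_ids, provenance = list(),
                       flags = NULL) {
  scaffold_ids <- unique(as.character(scaffold_ids))
  if (length(scaffold_ids) == 0) stop("a bin must contain scaffolds")
  if (is.null(flags)) {
    flags <- data.frame(scaffold_id = character(0), flag = character(0))
  }
  structure(list(bin_id = bin_id, scaffold_ids = scaffold_ids,
                 provenance = provenance, flags = flags),
            class = "genome_bin")
}

#' @export
print.genome_bin <- function(x, ...) {
  cat("genome_bin", x$bin_id, ":", length(x$scaffold_ids), "scaffolds")
  if (nrow(x$flags)) cat(",", nrow(x$flags), "flagged")
  cat("\n")
  invisible(x)
}

# Even-odd (ray casting) point-in-polygon, boundary points counted inside.
# Vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary: point on segment (i,j)
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-12 & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

check_simple_polygon <- function(vx, vy) {
  n <- length(vx)
  if (n < 3) stop("polygon needs at least 3 vertices")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      p1 <- c(vx[i], vy[i]); p2 <- c(vx[i %% n + 1], vy[i %% n + 1])
      p3 <- c(vx[j], vy[j]); p4 <- c(vx[j %% n + 1], vy[j %% n + 1])
      if (segments_intersect(p1, p2, p3, p4)) {
        stop("self-intersecting polygon")
      }
    }
  }
  invisible(TRUE)
}

#' Select scaffolds inside a polygon in differential-coverage space
#'
#' The programmatic counterpart of drawing a selection on a
#' differential-coverage plot: scaffolds whose
#' `(log10(depth_x + eps), log10(depth_y + eps))` point lies inside or on a
#' polygon are returned. Membership uses the even-odd rule with boundary
#' points counted as inside; the small pseudo-depth `eps` admits scaffolds
#' with zero depth in one sample.
#'
#' @param profiles A `coverage_profiles` data.frame.
#' @param sample_x,sample_y Sample identifiers.
#' @param polygon Two-column matrix (or data.frame) of vertices in
#'   log10-depth space, >= 3 rows, simple (non-self-intersecting).
#' @param eps Pseudo-depth (default 0.01).
#' @return Character vector of selected scaffold ids.
#' @export
select_by_polygon <- function(profiles, sample_x, sample_y, polygon,
                              eps = 0.01) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) stop("polygon needs at least 3 vertices")
  cx <- paste0("depth_", sample_x); cy <- paste0("depth_", sample_y)
  if (!all(c(cx, cy) %in% names(profiles))) {
    stop("samples not present in profiles: ", sample_x, ", ", sample_y)
  }
  check_simple_polygon(polygon[, 1], polygon[, 2])
  px <- log10(profiles[[cx]] + eps)
  py <- log10(profiles[[cy]] + eps)
  profiles$scaffold_id[point_in_polygon(px, py, polygon[, 1], polygon[, 2])]
}

#' Density-connected candidate bins in differential-coverage space
#'
#' Automated stand-in for interactive polygon selection: scaffolds are
#' neighbours when their Euclidean distance in 2-D log10-depth space is at
#' most `radius`; connected components with at least `min_members` members
#' are returned, largest first (ties broken by lexicographically smallest
#' member), so the result is independent of input order.
#'
#' @inheritParams select_by_polygon
#' @param radius Neighbourhood radius in log10-depth units.
#' @param min_members Minimum component size to report (default 3).
#' @return List of character vectors of scaffold ids (each sorted).
#' @export
cluster_coverage <- function(profiles, sample_x, sample_y, radius = 0.15,
                             min_members = 3, eps = 0.01) {
  stopifnot(radius > 0)
  cx <- paste0("depth_", sample_x); cy <- paste0("depth_", sample_y)
  if (!all(c(cx, cy) %in% names(profiles))) {
    stop("samples not present in profiles")
  }
  x <- log10(profiles[[cx]] + eps)
  y <- log10(profiles[[cy]] + eps)
  n <- length(x)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      k <- queue[[1]]; queue <- queue[-1]
      d2 <- (x - x[k])^2 + (y - y[k])^2
      nbr <- which(d2 <= radius^2 & comp == 0L)
      if (length(nbr)) {
        comp[nbr] <- cur
        queue <- c(queue, nbr)
      }
    }
  }
  groups <- split(profiles$scaffold_id, comp)
  groups <- lapply(groups, sort)
  groups <- groups[vapply(groups, length, 0L) >= min_members]
  ord <- order(-vapply(groups, length, 0L),
               vapply(groups, `[`, "", 1))
  unname(groups[ord])
}

#' Refine a candidate bin with linkage and marker evidence
#'
#' Three deterministic steps: (1) expand the candidate along the scaffold
#' linkage graph (`rounds` BFS rounds); (2) flag scaffolds whose removal
#' would eliminate a duplicated single-copy marker while removing less than
#' `max_trim_frac` of the bin's length (these are typical contaminant
#' scaffolds); (3) recompute completeness and duplication. Flagged
#' scaffolds are removed only when `auto_trim = TRUE`.
#'
#' @param candidate Character vector of scaffold ids (or `genome_bin`).
#' @param profiles Coverage profiles (for scaffold lengths).
#' @param hits Marker hits ([detect_markers()]).
#' @param catalog A [marker_catalog()].
#' @param edges Linkage edges ([build_linkage()]).
#' @param rounds Linkage expansion rounds (default 1).
#' @param auto_trim Remove flagged scaffolds (default FALSE).
#' @param max_trim_frac Maximum fraction of bin length a flagged scaffold
#'   may carry (default 0.01).
#' @param bin_id Identifier for the refined bin.
#' @return List with the refined `bin` (a `genome_bin`), `added`, `flagged`,
#'   and `before`/`after` named vectors of completeness and duplication.
#' @export
refine_bin <- function(candidate, profiles, hits, catalog, edges,
                       rounds = 1, auto_trim = FALSE, max_trim_frac = 0.01,
                       bin_id = "bin_1") {
  if (inherits(candidate, "genome_bin")) candidate <- candidate$scaffold_ids
  before <- c(completeness = completeness(candidate, hits, catalog),
              duplication = duplication(candidate, hits, catalog))
  ex <- expand_bin(candidate, edges, rounds)
  members <- ex$scaffolds
  len <- stats::setNames(profiles$length_bp, profiles$scaffold_id)[members]
  len[is.na(len)] <- 0
  bin_len <- sum(len)
  h <- hits[hits$scaffold_id %in% members, , drop = FALSE]
  cnt <- table(h$marker_id)
  dup_markers <- names(cnt)[cnt >= 2]
  flagged <- character(0)
  for (s in members) {
    ms <- h$marker_id[h$scaffold_id == s]
    if (!length(ms)) next
    on_s <- table(ms)
    elim <- any(names(on_s) %in% dup_markers &
                  (cnt[names(on_s)] - on_s) >= 1)
    if (elim && len[s] < max_trim_frac * bin_len) flagged <- c(flagged, s)
  }
  final <- members
  if (auto_trim && length(flagged)) final <- setdiff(members, flagged)
  flags <- rbind(
    if (length(ex$added)) data.frame(scaffold_id = ex$added,
                                     flag = "linkage-added"),
    if (length(flagged)) data.frame(scaffold_id = flagged,
                                    flag = "duplicate-marker"))
  bin <- genome_bin(bin_id, final,
                    provenance = list(method = "refine_bin", rounds = rounds,
                                      auto_trim = auto_trim,
                                      max_trim_frac = max_trim_frac),
                    flags = flags %||%
                      data.frame(scaffold_id = character(0), flag = character(0)))
  after <- c(completeness = completeness(final, hits, catalog),
             duplication = duplication(final, hits, catalog))
  list(bin = bin, added = ex$added, flagged = flagged,
       before = before, after = after)
}

#' Write bin membership as TSV
#'
#' Columns `bin_id, scaffold_id, flag` (flag empty when none).
#'
#' @param bins A `genome_bin` or list of them.
#' @param path File path.
#' @export
write_bins <- function(bins, path) {
  if (inherits(bins, "genome_bin")) bins <- list(bins)
  rows <- lapply(bins, function(b) {
    fl <- stats::setNames(b$flags$flag, b$flags$scaffold_id)
    data.frame(bin_id = b$bin_id, scaffold_id = b$scaffold_ids,
               flag = ifelse(b$scaffold_ids %in% names(fl),
                             fl[b$scaffold_ids], ""),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
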