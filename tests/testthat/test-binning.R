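square_prof <- function(dx, dy) {
  data.frame(scaffold_id = sprintf("s%d", seq_along(dx)), length_bp = 1000L,
             gc_pct = 50, depth_S1 = dx, depth_S2 = dy)
}

test_that("polygon selection in log-depth space follows the even-odd rule", {
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  prof <- square_prof(c(10, 1000), c(10, 1000))
  sel <- select_by_polygon(prof, "S1", "S2", sq)
  expect_equal(sel, "s1")  # (~1,~1) inside; (3,3) outside
  # boundary counts as inside: depth such that log10(d + 0.01) == 2
  prof_b <- square_prof(10^2 - 0.01, 10^2 - 0.01)
  expect_equal(select_by_polygon(prof_b, "S1", "S2", sq), "s1")
  expect_error(select_by_polygon(prof, "S1", "S2", sq[1:2, , drop = FALSE]),
               "3 vertices")
  bowtie <- cbind(c(0, 2, 2, 0), c(0, 2, 0, 2))
  expect_error(select_by_polygon(prof, "S1", "S2", bowtie),
               "self-intersecting")
  expect_error(select_by_polygon(prof, "S1", "zzz", sq), "not present")
})

test_that("polygon membership equals a crossing-number oracle on random points", {
  set.seed(71)
  for (case in 1:5) {
    # random simple (star-shaped) polygon around the origin
    k <- sample(3:8, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    r <- runif(k, 0.5, 2)
    vx <- r * cos(ang); vy <- r * sin(ang)
    px <- runif(200, -2.2, 2.2); py <- runif(200, -2.2, 2.2)
    got <- ebprbin:::point_in_polygon(px, py, vx, vy)
    want <- mapply(oracle_point_in_polygon, px, py,
                   MoreArgs = list(vx = vx, vy = vy))
    expect_identical(got, unname(want))
  }
})

test_that("density clustering separates well-spaced groups deterministically", {
  set.seed(72)
  centers <- list(c(1, 2), c(2, 1))
  dx <- c(); dy <- c()
  for (cc in centers) {
    dx <- c(dx, 10^(cc[1] + runif(50, -0.05, 0.05)))
    dy <- c(dy, 10^(cc[2] + runif(50, -0.05, 0.05)))
  }
  prof <- square_prof(dx, dy)
  cand <- cluster_coverage(prof, "S1", "S2", radius = 0.2, min_members = 3)
  expect_length(cand, 2L)
  expect_equal(vapply(cand, length, 0L), c(50L, 50L))
  # one blanket cluster at huge radius
  expect_length(cluster_coverage(prof, "S1", "S2", radius = 10), 1L)
  # input order does not matter
  shuf <- prof[sample(nrow(prof)), ]
  expect_identical(cluster_coverage(shuf, "S1", "S2", radius = 0.2), cand)
})

test_that("the demo community is recovered genome by genome", {
  run <- demo_run()
  cand <- cluster_coverage(length_filter(run$profiles, 1000), "A", "B",
                           radius = 0.15, min_members = 3)
  rv <- bin_recovery(cand, run$truth)
  expect_true(all(rv$f1 >= 0.95))
})

test_that("equal-abundance genomes are NOT separable by coverage alone", {
  # two genomes with identical abundance in both samples but distinct GC:
  # differential coverage has no contrast to work with, and the suite
  # documents that premise by asserting the failure
  ab <- cbind(A = c(0.5, 0.5), B = c(0.5, 0.5))
  spec <- community_spec(2, genome_length_bp = 5e4, gc_target = c(0.35, 0.65),
                         fragment_mean_bp = 5000, fragment_min_bp = 2000,
                         abundance_matrix = ab, seed = 73)
  tr <- generate_community(spec)
  prof <- compute_coverage(
    filter_alignments(simulate_alignments(tr, depth_per_sample = 20)),
    tr$scaffolds)
  cand <- cluster_coverage(prof, "A", "B", radius = 0.15, min_members = 3)
  rv <- bin_recovery(cand, tr)
  expect_true(all(rv$f1 < 0.95))
})

test_that("refinement adds linked scaffolds and flags duplicate-marker intruders", {
  tr <- small_truth()
  hits <- detect_markers(tr$scaffolds, tr$catalog)
  prof <- compute_coverage(
    filter_alignments(simulate_alignments(tr, depth_per_sample = 10,
                                          read_bp = 100)), tr$scaffolds)
  g1 <- tr$scaffold_map$scaffold_id[tr$scaffold_map$genome_id == "G01"]
  # candidate missing one marker-bearing scaffold that linkage can restore
  missing <- g1[length(g1)]
  cand <- setdiff(g1, missing)
  edges <- data.frame(scaffold_a = g1[length(g1) - 1], scaffold_b = missing,
                      n_links = 5L, library = "pe")
  res <- refine_bin(cand, prof, hits, tr$catalog, edges)
  expect_true(missing %in% res$added)
  expect_gt(res$after["completeness"], res$before["completeness"])

  # candidate polluted by one small foreign scaffold carrying duplicated markers
  tiny <- Biostrings::DNAStringSet(c(intruder = paste0(
    strrep("A", 10),
    paste(tr$signatures$signature[tr$signatures$genome_id == "G01"][1:2],
          collapse = strrep("T", 10)),
    strrep("A", 10))))
  scaf2 <- c(tr$scaffolds, tiny)
  hits2 <- detect_markers(scaf2, tr$catalog)
  prof2 <- rbind(prof, data.frame(scaffold_id = "intruder",
                                  length_bp = Biostrings::width(tiny),
                                  gc_pct = 30, depth_S1 = 1, depth_S2 = 1))
  res2 <- refine_bin(c(g1, "intruder"), prof2, hits2, tr$catalog,
                     edges[0, ], auto_trim = TRUE)
  expect_equal(res2$flagged, "intruder")
  expect_equal(unname(res2$after["duplication"]), 0)
  expect_equal(unname(res2$before["duplication"]), 100 * 2 / 107)

  # no edges, no duplicates: a fixed point
  res3 <- refine_bin(g1, prof, hits, tr$catalog, edges[0, ])
  expect_setequal(res3$bin$scaffold_ids, g1)
  expect_equal(res3$before, res3$after)
})

test_that("bins carry provenance and write to TSV", {
  b <- genome_bin("bin_01", c("a", "b"),
                  provenance = list(sample_x = "A", sample_y = "B",
                                    method = "polygon"),
                  flags = data.frame(scaffold_id = "b",
                                     flag = "linkage-added"))
  f <- tempfile(fileext = ".tsv")
  write_bins(b, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), 2L)
  expect_equal(back$flag[back$scaffold_id == "b"], "linkage-added")
  expect_error(genome_bin("empty", character(0)), "scaffolds")
})
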