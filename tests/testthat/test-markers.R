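test_that("signature detection finds all planted markers, both strands", {
  spec <- community_spec(1, genome_length_bp = 10000, fragment_mean_bp = 10000,
                         abundance_matrix = matrix(1, 1, 1), seed = 41)
  tr <- generate_community(spec)
  hits <- detect_markers(tr$scaffolds, tr$catalog)
  expect_equal(nrow(hits), 107L)
  # reverse-complement the scaffold: every signature now sits on the minus strand
  rc <- Biostrings::reverseComplement(tr$scaffolds)
  names(rc) <- names(tr$scaffolds)
  hits_rc <- detect_markers(rc, tr$catalog)
  expect_equal(nrow(hits_rc), 107L)
  expect_true(all(hits_rc$strand == "-"))
})

test_that("signature detection agrees with a brute-force substring scan", {
  tr <- small_truth()
  hits <- detect_markers(tr$scaffolds, tr$catalog)
  reg <- tr$signatures
  brute <- 0L
  for (i in seq_len(nrow(reg))) {
    for (sid in names(tr$scaffolds)) {
      s <- as.character(tr$scaffolds[[sid]])
      brute <- brute + lengths(regmatches(
        s, gregexpr(reg$signature[i], s, fixed = TRUE)))
      found <- gregexpr(reg$signature[i], s, fixed = TRUE)[[1]]
      expected <- hits$start_bp[hits$scaffold_id == sid &
                                  hits$marker_id == reg$marker_id[i] &
                                  hits$taxonomy_label == reg$taxonomy_label[i] &
                                  hits$strand == "+"]
      expect_setequal(expected, found[found > 0])
    }
  }
  expect_equal(nrow(hits[hits$strand == "+", ]), brute)
})

test_that("imported tables are ingested with unknown markers skipped", {
  cat10 <- marker_catalog(10)
  tab <- data.frame(scaffold_id = c("s1", "s1", "s2"),
                    marker_id = c("ESCG_001", "ESCG_002", "NOT_A_MARKER"),
                    taxonomy_label = "Betaproteobacteria",
                    start_bp = c(10L, 50L, 5L))
  expect_warning(hits <- detect_markers(catalog = cat10, mode = "imported",
                                        table = tab),
                 "NOT_A_MARKER")
  expect_equal(nrow(hits), 2L)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(hits2 <- detect_markers(catalog = cat10, mode = "imported",
                                         table = f))
  expect_equal(hits2, hits)
})

test_that("completeness and duplication arithmetic match their definitions", {
  cat10 <- marker_catalog(10)
  mk_hit <- function(m, s = "sA") data.frame(
    scaffold_id = s, marker_id = m, taxonomy_label = "x", start_bp = 1L,
    strand = "+")
  # 9 distinct, one of them twice
  hits <- do.call(rbind, c(lapply(sprintf("ESCG_%03d", 1:9), mk_hit),
                           list(mk_hit("ESCG_001"))))
  expect_equal(completeness("sA", hits, cat10), 90)
  expect_equal(duplication("sA", hits, cat10), 10)
  expect_equal(completeness("sA", hits[0, ], cat10), 0)
  # one marker present three times, others once
  h3 <- do.call(rbind, c(lapply(sprintf("ESCG_%03d", 1:10), mk_hit),
                         lapply(rep("ESCG_005", 2), mk_hit)))
  expect_equal(duplication("sA", h3, cat10), 2 * 100 / 10)
  expect_equal(completeness("sA", h3, cat10), 100)
  expect_error(completeness("sA", hits, marker_catalog(character(0))))
})

test_that("catalog-107 duplication example: 110 hits over 107 distinct", {
  cat107 <- marker_catalog(107)
  ids <- sprintf("ESCG_%03d", 1:107)
  hits <- data.frame(scaffold_id = "s", marker_id = c(ids, ids[1:3]),
                     taxonomy_label = "x", start_bp = 1L, strand = "+")
  expect_equal(round(duplication("s", hits, cat107), 1), 2.8)
})

test_that("metrics are monotone under merging disjoint bins", {
  tr <- small_truth()
  hits <- detect_markers(tr$scaffolds, tr$catalog)
  g1 <- tr$scaffold_map$scaffold_id[tr$scaffold_map$genome_id == "G01"]
  g2 <- tr$scaffold_map$scaffold_id[tr$scaffold_map$genome_id == "G02"]
  expect_gte(completeness(c(g1, g2), hits, tr$catalog),
             completeness(g1, hits, tr$catalog))
  expect_gte(duplication(c(g1, g2), hits, tr$catalog),
             duplication(g1, hits, tr$catalog))
  # clean single-genome bin: complete and duplication-free
  expect_equal(completeness(g1, hits, tr$catalog), 100)
  expect_equal(duplication(g1, hits, tr$catalog), 0)
  # merged bin duplicates every marker once
  expect_equal(duplication(c(g1, g2), hits, tr$catalog), 100)
})

test_that("majority taxonomy labels a bin", {
  hits <- data.frame(scaffold_id = c("a", "a", "b"),
                     marker_id = sprintf("ESCG_%03d", 1:3),
                     taxonomy_label = c("Beta", "Beta", "Gamma"),
                     start_bp = 1L, strand = "+")
  expect_equal(bin_taxonomy(c("a", "b"), hits), "Beta")
  expect_true(is.na(bin_taxonomy("zzz", hits)))
})
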