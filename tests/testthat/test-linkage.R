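spanning_pair <- function(q, a, b, lib = "pe") {
  rbind(mk_rec(q, flag = 99L, rname = a, mrnm = b, library = lib),
        mk_rec(q, flag = 147L, rname = b, mrnm = a, library = lib))
}

test_that("edges require min_links spanning pairs", {
  rec <- do.call(rbind, lapply(sprintf("p%d", 1:5), spanning_pair,
                               a = "A", b = "B"))
  e <- build_linkage(rec, min_links = 2)
  expect_equal(nrow(e), 1L)
  expect_equal(e$n_links, 5L)
  expect_setequal(c(e$scaffold_a, e$scaffold_b), c("A", "B"))
  single <- spanning_pair("only", "C", "D")
  expect_equal(nrow(build_linkage(single, min_links = 2)), 0L)
  expect_equal(nrow(build_linkage(single, min_links = 1)), 1L)
})

test_that("intra-scaffold pairs and secondary alignments are ignored", {
  intra <- rbind(mk_rec("i", flag = 99L, rname = "A", mrnm = "A"),
                 mk_rec("i", flag = 147L, rname = "A", mrnm = "A"))
  expect_equal(nrow(build_linkage(intra, min_links = 1)), 0L)
  sec <- spanning_pair("s", "A", "B")
  sec$flag <- sec$flag + 256L
  expect_equal(nrow(build_linkage(sec, min_links = 1)), 0L)
})

test_that("mixed libraries are labeled", {
  rec <- rbind(spanning_pair("p1", "A", "B", "pe"),
               spanning_pair("m1", "A", "B", "mp"))
  e <- build_linkage(rec, min_links = 2)
  expect_equal(e$library, "mixed")
})

test_that("edge counts equal the brute-force spanning-pair count", {
  set.seed(55)
  for (case in 1:50) {
    scafs <- sprintf("s%d", 1:6)
    rec <- do.call(rbind, lapply(1:40, function(i) {
      ab <- sample(scafs, 2, replace = TRUE)
      spanning_pair(sprintf("c%d_q%02d", case, i), ab[1], ab[2])
    }))
    e <- build_linkage(rec, min_links = 1)
    oracle <- oracle_linkage_counts(rec)
    got <- setNames(e$n_links, paste(e$scaffold_a, e$scaffold_b, sep = "|"))
    expect_equal(sort(names(got)), sort(names(oracle)))
    for (k in names(oracle)) expect_equal(unname(got[k]), oracle[[k]])
  }
})

test_that("simulated linkage recovers nearly all truth adjacencies at 20x", {
  spec <- community_spec(2, genome_length_bp = 5e4, fragment_mean_bp = 5000,
                         fragment_min_bp = 2000, seed = 61)
  tr <- generate_community(spec)
  rec <- filter_alignments(
    simulate_alignments(tr, depth_per_sample = 20, read_bp = 100,
                        insert_bp = 300))
  e <- build_linkage(rec, min_links = 2)
  edge_key <- paste(e$scaffold_a, e$scaffold_b)
  adj_key <- paste(pmin(tr$adjacency$scaffold_a, tr$adjacency$scaffold_b),
                   pmax(tr$adjacency$scaffold_a, tr$adjacency$scaffold_b))
  expect_gte(mean(adj_key %in% edge_key), 0.95)
})

test_that("bin expansion is monotone BFS reaching a fixed point", {
  edges <- data.frame(scaffold_a = c("A", "B"), scaffold_b = c("B", "C"),
                      n_links = 3L, library = "pe")
  expect_setequal(expand_bin("A", edges, rounds = 1)$scaffolds, c("A", "B"))
  expect_equal(expand_bin("A", edges, rounds = 0)$scaffolds, "A")
  r2 <- expand_bin("A", edges, rounds = 2)
  expect_setequal(r2$scaffolds, c("A", "B", "C"))
  expect_setequal(r2$added, c("B", "C"))
  # fixed point: more rounds change nothing
  expect_setequal(expand_bin("A", edges, rounds = 10)$scaffolds,
                  c("A", "B", "C"))
})

test_that("read extraction follows the either-mate rule and a brute-force scan", {
  tr <- small_truth()
  rec <- simulate_alignments(tr, depth_per_sample = 5, read_bp = 100)
  bin <- tr$scaffold_map$scaffold_id[tr$scaffold_map$genome_id == "G01"][1:2]
  ids <- extract_read_ids(bin, rec)
  brute <- sort(unique(rec$qname[(rec$rname %in% bin &
                                    !bitwAnd(rec$flag, 4L)) |
                                   rec$mrnm %in% bin]))
  expect_identical(ids, brute)
  expect_false(is.unsorted(ids))
  expect_equal(extract_read_ids("no_such_scaffold", rec), character(0))
  # a pair with only one mate in-bin is still included
  lone <- spanning_pair("half_in", bin[1], "G02_S001")
  expect_true("half_in" %in% extract_read_ids(bin[1], rbind(rec, lone)))
})
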