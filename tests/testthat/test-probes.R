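plant_site <- function(probe, left = 30, right = 30, subs = integer(0)) {
  site <- strsplit(rev_comp(probe$sequence), "")[[1]]
  for (k in subs) site[k] <- setdiff(c("A", "C", "G", "T"), site[k])[1]
  paste0(strrep("A", left), paste(site, collapse = ""), strrep("C", right))
}

test_that("probe specs validate alphabet and declared spans", {
  expect_error(probe_spec("bad", "ACGTN"), "non-degenerate")
  expect_error(probe_spec("off", strrep("A", 24), 207, 231), "inconsistent")
  p <- probe_spec("ok", "acg tua", 100, 105)
  expect_equal(p$sequence, "ACGTTA")
})

test_that("bundled probe set has consistent spans and single-mismatch competitors", {
  p <- prop_probes()
  expect_equal(nchar(p$Prop207$sequence),
               p$Prop207$ecoli_end - p$Prop207$ecoli_start + 1)
  expect_equal(nchar(p$Prop470$sequence), 25L)
  expect_equal(competitor_check(p$Prop207, p$Prop207c)$distance, 1L)
  expect_equal(competitor_check(p$Prop207, p$Prop207c)$positions, 12L)
  for (comp in c("Prop470c1", "Prop470c2", "Prop470c3")) {
    expect_equal(competitor_check(p$Prop470, p[[comp]])$distance, 1L)
  }
  expect_equal(competitor_check(p$Prop207, p$Prop207)$distance, 0L)
  expect_error(competitor_check(p$Prop207, p$Prop470), "lengths differ")
})

test_that("exact and mismatched sites are found at the right thresholds", {
  p <- prop_probes()$Prop207
  hit <- match_probe(p, plant_site(p), 0)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 31L)
  expect_equal(hit$mismatches, 0L)
  # two substitutions: invisible at 1 mismatch, found at 2 — the situation
  # where a probe still lights up a non-target strain
  two <- plant_site(p, subs = c(5, 15))
  expect_equal(nrow(match_probe(p, two, 1)), 0L)
  h2 <- match_probe(p, two, 2)
  expect_equal(h2$mismatches, 2L)
  # self-site sanity: RC of the probe matches at position 1
  expect_equal(match_probe(p, rev_comp(p$sequence), 0)$start, 1L)
})

test_that("degenerate target bases match any expansion; others are logged", {
  p <- probe_spec("toy", "ACGT")  # site = RC = ACGT
  expect_equal(nrow(match_probe(p, "ACGT", 0)), 1L)
  expect_equal(nrow(match_probe(p, "RCGT", 0)), 1L)   # R = A/G covers A
  expect_equal(nrow(match_probe(p, "YCGT", 0)), 0L)   # Y = C/T does not
  expect_equal(nrow(match_probe(p, "NNNN", 0)), 1L)
  expect_message(h <- match_probe(p, "AC-TACGT", 1), "non-IUPAC")
  expect_true(any(h$mismatches == 1 & h$start == 1))
  # RNA targets are fine
  expect_equal(nrow(match_probe(p, "ACGU", 0)), 1L)
})

test_that("single-indel sites are reported as one mismatch-equivalent", {
  p <- probe_spec("toy", "ACGTACGTAC")  # site GTACGTACGT
  site <- "GTACGTACGT"
  tgt_del <- paste0("AAAA", sub("^(.{4}).", "\\1", site), "AAAA")  # delete pos 5
  expect_equal(nrow(match_probe(p, tgt_del, 1, allow_single_indel = FALSE)), 0L)
  h <- match_probe(p, tgt_del, 1, allow_single_indel = TRUE)
  expect_true(any(grepl("^del@", h$indel)))
  expect_true(all(h$mismatches >= 1))
  tgt_ins <- paste0("AAAA", substr(site, 1, 4), "T", substr(site, 5, 10), "AAAA")
  h2 <- match_probe(p, tgt_ins, 1, allow_single_indel = TRUE)
  expect_true(any(grepl("^ins@", h2$indel)))
  # without the flag nothing is found
  expect_equal(nrow(match_probe(p, tgt_ins, 1)), 0L)
})

test_that("match lists equal the brute-force all-window scan", {
  set.seed(91)
  for (i in 1:100) {
    probe_seq <- random_seq(sample(8:14, 1))
    target <- random_seq(80)
    mm <- sample(0:3, 1)
    got <- match_probe(probe_spec("p", probe_seq), target, mm)
    want <- oracle_match_probe(probe_seq, target, mm)
    ord <- order(got$start)
    expect_equal(got$start[ord], want$start)
    expect_equal(got$mismatches[ord], want$mismatches)
  }
})

test_that("coverage tables mirror the plan and are monotone in mismatches", {
  probes <- prop_probes()[c("Prop207", "Prop470")]
  plan <- data.frame(
    taxonomy = c("TargetClade", "TargetClade", "NearClade", "Outgroup"),
    probe = c("Prop207", "Prop470", "Prop207", "Prop207"),
    mismatches = c(0L, 0L, 2L, 5L))
  set <- generate_16s_set(probes, c(TargetClade = 6, NearClade = 4,
                                    Outgroup = 3),
                          plan, seq_length = 400, seed = 17)
  ct0 <- coverage_table(probes, set$sequences, set$taxonomy, 0)
  p207 <- ct0[ct0$probe == "Prop207", ]
  expect_equal(p207$pct_TargetClade, 100)
  expect_equal(p207$pct_NearClade, 0)
  expect_equal(p207$pct_Outgroup, 0)
  expect_equal(ct0$pct_TargetClade[ct0$probe == "Prop470"], 100)
  ct2 <- coverage_table(probes, set$sequences, set$taxonomy, 2)
  expect_equal(ct2$pct_NearClade[ct2$probe == "Prop207"], 100)
  # monotone non-decreasing in the allowance, bounded by [0, 100]
  for (mm in 0:2) {
    ct <- coverage_table(probes, set$sequences, set$taxonomy, mm)
    pc <- unlist(ct[grep("^pct_", names(ct))])
    expect_true(all(pc >= 0 & pc <= 100, na.rm = TRUE))
  }
  expect_true(all(
    unlist(ct2[grep("^pct_", names(ct2))]) >=
      unlist(ct0[grep("^pct_", names(ct0))])))
  # taxa listed but empty are NA; off-list hits counted as "other"
  ct_na <- coverage_table(probes, set$sequences, set$taxonomy, 0,
                          taxa = c("TargetClade", "Ghost"))
  expect_true(is.na(ct_na$pct_Ghost[1]))
  expect_equal(ct_na$total_other_hits[ct_na$probe == "Prop207"], 0L)
})

test_that("reference-position mapping locates unique sites", {
  p <- prop_probes()$Prop207
  ref <- paste0(strrep("G", 206), rev_comp(p$sequence), strrep("T", 100))
  span <- map_ecoli_positions(p, ref)
  expect_equal(unname(span), c(207L, 230L))
  expect_equal(span[["end"]] - span[["start"]] + 1, nchar(p$sequence))
  expect_error(map_ecoli_positions(p, strrep("A", 400)), "no binding site")
  amb <- paste0(rev_comp(p$sequence), strrep("T", 20), rev_comp(p$sequence))
  expect_error(map_ecoli_positions(p, amb), "ambiguous")
})

test_that("probe tables round-trip through TSV", {
  probes <- prop_probes()
  f <- tempfile(fileext = ".tsv")
  write_probes(probes, f)
  back <- read_probes(f)
  expect_equal(names(back), names(probes))
  expect_equal(back$Prop470$sequence, probes$Prop470$sequence)
  expect_equal(back$Prop207$competitors, "Prop207c")
})
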