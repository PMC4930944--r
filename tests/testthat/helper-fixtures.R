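# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# two-genome community, 20 kb genomes, 5 kb scaffolds
small_truth <- function(seed = 3) {
  cached(paste0("small_truth_", seed), function() {
    generate_community(community_spec(
      2, genome_length_bp = 2e4, fragment_mean_bp = 5000, seed = seed))
  })
}

# the stock 10-genome, 2-sample demonstration community with alignments,
# filtered records and coverage profiles (used by binning + acceptance)
demo_run <- function(seed = 7) {
  cached(paste0("demo_run_", seed), function() {
    truth <- generate_community(demo_community_spec(seed = seed))
    records <- simulate_alignments(truth, depth_per_sample = 20)
    filtered <- filter_alignments(records)
    profiles <- compute_coverage(filtered, truth$scaffolds)
    list(truth = truth, records = records, filtered = filtered,
         profiles = profiles)
  })
}

# hand-built alignment record rows for filter/linkage unit tests
mk_rec <- function(qname = "r1", flag = 0L, rname = "s1", pos = 1L,
                   cigar = "100M", mrnm = "*", mpos = 0L, read_len = 100L,
                   nm = 0L, sample = "S1", library = "pe") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = 60L, cigar = cigar, mrnm = mrnm, mpos = mpos,
             tlen = 0L, read_len = read_len, nm = nm, sample = sample,
             library = library, stringsAsFactors = FALSE)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# sequence with an exact GC fraction (deterministic base counts)
random_gc_seq <- function(n, gc) {
  g <- round(n * gc / 2); c_ <- round(n * gc) - g
  a <- floor((n - g - c_) / 2); t <- n - g - c_ - a
  paste(sample(rep(c("G", "C", "A", "T"), c(g, c_, a, t))), collapse = "")
}
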