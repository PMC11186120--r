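# Shared fixtures for the test suite. All synthetic data is built in code.

# benchmark-style thresholds (mono through hexa), extended to m = 7, 8 for
# minisatellite coverage
bench_params <- function(extended = FALSE) {
  th <- c("1" = 12, "2" = 5, "3" = 4, "4" = 3, "5" = 3, "6" = 3)
  if (extended) th <- c(th, "7" = 3, "8" = 3)
  mining_params(th, interval = 10L)
}

# analysis-style thresholds used for cohort work
analysis_params <- function() {
  mining_params(c("1" = 8, "2" = 6, "3" = 4, "4" = 3, "5" = 3, "6" = 3),
                interval = 10L)
}

# the three-record worked example: (m, E, start, end) =
# (3,2,4,8), (2,3,9,14), (2,6,24,35)
worked_example_records <- function() {
  data.frame(seq_id = "seq1",
             motif = c("ATG", "AT", "GC"),
             m = c(3L, 2L, 2L),
             exponent = c(2L, 3L, 6L),
             start = c(4L, 9L, 24L),
             end = c(8L, 14L, 35L),
             stringsAsFactors = FALSE)
}

make_ssr <- function(motif, exponent, start, seq_id = "s") {
  m <- nchar(motif)
  data.frame(seq_id = seq_id, motif = motif, m = m,
             exponent = as.integer(exponent), start = as.integer(start),
             end = as.integer(start + m * exponent - 1L),
             stringsAsFactors = FALSE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# a random primitive motif of length m
random_primitive_motif <- function(m) {
  repeat {
    mot <- random_seq(m)
    if (is_primitive_motif(mot)) return(mot)
  }
}

# a small annotated test genome written as GenBank, with one planted
# repeat per CDS
write_test_genbank <- function(path, seed = 11L, params = analysis_params()) {
  plants <- data.frame(motif = c("A", "CGG"), exponent = c(8L, 5L),
                       position = c(301L, 901L), stringsAsFactors = FALSE)
  g <- synth_genome(seed, 1500L, plants, params, seq_id = "TEST_01.1")
  feats <- data.frame(
    gene = c("appY", "accC"), locus_tag = c("b0564", "b3256"),
    product = c("DNA-binding transcriptional activator",
                "acetyl-CoA carboxylase"),
    strand = c("+", "-"), start = c(250L, 850L), end = c(400L, 1000L),
    stringsAsFactors = FALSE)
  write_genbank(g$record, feats, path)
  list(genome = g, features = feats)
}
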