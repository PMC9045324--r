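# Independent oracles and tiny fixture builders used across the suite.

# IUPAC code -> set of concrete bases
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Brute-force position-by-position site scan: for every offset of the site
# over the (optionally circularised) sequence, test base membership in the
# IUPAC set of each site letter. Sequence N matches nothing. Returns cut
# positions (prefix lengths), top strand plus mapped bottom strand.
oracle_find_sites <- function(sequence, site, cut_offset,
                              topology = "linear") {
  L <- nchar(sequence)
  w <- nchar(site)
  subject <- if (topology == "circular" && L >= w)
    paste0(sequence, substr(sequence, 1, w - 1)) else sequence
  n <- nchar(subject)
  if (n < w) return(integer(0))
  chars <- strsplit(subject, "")[[1]]
  scan_one <- function(st) {
    # position-by-position set membership, one vectorised pass per site
    # letter offset
    sc <- strsplit(st, "")[[1]]
    npos <- n - w + 1
    hit <- rep(TRUE, npos)
    for (j in seq_len(w))
      hit <- hit & chars[j:(j + npos - 1)] %in% iupac_sets[[sc[j]]]
    which(hit) - 1L
  }
  cuts <- scan_one(site) + cut_offset
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(site)))
  if (!identical(site, rc))
    cuts <- c(cuts, scan_one(rc) + (w - cut_offset))
  if (topology == "circular") cuts <- cuts %% L
  else cuts <- cuts[cuts > 0 & cuts < L]
  sort(unique(as.integer(cuts)))
}

random_dna <- function(n, gc = 0.7) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# minimal two-record GenBank flat file (one circular, one linear) with CDS
# features, written to a temp file
write_mini_genbank <- function(path) {
  lines <- c(
    "LOCUS       ctgA                 120 bp    DNA     linear   BCT 01-JAN-2024",
    "DEFINITION  test record A.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             10..48",
    '                     /product="IS5 family transposase"',
    "     CDS             complement(60..98)",
    '                     /product="GntR family transcriptional',
    '                     regulator"',
    "     CDS             100..117",
    '                     /product="hypothetical protein"',
    "ORIGIN",
    "        1 atgcatgcat gcatgcatgc atgcatgcat gcatgcatgc atgcatgcat gcatgcatgc",
    "       61 atgcatgcat gcatgcatgc atgcatgcat gcatgcatgc atgcatgcat gcatgcatgc",
    "//",
    "LOCUS       ctgB                  60 bp    DNA     circular BCT 01-JAN-2024",
    "DEFINITION  test record B.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             5..34",
    '                     /product="DeoR transcriptional regulator"',
    "ORIGIN",
    "        1 gggtttaaag ggtttaaagg gtttaaaggg tttaaaggtt aaatttggcc aaatttggcc",
    "//")
  writeLines(lines, path)
  path
}
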