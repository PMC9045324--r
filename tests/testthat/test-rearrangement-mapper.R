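test_that("self-comparison yields one forward block, no events, no SNPs", {
  set.seed(2)
  s <- random_dna(5000, gc = 0.7)
  cmp <- compare_replicons(s, s, k = 21)
  expect_equal(nrow(cmp$blocks), 1L)
  expect_equal(cmp$blocks$orientation, "forward")
  expect_equal(c(cmp$blocks$a_start, cmp$blocks$a_end), c(1L, 5000L))
  expect_equal(cmp$blocks$identity, 1.0)
  expect_equal(nrow(cmp$events), 0L)
  expect_equal(nrow(cmp$snps), 0L)
  # a single anchor covers the identity diagonal
  a <- find_anchors(s, s, k = 21)
  expect_equal(nrow(a[a$orientation == "forward", ]), 1L)
  expect_equal(a$length[a$orientation == "forward"], 5000L)
})

test_that("a reverse-complemented sequence gives one spanning reverse anchor", {
  set.seed(3)
  s <- random_dna(2000, gc = 0.7)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- find_anchors(s, rc, k = 21)
  expect_equal(nrow(a), 1L)
  expect_equal(a$orientation, "reverse")
  expect_equal(a$length, 2000L)
  expect_equal(c(a$pos_a, a$pos_b), c(1L, 1L))
  expect_error(find_anchors("ACGT", s, k = 21), "exceeds")
})

test_that("an interior inversion appears as reverse block between forward flanks", {
  set.seed(4)
  s <- random_dna(10000, gc = 0.7)
  inv <- apply_events(replicon("a", s),
                      data.frame(type = "inversion", locus = 4001,
                                 length = 3000), seed = 1)
  cmp <- compare_replicons(s, inv$replicon)
  expect_equal(nrow(cmp$blocks), 3L)
  expect_equal(cmp$blocks$orientation, c("forward", "reverse", "forward"))
  ev <- cmp$events
  expect_equal(ev$type, "inversion")
  expect_lt(abs(ev$a_locus - 4001), 22)
  # dot-plot export carries the anti-diagonal segment
  path <- tempfile(fileext = ".tsv")
  export_dotplot(cmp$anchors, path)
  dots <- read.table(path, sep = "\t", comment.char = "#",
                     col.names = c("pos_a", "pos_b", "length",
                                   "orientation"))
  expect_true(any(dots$orientation == "reverse"))
  # empty anchor set still writes a parseable header
  p2 <- tempfile(fileext = ".tsv")
  export_dotplot(cmp$anchors[0, ], p2)
  expect_true(startsWith(readLines(p2, n = 1), "# replicontools"))
})

test_that("planted insertions and deletions are typed and located", {
  set.seed(6)
  s <- random_dna(20000, gc = 0.7)
  d <- apply_events(replicon("a", s),
                    data.frame(type = c("insertion", "deletion"),
                               locus = c(5000, 14000),
                               length = c(2000, 1500)), seed = 2)
  cmp <- compare_replicons(s, d$replicon)
  ins <- cmp$events[cmp$events$type == "insertion", ]
  del <- cmp$events[cmp$events$type == "deletion", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(nrow(del), 1L)
  expect_lt(abs(ins$a_locus - 5000), 22)
  expect_lt(abs(ins$position - d$truth$b_position[1]), 22)
  expect_lt(abs(del$a_locus - 14000), 22)
  expect_lt(abs(del$length - 1500), 22)

  # involution: swapping the two replicons swaps the event types
  back <- compare_replicons(d$replicon, s)
  expect_equal(sort(back$events$type), sort(c("deletion", "insertion")))
  expect_lt(abs(back$events$a_locus[back$events$type == "deletion"] -
                  d$truth$b_position[1]), 22)
})

test_that("a translocated block is reported once, not as del + ins", {
  set.seed(8)
  s <- random_dna(30000, gc = 0.7)
  d <- apply_events(replicon("a", s),
                    data.frame(type = "translocation", locus = 5000,
                               length = 1200, dest = 20000), seed = 3)
  cmp <- compare_replicons(s, d$replicon)
  expect_equal(cmp$events$type, "translocation")
  expect_lt(abs(cmp$events$a_locus - 5000), 22)
})

test_that("seeded event sets round-trip through the mapper", {
  set.seed(90)
  types_all <- c("insertion", "deletion", "inversion", "translocation")
  n_ok <- 0; n_runs <- 15
  for (run in seq_len(n_runs)) {
    s <- random_dna(30000, gc = 0.7)
    n_ev <- sample(1:2, 1)
    loci <- sort(sample(seq(3000, 21000, by = 6000), n_ev))
    ev <- data.frame(type = sample(types_all, n_ev, replace = TRUE),
                     locus = loci,
                     length = sample(600:2000, n_ev, replace = TRUE),
                     dest = NA_integer_)
    # translocation displacement must exceed the chaining gap tolerance
    ev$type[ev$type == "translocation" & ev$locus > 15000] <- "deletion"
    ev$dest[ev$type == "translocation"] <- 27000
    if (sum(ev$type == "translocation") > 1)
      ev$type[which(ev$type == "translocation")[2]] <- "deletion"
    d <- apply_events(replicon("a", s), ev, seed = run)
    cmp <- compare_replicons(s, d$replicon)
    hit <- TRUE
    for (r in seq_len(nrow(d$truth))) {
      cand <- cmp$events[cmp$events$type == d$truth$type[r] &
                           abs(cmp$events$a_locus - d$truth$a_locus[r]) <=
                           21, , drop = FALSE]
      if (nrow(cand) == 0L) hit <- FALSE
    }
    if (hit) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, n_runs - 1)
})

test_that("planted substitutions and short indels are recovered exactly", {
  set.seed(12)
  s <- random_dna(30000, gc = 0.7)
  sub_loci <- seq(2000, 20000, by = 2000)
  del_loci <- c(23000, 26000)
  ev <- rbind(
    data.frame(type = "substitution", locus = sub_loci, length = 1),
    data.frame(type = "deletion", locus = del_loci, length = 1))
  d <- apply_events(replicon("a", s), ev, seed = 5)
  cmp <- compare_replicons(s, d$replicon)
  subs <- cmp$snps[cmp$snps$type == "substitution", ]
  dels <- cmp$snps[cmp$snps$type == "deletion", ]
  expect_equal(subs$pos_a, sub_loci)
  expect_equal(dels$pos_a, del_loci)
  truth_subs <- d$truth[d$truth$type == "substitution", ]
  expect_equal(subs$ref, truth_subs$ref)
  expect_equal(subs$alt, truth_subs$alt)
  expect_equal(nrow(cmp$events), 0L)  # nothing at event scale
})

test_that("coding effects follow codon arithmetic on both strands", {
  # forward CDS 4..15 ( ATG GCT TGG TAA ), feature context
  seq_a <- paste0("AAA", "ATGGCTTGGTAA", "TTT")
  fts <- feature_table("a", 4, 15, "+", "CDS", "some protein")
  # GCT -> GCC : synonymous (codon 2, third position = pos 9)
  expect_equal(classify_snp_effect(
    list(pos_a = 9, ref = "T", alt = "C", type = "substitution"),
    fts, seq_a), "synonymous")
  # GCT -> GAT : missense (pos 8)
  expect_equal(classify_snp_effect(
    list(pos_a = 8, ref = "C", alt = "A", type = "substitution"),
    fts, seq_a), "missense")
  # TGG -> TGA : nonsense (pos 12)
  expect_equal(classify_snp_effect(
    list(pos_a = 12, ref = "G", alt = "A", type = "substitution"),
    fts, seq_a), "nonsense")
  # 1-bp deletion in CDS: frameshift; 3-bp: in-frame
  expect_equal(classify_snp_effect(
    list(pos_a = 8, ref = "C", alt = "-", type = "deletion"),
    fts, seq_a), "frameshift")
  expect_equal(classify_snp_effect(
    list(pos_a = 8, ref = "CTT", alt = "-", type = "deletion"),
    fts, seq_a), "indel_inframe")
  # outside any CDS
  expect_equal(classify_snp_effect(
    list(pos_a = 2, ref = "A", alt = "G", type = "substitution"),
    fts, seq_a), "intergenic")

  # reverse strand: CDS on minus strand reading TTACCAAGCCAT backwards
  seq_b <- paste0("AAA", "TTACCAAGCCAT", "TTT")  # revcomp = ATGGCTTGGTAA
  ftsb <- feature_table("a", 4, 15, "-", "CDS", "some protein")
  # top-strand pos 10 is the third base of minus-strand codon 2 (GCT);
  # A->G on top reads T->C in the codon: GCT -> GCC, synonymous
  expect_equal(classify_snp_effect(
    list(pos_a = 10, ref = "A", alt = "G", type = "substitution"),
    ftsb, seq_b), "synonymous")
})
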