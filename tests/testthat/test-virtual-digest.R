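test_that("find_sites matches hand-scanned cut positions", {
  expect_equal(find_sites(replicon("x", "AAATTTAAACCC"), "DraI"), 6L)
  expect_equal(find_sites(replicon("x", "GGATTAATGG"), "AseI"), 4L)
  expect_equal(find_sites(replicon("x", "GGGGGG"), "DraI"), integer(0))
  # N in the sequence never matches
  expect_equal(find_sites(replicon("x", "AAATTNAAACCC"), "DraI"),
               integer(0))
  # duplicate cut positions collapse
  r <- replicon("x", "TTTAAATTTAAA")
  expect_equal(find_sites(r, "DraI"), c(3L, 9L))
})

test_that("non-palindromic sites are found on the bottom strand", {
  enz <- restriction_enzyme("FakeI", "GACGC", 2)
  # revcomp(GACGC) = GCGTC present on top strand => site on bottom strand
  r <- replicon("x", "AAAGCGTCAAAA")
  got <- find_sites(r, enz)
  expect_equal(got, oracle_find_sites(r$sequence, "GACGC", 2))
  expect_length(got, 1L)
  # palindromic site counted once
  r2 <- replicon("y", "AATTTAAATT")
  expect_equal(find_sites(r2, "DraI"),
               oracle_find_sites(r2$sequence, "TTTAAA", 3))
})

test_that("site scanning agrees with the brute-force oracle on random DNA", {
  set.seed(101)
  enzymes <- list(c("TTTAAA", 3), c("ATTAAT", 2), c("CTTAAG", 1),
                  c("TCTAGA", 1), c("GRCGYC", 2))  # incl. ambiguous site
  for (i in 1:40) {
    L <- sample(200:2000, 1)
    s <- random_dna(L, gc = runif(1, 0.3, 0.75))
    topo <- sample(c("linear", "circular"), 1)
    e <- enzymes[[sample(length(enzymes), 1)]]
    enz <- restriction_enzyme("E", e[[1]], as.integer(e[[2]]))
    expect_equal(find_sites(replicon("r", s, topo), enz),
                 oracle_find_sites(s, e[[1]], as.integer(e[[2]]), topo),
                 info = paste("seed case", i))
  }
})

test_that("fragment counts and sums obey the digestion identities", {
  r <- replicon("lin", "AAATTTAAACCC")          # one DraI cut
  expect_equal(sort(digest_replicon(r, "DraI")$fragment_bp), c(6L, 6L))
  rc <- replicon("circ", "AAATTTAAACCC", "circular")
  expect_equal(digest_replicon(rc, "DraI")$fragment_bp, 12L)  # linearised
  expect_equal(digest_replicon(replicon("u", "GGGGCCCC"), "DraI")$fragment_bp,
               8L)                               # uncut linear
  # genome digest = multiset union
  two <- list(replicon("a", "GGGGCC"), replicon("b", "CCCCGG"))
  expect_equal(nrow(digest_genome(two, "DraI")), 2L)

  set.seed(21)
  for (i in 1:25) {
    L <- sample(500:5000, 1)
    topo <- sample(c("linear", "circular"), 1)
    r <- replicon("r", random_dna(L, gc = 0.45), topo)
    for (e in c("DraI", "AseI")) {
      fr <- digest_replicon(r, e)$fragment_bp
      expect_equal(sum(fr), L)
      n_cuts <- length(find_sites(r, e))
      expected_n <- if (topo == "linear") n_cuts + 1L else max(1L, n_cuts)
      expect_length(fr, expected_n)
    }
  }
})

test_that("circular digestion is rotation invariant", {
  set.seed(33)
  for (i in 1:15) {
    s <- random_dna(800, gc = 0.4)
    r1 <- replicon("r", s, "circular")
    k <- sample(799, 1)
    r2 <- replicon("r", paste0(substr(s, k + 1, 800), substr(s, 1, k)),
                   "circular")
    expect_equal(sort(digest_replicon(r1, "DraI")$fragment_bp),
                 sort(digest_replicon(r2, "DraI")$fragment_bp))
  }
})

test_that("visibility filtering drops sub-threshold fragments", {
  fs <- digest_genome(list(replicon("a", random_dna(1000))), "DraI")
  fs2 <- fragment_set("g", "DraI", c(50000, 29000, 31000), "linear")
  vis <- visible_fragments(fs2, gel_model(min_visible_bp = 30000))
  expect_equal(sort(vis$fragment_bp), c(31000, 50000))
  expect_equal(attr(vis, "n_removed"), 1L)
  empty <- visible_fragments(fragment_set("g", "DraI", integer(0), "linear"))
  expect_equal(nrow(empty), 0L)
})

test_that("migration position follows the log-size calibration", {
  gel <- gel_model(a = 140, b = 20)
  expect_equal(migration_position(1e5, gel)$position, 40)
  expect_equal(migration_position(1e6, gel)$position, 20)
  m <- migration_position(c(1e5, 2e5), gel)
  expect_true(m$position[2] < m$position[1])  # bigger runs less far
  out <- migration_position(2e4, gel)
  expect_true(out$compressed)
})

test_that("band matching maximises matches under the error cap", {
  pred <- fragment_set("g", "DraI", c(400000, 300000, 100000, 20000),
                       "linear")
  rep_ <- match_bands(pred, c(410000, 305000, 98000))
  expect_equal(nrow(rep_$matches), 3L)
  expect_length(rep_$unmatched_predicted_visible, 0L)
  expect_length(rep_$unmatched_observed, 0L)
  expect_equal(rep_$n_invisible, 1L)
  expect_true(all(rep_$matches$rel_error <= 0.05))

  ident <- match_bands(fragment_set("g", "E", 100000, "linear"), 100000)
  expect_equal(ident$matches$rel_error, 0)

  off <- match_bands(fragment_set("g", "E", 100000, "linear"), 200000)
  expect_equal(nrow(off$matches), 0L)
  expect_equal(off$unmatched_predicted_visible, 100000)
  expect_equal(off$unmatched_observed, 200000)
})

test_that("match count never exceeds min(|visible predicted|, |observed|)", {
  set.seed(5)
  for (i in 1:20) {
    p <- sample(30000:900000, sample(1:8, 1))
    o <- sample(30000:900000, sample(1:8, 1))
    rep_ <- match_bands(fragment_set("g", "E", p, "linear"), o)
    expect_lte(length(unique(rep_$matches$comigration_group)),
               min(length(p), length(o)))
  }
})

test_that("co-migrating predicted fragments share one observed band", {
  pred <- fragment_set("g", "AseI", c(100000, 101000, 500000), "linear")
  rep_ <- match_bands(pred, c(100500, 498000))
  expect_equal(nrow(rep_$matches), 3L)     # both near-equal fragments match
  grp <- rep_$matches$comigration_group[rep_$matches$observed_bp == 100500]
  expect_length(unique(grp), 1L)           # one shared group
  expect_length(rep_$unmatched_predicted_visible, 0L)
})
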