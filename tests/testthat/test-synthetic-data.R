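test_that("replicon generation is seeded and hits the GC target", {
  r1 <- generate_replicon(5000, 0.72, seed = 9)
  r2 <- generate_replicon(5000, 0.72, seed = 9)
  expect_identical(r1$sequence, r2$sequence)
  expect_false(identical(r1$sequence,
                         generate_replicon(5000, 0.72, seed = 10)$sequence))
  expect_equal(r1$topology, "linear")

  big <- generate_replicon(1000000, 0.72, seed = 3)
  expect_lt(abs(gc_content(big) - 0.72), 0.005)  # binomial sigma ~ 4.5e-4

  at <- generate_replicon(500, 0, seed = 1)
  expect_false(grepl("[GC]", at$sequence))
})

test_that("sim_config validates fields and survives a YAML round trip", {
  cfg <- sim_config(seed = 7, length = 50000, gc_target = 0.7,
                    cassettes = data.frame(category = "transposase",
                                           count = 2, length = 900))
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$length, 50000L)
  expect_equal(back$cassettes$count, 2)
  expect_equal(back$gel$min_visible, 30000)
  expect_error(sim_config(length = -1), "length")
  expect_error(sim_config(gc_target = 1.5), "gc_target")
})

test_that("cassette planting respects windows and recovers categories", {
  r <- generate_replicon(300000, 0.72, seed = 31, id = "p")
  spec <- data.frame(category = "transposase", count = 11, length = 1000,
                     window_start = 160000, window_end = 200000)
  fts <- plant_cassettes(r, spec, seed = 6)
  expect_equal(nrow(fts), 11L)
  expect_true(all(fts$start >= 160000 & fts$end <= 200000))
  expect_true(all(diff(sort(fts$start)) >= 1000))  # non-overlapping
  expect_equal(fts$category, rep("transposase", 11))

  expect_equal(nrow(plant_cassettes(r, spec[0, ], seed = 1)), 0L)
  # impossible packing errors out
  too_many <- data.frame(category = "hypothetical", count = 50,
                         length = 1000, window_start = 1,
                         window_end = 20000)
  expect_error(plant_cassettes(r, too_many, seed = 1, max_tries = 50),
               "cannot place")

  mixed <- plant_cassettes(r, data.frame(
    category = c("transposase", "transcriptional_regulator",
                 "hypothetical"),
    count = c(3, 2, 4), length = c(900, 600, 450)), seed = 8)
  expect_equal(as.vector(table(mixed$category)[c(
    "transposase", "transcriptional_regulator", "hypothetical")]),
    c(3L, 2L, 4L))
})

test_that("event application conserves length bookkeeping exactly", {
  r <- generate_replicon(50000, 0.7, seed = 17)
  ev <- data.frame(type = c("insertion", "deletion", "inversion"),
                   locus = c(10000, 25000, 40000),
                   length = c(700, 400, 900))
  d <- apply_events(r, ev, seed = 2)
  expect_equal(d$replicon$length, 50000 + 700 - 400)
  expect_equal(nrow(d$truth), 3L)

  # empty event list: identity
  expect_identical(apply_events(r, NULL)$replicon$sequence, r$sequence)

  # inversion applied twice restores the original
  inv <- data.frame(type = "inversion", locus = 20000, length = 1500)
  once <- apply_events(r, inv, seed = 1)
  twice <- apply_events(once$replicon, inv, seed = 1)
  expect_identical(twice$replicon$sequence, r$sequence)

  # overlapping events are rejected
  bad <- data.frame(type = c("deletion", "inversion"),
                    locus = c(1000, 1200), length = c(500, 500))
  expect_error(apply_events(r, bad), "overlapping")
})

test_that("donor-copy insertion reproduces the plasmid size arithmetic", {
  r <- generate_replicon(292604, 0.7, seed = 41, id = "p")
  ev <- data.frame(type = "insertion", locus = 204852, length = 6708,
                   donor_start = 50000)
  d <- apply_events(r, ev, seed = 1)
  expect_equal(d$replicon$length, 299312L)  # 292,604 + 6,708
  expect_equal(d$truth$b_position, 204853L)
  # inserted material is the stated donor interval
  expect_identical(substr(d$replicon$sequence, 204853, 204853 + 6707),
                   substr(r$sequence, 50000, 50000 + 6707))

  # explicit material from another replicon inserts verbatim
  donor <- generate_replicon(8000, 0.72, seed = 43, id = "chr")
  frag <- substr(donor$sequence, 1, 6708)
  d2 <- apply_events(r, data.frame(type = "insertion", locus = 204852,
                                   length = 6708, seq = frag), seed = 1)
  expect_identical(substr(d2$replicon$sequence, 204853, 204853 + 6707),
                   frag)
  expect_error(apply_events(r, data.frame(type = "insertion", locus = 100,
                                          length = 10, seq = "ACGT")),
               "disagrees")
})

test_that("inverted-repeat construction satisfies its identities", {
  src <- generate_replicon(170000, 0.7, seed = 23)
  sim <- make_inverted_repeat_plasmid(src, R = 150000, C = 20000)
  expect_equal(sim$full$length, 320000L)
  expect_equal(sim$collapsed$length, 170000L)
  pre <- substr(sim$full$sequence, 1, 150000)
  suf <- substr(sim$full$sequence, 170001, 320000)
  expect_identical(pre, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(suf))))
  expect_error(make_inverted_repeat_plasmid(src, 0, 10), "positive")
  expect_error(make_inverted_repeat_plasmid(src, 160000, 20000), "exceeds")
})

test_that("coverage simulation is an exact seeded step function", {
  tr0 <- simulate_coverage(1000, c(1, 600), baseline = 40, noise = 0,
                           seed = 1)
  expect_equal(tr0$depth, c(rep(80, 600), rep(40, 400)))

  tr1 <- simulate_coverage(120000, c(1, 100000), baseline = 40,
                           noise = 0.15, seed = 4)
  tr2 <- simulate_coverage(120000, c(1, 100000), baseline = 40,
                           noise = 0.15, seed = 4)
  expect_identical(tr1$depth, tr2$depth)
  arm_mean <- mean(tr1$depth[1:100000])
  cen_mean <- mean(tr1$depth[100001:120000])
  expect_lt(abs(arm_mean / cen_mean - 2), 0.02)
})

test_that("gel observation drops, perturbs and merges bands as configured", {
  frags <- fragment_set("p", "DraI", c(500000, 120000, 50000, 20000),
                        "linear")
  exact <- simulate_gel_observation(frags, size_error = 0,
                                    min_visible = 30000, seed = 1)
  expect_equal(exact, c(500000, 120000, 50000))

  noisy <- simulate_gel_observation(frags, size_error = 0.02,
                                    min_visible = 30000, seed = 2)
  expect_length(noisy, 3L)
  expect_true(all(abs(noisy - c(500000, 120000, 50000)) /
                    c(500000, 120000, 50000) < 0.1))
  expect_identical(noisy,
                   simulate_gel_observation(frags, size_error = 0.02,
                                            min_visible = 30000, seed = 2))

  merged <- simulate_gel_observation(
    fragment_set("p", "E", c(100000, 100500), "linear"),
    size_error = 0, min_visible = 30000, merge_within = 0.02, seed = 1)
  expect_length(merged, 1L)
})

test_that("gel round trip: simulated bands match predicted fragments", {
  set.seed(61)
  ok <- 0
  for (i in 1:20) {
    r <- replicon("g", random_dna(200000, gc = 0.68))
    frags <- digest_replicon(r, "DraI")
    obs <- simulate_gel_observation(frags, size_error = 0.02,
                                    min_visible = 30000, seed = 500 + i)
    rep_ <- match_bands(frags, obs, rel_tol = 3 * 0.02)
    vis <- visible_fragments(frags)
    if (nrow(rep_$matches) == nrow(vis)) ok <- ok + 1
  }
  expect_gte(ok, 19)
})
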