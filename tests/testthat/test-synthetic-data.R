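test_that("sequence generation is seed-deterministic with the right AT fraction", {
  a <- random_sequence(1000, 0.6, seed = 1)
  b <- random_sequence(1000, 0.6, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, random_sequence(1000, 0.6, seed = 2)))

  s <- random_sequence(10000, 0.6, seed = 3)
  at <- sum(strsplit(s, "")[[1]] %in% c("A", "T")) / 10000
  expect_lt(abs(at - 0.6), 0.03)
  expect_error(random_sequence(0), "positive")
  expect_error(random_sequence(10, at_fraction = 1.5), "0, 1")
})

test_that("motif-free mode leaves no MRS element hits", {
  s <- random_sequence(5000, 0.62, seed = 4, motif_free = TRUE)
  expect_equal(nrow(scan_motifs(s, "E8")), 0)
  expect_equal(nrow(scan_motifs(s, "E16")), 0)
})

test_that("planted MRSs carry the advertised truth and are recovered", {
  bg <- random_sequence(1200, seed = 5, motif_free = TRUE)

  # the published site-1 geometry: 16-mer end + 48 -> gap +47
  p <- plant_mrs(bg, pos16 = 301, strand16 = "C", mismatches16 = 1,
                 pos8 = 301 + 16 + 47, strand8 = "W", seed = 6)
  expect_equal(p$truth$gap, 47L)
  hits8 <- scan_motifs(p$seq, "E8")
  hits16 <- scan_motifs(p$seq, "E16")
  expect_equal(hits8$start, p$truth$start8)
  expect_equal(hits16$start, p$truth$start16)
  expect_equal(hits16$strand, "C")
  expect_equal(hits16$mismatches, 1L)
  pairs <- pair_elements(hits8, hits16)
  expect_equal(pairs$gap, 47L)

  # 8-mer nested inside the 16-mer: categorical overlap
  po <- plant_mrs(bg, pos16 = 501, strand16 = "W", mismatches16 = 0,
                  pos8 = 503, strand8 = "W", seed = 7, allow_overlap = TRUE)
  expect_true(po$truth$overlap)
  expect_error(plant_mrs(bg, pos16 = 501, pos8 = 503, seed = 7), "overlap")

  # substituting an N position is not a mismatch
  s16 <- realise_pattern_for_test("AWWRTAANNWWGNNNC")
  sub <- s16
  substr(sub, 8, 8) <- setdiff(c("A", "C", "G", "T"), substr(sub, 8, 8))[1]
  expect_equal(count_mismatches(sub, "AWWRTAANNWWGNNNC"), 0)
})

test_that("cleavage-read simulation is deterministic and truth-complete", {
  bundle <- synthetic_bundle()
  picks <- c(129500L, 130700L)
  a <- simulate_cleavage_reads(bundle$ref, bundle$config, picks)
  b <- simulate_cleavage_reads(bundle$ref, bundle$config, picks)
  expect_identical(a$reads, b$reads)
  expect_equal(a$truth$breakpoint, picks)
  expect_equal(a$truth$size,
               picks - bundle$config$if5 + 1L +
                 (bundle$config$ir5 - bundle$config$region_start + 1L))
  expect_error(
    simulate_cleavage_reads(bundle$ref, bundle$config, 999L),
    "outside the region")

  intact <- simulate_cleavage_reads(bundle$ref, bundle$config, integer(0),
                                    mode = "age_only")
  expect_equal(nrow(intact$reads), 1)
  expect_equal(intact$truth$size, bundle$config$intact_size)
  expect_true(is.na(intact$truth$breakpoint))
})

test_that("translocation reads plant exactly k ambiguous junction bases", {
  host <- tibble::tibble(id = "host",
                         seq = random_sequence(2000, seed = 8,
                                               motif_free = TRUE),
                         length = 2000L)
  donor <- tibble::tibble(id = "donor", seq = random_sequence(1500, seed = 9),
                          length = 1500L)
  for (k in c(0L, 4L, 10L)) {
    tr <- simulate_translocation_read(host, donor, break_a = 1000L,
                                      donor_start = 401L, donor_end = 520L,
                                      micro_k = k, flank_5p = 120,
                                      flank_3p = 120)
    # the partner copy now shares exactly k bases with the host continuation
    shared <- junction_microhomology(
      extract_interval(host$seq, 1001, 1025),
      extract_interval(tr$partner$seq, 401, 425))
    expect_equal(shared$length, k)
    expect_equal(nchar(tr$read$seq), 120 + 120 + 120)
  }
  expect_error(
    simulate_translocation_read(host, donor, 1000L, 401L, 410L, micro_k = 11L),
    "exceeds")
})

test_that("band-count simulation is reproducible and well-shaped", {
  a <- simulate_band_counts(c(x = 2, y = 3), seed = 10)
  b <- simulate_band_counts(c(x = 2, y = 3), seed = 10)
  expect_identical(a$counts, b$counts)
  expect_equal(nrow(a$counts), 2 * 3 * 6)
  expect_true(all(a$counts$count >= 0))
})
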