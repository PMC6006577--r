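test_that("mismatch counting follows the IUPAC classes", {
  expect_equal(count_mismatches("AATAACAA", "AATAAYAA"), 0)
  expect_equal(count_mismatches("AATAAGAA", "AATAAYAA"), 1)
  expect_equal(count_mismatches("AAAAAAATTTTGTACC", "AWWRTAANNWWGNNNC"), 1)
  # a reference N satisfies only an N pattern symbol (conservative rule)
  expect_equal(count_mismatches("NATAACAA", "AATAAYAA"), 1)
  expect_equal(count_mismatches("AATAACAN", "AATAAYAA"), 1)
  expect_equal(count_mismatches("AATATAANNTTGAAAC", "AWWRTAANNWWGNNNC"), 0)
  expect_error(count_mismatches("AAT", "AATAAYAA"), "length")
})

test_that("scan reports planted and overlapping hits with exact coordinates", {
  bg <- random_sequence(30, seed = 11, motif_free = TRUE)
  seq <- paste0(substr(bg, 1, 10), "AATAATAA", substr(bg, 19, 30))
  hits <- scan_motifs(seq, "E8")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 11L)
  expect_equal(hits$end, 18L)
  expect_equal(hits$strand, "W")

  # tandem AAT repeats give all three overlapping frames
  hits <- scan_motifs("AATAATAATAATAA", "E8", strands = "W")
  expect_equal(hits$start, c(1L, 4L, 7L))
})

test_that("Crick hits mirror the reverse-complement scan", {
  for (seed in 1:5) {
    seq <- random_sequence(800, at_fraction = 0.6, seed = seed)
    for (el in c("E8", "E16")) {
      fwd <- scan_motifs(seq, el)
      rc <- scan_motifs(revcomp(seq), el)
      expect_equal(nrow(rc), nrow(fwd))
      if (nrow(fwd) == 0) next
      n <- nchar(seq)
      reflected <- dplyr::arrange(
        dplyr::mutate(rc,
                      start2 = n - end + 1L, end2 = n - start + 1L,
                      strand2 = ifelse(strand == "W", "C", "W")),
        start2, strand2)
      expect_equal(reflected$start2, fwd$start)
      expect_equal(reflected$end2, fwd$end)
      expect_equal(reflected$strand2, fwd$strand)
      expect_equal(reflected$mismatches, fwd$mismatches)
    }
  }
})

test_that("scanner agrees with Biostrings degenerate matching", {
  for (seed in 1:3) {
    seq <- random_sequence(2000, at_fraction = 0.6, seed = seed * 7)
    for (el in c("E8", "E16")) {
      pat <- mrs_pattern(el)
      mine <- scan_motifs(seq, el, strands = "W")
      ext <- Biostrings::matchPattern(
        pat$symbols, Biostrings::DNAString(seq),
        max.mismatch = pat$max_mismatch, fixed = "subject")
      expect_equal(mine$start, BiocGenerics::start(ext))
    }
  }
})

test_that("raising the budgets never removes hits or pairs", {
  seq <- random_sequence(3000, at_fraction = 0.65, seed = 42)
  h0 <- scan_motifs(seq, "E16", max_mismatch = 0)
  h1 <- scan_motifs(seq, "E16", max_mismatch = 1)
  key <- function(h) paste(h$start, h$strand)
  expect_true(all(key(h0) %in% key(h1)))

  h8 <- scan_motifs(seq, "E8")
  p200 <- pair_elements(h8, h1, max_gap = 200)
  p250 <- pair_elements(h8, h1, max_gap = 250)
  expect_true(all(paste(p200$start16, p200$start8) %in%
                    paste(p250$start16, p250$start8)))
})

test_that("gap convention reproduces the published arithmetic", {
  expect_equal(element_gap(26055, 26070, 26118, 26125)$gap, 47L)
  expect_equal(element_gap(26613, 26628, 26565, 26572)$gap, -40L)
  expect_true(element_gap(99259, 99274, 99261, 99268)$overlap)
  # the SAR1-resident pair sits at the boundary of the widened rule
  h16 <- tibble::tibble(element = "E16", start = 133546L, end = 133561L,
                        strand = "C", matched_seq = "x", mismatches = 0L)
  h8 <- tibble::tibble(element = "E8", start = 133810L, end = 133817L,
                       strand = "W", matched_seq = "y", mismatches = 0L)
  expect_equal(pair_elements(h8, h16, max_gap = 250)$gap, 248L)
  expect_equal(nrow(pair_elements(h8, h16, max_gap = 200)), 0)
})

test_that("same-element motifs within 200 bp collapse into one MRS", {
  ctl <- abl_mrs_catalogue()
  four <- ctl[ctl$site == 4, ]
  h16 <- tibble::tibble(element = "E16", start = four$start16,
                        end = four$end16, strand = four$strand16,
                        matched_seq = four$seq16, mismatches = 0L)
  h8 <- dplyr::distinct(tibble::tibble(
    element = "E8", start = four$start8, end = four$end8,
    strand = four$strand8, matched_seq = four$seq8, mismatches = 0L))
  pairs <- pair_elements(h8, h16, max_gap = 250)
  expect_equal(dplyr::n_distinct(pairs$mrs_id), 1)
  expect_equal(nrow(pairs), 2)         # both member combinations reported
  expect_setequal(ifelse(pairs$overlap, "Overlap", sprintf("%+d", pairs$gap)),
                  c("Overlap", "-178"))
})

test_that("site clustering merges nearby MRSs and separates distant ones", {
  mk <- function(s16, s8) {
    h16 <- tibble::tibble(element = "E16", start = s16, end = s16 + 15L,
                          strand = "W", matched_seq = "x", mismatches = 0L)
    h8 <- tibble::tibble(element = "E8", start = s8, end = s8 + 7L,
                         strand = "W", matched_seq = "y", mismatches = 0L)
    pair_elements(h8, h16, max_gap = 250)
  }
  # spans ~700 bp apart -> one site; ~2.7 kb apart -> two
  near <- cluster_sites(dplyr::bind_rows(mk(80698, 80726), mk(81422, 81450)),
                        proximity = 1000)
  expect_equal(dplyr::n_distinct(near$site_id), 1)
  far <- cluster_sites(dplyr::bind_rows(mk(105498, 105520), mk(108315, 108340)),
                       proximity = 1000)
  expect_equal(dplyr::n_distinct(far$site_id), 2)
  single <- cluster_sites(mk(500, 530), proximity = 1000)
  expect_equal(unique(single$site_id), 1L)
  expect_error(cluster_sites(mk(500, 530), proximity = -1), ">= 0")
})

test_that("an empty site list tabulates to an empty table with header", {
  tab <- tabulate_sites(cluster_sites(pair_elements(
    scan_motifs("GGGGGGGGGGGGGGGGGGGG", "E8"),
    scan_motifs("GGGGGGGGGGGGGGGGGGGG", "E16"))))
  expect_equal(nrow(tab), 0)
  expect_true(all(c("site_id", "distance", "location") %in% names(tab)))
})
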