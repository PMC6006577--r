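test_that("anchoring maps identity, chimeric and reverse-complement reads", {
  ref <- tibble::tibble(id = "g", seq = random_sequence(4000, seed = 51),
                        length = 4000L)
  read <- extract_interval(ref$seq, 1001, 1500)
  blocks <- anchor_read(read, ref)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$read_start, 1L)
  expect_equal(blocks$read_end, 500L)
  expect_equal(blocks$ref_start, 1001L)
  expect_equal(blocks$strand, "W")

  # chimeric read: two host blocks flanking an unplaced middle
  insert <- random_sequence(180, seed = 52)
  chimera <- paste0(extract_interval(ref$seq, 500, 800), insert,
                    extract_interval(ref$seq, 2000, 2300))
  blocks <- anchor_read(chimera, ref)
  host <- blocks[blocks$ref_id == "g" & blocks$strand == "W", ]
  expect_gte(nrow(host), 2)
  expect_equal(host$ref_start[1], 500L)
  expect_equal(host$ref_end[nrow(host)], 2300L)

  rc_blocks <- anchor_read(revcomp(read), ref)
  expect_equal(rc_blocks$strand, "C")
  expect_equal(rc_blocks$ref_start, 1001L)
  expect_equal(rc_blocks$ref_end, 1500L)

  expect_error(anchor_read(strrep("N", 100), ref), "Unmappable")
})

test_that("simulated amplicons call their planted breakpoints", {
  bundle <- synthetic_bundle()
  picks <- c(129152L, 129823L, 130633L, 131232L)
  sim <- simulate_cleavage_reads(bundle$ref, bundle$config, picks)
  res <- map_reads(sim$reads, bundle$ref, bundle$config)
  expect_equal(sort(res$breakpoints$position), sort(picks))

  intact <- simulate_cleavage_reads(bundle$ref, bundle$config, integer(0),
                                    mode = "age_only")
  res <- map_reads(intact$reads, bundle$ref, bundle$config)
  expect_equal(nrow(res$breakpoints), 0)
})

test_that("junction microhomology is the bounded shared prefix", {
  expect_equal(junction_microhomology("TGCCAGTT", "TGCCTTAA"),
               list(length = 4L, seq = "TGCC"))
  expect_equal(junction_microhomology("CATG", "GATG")$length, 0L)
  expect_equal(junction_microhomology("ACGTACGG", "ACGTACTT"),
               list(length = 6L, seq = "ACGTAC"))
  expect_equal(junction_microhomology("ACGTACGG", "ACGTACGG", max_k = 5)$length,
               5L)
  expect_equal(junction_microhomology("ACG", "ACGTACGG")$length, 3L)
  expect_error(junction_microhomology("", "ACGT"), "Empty")
})

test_that("insert detection follows the donor-maximal junction convention", {
  # shared junction bases are assigned to the insert, so the host breakpoint
  # precedes them even though the exact matcher extends past the junction
  host <- tibble::tibble(id = "host",
                         seq = random_sequence(3000, seed = 61,
                                               motif_free = TRUE),
                         length = 3000L)
  donor <- tibble::tibble(id = "donor", seq = random_sequence(2000, seed = 62),
                          length = 2000L)
  for (k in c(0L, 3L, 7L)) {
    tr <- simulate_translocation_read(host, donor, break_a = 1500L,
                                      donor_start = 601L, donor_end = 800L,
                                      micro_k = k, flank_5p = 150,
                                      flank_3p = 150)
    blocks <- anchor_read(tr$read$seq, dplyr::bind_rows(host, tr$partner))
    ins <- detect_insert(blocks, tr$read$seq, host, tr$partner)
    expect_equal(ins$micro5_len, k)
    expect_equal(ins$break_5p, 1500L)
    expect_equal(ins$insert_len, 200L)
    expect_equal(ins$insert_read_start, 151L)
    expect_equal(ins$donor_start, 601L)
    expect_equal(ins$donor_end_exclusive, 801L)
  }
})

test_that("an insert with no donor placement is reported as unknown", {
  host <- tibble::tibble(id = "host",
                         seq = random_sequence(3000, seed = 63),
                         length = 3000L)
  foreign <- random_sequence(147, seed = 64)
  # guard the junction bases so the foreign segment's bounds are unambiguous
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  substr(foreign, 1, 1) <- other(extract_interval(host$seq, 1525, 1525))
  substr(foreign, 147, 147) <- other(extract_interval(host$seq, 1524, 1524))
  read <- paste0(extract_interval(host$seq, 1001, 1524), foreign,
                 extract_interval(host$seq, 1525, 1595))
  blocks <- anchor_read(read, host)
  ins <- detect_insert(blocks, read, host)
  expect_equal(ins$donor, "unknown")
  expect_equal(ins$insert_len, 147L)
  expect_true(is.na(ins$donor_start))

  # fully covered read: no insert
  plain <- extract_interval(host$seq, 1001, 1600)
  expect_equal(nrow(detect_insert(anchor_read(plain, host), plain, host)), 0)
})

test_that("breakpoint annotation uses inclusive bounds and site distances", {
  model <- abl_gene_model()
  calls <- tibble::tibble(position = c(129000L, 134000L, 130633L, 1000L))
  ann <- annotate_breakpoint(calls, model)
  expect_equal(ann$in_SAR1, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(ann$feature[4], "Exon 1")

  # a user-supplied SAR interval covering the reported break cluster
  sar <- tibble::tibble(label = "SAR_user", start = 129000L, end = 131500L,
                        type = "annotation")
  model2 <- dplyr::bind_rows(tibble::as_tibble(model), sar)
  attributes(model2)[c("gene_id", "gene_length")] <-
    attributes(model)[c("gene_id", "gene_length")]
  class(model2) <- class(model)
  ann2 <- annotate_breakpoint(tibble::tibble(position = abl_breakpoints()$position),
                              model2)
  expect_true(all(ann2$in_SAR_user))

  sites <- tibble::tibble(site_id = 1L, span_start = 500L, span_end = 600L)
  d <- annotate_breakpoint(tibble::tibble(position = c(450L, 550L, 700L)),
                           model, sites = sites)
  expect_equal(d$nearest_site_distance, c(50L, 0L, 100L))
})
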