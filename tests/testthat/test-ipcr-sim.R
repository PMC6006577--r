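toy_with_sites <- function() {
  # 100 nt with XbaI recognitions starting at 20 and 70
  bg <- random_sequence(100, seed = 21, motif_free = TRUE)
  s <- bg
  substr(s, 20, 25) <- "TCTAGA"
  substr(s, 70, 75) <- "TCTAGA"
  s
}

test_that("digestion yields coordinate-ordered fragments with enzyme ends", {
  s <- toy_with_sites()
  frags <- digest(s, "XbaI")
  expect_equal(nrow(frags), 3)
  # T^CTAGA: cut after the site's first base
  expect_equal(frags$start, c(1L, 21L, 71L))
  expect_equal(frags$end, c(20L, 70L, 100L))
  expect_equal(frags$left_end, c("other", "XbaI", "XbaI"))
  expect_equal(frags$right_end, c("XbaI", "XbaI", "other"))
  # digestion conserves total length
  expect_equal(sum(nchar(frags$seq)), nchar(s))
  expect_equal(paste(frags$seq, collapse = ""), s)

  none <- digest("GGGGCCCCGGGGCCCC", "XbaI")
  expect_equal(nrow(none), 1)
  expect_equal(none$left_end, "other")
})

test_that("degenerate recognitions expand (BsaAI YACGTR)", {
  expect_equal(find_sites("TTACGTATT", "BsaAI"), 2L)
  frags <- digest("TTACGTATT", "BsaAI")
  expect_equal(nrow(frags), 2)
  # YAC^GTR: blunt cut after the third recognition base
  expect_equal(frags$end[1], 4L)
})

test_that("apoptotic breaks partition a fragment at the retained base", {
  s <- toy_with_sites()
  frag <- digest(s, "XbaI")[2, ]      # origin 21..70
  kids <- apply_break(frag, 40)
  expect_equal(kids$start, c(21L, 41L))
  expect_equal(kids$end, c(40L, 70L))
  expect_equal(kids$right_end[1], "apoptotic_blunt")
  expect_equal(kids$left_end[2], "apoptotic_blunt")
  expect_equal(sum(nchar(kids$seq)), nchar(frag$seq))
  expect_error(apply_break(frag, 70), "strictly inside")
  expect_error(apply_break(frag, 20), "strictly inside")
})

test_that("fill-in and circularisation follow the overhang arithmetic", {
  s <- toy_with_sites()
  frag <- digest(s, "XbaI")[2, ]      # intact XbaI fragment, 50 bp
  tpl <- fill_and_circularize(frag)
  # both-XbaI circle gains the 4 nt CTAG fill at the downstream end
  expect_equal(nchar(tpl$circle_seq), nchar(frag$seq) + 4)
  # junction reads ...TCTAG|CTAGA... (4 bp duplication; site not regenerated)
  joined <- paste0(substr(tpl$circle_seq, nchar(tpl$circle_seq) - 4,
                          nchar(tpl$circle_seq)),
                   substr(tpl$circle_seq, 1, 5))
  expect_equal(joined, "TCTAGCTAGA")

  # upstream XbaI end + downstream apoptotic blunt end: no bases added
  kids <- apply_break(frag, 40)
  tpl2 <- fill_and_circularize(kids[1, ])
  expect_equal(nchar(tpl2$circle_seq), nchar(kids$seq[1]))
  # circle identity is rotation-invariant
  expect_true(same_circle(tpl2, rotate_template(tpl2, 13)))
  expect_false(same_circle(tpl, tpl2))

  bad <- kids[1, ]
  bad$left_end <- "other"
  expect_error(fill_and_circularize(bad), "Unfillable")
})

test_that("secondary digestion selects templates as the assay intends", {
  bundle <- synthetic_bundle()
  ref <- bundle$ref
  config <- bundle$config
  frags <- digest(ref$seq, "XbaI")
  region <- frags[frags$start == config$region_start, ]
  intact <- fill_and_circularize(region, ref$seq)
  broken <- fill_and_circularize(apply_break(region, 130000L)[1, ], ref$seq)

  kept <- select_templates(list(intact, broken), mode = "age_only",
                           config = config)
  expect_length(kept, 2)

  kept <- select_templates(list(intact, broken), mode = "age_ecoRI",
                           config = config)
  expect_length(kept, 1)
  expect_true(same_circle(kept[[1]], broken))
  expect_match(attr(kept, "excluded")$reason, "EcoRI site")
  # the retained arc never contains the eliminator recognition
  arc <- predict_products(kept[[1]], config$primers)
  expect_equal(length(find_sites(arc$seq[arc$round == "inner"], "EcoRI")), 0)

  no_age <- fill_and_circularize(digest(toy_with_sites(), "XbaI")[2, ])
  kept <- select_templates(list(no_age), mode = "age_only", config = config)
  expect_length(kept, 0)
  expect_match(attr(kept, "excluded")$reason, "no AgeI")
})

test_that("product sizes shrink monotonically as the break approaches the primer", {
  bundle <- synthetic_bundle()
  config <- bundle$config
  frags <- digest(bundle$ref$seq, "XbaI")
  region <- frags[frags$start == config$region_start, ]
  intact <- predict_products(fill_and_circularize(region, bundle$ref$seq),
                             config$primers)
  expect_equal(intact$size[intact$round == "inner"], config$intact_size)
  expect_gt(config$intact_size, 2800)
  expect_lt(config$intact_size, 3200)

  breaks <- c(131500L, 130500L, 129800L, 129200L)
  sizes <- vapply(breaks, function(b) {
    tpl <- fill_and_circularize(apply_break(region, b)[1, ], bundle$ref$seq)
    p <- predict_products(tpl, config$primers)
    p$size[p$round == "inner"]
  }, numeric(1))
  expect_true(all(diff(sizes) < 0))
  expect_true(all(sizes < config$intact_size))
})

test_that("size_to_breakpoint inverts product prediction exactly", {
  bundle <- synthetic_bundle()
  config <- bundle$config
  frags <- digest(bundle$ref$seq, "XbaI")
  region <- frags[frags$start == config$region_start, ]
  for (b in c(129100L, 129823L, 130633L, 131232L, 131900L)) {
    tpl <- fill_and_circularize(apply_break(region, b)[1, ], bundle$ref$seq)
    p <- predict_products(tpl, config$primers)
    expect_equal(size_to_breakpoint(p$size[p$round == "inner"], config), b)
  }
  expect_message(
    expect_true(is.na(size_to_breakpoint(config$intact_size, config))),
    "no break")
  expect_error(size_to_breakpoint(0, config), "positive")
  expect_error(size_to_breakpoint(config$intact_size + 1, config), "exceeds")
})

test_that("a template without a primer site yields no product", {
  s <- paste0(random_sequence(300, seed = 33), "ACCGGT",
              random_sequence(300, seed = 34))
  tpl <- structure(list(circle_seq = s, origin_start = 1,
                        origin_end = nchar(s), left_end = "other",
                        right_end = "other", fill_right = ""),
                   class = "ipcr_template")
  expect_error(predict_products(tpl, default_primers()), "no product")
  expect_null(predict_products(tpl, default_primers(), quiet = TRUE))
})
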