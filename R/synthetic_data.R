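# Run code under a local RNG state so generators are reproducible without
# disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random DNA sequence with a given AT fraction
#'
#' Bases are drawn independently with `P(A) = P(T) = at_fraction / 2` and
#' `P(C) = P(G) = (1 - at_fraction) / 2`. In motif-free mode, windows
#' matching either MRS element (8-mer exact, 16-mer with one mismatch, both
#' strands) are re-randomised until none remain, so every subsequent motif
#' hit is a planted one.
#'
#' @param length Sequence length (bp), > 0.
#' @param at_fraction AT fraction in `[0, 1]`; default 0.5.
#' @param seed Integer seed; same (spec, seed) gives an identical sequence.
#' @param motif_free Reject accidental MRS element matches (default FALSE).
#' @return A DNA string.
#' @export
random_sequence <- function(length, at_fraction = 0.5, seed = NULL,
                            motif_free = FALSE) {
  if (length <= 0) abort("length must be positive.")
  if (at_fraction < 0 || at_fraction > 1) {
    abort("at_fraction must lie in [0, 1].")
  }
  with_local_seed(seed, {
    p <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
           G = (1 - at_fraction) / 2, T = at_fraction / 2)
    seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
                 collapse = "")
    if (motif_free) seq <- scrub_motifs(seq, at_fraction = at_fraction)
    seq
  })
}

# Re-randomise every window matching an MRS element until the sequence is
# motif-free, leaving positions in `protect` (logical vector) untouched.
scrub_motifs <- function(seq, at_fraction = 0.5, protect = NULL,
                         expected = NULL, max_iter = 60) {
  p <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
         G = (1 - at_fraction) / 2, T = at_fraction / 2)
  n <- nchar(seq)
  if (is.null(protect)) protect <- rep(FALSE, n)
  for (iter in seq_len(max_iter)) {
    hits <- dplyr::bind_rows(scan_motifs(seq, "E8"), scan_motifs(seq, "E16"))
    if (!is.null(expected) && nrow(hits) > 0) {
      key <- paste(hits$element, hits$start, hits$strand)
      hits <- hits[!key %in% expected, ]
    }
    if (nrow(hits) == 0) return(seq)
    pos <- unique(unlist(purrr::map2(hits$start, hits$end, seq_len2)))
    pos <- pos[!protect[pos]]
    if (length(pos) == 0) {
      abort("Spurious motif hit lies entirely within protected bases.")
    }
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[pos] <- sample(names(p), length(pos), replace = TRUE, prob = p)
    seq <- paste(chars, collapse = "")
  }
  abort("Motif scrubbing did not converge.")
}

# Realise a degenerate IUPAC pattern as a concrete sequence with exactly
# `mismatches` substitutions at informative (non-N) positions.
realise_pattern <- function(symbols, mismatches = 0) {
  syms <- strsplit(symbols, "", fixed = TRUE)[[1]]
  bases <- vapply(syms, function(s) {
    cls <- IUPAC_CLASS[[s]]
    cls[sample.int(length(cls), 1)]
  }, character(1), USE.NAMES = FALSE)
  if (mismatches > 0) {
    informative <- which(vapply(syms, function(s)
      length(IUPAC_CLASS[[s]]) < 4, logical(1)))
    at <- sample(informative, mismatches)
    for (j in at) {
      outside <- setdiff(c("A", "C", "G", "T"), IUPAC_CLASS[[syms[j]]])
      bases[j] <- outside[sample.int(length(outside), 1)]
    }
  }
  paste(bases, collapse = "")
}

#' Plant one MRS (16 bp + 8 bp element) into a sequence
#'
#' Concrete realisations of the degenerate patterns are written at the given
#' positions (Crick plants are written as the Watson-strand reverse
#' complement). The truth record carries the gap under the scanner's
#' convention (bases strictly between the intervals, negative when the 8 bp
#' element is upstream, overlap reported categorically).
#'
#' @param seq Background DNA string.
#' @param pos16,pos8 Start positions (1-based) of the two elements.
#' @param strand16,strand8 `"W"` or `"C"`.
#' @param mismatches16 Substitutions planted into the 16-mer (0 or 1).
#' @param seed Integer seed for the degenerate-base realisation.
#' @param allow_overlap Permit the two planted intervals to intersect
#'   (they then share no bases in conflict only if the realisations agree;
#'   overlapping plants are written 16-mer first, 8-mer second).
#' @return A list: `seq` (with plants), `truth` (tibble with intervals,
#'   strands, planted sequences, `gap`, `overlap`).
#' @export
plant_mrs <- function(seq, pos16, strand16 = "W", mismatches16 = 0,
                      pos8, strand8 = "W", seed = NULL,
                      allow_overlap = FALSE) {
  n <- nchar(seq)
  end16 <- pos16 + 15L
  end8 <- pos8 + 7L
  if (pos16 < 1 || end16 > n || pos8 < 1 || end8 > n) {
    abort("Planted element extends beyond the sequence.")
  }
  overlap <- pos16 <= end8 && pos8 <= end16
  if (overlap && !allow_overlap) {
    abort("Planted elements overlap; set allow_overlap = TRUE if intended.")
  }
  with_local_seed(seed, {
    s16 <- realise_pattern("AWWRTAANNWWGNNNC", mismatches16)
    s8 <- realise_pattern("AATAAYAA", 0)
    subseq_chr(seq, pos16, end16) <- if (strand16 == "W") s16 else revcomp(s16)
    subseq_chr(seq, pos8, end8) <- if (strand8 == "W") s8 else revcomp(s8)
    g <- element_gap(pos16, end16, pos8, end8)
    list(
      seq = seq,
      truth = tibble(
        start16 = pos16, end16 = end16, strand16 = strand16, seq16 = s16,
        mismatches16 = mismatches16,
        start8 = pos8, end8 = end8, strand8 = strand8, seq8 = s8,
        gap = g$gap, overlap = g$overlap
      )
    )
  })
}

# Fixed layout of the synthetic assay region (gene-local coordinates).
# The region of study is the XbaI fragment 128301..132000 (3.7 kb): primer
# cassette at its 5' end, AgeI inside the cassette, EcoRI (5'-mode
# eliminator) and BsaAI (3'-mode eliminator) towards the 3' end.
synthetic_layout <- function() {
  primers <- default_primers()
  tibble(
    feature = c("xbaI_left", "inner_reverse", "outer_reverse", "ageI",
                "outer_forward", "inner_forward", "tgcc_junction", "ecoRI",
                "bsaAI", "xbaI_right"),
    start = c(128300L, 128340L, 128390L, 128450L, 128960L, 129000L,
              130001L, 131400L, 131700L, 132000L),
    seq = c("TCTAGA", revcomp(primers$inner_reverse),
            revcomp(primers$outer_reverse), "ACCGGT",
            primers$outer_forward, primers$inner_forward, "TGCC",
            "GAATTC", "TACGTA", "TCTAGA")
  )
}

#' Build the synthetic ABL-like reference
#'
#' Emulates the study's gene-scale inputs: a motif-free random background of
#' 173,795 bp into which the full curated MRS catalogue
#' ([abl_mrs_catalogue()]) is planted at its published coordinates and
#' strands, plus the assay features of the region of study (XbaI sites
#' flanking a 3.7 kb fragment, the nested primer cassette, AgeI, EcoRI and
#' BsaAI sites, and the TGCC junction motif used by the translocation
#' example). The background is re-randomised until the only MRS element
#' hits genome-wide are the planted ones and the only assay enzyme sites
#' within the region are the planted ones.
#'
#' @param seed Integer seed for the background.
#' @return A list: `ref` (one-row tibble `id`/`seq`/`length`), `model`
#'   (the synthetic gene model), `config` (the [assay_config()]), `layout`
#'   (feature coordinates), `catalogue` (the planted MRS truth).
#' @export
build_synthetic_abl <- function(seed = 1) {
  catalogue <- abl_mrs_catalogue()
  layout <- synthetic_layout()
  gene_length <- 173795L

  seq <- random_sequence(gene_length, at_fraction = 0.5, seed = seed)

  # planting plan: motif elements (strand-aware) + assay features
  plants <- dplyr::bind_rows(
    dplyr::distinct(tibble(
      start = catalogue$start16, end = catalogue$end16,
      seq = ifelse(catalogue$strand16 == "W", catalogue$seq16,
                   revcomp(catalogue$seq16))
    )),
    dplyr::distinct(tibble(
      start = catalogue$start8, end = catalogue$end8,
      seq = ifelse(catalogue$strand8 == "W", catalogue$seq8,
                   revcomp(catalogue$seq8))
    )),
    tibble(start = layout$start, end = layout$start + nchar(layout$seq) - 1L,
           seq = layout$seq)
  )
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  protect <- rep(FALSE, gene_length)
  for (i in seq_len(nrow(plants))) {
    idx <- plants$start[i]:plants$end[i]
    want <- strsplit(plants$seq[i], "", fixed = TRUE)[[1]]
    clash <- protect[idx] & chars[idx] != want
    if (any(clash)) abort("Inconsistent overlapping plants in the catalogue.")
    chars[idx] <- want
    protect[idx] <- TRUE
  }
  seq <- paste(chars, collapse = "")

  expected <- c(
    paste("E16", ifelse(catalogue$strand16 == "W", catalogue$start16,
                        catalogue$start16), catalogue$strand16),
    paste("E8", catalogue$start8, catalogue$strand8)
  )
  seq <- with_local_seed(seed + 104729L, {
    scrub_background(seq, protect = protect, expected = unique(expected))
  })

  ref <- tibble(id = "ABL_synthetic", seq = seq, length = gene_length)
  model <- abl_gene_model()
  config <- assay_config(seq, region_start = 128301L, region_end = 132000L)
  list(ref = ref, model = model, config = config, layout = layout,
       catalogue = catalogue)
}

# Fixpoint scrub of the planted reference: no MRS element hit beyond the
# expected (planted) set genome-wide, and no assay-enzyme recognition site
# beyond the planted ones inside (and just around) the region of study.
# Offending unprotected bases are re-randomised until both conditions hold.
scrub_background <- function(seq, protect, expected, max_iter = 80,
                             region_window = c(128280L, 132030L)) {
  enzymes <- c("XbaI", "AgeI", "EcoRI", "BsaAI")
  lo <- region_window[1]
  hi <- region_window[2]
  for (iter in seq_len(max_iter)) {
    bad <- integer(0)
    hits <- dplyr::bind_rows(scan_motifs(seq, "E8"), scan_motifs(seq, "E16"))
    if (nrow(hits) > 0) {
      key <- paste(hits$element, hits$start, hits$strand)
      hits <- hits[!key %in% expected, ]
      bad <- c(bad, unlist(purrr::map2(hits$start, hits$end, seq_len2)))
    }
    window <- subseq_chr(seq, lo, hi)
    for (e in enzymes) {
      sites <- find_sites(window, e) + lo - 1L
      L <- nchar(restriction_enzyme(e)$recognition)
      for (h in sites) {
        idx <- h:(h + L - 1L)
        if (!all(protect[idx])) bad <- c(bad, idx)
      }
    }
    bad <- unique(bad)
    bad <- bad[!protect[bad]]
    if (length(bad) == 0) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[bad] <- sample(c("A", "C", "G", "T"), length(bad), replace = TRUE)
    seq <- paste(chars, collapse = "")
  }
  abort("Background scrubbing did not converge.")
}

seq_len2 <- function(a, b) a:b

#' Build a synthetic translocation-partner reference
#'
#' A random partner gene emulating the published donor: 578,576 bp, so the
#' printed donor interval (108,006-108,234) exists on it. Junction
#' compatibility (microhomology bases, boundary guards) is arranged by
#' [simulate_translocation_read()], which edits its copy of the partner and
#' records the edits.
#'
#' @param seed Integer seed.
#' @param length Partner length in bp (default 578,576).
#' @return One-row tibble `id`/`seq`/`length`.
#' @export
build_synthetic_partner <- function(seed = 2, length = 578576L) {
  tibble(id = "LHFPL3_synthetic",
         seq = random_sequence(length, at_fraction = 0.5, seed = seed),
         length = length)
}

#' Simulate nested IPCR amplicon reads for a set of breakpoints
#'
#' For every breakpoint the XbaI fragment of the region of study is broken,
#' the primer-proximal (5') child is filled and circularised, the circle is
#' passed through the requested secondary-digest selection, and the nested
#' product becomes one read. An empty breakpoint list yields the intact
#' template (a single product of approximately 3 kb under `age_only`). The
#' whole construction is deterministic.
#'
#' @param ref Reference DNA string or one-row tibble.
#' @param config The [assay_config()].
#' @param breakpoints Integer vector of break positions inside the region of
#'   study (may be empty).
#' @param mode Secondary digestion mode (see [select_templates()]).
#' @param prefix Read-id prefix.
#' @return A list: `reads` (tibble `id`/`seq`), `truth` (tibble `id`,
#'   `breakpoint` with `NA` for the intact template, `size`), `excluded`
#'   (selection exclusions).
#' @export
simulate_cleavage_reads <- function(ref, config, breakpoints,
                                    mode = "age_ecoRI", prefix = "read") {
  if (is.data.frame(ref)) ref <- ref$seq[[1]]
  bad <- breakpoints[breakpoints <= config$region_start |
                       breakpoints >= config$region_end]
  if (length(bad) > 0) {
    abort(sprintf("Breakpoint %d outside the region of study (%d-%d).",
                  bad[1], config$region_start, config$region_end))
  }
  frags <- digest(ref, "XbaI")
  region <- frags[frags$start == config$region_start &
                    frags$end == config$region_end, ]
  if (nrow(region) != 1) {
    abort("Region of study is not an intact XbaI fragment of this reference.")
  }

  templates <- list()
  truth_bp <- integer(0)
  if (length(breakpoints) == 0) {
    templates[[1]] <- fill_and_circularize(region, ref)
    truth_bp <- NA_integer_
  } else {
    for (b in breakpoints) {
      children <- apply_break(region, b)
      templates[[length(templates) + 1L]] <-
        fill_and_circularize(children[1, ], ref)
      truth_bp <- c(truth_bp, b)
    }
  }
  kept <- select_templates(templates, mode = mode, config = config)
  kept_idx <- setdiff(seq_along(templates), attr(kept, "excluded")$index)
  rows <- purrr::map2(kept, kept_idx, function(tpl, i) {
    prod <- predict_products(tpl, config$primers)
    inner <- prod[prod$round == "inner", ]
    tibble(id = sprintf("%s_%03d", prefix, i), seq = inner$seq,
           breakpoint = truth_bp[i], size = inner$size)
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0) {
    rows <- tibble(id = character(0), seq = character(0),
                   breakpoint = integer(0), size = integer(0))
  }
  list(
    reads = rows[, c("id", "seq")],
    truth = rows[, c("id", "breakpoint", "size")],
    excluded = attr(kept, "excluded")
  )
}

#' Simulate a shift-translocation read with planted microhomology
#'
#' Builds a chimeric read: primary-gene 5' arm ending at `break_a`, a donor
#' insert of `donor_start..donor_end` from the partner, then the primary
#' gene resuming at `break_a + 1`. The partner copy is edited so that the
#' first `micro_k` insert bases equal the primary gene's continuation after
#' `break_a` (the planted microhomology) and so that the junctions do not
#' extend further by chance (boundary guards); every edit is recorded. Use
#' the returned partner for mapping.
#'
#' @param ref_a Primary reference (string or one-row tibble).
#' @param ref_b Partner reference (one-row tibble `id`/`seq`).
#' @param break_a Primary-gene break position (5' junction; 1-based).
#' @param donor_start,donor_end Donor interval on the partner (1-based
#'   inclusive).
#' @param micro_k Planted 5'-junction microhomology length (`<=` insert
#'   length).
#' @param flank_5p,flank_3p Primary-gene arm lengths (defaults 184 and 586,
#'   the published read geometry).
#' @param read_id Read identifier.
#' @return A list: `read` (tibble `id`/`seq`), `partner` (edited copy for
#'   mapping), `truth` (tibble with the planted geometry), `edits` (tibble
#'   of partner-base edits).
#' @export
simulate_translocation_read <- function(ref_a, ref_b, break_a,
                                        donor_start, donor_end, micro_k,
                                        flank_5p = 184, flank_3p = 586,
                                        read_id = "trl_read") {
  if (is.data.frame(ref_a)) ref_a <- ref_a$seq[[1]]
  insert_len <- donor_end - donor_start + 1L
  if (micro_k > insert_len) abort("micro_k exceeds the insert length.")
  if (break_a - flank_5p + 1L < 1 || break_a + flank_3p > nchar(ref_a)) {
    abort("Flanks extend beyond the primary reference.")
  }
  b_seq <- ref_b$seq[[1]]
  edits <- list()
  set_base <- function(pos, base) {
    old <- subseq_chr(b_seq, pos, pos)
    if (old != base) {
      edits[[length(edits) + 1L]] <<- tibble(pos = pos, from = old, to = base)
      subseq_chr(b_seq, pos, pos) <<- base
    }
  }
  other_base <- function(...) {
    setdiff(c("A", "C", "G", "T"), c(...))[1]
  }

  # plant the shared junction bases into the partner copy
  if (micro_k > 0) {
    shared <- subseq_chr(ref_a, break_a + 1L, break_a + micro_k)
    for (j in seq_len(micro_k)) {
      set_base(donor_start + j - 1L, substr(shared, j, j))
    }
  }
  # guards: the 5' microhomology must be exactly micro_k ...
  if (donor_start + micro_k <= nchar(b_seq)) {
    a_next <- subseq_chr(ref_a, break_a + micro_k + 1L, break_a + micro_k + 1L)
    cur <- subseq_chr(b_seq, donor_start + micro_k, donor_start + micro_k)
    if (cur == a_next) set_base(donor_start + micro_k, other_base(a_next))
  }
  # ... the donor placement must not extend left past the planted bases ...
  if (donor_start > 1L) {
    a_at <- subseq_chr(ref_a, break_a, break_a)
    cur <- subseq_chr(b_seq, donor_start - 1L, donor_start - 1L)
    if (cur == a_at) set_base(donor_start - 1L, other_base(a_at))
  }
  # ... and the 3' junction carries no accidental microhomology
  a_at <- subseq_chr(ref_a, break_a, break_a)
  if (subseq_chr(b_seq, donor_end, donor_end) == a_at && micro_k < insert_len) {
    set_base(donor_end, other_base(a_at))
  }

  insert <- subseq_chr(b_seq, donor_start, donor_end)
  read <- paste0(
    subseq_chr(ref_a, break_a - flank_5p + 1L, break_a),
    insert,
    subseq_chr(ref_a, break_a + 1L, break_a + flank_3p)
  )
  partner <- tibble(id = ref_b$id[[1]], seq = b_seq, length = nchar(b_seq))
  list(
    read = tibble(id = read_id, seq = read),
    partner = partner,
    truth = tibble(
      break_a = break_a, donor_start = donor_start, donor_end = donor_end,
      insert_len = insert_len, micro_k = as.integer(micro_k),
      read_insert_start = flank_5p + 1L,
      read_insert_end = flank_5p + insert_len
    ),
    edits = if (length(edits)) dplyr::bind_rows(edits) else
      tibble(pos = integer(0), from = character(0), to = character(0))
  )
}

#' Simulate replicate IPCR band-count tables
#'
#' Poisson counts around per-sample mean cleavage frequencies, organised as
#' independent experiments with a fixed number of IPCR replicates each
#' (the assay's design: three experiments of four to seven replicates).
#'
#' @param means Named numeric vector of per-sample mean band counts.
#' @param n_experiments Experiments per sample (default 3).
#' @param replicates Replicates per experiment (default 6).
#' @param seed Integer seed.
#' @return A list: `counts` (tibble `sample`/`experiment`/`replicate`/
#'   `count`), `truth` (the planted means).
#' @export
simulate_band_counts <- function(means, n_experiments = 3, replicates = 6,
                                 seed = NULL) {
  with_local_seed(seed, {
    counts <- purrr::imap(means, function(m, s) {
      tidyr::expand_grid(experiment = seq_len(n_experiments),
                         replicate = seq_len(replicates)) |>
        dplyr::mutate(sample = s, count = stats::rpois(dplyr::n(), m),
                      .before = 1)
    })
    list(
      counts = dplyr::bind_rows(counts),
      truth = tibble(sample = names(means), mean = unname(means))
    )
  })
}
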