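#' The two MRS degenerate elements
#'
#' The MAR/SAR recognition signature (MRS) is bipartite: an 8 bp element
#' `AATAAYAA` (Y = C/T) that must match exactly, and a 16 bp element
#' `AWWRTAANNWWGNNNC` (W = A/T, R = A/G, N = any) in which one mismatch is
#' tolerated. The two elements may lie on either strand, in either order, and
#' may overlap.
#'
#' @param element `"E8"` or `"E16"`.
#' @return A list with `element`, `symbols` and `max_mismatch` (0 for E8,
#'   1 for E16).
#' @export
#' @examples
#' mrs_pattern("E16")
mrs_pattern <- function(element = c("E8", "E16")) {
  element <- match.arg(element)
  if (element == "E8") {
    list(element = "E8", symbols = "AATAAYAA", max_mismatch = 0L)
  } else {
    list(element = "E16", symbols = "AWWRTAANNWWGNNNC", max_mismatch = 1L)
  }
}

as_pattern <- function(pattern) {
  if (is.character(pattern)) return(mrs_pattern(pattern))
  pattern
}

#' Count mismatches between a window and a degenerate pattern
#'
#' A position mismatches when the window base is not in the IUPAC class of the
#' pattern symbol. A reference `N` never satisfies a non-N pattern symbol
#' (conservative: undetermined bases cannot support a motif call).
#'
#' @param window DNA string of the same length as the pattern.
#' @param pattern A pattern from [mrs_pattern()], or an IUPAC string.
#' @return Integer mismatch count.
#' @export
#' @examples
#' count_mismatches("AATAACAA", "AATAAYAA") # 0
#' count_mismatches("AATAAGAA", "AATAAYAA") # 1
count_mismatches <- function(window, pattern) {
  symbols <- if (is.character(pattern)) pattern else pattern$symbols
  if (nchar(window) != nchar(symbols)) {
    abort(sprintf("Window length (%d) != pattern length (%d).",
                  nchar(window), nchar(symbols)))
  }
  w <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  p <- strsplit(symbols, "", fixed = TRUE)[[1]]
  sum(vapply(seq_along(p), function(j) {
    cls <- IUPAC_CLASS[[p[j]]]
    if (is.null(cls)) abort(sprintf("Unsupported pattern symbol '%s'.", p[j]))
    # N in the reference only matches an N pattern symbol
    if (w[j] == "N") !identical(p[j], "N") else !(w[j] %in% cls)
  }, logical(1)))
}

# Vectorised single-strand scan: mismatch count for every window start.
# Returns an integer vector of length n - L + 1.
scan_mismatch_vector <- function(code, symbols) {
  p <- strsplit(symbols, "", fixed = TRUE)[[1]]
  L <- length(p)
  n <- length(code)
  if (n < L) return(integer(0))
  nw <- n - L + 1L
  mm <- integer(nw)
  for (j in seq_len(L)) {
    cls <- IUPAC_CLASS[[p[j]]]
    # membership over the encoded alphabet A,C,G,T,N; N (code 5) only
    # satisfies an N pattern symbol
    memb <- c(DNA_BASES[1:4] %in% cls, identical(p[j], "N"))
    mm <- mm + !memb[code[j:(j + nw - 1L)]]
  }
  mm
}

#' Scan a sequence for a degenerate element
#'
#' Every window on the requested strands with at most `max_mismatch`
#' mismatches is reported. Crick-strand hits carry Watson-strand coordinates
#' and the matched sequence as read 5'->3' on the Crick strand. Output is
#' sorted by start, Watson before Crick on ties.
#'
#' @param seq DNA string (or one-row tibble from [read_fasta()]).
#' @param pattern `"E8"`, `"E16"`, or a pattern list from [mrs_pattern()].
#' @param strands `"both"` (default), `"W"` or `"C"`.
#' @param max_mismatch Override of the pattern's mismatch budget.
#' @return A tibble of hits: `element`, `start`, `end`, `strand`,
#'   `matched_seq`, `mismatches`.
#' @export
#' @examples
#' scan_motifs("GGGGGGAATAACAAGGG", "E8")
scan_motifs <- function(seq, pattern, strands = c("both", "W", "C"),
                        max_mismatch = NULL) {
  if (is.data.frame(seq)) seq <- seq$seq[[1]]
  strands <- match.arg(strands)
  pattern <- as_pattern(pattern)
  max_mismatch <- max_mismatch %||% pattern$max_mismatch
  L <- nchar(pattern$symbols)
  n <- nchar(seq)
  if (n < L) abort("Sequence shorter than the pattern.")

  out <- list()
  if (strands %in% c("both", "W")) {
    mm <- scan_mismatch_vector(encode_dna(seq), pattern$symbols)
    keep <- which(mm <= max_mismatch)
    if (length(keep)) {
      out$W <- tibble(
        element = pattern$element, start = keep, end = keep + L - 1L,
        strand = "W",
        matched_seq = substring(seq, keep, keep + L - 1L),
        mismatches = mm[keep]
      )
    }
  }
  if (strands %in% c("both", "C")) {
    rc <- revcomp(seq)
    mm <- scan_mismatch_vector(encode_dna(rc), pattern$symbols)
    keep <- which(mm <= max_mismatch)
    if (length(keep)) {
      # reflect Crick window [i, i+L-1] on rc back to Watson coordinates
      out$C <- tibble(
        element = pattern$element,
        start = n - (keep + L - 1L) + 1L, end = n - keep + 1L,
        strand = "C",
        matched_seq = substring(rc, keep, keep + L - 1L),
        mismatches = mm[keep]
      )
    }
  }
  hits <- dplyr::bind_rows(out)
  if (nrow(hits) == 0) {
    return(tibble(element = character(), start = integer(), end = integer(),
                  strand = character(), matched_seq = character(),
                  mismatches = integer()))
  }
  dplyr::arrange(hits, .data$start, .data$strand)
}

#' Signed gap between two motif intervals
#'
#' The gap is the number of bases strictly between the two intervals,
#' negative when the 8 bp element precedes the 16 bp element; intersecting
#' intervals are reported categorically as an overlap (`NA` gap), never as a
#' gap of zero or less.
#'
#' @param start16,end16,start8,end8 Interval bounds of the two elements.
#' @return A list with `gap` (integer or `NA`) and `overlap` (logical).
#' @export
#' @examples
#' element_gap(26055, 26070, 26118, 26125) # +47
#' element_gap(26613, 26628, 26565, 26572) # -40
element_gap <- function(start16, end16, start8, end8) {
  start16 <- as.integer(start16)
  end16 <- as.integer(end16)
  start8 <- as.integer(start8)
  end8 <- as.integer(end8)
  if (start16 <= end8 && start8 <= end16) {
    return(list(gap = NA_integer_, overlap = TRUE))
  }
  if (start8 > end16) {
    list(gap = start8 - end16 - 1L, overlap = FALSE)        # 8-mer downstream
  } else {
    list(gap = -(start16 - end8 - 1L), overlap = FALSE)     # 8-mer upstream
  }
}

# Single-linkage grouping of hit intervals: motifs of one element type whose
# intervals are within `merge_distance` bases of each other (strictly-between
# count) chain into one group.
merge_same_element <- function(hits, merge_distance) {
  if (nrow(hits) == 0) return(hits)
  hits <- dplyr::arrange(hits, .data$start, .data$end)
  grp <- integer(nrow(hits))
  grp[1] <- 1L
  run_end <- hits$end[1]
  for (i in seq_len(nrow(hits))[-1]) {
    between <- hits$start[i] - run_end - 1L
    grp[i] <- if (between <= merge_distance) grp[i - 1] else grp[i - 1] + 1L
    run_end <- max(run_end, hits$end[i])
  }
  hits$merge_group <- grp
  hits
}

#' Pair 8 bp and 16 bp element hits into MRSs
#'
#' Motifs of the same element type within `merge_distance` bp of each other
#' collapse into a single merged element first. Each merged-16mer x merged-8mer
#' combination whose best member pair overlaps or lies within `max_gap` bp is
#' one MRS. Within a merged pair the representative combination is the one
#' minimising the absolute gap (overlap ranks best); all member combinations
#' are kept for tabulation.
#'
#' @param hits8,hits16 Hit tibbles from [scan_motifs()] over the same
#'   sequence.
#' @param max_gap Maximum distance (bp) between the two elements; default 250.
#'   Use 200 for the original MRS rule.
#' @param merge_distance Same-element collapse distance; default 200 bp.
#' @return A tibble with one row per member combination: `mrs_id`,
#'   `representative` (logical), both element intervals/strands/sequences,
#'   `gap` (signed bp, `NA` on overlap), `overlap`, and the MRS `span_start`/
#'   `span_end` (over all member motifs of the MRS).
#' @export
pair_elements <- function(hits8, hits16, max_gap = 250, merge_distance = 200) {
  if (max_gap < 0) abort("max_gap must be >= 0.")
  if (merge_distance < 0) abort("merge_distance must be >= 0.")
  if (nrow(hits8) == 0 || nrow(hits16) == 0) return(empty_pairs())

  h8 <- merge_same_element(hits8, merge_distance)
  h16 <- merge_same_element(hits16, merge_distance)

  combos <- tidyr::expand_grid(g16 = unique(h16$merge_group),
                               g8 = unique(h8$merge_group))
  rows <- purrr::pmap(combos, function(g16, g8) {
    m16 <- h16[h16$merge_group == g16, ]
    m8 <- h8[h8$merge_group == g8, ]
    pairs <- tidyr::expand_grid(i = seq_len(nrow(m16)), j = seq_len(nrow(m8)))
    gaps <- purrr::pmap(pairs, function(i, j) {
      element_gap(m16$start[i], m16$end[i], m8$start[j], m8$end[j])
    })
    d <- dplyr::mutate(
      pairs,
      gap = vapply(gaps, `[[`, integer(1), "gap"),
      overlap = vapply(gaps, `[[`, logical(1), "overlap"),
      rank_gap = ifelse(.data$overlap, -1L, abs(.data$gap))
    )
    best <- which.min(d$rank_gap)
    if (!(d$overlap[best] || abs(d$gap[best]) <= max_gap)) return(NULL)
    dplyr::mutate(
      d,
      g16 = g16, g8 = g8,
      representative = dplyr::row_number() == best,
      start16 = m16$start[.data$i], end16 = m16$end[.data$i],
      strand16 = m16$strand[.data$i], seq16 = m16$matched_seq[.data$i],
      mismatches16 = m16$mismatches[.data$i],
      start8 = m8$start[.data$j], end8 = m8$end[.data$j],
      strand8 = m8$strand[.data$j], seq8 = m8$matched_seq[.data$j],
      span_start = min(m16$start, m8$start),
      span_end = max(m16$end, m8$end)
    )
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0) return(empty_pairs())
  rows <- dplyr::arrange(rows, .data$span_start, .data$start16, .data$start8)
  combo <- paste(rows$g16, rows$g8, sep = "/")
  rows$mrs_id <- match(combo, unique(combo))
  dplyr::select(rows, "mrs_id", "representative", "seq16", "strand16",
                "start16", "end16", "mismatches16", "seq8", "strand8",
                "start8", "end8", "gap", "overlap", "span_start", "span_end")
}

empty_pairs <- function() {
  tibble(mrs_id = integer(), representative = logical(), seq16 = character(),
         strand16 = character(), start16 = integer(), end16 = integer(),
         mismatches16 = integer(), seq8 = character(), strand8 = character(),
         start8 = integer(), end8 = integer(), gap = integer(),
         overlap = logical(), span_start = integer(), span_end = integer())
}

#' Cluster MRSs into candidate MAR/SAR sites
#'
#' Single-linkage clustering on MRS spans: MRSs whose spans lie within
#' `proximity` bp of each other join one candidate site. Sites are numbered
#' 1..K in coordinate order.
#'
#' @param pairs Output of [pair_elements()].
#' @param proximity Linkage distance in bp (default 1000).
#' @return `pairs` with an added `site_id` column.
#' @export
cluster_sites <- function(pairs, proximity = 1000) {
  if (proximity < 0) abort("proximity must be >= 0.")
  if (nrow(pairs) == 0) return(dplyr::mutate(pairs, site_id = integer()))
  spans <- dplyr::distinct(pairs, .data$mrs_id, .data$span_start, .data$span_end)
  spans <- dplyr::arrange(spans, .data$span_start, .data$span_end)
  site <- integer(nrow(spans))
  site[1] <- 1L
  run_end <- spans$span_end[1]
  for (i in seq_len(nrow(spans))[-1]) {
    between <- spans$span_start[i] - run_end - 1L
    site[i] <- if (between <= proximity) site[i - 1] else site[i - 1] + 1L
    run_end <- max(run_end, spans$span_end[i])
  }
  spans$site_id <- site
  out <- dplyr::left_join(pairs, spans,
                          by = c("mrs_id", "span_start", "span_end"))
  dplyr::relocate(out, "site_id")
}

#' Scan a sequence for candidate MAR/SAR sites
#'
#' Convenience composition: scan both elements, pair, cluster.
#'
#' @inheritParams scan_motifs
#' @inheritParams pair_elements
#' @inheritParams cluster_sites
#' @return The clustered pair tibble of [cluster_sites()].
#' @export
scan_mar_sar <- function(seq, max_gap = 250, merge_distance = 200,
                         proximity = 1000, strands = "both",
                         max_mismatch16 = 1) {
  hits8 <- scan_motifs(seq, "E8", strands = strands)
  hits16 <- scan_motifs(seq, "E16", strands = strands,
                        max_mismatch = max_mismatch16)
  pairs <- pair_elements(hits8, hits16, max_gap = max_gap,
                         merge_distance = merge_distance)
  cluster_sites(pairs, proximity = proximity)
}

#' Tabulate candidate MAR/SAR sites
#'
#' One row per member element combination, grouped by site, with the matched
#' sequences, strands, intervals, signed distance (or `"Overlap"`), and the
#' exon/intron location of each site.
#'
#' @param sites Clustered pairs from [cluster_sites()] / [scan_mar_sar()].
#' @param model Optional gene model for the location column.
#' @return A report tibble; zero rows (with header) for an empty site list.
#' @export
tabulate_sites <- function(sites, model = NULL) {
  if (nrow(sites) == 0) {
    return(tibble(site_id = integer(), mrs_id = integer(), seq16 = character(),
                  strand16 = character(), pos16 = character(),
                  seq8 = character(), strand8 = character(),
                  pos8 = character(), distance = character(),
                  location = character()))
  }
  out <- dplyr::mutate(
    sites,
    pos16 = sprintf("%s-%s", format(.data$start16, big.mark = ","),
                    format(.data$end16, big.mark = ",")),
    pos8 = sprintf("%s-%s", format(.data$start8, big.mark = ","),
                   format(.data$end8, big.mark = ",")),
    distance = ifelse(.data$overlap, "Overlap", sprintf("%+d", .data$gap)),
    location = if (is.null(model)) NA_character_ else
      locate_feature(model, .data$span_start)
  )
  dplyr::select(out, "site_id", "mrs_id", "seq16", "strand16", "pos16",
                "seq8", "strand8", "pos8", "distance", "location")
}
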