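# first-mismatch comparison of read[a..] vs ref[b..]; returns match length
match_run <- function(read_int, ref_int, a, b) {
  max_len <- min(length(read_int) - a, length(ref_int) - b) + 1L
  if (max_len <= 0) return(0L)
  d <- which(read_int[a:(a + max_len - 1L)] != ref_int[b:(b + max_len - 1L)])
  if (length(d) == 0) max_len else d[1] - 1L
}

#' Anchor a read to reference sequences by maximal exact matches
#'
#' Greedy left-to-right anchoring: at each uncovered read position a seed of
#' `min_anchor` bases is searched in every reference on both strands; the
#' seed match with the longest exact extension becomes a block (ties:
#' Watson before Crick, then earlier reference position). Unmatched read
#' stretches stay uncovered. Crick blocks carry Watson-strand reference
#' coordinates and `strand = "C"`.
#'
#' @param read DNA string (one read).
#' @param references Tibble with `id` and `seq` (as from [read_fasta()]), or
#'   a named character vector.
#' @param min_anchor Minimum block length (default 20 nt).
#' @return Tibble of blocks: `read_start`, `read_end`, `ref_id`,
#'   `ref_start`, `ref_end`, `strand`, ordered by read position.
#' @export
anchor_read <- function(read, references, min_anchor = 20) {
  if (is.character(references)) {
    references <- tibble(id = names(references) %||%
                           paste0("ref", seq_along(references)),
                         seq = unname(references))
  }
  read <- toupper(read)
  n <- nchar(read)
  if (n < min_anchor) abort("Read shorter than min_anchor.")
  read_int <- utf8ToInt(read)

  refs <- purrr::pmap(references, function(id, seq, ...) {
    list(id = id, fwd = utf8ToInt(seq), rev = utf8ToInt(revcomp(seq)),
         fwd_chr = seq, rev_chr = revcomp(seq), len = nchar(seq))
  })

  blocks <- list()
  i <- 1L
  while (i <= n - min_anchor + 1L) {
    seed <- substr(read, i, i + min_anchor - 1L)
    best <- NULL
    for (r in refs) {
      for (strand in c("W", "C")) {
        subject_chr <- if (strand == "W") r$fwd_chr else r$rev_chr
        subject_int <- if (strand == "W") r$fwd else r$rev
        occ <- gregexpr(seed, subject_chr, fixed = TRUE)[[1]]
        occ <- occ[occ > 0]
        if (length(occ) > 50) occ <- occ[1:50]
        for (p in occ) {
          len <- match_run(read_int, subject_int, i, p)
          cand <- list(len = len, ref = r, strand = strand, pos = p)
          if (is.null(best) || len > best$len ||
              (len == best$len && best$strand == "C" && strand == "W")) {
            best <- cand
          }
        }
      }
    }
    if (is.null(best)) {
      i <- i + 1L
      next
    }
    L <- best$ref$len
    if (best$strand == "W") {
      rs <- best$pos
      re <- best$pos + best$len - 1L
    } else {
      rs <- L - (best$pos + best$len - 1L) + 1L
      re <- L - best$pos + 1L
    }
    blocks[[length(blocks) + 1L]] <- tibble(
      read_start = i, read_end = i + best$len - 1L,
      ref_id = best$ref$id, ref_start = rs, ref_end = re,
      strand = best$strand
    )
    i <- i + best$len
  }
  if (length(blocks) == 0) abort("Unmappable read: no anchor block found.")
  dplyr::bind_rows(blocks)
}

#' Call a chromosome breakpoint from an anchored IPCR amplicon
#'
#' An amplicon reads forward-primer arm, ligation junction, then the
#' region-start arm. The primer-proximal block's junction edge gives the
#' breakpoint. When the reference continuation beyond the break happens to
#' share leading bases with the region-start arm, the exact matcher extends
#' the first block past the junction by that shared length; the call
#' compensates exactly by the downstream block's offset from the region
#' start, so planted breaks are always recovered at base precision.
#'
#' @param blocks Block tibble from [anchor_read()] for one amplicon read.
#' @param config The [assay_config()] the amplicon was generated under.
#' @return A tibble with `position` (one row), or zero rows for an intact
#'   template (no break detectable).
#' @export
call_breakpoints <- function(blocks, config) {
  blocks <- dplyr::arrange(blocks, .data$read_start)
  b1 <- blocks[1, ]
  if (b1$read_start != 1L || b1$strand != "W" ||
      b1$ref_start > config$if5 || b1$ref_end < config$if5) {
    abort("Blocks inconsistent with the assay geometry: no forward-primer block.")
  }
  junction <- blocks[blocks$strand == "W" &
                       blocks$ref_start >= config$region_start &
                       blocks$ref_start <= config$region_start + 25L &
                       blocks$read_start > b1$read_start, ]
  if (nrow(junction) == 0) {
    abort("Blocks inconsistent with the assay geometry: no junction arm.")
  }
  j <- junction$ref_start[1] - config$region_start
  position <- b1$ref_end - j
  if (position >= config$region_end) {
    return(tibble(position = integer(0)))
  }
  tibble(position = as.integer(position))
}

#' Detect a translocated insert in an anchored read
#'
#' An uncovered read interval flanked by two primary-reference blocks is a
#' candidate shift-translocation insert. The candidate is searched against
#' the partner references for an exact full-length placement (both strands);
#' when found, the placement is extended leftwards over junction bases shared
#' with the upstream primary block (microhomology bases are assigned to the
#' insert, so the primary-gene breakpoint precedes them). Uncovered stretches
#' shorter than `min_insert` are junction noise; an uncovered stretch at a
#' read end is not a shift translocation.
#'
#' @param blocks Block tibble from [anchor_read()].
#' @param read The read DNA string.
#' @param primary Primary reference as a one-row tibble (`id`, `seq`) or a
#'   single named string.
#' @param partners Optional partner references (tibble `id`,`seq`).
#' @param min_insert Minimum insert width (default 4 nt).
#' @param max_k Microhomology search cap (default 25 nt).
#' @return A tibble with zero rows (no insert) or one row: insert read
#'   interval and length, donor id (or `"unknown"`), donor interval in both
#'   the 1-based inclusive and the end-exclusive printed conventions, donor
#'   strand, 5' and 3' junction microhomology (length and sequence), and the
#'   primary-gene breakpoints flanking the insert.
#' @export
detect_insert <- function(blocks, read, primary, partners = NULL,
                          min_insert = 4, max_k = 25) {
  if (is.character(primary)) {
    primary <- tibble(id = names(primary) %||% "primary", seq = unname(primary))
  }
  pb <- dplyr::filter(blocks, .data$ref_id == primary$id[[1]],
                      .data$strand == "W")
  pb <- dplyr::arrange(pb, .data$read_start)
  empty <- tibble(
    insert_read_start = integer(0), insert_read_end = integer(0),
    insert_len = integer(0), donor = character(0),
    donor_start = integer(0), donor_end = integer(0),
    donor_end_exclusive = integer(0), donor_strand = character(0),
    micro5_len = integer(0), micro5_seq = character(0),
    micro3_len = integer(0), micro3_seq = character(0),
    break_5p = integer(0), resume_3p = integer(0)
  )
  if (nrow(pb) < 2) return(empty)
  gaps <- pb$read_start[-1] - pb$read_end[-nrow(pb)] - 1L
  k <- which(gaps >= min_insert)
  if (length(k) == 0) return(empty)
  k <- k[1]
  b1 <- pb[k, ]
  b2 <- pb[k + 1, ]
  e1 <- b1$read_end
  s2 <- b2$read_start
  # 3' junction bases shared between the donor end and the primary-gene
  # resumption belong to the primary gene: left-extend the downstream block
  # (the greedy cover may have assigned them to the donor)
  while (s2 - 1L > e1 && b2$ref_start > 1L &&
         substr(read, s2 - 1L, s2 - 1L) ==
           substr(primary$seq[[1]], b2$ref_start - 1L, b2$ref_start - 1L)) {
    s2 <- s2 - 1L
    b2$ref_start <- b2$ref_start - 1L
  }
  candidate <- subseq_chr(read, e1 + 1L, s2 - 1L)

  donor <- "unknown"
  donor_strand <- NA_character_
  d_start <- NA_integer_
  t <- 0L
  donor_seq <- NULL
  if (!is.null(partners) && nrow(partners) > 0) {
    for (pi in seq_len(nrow(partners))) {
      for (strand in c("W", "C")) {
        subject <- if (strand == "W") partners$seq[[pi]] else
          revcomp(partners$seq[[pi]])
        hit <- regexpr(candidate, subject, fixed = TRUE)
        if (hit > 0) {
          donor <- partners$id[[pi]]
          donor_strand <- strand
          donor_seq <- subject
          d_start <- as.integer(hit)
          break
        }
      }
      if (donor != "unknown") break
    }
  }

  if (donor != "unknown") {
    # assign junction-shared bases to the insert: walk the placement leftwards
    # while the read base is also the donor's preceding base
    while (t < max_k && e1 - t >= 1L && d_start - t - 1L >= 1L &&
           substr(read, e1 - t, e1 - t) ==
             substr(donor_seq, d_start - t - 1L, d_start - t - 1L)) {
      t <- t + 1L
    }
  }
  ins_start <- e1 + 1L - t
  ins_end <- s2 - 1L
  ins_len <- ins_end - ins_start + 1L
  break_5p <- b1$ref_end - t
  insert_seq <- subseq_chr(read, ins_start, ins_end)

  # 5' junction: first insert bases shared with the primary-gene continuation
  upstream_next <- subseq_chr(primary$seq[[1]], break_5p + 1L,
                              min(break_5p + max_k, nchar(primary$seq[[1]])))
  m5 <- junction_microhomology(upstream_next,
                               subseq_chr(insert_seq, 1L,
                                          min(max_k, ins_len)),
                               max_k = max_k)
  # 3' junction: last insert bases shared with the primary gene upstream of
  # the resumption point (suffix form of the same computation)
  resume <- b2$ref_start
  up3 <- subseq_chr(primary$seq[[1]], max(1L, resume - max_k), resume - 1L)
  ins3 <- subseq_chr(insert_seq, max(1L, ins_len - max_k + 1L), ins_len)
  m3 <- junction_microhomology(reverse_chr(up3), reverse_chr(ins3),
                               max_k = max_k)
  m3$seq <- reverse_chr(m3$seq)

  if (donor != "unknown" && donor_strand == "C") {
    # report donor coordinates on the Watson strand of the partner
    L <- nchar(donor_seq)
    w_start <- L - (d_start - t + ins_len - 1L) + 1L
    d_start_w <- w_start
  } else {
    d_start_w <- if (donor == "unknown") NA_integer_ else d_start - t
  }
  tibble(
    insert_read_start = ins_start, insert_read_end = ins_end,
    insert_len = ins_len, donor = donor,
    donor_start = d_start_w,
    donor_end = if (is.na(d_start_w)) NA_integer_ else d_start_w + ins_len - 1L,
    donor_end_exclusive = if (is.na(d_start_w)) NA_integer_ else
      d_start_w + ins_len,
    donor_strand = donor_strand,
    micro5_len = m5$length, micro5_seq = m5$seq,
    micro3_len = m3$length, micro3_seq = m3$seq,
    break_5p = as.integer(break_5p), resume_3p = as.integer(resume)
  )
}

reverse_chr <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}

#' Junction microhomology between two DNA ends
#'
#' The microhomology length is the largest `k <= max_k` such that the first
#' `k` insert bases equal the first `k` bases of the upstream reference
#' continuation: those bases are assignable to either donor, which is the
#' signature of microhomology-mediated end joining. The symmetric 3' version
#' is obtained by passing both contexts reversed.
#'
#' @param upstream_next Reference continuation just past the upstream
#'   breakpoint (5'->3').
#' @param insert_prefix First bases of the inserted/joined segment (5'->3').
#' @param max_k Search cap (default 25).
#' @return A list with `length` and `seq` (the shared bases; `""` when no
#'   microhomology).
#' @export
#' @examples
#' junction_microhomology("TGCCAGTT", "TGCCTTAA")
junction_microhomology <- function(upstream_next, insert_prefix, max_k = 25) {
  if (nchar(upstream_next) == 0 || nchar(insert_prefix) == 0) {
    abort("Empty junction context.")
  }
  kmax <- min(max_k, nchar(upstream_next), nchar(insert_prefix))
  a <- utf8ToInt(subseq_chr(upstream_next, 1L, kmax))
  b <- utf8ToInt(subseq_chr(insert_prefix, 1L, kmax))
  d <- which(a != b)
  k <- if (length(d) == 0) kmax else d[1] - 1L
  list(length = as.integer(k),
       seq = if (k > 0) subseq_chr(insert_prefix, 1L, k) else "")
}

#' Annotate breakpoint calls against named gene annotations
#'
#' Adds one logical membership column per annotation (inclusive interval
#' boundaries) and, when a site table is supplied, the distance to the
#' nearest candidate MAR/SAR span (0 when inside one).
#'
#' @param calls Tibble with a `position` column.
#' @param model A gene model (its `type == "annotation"` rows are used).
#' @param sites Optional clustered site tibble from [scan_mar_sar()].
#' @return `calls` with `in_<label>` flag columns, `feature` (exon/intron
#'   label) and optionally `nearest_site_distance`.
#' @export
annotate_breakpoint <- function(calls, model, sites = NULL) {
  ann <- model[model$type == "annotation", ]
  out <- calls
  for (i in seq_len(nrow(ann))) {
    out[[paste0("in_", ann$label[i])]] <-
      calls$position >= ann$start[i] & calls$position <= ann$end[i]
  }
  out$feature <- locate_feature(model, calls$position)
  if (!is.null(sites) && nrow(sites) > 0) {
    spans <- dplyr::distinct(sites, .data$site_id, .data$span_start,
                             .data$span_end)
    out$nearest_site_distance <- vapply(calls$position, function(p) {
      d <- pmax(spans$span_start - p, p - spans$span_end, 0L)
      as.integer(min(d))
    }, integer(1))
  }
  out
}

#' Map IPCR amplicon reads and call breakpoints and translocations
#'
#' Runs [anchor_read()], [call_breakpoints()] and [detect_insert()] over a
#' set of reads.
#'
#' @param reads Tibble with `id` and `seq` (as from [read_fasta()]).
#' @param primary One-row tibble (`id`, `seq`) for the assayed gene.
#' @param config The [assay_config()] used to generate the amplicons.
#' @param partners Optional partner references for insert placement.
#' @param min_anchor Passed to [anchor_read()].
#' @return A list of two tibbles: `breakpoints` (`read_id`, `position`) and
#'   `translocations` (one row per detected insert, with `read_id`).
#' @export
map_reads <- function(reads, primary, config, partners = NULL,
                      min_anchor = 20) {
  refs <- dplyr::bind_rows(primary, partners)
  bp <- list()
  tr <- list()
  for (i in seq_len(nrow(reads))) {
    blocks <- anchor_read(reads$seq[[i]], refs, min_anchor = min_anchor)
    ins <- detect_insert(blocks, reads$seq[[i]], primary, partners)
    if (nrow(ins) > 0) {
      tr[[length(tr) + 1L]] <- dplyr::mutate(ins, read_id = reads$id[[i]],
                                             .before = 1)
      next
    }
    primary_blocks <- blocks[blocks$ref_id == primary$id[[1]], ]
    calls <- call_breakpoints(primary_blocks, config)
    if (nrow(calls) > 0) {
      bp[[length(bp) + 1L]] <- dplyr::mutate(calls, read_id = reads$id[[i]],
                                             .before = 1)
    }
  }
  list(
    breakpoints = if (length(bp)) dplyr::bind_rows(bp) else
      tibble(read_id = character(0), position = integer(0)),
    translocations = dplyr::bind_rows(tr)
  )
}
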