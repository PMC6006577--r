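#' Restriction enzymes used by the assay
#'
#' Recognition sequences and cut offsets follow the standard REBASE
#' definitions: XbaI `T^CTAGA` (4 nt 5' overhang `CTAG`), AgeI `A^CCGGT`,
#' EcoRI `G^AATTC`, BsaAI `YAC^GTR` (blunt). All four recognitions are
#' palindromic, so Watson-strand matches enumerate every site once.
#'
#' @param name Enzyme name.
#' @return A list with `name`, `recognition` (IUPAC), `cut_offset` (top
#'   strand; the cut falls after this many recognition bases) and `end_type`.
#' @export
restriction_enzyme <- function(name = c("XbaI", "AgeI", "EcoRI", "BsaAI")) {
  name <- match.arg(name)
  switch(name,
    XbaI  = list(name = "XbaI", recognition = "TCTAGA", cut_offset = 1L,
                 end_type = "five_prime_overhang"),
    AgeI  = list(name = "AgeI", recognition = "ACCGGT", cut_offset = 1L,
                 end_type = "five_prime_overhang"),
    EcoRI = list(name = "EcoRI", recognition = "GAATTC", cut_offset = 1L,
                 end_type = "five_prime_overhang"),
    BsaAI = list(name = "BsaAI", recognition = "YACGTR", cut_offset = 3L,
                 end_type = "blunt")
  )
}

# 5' overhang width: bases between the two staggered cuts (0 for blunt).
overhang_width <- function(enzyme) {
  nchar(enzyme$recognition) - 2L * enzyme$cut_offset
}

#' Locate recognition sites of an enzyme
#'
#' Degenerate recognition symbols are expanded via the IUPAC classes. Only
#' Watson-strand matches are enumerated (the supported recognitions are
#' palindromic).
#'
#' @param seq DNA string.
#' @param enzyme From [restriction_enzyme()] or an enzyme name.
#' @return Integer vector of 1-based site start positions.
#' @export
find_sites <- function(seq, enzyme) {
  if (is.character(enzyme)) enzyme <- restriction_enzyme(enzyme)
  mm <- scan_mismatch_vector(encode_dna(seq), enzyme$recognition)
  which(mm == 0L)
}

#' Digest a sequence with a restriction enzyme
#'
#' Fragments are reported in coordinate order as top-strand cut-to-cut
#' intervals (the cut falls after `site_start + cut_offset - 1`). End
#' annotations carry the enzyme identity; outermost ends are `"other"`.
#' Incomplete digestion is modelled by `cut_probability < 1` (each site cut
#' independently).
#'
#' @param seq DNA string (or one-row tibble from [read_fasta()]).
#' @param enzyme From [restriction_enzyme()] or an enzyme name.
#' @param cut_probability Per-site cut probability, default 1 (complete
#'   digestion).
#' @return A tibble of fragments: `start`, `end`, `seq`, `left_end`,
#'   `right_end`; zero sites give the input back as one fragment. The parent
#'   sequence is attached as attribute `ref`.
#' @export
digest <- function(seq, enzyme, cut_probability = 1) {
  if (is.data.frame(seq)) seq <- seq$seq[[1]]
  if (is.character(enzyme)) enzyme <- restriction_enzyme(enzyme)
  sites <- find_sites(seq, enzyme)
  if (cut_probability < 1 && length(sites) > 0) {
    sites <- sites[stats::runif(length(sites)) < cut_probability]
  }
  cuts <- sites + enzyme$cut_offset - 1L
  bounds <- c(0L, cuts, nchar(seq))
  frags <- tibble(
    start = bounds[-length(bounds)] + 1L,
    end = bounds[-1],
    seq = substring(seq, bounds[-length(bounds)] + 1L, bounds[-1]),
    left_end = c("other", rep(enzyme$name, length(cuts))),
    right_end = c(rep(enzyme$name, length(cuts)), "other")
  )
  attr(frags, "ref") <- seq
  attr(frags, "enzyme") <- enzyme$name
  frags
}

#' Introduce an apoptotic blunt break into a fragment
#'
#' The break is defined so the left child ends at `breakpoint` (the reported
#' breakpoint base is the last retained base of the primer-proximal
#' fragment). Both break-side ends are typed `apoptotic_blunt`.
#'
#' @param fragment A one-row fragment tibble (from [digest()]).
#' @param breakpoint 1-based position; must satisfy
#'   `start <= breakpoint < end` (a breakpoint on the right boundary is an
#'   error: it would not split the fragment).
#' @return A two-row fragment tibble (left child, right child).
#' @export
apply_break <- function(fragment, breakpoint) {
  if (nrow(fragment) != 1) abort("apply_break() takes a single fragment row.")
  if (breakpoint < fragment$start || breakpoint >= fragment$end) {
    abort(sprintf(
      "Breakpoint %d is not strictly inside fragment [%d, %d].",
      breakpoint, fragment$start, fragment$end))
  }
  offset <- breakpoint - fragment$start + 1L
  out <- tibble(
    start = c(fragment$start, breakpoint + 1L),
    end = c(breakpoint, fragment$end),
    seq = c(subseq_chr(fragment$seq, 1, offset),
            subseq_chr(fragment$seq, offset + 1L, nchar(fragment$seq))),
    left_end = c(fragment$left_end, "apoptotic_blunt"),
    right_end = c("apoptotic_blunt", fragment$right_end)
  )
  attr(out, "ref") <- attr(fragment, "ref")
  out
}

#' Klenow fill-in and circularisation of a fragment
#'
#' A 5'-overhang end is filled to blunt before ligation. Filling a fragment's
#' downstream (right) restriction end extends its top strand by the overhang
#' bases (`CTAG` for XbaI), taken from the genomic continuation; an upstream
#' (left) restriction end already carries its overhang-derived bases on the
#' top strand, so filling completes the bottom strand without changing the
#' sequence. Consequently an intact XbaI fragment circularises to fragment
#' length + 4 with junction `...TCTAG|CTAGA...` (a 4 bp duplication; the
#' XbaI site is not regenerated), and a fragment with an upstream XbaI end
#' and a downstream apoptotic blunt end circularises with no added bases and
#' junction `...<break base>|CTAGA...`.
#'
#' @param fragment A one-row fragment tibble; ends must be restriction ends
#'   or `apoptotic_blunt`.
#' @param ref Reference sequence the fragment came from; defaults to the
#'   `ref` attribute set by [digest()].
#' @return An `ipcr_template` list: `circle_seq` (linearised at the origin
#'   start; the ligation junction sits between the last and first base),
#'   `origin_start`, `origin_end`, `left_end`, `right_end`, `fill_right`
#'   (bases appended by the right-end fill).
#' @export
fill_and_circularize <- function(fragment, ref = NULL) {
  if (nrow(fragment) != 1) abort("fill_and_circularize() takes one fragment.")
  ref <- ref %||% attr(fragment, "ref")
  fillable <- c("XbaI", "AgeI", "EcoRI", "BsaAI", "apoptotic_blunt")
  if (!(fragment$left_end %in% fillable) || !(fragment$right_end %in% fillable)) {
    abort(sprintf("Unfillable end type: %s/%s.",
                  fragment$left_end, fragment$right_end))
  }
  fill_right <- ""
  if (fragment$right_end %in% c("XbaI", "AgeI", "EcoRI")) {
    enz <- restriction_enzyme(fragment$right_end)
    w <- overhang_width(enz)
    if (fragment$end + w > nchar(ref)) {
      abort("Right-end overhang extends beyond the reference.")
    }
    fill_right <- subseq_chr(ref, fragment$end + 1L, fragment$end + w)
  }
  structure(
    list(
      circle_seq = paste0(fragment$seq, fill_right),
      origin_start = fragment$start,
      origin_end = fragment$end,
      left_end = fragment$left_end,
      right_end = fragment$right_end,
      fill_right = fill_right
    ),
    class = "ipcr_template"
  )
}

#' Rotate the linear representation of a circular template
#'
#' Circle identity is rotation-invariant; this re-linearises the same circle
#' at a different offset.
#'
#' @param template An `ipcr_template`.
#' @param offset Number of leading bases moved to the end.
#' @return The rotated template.
#' @export
rotate_template <- function(template, offset) {
  s <- template$circle_seq
  n <- nchar(s)
  offset <- ((offset %% n) + n) %% n
  if (offset > 0) {
    template$circle_seq <- paste0(subseq_chr(s, offset + 1L, n),
                                  subseq_chr(s, 1L, offset))
  }
  template
}

#' Test whether two templates describe the same circle
#'
#' @param a,b `ipcr_template` objects.
#' @return `TRUE` when the circular sequences are rotation-equal.
#' @export
same_circle <- function(a, b) {
  nchar(a$circle_seq) == nchar(b$circle_seq) &&
    grepl(a$circle_seq, paste0(b$circle_seq, b$circle_seq), fixed = TRUE)
}

# Count recognition sites on a circle (matches may wrap the junction).
circular_sites <- function(circle_seq, enzyme) {
  if (is.character(enzyme)) enzyme <- restriction_enzyme(enzyme)
  n <- nchar(circle_seq)
  L <- nchar(enzyme$recognition)
  doubled <- paste0(circle_seq, subseq_chr(circle_seq, 1L, min(L - 1L, n)))
  hits <- find_sites(doubled, enzyme)
  hits[hits <= n]
}

#' Select amplifiable templates after secondary digestion
#'
#' `age_only` keeps every circle linearisable by AgeI (exactly one site). The
#' elimination modes additionally drop any circle whose amplified arc (inner
#' forward primer, across the ligation junction, to the inner reverse primer)
#' still contains the elimination enzyme's recognition site: intact circles
#' retain it and are removed; circles from sufficiently cleaved fragments
#' have lost it and survive. Circles with no AgeI site are not amplifiable
#' and are excluded with a reason.
#'
#' @param circles A list of `ipcr_template` objects.
#' @param mode `"age_only"`, `"age_ecoRI"` or `"age_bsaAI"`.
#' @param config Assay configuration from [assay_config()] (for primers).
#' @return The retained sublist; excluded templates are recorded in the
#'   `excluded` attribute (a tibble of reasons).
#' @export
select_templates <- function(circles,
                             mode = c("age_only", "age_ecoRI", "age_bsaAI"),
                             config) {
  mode <- match.arg(mode)
  eliminator <- switch(mode, age_only = NULL, age_ecoRI = "EcoRI",
                       age_bsaAI = "BsaAI")
  keep <- logical(length(circles))
  reasons <- character(length(circles))
  for (i in seq_along(circles)) {
    tpl <- circles[[i]]
    n_age <- length(circular_sites(tpl$circle_seq, "AgeI"))
    if (n_age == 0) {
      reasons[i] <- "no AgeI site: not linearisable, not amplifiable"
      next
    }
    if (n_age > 1) {
      reasons[i] <- "multiple AgeI sites: amplified arc destroyed"
      next
    }
    if (!is.null(eliminator)) {
      arc <- amplified_arc(tpl, config)
      if (is.null(arc)) {
        reasons[i] <- "primers do not anneal convergently"
        next
      }
      if (length(find_sites(arc, eliminator)) > 0) {
        reasons[i] <- sprintf("%s site within the amplified arc", eliminator)
        next
      }
    }
    keep[i] <- TRUE
  }
  out <- circles[keep]
  attr(out, "excluded") <- tibble(
    index = which(!keep), reason = reasons[!keep]
  )
  out
}

# The inner-primer-to-inner-primer arc (sequence) on the circle, or NULL when
# either primer is absent or the orientation is divergent.
amplified_arc <- function(template, config) {
  p <- predict_products(template, config$primers, quiet = TRUE)
  if (is.null(p)) NULL else p$seq[p$round == "inner"]
}

#' Predict the nested IPCR products of a template
#'
#' Primer annealing is modelled as exact string matching. Each round's
#' product runs from the forward primer's 5' base around the circle (across
#' the ligation junction) to the reverse primer's 5' base. The inner product
#' must nest within the outer one.
#'
#' @param template An `ipcr_template`.
#' @param primers A named list with `outer_forward`, `outer_reverse`,
#'   `inner_forward`, `inner_reverse` (5'->3' DNA strings), or an
#'   [assay_config()] (its `primers` element is used).
#' @param quiet Return `NULL` instead of erroring when no product forms.
#' @return A tibble with one row per round: `round`, `size`, `seq`; or
#'   `NULL` if `quiet` and a primer is missing/divergent.
#' @export
predict_products <- function(template, primers, quiet = FALSE) {
  if (!is.null(primers$primers)) primers <- primers$primers
  s <- template$circle_seq
  n <- nchar(s)
  doubled <- paste0(s, s)
  fail <- function(msg) {
    if (quiet) return(NULL)
    abort(msg)
  }

  one_round <- function(fwd, rev, round) {
    f_hits <- gregexpr(fwd, doubled, fixed = TRUE)[[1]]
    f_hits <- unique(((f_hits[f_hits > 0] - 1L) %% n) + 1L)
    r_site <- revcomp(rev)
    r_hits <- gregexpr(r_site, doubled, fixed = TRUE)[[1]]
    r_hits <- unique(((r_hits[r_hits > 0] - 1L) %% n) + 1L)
    if (length(f_hits) != 1 || length(r_hits) != 1) return(NULL)
    f5 <- f_hits[1]                              # forward primer 5' base
    r5 <- r_hits[1] + nchar(rev) - 1L            # reverse primer 5' base
    r5 <- ((r5 - 1L) %% n) + 1L
    size <- ((r5 - f5) %% n) + 1L
    tibble(round = round, size = size,
           seq = subseq_chr(doubled, f5, f5 + size - 1L))
  }

  outer <- one_round(primers$outer_forward, primers$outer_reverse, "outer")
  if (is.null(outer)) return(fail("Outer primers missing or divergent: no product."))
  inner <- one_round(primers$inner_forward, primers$inner_reverse, "inner")
  if (is.null(inner)) return(fail("Inner primers missing or divergent: no product."))
  if (inner$size > outer$size) {
    return(fail("Inner product is not nested within the outer product."))
  }
  dplyr::bind_rows(outer, inner)
}

#' Build an assay configuration
#'
#' Locates the primer annealing sites and the assay enzymes' recognition
#' sites inside the XbaI-flanked region of study and stores the geometry all
#' simulation and interpretation functions share.
#'
#' @param ref Reference DNA string (or one-row tibble from [read_fasta()]).
#' @param region_start,region_end The region of study: top-strand cut-to-cut
#'   interval of the XbaI fragment under assay (1-based inclusive).
#' @param primers Named list of the four nested primers (defaults to
#'   [default_primers()]).
#' @return An `assay_config` list with the region, primers, primer 5'-base
#'   genomic coordinates (`if5`, `ir5`, `of5`, `or5`), and the intact inner
#'   product size.
#' @export
assay_config <- function(ref, region_start, region_end,
                         primers = default_primers()) {
  if (is.data.frame(ref)) ref <- ref$seq[[1]]
  region <- subseq_chr(ref, region_start, region_end)

  locate_one <- function(primer, sense) {
    target <- if (sense == "forward") primer else revcomp(primer)
    hits <- gregexpr(target, region, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (length(hits) != 1) {
      abort(sprintf("Primer must anneal exactly once in the region (found %d).",
                    length(hits)))
    }
    start <- region_start + hits[1] - 1L
    c(start = start, end = start + nchar(primer) - 1L)
  }
  ofp <- locate_one(primers$outer_forward, "forward")
  ifp <- locate_one(primers$inner_forward, "forward")
  orp <- locate_one(primers$outer_reverse, "reverse")
  irp <- locate_one(primers$inner_reverse, "reverse")
  config <- structure(list(
    region_start = region_start, region_end = region_end,
    primers = primers,
    of5 = unname(ofp["start"]), if5 = unname(ifp["start"]),
    or5 = unname(orp["end"]), ir5 = unname(irp["end"])
  ), class = "assay_config")
  # intact inner product: forward 5' -> region end, 4 nt XbaI fill, region
  # start -> reverse 5'
  config$intact_size <-
    (region_end - config$if5 + 1L) + 4L + (config$ir5 - region_start + 1L)
  config
}

#' The four nested IPCR primers
#'
#' The published primer set for the ABL assay: first-round (outer) and
#' second-round (inner) forward/reverse primers, 5'->3'.
#'
#' @return Named list of four DNA strings.
#' @export
default_primers <- function() {
  list(
    outer_reverse = "GGTACCTGGTGTCTGTCTCTATC",
    outer_forward = "AGAAGGTTTATGGGAGATGG",
    inner_reverse = "TCTCTCATATCTCAGAGCCTTC",
    inner_forward = "CTTCAGGAGCTCAGACTTTTAC"
  )
}

#' Interpret a product size as a breakpoint position
#'
#' Exact inverse of [predict_products()] under the perfect-annealing model
#' for the standard geometry (primer cassette at the 5' end of the region of
#' study; the retained fragment runs from the region start to the break).
#'
#' @param size Observed inner product size (bp).
#' @param config An [assay_config()].
#' @return The estimated breakpoint (1-based bp); `NA` with a message when
#'   `size` equals the intact product size (no break detectable).
#' @export
size_to_breakpoint <- function(size, config) {
  if (size <= 0) abort("Product size must be positive.")
  if (size > config$intact_size) {
    abort(sprintf("Size %d exceeds the intact product size (%d bp).",
                  size, config$intact_size))
  }
  if (size == config$intact_size) {
    message("Product size equals the intact size: no break detectable.")
    return(NA_integer_)
  }
  tail_len <- config$ir5 - config$region_start + 1L
  config$if5 + (size - tail_len) - 1L
}
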