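#' Curated ABL MRS catalogue
#'
#' The published catalogue of MRS elements in the ABL gene (gene-local
#' 1-based coordinates): one row per reported 16 bp x 8 bp element
#' combination, with matched sequences in match orientation, strands
#' (W = Watson, C = Crick), intervals, the reported signed distance (or
#' `"Overlap"`), and the exon/intron location. Used both as a desk-check of
#' the distance convention and as the planting plan for the synthetic
#' reference builder.
#'
#' @return A tibble with columns `site`, `mrs`, `seq16`, `strand16`,
#'   `start16`, `end16`, `seq8`, `strand8`, `start8`, `end8`, `distance`,
#'   `location`.
#' @export
abl_mrs_catalogue <- function() {
  path <- system.file("extdata", "abl_mrs_catalogue.tsv", package = "mrsbreak")
  out <- utils::read.delim(path, colClasses = c(
    site = "integer", mrs = "character", seq16 = "character",
    strand16 = "character", start16 = "integer", end16 = "integer",
    seq8 = "character", strand8 = "character", start8 = "integer",
    end8 = "integer", distance = "character", location = "character"
  ))
  as_tibble(out)
}

#' Reported apoptosis-induced breakpoints in the ABL gene
#'
#' The 27 chromosome-break positions (gene-local 1-based bp) identified by
#' nested IPCR in hydrogen-peroxide-treated cells: 18 in the NP69 line and 9
#' in the HK1 line. Used as planted break positions by the assay simulator.
#'
#' @return A tibble with columns `cell_line` and `position`.
#' @export
abl_breakpoints <- function() {
  tibble(
    cell_line = c(rep("NP69", 18), rep("HK1", 9)),
    position = c(
      129265L, 129287L, 129372L, 129408L, 129520L, 129534L, 129628L,
      129823L, 130633L, 130634L, 130638L, 130687L, 130699L, 130719L,
      130822L, 130864L, 131108L, 131232L,
      129152L, 129461L, 129739L, 130653L, 130696L, 130791L, 130854L,
      130921L, 131042L
    )
  )
}

#' Synthetic ABL-like gene model
#'
#' An 11-exon gene model over a 173,795 bp gene-local axis, constructed to be
#' consistent with the published constraints (intron 1 is ~140 kb and hosts
#' MRS sites 1-9; sites 10, 11 and 12 fall in introns 3, 7 and 10), with
#' annotations for SAR1, the three breakpoint cluster regions and the
#' XbaI-flanked region of study. The exon boundaries themselves are synthetic
#' placements, not the real gene structure.
#'
#' @return A `gene_model` tibble (see [load_gene_model()]).
#' @export
abl_gene_model <- function() {
  path <- system.file("extdata", "abl_synthetic_model.tsv", package = "mrsbreak")
  load_gene_model(path, gene_length = 173795L, gene_id = "ABL_synthetic")
}
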