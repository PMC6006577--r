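#' Read DNA sequences from a FASTA file
#'
#' Reads one or more records, normalises residues to uppercase and validates
#' the alphabet (A/C/G/T/N; `U` and any other character are rejected with the
#' offending position reported). Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `seq` (uppercase residue string) and `length` (bp).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgtn"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("No FASTA records in %s", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("Empty FASTA record: %s", ids[which(nchar(seqs) == 0)[1]]))
  }
  seqs <- vapply(seq_along(seqs), function(i) normalise_dna(seqs[i], ids[i]),
                 character(1))
  tibble(id = ids, seq = unname(seqs), length = nchar(seqs))
}

#' Write sequences to a FASTA file
#'
#' Lines are wrapped at 60 columns. Reading the file back with [read_fasta()]
#' reproduces the residues byte-identically.
#'
#' @param sequences A tibble with columns `id` and `seq` (as from
#'   [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.character(sequences)) {
    sequences <- tibble(id = names(sequences) %||% paste0("seq", seq_along(sequences)),
                        seq = unname(sequences))
  }
  set <- Biostrings::DNAStringSet(sequences$seq)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Load a gene model from a tab-delimited interval file
#'
#' The file is BED-like but 1-based fully inclusive (documented deliberately:
#' BED proper is 0-based half-open). Columns: `label`, `start`, `end` and an
#' optional `strand`. Labels starting with `exon`/`intron` (case-insensitive,
#' e.g. "Exon 1", "intron1") are classified as gene structure; everything else
#' (e.g. `SAR1`, `BCRA`, `region_of_study`) is a named annotation.
#'
#' @param path Path to the interval file. A header line is detected and
#'   skipped if the second field is not numeric.
#' @param gene_length Optional total gene length (bp); when given, intervals
#'   beyond it are an error and it is stored on the result.
#' @param gene_id Identifier stored on the result.
#' @return A tibble of intervals sorted by `start` with columns `label`,
#'   `start`, `end`, `strand`, `type` (`"exon"`, `"intron"` or
#'   `"annotation"`), carrying attributes `gene_id` and `gene_length`; class
#'   `gene_model`.
#' @export
load_gene_model <- function(path, gene_length = NULL, gene_id = basename(path)) {
  if (!file.exists(path)) abort(sprintf("Gene model file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) > 0 && is.na(suppressWarnings(as.numeric(fields[[1]][2])))) {
    fields <- fields[-1] # header row
  }
  if (length(fields) == 0) abort("Gene model file has no interval rows.")
  model <- tibble(
    label  = vapply(fields, `[[`, character(1), 1),
    start  = as.integer(vapply(fields, `[[`, character(1), 2)),
    end    = as.integer(vapply(fields, `[[`, character(1), 3)),
    strand = vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "W",
                    character(1))
  )
  validate_gene_model(model, gene_length = gene_length, gene_id = gene_id)
}

# Shared validation for file-loaded and programmatically built models.
validate_gene_model <- function(model, gene_length = NULL, gene_id = "gene") {
  if (any(is.na(model$start)) || any(is.na(model$end))) {
    abort("Gene model has non-numeric start/end fields.")
  }
  if (any(model$start < 1)) {
    abort("Gene model intervals must be 1-based: found start < 1.")
  }
  if (any(model$start > model$end)) {
    bad <- model$label[which(model$start > model$end)[1]]
    abort(sprintf("Interval '%s' has start > end.", bad))
  }
  if (!is.null(gene_length) && any(model$end > gene_length)) {
    bad <- model$label[which(model$end > gene_length)[1]]
    abort(sprintf("Interval '%s' extends beyond the gene length (%d bp).",
                  bad, gene_length))
  }
  model$type <- dplyr::case_when(
    grepl("^exon", model$label, ignore.case = TRUE)   ~ "exon",
    grepl("^intron", model$label, ignore.case = TRUE) ~ "intron",
    TRUE                                              ~ "annotation"
  )
  struct <- model[model$type != "annotation", ]
  if (anyDuplicated(struct$label)) {
    abort(sprintf("Duplicate exon/intron label: %s",
                  struct$label[duplicated(struct$label)][1]))
  }
  # exons and introns must not overlap one another
  if (nrow(struct) > 1) {
    s <- struct[order(struct$start), ]
    if (any(s$start[-1] <= s$end[-nrow(s)])) {
      abort("Exon/intron intervals overlap.")
    }
  }
  model <- dplyr::arrange(model, .data$start, .data$end)
  attr(model, "gene_id") <- gene_id
  attr(model, "gene_length") <- gene_length %||% max(model$end)
  class(model) <- c("gene_model", class(model))
  model
}

#' Locate the exon/intron containing a position
#'
#' Boundary positions belong to the interval whose closed `[start, end]` span
#' contains them. When the exons and introns tile the gene this is total over
#' `[1, gene_length]`.
#'
#' @param model A gene model from [load_gene_model()].
#' @param pos Integer vector of 1-based positions.
#' @return Character vector of exon/intron labels, one per position.
#' @export
locate_feature <- function(model, pos) {
  gl <- attr(model, "gene_length")
  if (any(pos < 1) || any(pos > gl)) {
    abort(sprintf("Position outside the gene [1, %d].", gl))
  }
  struct <- model[model$type %in% c("exon", "intron"), ]
  vapply(pos, function(p) {
    hit <- which(struct$start <= p & struct$end >= p)
    if (length(hit) == 0) {
      abort(sprintf("Position %d falls in no exon/intron interval.", p))
    }
    struct$label[hit[1]]
  }, character(1))
}

#' Extract a subsequence by a 1-based inclusive interval
#'
#' @param seq DNA string.
#' @param start,end 1-based inclusive bounds.
#' @return The subsequence; its width is `end - start + 1`.
#' @export
extract_interval <- function(seq, start, end) {
  if (start < 1 || end > nchar(seq) || start > end) {
    abort("Invalid interval for sequence of this length.")
  }
  subseq_chr(seq, start, end)
}

#' Length of a 1-based inclusive interval
#'
#' All package coordinates are 1-based and fully inclusive, so a span printed
#' as `185-412` is `412 - 185 + 1 = 228` bp.
#'
#' @param start,end Interval bounds.
#' @return Integer widths.
#' @export
interval_width <- function(start, end) {
  as.integer(end) - as.integer(start) + 1L
}
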