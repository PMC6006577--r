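# Independent oracles and shared fixtures.

# Naive position-by-position degenerate matcher, independent of the
# package's vectorised scanner. Returns hits in the same column layout.
naive_scan <- function(seq, element, max_mismatch = NULL) {
  pat <- mrs_pattern(element)
  max_mismatch <- if (is.null(max_mismatch)) pat$max_mismatch else max_mismatch
  syms <- strsplit(pat$symbols, "", fixed = TRUE)[[1]]
  L <- length(syms)
  classes <- lapply(syms, function(s) {
    cls <- switch(s, A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
                  N = c("A", "C", "G", "T"))
    cls
  })
  scan_one <- function(chars, strand, n) {
    out <- list()
    for (i in seq_len(length(chars) - L + 1)) {
      mm <- 0L
      for (j in seq_len(L)) {
        base <- chars[i + j - 1]
        ok <- if (base == "N") identical(syms[j], "N") else
          base %in% classes[[j]]
        if (!ok) mm <- mm + 1L
        if (mm > max_mismatch) break
      }
      if (mm <= max_mismatch) {
        if (strand == "W") {
          st <- i
        } else {
          st <- n - (i + L - 1) + 1
        }
        out[[length(out) + 1]] <- data.frame(
          element = element, start = as.integer(st),
          end = as.integer(st + L - 1), strand = strand,
          matched_seq = paste(chars[i:(i + L - 1)], collapse = ""),
          mismatches = mm)
      }
    }
    out
  }
  n <- nchar(seq)
  w <- scan_one(strsplit(seq, "")[[1]], "W", n)
  c_ <- scan_one(strsplit(revcomp(seq), "")[[1]], "C", n)
  hits <- do.call(rbind, c(w, c_))
  if (is.null(hits)) {
    return(tibble::tibble(element = character(), start = integer(),
                          end = integer(), strand = character(),
                          matched_seq = character(), mismatches = integer()))
  }
  hits <- hits[order(hits$start, hits$strand), ]
  rownames(hits) <- NULL
  tibble::as_tibble(hits)
}

# Independent quadratic MRS builder: same-element single-linkage chaining,
# then every merged-group cross pair retained when its best combination
# overlaps or is within max_gap.
naive_mrs <- function(hits8, hits16, max_gap = 250, merge_distance = 200) {
  chain <- function(h) {
    h <- h[order(h$start, h$end), ]
    g <- integer(nrow(h))
    if (nrow(h) == 0) return(h)
    g[1] <- 1
    run_end <- h$end[1]
    for (i in seq_len(nrow(h))[-1]) {
      g[i] <- if (h$start[i] - run_end - 1 <= merge_distance) g[i - 1] else
        g[i - 1] + 1
      run_end <- max(run_end, h$end[i])
    }
    h$g <- g
    h
  }
  h8 <- chain(hits8)
  h16 <- chain(hits16)
  out <- list()
  for (a in unique(h16$g)) {
    for (b in unique(h8$g)) {
      m16 <- h16[h16$g == a, ]
      m8 <- h8[h8$g == b, ]
      best <- Inf
      for (i in seq_len(nrow(m16))) {
        for (j in seq_len(nrow(m8))) {
          gp <- element_gap(m16$start[i], m16$end[i], m8$start[j], m8$end[j])
          score <- if (gp$overlap) -1 else abs(gp$gap)
          best <- min(best, score)
        }
      }
      if (best <= max_gap) {
        out[[length(out) + 1]] <- data.frame(
          span_start = min(m16$start, m8$start),
          span_end = max(m16$end, m8$end))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(span_start = integer(0), span_end = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$span_start, res$span_end), , drop = FALSE]
}

realise_pattern_for_test <- function(symbols) {
  mrsbreak:::realise_pattern(symbols)
}

# The synthetic gene bundle is expensive to build; share one per run.
.fixture_env <- new.env(parent = emptyenv())

synthetic_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- build_synthetic_abl(seed = 101)
  }
  .fixture_env$bundle
}

synthetic_partner_fixture <- function() {
  if (is.null(.fixture_env$partner)) {
    .fixture_env$partner <- build_synthetic_partner(seed = 102)
  }
  .fixture_env$partner
}
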