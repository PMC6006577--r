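#' Gene cleavage frequency from replicate band counts
#'
#' The cleavage frequency is the average number of cleaved-gene IPCR bands
#' per replicate: replicate counts are averaged within each independent
#' experiment, then the per-experiment means are averaged; the SD is taken
#' across experiments.
#'
#' @param counts Tibble with columns `sample`, `experiment`, `replicate`,
#'   `count` (non-negative integers).
#' @param replicate_range Expected replicates per experiment (inclusive
#'   bounds); counts outside it raise a warning, not an error. Default
#'   `c(4, 7)`.
#' @return A tibble with one row per sample: `sample`, `mean`, `sd`,
#'   `n_experiments`.
#' @export
#' @examples
#' counts <- tibble::tibble(sample = "treated", experiment = c(1, 1, 2, 2),
#'                          replicate = c(1, 2, 1, 2), count = c(2, 4, 3, 5))
#' cleavage_frequency(counts, replicate_range = c(2, 7))
cleavage_frequency <- function(counts, replicate_range = c(4, 7)) {
  if (nrow(counts) == 0) abort("Empty band-count table.")
  if (any(counts$count < 0)) abort("Band counts must be non-negative.")
  nrep <- dplyr::count(counts, .data$sample, .data$experiment)
  off <- nrep[nrep$n < replicate_range[1] | nrep$n > replicate_range[2], ]
  if (nrow(off) > 0) {
    warn(sprintf(
      "%d experiment(s) have replicate counts outside [%d, %d].",
      nrow(off), replicate_range[1], replicate_range[2]))
  }
  per_exp <- dplyr::summarise(
    dplyr::group_by(counts, .data$sample, .data$experiment),
    exp_mean = mean(.data$count), .groups = "drop_last")
  dplyr::ungroup(dplyr::summarise(
    per_exp,
    mean = mean(.data$exp_mean),
    sd = stats::sd(.data$exp_mean),
    n_experiments = dplyr::n()
  ))
}

#' Fold change of cleavage frequency, treated vs control
#'
#' @param treated,control Single rows (or means) from
#'   [cleavage_frequency()], or bare numeric means.
#' @return A list with `fold_change` (full precision) and `fold_change_1dp`
#'   (rounded to one decimal, the conventional reporting style).
#' @export
#' @examples
#' fold_change(3.4, 2.0)
fold_change <- function(treated, control) {
  t_mean <- if (is.data.frame(treated)) treated$mean[[1]] else treated
  c_mean <- if (is.data.frame(control)) control$mean[[1]] else control
  if (c_mean <= 0) abort("Control mean must be positive for a fold change.")
  fc <- t_mean / c_mean
  list(fold_change = fc, fold_change_1dp = round(fc, 1))
}

#' Two-sided two-sample t test on per-experiment cleavage frequencies
#'
#' Equal-variance Student's form by default (`var_equal = FALSE` gives
#' Welch). A thin, assay-shaped wrapper over [stats::t.test()] returning an
#' object with [generics::tidy()] and [generics::glance()] methods.
#'
#' @param a,b Numeric vectors (e.g. per-experiment means), each of length
#'   >= 2.
#' @param var_equal Use the pooled-variance Student form (default `TRUE`).
#' @return A `cleavage_test` object: the `htest` plus the group summaries.
#' @export
#' @examples
#' cleavage_t_test(c(2, 3, 4), c(4, 5, 6))
cleavage_t_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 values.")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal,
                      alternative = "two.sided")
  structure(
    list(htest = ht, mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b), var_equal = var_equal),
    class = "cleavage_test"
  )
}

#' @export
print.cleavage_test <- function(x, ...) {
  cat(sprintf(
    "Two-sided %s t test: t = %.4f, df = %.5g, p = %.6g\n  group means: %.4g vs %.4g (n = %d, %d)\n",
    if (x$var_equal) "Student's" else "Welch's",
    unname(x$htest$statistic), unname(x$htest$parameter),
    x$htest$p.value, x$mean_a, x$mean_b, x$n_a, x$n_b))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cleavage t-test result
#'
#' @param x A `cleavage_test`.
#' @param ... Unused.
#' @return One-row tibble: estimates, statistic, df, p-value, CI, method.
#' @export
tidy.cleavage_test <- function(x, ...) {
  tibble(
    estimate = x$mean_a - x$mean_b,
    estimate1 = x$mean_a, estimate2 = x$mean_b,
    statistic = unname(x$htest$statistic),
    p.value = x$htest$p.value,
    parameter = unname(x$htest$parameter),
    conf.low = x$htest$conf.int[1], conf.high = x$htest$conf.int[2],
    method = x$htest$method, alternative = x$htest$alternative
  )
}

#' Glance at a cleavage t-test result
#'
#' @param x A `cleavage_test`.
#' @param ... Unused.
#' @return One-row tibble with the statistic, p-value and significance at
#'   the conventional 0.05 threshold.
#' @export
glance.cleavage_test <- function(x, ...) {
  tibble(
    statistic = unname(x$htest$statistic),
    p.value = x$htest$p.value,
    significant = x$htest$p.value < 0.05,
    n_a = x$n_a, n_b = x$n_b
  )
}

#' Compare treated vs control band-count tables
#'
#' Computes the per-sample cleavage frequency summary, the fold change and
#' the two-sided t test on per-experiment means.
#'
#' @param counts Band-count tibble (see [cleavage_frequency()]).
#' @param control Name of the control sample in `counts`.
#' @param replicate_range Passed to [cleavage_frequency()].
#' @param var_equal Passed to [cleavage_t_test()].
#' @return A tibble with one row per non-control sample: frequency summary,
#'   `fold_change`, `t`, `p_value`.
#' @export
compare_cleavage <- function(counts, control, replicate_range = c(4, 7),
                             var_equal = TRUE) {
  summary <- cleavage_frequency(counts, replicate_range = replicate_range)
  if (!control %in% summary$sample) {
    abort(sprintf("Control sample '%s' not in the table.", control))
  }
  per_exp <- dplyr::summarise(
    dplyr::group_by(counts, .data$sample, .data$experiment),
    exp_mean = mean(.data$count), .groups = "drop")
  ctrl_means <- per_exp$exp_mean[per_exp$sample == control]
  treated <- summary[summary$sample != control, ]
  rows <- purrr::map(treated$sample, function(s) {
    t_means <- per_exp$exp_mean[per_exp$sample == s]
    tt <- cleavage_t_test(t_means, ctrl_means, var_equal = var_equal)
    fc <- fold_change(mean(t_means), mean(ctrl_means))
    tibble(sample = s, mean = mean(t_means), sd = stats::sd(t_means),
           n_experiments = length(t_means),
           control_mean = mean(ctrl_means),
           fold_change = fc$fold_change,
           fold_change_1dp = fc$fold_change_1dp,
           t = unname(tt$htest$statistic), p_value = tt$htest$p.value)
  })
  dplyr::bind_rows(rows)
}
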