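# DFE histograms, frequency-weighted DFE, mutational loads, positional
# fitness scores and compensatory-mutation calls.

fit_records <- function(x) {
  if (inherits(x, "drift_fit")) x$records else x
}

#' Histogram of fitness effects by mutation class
#'
#' Bins wrel values into half-open `[x, x + bin_width)` bins from 0 to
#' `top_bin`, with a final open bin for values above `top_bin`, tallied
#' separately for missense, nonsense and synonymous mutations. Eliminated
#' mutations (wrel = 0) fall in the first bin and are also reported
#' separately.
#'
#' @param records A `drift_fit` or its `records` data.frame.
#' @param bin_width Bin width (default 0.1).
#' @param top_bin Lower edge of the open top bin (default 1.4).
#' @return data.frame: `bin` label, `lower`, `upper`, counts per class,
#'   `total`; attribute `eliminated` holds per-class wrel = 0 counts.
#' @export
dfe_histogram <- function(records, bin_width = 0.1, top_bin = 1.4) {
  rec <- fit_records(records)
  rec <- rec[!is.na(rec$wrel), , drop = FALSE]
  edges <- seq(0, top_bin - bin_width, by = bin_width)
  labels <- c(sprintf("[%.1f,%.1f)", edges, edges + bin_width),
              sprintf(">%.1f", top_bin))
  idx <- findInterval(rec$wrel, c(edges, top_bin))
  classes <- c("missense", "nonsense", "synonymous")
  out <- data.frame(bin = labels,
                    lower = c(edges, top_bin),
                    upper = c(edges + bin_width, Inf))
  for (cl in classes) {
    out[[cl]] <- tabulate(idx[rec$class == cl], nbins = length(labels))
  }
  out$total <- out$missense + out$nonsense + out$synonymous
  attr(out, "eliminated") <- vapply(classes, function(cl) {
    sum(rec$class == cl & rec$wrel == 0)
  }, 0L)
  out
}

#' Frequency-weighted distribution of fitness effects
#'
#' Share of the selected pool's total mutation frequency falling in each
#' wrel range: frequencies of all mutations within a range are summed and
#' divided by the sum over all mutations. Shares sum to 1.
#'
#' @param records A `drift_fit` or records data.frame with `wrel` and
#'   `f_gn`.
#' @param breaks Range boundaries on the wrel axis (default: the category
#'   boundaries 0.6, 0.8, 1.1).
#' @param classes Restrict to these mutation classes (default all).
#' @return data.frame with `range`, `share`, `freq_sum`.
#' @export
frequency_weighted_dfe <- function(records, breaks = c(0.6, 0.8, 1.1),
                                   classes = NULL) {
  rec <- fit_records(records)
  rec <- rec[!is.na(rec$wrel), , drop = FALSE]
  if (!is.null(classes)) rec <- rec[rec$class %in% classes, , drop = FALSE]
  tot <- sum(rec$f_gn)
  if (!(tot > 0)) stop("all selected-pool frequencies are zero")
  cuts <- c(-Inf, breaks, Inf)
  lab <- c(sprintf("<=%.2g", breaks[1]),
           if (length(breaks) > 1)
             sprintf("(%.2g,%.2g]", breaks[-length(breaks)], breaks[-1]),
           sprintf(">%.2g", breaks[length(breaks)]))
  grp <- cut(rec$wrel, cuts, labels = lab, right = TRUE)
  fs <- tapply(rec$f_gn, grp, sum)
  fs[is.na(fs)] <- 0
  data.frame(range = lab, freq_sum = as.numeric(fs),
             share = as.numeric(fs) / tot, row.names = NULL)
}

#' Log fold change of frequency shares between two rounds
#'
#' @param summary_a,summary_b Outputs of [frequency_weighted_dfe()] on the
#'   earlier and later rounds (matching ranges).
#' @param log_base Base of the logarithm (default 10).
#' @return data.frame with `range`, `log_fold_change` (NA where the
#'   denominator share is zero, flagged in `undefined`).
#' @export
fold_change <- function(summary_a, summary_b, log_base = 10) {
  stopifnot(identical(summary_a$range, summary_b$range))
  undef <- summary_a$share == 0
  lfc <- ifelse(undef, NA_real_,
                log(summary_b$share / summary_a$share, base = log_base))
  data.frame(range = summary_a$range, log_fold_change = lfc,
             undefined = undef)
}

#' Per-round mutational loads
#'
#' `Nt` is the average number of nucleotide mutations per gene (sum of
#' nucleotide-level net frequencies), `Na` the average number of
#' nonsynonymous (missense + nonsense) amino-acid mutations per gene, `Ns`
#' the synonymous load, and `Na/Ns` their ratio. If fitted records are
#' supplied, loads are also split by fitness category.
#'
#' @param ft A `freq_table` (codon-level) for one library.
#' @param fit Optional `drift_fit` on the same library for category loads.
#' @return A list of class `mutational_loads`: `Nt`, `Na`, `Ns`, `NaNs`
#'   (NA-flagged when Ns is 0), and `by_category` when `fit` is given.
#' @export
mutational_loads <- function(ft, fit = NULL) {
  d <- ft[ft$codon_pos > 0, , drop = FALSE]
  nt <- sum(d$net_freq * d$n_nt_changes)
  aa <- aggregate_frequencies(d, max_nt_changes = 3L)
  na_load <- sum(aa$net_freq[aa$class %in% c("missense", "nonsense")])
  ns_load <- sum(aa$net_freq[aa$class == "synonymous"])
  by_cat <- NULL
  if (!is.null(fit)) {
    rec <- fit_records(fit)
    ok <- !is.na(rec$category)
    by_cat <- tapply(rec$f_gn[ok],
                     factor(rec$category[ok], WREL_CATEGORIES), sum)
    by_cat[is.na(by_cat)] <- 0
  }
  structure(list(Nt = nt, Na = na_load, Ns = ns_load,
                 NaNs = if (ns_load > 0) na_load / ns_load else NA_real_,
                 by_category = by_cat,
                 library_id = ft$library_id[1], round = ft$round[1]),
            class = "mutational_loads")
}

#' @export
print.mutational_loads <- function(x, ...) {
  cat(sprintf("Loads for '%s' (round %s): Nt = %.3f, Na = %.3f, Ns = %.3f, Na/Ns = %s\n",
              x$library_id, x$round, x$Nt, x$Na, x$Ns,
              if (is.na(x$NaNs)) "undefined" else sprintf("%.2f", x$NaNs)))
  if (!is.null(x$by_category)) {
    cat("  by category:",
        paste(names(x$by_category), signif(x$by_category, 3),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Positional fitness score
#'
#' Frequency-weighted positional wrel: for each ORF position,
#' `sum_i wrel_i * log2(1 + 10 * f_i)` over the single-nucleotide mutations
#' `i` at the position, with `f_i` the mutation's net frequency in the
#' scoring library. The normalized variant divides by
#' `sum_i log2(1 + 10 * f_i)`, giving a weighted average.
#'
#' @param records A `drift_fit` or records data.frame with `wrel`, `f_gn`.
#' @param normalized Return the weighted average rather than the sum.
#' @return data.frame with `codon_pos` and `score` (0 for positions with no
#'   observed mutation; NA in normalized form when all weights vanish).
#' @export
positional_wrel <- function(records, normalized = FALSE) {
  rec <- fit_records(records)
  rec <- rec[!is.na(rec$wrel), , drop = FALSE]
  w <- log2(1 + 10 * rec$f_gn)
  num <- tapply(rec$wrel * w, rec$codon_pos, sum)
  den <- tapply(w, rec$codon_pos, sum)
  score <- if (normalized) {
    ifelse(den > 0, num / den, NA_real_)
  } else {
    num
  }
  data.frame(codon_pos = as.integer(names(num)), score = as.numeric(score),
             row.names = NULL)
}

#' Call candidate compensatory mutations
#'
#' Compensatory mutations are enriched mutations: individual mutations with
#' wrel above the beneficial threshold, or positions whose normalized
#' positional score exceeds it.
#'
#' @param records A `drift_fit` or records data.frame.
#' @param thresholds A `wrel_thresholds` (taken from the fit if omitted).
#' @return list with `mutations` (records above threshold) and `positions`
#'   (positions with normalized positional score above threshold).
#' @export
call_compensatory <- function(records, thresholds = NULL) {
  if (inherits(records, "drift_fit") && is.null(thresholds)) {
    thresholds <- records$thresholds
  }
  if (is.null(thresholds)) stop("thresholds required")
  rec <- fit_records(records)
  rec <- rec[!is.na(rec$wrel), , drop = FALSE]
  muts <- rec[rec$wrel > thresholds$beneficial_min, , drop = FALSE]
  pos <- positional_wrel(rec, normalized = TRUE)
  pos <- pos[!is.na(pos$score) & pos$score > thresholds$beneficial_min, ,
             drop = FALSE]
  list(mutations = muts, positions = pos)
}
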