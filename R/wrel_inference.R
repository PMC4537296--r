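# Relative fitness (Wrel) inference.
#
# Model: each round, a mutation's frequency is (inherited + newly arising)
# times its per-round relative fitness w, so after n rounds
#   f(Gn) / f(G0) = sum_{k=1..n} w^k.
# The sum has no closed-form inverse for general n; w is recovered by a
# monotone grid with linear interpolation.

#' Expected frequency ratio after n rounds
#'
#' `sum_{k=1..n} w^k`: the factor by which a mutation with per-round
#' relative fitness `w` is expected to multiply its per-round occurrence
#' frequency after `n` rounds of mutagenesis and selection. Neutral (w = 1)
#' gives exactly n; lethal (w = 0) gives 0.
#'
#' @param n Round index (>= 1).
#' @param w Relative fitness values (vectorized, >= 0).
#' @return Expected `f(Gn)/f(G0)` ratio per `w`.
#' @export
expected_ratio <- function(n, w) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(all(w >= 0))
  out <- numeric(length(w))
  for (k in seq_len(n)) out <- out + w^k
  out
}

#' Invert the expected-ratio curve to a relative fitness
#'
#' Finds, for each observed ratio, the `w` whose expected ratio matches it,
#' on a grid from 0 to `w_max` in steps of `grid_step` with linear
#' interpolation between adjacent grid ratios (the curve is strictly
#' increasing). Ratios of 0 map to w = 0; ratios above the ratio attainable
#' at `w_max` are capped at `w_max` and flagged.
#'
#' @param ratio Observed `f(Gn)/f(G0)` ratios (>= 0).
#' @param n Round index.
#' @param grid_step Grid resolution in w.
#' @param w_max Upper bound of the fitness scale.
#' @return A data.frame with `wrel` and logical `capped`.
#' @export
invert_ratio <- function(ratio, n, grid_step = 0.01, w_max = 3.5) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(all(ratio >= 0, na.rm = TRUE))
  grid_w <- seq(0, w_max, by = grid_step)
  grid_r <- expected_ratio(n, grid_w)
  idx <- findInterval(ratio, grid_r, rightmost.closed = FALSE)
  wrel <- rep(NA_real_, length(ratio))
  capped <- rep(FALSE, length(ratio))
  ok <- !is.na(ratio)
  over <- ok & idx >= length(grid_w)
  wrel[over] <- w_max
  capped[over] <- ratio[over] > grid_r[length(grid_r)]
  interior <- ok & !over
  if (any(interior)) {
    i <- pmax(idx[interior], 1L)
    lo <- grid_r[i]; hi <- grid_r[i + 1L]
    frac <- ifelse(hi > lo, (ratio[interior] - lo) / (hi - lo), 0)
    wrel[interior] <- grid_w[i] + frac * grid_step
    exact0 <- ratio[interior] == 0
    wrel[interior][exact0] <- 0
  }
  data.frame(wrel = wrel, capped = capped)
}

#' Fit per-mutation relative fitness effects from a drift
#'
#' The central estimator: given codon-level frequency tables for the naive
#' pool (round 0) and a selected pool (round `n`), aggregates to amino-acid
#' mutations, forms the enrichment ratio `f(Gn)/f(G0)` and inverts the
#' geometric-series selection model to assign each single-nucleotide
#' amino-acid mutation a relative fitness `wrel` in `[0, w_max]` and a
#' five-way fitness category. Mutations below the sequencing-error
#' background in the naive pool take their occurrence rate from the base
#' substitution table; mutations with zero net frequency in the selected
#' pool are assigned `wrel = 0` (eliminated by selection).
#'
#' @param g0 `freq_table` for the naive (unselected) library.
#' @param gn `freq_table` for the selected library.
#' @param n Round index of `gn` (>= 1).
#' @param gene The [reference_gene()].
#' @param subst Optional `nt_subst_matrix`; computed from `g0` when NULL.
#' @param grid_step,w_max Grid parameters for [invert_ratio()].
#' @param thresholds `"empirical"` (derive from this fit's synonymous and
#'   nonsense distributions), `"paper_default"` (fixed 0.3/0.6/0.8/1.1), or
#'   a `wrel_thresholds` object.
#' @return An object of class `drift_fit`: list with `records` (one row per
#'   single-nucleotide amino-acid mutation: `codon_pos`, `ref_aa`,
#'   `alt_aa`, `class`, `f_g0`, `f_gn`, `ratio`, `wrel`, `category`, flag
#'   columns), `thresholds`, `n`, `library_id`, `subst`, `qc` counts.
#' @export
drift_fit <- function(g0, gn, n, gene, subst = NULL,
                      grid_step = 0.01, w_max = 3.5,
                      thresholds = c("empirical", "paper_default")) {
  stopifnot(inherits(gene, "reference_gene"))
  if (n < 1) stop("round index n must be >= 1")
  a0 <- aggregate_frequencies(g0)
  an <- aggregate_frequencies(gn)
  key0 <- paste(a0$codon_pos, a0$alt_aa)
  keyn <- paste(an$codon_pos, an$alt_aa)
  if (!setequal(key0, keyn)) {
    stop("naive and selected tables cover different mutational spaces")
  }
  an <- an[match(key0, keyn), ]
  rec <- data.frame(codon_pos = a0$codon_pos, ref_aa = a0$ref_aa,
                    alt_aa = a0$alt_aa, class = a0$class,
                    f_g0 = a0$net_freq, f_gn = an$net_freq,
                    below_background_g0 = a0$below_background,
                    stringsAsFactors = FALSE)

  if (is.null(subst)) subst <- substitution_matrix(g0, gene)
  # expected occurrence rate for below-background naive frequencies: sum of
  # substitution-table rates over the contributing codon variants
  if (any(rec$below_background_g0)) {
    space <- enumerate_codon_variants(gene, max_nt_changes = 1L)
    space$rate <- expected_g0_frequency(space, subst)
    exp_aa <- tapply(space$rate,
                     paste(space$codon_pos, space$alt_aa), sum)
    sub <- rec$below_background_g0
    rec$f_g0[sub] <- unname(exp_aa[paste(rec$codon_pos, rec$alt_aa)[sub]])
  }

  rec$undefined <- is.na(rec$f_g0) | rec$f_g0 <= 0
  rec$ratio <- ifelse(rec$undefined, NA_real_, rec$f_gn / rec$f_g0)
  inv <- invert_ratio(ifelse(is.na(rec$ratio), 0, rec$ratio), n,
                      grid_step = grid_step, w_max = w_max)
  rec$wrel <- ifelse(rec$undefined, NA_real_, inv$wrel)
  rec$capped <- !rec$undefined & inv$capped
  rec$eliminated <- !rec$undefined & rec$f_gn == 0
  rec$wrel[rec$eliminated] <- 0

  if (inherits(thresholds, "wrel_thresholds")) {
    thr <- thresholds
  } else {
    mode <- match.arg(thresholds)
    thr <- if (mode == "paper_default") {
      derive_thresholds(mode = "paper_default")
    } else {
      derive_thresholds(
        syn_wrels = rec$wrel[rec$class == "synonymous" & !rec$undefined],
        nonsense_wrels = rec$wrel[rec$class == "nonsense" & !rec$undefined],
        mode = "empirical")
    }
  }
  rec$category <- rep(NA_character_, nrow(rec))
  ok <- !rec$undefined
  rec$category[ok] <- as.character(classify_wrel(rec$wrel[ok], thr))

  structure(list(records = rec, thresholds = thr, n = n,
                 library_id = gn$library_id[1],
                 naive_library_id = g0$library_id[1],
                 subst = subst, grid_step = grid_step, w_max = w_max,
                 qc = c(n_mutations = nrow(rec),
                        n_undefined = sum(rec$undefined),
                        n_below_background_g0 = sum(rec$below_background_g0),
                        n_eliminated = sum(rec$eliminated),
                        n_capped = sum(rec$capped))),
            class = "drift_fit")
}

WREL_CATEGORIES <- c("highly_deleterious", "deleterious", "nearly_neutral",
                     "neutral", "beneficial")

#' Derive fitness-category thresholds
#'
#' Empirical mode uses the distributions of synonymous and nonsense
#' mutations as internal calibrators: the deleterious boundary is the
#' synonymous mean minus 2 SD (computed per library, then averaged), the
#' nearly-neutral boundary the synonymous mean minus 1 SD, the beneficial
#' boundary the synonymous mean plus 2 SD, and the highly-deleterious
#' boundary the nonsense mean plus 2 SD. `paper_default` mode returns the
#' fixed boundaries 0.3 / 0.6 / 0.8 / 1.1. Raw (unrounded) values are kept;
#' `round_thresholds()` gives the one-decimal reporting form.
#'
#' @param syn_wrels Synonymous wrel values: numeric vector, or a list of
#'   vectors (one per library).
#' @param nonsense_wrels Nonsense wrel values, same forms.
#' @param mode `"empirical"` or `"paper_default"`.
#' @return A `wrel_thresholds` object with `highly_deleterious_max`,
#'   `deleterious_max`, `nearly_neutral_max`, `beneficial_min`, and a
#'   `provenance` list (per-library means/SDs).
#' @export
derive_thresholds <- function(syn_wrels = NULL, nonsense_wrels = NULL,
                              mode = c("empirical", "paper_default")) {
  mode <- match.arg(mode)
  if (mode == "paper_default") {
    return(new_thresholds(0.3, 0.6, 0.8, 1.1,
                          provenance = list(mode = "paper_default")))
  }
  syn <- if (is.list(syn_wrels)) syn_wrels else list(syn_wrels)
  if (any(vapply(syn, length, 0L) < 2)) {
    stop("need at least 2 synonymous wrel values per library")
  }
  syn_mean <- vapply(syn, mean, 0)
  syn_sd <- vapply(syn, stats::sd, 0)
  del <- mean(syn_mean - 2 * syn_sd)
  nn <- mean(syn_mean - syn_sd)
  ben <- mean(syn_mean + 2 * syn_sd)
  hd <- NA_real_
  non_mean <- non_sd <- NULL
  if (!is.null(nonsense_wrels)) {
    non <- if (is.list(nonsense_wrels)) nonsense_wrels else list(nonsense_wrels)
    non_mean <- vapply(non, mean, 0)
    non_sd <- vapply(non, function(x) if (length(x) > 1) stats::sd(x) else 0, 0)
    hd <- mean(non_mean + 2 * non_sd)
  }
  new_thresholds(hd, del, nn, ben,
                 provenance = list(mode = "empirical",
                                   syn_mean = syn_mean, syn_sd = syn_sd,
                                   nonsense_mean = non_mean,
                                   nonsense_sd = non_sd))
}

new_thresholds <- function(hd, del, nn, ben, provenance) {
  if (!is.na(hd) && hd > del) {
    stop("highly_deleterious_max must not exceed deleterious_max")
  }
  # degenerate (zero-variance) calibrator distributions collapse boundaries,
  # so ordering is required only weakly
  if (!(del <= nn && nn <= ben)) {
    stop("thresholds must satisfy deleterious <= nearly_neutral <= beneficial")
  }
  structure(list(highly_deleterious_max = hd, deleterious_max = del,
                 nearly_neutral_max = nn, beneficial_min = ben,
                 provenance = provenance),
            class = "wrel_thresholds")
}

#' Round thresholds to one decimal for reporting
#'
#' @param thr A `wrel_thresholds` object.
#' @return A `wrel_thresholds` with boundaries rounded to one decimal (raw
#'   values kept in `provenance$raw`).
#' @export
round_thresholds <- function(thr) {
  new_thresholds(round(thr$highly_deleterious_max, 1),
                 round(thr$deleterious_max, 1),
                 round(thr$nearly_neutral_max, 1),
                 round(thr$beneficial_min, 1),
                 provenance = c(thr$provenance, list(raw = unclass(thr))))
}

#' @export
print.wrel_thresholds <- function(x, ...) {
  cat(sprintf(
    "Wrel thresholds: highly-deleterious <= %.3g < deleterious <= %.3g < nearly-neutral <= %.3g < neutral <= %.3g < beneficial\n",
    x$highly_deleterious_max, x$deleterious_max, x$nearly_neutral_max,
    x$beneficial_min))
  invisible(x)
}

#' Classify relative fitness values
#'
#' Half-open partition of the fitness scale: `(-, hd]` highly deleterious,
#' `(hd, del]` deleterious, `(del, nn]` nearly neutral, `(nn, ben]` neutral,
#' `(ben, -)` beneficial. Highly-deleterious is a sub-class of deleterious
#' in summaries.
#'
#' @param wrel Numeric wrel values (>= 0).
#' @param thresholds A `wrel_thresholds` object.
#' @return Factor with levels highly_deleterious, deleterious,
#'   nearly_neutral, neutral, beneficial.
#' @export
classify_wrel <- function(wrel, thresholds) {
  if (any(wrel < 0, na.rm = TRUE)) stop("negative wrel")
  hd <- thresholds$highly_deleterious_max
  if (is.na(hd)) hd <- -Inf
  out <- ifelse(wrel <= hd, "highly_deleterious",
         ifelse(wrel <= thresholds$deleterious_max, "deleterious",
         ifelse(wrel <= thresholds$nearly_neutral_max, "nearly_neutral",
         ifelse(wrel <= thresholds$beneficial_min, "neutral", "beneficial"))))
  factor(out, levels = WREL_CATEGORIES)
}

# ---- drift_fit methods -----------------------------------------------------

#' @export
print.drift_fit <- function(x, ...) {
  cat("Relative fitness fit: library '", x$library_id, "' (round ", x$n,
      ") vs naive '", x$naive_library_id, "'\n", sep = "")
  cat(" ", x$qc[["n_mutations"]], "amino-acid mutations;",
      x$qc[["n_eliminated"]], "eliminated,",
      x$qc[["n_below_background_g0"]], "below background in naive pool,",
      x$qc[["n_capped"]], "capped,", x$qc[["n_undefined"]], "undefined\n")
  print(x$thresholds)
  invisible(x)
}

#' @export
summary.drift_fit <- function(object, ...) {
  rec <- object$records
  by_class <- lapply(split(rec$wrel[!rec$undefined],
                           rec$class[!rec$undefined]),
                     function(w) c(n = length(w), mean = mean(w),
                                   sd = stats::sd(w)))
  comp <- table(class = rec$class[!rec$undefined],
                category = rec$category[!rec$undefined])
  out <- list(library_id = object$library_id, n = object$n,
              by_class = by_class, composition = comp,
              thresholds = object$thresholds, qc = object$qc)
  class(out) <- "summary.drift_fit"
  out
}

#' @export
print.summary.drift_fit <- function(x, ...) {
  cat("Fitness-effect summary for '", x$library_id, "' (round ", x$n, ")\n",
      sep = "")
  for (cl in names(x$by_class)) {
    s <- x$by_class[[cl]]
    cat(sprintf("  %-11s n = %4d  mean wrel = %.3f  SD = %.3f\n",
                cl, s[["n"]], s[["mean"]], s[["sd"]]))
  }
  cat("Category composition:\n")
  print(x$composition)
  print(x$thresholds)
  invisible(x)
}

#' @export
coef.drift_fit <- function(object, ...) {
  rec <- object$records
  stats::setNames(rec$wrel, paste0(rec$ref_aa, rec$codon_pos, rec$alt_aa))
}

#' @export
fitted.drift_fit <- function(object, ...) {
  rec <- object$records
  expected_ratio(object$n, ifelse(is.na(rec$wrel), 0, rec$wrel))
}

#' @export
residuals.drift_fit <- function(object, ...) {
  object$records$ratio - fitted(object)
}

#' Predict selected-pool frequencies from a fitted drift
#'
#' Expected `f(Gn)` for the fitted mutations after `n` rounds (default: the
#' fitted round), i.e. `f(G0) * sum_{k=1..n} wrel^k`.
#'
#' @param object A `drift_fit`.
#' @param n Round index to predict (defaults to the fitted round).
#' @param ... Unused.
#' @return Numeric vector of expected frequencies, one per record.
#' @export
predict.drift_fit <- function(object, n = object$n, ...) {
  rec <- object$records
  rec$f_g0 * expected_ratio(n, ifelse(is.na(rec$wrel), 0, rec$wrel))
}

#' Plot the distribution of fitness effects of a fit
#'
#' Stacked-by-class histogram of wrel values in 0.1-wide bins, with the
#' final bin open above `top_bin`.
#'
#' @param x A `drift_fit`.
#' @param bin_width,top_bin Binning parameters (see [dfe_histogram()]).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.drift_fit <- function(x, bin_width = 0.1, top_bin = 1.4, ...) {
  h <- dfe_histogram(x$records, bin_width = bin_width, top_bin = top_bin)
  m <- t(as.matrix(h[, c("missense", "nonsense", "synonymous")]))
  graphics::barplot(m, names.arg = h$bin, las = 2, legend.text = rownames(m),
                    xlab = "relative fitness (wrel)",
                    ylab = "mutations", ...)
  invisible(x)
}

#' Export a fitted drift to TSV
#'
#' @param fit A `drift_fit`.
#' @param path Output path.
#' @export
write_fit_tsv <- function(fit, path) {
  rec <- fit$records
  rec$library_id <- fit$library_id
  rec$n <- fit$n
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
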