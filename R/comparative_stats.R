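# Comparison of the experimental fitness map with external predictor,
# conservation and biophysical-constraint score tables. Scores are consumed
# from TSV, never computed here.

#' Read a predictor/constraint score table
#'
#' Expected TSV columns (missing ones tolerated, missing values as NA):
#' `codon_pos`, `ref_aa`, `alt_aa`, `provean`, `sift`, `ddg`,
#' `dist_center_A`, `local_closeness`, `rate4site_mu`, `min_div`,
#' `ortholog_observed`.
#'
#' @param path TSV path.
#' @return data.frame of scores keyed by (codon_pos, ref_aa, alt_aa).
#' @export
read_predictor_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon_pos", "ref_aa", "alt_aa")
  if (!all(need %in% names(d))) {
    stop("predictor table must have columns ", paste(need, collapse = ", "))
  }
  d
}

join_scores <- function(records, scores) {
  rec <- fit_records(records)
  key_r <- paste(rec$codon_pos, rec$alt_aa)
  key_s <- paste(scores$codon_pos, scores$alt_aa)
  idx <- match(key_r, key_s)
  merged <- cbind(rec, scores[idx, setdiff(names(scores), names(rec)),
                              drop = FALSE])
  attr(merged, "n_dropped") <- sum(is.na(idx))
  merged
}

#' Confusion summary from raw counts
#'
#' @param tp,tn,fp,fn Counts.
#' @return A `confusion_summary`: counts plus TPR, TNR, FPR, FNR, accuracy.
#' @export
confusion_summary <- function(tp, tn, fp, fn) {
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 TPR = tp / (tp + fn), TNR = tn / (tn + fp),
                 FPR = fp / (tn + fp), FNR = fn / (tp + fn),
                 accuracy = (tp + tn) / (tp + tn + fp + fn)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  TN %d  FP %d\n", x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("TPR %.1f%%  TNR %.1f%%  accuracy %.1f%%\n",
              100 * x$TPR, 100 * x$TNR, 100 * x$accuracy))
  invisible(x)
}

#' Benchmark a deleteriousness predictor against the fitness map
#'
#' Truth labels come from the drift: deleterious when
#' `wrel <= wrel_deleterious_cutoff`, neutral otherwise (or only when
#' `wrel > neutral_min` if nearly-neutral mutations are excluded). The
#' predictor calls deleterious when its score is at or below `score_cutoff`.
#'
#' @param records A `drift_fit` or records data.frame.
#' @param scores Predictor table (see [read_predictor_table()]).
#' @param score_col Column of `scores` holding the predictor score.
#' @param score_cutoff Predictor deleterious cutoff (default -2.5, the
#'   PROVEAN convention).
#' @param wrel_deleterious_cutoff Truth deleterious boundary (default 0.6).
#' @param exclude_nearly_neutral Drop mutations with
#'   `wrel in (wrel_deleterious_cutoff, neutral_min]` before counting.
#' @param neutral_min Neutral truth boundary used when excluding
#'   nearly-neutral mutations (default 0.8).
#' @return A `confusion_summary`; attributes `n_used`, `n_excluded`,
#'   `n_dropped` (no score or no wrel).
#' @export
confusion_vs_predictor <- function(records, scores, score_col = "provean",
                                   score_cutoff = -2.5,
                                   wrel_deleterious_cutoff = 0.6,
                                   exclude_nearly_neutral = FALSE,
                                   neutral_min = 0.8) {
  m <- join_scores(records, scores)
  s <- m[[score_col]]
  ok <- !is.na(s) & !is.na(m$wrel)
  if (!any(ok)) stop("no mutations shared between fitness map and scores")
  m <- m[ok, ]; s <- s[ok]
  excluded <- 0L
  if (exclude_nearly_neutral) {
    nn <- m$wrel > wrel_deleterious_cutoff & m$wrel <= neutral_min
    excluded <- sum(nn)
    m <- m[!nn, ]; s <- s[!nn]
  }
  truth_del <- m$wrel <= wrel_deleterious_cutoff
  pred_del <- s <= score_cutoff
  cs <- confusion_summary(tp = sum(truth_del & pred_del),
                          tn = sum(!truth_del & !pred_del),
                          fp = sum(!truth_del & pred_del),
                          fn = sum(truth_del & !pred_del))
  attr(cs, "n_used") <- nrow(m)
  attr(cs, "n_excluded") <- excluded
  cs
}

#' Correlation between wrel and a predictor score
#'
#' @param records A `drift_fit` or records data.frame.
#' @param scores Predictor table.
#' @param score_col Score column name.
#' @return list with `pearson`, `spearman`, `n`, and the paired `data` for
#'   scatter export.
#' @export
score_wrel_correlation <- function(records, scores, score_col = "provean") {
  m <- join_scores(records, scores)
  s <- m[[score_col]]
  ok <- !is.na(s) & !is.na(m$wrel)
  if (sum(ok) < 3) stop("need at least 3 paired (wrel, score) points")
  list(pearson = stats::cor(m$wrel[ok], s[ok]),
       spearman = stats::cor(m$wrel[ok], s[ok], method = "spearman"),
       n = sum(ok),
       data = data.frame(codon_pos = m$codon_pos[ok], ref_aa = m$ref_aa[ok],
                         alt_aa = m$alt_aa[ok], wrel = m$wrel[ok],
                         score = s[ok]))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The maximum absolute gap between the two empirical CDFs, computed
#' directly from the pooled sample points, with the classical asymptotic
#' p-value `2 * sum (-1)^(k-1) exp(-2 k^2 z^2)`, `z = D * sqrt(n1 n2 /
#' (n1 + n2))`.
#'
#' @param x,y Numeric samples (at least 2 points each).
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 points")
  pts <- sort(unique(c(x, y)))
  cdf_x <- vapply(pts, function(t) mean(x <= t), 0)
  cdf_y <- vapply(pts, function(t) mean(y <= t), 0)
  d <- max(abs(cdf_x - cdf_y))
  n1 <- length(x); n2 <- length(y)
  z <- d * sqrt(n1 * n2 / (n1 + n2))
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * z^2))
  list(statistic = d, p_value = max(min(p, 1), 0))
}

#' Compare constraint distributions between fitness groups
#'
#' For each constraint variable, the empirical distributions in a
#' "deleterious" group (`wrel <= 0.6`) and a "neutral/beneficial" group
#' (`wrel >= 0.8`) — or, with `grouping = "ortholog"`, in ortholog-observed
#' versus unobserved exchanges — are compared with the two-sample KS test.
#'
#' @param records A `drift_fit` or records data.frame.
#' @param scores Predictor/constraint table.
#' @param vars Constraint columns to compare (default ddg, dist_center_A,
#'   local_closeness, intersected with available columns).
#' @param grouping `"wrel"` or `"ortholog"`.
#' @param deleterious_max,neutral_min Group boundaries on the wrel scale.
#' @return data.frame with one row per variable: group sizes, KS statistic,
#'   p-value.
#' @export
constraint_distributions <- function(records, scores,
                                     vars = c("ddg", "dist_center_A",
                                              "local_closeness"),
                                     grouping = c("wrel", "ortholog"),
                                     deleterious_max = 0.6,
                                     neutral_min = 0.8) {
  grouping <- match.arg(grouping)
  m <- join_scores(records, scores)
  vars <- intersect(vars, names(m))
  if (length(vars) == 0) stop("no constraint columns found")
  if (grouping == "wrel") {
    g1 <- !is.na(m$wrel) & m$wrel <= deleterious_max
    g2 <- !is.na(m$wrel) & m$wrel >= neutral_min
    labels <- c("deleterious", "neutral_beneficial")
  } else {
    if (is.null(m$ortholog_observed)) stop("no ortholog_observed column")
    g2 <- !is.na(m$ortholog_observed) & as.logical(m$ortholog_observed)
    g1 <- !is.na(m$ortholog_observed) & !as.logical(m$ortholog_observed)
    labels <- c("ortholog_unobserved", "ortholog_observed")
  }
  out <- do.call(rbind, lapply(vars, function(v) {
    a <- m[[v]][g1]; b <- m[[v]][g2]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      stop("group with fewer than 2 members for ", v)
    }
    ks <- ks_two_sample(a, b)
    data.frame(variable = v, group1 = labels[1], n1 = length(a),
               group2 = labels[2], n2 = length(b),
               ks_statistic = ks$statistic, p_value = ks$p_value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fitness-category shares by ortholog divergence bin
#'
#' Mutations observed in orthologs are binned by the sequence divergence of
#' the closest ortholog carrying the exchange; exchanges unobserved in any
#' ortholog form their own stratum. Within each bin the fraction of
#' mutations per fitness category is reported (shares sum to 1 per bin).
#'
#' @param records A `drift_fit` or records data.frame with `category`.
#' @param scores Table with `min_div` (fraction) and `ortholog_observed`.
#' @param bin_edges Divergence bin edges (default 0.35, 0.5).
#' @return data.frame: `bin`, `category`, `n`, `share`.
#' @export
divergence_binning <- function(records, scores, bin_edges = c(0.35, 0.5)) {
  m <- join_scores(records, scores)
  m <- m[!is.na(m$category), , drop = FALSE]
  observed <- !is.na(m$ortholog_observed) & as.logical(m$ortholog_observed)
  lab <- c(sprintf("<=%g", bin_edges[1]),
           if (length(bin_edges) > 1)
             sprintf("(%g,%g]", bin_edges[-length(bin_edges)], bin_edges[-1]),
           sprintf(">%g", bin_edges[length(bin_edges)]))
  bin <- rep("unobserved", nrow(m))
  bin[observed] <- as.character(cut(m$min_div[observed],
                                    c(-Inf, bin_edges, Inf), labels = lab))
  out <- do.call(rbind, lapply(split(seq_len(nrow(m)), bin), function(i) {
    tab <- table(factor(m$category[i], WREL_CATEGORIES))
    data.frame(bin = bin[i[1]], category = names(tab), n = as.integer(tab),
               share = as.integer(tab) / length(i),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
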