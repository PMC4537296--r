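# Read mapping, codon-level counting and background subtraction.
#
# Coordinates: the mapping reference is upstream + ORF concatenated;
# nucleotide offsets are 1-based in that concatenated sequence. Codon
# positions are -U..-1 (upstream control) and 1..L (ORF).

reference_string <- function(gene) {
  paste(c(gene$upstream_codons, gene$orf_codons), collapse = "")
}

n_upstream <- function(gene) length(gene$upstream_codons)

# concatenated codon index -> signed codon position
codon_index_to_pos <- function(j, gene) {
  u <- n_upstream(gene)
  ifelse(j <= u, j - u - 1L, j - u)
}

codon_at <- function(gene, pos) {
  u <- n_upstream(gene)
  ifelse(pos < 0, gene$upstream_codons[pos + u + 1L], gene$orf_codons[pos])
}

#' Map short reads to the reference by exhaustive ungapped alignment
#'
#' Each read is tried at every ungapped offset of the concatenated
#' upstream+ORF reference; it is assigned the offset with the fewest
#' mismatches (ties to the smallest offset) provided the mismatch count does
#' not exceed `max_mismatches`. Reads shorter than `min_run` are discarded.
#' Indels are out of scope: alignment is substitution-only.
#'
#' @param reads Character vector of read sequences (A/C/G/T).
#' @param gene A [reference_gene()].
#' @param max_mismatches Maximum mismatches for a valid placement.
#' @param min_run Minimal read length retained.
#' @return A data.frame of class `read_placements` with columns `seq`,
#'   `offset` (1-based nt offset, NA if unmapped), `mismatches`, `mapped`.
#' @export
map_reads <- function(reads, gene, max_mismatches = 6L, min_run = 24L) {
  if (length(reads) == 0) {
    warning("empty read set")
    return(placements_frame(character(0), integer(0), integer(0), logical(0)))
  }
  reads <- toupper(as.character(reads))
  refc <- strsplit(reference_string(gene), "")[[1]]
  rl <- length(refc)
  window_cache <- new.env(parent = emptyenv())
  offsets <- rep(NA_integer_, length(reads))
  mism <- rep(NA_integer_, length(reads))
  for (i in seq_along(reads)) {
    len <- nchar(reads[i])
    if (len < min_run || len > rl) next
    key <- as.character(len)
    win <- window_cache[[key]]
    if (is.null(win)) {
      noff <- rl - len + 1L
      win <- matrix("", nrow = noff, ncol = len)
      for (j in seq_len(len)) win[, j] <- refc[seq_len(noff) + j - 1L]
      window_cache[[key]] <- win
    }
    rc <- strsplit(reads[i], "")[[1]]
    counts <- rowSums(win != matrix(rc, nrow = nrow(win), ncol = len,
                                    byrow = TRUE))
    best <- which.min(counts)  # ties -> smallest offset
    if (counts[best] <= max_mismatches) {
      offsets[i] <- best
      mism[i] <- as.integer(counts[best])
    }
  }
  placements_frame(reads, offsets, mism, !is.na(offsets))
}

placements_frame <- function(seq, offset, mismatches, mapped) {
  structure(data.frame(seq = seq, offset = offset, mismatches = mismatches,
                       mapped = mapped, stringsAsFactors = FALSE),
            class = c("read_placements", "data.frame"))
}

#' Count codon mutations from placed reads
#'
#' A codon contributes counts from a read only if all three of its bases lie
#' within the read and outside the `edge_trim` bases trimmed at each read
#' end (read edges carry elevated sequencing error). A read whose trimmed
#' span covers a codon adds to that codon's coverage; if the observed codon
#' differs from the reference it also increments the corresponding
#' (position, alternative codon) count. A codon overlapping the trimmed edge
#' contributes neither count nor coverage, keeping frequencies unbiased.
#'
#' @param placements A `read_placements` frame from [map_reads()] (or any
#'   data.frame with `seq` and `offset`; rows with NA offset are ignored).
#' @param gene A [reference_gene()].
#' @param edge_trim Bases masked at each read end.
#' @param library_id,round Labels carried into downstream tables.
#' @return A `codon_counts` object: list with `counts` (codon_pos,
#'   ref_codon, alt_codon, count), `coverage` (codon_pos, coverage),
#'   `library_id`, `round`, `n_reads`.
#' @export
count_codon_mutations <- function(placements, gene, edge_trim = 2L,
                                  library_id = "lib", round = NA_integer_) {
  pl <- placements[!is.na(placements$offset), , drop = FALSE]
  u <- n_upstream(gene)
  ncod <- u + length(gene$orf_codons)
  ref_codons_all <- c(gene$upstream_codons, gene$orf_codons)
  coverage <- integer(ncod)
  counts <- new.env(parent = emptyenv())
  if (nrow(pl) > 0) {
    pl$len <- nchar(pl$seq)
    for (grp in split(pl, paste(pl$offset, pl$len))) {
      off <- grp$offset[1]; len <- grp$len[1]
      lo <- off + edge_trim
      hi <- off + len - 1L - edge_trim
      if (hi - lo + 1L < 3L) next
      j1 <- ceiling((lo - 1L) / 3L) + 1L   # first codon fully inside span
      j2 <- hi %/% 3L                      # last codon fully inside span
      if (j2 < j1) next
      j2 <- min(j2, ncod)
      js <- j1:j2
      coverage[js] <- coverage[js] + nrow(grp)
      for (j in js) {
        rel <- 3L * (j - 1L) + 1L - off + 1L  # codon start within read
        obs <- substr(grp$seq, rel, rel + 2L)
        mut <- obs != ref_codons_all[j]
        if (any(mut)) {
          for (alt in unique(obs[mut])) {
            key <- paste0(j, ":", alt)
            counts[[key]] <- (counts[[key]] %||% 0L) + sum(obs[mut] == alt)
          }
        }
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) > 0) {
    parts <- strsplit(keys, ":", fixed = TRUE)
    j <- as.integer(vapply(parts, `[`, "", 1))
    alt <- vapply(parts, `[`, "", 2)
    cnt_df <- data.frame(codon_pos = codon_index_to_pos(j, gene),
                         ref_codon = ref_codons_all[j], alt_codon = alt,
                         count = vapply(keys, function(k) counts[[k]], 0L),
                         stringsAsFactors = FALSE)
    cnt_df <- cnt_df[order(cnt_df$codon_pos, cnt_df$alt_codon), ]
    rownames(cnt_df) <- NULL
  } else {
    cnt_df <- data.frame(codon_pos = integer(0), ref_codon = character(0),
                         alt_codon = character(0), count = integer(0),
                         stringsAsFactors = FALSE)
  }
  cov_df <- data.frame(codon_pos = codon_index_to_pos(seq_len(ncod), gene),
                       coverage = coverage)
  codon_counts(cnt_df, cov_df, library_id = library_id, round = round,
               n_reads = nrow(pl))
}

#' Assemble a codon count table
#'
#' Constructor for pre-computed count tables (e.g. from an external aligner
#' or the simulator's direct-count mode), bypassing [map_reads()].
#'
#' @param counts data.frame with `codon_pos`, `ref_codon`, `alt_codon`,
#'   `count`.
#' @param coverage data.frame with `codon_pos`, `coverage`.
#' @param library_id,round Labels.
#' @param n_reads Optional read count for the log.
#' @return A `codon_counts` object.
#' @export
codon_counts <- function(counts, coverage, library_id = "lib",
                         round = NA_integer_, n_reads = NA_integer_) {
  stopifnot(all(c("codon_pos", "ref_codon", "alt_codon", "count") %in%
                  names(counts)),
            all(c("codon_pos", "coverage") %in% names(coverage)))
  if (any(counts$count < 0) || any(coverage$coverage < 0)) {
    stop("negative counts or coverage")
  }
  structure(list(counts = counts, coverage = coverage,
                 library_id = library_id, round = round, n_reads = n_reads),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon counts for library '", x$library_id, "' (round ", x$round,
      "): ", nrow(x$counts), " mutated (pos, codon) entries, ",
      sum(x$counts$count), " mutation observations\n", sep = "")
  invisible(x)
}

position_frequency <- function(cc) {
  # total mutated fraction per codon position
  tot <- tapply(cc$counts$count, cc$counts$codon_pos, sum)
  cov <- cc$coverage
  f <- numeric(nrow(cov))
  idx <- match(as.integer(names(tot)), cov$codon_pos)
  f[idx[!is.na(idx)]] <- unname(tot)[!is.na(idx)]
  ifelse(cov$coverage > 0, f / cov$coverage, NA_real_)
}

#' Estimate the sequencing-error background
#'
#' Per-position mutation frequencies over the unmutagenized upstream region
#' summarize the error floor of the library: their mean is subtracted from
#' all ORF frequencies, the per-position values are kept as a diagnostic.
#'
#' @param counts A `codon_counts` object covering the upstream region.
#' @param gene A [reference_gene()] with at least one upstream codon.
#' @return A `background_model`: list with `mean`, `sd`, `per_position`
#'   (codon_pos, frequency), `library_id`.
#' @export
estimate_background <- function(counts, gene) {
  f <- position_frequency(counts)
  up <- counts$coverage$codon_pos < 0 & !is.na(f)
  if (!any(up)) stop("no covered upstream positions: cannot estimate background")
  per_pos <- data.frame(codon_pos = counts$coverage$codon_pos[up],
                        frequency = f[up])
  structure(list(mean = mean(per_pos$frequency),
                 sd = if (nrow(per_pos) > 1) stats::sd(per_pos$frequency) else 0,
                 per_position = per_pos,
                 library_id = counts$library_id),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Background for '%s': mean %.3g (SD %.3g) over %d upstream positions\n",
              x$library_id, x$mean, x$sd, nrow(x$per_position)))
  invisible(x)
}

#' Net (background-subtracted) frequencies per codon variant
#'
#' Builds the full single-nucleotide codon-variant table of the ORF (plus
#' any observed multi-nucleotide variants), computes raw frequencies as
#' count/coverage and net frequencies as `max(raw - background mean, 0)`.
#' Variants at or below the background are flagged and given net frequency 0.
#'
#' @param counts A `codon_counts` object.
#' @param bg A `background_model` (or a scalar background frequency).
#' @param gene A [reference_gene()].
#' @return A data.frame of class `freq_table`: `library_id`, `round`,
#'   `codon_pos`, `ref_codon`, `alt_codon`, `n_nt_changes`, `ref_aa`,
#'   `alt_aa`, `class`, `count`, `coverage`, `raw_freq`, `net_freq`,
#'   `below_background`.
#' @export
net_frequencies <- function(counts, bg, gene) {
  bg_mean <- if (inherits(bg, "background_model")) bg$mean else as.numeric(bg)
  space <- enumerate_codon_variants(gene, max_nt_changes = 1L)
  cnt <- counts$counts[counts$counts$codon_pos > 0, , drop = FALSE]
  key_space <- paste(space$codon_pos, space$alt_codon)
  key_cnt <- paste(cnt$codon_pos, cnt$alt_codon)
  space$count <- 0L
  hit <- match(key_cnt, key_space)
  space$count[hit[!is.na(hit)]] <- cnt$count[!is.na(hit)]
  extra <- cnt[is.na(hit), , drop = FALSE]
  if (nrow(extra) > 0) {
    # observed multi-nucleotide variants: enumerated and counted, but they
    # are excluded from single-nucleotide fitness inference downstream
    extra$n_nt_changes <- mapply(function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, extra$ref_codon, extra$alt_codon)
    extra$ref_aa <- translate_codons(extra$ref_codon, gene$code)
    extra$alt_aa <- translate_codons(extra$alt_codon, gene$code)
    extra$class <- classify_variant(extra$ref_codon, extra$alt_codon, gene$code)
    space <- rbind(space[c("codon_pos", "ref_codon", "alt_codon",
                           "n_nt_changes", "ref_aa", "alt_aa", "class",
                           "count")],
                   extra[c("codon_pos", "ref_codon", "alt_codon",
                           "n_nt_changes", "ref_aa", "alt_aa", "class",
                           "count")])
  }
  cov <- counts$coverage$coverage[match(space$codon_pos,
                                        counts$coverage$codon_pos)]
  space$coverage <- ifelse(is.na(cov), 0L, cov)
  space$raw_freq <- ifelse(space$coverage > 0,
                           space$count / space$coverage, NA_real_)
  space$net_freq <- pmax(space$raw_freq - bg_mean, 0)
  space$below_background <- !is.na(space$raw_freq) & space$raw_freq <= bg_mean
  space$net_freq[space$below_background] <- 0
  out <- cbind(data.frame(library_id = counts$library_id,
                          round = counts$round, stringsAsFactors = FALSE),
               space)
  out <- out[order(out$codon_pos, out$alt_codon), ]
  rownames(out) <- NULL
  class(out) <- c("freq_table", "data.frame")
  out
}

#' Combine codon-variant frequencies per amino-acid mutation
#'
#' Frequencies of all codon variants yielding the same amino-acid change at
#' a position are summed. By default only single-nucleotide variants enter.
#'
#' @param ft A `freq_table` from [net_frequencies()].
#' @param max_nt_changes Keep variants with at most this many nucleotide
#'   changes (default 1).
#' @return A data.frame with one row per `(codon_pos, alt_aa)`: summed
#'   `raw_freq` and `net_freq`, `below_background` (all contributing
#'   variants below background), `class`, `n_codon_variants`.
#' @export
aggregate_frequencies <- function(ft, max_nt_changes = 1L) {
  d <- ft[ft$n_nt_changes <= max_nt_changes & ft$codon_pos > 0, , drop = FALSE]
  sp <- split(d, interaction(d$codon_pos, d$alt_aa, drop = TRUE))
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(library_id = g$library_id[1], round = g$round[1],
               codon_pos = g$codon_pos[1], ref_aa = g$ref_aa[1],
               alt_aa = g$alt_aa[1], class = g$class[1],
               n_codon_variants = nrow(g),
               raw_freq = sum(g$raw_freq), net_freq = sum(g$net_freq),
               below_background = all(g$below_background),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$codon_pos, out$alt_aa), ]
  rownames(out) <- NULL
  out
}

single_nt_change <- function(ref_codon, alt_codon) {
  # (offset within codon, ref base, alt base) for Hamming-1 codon pairs
  r <- strsplit(ref_codon, "")
  a <- strsplit(alt_codon, "")
  idx <- mapply(function(x, y) which(x != y)[1], r, a)
  data.frame(nt_offset = idx,
             ref_base = mapply(function(x, i) x[i], r, idx),
             alt_base = mapply(function(x, i) x[i], a, idx),
             stringsAsFactors = FALSE)
}

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Per-site nucleotide substitution rates from a naive library
#'
#' Summed net frequencies of each base change, divided by the number of
#' reference ORF sites carrying the source base, give per-site per-round
#' substitution rates. The transition/transversion ratio is the ratio of
#' total transition to total transversion frequency mass.
#'
#' @param ft A `freq_table` for the naive (round-0) library.
#' @param gene A [reference_gene()].
#' @return An `nt_subst_matrix`: list with `rates` (4x4, NA diagonal),
#'   `titv`, `n_sites` (reference base counts).
#' @export
substitution_matrix <- function(ft, gene) {
  d <- ft[ft$n_nt_changes == 1 & ft$codon_pos > 0, , drop = FALSE]
  ch <- single_nt_change(d$ref_codon, d$alt_codon)
  orf_nt <- strsplit(paste(gene$orf_codons[seq_len(gene$L)], collapse = ""),
                     "")[[1]]
  n_sites <- table(factor(orf_nt, BASES))
  rates <- matrix(NA_real_, 4, 4, dimnames = list(BASES, BASES))
  mass <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  agg <- tapply(d$net_freq, list(factor(ch$ref_base, BASES),
                                 factor(ch$alt_base, BASES)), sum)
  mass[!is.na(agg)] <- agg[!is.na(agg)]
  for (b in BASES) {
    if (n_sites[b] == 0) next
    for (b2 in setdiff(BASES, b)) rates[b, b2] <- mass[b, b2] / n_sites[b]
  }
  is_ti <- outer(BASES, BASES, function(x, y) TRANSITIONS[x] == y)
  dimnames(is_ti) <- list(BASES, BASES)
  ti_mass <- sum(mass[is_ti])
  tv_mass <- sum(mass[!is_ti & row(mass) != col(mass)])
  structure(list(rates = rates,
                 titv = if (tv_mass > 0) ti_mass / tv_mass else NA_real_,
                 n_sites = n_sites),
            class = "nt_subst_matrix")
}

#' @export
print.nt_subst_matrix <- function(x, ...) {
  cat("Per-site substitution rates (row = from, col = to); ti/tv =",
      format(x$titv, digits = 3), "\n")
  print(signif(x$rates, 3))
  invisible(x)
}

#' Expected naive-pool frequency of a single-nucleotide variant
#'
#' For mutations observed below the sequencing-error background in the naive
#' pool, the rate of occurrence is taken from the base substitution table
#' instead of the (unreliable) observed frequency.
#'
#' @param variants data.frame with `ref_codon`, `alt_codon` rows, all
#'   single-nucleotide changes.
#' @param subst An `nt_subst_matrix`.
#' @return Numeric vector of expected frequencies.
#' @export
expected_g0_frequency <- function(variants, subst) {
  r <- strsplit(variants$ref_codon, "")
  a <- strsplit(variants$alt_codon, "")
  d <- mapply(function(x, y) sum(x != y), r, a)
  if (any(d != 1)) {
    stop("expected_g0_frequency supports single-nucleotide variants only")
  }
  ch <- single_nt_change(variants$ref_codon, variants$alt_codon)
  subst$rates[cbind(ch$ref_base, ch$alt_base)]
}
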