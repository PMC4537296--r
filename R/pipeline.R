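# Format adapters and the end-to-end pipeline driver.

#' Read short reads from FASTQ or TSV
#'
#' FASTQ qualities are ignored. A TSV must have a `sequence` column and may
#' carry a `known_offset` column (from the simulator's read emitter).
#'
#' @param path Input path; format guessed from the extension
#'   (`.fastq`/`.fq` vs anything else = TSV).
#' @return Character vector of read sequences; `known_offset` attribute when
#'   present.
#' @export
read_reads <- function(path) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
    s <- Biostrings::readDNAStringSet(path, format = "fastq")
    return(as.character(s))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sequence" %in% names(d)) {
    names(d)[1] <- "sequence"
  }
  out <- d$sequence
  if ("known_offset" %in% names(d)) attr(out, "known_offset") <- d$known_offset
  out
}

#' Import ungapped placements from a SAM file
#'
#' Accepts alignments produced by an external mapper as an alternative to
#' [map_reads()]. Only ungapped records (cigar `<n>M`) on the forward
#' strand are used; others are dropped with a message.
#'
#' @param path SAM file path.
#' @return A `read_placements` data.frame (`seq`, `offset`, `mismatches` NA,
#'   `mapped`).
#' @export
read_sam_placements <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  b <- Rsamtools::scanBam(bam,
                          param = Rsamtools::ScanBamParam(
                            what = c("pos", "cigar", "seq", "strand")))[[1]]
  seqs <- as.character(b$seq)
  ungapped <- !is.na(b$cigar) & grepl("^[0-9]+M$", b$cigar) &
    (is.na(b$strand) | b$strand != "-")
  dropped <- sum(!ungapped)
  if (dropped > 0) message(dropped, " non-ungapped/reverse records dropped")
  placements_frame(seqs[ungapped], b$pos[ungapped],
                   rep(NA_integer_, sum(ungapped)),
                   rep(TRUE, sum(ungapped)))
}

#' Read a pre-computed codon count table from TSV
#'
#' Columns: `codon_pos`, `ref_codon`, `alt_codon`, `count`, `coverage`
#' (coverage repeated per position), plus optional `library_id`, `round`.
#'
#' @param path TSV path.
#' @param library_id,round Overrides for the labels.
#' @return A `codon_counts` object.
#' @export
read_count_table <- function(path, library_id = NULL, round = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon_pos", "ref_codon", "alt_codon", "count", "coverage")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("malformed count table ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  cov <- unique(d[c("codon_pos", "coverage")])
  if (anyDuplicated(cov$codon_pos)) {
    stop("inconsistent coverage for a codon position in ", path)
  }
  codon_counts(d[d$count > 0, c("codon_pos", "ref_codon", "alt_codon",
                                "count")],
               cov,
               library_id = library_id %||%
                 (if ("library_id" %in% names(d)) d$library_id[1] else "lib"),
               round = round %||%
                 (if ("round" %in% names(d)) d$round[1] else NA_integer_))
}

#' Write a codon count table to TSV
#'
#' @param counts A `codon_counts` object.
#' @param path Output path.
#' @export
write_count_table <- function(counts, path) {
  d <- counts$counts
  d$coverage <- counts$coverage$coverage[match(d$codon_pos,
                                               counts$coverage$codon_pos)]
  d$library_id <- counts$library_id
  d$round <- counts$round
  # keep zero-count coverage rows so the table round-trips
  zero <- counts$coverage[!(counts$coverage$codon_pos %in% d$codon_pos), ]
  if (nrow(zero) > 0) {
    d <- rbind(d, data.frame(codon_pos = zero$codon_pos, ref_codon = NA,
                             alt_codon = NA, count = 0L,
                             coverage = zero$coverage,
                             library_id = counts$library_id,
                             round = counts$round))
  }
  d <- d[order(d$codon_pos, d$alt_codon), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a frequency table to TSV
#'
#' @param ft A `freq_table`.
#' @param path Output path.
#' @export
write_freq_tsv <- function(ft, path) {
  utils::write.table(as.data.frame(ft), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

resolve_counts <- function(lib, gene, edge_trim) {
  if (inherits(lib$input, "codon_counts")) {
    cc <- lib$input
    cc$library_id <- lib$id
    cc$round <- lib$round
    return(cc)
  }
  if (is.data.frame(lib$input) || is.character(lib$input)) {
    kind <- lib$kind %||% "counts_tsv"
    if (kind == "counts_tsv") {
      return(read_count_table(lib$input, library_id = lib$id,
                              round = lib$round))
    }
    reads <- if (kind == "sam") NULL else if (is.character(lib$input) &&
                                              length(lib$input) == 1 &&
                                              file.exists(lib$input)) {
      read_reads(lib$input)
    } else {
      lib$input
    }
    placements <- if (kind == "sam") {
      read_sam_placements(lib$input)
    } else {
      map_reads(reads, gene)
    }
    return(count_codon_mutations(placements, gene, edge_trim = edge_trim,
                                 library_id = lib$id, round = lib$round))
  }
  stop("library '", lib$id, "': unsupported input")
}

#' Run the full drift-analysis pipeline
#'
#' Counting, background estimation, net frequencies, relative-fitness
#' fitting, classification, DFE and load summaries, and (when predictor
#' tables are supplied) predictor comparison, for a set of libraries. The
#' library with round 0 is the naive pool and is required for fitting.
#'
#' @param gene A [reference_gene()].
#' @param libraries List of libraries; each a list with `id`, `round`
#'   (0 = naive), `input` (a `codon_counts`, a reads vector, or a file
#'   path), and optional `kind` (`"counts_tsv"`, `"reads"`, `"sam"`).
#' @param edge_trim Edge filter width for read counting (default 2).
#' @param thresholds Passed to [drift_fit()].
#' @param grid_step,w_max Grid parameters for [drift_fit()].
#' @param predictors Optional predictor table (data.frame or TSV path).
#' @param outdir Optional directory; when given, all tables are written as
#'   TSV with a manifest, deterministically.
#' @return A list bundle: `gene`, per-library `counts`, `backgrounds`,
#'   `freqs`, `fits` (one per selected library), `summaries` (histograms,
#'   frequency-weighted DFE, loads, positional scores), `comparisons`
#'   (NULL without predictors), `log` (filter counts).
#' @export
run_pipeline <- function(gene, libraries, edge_trim = 2L,
                         thresholds = "empirical", grid_step = 0.01,
                         w_max = 3.5, predictors = NULL, outdir = NULL) {
  rounds <- vapply(libraries, function(l) as.integer(l$round), 0L)
  ids <- vapply(libraries, function(l) as.character(l$id), "")
  if (anyDuplicated(ids)) stop("duplicate library ids")
  if (sum(rounds == 0) != 1) {
    stop("exactly one naive (round 0) library is required")
  }
  counts <- lapply(libraries, resolve_counts, gene = gene,
                   edge_trim = edge_trim)
  names(counts) <- ids
  backgrounds <- lapply(counts, estimate_background, gene = gene)
  freqs <- Map(function(cc, bg) net_frequencies(cc, bg, gene),
               counts, backgrounds)
  naive_id <- ids[rounds == 0]
  g0 <- freqs[[naive_id]]
  subst <- substitution_matrix(g0, gene)
  sel <- ids[rounds > 0]
  fits <- lapply(sel, function(id) {
    drift_fit(g0, freqs[[id]], n = rounds[ids == id], gene = gene,
              subst = subst, grid_step = grid_step, w_max = w_max,
              thresholds = thresholds)
  })
  names(fits) <- sel
  summaries <- lapply(fits, function(f) {
    list(histogram = dfe_histogram(f),
         freq_weighted = frequency_weighted_dfe(f),
         loads = mutational_loads(freqs[[f$library_id]], f),
         positional = positional_wrel(f),
         compensatory = call_compensatory(f))
  })
  comparisons <- NULL
  if (!is.null(predictors)) {
    scores <- if (is.character(predictors)) {
      read_predictor_table(predictors)
    } else {
      predictors
    }
    comparisons <- lapply(fits, function(f) {
      list(confusion = confusion_vs_predictor(f, scores),
           correlation = score_wrel_correlation(f, scores))
    })
  } else if (length(fits) > 0) {
    message("no predictor tables supplied; comparison stage skipped")
  }
  log <- list(
    libraries = data.frame(
      library_id = ids, round = rounds,
      n_reads = vapply(counts, function(cc) as.integer(cc$n_reads), 0L),
      background_mean = vapply(backgrounds, function(b) b$mean, 0)),
    fits = if (length(fits) > 0)
      do.call(rbind, lapply(fits, function(f) as.data.frame(t(f$qc))))
    else NULL)
  bundle <- list(gene = gene, counts = counts, backgrounds = backgrounds,
                 freqs = freqs, subst = subst, fits = fits,
                 summaries = summaries, comparisons = comparisons,
                 log = log)
  if (!is.null(outdir)) write_bundle(bundle, outdir, edge_trim, grid_step,
                                     w_max)
  bundle
}

write_bundle <- function(bundle, outdir, edge_trim, grid_step, w_max) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(bundle$counts)) {
    write_count_table(bundle$counts[[id]],
                      file.path(outdir, paste0("counts_", id, ".tsv")))
    write_freq_tsv(bundle$freqs[[id]],
                   file.path(outdir, paste0("freq_", id, ".tsv")))
  }
  for (id in names(bundle$fits)) {
    write_fit_tsv(bundle$fits[[id]],
                  file.path(outdir, paste0("wrel_", id, ".tsv")))
    utils::write.table(bundle$summaries[[id]]$histogram,
                       file.path(outdir, paste0("dfe_", id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$summaries[[id]]$positional,
                       file.path(outdir, paste0("positional_", id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  thr <- if (length(bundle$fits) > 0) bundle$fits[[1]]$thresholds else NULL
  manifest <- c(
    paste0("package_version: ",
           as.character(utils::packageVersion("driftDFE"))),
    paste0("edge_trim: ", edge_trim),
    paste0("grid_step: ", grid_step),
    paste0("w_max: ", w_max),
    if (!is.null(thr)) c(
      paste0("threshold_highly_deleterious_max: ",
             thr$highly_deleterious_max),
      paste0("threshold_deleterious_max: ", thr$deleterious_max),
      paste0("threshold_nearly_neutral_max: ", thr$nearly_neutral_max),
      paste0("threshold_beneficial_min: ", thr$beneficial_min)))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}
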