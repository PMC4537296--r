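# Forward simulator of the laboratory drift: Poisson mutagenesis with a
# nucleotide substitution spectrum, multiplicative per-mutation selection by
# weighted multinomial resampling at constant population size, and a
# sequencing readout with a uniform per-base error background.

#' Random reference gene for simulations
#'
#' Random codons excluding stop codons, with an optional unmutagenized
#' upstream region, seeded for reproducibility.
#'
#' @param L Number of ORF codons.
#' @param upstream_L Number of upstream control codons (default 20).
#' @param seed Optional RNG seed.
#' @param gene_id Identifier.
#' @return A [reference_gene()].
#' @export
random_gene <- function(L, upstream_L = 20, seed = NULL, gene_id = "sim_gene") {
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  non_stop <- names(code)[code != "*"]
  reference_gene(orf = sample(non_stop, L, replace = TRUE),
                 upstream = if (upstream_L > 0)
                   sample(non_stop, upstream_L, replace = TRUE)
                 else character(0),
                 gene_id = gene_id)
}

#' Substitution matrix with a target transition/transversion ratio
#'
#' Conditional probabilities of each alternative base given the reference
#' base: every base has one transition partner and two transversion
#' partners, so an event-level ti/tv ratio `titv` needs transition
#' probability `titv / (1 + titv)`, split equally over the two
#' transversions otherwise.
#'
#' @param titv Target transition/transversion ratio (default 1.3, typical
#'   of error-prone PCR spectra resembling E. coli divergence).
#' @return 4x4 matrix of conditional alternative-base probabilities (rows =
#'   reference base, NA diagonal; rows sum to 1).
#' @export
default_subst_matrix <- function(titv = 1.3) {
  p_ti <- titv / (1 + titv)
  m <- matrix(NA_real_, 4, 4, dimnames = list(BASES, BASES))
  for (b in BASES) {
    for (b2 in setdiff(BASES, b)) {
      m[b, b2] <- if (TRANSITIONS[b] == b2) p_ti else (1 - p_ti) / 2
    }
  }
  m
}

#' Index of all single-nucleotide mutations of a gene
#'
#' One row per (ORF nucleotide site, alternative base): the atomic mutation
#' unit of the simulator. Row order is site-major, then alternative bases in
#' A<C<G<T order; the row number is the mutation id used throughout the
#' simulator.
#'
#' @param gene A [reference_gene()].
#' @return data.frame: `id`, `nt_site` (1-based ORF nucleotide), `ref_base`,
#'   `alt_base`, `codon_pos`, `nt_offset` (1..3 within codon), `ref_codon`,
#'   `alt_codon`, `class`.
#' @export
mutation_index <- function(gene) {
  L <- gene$L
  orf_nt <- strsplit(paste(gene$orf_codons[seq_len(L)], collapse = ""),
                     "")[[1]]
  site <- rep(seq_len(3 * L), each = 3)
  ref_base <- orf_nt[site]
  alt_base <- unlist(lapply(orf_nt, function(b) setdiff(BASES, b)),
                     use.names = FALSE)
  codon_pos <- (site - 1L) %/% 3L + 1L
  nt_offset <- (site - 1L) %% 3L + 1L
  ref_codon <- gene$orf_codons[codon_pos]
  alt_codon <- mapply(function(cd, off, ab) {
    substr(cd, off, off) <- ab
    cd
  }, ref_codon, nt_offset, alt_base, USE.NAMES = FALSE)
  data.frame(id = seq_along(site), nt_site = site, ref_base = ref_base,
             alt_base = alt_base, codon_pos = codon_pos,
             nt_offset = nt_offset, ref_codon = ref_codon,
             alt_codon = alt_codon,
             class = classify_variant(ref_codon, alt_codon, gene$code),
             stringsAsFactors = FALSE)
}

#' Default fitness-effect mixture for simulated missense mutations
#'
#' A point mass of lethal mutations, a deleterious interval, a
#' nearly-neutral band, a neutral mass and a small beneficial tail —
#' emulating the continuum shape of an experimentally inferred DFE in which
#' about two thirds of missense mutations are deleterious and a few percent
#' are enriched.
#'
#' @return A list of mixture components, each with `weight`, `dist`
#'   (`"point"` or `"uniform"`) and parameters.
#' @export
default_dfe_spec <- function() {
  list(
    list(weight = 0.33, dist = "point", value = 0),
    list(weight = 0.34, dist = "uniform", min = 0.0, max = 0.6),
    list(weight = 0.16, dist = "uniform", min = 0.6, max = 0.8),
    list(weight = 0.14, dist = "uniform", min = 0.8, max = 1.1),
    list(weight = 0.03, dist = "uniform", min = 1.1, max = 1.6))
}

sample_mixture <- function(spec, n) {
  w <- vapply(spec, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  comp <- sample.int(length(spec), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (j in seq_along(spec)) {
    i <- comp == j
    if (!any(i)) next
    s <- spec[[j]]
    out[i] <- switch(s$dist,
                     point = s$value,
                     uniform = stats::runif(sum(i), s$min, s$max),
                     stop("unknown mixture dist: ", s$dist))
  }
  out
}

#' Assign true fitness effects to every single-nucleotide mutation
#'
#' Missense mutations draw from `dfe_spec`; synonymous mutations are
#' neutral (w = 1) and nonsense mutations lethal (w = 0) unless overridden.
#'
#' @param gene A [reference_gene()].
#' @param dfe_spec Missense fitness mixture (see [default_dfe_spec()]).
#' @param synonymous_w,nonsense_w Fixed fitness for those classes.
#' @param seed Optional RNG seed.
#' @return The [mutation_index()] table with a true-fitness column `w`;
#'   class `fitness_map`.
#' @export
make_fitness_map <- function(gene, dfe_spec = default_dfe_spec(),
                             synonymous_w = 1, nonsense_w = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- mutation_index(gene)
  idx$w <- NA_real_
  mis <- idx$class == "missense"
  idx$w[mis] <- sample_mixture(dfe_spec, sum(mis))
  idx$w[idx$class == "synonymous"] <- synonymous_w
  idx$w[idx$class == "nonsense"] <- nonsense_w
  if (any(idx$w < 0)) stop("negative fitness in map")
  class(idx) <- c("fitness_map", "data.frame")
  idx
}

#' Simulate a mutagenesis-selection drift
#'
#' Each round, every gene copy gains Poisson(`lambda`) nucleotide
#' substitutions at uniform ORF sites with matrix-weighted alternative
#' bases; the next generation is then drawn by multinomial resampling with
#' gene weights `(prod_i w_i)^enrichment_cycles` at constant population
#' size. The naive pool (G0) is the round-1 mutagenized population before
#' any selection. Population state is a frequency-space approximation: each
#' gene is the set of mutation events it carries; alternative bases are
#' drawn relative to the reference base, and repeated hits at one site are
#' kept as separate events (negligibly rare at realistic rates).
#'
#' @param gene A [reference_gene()].
#' @param truth A `fitness_map` from [make_fitness_map()].
#' @param rounds Number of drift rounds.
#' @param lambda Mean nucleotide mutations per gene per round (default 2.2).
#' @param population Number of gene copies (default 2e4, a frequency-space
#'   stand-in for the >= 1e5 transformants of a bench drift).
#' @param enrichment_cycles Selection multiplicity per round (default 1,
#'   matching the one-multiplication-per-round inference model).
#' @param subst Alternative-base probability matrix
#'   (default [default_subst_matrix()]).
#' @param keep_populations Rounds whose post-selection populations to retain
#'   (0 = naive pre-selection pool) for read-level sequencing.
#' @param seed Optional RNG seed.
#' @return A `drift_sim` object: `freq` (mutations x rounds matrix of
#'   post-selection carrier frequencies), `freq_g0` (naive pool
#'   frequencies), `loads` (per-round mean mutation events per gene, pre-
#'   and post-selection), `populations` (kept rounds), `truth`, `gene`, and
#'   the run parameters.
#' @export
simulate_drift <- function(gene, truth, rounds, lambda = 2.2,
                           population = 2e4, enrichment_cycles = 1,
                           subst = default_subst_matrix(),
                           keep_populations = c(0, rounds), seed = NULL) {
  stopifnot(rounds >= 1, lambda > 0, population >= 100)
  if (!is.null(seed)) set.seed(seed)
  idx <- truth
  L <- gene$L
  n_sites <- 3L * L
  orf_nt <- idx$ref_base[seq(1, nrow(idx), by = 3)]
  # per site: the 3 alternative-base mutation ids and their probabilities
  alt_prob <- subst[cbind(idx$ref_base, idx$alt_base)]
  w_vec <- idx$w
  we <- w_vec^enrichment_cycles

  pop <- rep(list(integer(0)), population)
  freq <- matrix(0, nrow = nrow(idx), ncol = rounds)
  freq_g0 <- NULL
  populations <- list()
  loads <- data.frame(round = seq_len(rounds), pre_mean = NA_real_,
                      post_mean = NA_real_)
  carrier_freq <- function(p) {
    tabulate(unlist(lapply(p, unique), use.names = FALSE),
             nbins = nrow(idx)) / length(p)
  }
  for (r in seq_len(rounds)) {
    k <- stats::rpois(population, lambda)
    tot <- sum(k)
    if (tot > 0) {
      sites <- sample.int(n_sites, tot, replace = TRUE)
      base_ids <- (sites - 1L) * 3L
      # choose among the 3 alternatives of each hit site by matrix weight
      pick <- integer(tot)
      u <- stats::runif(tot)
      p1 <- alt_prob[base_ids + 1L]
      p2 <- alt_prob[base_ids + 2L]
      pick <- 1L + (u > p1) + (u > p1 + p2)
      new_ids <- base_ids + pick
      gene_of <- rep.int(seq_len(population), k)
      hit <- which(k > 0)
      pop[hit] <- Map(c, pop[hit], split(new_ids, gene_of))
    }
    loads$pre_mean[r] <- mean(lengths(pop))
    if (r == 1) {
      freq_g0 <- carrier_freq(pop)
      if (0 %in% keep_populations) populations[["0"]] <- pop
    }
    wts <- vapply(pop, function(g) prod(we[g]), 0)
    if (!any(wts > 0)) {
      stop("population extinct (all weights zero) at round ", r)
    }
    pop <- pop[sample.int(population, population, replace = TRUE,
                          prob = wts)]
    loads$post_mean[r] <- mean(lengths(pop))
    freq[, r] <- carrier_freq(pop)
    if (r %in% keep_populations) populations[[as.character(r)]] <- pop
  }
  structure(list(gene = gene, truth = idx, freq = freq, freq_g0 = freq_g0,
                 loads = loads, populations = populations,
                 lambda = lambda, population = population,
                 rounds = rounds, enrichment_cycles = enrichment_cycles,
                 subst = subst),
            class = "drift_sim")
}

#' @export
print.drift_sim <- function(x, ...) {
  cat("Simulated drift:", x$rounds, "rounds, population", x$population,
      ", lambda", x$lambda, "\n")
  cat(sprintf("  final mean load %.2f mutations/gene; %d tracked mutations\n",
              x$loads$post_mean[x$rounds], nrow(x$truth)))
  invisible(x)
}

#' Sequence a simulated pool
#'
#' Two readout modes. `"counts"`: per-position coverage equals `depth`, and
#' each single-nucleotide variant's count is binomial at its population
#' frequency plus the per-variant error rate `error_rate / 3`; upstream
#' control codons receive error-only counts, giving a realistic background
#' region. `"reads"`: draws fixed-length reads at uniform offsets from
#' randomly sampled gene copies (covering upstream + ORF), applies the
#' gene's mutations and injects uniform base-call errors.
#'
#' @param sim A `drift_sim`.
#' @param round Which pool to sequence: 0 for the naive pool, otherwise a
#'   post-selection round (must be in `freq`, or in `populations` for read
#'   mode).
#' @param depth Reads covering each position (counts mode) or number of
#'   reads (reads mode).
#' @param read_length Read length for reads mode (default 40).
#' @param error_rate Uniform per-base error probability (default 1e-4, an
#'   effective post-filtering short-read error floor).
#' @param mode `"counts"` or `"reads"`.
#' @param library_id Label for the emitted table.
#' @param seed Optional RNG seed.
#' @return `"counts"`: a `codon_counts` object. `"reads"`: a data.frame
#'   with `seq`, `true_offset`, `gene_index`.
#' @export
sequence_population <- function(sim, round, depth, read_length = 40,
                                error_rate = 1e-4,
                                mode = c("counts", "reads"),
                                library_id = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  gene <- sim$gene
  if (is.null(library_id)) library_id <- paste0("G", round)
  if (mode == "counts") {
    f <- if (round == 0) sim$freq_g0 else sim$freq[, round]
    idx <- sim$truth
    p <- pmin(f + error_rate / 3, 1)
    cnt <- stats::rbinom(length(p), depth, p)
    keep <- cnt > 0
    counts <- data.frame(codon_pos = idx$codon_pos[keep],
                         ref_codon = idx$ref_codon[keep],
                         alt_codon = idx$alt_codon[keep],
                         count = cnt[keep], stringsAsFactors = FALSE)
    # error-only counts over the upstream control region
    u <- n_upstream(gene)
    if (u > 0) {
      up <- enumerate_upstream_variants(gene)
      ucnt <- stats::rbinom(nrow(up), depth, error_rate / 3)
      ukeep <- ucnt > 0
      counts <- rbind(data.frame(codon_pos = up$codon_pos[ukeep],
                                 ref_codon = up$ref_codon[ukeep],
                                 alt_codon = up$alt_codon[ukeep],
                                 count = ucnt[ukeep],
                                 stringsAsFactors = FALSE),
                      counts)
    }
    cov <- data.frame(
      codon_pos = c(if (u > 0) -(u:1), seq_len(length(gene$orf_codons))),
      coverage = depth)
    return(codon_counts(counts, cov, library_id = library_id,
                        round = if (round == 0) 0L else as.integer(round)))
  }
  pop <- sim$populations[[as.character(round)]]
  if (is.null(pop)) {
    stop("population for round ", round,
         " not retained; set keep_populations in simulate_drift()")
  }
  refc <- strsplit(reference_string(gene), "")[[1]]
  rl <- length(refc)
  if (read_length > rl) stop("read_length exceeds reference length")
  up_nt <- 3L * n_upstream(gene)
  idx <- sim$truth
  n_reads <- depth
  gi <- sample.int(length(pop), n_reads, replace = TRUE)
  off <- sample.int(rl - read_length + 1L, n_reads, replace = TRUE)
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    rc <- refc[off[i]:(off[i] + read_length - 1L)]
    muts <- pop[[gi[i]]]
    if (length(muts) > 0) {
      ntpos <- up_nt + idx$nt_site[muts]
      inside <- ntpos >= off[i] & ntpos <= off[i] + read_length - 1L
      if (any(inside)) {
        rc[ntpos[inside] - off[i] + 1L] <- idx$alt_base[muts[inside]]
      }
    }
    if (error_rate > 0) {
      err <- which(stats::runif(read_length) < error_rate)
      for (j in err) rc[j] <- sample(setdiff(BASES, rc[j]), 1)
    }
    seqs[i] <- paste(rc, collapse = "")
  }
  data.frame(seq = seqs, true_offset = off, gene_index = gi,
             stringsAsFactors = FALSE)
}

# single-nt variants of the upstream control codons (for error-only counts)
enumerate_upstream_variants <- function(gene) {
  u <- n_upstream(gene)
  out <- do.call(rbind, lapply(seq_len(u), function(j) {
    cd <- gene$upstream_codons[j]
    alts <- codon_alternatives(cd)
    alts <- alts[alts$n_nt_changes == 1, ]
    data.frame(codon_pos = j - u - 1L, ref_codon = cd,
               alt_codon = alts$alt_codon, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
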