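#' Construct a reference gene
#'
#' Bundles the mutagenized open reading frame with the unmutagenized upstream
#' region that serves as the sequencing-error control, and fixes the codon
#' coordinate system used throughout the package: ORF codons are numbered
#' 1..L, upstream codons -U..-1 (immediately 5' of codon 1).
#'
#' @param orf ORF sequence: a single DNA string (length a multiple of 3) or a
#'   character vector of codons. Must contain no internal stop codon; a
#'   terminal stop is allowed and excluded from the mutational space by
#'   default.
#' @param upstream Upstream (unmutagenized) sequence, same forms as `orf`.
#'   May be empty.
#' @param gene_id Identifier carried through output tables.
#' @param code Genetic code: named character vector mapping codons to
#'   one-letter amino acids with `"*"` for stop. Defaults to the standard
#'   code shipped with Biostrings.
#' @return An object of class `reference_gene` with elements `gene_id`,
#'   `orf_codons`, `upstream_codons`, `code`, and `L` (number of ORF codons,
#'   excluding a terminal stop if present).
#' @export
reference_gene <- function(orf, upstream = character(0), gene_id = "gene",
                           code = Biostrings::GENETIC_CODE) {
  orf_codons <- as_codons(orf, "orf")
  upstream_codons <- as_codons(upstream, "upstream")
  aas <- translate_codons(orf_codons, code)
  n <- length(orf_codons)
  has_terminal_stop <- n > 0 && aas[n] == "*"
  internal <- if (has_terminal_stop) aas[-n] else aas
  if (any(internal == "*")) {
    stop("ORF contains an internal stop codon at codon position ",
         which(internal == "*")[1])
  }
  structure(
    list(gene_id = gene_id,
         orf_codons = orf_codons,
         upstream_codons = upstream_codons,
         code = code,
         has_terminal_stop = has_terminal_stop,
         L = n - as.integer(has_terminal_stop)),
    class = "reference_gene")
}

#' @export
print.reference_gene <- function(x, ...) {
  cat("Reference gene '", x$gene_id, "': ", x$L, " codons",
      if (x$has_terminal_stop) " (+ terminal stop)",
      ", ", length(x$upstream_codons), " upstream control codons\n", sep = "")
  invisible(x)
}

# Split an arbitrary DNA input into validated codons.
as_codons <- function(x, what) {
  if (length(x) == 0) return(character(0))
  x <- toupper(as.character(x))
  if (length(x) == 1 && nchar(x) > 3) {
    if (nchar(x) %% 3 != 0) {
      stop(what, " sequence length (", nchar(x), ") is not a multiple of 3")
    }
    x <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  }
  bad <- nchar(x) != 3 | grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid base or codon in ", what, " at codon position ",
         which(bad)[1], " ('", x[which(bad)[1]], "')")
  }
  x
}

translate_codons <- function(codons, code) {
  aa <- unname(code[codons])
  if (anyNA(aa)) stop("codon not in genetic code: ", codons[which(is.na(aa))[1]])
  aa
}

#' Read a reference gene from FASTA
#'
#' The FASTA record holds the full amplicon; `orf_offset` gives the 0-based
#' nucleotide offset where the mutagenized ORF starts. Everything upstream of
#' that offset is treated as the unmutagenized background-control region.
#'
#' @param path Path to a FASTA file (first record used).
#' @param orf_offset 0-based nucleotide offset of the ORF start; must be a
#'   multiple of 3 so upstream codons stay in frame with the read counter.
#' @inheritParams reference_gene
#' @return A `reference_gene`.
#' @export
read_reference <- function(path, orf_offset, gene_id = NULL,
                           code = Biostrings::GENETIC_CODE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  full <- as.character(seqs[[1]])
  if (orf_offset %% 3 != 0) stop("orf_offset must be a multiple of 3")
  if (orf_offset >= nchar(full)) stop("orf_offset beyond sequence end")
  reference_gene(orf = substr(full, orf_offset + 1, nchar(full)),
                 upstream = if (orf_offset > 0) substr(full, 1, orf_offset) else character(0),
                 gene_id = gene_id %||% names(seqs)[1],
                 code = code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

# All 4^k - 1 alternative codons per Hamming distance, cached per ref codon.
codon_alternatives <- function(ref_codon) {
  ref <- strsplit(ref_codon, "")[[1]]
  grid <- expand.grid(b1 = BASES, b2 = BASES, b3 = BASES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  alt <- paste0(grid$b1, grid$b2, grid$b3)
  d <- (grid$b1 != ref[1]) + (grid$b2 != ref[2]) + (grid$b3 != ref[3])
  data.frame(alt_codon = alt, n_nt_changes = d,
             stringsAsFactors = FALSE)[d > 0, ]
}

#' Enumerate the codon-level mutational space
#'
#' Lists every alternative codon at every ORF position within a Hamming
#' distance bound. With `max_nt_changes = 1` there are exactly `9 * L`
#' variants; with 3, `63 * L`. Order is deterministic: by codon position,
#' then alternative codon, lexicographically.
#'
#' @param gene A [reference_gene()].
#' @param max_nt_changes Maximum number of nucleotide changes per codon
#'   (1 to 3).
#' @param include_terminal_stop Include the ORF's terminal stop codon as a
#'   mutable position. Off by default, matching the convention of counting
#'   only amino-acid positions.
#' @return A data.frame with columns `codon_pos`, `ref_codon`, `alt_codon`,
#'   `n_nt_changes`, `ref_aa`, `alt_aa`, `class`
#'   (synonymous/missense/nonsense).
#' @export
enumerate_codon_variants <- function(gene, max_nt_changes = 1L,
                                     include_terminal_stop = FALSE) {
  stopifnot(inherits(gene, "reference_gene"))
  if (max_nt_changes < 1 || max_nt_changes > 3) {
    stop("max_nt_changes must be in 1..3")
  }
  codons <- gene$orf_codons
  npos <- if (gene$has_terminal_stop && !include_terminal_stop)
    gene$L else length(codons)
  if (npos == 0) return(empty_variant_table())
  per_codon <- lapply(unique(codons[seq_len(npos)]), function(cd) {
    alts <- codon_alternatives(cd)
    alts <- alts[alts$n_nt_changes <= max_nt_changes, ]
    alts <- alts[order(alts$alt_codon), ]
    alts
  })
  names(per_codon) <- unique(codons[seq_len(npos)])
  pieces <- lapply(seq_len(npos), function(i) {
    alts <- per_codon[[codons[i]]]
    data.frame(codon_pos = i, ref_codon = codons[i],
               alt_codon = alts$alt_codon, n_nt_changes = alts$n_nt_changes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$ref_aa <- translate_codons(out$ref_codon, gene$code)
  out$alt_aa <- translate_codons(out$alt_codon, gene$code)
  out$class <- classify_variant(out$ref_codon, out$alt_codon, gene$code)
  rownames(out) <- NULL
  out
}

empty_variant_table <- function() {
  data.frame(codon_pos = integer(0), ref_codon = character(0),
             alt_codon = character(0), n_nt_changes = integer(0),
             ref_aa = character(0), alt_aa = character(0),
             class = character(0), stringsAsFactors = FALSE)
}

#' Classify a codon change
#'
#' @param ref_codon,alt_codon Codon strings (vectorized).
#' @param code Genetic code table.
#' @return `"synonymous"`, `"missense"` or `"nonsense"` per pair. A pair with
#'   `alt_codon == ref_codon` is rejected: it is not a mutation.
#' @export
classify_variant <- function(ref_codon, alt_codon,
                             code = Biostrings::GENETIC_CODE) {
  if (any(ref_codon == alt_codon)) stop("alt_codon equals ref_codon: not a mutation")
  ref_aa <- translate_codons(ref_codon, code)
  alt_aa <- translate_codons(alt_codon, code)
  ifelse(alt_aa == "*", "nonsense",
         ifelse(alt_aa == ref_aa, "synonymous", "missense"))
}

#' Aggregate codon variants to amino-acid mutations
#'
#' Collapses codon variants to distinct `(codon_pos, alt_aa)` records, the
#' unit at which frequencies are combined and fitness effects assigned.
#' `accessible_by` is the minimal number of nucleotide changes over the
#' contributing codon variants.
#'
#' @param variants Output of [enumerate_codon_variants()] (or any subset).
#' @param gene The matching [reference_gene()].
#' @return A data.frame with columns `codon_pos`, `ref_aa`, `alt_aa`,
#'   `class`, `accessible_by`, `n_codon_variants`, `alt_codons`
#'   (comma-separated contributing codons).
#' @export
aggregate_to_aa <- function(variants, gene) {
  if (nrow(variants) == 0) {
    return(data.frame(codon_pos = integer(0), ref_aa = character(0),
                      alt_aa = character(0), class = character(0),
                      accessible_by = integer(0), n_codon_variants = integer(0),
                      alt_codons = character(0), stringsAsFactors = FALSE))
  }
  key <- interaction(variants$codon_pos, variants$alt_aa, drop = TRUE)
  sp <- split(variants, key)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$alt_codon), ]
    data.frame(codon_pos = d$codon_pos[1], ref_aa = d$ref_aa[1],
               alt_aa = d$alt_aa[1], class = d$class[1],
               accessible_by = min(d$n_nt_changes),
               n_codon_variants = nrow(d),
               alt_codons = paste(d$alt_codon, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$codon_pos, out$alt_aa), ]
  rownames(out) <- NULL
  out
}

#' Summarize the mutational space
#'
#' Counts codon variants and aggregated amino-acid mutations by class and
#' number of nucleotide changes (for amino-acid records, the minimal number
#' over contributing codons). Codon-variant rows always partition the
#' `9L` / `63L` totals.
#'
#' @param gene A [reference_gene()].
#' @param max_nt_changes Upper bound on nucleotide changes per codon.
#' @return A list of class `space_summary` with two count matrices
#'   (`codon_variants`, `aa_mutations`; rows = synonymous/missense/nonsense,
#'   columns = 1..max_nt_changes) and the totals.
#' @export
space_summary <- function(gene, max_nt_changes = 1L) {
  variants <- enumerate_codon_variants(gene, max_nt_changes)
  aa <- aggregate_to_aa(variants, gene)
  classes <- c("synonymous", "missense", "nonsense")
  nts <- seq_len(max_nt_changes)
  tab <- function(df, col) {
    m <- matrix(0L, nrow = 3, ncol = length(nts),
                dimnames = list(classes, paste0(nts, "nt")))
    t0 <- table(factor(df$class, classes), factor(df[[col]], nts))
    m[rownames(t0), colnames(m)] <- t0
    m
  }
  structure(list(codon_variants = tab(variants, "n_nt_changes"),
                 aa_mutations = tab(aa, "accessible_by"),
                 n_codon_variants = nrow(variants),
                 n_aa_mutations = nrow(aa),
                 L = gene$L),
            class = "space_summary")
}

#' @export
print.space_summary <- function(x, ...) {
  cat("Mutational space of", x$L, "codons\n")
  cat("Codon variants (", x$n_codon_variants, " total):\n", sep = "")
  print(x$codon_variants)
  cat("Amino-acid mutations (", x$n_aa_mutations,
      " total, by minimal accessibility):\n", sep = "")
  print(x$aa_mutations)
  invisible(x)
}

#' Write a mutational-space table to TSV
#'
#' @param variants Variant table from [enumerate_codon_variants()].
#' @param path Output path.
#' @export
write_space_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
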