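# Shared fixtures, all generated in code.

# a tiny fixed gene used across tests: 8 ORF codons + 2 upstream codons
tiny_gene <- function() {
  reference_gene(orf = c("ATG", "TGG", "CTG", "AAA",
                         "GGC", "TCT", "GAT", "CGT"),
                 upstream = c("CAT", "GAA"),
                 gene_id = "tiny")
}

# independent translation oracle (Biostrings, not the package's code path)
oracle_translate <- function(codons) {
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(codons), no.init.codon = TRUE))
}

# brute-force classification oracle
oracle_classify <- function(ref_codon, alt_codon) {
  ra <- oracle_translate(ref_codon)
  aa <- oracle_translate(alt_codon)
  ifelse(aa == "*", "nonsense", ifelse(aa == ra, "synonymous", "missense"))
}

# codon_counts built directly from a named count vector "pos:alt" -> count,
# with uniform coverage over all positions of the gene
make_counts <- function(gene, counts = c(), coverage = 1000,
                        library_id = "lib", round = NA_integer_) {
  u <- length(gene$upstream_codons)
  pos <- c(if (u > 0) -(u:1), seq_along(gene$orf_codons))
  cov <- data.frame(codon_pos = pos, coverage = coverage)
  if (length(counts) > 0) {
    parts <- strsplit(names(counts), ":", fixed = TRUE)
    cp <- as.integer(vapply(parts, `[`, "", 1))
    alt <- vapply(parts, `[`, "", 2)
    ref <- vapply(cp, function(p) {
      if (p < 0) gene$upstream_codons[p + u + 1] else gene$orf_codons[p]
    }, "")
    cnt <- data.frame(codon_pos = cp, ref_codon = ref, alt_codon = alt,
                      count = as.integer(counts), stringsAsFactors = FALSE)
  } else {
    cnt <- data.frame(codon_pos = integer(0), ref_codon = character(0),
                      alt_codon = character(0), count = integer(0))
  }
  codon_counts(cnt, cov, library_id = library_id, round = round)
}

# a two-point sample with exact mean m and sample SD s
two_point_sample <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))

# wrel records frame for summary-level tests
make_records <- function(wrel, f_gn = rep(0.01, length(wrel)),
                         class = rep("missense", length(wrel)),
                         codon_pos = seq_along(wrel)) {
  n <- length(wrel)
  data.frame(codon_pos = codon_pos,
             ref_aa = rep("A", n), alt_aa = LETTERS[(seq_len(n) %% 20) + 1],
             class = class, f_g0 = rep(0.001, n), f_gn = f_gn,
             ratio = rep(NA_real_, n), wrel = wrel,
             category = as.character(
               classify_wrel(wrel, derive_thresholds(mode = "paper_default"))),
             undefined = rep(FALSE, n), stringsAsFactors = FALSE)
}
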