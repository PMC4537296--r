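test_that("mapper recovers exact substrings and rejects bad reads", {
  g <- tiny_gene()
  ref <- driftDFE:::reference_string(g)
  reads <- substring(ref, c(1, 4, 7), c(1, 4, 7) + 23)
  pl <- map_reads(reads, g)
  expect_true(all(pl$mapped))
  expect_equal(pl$offset, c(1L, 4L, 7L))
  expect_equal(pl$mismatches, c(0L, 0L, 0L))
  # a read garbled beyond the mismatch limit stays unmapped
  bad <- paste(rep("A", 24), collapse = "")
  pl2 <- map_reads(bad, g)
  expect_false(pl2$mapped[1])
  # reads shorter than min_run are discarded
  pl3 <- map_reads(substr(ref, 1, 20), g)
  expect_false(pl3$mapped[1])
  expect_warning(map_reads(character(0), g), "empty")
})

test_that("mapper recovers simulator-known offsets", {
  g <- random_gene(20, upstream_L = 4, seed = 21)
  tr <- make_fitness_map(g, seed = 22)
  sim <- simulate_drift(g, tr, rounds = 1, population = 200, seed = 23,
                        keep_populations = 0)
  rd <- sequence_population(sim, 0, depth = 120, mode = "reads",
                            error_rate = 0, seed = 24)
  pl <- map_reads(rd$seq, g)
  expect_true(mean(pl$mapped) > 0.95)
  ok <- pl$mapped
  expect_true(mean(pl$offset[ok] == rd$true_offset[ok]) > 0.95)
})

test_that("counting from reads honours intact-codon and edge rules", {
  g <- tiny_gene()  # upstream CAT GAA, ORF ATG TGG CTG AAA
  ref <- driftDFE:::reference_string(g)
  # a perfect read over the whole reference: zero counts, coverage > 0
  pl <- map_reads(substr(ref, 1, nchar(ref)), g)
  cc <- count_codon_mutations(pl, g, edge_trim = 0)
  expect_equal(nrow(cc$counts), 0)
  expect_true(all(cc$coverage$coverage == 1))
  # one internal codon mismatch -> exactly one count
  mut <- ref
  substr(mut, 10, 10) <- "C"  # codon 4 of 6 (ORF codon 2 TGG -> CGG)
  cc2 <- count_codon_mutations(map_reads(mut, g), g, edge_trim = 2)
  expect_equal(nrow(cc2$counts), 1)
  expect_equal(cc2$counts$codon_pos, 2)
  expect_equal(cc2$counts$alt_codon, "CGG")
  expect_equal(cc2$counts$count, 1)
  # the same mismatch inside the trimmed edge: neither count nor coverage
  short <- substr(mut, 9, nchar(ref))   # mismatch now at read position 2
  pl3 <- map_reads(short, g, min_run = 12)
  cc3 <- count_codon_mutations(pl3, g, edge_trim = 2)
  expect_equal(nrow(cc3$counts), 0)
  cov3 <- cc3$coverage
  expect_equal(cov3$coverage[cov3$codon_pos == 2], 0)
  expect_equal(cov3$coverage[cov3$codon_pos == 3], 1)
})

test_that("background model reproduces upstream frequencies", {
  g <- tiny_gene()
  cc <- make_counts(g, c("-2:CAA" = 1, "-1:GAT" = 3), coverage = 1000)
  bg <- estimate_background(cc, g)
  expect_equal(bg$mean, mean(c(0.001, 0.003)))
  expect_equal(nrow(bg$per_position), 2)
  cc2 <- make_counts(g, c("-2:CAA" = 1, "-1:GAT" = 1), coverage = 1000)
  bg2 <- estimate_background(cc2, g)
  expect_equal(bg2$mean, 0.001)
  expect_equal(bg2$sd, 0)
  # no upstream coverage -> error
  g0 <- reference_gene(c("ATG", "AAA"))
  expect_error(estimate_background(make_counts(g0, coverage = 10), g0),
               "upstream")
})

test_that("simulated error background matches the closed form", {
  g <- random_gene(10, upstream_L = 20, seed = 31)
  tr <- make_fitness_map(g, seed = 32)
  sim <- simulate_drift(g, tr, rounds = 1, population = 200, seed = 33)
  eps <- 2e-3
  depth <- 50000
  cc <- sequence_population(sim, 0, depth = depth, error_rate = eps,
                            seed = 34)
  bg <- estimate_background(cc, g)
  expected <- 1 - (1 - eps)^3
  # binomial SE of a per-position frequency, averaged over 20 positions
  se <- sqrt(expected * (1 - expected) / depth / 20)
  expect_lt(abs(bg$mean - expected), 3 * se + 1e-6)
})

test_that("net frequencies subtract the background and flag below-background", {
  g <- tiny_gene()
  cc <- make_counts(g, c("3:TTG" = 5, "3:CTA" = 3, "4:AAC" = 1),
                    coverage = 1000, round = 0)
  ft <- net_frequencies(cc, 0.001, g)
  expect_s3_class(ft, "freq_table")
  expect_equal(nrow(ft), 9 * length(g$orf_codons))  # full single-nt ORF space
  r <- ft[ft$codon_pos == 3 & ft$alt_codon == "TTG", ]
  expect_equal(r$raw_freq, 0.005)
  expect_equal(r$net_freq, 0.004)
  expect_false(r$below_background)
  r2 <- ft[ft$codon_pos == 4 & ft$alt_codon == "AAC", ]
  expect_equal(r2$net_freq, 0)
  expect_true(r2$below_background)
  expect_true(all(ft$raw_freq >= 0 & ft$raw_freq <= 1))
  # aggregation sums codon routes to the same amino acid (both syn for Leu)
  aa <- aggregate_frequencies(ft)
  syn3 <- aa[aa$codon_pos == 3 & aa$class == "synonymous", ]
  expect_equal(syn3$net_freq, 0.004 + 0.002)
})

test_that("counts never exceed coverage in the counting path", {
  g <- random_gene(8, upstream_L = 2, seed = 41)
  tr <- make_fitness_map(g, seed = 42)
  sim <- simulate_drift(g, tr, rounds = 2, population = 150, seed = 43,
                        keep_populations = c(0, 2))
  rd <- sequence_population(sim, 2, depth = 300, mode = "reads",
                            read_length = 24, error_rate = 0.01, seed = 44)
  cc <- count_codon_mutations(map_reads(rd$seq, g), g)
  tot <- tapply(cc$counts$count, cc$counts$codon_pos, sum)
  cov <- cc$coverage$coverage[match(as.integer(names(tot)),
                                    cc$coverage$codon_pos)]
  expect_true(all(tot <= cov))
})

test_that("substitution matrix arithmetic and ti/tv conventions", {
  g <- reference_gene(c("GCA", "TTG"))  # all four bases present
  # one variant per substitution type; transitions get 130, transversions 100
  v <- enumerate_codon_variants(g, 1)
  ch <- driftDFE:::single_nt_change(v$ref_codon, v$alt_codon)
  type <- paste(ch$ref_base, ch$alt_base)
  pick <- v[!duplicated(type), ]
  is_ti <- driftDFE:::TRANSITIONS[ch$ref_base[!duplicated(type)]] ==
    ch$alt_base[!duplicated(type)]
  counts <- stats::setNames(ifelse(is_ti, 130L, 100L),
                            paste0(pick$codon_pos, ":", pick$alt_codon))
  cc <- make_counts(g, counts, coverage = 1e6, round = 0)
  ft <- net_frequencies(cc, 0, g)
  sm <- substitution_matrix(ft, g)
  expect_equal(sm$titv, (4 * 130) / (8 * 100))
  # equal counts for all 12 types -> ti/tv = 4/8 = 0.5
  counts2 <- stats::setNames(rep(100L, nrow(pick)),
                             paste0(pick$codon_pos, ":", pick$alt_codon))
  sm2 <- substitution_matrix(net_frequencies(make_counts(g, counts2, 1e6), 0, g), g)
  expect_equal(sm2$titv, 0.5)
})

test_that("simulated spectrum is recovered by the substitution matrix", {
  g <- random_gene(30, upstream_L = 5, seed = 51)
  tr <- make_fitness_map(g, seed = 52)
  sim <- simulate_drift(g, tr, rounds = 1, population = 5000, seed = 53,
                        subst = default_subst_matrix(titv = 1.3))
  cc <- sequence_population(sim, 0, depth = 2e5, error_rate = 0, seed = 54)
  ft <- net_frequencies(cc, estimate_background(cc, g), g)
  sm <- substitution_matrix(ft, g)
  # event-level ti/tv should recover the simulated 1.3 within sampling error
  expect_lt(abs(sm$titv - 1.3), 0.25)
})

test_that("expected naive frequency reads the matrix", {
  g <- tiny_gene()
  sm <- list(rates = matrix(0, 4, 4, dimnames = list(c("A","C","G","T"),
                                                     c("A","C","G","T"))),
             titv = NA)
  class(sm) <- "nt_subst_matrix"
  sm$rates["A", "G"] <- 1e-3
  v <- data.frame(ref_codon = "AAA", alt_codon = "AGA")
  expect_equal(expected_g0_frequency(v, sm), 1e-3)
  v0 <- data.frame(ref_codon = "AAA", alt_codon = "ACA")
  expect_equal(expected_g0_frequency(v0, sm), 0)
  expect_error(expected_g0_frequency(
    data.frame(ref_codon = "AAA", alt_codon = "AGG"), sm),
    "single-nucleotide")
})

test_that("error-free reads of a wild-type pool give all-zero counts", {
  g <- random_gene(10, upstream_L = 3, seed = 61)
  tr <- make_fitness_map(g, dfe_spec = list(list(weight = 1, dist = "point",
                                                 value = 1)),
                         nonsense_w = 1, seed = 62)
  sim <- simulate_drift(g, tr, rounds = 1, population = 100, lambda = 1e-9,
                        seed = 63)
  rd <- sequence_population(sim, 0, depth = 200, mode = "reads",
                            read_length = 30, error_rate = 0, seed = 64)
  ref <- driftDFE:::reference_string(g)
  expect_true(all(mapply(function(s, o) {
    s == substr(ref, o, o + nchar(s) - 1)
  }, rd$seq, rd$true_offset)))
  cc <- count_codon_mutations(map_reads(rd$seq, g), g)
  expect_equal(nrow(cc$counts), 0)
})
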