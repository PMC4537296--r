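test_that("DFE histogram bins and conserves counts", {
  rec <- make_records(c(0.05, 0.5, 1.0, 1.5))
  h <- dfe_histogram(rec)
  expect_equal(h$total[h$bin == "[0.0,0.1)"], 1)
  expect_equal(h$total[h$bin == "[0.5,0.6)"], 1)
  expect_equal(h$total[h$bin == "[1.0,1.1)"], 1)
  expect_equal(h$total[h$bin == ">1.4"], 1)
  expect_equal(sum(h$total), 4)
  # empty input -> all-zero histogram
  h0 <- dfe_histogram(make_records(numeric(0)))
  expect_true(all(h0$total == 0))
  # conservation on a random fit
  rec2 <- make_records(runif(200, 0, 2),
                       class = sample(c("missense", "nonsense", "synonymous"),
                                      200, replace = TRUE))
  h2 <- dfe_histogram(rec2)
  expect_equal(sum(h2$total), 200)
  expect_equal(sum(h2$missense), sum(rec2$class == "missense"))
  # eliminated mutations tallied separately but kept in the first bin
  rec3 <- make_records(c(0, 0, 0.05))
  h3 <- dfe_histogram(rec3)
  expect_equal(h3$total[1], 3)
  expect_equal(unname(attr(h3, "eliminated")[["missense"]]), 2)
})

test_that("frequency-weighted DFE shares sum to one", {
  rec <- make_records(c(0.3, 1.0), f_gn = c(0.02, 0.02))
  fw <- frequency_weighted_dfe(rec)
  expect_equal(sum(fw$share), 1)
  expect_equal(fw$share[fw$range == "<=0.6"], 0.5)
  # single mutation -> share 1 in its range
  fw1 <- frequency_weighted_dfe(make_records(0.7, f_gn = 0.05))
  expect_equal(fw1$share[fw1$range == "(0.6,0.8]"], 1)
  expect_error(frequency_weighted_dfe(make_records(c(0.5, 1), f_gn = c(0, 0))),
               "zero")
})

test_that("fold changes are log ratios with antisymmetry", {
  a <- data.frame(range = c("r1", "r2"), share = c(0.25, 0.75))
  b <- data.frame(range = c("r1", "r2"), share = c(0.5, 0.5))
  fc <- fold_change(a, b, log_base = 2)
  expect_equal(fc$log_fold_change[1], 1)    # doubling, base 2
  expect_equal(fold_change(a, a)$log_fold_change, c(0, 0))
  expect_equal(fold_change(b, a, log_base = 2)$log_fold_change,
               -fc$log_fold_change)
  z <- data.frame(range = c("r1", "r2"), share = c(0, 1))
  fcz <- fold_change(z, b)
  expect_true(fcz$undefined[1] && is.na(fcz$log_fold_change[1]))
})

test_that("mutational loads sum net frequencies per class", {
  g <- tiny_gene()
  # Na mass 0.013 (missense 4:GAA + nonsense 2:TGA), Ns mass 0.005 (3:TTG)
  cc <- make_counts(g, c("3:TTG" = 5000, "4:GAA" = 8000, "2:TGA" = 5000),
                    coverage = 1e6, round = 3)
  ft <- net_frequencies(cc, 0, g)
  ld <- mutational_loads(ft)
  expect_equal(ld$Ns, 0.005)
  expect_equal(ld$Na, 0.013)
  expect_equal(ld$NaNs, 2.6)
  expect_equal(ld$Nt, 0.018)
  # zero synonymous load -> undefined ratio
  cc2 <- make_counts(g, c("4:GAA" = 8000), coverage = 1e6)
  expect_true(is.na(mutational_loads(net_frequencies(cc2, 0, g))$NaNs))
})

test_that("neutral simulation accumulates load linearly with no purging", {
  g <- random_gene(15, upstream_L = 0, seed = 81)
  tr <- make_fitness_map(g, dfe_spec = list(list(weight = 1, dist = "point",
                                                 value = 1)),
                         nonsense_w = 1, seed = 82)
  n <- 4; lambda <- 2; N <- 4000
  sim <- simulate_drift(g, tr, rounds = n, lambda = lambda, population = N,
                        seed = 83)
  # drift-inflated standard error of the mean load: resampling propagates
  # prior rounds' variance, giving var ~ lambda * n(n+1)/2 / N
  se <- sqrt(lambda * n * (n + 1) / 2 / N)
  expect_lt(abs(sim$loads$post_mean[n] - n * lambda), 3 * se)
  expect_lt(abs(sim$loads$pre_mean[1] - lambda), 3 * sqrt(lambda / N))
})

test_that("positional score is the frequency-weighted wrel sum", {
  rec <- make_records(c(1, 0.5, 0.5), f_gn = c(0.1, 0.1, 0.1),
                      codon_pos = c(1, 2, 2))
  ps <- positional_wrel(rec)
  expect_equal(ps$score[ps$codon_pos == 1], 1 * log2(1 + 10 * 0.1))
  expect_equal(ps$score[ps$codon_pos == 2], 2 * 0.5 * log2(2))
  psn <- positional_wrel(rec, normalized = TRUE)
  expect_equal(psn$score[psn$codon_pos == 2], 0.5)
  # no observed mutations at a position -> zero score
  rec0 <- make_records(c(1, 0.8), f_gn = c(0, 0.05), codon_pos = c(3, 4))
  ps0 <- positional_wrel(rec0)
  expect_equal(ps0$score[ps0$codon_pos == 3], 0)
})

test_that("compensatory calls require enrichment beyond the threshold", {
  thr <- derive_thresholds(mode = "paper_default")
  rec <- make_records(c(1.3, 1.0, 0.4), f_gn = c(0.05, 0.05, 0.01))
  cs <- call_compensatory(rec, thr)
  expect_equal(nrow(cs$mutations), 1)
  expect_equal(cs$mutations$wrel, 1.3)
  rec_flat <- make_records(rep(1, 5))
  cs0 <- call_compensatory(rec_flat, thr)
  expect_equal(nrow(cs0$mutations), 0)
  expect_equal(nrow(cs0$positions), 0)
})

test_that("a simulated beneficial mutation is called compensatory", {
  g <- random_gene(12, upstream_L = 3, seed = 91)
  tr <- make_fitness_map(g, dfe_spec = list(list(weight = 1, dist = "point",
                                                 value = 1)), seed = 92)
  ben <- which(tr$class == "missense")[1]
  tr$w[ben] <- 1.5
  sim <- simulate_drift(g, tr, rounds = 5, population = 5000, seed = 93)
  cc0 <- sequence_population(sim, 0, depth = 1e5, seed = 94)
  cc5 <- sequence_population(sim, 5, depth = 1e5, seed = 95)
  f0 <- net_frequencies(cc0, estimate_background(cc0, g), g)
  f5 <- net_frequencies(cc5, estimate_background(cc5, g), g)
  fit <- drift_fit(f0, f5, n = 5, gene = g, thresholds = "paper_default")
  calls <- call_compensatory(fit)
  key <- paste(tr$codon_pos[ben],
               unname(Biostrings::GENETIC_CODE[tr$alt_codon[ben]]))
  expect_true(key %in% paste(calls$mutations$codon_pos,
                             calls$mutations$alt_aa))
})
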