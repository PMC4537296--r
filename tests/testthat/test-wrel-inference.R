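test_that("expected ratio follows the geometric accumulation model", {
  expect_equal(expected_ratio(3, 1), 3)
  expect_equal(expected_ratio(17, 1), 17)
  expect_equal(expected_ratio(5, 0), 0)
  # direct-summation oracle
  direct <- function(n, w) sum(w^(1:n))
  for (n in c(1, 3, 7, 17)) {
    for (w in c(0, 0.25, 0.5, 1, 1.7, 3.5)) {
      expect_equal(expected_ratio(n, w), direct(n, w))
    }
  }
  expect_equal(expected_ratio(17, 0.5), 1 - 0.5^17)
  # strictly increasing in w
  for (n in c(1, 5, 20)) {
    r <- expected_ratio(n, seq(0.01, 3.5, by = 0.05))
    expect_true(all(diff(r) > 0))
  }
  expect_error(expected_ratio(0, 1), "n must be")
})

test_that("grid inversion recovers fitness within one grid step", {
  expect_equal(invert_ratio(3, 3)$wrel, 1)
  expect_equal(invert_ratio(0, 5)$wrel, 0)
  expect_equal(invert_ratio(expected_ratio(7, 0.8), 7)$wrel, 0.8,
               tolerance = 0.01)
  # forward-inverse identity across the grid and round counts
  for (n in c(1, 2, 5, 10, 20)) {
    w <- seq(0, 3.5, by = 0.07)
    back <- invert_ratio(expected_ratio(n, w), n)$wrel
    expect_lt(max(abs(back - w)), 0.01 + 1e-9)
  }
  # capping above the attainable maximum
  top <- expected_ratio(3, 3.5)
  inv <- invert_ratio(top * 1.5, 3)
  expect_equal(inv$wrel, 3.5)
  expect_true(inv$capped)
  expect_false(invert_ratio(top, 3)$capped)
  expect_error(invert_ratio(1, 0), "n must be")
})

test_that("threshold derivation reproduces the calibrator arithmetic", {
  thr <- derive_thresholds(two_point_sample(0.82, 0.12),
                           two_point_sample(0.042, 0.15))
  expect_equal(thr$deleterious_max, 0.82 - 2 * 0.12)
  expect_equal(thr$nearly_neutral_max, 0.82 - 0.12)
  expect_equal(thr$beneficial_min, 0.82 + 2 * 0.12)
  expect_equal(thr$highly_deleterious_max, 0.042 + 2 * 0.15)
  # per-library thresholds are averaged
  thr3 <- derive_thresholds(list(two_point_sample(0.82, 0.12),
                                 two_point_sample(0.84, 0.145),
                                 two_point_sample(0.91, 0.095)))
  expect_equal(thr3$deleterious_max, mean(c(0.58, 0.55, 0.72)),
               tolerance = 1e-9)
  # degenerate distribution collapses boundaries without error
  thr0 <- derive_thresholds(c(1, 1, 1))
  expect_equal(thr0$deleterious_max, 1)
  expect_error(derive_thresholds(0.5), "at least 2")
  # rounding for reporting
  expect_equal(round_thresholds(thr3)$deleterious_max, 0.6)
})

test_that("classification partitions the fitness scale", {
  thr <- derive_thresholds(mode = "paper_default")
  expect_equal(as.character(classify_wrel(0.25, thr)), "highly_deleterious")
  expect_equal(as.character(classify_wrel(0.7, thr)), "nearly_neutral")
  expect_equal(as.character(classify_wrel(1.2, thr)), "beneficial")
  expect_equal(as.character(classify_wrel(c(0.3, 0.6, 0.8, 1.1), thr)),
               c("highly_deleterious", "deleterious", "nearly_neutral",
                 "neutral"))
  # exactly one category everywhere on the scale
  w <- seq(0, 3.5, by = 0.013)
  cats <- classify_wrel(w, thr)
  expect_false(anyNA(cats))
  expect_error(classify_wrel(-0.1, thr), "negative")
})

test_that("drift_fit assigns neutral, eliminated and substituted records", {
  g <- tiny_gene()
  cov <- 1e6
  # codon 3 CTG: TTG (syn) behaves neutrally over 17 rounds; CAG (missense)
  # eliminated; GTG (missense) below background in the naive pool
  g0 <- make_counts(g, c("3:TTG" = 10000, "3:CAG" = 10000, "4:GAA" = 12000,
                         "4:AGA" = 9000, "2:TGA" = 8000,
                         "-1:GAT" = 1000, "-2:CAA" = 1000),
                    coverage = cov, library_id = "G0", round = 0)
  gn <- make_counts(g, c("3:TTG" = 170000, "4:GAA" = 200000,
                         "-1:GAT" = 1000, "-2:CAA" = 1000),
                    coverage = cov, library_id = "G17", round = 17)
  f0 <- net_frequencies(g0, estimate_background(g0, g), g)
  fn <- net_frequencies(gn, estimate_background(gn, g), g)
  fit <- drift_fit(f0, fn, n = 17, gene = g, thresholds = "paper_default")
  rec <- fit$records
  ttg <- rec[rec$codon_pos == 3 & rec$class == "synonymous", ]
  # f ratio 0.17/0.01 (net of 0.001 background) ~ 17 -> wrel ~ 1
  expect_equal(ttg$wrel, 1, tolerance = 0.02)
  expect_equal(as.character(ttg$category), "neutral")
  cag <- rec[rec$codon_pos == 3 & rec$alt_aa == "Q", ]
  expect_true(cag$eliminated)
  expect_equal(cag$wrel, 0)
  expect_equal(as.character(cag$category), "highly_deleterious")
  # below-background naive frequency replaced by the substitution-table rate:
  # GAT -> GGT (Asp -> Gly) is an A -> G change, a type with naive mass
  ggt <- rec[rec$codon_pos == 7 & rec$alt_aa == "G", ]
  expect_true(ggt$below_background_g0)
  expect_true(is.finite(ggt$f_g0) && ggt$f_g0 > 0)
  # every defined record gets exactly one category
  expect_false(anyNA(rec$category[!rec$undefined]))
})

test_that("drift_fit methods behave like a model object", {
  g <- random_gene(12, upstream_L = 3, seed = 71)
  tr <- make_fitness_map(g, seed = 72)
  sim <- simulate_drift(g, tr, rounds = 3, population = 800, seed = 73)
  f0cc <- sequence_population(sim, 0, depth = 5e4, seed = 74)
  f3cc <- sequence_population(sim, 3, depth = 5e4, seed = 75)
  f0 <- net_frequencies(f0cc, estimate_background(f0cc, g), g)
  f3 <- net_frequencies(f3cc, estimate_background(f3cc, g), g)
  fit <- drift_fit(f0, f3, n = 3, gene = g, thresholds = "paper_default")
  expect_s3_class(fit, "drift_fit")
  expect_output(print(fit), "Relative fitness fit")
  s <- summary(fit)
  expect_output(print(s), "Category composition")
  cf <- coef(fit)
  expect_equal(length(cf), nrow(fit$records))
  expect_true(all(cf >= 0 & cf <= 3.5, na.rm = TRUE))
  pred <- predict(fit)
  ok <- !fit$records$undefined & !fit$records$capped
  # predictions reproduce observed selected-pool frequencies up to grid error
  expect_equal(pred[ok], fit$records$f_gn[ok], tolerance = 0.05)
  res <- residuals(fit)
  expect_equal(length(res), nrow(fit$records))
  pdf(NULL); plot(fit); dev.off()
})
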