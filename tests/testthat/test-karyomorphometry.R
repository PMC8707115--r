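test_that("arm ratio normalises orientation and rejects bad input", {
  expect_equal(arm_ratio(4.90, 2.00), 2.45)
  expect_equal(arm_ratio(3.0, 3.0), 1.0)
  expect_equal(arm_ratio(1.20, 1.63), 1.63 / 1.20)  # swapped arms
  expect_true(round(arm_ratio(1.63, 1.20), 2) == 1.36)
  expect_error(arm_ratio(0, 1), "positive")
  expect_error(arm_ratio(2, -1), "positive")
})

test_that("morphology classes follow the arm-ratio intervals", {
  expect_equal(classify_levan(c(1.0, 1.19, 1.5)), c("m", "m", "m"))
  expect_equal(classify_levan(c(1.61, 1.70, 2.28, 3.0)),
               c("sm", "sm", "sm", "sm"))
  expect_equal(classify_levan(c(3.01, 7.0)), c("st", "st"))
  expect_equal(classify_levan(7.01), "t")
  expect_error(classify_levan(0.9), "orientation")
})

test_that("classification is monotone in the arm ratio", {
  order_of <- function(cls) match(cls, c("m", "sm", "st", "t"))
  r <- sort(c(seq(1, 10, by = 0.07), 1.5, 3, 7, 1.51, 3.01, 7.01))
  expect_true(all(diff(order_of(classify_levan(r))) >= 0))
})

test_that("relative lengths are percentages summing to 100", {
  expect_equal(relative_length(5, c(5)), 100)
  expect_equal(relative_length(2, c(2, 2, 2, 2)), 25)
  expect_equal(round(relative_length(8.79, c(rep(55.97 / 8, 8))), 2), 15.70,
               tolerance = 0.01)
  set.seed(1)
  for (i in 1:10) {
    tl <- runif(2 * sample(4:20, 1), 0.5, 9)
    expect_equal(sum(relative_length(tl)), 100, tolerance = 1e-9)
  }
  expect_error(relative_length(1, numeric(0)), "positive")
  expect_error(relative_length(1, c(1, -2)), "positive")
})

test_that("a noise-free spread from the smallest new karyotype recovers its classes", {
  # single spread whose arm pairs equal the published per-chromosome means
  prof_pub <- attina_karyomorph_tables()[["Mycocepurus goeldii"]]
  spread <- profile_means_as_spread(prof_pub)
  prof <- aggregate_spreads(spread)
  expect_equal(nrow(prof), 8L)
  expect_equal(prof$morphology, c("m", "m", "m", "m", "sm", "sm", "sm", "sm"))
  # single spread: SDs are zero, means equal the raw values
  expect_true(all(prof$sd_TL == 0) && all(prof$sd_r == 0))
  # reconstructed TL = mean_L + mean_S; the printed TL column agrees within
  # print rounding except for one homologue row where the published L and
  # TL cells are mutually inconsistent by 0.10 um
  expect_equal(sort(prof$mean_TL), sort(prof_pub$mean_L + prof_pub$mean_S),
               tolerance = 1e-9)
  gaps <- abs(sort(prof$mean_TL) - sort(prof_pub$mean_TL))
  expect_lte(sum(gaps > 0.011), 1L)
  expect_lte(max(gaps), 0.101)
  expect_equal(sum(prof$mean_RL), 100, tolerance = 1e-9)
})

test_that("aggregation rejects spreads with unequal chromosome counts", {
  s1 <- data.frame(spread_id = "a", chromosome_index = 1:4,
                   long_um = c(4, 4, 3, 3), short_um = c(2, 2, 1, 1))
  s2 <- data.frame(spread_id = "b", chromosome_index = 1:2,
                   long_um = c(4, 4), short_um = c(2, 2))
  expect_error(aggregate_spreads(rbind(s1, s2)), "inconsistent")
  expect_error(aggregate_spreads(rbind(s1, s2)), "a \\(4\\).*b \\(2\\)")
})

test_that("mean total lengths are recovered from many simulated spreads", {
  truth <- toy_truth()
  spreads <- simulate_spreads(truth, n_spreads = 50, condensation_sd = 0.02,
                              arm_noise_sd = 0.01, seed = 42)
  prof <- aggregate_spreads(spreads)
  # homologue pairs share one truth value; compare pair means to truth
  pair_mean <- as.vector(tapply(prof$mean_TL, prof$pair, mean))
  # display order groups m pairs (sizes 10, 8) before sm (6.5, 5) before st (4)
  expect_equal(pair_mean, c(10, 8, 6.5, 5, 4), tolerance = 0.02)
  pair_sd <- as.vector(tapply(prof$sd_TL, prof$pair, mean))
  se <- pair_sd / sqrt(50)
  expect_true(all(abs(pair_mean - c(10, 8, 6.5, 5, 4)) <= 2.5 * se + 1e-9))
  expect_equal(prof$morphology, rep(toy_classes(), each = 2))
})

test_that("karyotype summaries aggregate number, formula, FN and KL", {
  kt <- attina_karyomorph_tables()
  s2 <- summarize_karyotype(kt[["Myrmicocrypta sp."]])
  expect_equal(s2$chromosome_number, 28L)
  expect_equal(format_formula(s2$formula), "24 m + 4 sm")
  expect_equal(s2$fundamental_number, 56L)
  expect_equal(round(s2$karyotype_length, 2), 82.47)

  s3 <- summarize_karyotype(kt[["Cyphomyrmex transversus"]])
  expect_equal(s3$chromosome_number, 42L)
  expect_equal(s3$fundamental_number, 84L)
  expect_equal(round(s3$karyotype_length, 2), 82.28)

  tiny <- data.frame(mean_TL = c(5, 5), morphology = c("m", "m"))
  st <- summarize_karyotype(tiny)
  expect_equal(st$chromosome_number, 2L)
  expect_equal(format_formula(st$formula), "2 m")
  expect_equal(st$fundamental_number, 4L)
  expect_equal(st$karyotype_length, 10)
})

test_that("chromosome number bounds the fundamental number", {
  set.seed(11)
  for (i in 1:25) {
    counts <- sample(0:8, 5, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 2
    f <- as_karyotype_formula(stats::setNames(counts,
                                              c("m", "sm", "st", "t", "a")))
    n2 <- sum(f)
    fn <- fundamental_number(f)
    expect_true(n2 <= fn && fn <= 2 * n2)
    if (f[["t"]] + f[["a"]] == 0) expect_equal(fn, 2 * n2)
  }
})

test_that("heteromorphic pairs are flagged on class or size differences", {
  truth <- toy_truth()
  base <- simulate_spreads(truth, n_spreads = 10, condensation_sd = 0,
                           arm_noise_sd = 0, seed = 1)
  # identical homologues: nothing flagged
  none <- detect_heteromorphism(base)
  expect_false(any(none$flagged))

  # push one homologue of pair 3 (true r = 2.0, sm) below the m boundary in
  # every spread: lengthen its short arm, keeping TL constant
  mod <- base
  idx <- which(mod$chromosome_index == 6)  # second homologue of pair 3
  tl <- mod$long_um[idx] + mod$short_um[idx]
  mod$long_um[idx] <- tl * 1.35 / 2.35     # r = 1.35 -> class m
  mod$short_um[idx] <- tl / 2.35
  res <- detect_heteromorphism(mod)
  expect_true(res$flagged[res$pair == 3])
  expect_false(any(res$flagged[res$pair != 3]))
  ev <- attr(res, "evidence")
  expect_true(all(ev$class_1[ev$pair == 3] != ev$class_2[ev$pair == 3]))

  # pure size heteromorphism: same class, TL ratio beyond the threshold
  big <- base
  idx2 <- which(big$chromosome_index == 1)
  big$long_um[idx2] <- big$long_um[idx2] * 1.4
  big$short_um[idx2] <- big$short_um[idx2] * 1.4
  res2 <- detect_heteromorphism(big, pair_index = 1)
  expect_true(res2$flagged)
  expect_error(detect_heteromorphism(base, pair_index = 99), "out of range")
})

test_that("formatted profile tables mirror the published layout", {
  prof <- attina_karyomorph_tables()[["Mycocepurus goeldii"]]
  tab <- format_profile_table(prof)
  expect_equal(tab$Chromosome, c("1", "(1)", "2", "(2)", "3", "(3)", "4",
                                 "(4)", "KL"))
  expect_equal(tab$TL[1], "8.79 ± 3.04")
  expect_equal(tab$TL[nrow(tab)], "55.97")
  expect_equal(tab$Classification[5], "Submetacentric")
})

test_that("haploid material is aggregated without homologue pairing", {
  truth <- true_karyotype(tl = c(8, 6, 4), r = c(1.2, 2.0, 4.0),
                          ploidy = "haploid")
  spreads <- simulate_spreads(truth, n_spreads = 5, condensation_sd = 0,
                              arm_noise_sd = 0, seed = 3)
  prof <- aggregate_spreads(spreads, ploidy = "haploid")
  expect_equal(nrow(prof), 3L)
  expect_equal(prof$pair, 1:3)  # no pairing: every chromosome its own unit
  s <- summarize_karyotype(prof, ploidy = "haploid")
  expect_equal(s$chromosome_number, 3L)
  expect_equal(s$ploidy, "haploid")
  # odd count under diploid assumption errors
  expect_error(aggregate_spreads(spreads, ploidy = "diploid"), "odd")
})
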