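test_that("CD topology classification finds the canonical signatures", {
  expect_equal(classify_cd_topology(gen_spectrum("parallel", 0)), "parallel")
  expect_equal(classify_cd_topology(gen_spectrum("antiparallel", 0)),
               "antiparallel")
  flat <- spectrum(220:350, rep(0, 131))
  expect_equal(classify_cd_topology(flat), "none")
  # a mixed-population spectrum carries both signatures
  par <- gen_spectrum("parallel", 0)
  anti <- gen_spectrum("antiparallel", 0)
  mixed <- spectrum(par$wavelengths, par$intensities + anti$intensities)
  expect_equal(classify_cd_topology(mixed), "mixed")
  expect_error(classify_cd_topology(spectrum(260:280, rnorm(21))), "230-300")
})

test_that("classification is invariant under uniform positive scaling", {
  for (topo in c("parallel", "antiparallel", "none")) {
    s <- gen_spectrum(topo, noise_sd = 0.5, seed = 5)
    for (c in c(0.1, 1, 25)) {
      scaled <- spectrum(s$wavelengths, s$intensities * c)
      expect_equal(classify_cd_topology(scaled), classify_cd_topology(s),
                   label = sprintf("%s x%g", topo, c))
    }
  }
})

test_that("fold enhancement is the ratio of group means, scale-covariant", {
  expect_equal(fold_enhancement(c(5, 5), c(5, 5))$fold, 1.0)
  expect_equal(fold_enhancement(c(3000), c(10))$fold, 300)
  expect_equal(fold_enhancement(c(90, 100, 110), c(1, 1, 1))$fold, 100)
  a <- c(200, 250, 300); b <- c(2, 3, 4)
  expect_equal(fold_enhancement(a * 7, b * 7)$fold, fold_enhancement(a, b)$fold,
               tolerance = 1e-12)
  expect_error(fold_enhancement(c(1, 2), c(0, 0)), "blank mean")
  expect_error(fold_enhancement(numeric(0), c(1)), "at least one")
})

test_that("the unpaired comparison matches the closed-form Welch t", {
  a <- c(12.1, 13.4, 11.8, 12.9, 13.1)
  b <- c(10.2, 10.9, 9.8, 10.5)
  got <- compare_conditions(a, b)
  # closed form: t = (ma - mb) / sqrt(sa^2/na + sb^2/nb), Welch-Satterthwaite df
  se2 <- var(a) / length(a) + var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                        (var(b) / length(b))^2 / (length(b) - 1))
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(got$t_statistic, t_hand, tolerance = 1e-9)
  expect_equal(got$p_value, p_hand, tolerance = 1e-9)
})

test_that("significance stars follow the published thresholds", {
  expect_equal(compare_conditions(c(1, 2, 3), c(1, 2, 3))$stars, "ns")
  expect_equal(compare_conditions(c(1, 2, 3), c(1, 2, 3))$t_statistic, 0)
  # unit-variance groups shifted by +10: p = 2.54e-4 lands in the ** band
  shift <- compare_conditions(c(1, 2, 3), c(11, 12, 13))
  expect_gt(shift$p_value, 1e-4)
  expect_lte(shift$p_value, 1e-3)
  expect_equal(shift$stars, "**")
  # near-constant groups shifted by +10 reach the *** band
  strong <- compare_conditions(c(0.9, 1.0, 1.1), c(10.9, 11.0, 11.1))
  expect_lte(strong$p_value, 1e-4)
  expect_equal(strong$stars, "***")
  # moderate separation lands in the single-star band (0.001, 0.05]
  mid <- compare_conditions(c(1, 2, 3), c(5, 6, 7))
  expect_gt(mid$p_value, 0.001)
  expect_lte(mid$p_value, 0.05)
  expect_equal(mid$stars, "*")
  expect_equal(compare_conditions(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_error(compare_conditions(c(1), c(1, 2)), ">= 2 replicates")
})

test_that("stop fractions recover planted values with the ionic ordering", {
  bands <- data.frame(lane = c("L1", "L2", "L3"),
                      condition = c("no_ion", "K", "Li"),
                      full_length_intensity = c(80, 40, 60),
                      stop_intensity = c(20, 60, 40))
  out <- stop_fraction(bands)
  expect_equal(out$stop_fraction, c(0.2, 0.6, 0.4))
  expect_gt(out$stop_fraction[out$condition == "K"],
            out$stop_fraction[out$condition == "Li"])
  expect_gt(out$stop_fraction[out$condition == "Li"],
            out$stop_fraction[out$condition == "no_ion"])
  expect_equal(stop_fraction(data.frame(lane = "x", condition = "K",
                                        full_length_intensity = 50,
                                        stop_intensity = 50))$stop_fraction, 0.5)
  expect_equal(stop_fraction(data.frame(lane = "x", condition = "K",
                                        full_length_intensity = 80,
                                        stop_intensity = 0))$stop_fraction, 0)
  expect_error(stop_fraction(data.frame(lane = "dead", condition = "K",
                                        full_length_intensity = 0,
                                        stop_intensity = 0)), "lane 'dead'")
})

test_that("stop fraction is bounded and monotone in the stop band", {
  set.seed(23)
  full <- runif(50, 0.1, 100)
  stopv <- runif(50, 0, 100)
  fr <- stop_fraction(data.frame(lane = as.character(1:50), condition = "K",
                                 full_length_intensity = full,
                                 stop_intensity = stopv))$stop_fraction
  expect_true(all(fr >= 0 & fr <= 1))
  ordered <- stop_fraction(data.frame(lane = as.character(1:20), condition = "K",
                                      full_length_intensity = 30,
                                      stop_intensity = sort(runif(20, 0, 50))))
  expect_true(all(diff(ordered$stop_fraction) >= 0))
})

test_that("the assay report assembles classifications, folds and fractions", {
  tht <- data.frame(group = rep(c("blank", "TERRA"), each = 3),
                    replicate = rep(1:3, 2),
                    intensity_488 = c(1.0, 1.1, 0.9, 299.5, 300, 300.5))
  bands <- data.frame(lane = "L1", condition = "K",
                      full_length_intensity = 40, stop_intensity = 60)
  rep <- assay_report(cd_spectra = list(terra = gen_spectrum("parallel", 0.3, 2)),
                      tht_table = tht, band_table = bands)
  expect_equal(rep$cd$terra, "parallel")
  expect_equal(rep$tht$TERRA$fold, 300)
  expect_equal(rep$tht$TERRA$stars, "***")
  expect_equal(rep$rt_stop[[1]]$stop_fraction, 0.6)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA)
  expect_equal(jsonlite::read_json(f)$tht$TERRA$fold, 300)
})
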