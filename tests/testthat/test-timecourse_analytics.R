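test_that("OD to DCW conversion uses the 2.01 factor", {
  expect_equal(odToDcw(1), 2.01)
  expect_equal(odToDcw(0), 0)
  expect_equal(odToDcw(2.5), 5.025)
  expect_error(odToDcw(-1), "negative")
})

test_that("cell constants derive 1.7e10 cells/g and 2.7 mL/g at two figures", {
  cc <- deriveCellConstants()
  expect_equal(signif(cc$cells_per_g, 2), 1.7e10)
  expect_equal(signif(cc$derived_cytosolic_volume_mL_per_g, 2), 2.7)
  # inverse proportionality in the cell mass
  cc2 <- deriveCellConstants(cellConstants(cell_mass_pg = 120))
  expect_equal(cc2$cells_per_g, cc$cells_per_g / 2)
})

test_that("cytosolic concentration conversion reproduces the worked examples", {
  expect_equal(cytosolicConcentration(520), 192, tolerance = 0.01)
  expect_equal(cytosolicConcentration(351), 129, tolerance = 0.01)
  expect_equal(cytosolicConcentration(0), 0)
  # unit-chain closure: od -> dcw -> specific -> mM has no hidden factors;
  # x umol per (g DCW) over (mL/g DCW) is umol/mL = mM exactly
  cc <- cellConstants(cytosolic_volume_mL_per_g = 2)
  expect_equal(cytosolicConcentration(10, cc), 5)
})

test_that("fold changes reproduce the 38x and 384x figures", {
  expect_equal(foldChange(19, 0.5), 38)
  expect_equal(foldChange(192, 0.5), 384)
  expect_equal(foldChange(7, 7), 1)
  expect_error(foldChange(1, 0), "positive")
})

test_that("mu_max fitting is exact on exponential data and flags flat series", {
  t <- seq(0, 12, by = 1)
  expect_equal(fitMuMax(t, 0.01 * exp(0.3 * t))$mu_max, 0.3,
               tolerance = 1e-9)
  f <- fitMuMax(t, 0.01 * exp(0.3 * t), window = c(2, 8))
  expect_equal(f$mu_max, 0.3, tolerance = 1e-9)
  expect_warning(ff <- fitMuMax(t, rep(5, length(t))), "no positive-slope")
  expect_equal(ff$mu_max, 0)
  expect_true(ff$flat)
  expect_error(fitMuMax(c(0, 1), c(1, 2)), "at least")
})

test_that("growth yield is the maximum DCW gained per glucose consumed", {
  t <- 0:6
  glc <- c(20, 18, 14, 8, 4, 2, 2)
  dcw <- 0.004 * (20 - glc) + 0.001       # true yield 0.004 from x0=0.001
  expect_equal(growthYield(t, dcw, glc), 0.004, tolerance = 1e-9)
  expect_equal(growthYield(t, rep(1, 7), glc), 0)
  expect_error(growthYield(t, dcw, rep(20, 7)), "no glucose consumed")
})

test_that("exponential rise fit recovers parameters and the 48 h read-off", {
  t <- c(0, 2, 4, 8, 12, 16, 24, 32, 40, 48)
  y <- 600 * (1 - exp(-0.1 * t))
  f <- fitExponentialRise(t, y)
  expect_equal(f$A, 600, tolerance = 1e-6)
  expect_equal(f$k, 0.1, tolerance = 1e-6)
  expect_equal(f$value_at_eval, 600 * (1 - exp(-4.8)), tolerance = 1e-6)
  expect_equal(f$value_at_eval, 595.1, tolerance = 1e-3)
  expect_error(fitExponentialRise(c(0, 10), c(0, 5)), "at least 3")
})

test_that("carbon totals reduce to the member fit and respect weights", {
  t <- c(0, 4, 8, 12, 16, 24, 32, 40, 48)
  tc <- data.frame(time_h = t,
                   M1 = 100 * (1 - exp(-0.08 * t)),
                   M2 = 50 * (1 - exp(-0.08 * t)))
  single <- carbonTotal(tc, "M1")
  direct <- fitExponentialRise(t, tc$M1)
  expect_equal(single$value_at_48h, direct$value_at_eval, tolerance = 1e-9)
  # carbon_mol with unit weights equals metabolite_mol
  cm <- carbonTotal(tc, c("M1", "M2"), mode = "carbon_mol",
                    carbon_counts = c(M1 = 1, M2 = 1))
  mm <- carbonTotal(tc, c("M1", "M2"))
  expect_equal(cm$value_at_48h, mm$value_at_48h, tolerance = 1e-9)
  # additivity on noiseless data (same k: sums stay exponential-rise)
  m1 <- carbonTotal(tc, "M1")$value_at_48h
  m2 <- carbonTotal(tc, "M2")$value_at_48h
  expect_equal(mm$value_at_48h, m1 + m2, tolerance = 1e-6)
  expect_error(carbonTotal(tc, character()), "empty")
  expect_error(carbonTotal(tc, "GHOST"), "absent")
  expect_error(carbonTotal(tc, c("M1", "M2"), mode = "carbon_mol"),
               "carbon_counts")
})

test_that("sigmoidal titer fits recover the plateau and reject decays", {
  t <- c(0, 4, 8, 12, 16, 20, 24, 30, 36, 48, 60, 72, 96)
  y <- 120 / (1 + exp(-(t - 24) / 6))
  f <- fitSigmoid3(t, y)
  expect_equal(f$a, 120, tolerance = 1e-6)
  expect_equal(f$final_titer, f$a)
  expect_equal(f$t0, 24, tolerance = 1e-6)
  expect_error(fitSigmoid3(t, rev(y)), "not increasing")
  expect_error(fitSigmoid3(c(0, 1, 2), c(1, 2, 3)), "at least 4")
})

test_that("specific rates regress amount on the biomass-time integral", {
  t <- seq(0, 10, by = 0.5)
  X <- 0.05 * exp(0.3 * t)                      # g DCW/L
  intX <- 0.05 / 0.3 * (exp(0.3 * t) - 1)
  M <- 1.0 * intX                               # q = 1 mmol/gDCW/h
  expect_equal(rateEstimate(t, X, M), 1.0, tolerance = 0.02)
  expect_equal(rateEstimate(t, X, rep(3, length(t))), 0, tolerance = 1e-9)
  expect_lt(rateEstimate(t, X, 10 - 0.5 * intX), 0)   # consumption
  expect_error(rateEstimate(t, X, M, phase = c(0, 0.6)), "fewer than 3")
})

test_that("time-course CSV reading validates structure", {
  p <- withr::local_tempfile(fileext = ".csv")
  df <- simulateTimecourse(fermentationSpec(seed = 7, noise_sigma = 0))
  write.csv(df, p, row.names = FALSE)
  back <- readTimeCourse(p)
  expect_setequal(names(back), names(df))
  expect_equal(nrow(back), nrow(df))
  bad <- df; bad$time_h[2] <- bad$time_h[1]
  write.csv(bad, p, row.names = FALSE)
  expect_error(readTimeCourse(p), "strictly increasing")
})
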