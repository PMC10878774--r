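# a cheap fixed "model truth" grid so synthetic-data tests never integrate
fake_truth <- function(protocols = c("mono_8x100us", "mono_8x5ms"),
                       conc = c(0, 10, 30, 50)) {
  g <- expand.grid(protocol = protocols, X_e_uM = conc,
                   stringsAsFactors = FALSE)
  g$molecules <- 8e5 * g$X_e_uM # ~4e7 at 50 uM, the observed scale
  g
}

test_that("synthetic uptake generation is deterministic and structured", {
  cfg <- synthetic_config(protocols = c("mono_8x100us", "mono_8x5ms"),
                          n_replicates = 4, seed = 11)
  truth <- fake_truth()
  a <- generate_uptake_measurements(cfg, truth)
  b <- generate_uptake_measurements(cfg, truth)
  expect_identical(a, b)
  # (2 protocols + control) x 4 concentrations x 4 replicates
  expect_equal(nrow(a), 3 * 4 * 4)
  expect_true(all(a$value >= 0))
  expect_true(all(c("mono_8x100us", "mono_8x5ms", "control") %in% a$protocol))

  # byte-identical CSV under a fixed seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(a, p1)
  write_measurements(generate_uptake_measurements(cfg, truth), p2)
  expect_identical(readLines(p1), readLines(p2))

  # a different seed moves the values but not the shape
  c2 <- generate_uptake_measurements(
    synthetic_config(protocols = cfg$protocols, n_replicates = 4, seed = 12),
    truth)
  expect_equal(dim(c2), dim(a))
  expect_false(isTRUE(all.equal(c2$value, a$value)))

  expect_error(generate_uptake_measurements(cfg, truth[truth$X_e_uM > 0, ]),
               "missing condition")
})

test_that("vanishing noise reproduces the model truth exactly", {
  cfg <- synthetic_config(protocols = "mono_8x100us", n_replicates = 3,
                          uptake_cv = 1e-12, baseline_slope = 0, seed = 5)
  truth <- fake_truth("mono_8x100us")
  m <- generate_uptake_measurements(cfg, truth)
  trt <- m[m$protocol != "control" & m$concentration_uM == 50, ]
  expect_equal(trt$value, rep(truth$molecules[truth$X_e_uM == 50], 3),
               tolerance = 1e-9)
})

test_that("sample means recover the configured distortion factor", {
  cfg <- synthetic_config(protocols = "mono_8x100us", concentrations_uM = 50,
                          n_replicates = 1e4, baseline_slope = 0,
                          distortion = 2.5, seed = 3)
  truth <- fake_truth("mono_8x100us", conc = 50)
  m <- generate_uptake_measurements(cfg, truth)
  trt <- m$value[m$protocol == "mono_8x100us"]
  se <- stats::sd(trt) / sqrt(length(trt))
  expect_lt(abs(mean(trt) - 2.5 * truth$molecules), 3 * se)
})

test_that("colony counts follow the survival link and plating efficiency", {
  truth <- fake_truth("mono_8x100us", conc = c(10, 30, 50))
  names(truth)[2] <- "concentration_uM"

  # no killing: expected counts are cells_plated x pe0 everywhere
  cfg0 <- synthetic_config(protocols = "mono_8x100us", kill_rate = 0,
                           wells = 400, plating_efficiency = 0.8, seed = 2)
  cnt0 <- generate_clonogenic_counts(cfg0, truth)
  expect_equal(mean(cnt0$colonies), 80, tolerance = 0.02)

  # overwhelming uptake kills every clone
  cfg_hi <- synthetic_config(protocols = "mono_8x100us", kill_rate = 1,
                             wells = 3, seed = 2)
  cnt_hi <- generate_clonogenic_counts(cfg_hi, truth)
  expect_true(all(cnt_hi$colonies[cnt_hi$protocol != "control"] == 0))

  # binomial mean at a point engineered to S = 0.5
  mol_half <- log(2) / 1e-7
  tab <- data.frame(protocol = "mono_8x100us", concentration_uM = 30,
                    molecules = mol_half)
  cfg_h <- synthetic_config(protocols = "mono_8x100us", kill_rate = 1e-7,
                            wells = 1e4, plating_efficiency = 0.8, seed = 9)
  cnt <- generate_clonogenic_counts(cfg_h, tab)
  w <- cnt$colonies[cnt$protocol == "mono_8x100us"]
  p_true <- 0.8 * 0.5
  se <- sqrt(100 * p_true * (1 - p_true)) / sqrt(length(w))
  expect_lt(abs(mean(w) - 100 * p_true), 3 * se)

  # determinism under the configuration seed
  expect_identical(generate_clonogenic_counts(cfg_h, tab),
                   generate_clonogenic_counts(cfg_h, tab))
})

test_that("survival normalization by control plating efficiency", {
  counts <- rbind(
    data.frame(protocol = "control", concentration_uM = 0, well = 1:3,
               cells_plated = 100, colonies = c(80, 78, 82)),
    data.frame(protocol = "a", concentration_uM = 50, well = 1:3,
               cells_plated = 100, colonies = c(80, 78, 82)),
    data.frame(protocol = "b", concentration_uM = 50, well = 1:3,
               cells_plated = 100, colonies = 0))
  s <- clonogenic_survival(counts)
  expect_equal(s$survival_fraction[s$protocol == "a"], 1)
  expect_equal(s$survival_fraction[s$protocol == "b"], 0)

  dead_ctl <- transform(counts, colonies = 0)
  expect_error(clonogenic_survival(dead_ctl), "control plating efficiency")

  # round trip: counts generated at known survival recover it
  tab <- data.frame(protocol = "a", concentration_uM = 30,
                    molecules = log(4) / 1e-7) # S = 0.25
  cfg <- synthetic_config(protocols = "a", kill_rate = 1e-7, wells = 300,
                          plating_efficiency = 0.8, seed = 21)
  rec <- clonogenic_survival(generate_clonogenic_counts(cfg, tab))
  expect_equal(rec$survival_fraction, 0.25, tolerance = 0.05)
})

test_that("kill-rate fitting is exact on clean data and scale-equivariant", {
  mols <- c(1e7, 2e7, 4e7, 5e7)
  k_true <- 8e-8
  clean <- data.frame(molecules = mols,
                      survival_fraction = exp(-k_true * mols))
  fit <- fit_kill_rate(clean, n_boot = 50)
  expect_equal(fit$k, k_true, tolerance = 1e-12)
  expect_equal(fit$n, 4)

  doubled <- transform(clean, molecules = molecules * 2)
  expect_equal(fit_kill_rate(doubled, n_boot = 50)$k, k_true / 2,
               tolerance = 1e-12)

  flat <- data.frame(molecules = mols, survival_fraction = 1)
  expect_error(fit_kill_rate(flat), "degenerate")
  expect_error(fit_kill_rate(clean[1:2, ]), "at least 3")
})
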