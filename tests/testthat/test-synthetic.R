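test_that("generation is deterministic in the seed", {
  cfg <- synthetic_config(seed = 71)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(tibble::as_tibble(a$panel), tibble::as_tibble(b$panel))
  expect_identical(unclass(a$weights), unclass(b$weights))
  ca <- generate_covariates(cfg)
  cb <- generate_covariates(cfg)
  expect_identical(ca$covariates, cb$covariates)

  c2 <- generate_panel(synthetic_config(seed = 72))
  expect_false(identical(tibble::as_tibble(a$panel),
                         tibble::as_tibble(c2$panel)))
})

test_that("generated artifacts pass panel validation and sizes", {
  cfg <- synthetic_config(seed = 73)
  sim <- generate_panel(cfg)
  expect_s3_class(sim$panel, "indicator_panel")
  expect_equal(nrow(sim$region_map), 31)
  expect_equal(unname(table(sim$region_map$region)[c("Eastern", "Central",
                                                     "Western")]),
               c(11, 8, 12), ignore_attr = TRUE)
  expect_equal(dim(sim$weights), c(31, 31))
  expect_true(all(rowSums(sim$weights) > 0))
  # some cells deleted, none below two observations per series
  counts <- tibble::as_tibble(sim$panel) |>
    dplyr::count(unit, indicator)
  expect_true(all(counts$n >= 2))
  expect_lt(nrow(sim$panel), 31 * 13 * 24)
  # imputation restores the full grid
  full <- impute_linear(sim$panel)
  expect_equal(nrow(full), 31 * 13 * 24)
})

test_that("without noise or spillover the structure is purely systematic", {
  cfg <- synthetic_config(seed = 74, rho = 0, noise_sd = 1e-12,
                          measurement_sd = 1e-12, missing_frac = 0)
  sim <- generate_panel(cfg)
  scored <- score_subsystems(sim$panel)
  tbl <- ccd_panel(scored$scores) |>
    dplyr::left_join(sim$region_map, by = "unit")
  spread <- tbl |>
    dplyr::group_by(region, year) |>
    dplyr::summarise(spread = max(D) - min(D), .groups = "drop")
  # within a region-year all units share the same latent level (up to
  # floating-point amplification through normalization)
  expect_lt(max(spread$spread), 1e-4)
})

test_that("latent trends produce rising scores with the configured growth", {
  cfg <- synthetic_config(seed = 75)
  sim <- generate_panel(cfg)
  scored <- score_subsystems(impute_linear(sim$panel))
  nat <- scored$scores |>
    dplyr::group_by(year) |>
    dplyr::summarise(EEC = mean(U_EEC), RPH = mean(U_RPH))
  expect_gt(nat$EEC[13], nat$EEC[1])
  expect_gt(nat$RPH[13], nat$RPH[1])
  # environment index grows faster than the health index, as configured
  expect_gt((nat$EEC[13] - nat$EEC[1]) / nat$EEC[1],
            (nat$RPH[13] - nat$RPH[1]) / nat$RPH[1])
})

test_that("covariates generated with zero coefficients are uninformative", {
  zs <- sapply(76:78, function(s) {
    cfg <- synthetic_config(seed = s,
                            tobit_beta = c(lnPGDP = 0, lnUR = 0, lnOPEN = 0,
                                           lnEL = 0, lnGHE = 0),
                            tobit_alpha = 0.55)
    gen <- generate_covariates(cfg)
    fit <- re_tobit(gen$ccd$D,
                    cbind(1, as.matrix(gen$covariates[names(cfg$tobit_beta)])),
                    gen$covariates$unit)
    fit$coefficients[-1] / fit$se[-1]
  })
  # fitted slopes are centered on zero: no |z| blowups, mean near zero
  expect_true(all(abs(zs) < 4))
  expect_lt(abs(mean(zs)), 1)
})

test_that("conditioning covariates on a CCD panel reproduces it exactly", {
  cfg <- synthetic_config(seed = 77)
  sim <- generate_panel(cfg)
  tbl <- ccd_panel(score_subsystems(impute_linear(sim$panel))$scores)
  gen <- generate_covariates(cfg, ccd_truth = tbl)
  expect_equal(nrow(gen$covariates), 31 * 13)
  # the configured linear relation holds exactly by construction
  beta <- cfg$tobit_beta
  X <- as.matrix(gen$covariates[names(beta)])
  resid <- gen$ccd$D - (gen$truth$alpha + drop(X %*% beta))
  # residual = u_i + e_it: small, with the configured scale
  expect_lt(sd(resid), 3 * sqrt(cfg$sigma_u^2 + cfg$sigma_e^2))
  expect_equal(gen$ccd$D, tbl$D[match(paste(gen$ccd$unit, gen$ccd$year),
                                      paste(tbl$unit, tbl$year))])
})
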