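test_that("zero-variance mixed fit reproduces the IRLS GLM estimates", {
  for (seed in 1:3) {
    pt <- simulate_glmm_pairs(seed = seed, sd_area = 0.5, sd_plot = 0.5)
    fit0 <- fit_glmm(pt, "sim", "resistance", coding = "proportion",
                     variance_structure = "zero")
    d <- fit0$data
    g <- glm(cbind(c, S - c) ~ iso_z * lle_combo, data = d, family = binomial)
    expect_equal(unname(fit0$fit$beta), unname(coef(g)), tolerance = 1e-6)
  }
})

test_that("single-factor binary model matches the Gauss-Hermite oracle", {
  withr::with_seed(31, {
    n_grp <- 40
    per <- 12
    group <- rep(seq_len(n_grp), each = per)
    u <- rnorm(n_grp, 0, 0.8)
    y <- rbinom(n_grp * per, 1, plogis(-0.4 + u[group]))
  })
  lfit <- lme4::glmer(y ~ 1 + (1 | group),
                      data = data.frame(y = y, group = factor(group)),
                      family = binomial, nAGQ = 25)
  oracle <- gh_oracle_fit(y, group)
  expect_equal(unname(lme4::fixef(lfit)[1]), oracle$intercept, tolerance = 1e-3)
  expect_equal(sqrt(unname(lme4::VarCorr(lfit)$group[1, 1])), oracle$sd,
               tolerance = 1e-3)
})

test_that("overdispersion is found in beta-binomial data and never in binary models", {
  # strongly overdispersed: latent per-observation noise
  pt_od <- simulate_glmm_pairs(seed = 7, plots_per_area = 8, sd_obs = 0.8)
  fit_od <- suppressWarnings(
    fit_glmm(pt_od, "sim", "resistance", coding = "proportion", olre = "off")
  )
  od <- overdispersion_check(fit_od)
  expect_gt(od$ratio, 1.3)
  expect_true(od$add_olre)

  # the auto policy adds the observation-level effect and the conditional
  # Pearson ratio moves towards one
  fit_auto <- suppressWarnings(
    fit_glmm(pt_od, "sim", "resistance", coding = "proportion", olre = "auto")
  )
  expect_true(fit_auto$olre_added)
  ratio_after <- corrscape:::pearson_dispersion(fit_auto$fit)$ratio
  expect_lt(abs(ratio_after - 1), abs(od$ratio - 1))

  # binary models never receive the observation-level effect
  fit_bin <- suppressWarnings(
    fit_glmm(pt_od, "sim", "resistance", coding = "binary", olre = "auto")
  )
  expect_false(fit_bin$olre_added)
  expect_true(is.na(overdispersion_check(fit_bin)$ratio))
})

test_that("equidispersed binomial data usually pass the dispersion test", {
  hits <- 0L
  for (seed in 1:10) {
    pt <- simulate_glmm_pairs(seed = 100 + seed, sd_obs = 0)
    fit <- suppressWarnings(
      fit_glmm(pt, "sim", "resistance", coding = "proportion", olre = "off")
    )
    od <- overdispersion_check(fit)
    if (!od$add_olre) hits <- hits + 1L
    expect_lt(abs(od$ratio - 1), 0.6)
  }
  expect_gte(hits, 8L) # nominal 5% false-trigger rate
})

test_that("fits are invariant to row order and plot relabelling", {
  pt <- simulate_glmm_pairs(seed = 12)
  f1 <- suppressWarnings(fit_glmm(pt, "sim", "resistance", olre = "off"))
  perm <- withr::with_seed(1, sample(nrow(pt)))
  pt2 <- pt[perm, ]
  f2 <- suppressWarnings(fit_glmm(pt2, "sim", "resistance", olre = "off"))
  expect_equal(lme4::fixef(f1$fit), lme4::fixef(f2$fit), tolerance = 1e-6)

  pt3 <- pt |>
    dplyr::mutate(plot_a = paste0("zz_", plot_a), plot_b = paste0("zz_", plot_b))
  f3 <- suppressWarnings(fit_glmm(pt3, "sim", "resistance", olre = "off"))
  expect_equal(lme4::fixef(f1$fit), lme4::fixef(f3$fit), tolerance = 1e-6)
})

test_that("the z-transform stored with a fit describes its included rows", {
  run <- cached_run(1)
  fit <- suppressWarnings(fit_glmm(run$pair_table, "all", "resistance"))
  included <- run$pair_table |>
    dplyr::filter(species_set == "all", !is.na(J), connected)
  expect_equal(fit$z_center, mean(included$resistance_ohm))
  expect_equal(fit$z_scale, sd(included$resistance_ohm))
  expect_equal(mean(fit$data$iso_z), 0, tolerance = 1e-12)
})

test_that("bootstrap term test is deterministic given a seed and calibrated in p", {
  pt <- simulate_glmm_pairs(seed = 3, beta = c(0.3, -1.2, 0.2, -0.1, 0.4, -0.3))
  fit <- suppressWarnings(fit_glmm(pt, "sim", "resistance", olre = "off"))
  b1 <- bootstrap_term_test(fit, B = 99, seed = 42)
  b2 <- bootstrap_term_test(fit, B = 99, seed = 42)
  expect_identical(b1$p_boot, b2$p_boot)
  expect_gt(b1$p_boot, 0)
  expect_lte(b1$p_boot, 1)
  # a strong true effect should be detected at small B
  expect_lte(b1$p_boot, 0.05)
})

test_that("cumulative-residual statistic is zero with perfectly fitted data", {
  d <- tibble::tibble(
    area = rep(1:2, each = 10),
    iso_z = rnorm(20),
    lle_combo = factor(rep("margin-margin", 20)),
    c = 10L, S = 20L, y_bin = 1L
  )
  fake <- structure(list(data = d, coding = "proportion"), class = "cs_glmm")
  lc <- linearity_check(fake, B = 50, seed = 1)
  expect_equal(lc$statistic, 0)
  expect_equal(lc$p, 1)
})

test_that("cumulative-residual check flags a strongly quadratic predictor", {
  withr::with_seed(9, {
    n <- 400
    iso <- rnorm(n)
    S <- rpois(n, 25) + 5
    eta <- 0.3 - 1.2 * iso^2 # quadratic truth, linear model
    c_ <- rbinom(n, S, plogis(eta))
    d <- tibble::tibble(
      area = rep(1:8, length.out = n), iso_z = iso,
      lle_combo = factor(rep("margin-margin", n)),
      c = c_, S = S, y_bin = as.integer(c_ > 0)
    )
  })
  fake <- structure(list(data = d, coding = "proportion"), class = "cs_glmm")
  lc <- linearity_check(fake, B = 200, seed = 2)
  expect_lt(lc$p, 0.05)
})

test_that("tidy and glance expose coefficients and variance components", {
  pt <- simulate_glmm_pairs(seed = 21)
  fit <- suppressWarnings(fit_glmm(pt, "sim", "resistance", olre = "off"))
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_named(td, c("term", "estimate", "std.error", "statistic"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, fit$n_obs)
  expect_true(all(c("var_area", "var_plot_a", "var_plot_b") %in% names(gl)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_model_summaries(list(fit), f)
  expect_true(file.exists(f))
  expect_gt(nrow(readr::read_csv(f, show_col_types = FALSE)), 6)
})
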