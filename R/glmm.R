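#' Fit the binomial-logit mixed model for one species set and isolation measure
#'
#' The model behind every row block of the results tables: response = Jaccard
#' similarity of a plot pair (proportion coding: `c` shared species of `S`
#' union species as binomial trials; binary coding: any shared species
#' yes/no), fixed effects = z-scored isolation measure, LLE-type combination
#' (baseline margin-margin) and their interaction, crossed random intercepts
#' for study area and for the first and second plot of the pair, and — for
#' proportion models that show significant overdispersion — an
#' observation-level random intercept. Fitting is by Laplace-approximate
#' maximum likelihood via [lme4::glmer()].
#'
#' Rows enter the model only if the species set's Jaccard is defined
#' (`S > 0`) and the pair is connected on the resistance raster; the same
#' rows are used for both isolation measures so their slopes are comparable.
#' The z-transform is computed on the included rows and its parameters are
#' stored for data-scale predictions.
#'
#' @param pair_table Output of [build_pair_table()].
#' @param species_set Species set name (see [build_pair_table()]).
#' @param measure `"resistance"` or `"euclidean"`.
#' @param coding `"auto"` (default, via [code_response()]), `"proportion"` or
#'   `"binary"`.
#' @param olre Observation-level random effect policy: `"auto"` adds it to
#'   proportion models whose Pearson dispersion is significantly above 1
#'   (chi-squared test at `alpha = 0.05`); `"on"`/`"off"` force it. Binary
#'   models never receive it.
#' @param zero_threshold Passed to [code_response()] for `coding = "auto"`.
#' @param min_rows Minimum number of usable rows.
#' @param variance_structure `"estimate"` (default) or `"zero"`, which fixes
#'   all random-effect variances at zero (penalised IRLS at theta = 0); the
#'   degenerate limit equals an ordinary binomial GLM and is used for
#'   diagnostics.
#' @return A `cs_glmm` object; see [tidy.cs_glmm()], [simple_slopes()],
#'   [predict_jaccard()].
#' @export
fit_glmm <- function(pair_table, species_set, measure = c("resistance", "euclidean"),
                     coding = c("auto", "proportion", "binary"),
                     olre = c("auto", "on", "off"),
                     zero_threshold = 0.5, min_rows = 30,
                     variance_structure = c("estimate", "zero")) {
  measure <- match.arg(measure)
  coding <- match.arg(coding)
  olre <- match.arg(olre)
  variance_structure <- match.arg(variance_structure)

  rows <- pair_table |>
    filter(.data$species_set == !!species_set, !is.na(.data$J), .data$connected)
  if (nrow(rows) < min_rows) {
    abort(sprintf("species set '%s': only %d usable pairs (need >= %d)",
                  species_set, nrow(rows), min_rows))
  }
  if (coding == "auto") coding <- code_response(rows, species_set, zero_threshold)

  iso_raw <- if (measure == "resistance") rows$resistance_ohm else rows$euclid_m
  iso_z <- z_transform(iso_raw)
  d <- rows |>
    mutate(
      iso_z = as.numeric(iso_z),
      lle_combo = droplevels(.data$lle_combo),
      obs = factor(seq_len(nrow(rows))),
      y_bin = as.integer(.data$J > 0)
    )

  resp <- if (coding == "proportion") "cbind(c, S - c)" else "y_bin"
  fix <- if (nlevels(d$lle_combo) > 1) "iso_z * lle_combo" else "iso_z"
  re <- "(1 | area) + (1 | plot_a) + (1 | plot_b)"
  form <- as.formula(paste(resp, "~", fix, "+", re))

  if (variance_structure == "zero") {
    fit0 <- glmm_theta_zero(form, d)
    return(new_cs_glmm(fit0, d, species_set, measure, coding, FALSE,
                       NA_real_, NA_real_, iso_z, theta_zero = TRUE))
  }

  fit <- glmer_quiet(form, d)
  olre_added <- FALSE
  ratio <- NA_real_
  ratio_p <- NA_real_
  if (coding == "proportion") {
    od <- pearson_dispersion(fit)
    ratio <- od$ratio
    ratio_p <- od$p
    if (olre == "on" || (olre == "auto" && od$p < 0.05)) {
      form2 <- as.formula(paste(resp, "~", fix, "+", re, "+ (1 | obs)"))
      fit <- glmer_quiet(form2, d)
      olre_added <- TRUE
    }
  }
  new_cs_glmm(fit, d, species_set, measure, coding, olre_added,
              ratio, ratio_p, iso_z)
}

glmer_quiet <- function(formula, data, nagq = 1) {
  withCallingHandlers(
    lme4::glmer(formula, data = data, family = binomial, nAGQ = nagq,
                control = lme4::glmerControl(check.conv.singular = "ignore")),
    message = function(m) invokeRestart("muffleMessage")
  )
}

# the deviance function returned by lme4's modular interface resolves a few
# unexported lme4 helpers through the caller's scope; bind them into its
# environment so it can be evaluated from inside this package
patch_devfun_scope <- function(devfun) {
  e <- environment(devfun)
  for (nm in c("GHrule", "pwrssUpdate", "GQdk")) {
    if (!exists(nm, envir = e, inherits = FALSE) &&
        exists(nm, envir = asNamespace("lme4"))) {
      assign(nm, get(nm, envir = asNamespace("lme4")), envir = e)
    }
  }
  devfun
}

# penalised IRLS with all random-effect variances fixed at zero: evaluate the
# profiled (nAGQ = 0) deviance function at theta = 0 and read off the fixed
# effects, which then coincide with the ordinary GLM estimates
glmm_theta_zero <- function(formula, data) {
  gf <- lme4::glFormula(formula, data = data, family = binomial,
                        control = lme4::glmerControl(check.conv.singular = "ignore"))
  devfun <- patch_devfun_scope(do.call(lme4::mkGlmerDevfun, gf))
  k <- length(environment(devfun)$pp$theta)
  dev <- devfun(rep(0, k))
  rho <- environment(devfun)
  beta <- rho$pp$beta(1)
  names(beta) <- colnames(gf$X)
  list(beta = beta, deviance = dev)
}

new_cs_glmm <- function(fit, data, species_set, measure, coding, olre_added,
                        ratio, ratio_p, iso_z, theta_zero = FALSE) {
  conv <- if (theta_zero) TRUE else length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  structure(
    list(
      fit = fit,
      data = data,
      species_set = species_set,
      measure = measure,
      coding = coding,
      olre_added = olre_added,
      pearson_ratio = ratio,
      pearson_p = ratio_p,
      z_center = attr(iso_z, "center"),
      z_scale = attr(iso_z, "scale"),
      n_obs = nrow(data),
      n_plots = length(unique(c(data$plot_a, data$plot_b))),
      n_groups = length(unique(data$area)),
      theta_zero = theta_zero,
      converged = conv
    ),
    class = "cs_glmm"
  )
}

#' @export
print.cs_glmm <- function(x, ...) {
  cat(sprintf(
    "<cs_glmm> %s ~ %s distance | %s coding%s | N = %d pairs, n = %d plots, g = %d areas\n",
    x$species_set, x$measure, x$coding,
    if (x$olre_added) " + OLRE" else "", x$n_obs, x$n_plots, x$n_groups
  ))
  if (x$theta_zero) {
    cat("  (random-effect variances fixed at zero)\n")
    print(round(x$fit$beta, 4))
  } else {
    print(round(lme4::fixef(x$fit), 4))
  }
  invisible(x)
}

# fixed effects and covariance regardless of backend
glmm_fixef <- function(object) {
  if (object$theta_zero) object$fit$beta else lme4::fixef(object$fit)
}

glmm_vcov <- function(object) {
  if (object$theta_zero) {
    abort("fixed-effect covariance is not available for the zero-variance fit")
  }
  as.matrix(vcov(object$fit))
}

#' Pearson overdispersion check for a proportion-coded model
#'
#' Ratio of the summed squared Pearson residuals to the residual degrees of
#' freedom (observations minus fixed-effect and variance parameters), with a
#' chi-squared test of the sum against the residual df. A significant ratio
#' above one triggers the observation-level random effect in
#' [fit_glmm()]; binary models are never tested (a Bernoulli response
#' cannot be overdispersed).
#'
#' @param object A `cs_glmm` with proportion coding.
#' @return One-row tibble `ratio`, `p`, `df`, `add_olre`.
#' @export
overdispersion_check <- function(object) {
  stopifnot(inherits(object, "cs_glmm"))
  if (object$coding == "binary") {
    return(tibble(ratio = NA_real_, p = NA_real_, df = NA_real_,
                  add_olre = FALSE))
  }
  od <- pearson_dispersion(object$fit)
  tibble(ratio = od$ratio, p = od$p, df = od$df, add_olre = od$p < 0.05)
}

pearson_dispersion <- function(fit) {
  rp <- residuals(fit, type = "pearson")
  n_var <- length(lme4::getME(fit, "theta"))
  df <- length(rp) - length(lme4::fixef(fit)) - n_var
  stat <- sum(rp^2)
  list(ratio = stat / df, p = pchisq(stat, df, lower.tail = FALSE), df = df)
}

#' Parametric-bootstrap test of the isolation main effect
#'
#' Simulates `B` response sets from the fitted null model (the model without
#' the isolation measure and its interaction with the LLE-type factor; a main
#' effect cannot be dropped below its interaction), refits null and full
#' model to each, and compares the observed likelihood-ratio statistic with
#' the bootstrap distribution: `p = (1 + #\{LRT* >= LRT_obs\}) / (B + 1)`.
#' Null simulations redraw the random effects, i.e. the bootstrap is
#' unconditional.
#'
#' For speed all likelihood-ratio statistics — observed and bootstrap — are
#' computed on the PIRLS-profiled (`nAGQ = 0`) deviance scale, with the
#' variance parameters re-optimised for every replicate; the observed and
#' simulated statistics are therefore exactly comparable.
#'
#' @param object A converged `cs_glmm`.
#' @param B Number of bootstrap replications.
#' @param seed Integer seed.
#' @return One-row tibble `species_set`, `measure`, `lrt`, `p_boot`, `B`,
#'   `n_failed`.
#' @export
bootstrap_term_test <- function(object, B = 999, seed = 1) {
  stopifnot(inherits(object, "cs_glmm"), !object$theta_zero)
  d <- object$data
  resp <- if (object$coding == "proportion") "cbind(c, S - c)" else "y_bin"
  fix_full <- if (nlevels(d$lle_combo) > 1) "iso_z * lle_combo" else "iso_z"
  fix_null <- if (nlevels(d$lle_combo) > 1) "lle_combo" else "1"
  re <- "(1 | area) + (1 | plot_a) + (1 | plot_b)"
  if (object$olre_added) re <- paste(re, "+ (1 | obs)")
  f_full <- as.formula(paste(resp, "~", fix_full, "+", re))
  f_null <- as.formula(paste(resp, "~", fix_null, "+", re))

  ctrl <- lme4::glmerControl(calc.derivs = FALSE, check.conv.singular = "ignore")
  mkdev <- function(f) {
    gf <- lme4::glFormula(f, data = d, family = binomial, control = ctrl)
    patch_devfun_scope(do.call(lme4::mkGlmerDevfun, gf))
  }
  dev_full <- mkdev(f_full)
  dev_null <- mkdev(f_null)
  k_full <- length(environment(dev_full)$pp$theta)
  k_null <- length(environment(dev_null)$pp$theta)

  opt_dev <- function(devfun, k, start) {
    o <- minqa::bobyqa(pmax(start, 0.01), devfun, lower = rep(0, k),
                       control = list(rhobeg = 0.2, rhoend = 2e-3))
    list(dev = o$fval, theta = o$par, ok = o$ierr == 0)
  }
  o_full <- opt_dev(dev_full, k_full, rep(0.5, k_full))
  o_null <- opt_dev(dev_null, k_null, rep(0.5, k_null))
  lrt_obs <- o_null$dev - o_full$dev

  # null model fitted through glmer (nAGQ = 0) purely to simulate responses
  null_fit <- withCallingHandlers(
    lme4::glmer(f_null, data = d, family = binomial, nAGQ = 0, control = ctrl),
    message = function(m) invokeRestart("muffleMessage")
  )

  rho_f <- environment(dev_full)
  rho_n <- environment(dev_null)
  lrt_star <- rep(NA_real_, B)
  n_failed <- 0L
  withr::with_seed(seed, {
    sims <- simulate(null_fit, nsim = B)
    for (b in seq_len(B)) {
      yb <- sims[[b]]
      ynew <- if (object$coding == "proportion") yb[, 1] / d$S else as.numeric(yb)
      rho_f$resp$setResp(ynew)
      rho_n$resp$setResp(ynew)
      of <- opt_dev(dev_full, k_full, o_full$theta)
      on <- opt_dev(dev_null, k_null, o_null$theta)
      if (!of$ok || !on$ok) n_failed <- n_failed + 1L
      lrt_star[b] <- on$dev - of$dev
    }
  })
  if (n_failed > 0.05 * B) {
    warn(sprintf("bootstrap_term_test: %d of %d replicates did not converge",
                 n_failed, B))
  }
  p <- (1 + sum(lrt_star >= lrt_obs, na.rm = TRUE)) / (B + 1)
  tibble(species_set = object$species_set, measure = object$measure,
         lrt = lrt_obs, p_boot = p, B = B, n_failed = n_failed)
}

#' Cumulative-residual linearity check
#'
#' A simplified goodness-of-link check for the linearity of the isolation
#' effect on the logit scale. Because cumulative-residual software does not
#' accept mixed models, the check refits the model as a fixed-effect GLM with
#' study area as an additional factor, orders the Pearson residuals by the
#' isolation predictor, and takes the supremum of the absolute cumulative
#' residual process (normalised by sqrt(n)). The null distribution is
#' obtained by a wild bootstrap with Rademacher weights on the residuals.
#'
#' @param object A `cs_glmm`.
#' @param B Number of wild-bootstrap resamples.
#' @param seed Integer seed.
#' @return One-row tibble `statistic`, `p`, `B`.
#' @export
linearity_check <- function(object, B = 1000, seed = 1) {
  stopifnot(inherits(object, "cs_glmm"))
  d <- object$data
  resp <- if (object$coding == "proportion") "cbind(c, S - c)" else "y_bin"
  fix <- if (nlevels(d$lle_combo) > 1) "iso_z * lle_combo" else "iso_z"
  form <- as.formula(paste(resp, "~", fix, "+ factor(area)"))
  g <- glm(form, data = d, family = binomial)
  r <- residuals(g, type = "pearson")
  ord <- order(d$iso_z)
  r <- r[ord]
  n <- length(r)
  stat <- max(abs(cumsum(r))) / sqrt(n)
  stat_star <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      w <- sample(c(-1, 1), n, replace = TRUE)
      max(abs(cumsum(w * r))) / sqrt(n)
    }, numeric(1))
  })
  tibble(statistic = stat, p = mean(stat_star >= stat), B = B)
}
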