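#' Maximum and minimum degrees of freedom for slope t-tests
#'
#' Degrees of freedom are ambiguous in mixed models, so slope tests are run
#' under two bracketing variants: `df_max = N - p - g - 1` with `N` the
#' number of pairs, and `df_min = n - p - g - 1` with `n` the number of
#' plots; `p` is the number of fixed-effect parameters and `g` the number of
#' study areas. The conservative `df_min` p-value is the headline one.
#'
#' @param N Number of observations (plot pairs).
#' @param n Number of plots.
#' @param p Number of fixed-effect parameters.
#' @param g Number of grouping levels of the study-area random factor.
#' @return One-row tibble `df_max`, `df_min`.
#' @export
#' @examples
#' dof(N = 132, n = 49, p = 6, g = 8) # 117 and 34
dof <- function(N, n, p, g) {
  stopifnot(N > 0, n > 0, p > 0, g > 0)
  df_max <- N - p - g - 1
  df_min <- n - p - g - 1
  if (df_max <= 0 || df_min <= 0) {
    abort(sprintf("non-positive degrees of freedom (df_max = %d, df_min = %d)",
                  df_max, df_min))
  }
  tibble(df_max = df_max, df_min = df_min)
}

#' Two-tailed t-test of a regression slope
#'
#' @param b Slope estimate.
#' @param se Its standard error (> 0).
#' @param df Degrees of freedom.
#' @return Tibble `t`, `p` (vectorised over the inputs).
#' @export
#' @examples
#' slope_t_test(-0.439, 0.190, df = 34)
slope_t_test <- function(b, se, df) {
  if (any(se <= 0)) abort("standard errors must be > 0")
  t <- b / se
  tibble(t = t, p = 2 * pt(-abs(t), df))
}

#' Standard error of a main-plus-interaction slope
#'
#' `sqrt(se_main^2 + 2 cov + se_int^2)`: the delta-method standard error of
#' the sum of a main effect and an interaction coefficient, given their
#' standard errors and covariance.
#'
#' @param se_main,se_int Standard errors of the two coefficients.
#' @param cov Their covariance.
#' @return Numeric standard error (vectorised).
#' @export
#' @examples
#' interaction_slope_se(0.2, 0.3, cov = 0) # sqrt(0.13)
interaction_slope_se <- function(se_main, se_int, cov = 0) {
  v <- se_main^2 + 2 * cov + se_int^2
  if (any(v <= 0)) abort("non-positive slope variance")
  sqrt(v)
}

#' Simple slopes of the isolation measure per LLE-type combination
#'
#' The margin-margin slope is the main effect of the isolation measure with
#' its own standard error. For the other combinations the slope is main
#' effect plus the respective interaction, with standard error
#' `sqrt(se_main^2 + 2 cov(main, int) + se_int^2)` taken from the fitted
#' model's fixed-effect covariance matrix. Each slope is t-tested under both
#' df variants of [dof()].
#'
#' @param object A `cs_glmm` from [fit_glmm()].
#' @return A `cs_slopes` tibble: `species_set`, `measure`, `lle_combo`, `b`,
#'   `se`, `t`, `df_max`, `df_min`, `p_max`, `p_min`.
#' @export
simple_slopes <- function(object) {
  stopifnot(inherits(object, "cs_glmm"))
  b <- glmm_fixef(object)
  V <- glmm_vcov(object)
  iso <- "iso_z"
  if (!iso %in% names(b)) abort("fit has no isolation main effect")
  combos <- levels(object$data$lle_combo)
  p_fixed <- length(b)
  df <- dof(object$n_obs, object$n_plots, p_fixed, object$n_groups)

  rows <- purrr::map(combos, function(cmb) {
    if (cmb == combos[1]) {
      slope <- b[[iso]]
      se <- sqrt(V[iso, iso])
    } else {
      int <- paste0(iso, ":lle_combo", cmb)
      if (!int %in% names(b)) return(NULL)
      slope <- b[[iso]] + b[[int]]
      se <- interaction_slope_se(sqrt(V[iso, iso]), sqrt(V[int, int]),
                                 cov = V[iso, int])
    }
    tt_max <- slope_t_test(slope, se, df$df_max)
    tt_min <- slope_t_test(slope, se, df$df_min)
    tibble(
      species_set = object$species_set, measure = object$measure,
      lle_combo = cmb, b = slope, se = se, t = tt_max$t,
      df_max = df$df_max, df_min = df$df_min,
      p_max = tt_max$p, p_min = tt_min$p
    )
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("cs_slopes", class(out))
  out
}

#' Z-test for the difference between two slopes
#'
#' Compares the resistance-distance slope `b1` with the Euclidean-distance
#' slope `b2` of the same species set and LLE combination:
#' `Z = (b1 - b2) / sqrt(se1^2 + se2^2)`, with a two-tailed standard-normal
#' p-value. Swapping the measures negates `delta` and `Z` and leaves `p`
#' unchanged.
#'
#' @param b1,se1 Slope and standard error of the resistance-distance model.
#' @param b2,se2 Slope and standard error of the Euclidean-distance model.
#' @return Tibble `delta`, `se_delta`, `z`, `p` (vectorised).
#' @export
#' @examples
#' delta_test(b1 = -1.149, se1 = 0.229, b2 = -0.439, se2 = 0.190)
delta_test <- function(b1, se1, b2, se2) {
  if (any(se1 <= 0) || any(se2 <= 0)) abort("standard errors must be > 0")
  delta <- b1 - b2
  se_delta <- sqrt(se1^2 + se2^2)
  z <- delta / se_delta
  tibble(delta = delta, se_delta = se_delta, z = z, p = 2 * pnorm(-abs(z)))
}

#' Slope comparison table across species sets
#'
#' Fits both isolation measures for each requested species set, computes the
#' simple slopes per LLE-type combination with their conservative t-tests,
#' and the Z-test of the slope difference (resistance minus Euclidean) —
#' one row per species set and combination, the layout of the study's main
#' results table. Optionally adds parametric-bootstrap p-values for the two
#' isolation main effects.
#'
#' @param pair_table Output of [build_pair_table()].
#' @param species_sets Character vector of species sets; defaults to all sets
#'   in the table.
#' @param B Bootstrap replications for the main-effect test; `0` skips it.
#' @param seed Seed for the bootstrap.
#' @param ... Passed on to [fit_glmm()].
#' @return A `cs_table1` tibble; failed species sets are dropped with a
#'   message.
#' @export
compare_isolation_models <- function(pair_table, species_sets = NULL,
                                     B = 0, seed = 1, ...) {
  if (is.null(species_sets)) species_sets <- unique(pair_table$species_set)
  fits <- list()
  rows <- purrr::imap(setNames(species_sets, species_sets), function(ss, nm) {
    fr <- try_fit(pair_table, ss, "resistance", ...)
    fe <- try_fit(pair_table, ss, "euclidean", ...)
    if (is.null(fr) || is.null(fe)) {
      inform(sprintf("species set '%s' skipped (model not fittable)", ss))
      return(NULL)
    }
    fits[[ss]] <<- list(resistance = fr, euclidean = fe)
    sr <- simple_slopes(fr)
    se_ <- simple_slopes(fe)
    joined <- left_join(
      rename(as_tibble(se_)[, c("species_set", "lle_combo", "b", "se", "p_min")],
             b_euclid = "b", se_euclid = "se", p_euclid = "p_min"),
      rename(as_tibble(sr)[, c("lle_combo", "b", "se", "p_min")],
             b_resist = "b", se_resist = "se", p_resist = "p_min"),
      by = "lle_combo"
    )
    dt <- delta_test(joined$b_resist, joined$se_resist,
                     joined$b_euclid, joined$se_euclid)
    out <- dplyr::bind_cols(joined, dt)
    if (B > 0) {
      out$p_boot_euclid <- bootstrap_term_test(fe, B = B, seed = child_seed(seed, 1))$p_boot
      out$p_boot_resist <- bootstrap_term_test(fr, B = B, seed = child_seed(seed, 2))$p_boot
    }
    out
  })
  out <- purrr::list_rbind(rows)
  attr(out, "fits") <- fits
  class(out) <- c("cs_table1", class(out))
  out
}

try_fit <- function(pair_table, ss, measure, ...) {
  tryCatch(fit_glmm(pair_table, ss, measure, ...), error = function(e) NULL)
}

#' @method autoplot cs_slopes
#' @export
autoplot.cs_slopes <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lle_combo, y = .data$b)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$b - 1.96 * .data$se,
                                          ymax = .data$b + 1.96 * .data$se)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "slope on logit scale (z-scored isolation)",
                  title = paste(df$species_set[1], "-", df$measure[1])) +
    ggplot2::theme_minimal()
}

#' @method autoplot cs_table1
#' @export
autoplot.cs_table1 <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(cols = c("b_euclid", "b_resist"),
                        names_to = "measure", values_to = "b") |>
    mutate(
      se = ifelse(.data$measure == "b_euclid", .data$se_euclid, .data$se_resist),
      measure = ifelse(.data$measure == "b_euclid", "Euclidean", "resistance")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lle_combo, y = .data$b,
                                   colour = .data$measure)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$b - 1.96 * .data$se,
                   ymax = .data$b + 1.96 * .data$se),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~species_set) +
    ggplot2::labs(x = NULL, y = "isolation slope (logit scale)") +
    ggplot2::theme_minimal()
}
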