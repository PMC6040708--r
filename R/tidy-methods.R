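#' Tidy the fixed effects of a fitted corridor model
#'
#' @param x A `cs_glmm`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic` (Wald z).
#' @method tidy cs_glmm
#' @export
tidy.cs_glmm <- function(x, ...) {
  b <- glmm_fixef(x)
  if (x$theta_zero) {
    return(tibble(term = names(b), estimate = unname(b),
                  std.error = NA_real_, statistic = NA_real_))
  }
  V <- glmm_vcov(x)
  se <- sqrt(diag(V))
  tibble(term = names(b), estimate = unname(b), std.error = unname(se),
         statistic = unname(b / se))
}

#' One-line summary of a fitted corridor model
#'
#' @param x A `cs_glmm`.
#' @param ... Unused.
#' @return One-row tibble with sample sizes, coding, random-effect variances,
#'   overdispersion ratio, log-likelihood and convergence flag.
#' @method glance cs_glmm
#' @export
glance.cs_glmm <- function(x, ...) {
  if (x$theta_zero) {
    return(tibble(
      species_set = x$species_set, measure = x$measure, coding = x$coding,
      n_obs = x$n_obs, n_plots = x$n_plots, n_groups = x$n_groups,
      olre = FALSE, var_area = 0, var_plot_a = 0, var_plot_b = 0,
      var_obs = 0, pearson_ratio = NA_real_, logLik = NA_real_,
      converged = TRUE
    ))
  }
  vc <- lme4::VarCorr(x$fit)
  getv <- function(nm) if (nm %in% names(vc)) unname(vc[[nm]][1, 1]) else 0
  tibble(
    species_set = x$species_set, measure = x$measure, coding = x$coding,
    n_obs = x$n_obs, n_plots = x$n_plots, n_groups = x$n_groups,
    olre = x$olre_added,
    var_area = getv("area"), var_plot_a = getv("plot_a"),
    var_plot_b = getv("plot_b"), var_obs = getv("obs"),
    pearson_ratio = x$pearson_ratio,
    logLik = as.numeric(logLik(x$fit)),
    converged = x$converged
  )
}

#' Export a model summary as a variance-component CSV
#'
#' Writes the fixed-effect estimates and random-effect variances of a set of
#' fits in long form (`species_set`, `measure`, `term`, `estimate`,
#' `std.error`, plus variance rows), mirroring a supplementary model-output
#' table.
#'
#' @param fits List of `cs_glmm` objects.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_model_summaries <- function(fits, path) {
  rows <- purrr::map(fits, function(f) {
    fx <- tidy(f) |>
      mutate(species_set = f$species_set, measure = f$measure, kind = "fixed")
    g <- glance(f)
    vr <- tibble(
      term = c("var:area", "var:plot_a", "var:plot_b", "var:obs"),
      estimate = c(g$var_area, g$var_plot_a, g$var_plot_b, g$var_obs),
      std.error = NA_real_, statistic = NA_real_,
      species_set = f$species_set, measure = f$measure, kind = "variance"
    )
    bind_rows(fx, vr)
  })
  readr::write_csv(purrr::list_rbind(rows), path)
  invisible(path)
}
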