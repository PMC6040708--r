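#' Predicted Jaccard similarity at a data-scale isolation value
#'
#' Population-level prediction from a fitted model: the isolation value is
#' z-scored with the transform stored in the fit, the fixed-effect linear
#' predictor is evaluated for the requested LLE-type combination with random
#' effects at zero, and mapped through the inverse logit.
#'
#' @param object A `cs_glmm`.
#' @param iso_value Isolation value(s) on the data scale (ohm or metres,
#'   matching the fit's measure). Values outside the observed range trigger a
#'   warning but are still computed.
#' @param combo LLE-type combination (default the margin-margin baseline).
#' @return Numeric vector of predicted Jaccard similarities in \[0, 1\].
#' @export
predict_jaccard <- function(object, iso_value, combo = "margin-margin") {
  stopifnot(inherits(object, "cs_glmm"))
  b <- glmm_fixef(object)
  z <- (iso_value - object$z_center) / object$z_scale
  obs_range <- range(object$data$iso_z)
  if (any(z < obs_range[1] - 1e-9 | z > obs_range[2] + 1e-9)) {
    warn("iso_value outside the observed isolation range; extrapolating")
  }
  eta <- b[["(Intercept)"]] + b[["iso_z"]] * z
  if (combo != levels(object$data$lle_combo)[1]) {
    dummy <- paste0("lle_combo", combo)
    int <- paste0("iso_z:lle_combo", combo)
    if (!dummy %in% names(b)) {
      abort(sprintf("combination '%s' not present in the fit", combo))
    }
    eta <- eta + b[[dummy]] + if (int %in% names(b)) b[[int]] * z else 0
  }
  unname(plogis(eta))
}

#' Translate a Jaccard increase into a count of shared species
#'
#' Because `J = c / S`, an increase `delta_J` of the Jaccard similarity of a
#' pair with union richness `S` corresponds to `delta_c = delta_J * S`
#' additional shared species; the count is rounded to the nearest integer.
#'
#' @param delta_j Increase in Jaccard similarity, in \[-1, 1\].
#' @param mean_s Mean cumulative (union) species number of the pairs.
#' @return Integer vector of additional shared species.
#' @export
#' @examples
#' delta_species(0.23, 36) # 8
delta_species <- function(delta_j, mean_s) {
  if (any(abs(delta_j) > 1)) abort("`delta_j` must lie in [-1, 1]")
  if (any(mean_s <= 0)) abort("`mean_s` must be > 0")
  as.integer(round(delta_j * mean_s))
}

#' Predicted similarity gains from maximum to minimum isolation
#'
#' For every species set with fits for both measures, evaluates the predicted
#' Jaccard similarity at the observed minimum and maximum of each isolation
#' measure (over the margin-margin pairs entering the model, by default),
#' the increase from maximum to minimum, the difference in increase between
#' resistance and Euclidean distance, and its translation into additional
#' shared species given the mean union richness of the margin-margin pairs.
#'
#' @param table1 A `cs_table1` from [compare_isolation_models()] (its fitted
#'   models are reused), or a named list of `list(resistance =, euclidean =)`
#'   `cs_glmm` pairs.
#' @param only_stronger_resistance If `TRUE` (default), report only species
#'   sets whose resistance increase exceeds the Euclidean increase.
#' @param range_scope `"margin-margin"` (default) or `"all"`: which included
#'   rows define the isolation extremes and mean union richness.
#' @return A `cs_table2` tibble.
#' @export
table2_report <- function(table1, only_stronger_resistance = TRUE,
                          range_scope = c("margin-margin", "all")) {
  range_scope <- match.arg(range_scope)
  fits <- if (inherits(table1, "cs_table1")) attr(table1, "fits") else table1
  rows <- purrr::imap(fits, function(fl, ss) {
    fr <- fl$resistance
    fe <- fl$euclidean
    if (is.null(fr) || is.null(fe)) return(NULL)
    scope_rows <- function(fit) {
      d <- fit$data
      if (range_scope == "margin-margin") {
        dd <- filter(d, .data$lle_combo == "margin-margin")
        if (nrow(dd) > 0) d <- dd
      }
      d
    }
    pred_incr <- function(fit) {
      d <- scope_rows(fit)
      iso <- if (fit$measure == "resistance") d$resistance_ohm else d$euclid_m
      cmb <- levels(fit$data$lle_combo)[1] # margin-margin whenever present
      j_min <- predict_jaccard(fit, min(iso), combo = cmb)
      j_max <- predict_jaccard(fit, max(iso), combo = cmb)
      c(j_min = j_min, j_max = j_max, incr = j_min - j_max)
    }
    pe <- pred_incr(fe)
    pr <- pred_incr(fr)
    mean_s <- mean(scope_rows(fr)$S)
    delta_incr <- unname(pr["incr"] - pe["incr"])
    tibble(
      species_set = ss,
      j_euclid_min = unname(pe["j_min"]), j_euclid_max = unname(pe["j_max"]),
      incr_euclid = unname(pe["incr"]),
      j_resist_min = unname(pr["j_min"]), j_resist_max = unname(pr["j_max"]),
      incr_resist = unname(pr["incr"]),
      delta_incr = delta_incr,
      mean_s = mean_s,
      delta_spec = delta_species(delta_incr, mean_s)
    )
  })
  out <- purrr::list_rbind(rows)
  if (only_stronger_resistance && nrow(out) > 0) {
    out <- filter(out, .data$incr_resist > .data$incr_euclid)
  }
  class(out) <- c("cs_table2", class(out))
  out
}

#' @method autoplot cs_table2
#' @export
autoplot.cs_table2 <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(cols = c("incr_euclid", "incr_resist"),
                        names_to = "measure", values_to = "increase") |>
    mutate(measure = ifelse(.data$measure == "incr_euclid",
                            "Euclidean", "resistance"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species_set, y = .data$increase,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "predicted Jaccard increase (max -> min isolation)") +
    ggplot2::theme_minimal()
}
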