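# Shared fixtures and independent oracles. Everything is generated in code;
# heavyweight objects are cached per session.

cs_test_cache <- new.env(parent = emptyenv())

# desk-scale study conditions: same design as the full survey (8 areas,
# 5-8 plots, density gradient) on 500-m areas with proportionally scaled
# plot spacing and frame
scaled_landscape_config <- function(seed) {
  landscape_config(
    area_side_m = 500, n_areas = 8, min_plot_spacing_m = 50,
    buffer_m = 150, seed = seed
  )
}

cached_run <- function(seed = 1) {
  key <- paste0("run", seed)
  if (is.null(cs_test_cache[[key]])) {
    cs_test_cache[[key]] <- suppressMessages(
      run_pipeline(scaled_landscape_config(seed), community_config(seed = seed))
    )
  }
  cs_test_cache[[key]]
}

# ---- dense pseudo-inverse oracle for effective resistance -------------------

# independent route: R_ab = L+_aa + L+_bb - 2 L+_ab with a dense Moore-Penrose
# pseudo-inverse of the full Laplacian (component-restricted)
dense_resistance_oracle <- function(edges, n, a, b) {
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$from[k]
    j <- edges$to[k]
    g <- edges$conductance[k]
    L[i, j] <- L[i, j] - g
    L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g
    L[j, j] <- L[j, j] + g
  }
  Lp <- MASS::ginv(L)
  Lp[a, a] + Lp[b, b] - 2 * Lp[a, b]
}

# random connected graph with random positive conductances
random_connected_graph <- function(n, extra_edges = n) {
  # random spanning tree first, then extra random edges
  perm <- sample(n)
  tree <- tibble::tibble(
    from = perm[2:n],
    to = perm[sapply(seq_len(n - 1), function(i) sample.int(i, 1))],
    conductance = runif(n - 1, 0.1, 10)
  )
  ex <- tibble::tibble(
    from = sample.int(n, extra_edges, replace = TRUE),
    to = sample.int(n, extra_edges, replace = TRUE),
    conductance = runif(extra_edges, 0.1, 10)
  )
  ex <- ex[ex$from != ex$to, ]
  rbind(tree, ex)
}

# ---- Gauss-Hermite oracle for the 1-RE binary mixed model -------------------

# independent route for the intercept-only logistic model with one grouping
# factor: marginal log-likelihood by Gauss-Hermite quadrature, maximised over
# (intercept, log sd)
gh_oracle_fit <- function(y, group, n_nodes = 60) {
  gh <- function(n) { # Golub-Welsch via eigen of the Jacobi matrix
    i <- seq_len(n - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- sqrt(i / 2)
    J[cbind(i + 1, i)] <- sqrt(i / 2)
    e <- eigen(J, symmetric = TRUE)
    list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
  }
  q <- gh(n_nodes)
  negll <- function(par) {
    b0 <- par[1]
    sig <- exp(par[2])
    u <- sqrt(2) * sig * q$nodes # u ~ N(0, sig^2)
    ll <- 0
    for (g in unique(group)) {
      yg <- y[group == g]
      lik_u <- vapply(u, function(uu) {
        p <- plogis(b0 + uu)
        prod(p^yg * (1 - p)^(1 - yg))
      }, numeric(1))
      ll <- ll + log(sum(q$weights * lik_u) / sqrt(pi))
    }
    -ll
  }
  o <- optim(c(0, log(0.5)), negll, method = "Nelder-Mead",
             control = list(reltol = 1e-12, maxit = 2000))
  list(intercept = o$par[1], sd = exp(o$par[2]), negll = o$value)
}

# ---- synthetic pair tables for direct GLMM testing --------------------------

# builds a pair table whose response is simulated from the model that
# fit_glmm() fits, with the linear predictor applied to the exact z-scores
# the fitter will reconstruct, so `beta` is recovered on the fitted scale
simulate_glmm_pairs <- function(n_areas = 8, plots_per_area = 6,
                                pairs_per_area = NULL,
                                beta = c(0.3, -0.8, 0.2, -0.1, 0.3, -0.2),
                                sd_area = 0.4, sd_plot = 0.4, sd_obs = 0,
                                s_mean = 25, seed = 1) {
  withr::with_seed(seed, {
    plots <- purrr::list_rbind(purrr::map(seq_len(n_areas), function(a) {
      tibble::tibble(area = a, plot = sprintf("a%d_p%d", a, seq_len(plots_per_area)))
    }))
    pairs <- purrr::list_rbind(purrr::map(split(plots, plots$area), function(d) {
      pr <- t(combn(nrow(d), 2))
      out <- tibble::tibble(area = d$area[1],
                            plot_a = d$plot[pr[, 1]], plot_b = d$plot[pr[, 2]])
      if (!is.null(pairs_per_area) && nrow(out) > pairs_per_area) {
        out <- out[sample.int(nrow(out), pairs_per_area), ]
      }
      out
    }))
    n <- nrow(pairs)
    pairs$lle_combo <- factor(
      sample(c("margin-margin", "margin-ditch", "ditch-ditch"), n, replace = TRUE),
      levels = c("margin-margin", "margin-ditch", "ditch-ditch")
    )
    iso <- rexp(n, rate = 1 / 300) + 50 # data-scale isolation values
    z <- as.numeric(z_transform(iso)) # exactly what fit_glmm reconstructs
    X <- model.matrix(~ z * lle_combo, data = data.frame(z = z, lle_combo = pairs$lle_combo))
    u_area <- rnorm(n_areas, 0, sd_area)
    u_plot <- rnorm(nrow(plots), 0, sd_plot)
    names(u_plot) <- plots$plot
    eta <- as.numeric(X %*% beta) + u_area[pairs$area] +
      u_plot[pairs$plot_a] + u_plot[pairs$plot_b] + rnorm(n, 0, sd_obs)
    S <- rpois(n, s_mean) + 5
    c_ <- rbinom(n, S, plogis(eta))
    pairs |>
      dplyr::mutate(
        euclid_m = iso, resistance_ohm = iso, connected = TRUE,
        species_set = "sim", c = c_, S = S,
        J = c_ / S
      )
  })
}

# slope-difference (resistance minus Euclidean) for the margin-margin simple
# slopes of one species set; NA when either model cannot be fitted
mm_slope_delta <- function(pair_table, species_set) {
  fr <- tryCatch(suppressWarnings(fit_glmm(pair_table, species_set, "resistance")),
                 error = function(e) NULL)
  fe <- tryCatch(suppressWarnings(fit_glmm(pair_table, species_set, "euclidean")),
                 error = function(e) NULL)
  if (is.null(fr) || is.null(fe)) return(NA_real_)
  sr <- simple_slopes(fr)
  se <- simple_slopes(fe)
  br <- sr$b[sr$lle_combo == "margin-margin"]
  be <- se$b[se$lle_combo == "margin-margin"]
  if (length(br) != 1 || length(be) != 1) return(NA_real_)
  br - be
}
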