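# Derivative-of-Gaussian regression family for serial-dependence biases.
#
# Adjustment errors pooled over participants are regressed on nonlinear
# transforms of the orientation difference delta: each predictor is
# delta * exp(-delta^2 / (2 w^2)) for a kernel width w chosen by grid
# search (the width with the highest r^2). The model family spans an
# intercept-only model, one- and two-kernel models, and variants whose
# kernel amplitudes interact with the location condition; models are
# compared by BIC.

#' Derivative-of-Gaussian regression basis
#'
#' The raw (un-normalized) predictor used for fitting:
#' `delta * exp(-delta^2 / (2 width^2))`. Odd in `delta`, with extrema at
#' `delta = +/-width` of magnitude `width * exp(-1/2)`. Coefficients on
#' this basis are converted to peak biases in degrees by [peak_bias()].
#'
#' @param delta Orientation differences in degrees.
#' @param width Gaussian width (standard deviation) in degrees, > 0.
#' @return Numeric vector of basis values.
#' @export
dog_basis <- function(delta, width) {
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) || width <= 0)
    stop("dog_basis(): width must be a single positive number")
  delta * exp(-delta^2 / (2 * width^2))
}

#' Specify one model of the serial-dependence family
#'
#' Five models: `"d0"` (intercept only), `"d1"` (one kernel), `"d2"` (two
#' kernels of independent widths, capturing a combination of attractive and
#' repulsive components), `"d1xloc"` and `"d2xloc"` (kernel amplitudes
#' additionally interact with the location-condition dummy, random = 0).
#'
#' @param name One of `"d0"`, `"d1"`, `"d2"`, `"d1xloc"`, `"d2xloc"`.
#' @return An object of class `model_spec` with fields `name`,
#'   `n_components` and `location_interaction`.
#' @export
model_spec <- function(name = c("d0", "d1", "d2", "d1xloc", "d2xloc")) {
  name <- match.arg(name)
  structure(list(name = name,
                 n_components = switch(name, d0 = 0L, d1 = 1L, d1xloc = 1L,
                                       d2 = 2L, d2xloc = 2L),
                 location_interaction = grepl("xloc", name)),
            class = "model_spec")
}

#' Gaussian-likelihood BIC from a residual sum of squares
#'
#' `n * log(rss / n) + k * log(n)`: the Bayesian Information Criterion of a
#' Gaussian regression up to an additive constant shared by all models fit
#' to the same observations (irrelevant to BIC differences).
#'
#' @param rss Residual sum of squares, > 0.
#' @param n_obs Number of observations.
#' @param n_params Number of mean parameters (intercept + slopes).
#' @return The BIC value.
#' @export
bic_gaussian <- function(rss, n_obs, n_params) {
  if (!is.finite(rss) || rss <= 0)
    stop("bic_gaussian(): rss must be positive (zero rss gives -Inf)")
  if (n_obs <= n_params)
    stop("bic_gaussian(): need n_obs > n_params")
  n_obs * log(rss / n_obs) + n_params * log(n_obs)
}

#' Fit one serial-dependence model with width grid search
#'
#' Builds the design of the requested [model_spec()] for every candidate
#' kernel width (for two-component models, every ordered pair
#' `w2 >= w1 + min_width_separation` — the second, typically repulsive,
#' component lies at larger delta), fits ordinary least squares on the
#' pooled single-trial data, and returns the width assignment with the
#' highest r^2 (ties broken toward smaller `w1`, then smaller `w2`).
#' Interaction models add `basis * loc` product columns with the location
#' dummy coded random = 0, sharing each component's width across
#' conditions.
#'
#' Two-kernel designs need a minimum width separation: bases at adjacent
#' widths are almost collinear (their difference spans the derivative of
#' the basis with respect to width), so an unconstrained r^2 search can
#' return adjacent-width pairs with enormous opposite-signed coefficients
#' whose individual peak biases are meaningless even though their sum fits
#' well. The default separation of 15 degrees keeps the two components
#' identified while leaving the attraction-at-small-delta /
#' repulsion-at-large-delta geometry free.
#'
#' @param data A data frame with columns `delta` (degrees, in (-90, 90]),
#'   `error` (degrees) and, for interaction models, `loc` (0 = random,
#'   1 = fixed).
#' @param spec A `model_spec` or model name.
#' @param width_grid Candidate widths in degrees (default 10-80 in
#'   1-degree steps).
#' @param min_width_separation Minimum `w2 - w1` (degrees) between the two
#'   kernel widths of two-component models.
#' @return An object of class `dog_fit`: `spec`, `widths`, `coefficients`
#'   (term/estimate/se/t/p), `r_squared`, `rss`, `n_obs`, `n_params`,
#'   `bic`.
#' @export
fit_dog_model <- function(data, spec, width_grid = 10:80,
                          min_width_separation = 15) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (!inherits(spec, "model_spec")) stop("spec must be a model_spec")
  if (!all(c("delta", "error") %in% names(data)))
    stop("data must contain columns 'delta' and 'error'")
  keep <- is.finite(data$delta) & is.finite(data$error)
  if (spec$location_interaction) {
    if (!"loc" %in% names(data))
      stop("interaction models need a 'loc' column (0 = random, 1 = fixed)")
    keep <- keep & is.finite(data$loc)
  }
  d <- data[keep, , drop = FALSE]
  xp <- dog_crossprods(d$delta, d$error,
                       if (spec$location_interaction) d$loc else NULL,
                       width_grid)
  fit_dog_core(xp, spec, min_width_separation)
}

# Sufficient cross-products for every model of the family on one dataset:
# G over the columns [1, basis(w) for each w, loc * basis(w) for each w],
# X'y and scalar summaries. The interaction blocks are cross-products over
# the loc == 1 rows only, so the cost is ~1.5x the plain basis crossprod.
dog_crossprods <- function(delta, y, loc, width_grid) {
  if (length(width_grid) < 1 || any(width_grid <= 0))
    stop("width_grid must be a nonempty vector of positive widths")
  width_grid <- sort(unique(width_grid))
  n <- length(delta)
  m <- length(width_grid)
  B <- vapply(width_grid, function(w) dog_basis(delta, w), numeric(n))
  cols <- cbind(rep(1, n), B)
  G0 <- crossprod(cols)
  g0 <- drop(crossprod(cols, y))
  has_loc <- !is.null(loc)
  if (has_loc) {
    if (!all(loc %in% c(0, 1)))
      stop("loc must be a 0/1 dummy (random = 0, fixed = 1)")
    sel <- loc == 1
    colsL <- cols[sel, , drop = FALSE]
    GL <- crossprod(colsL)
    gL <- drop(crossprod(colsL, y[sel]))
    G <- matrix(0, 1 + 2 * m, 1 + 2 * m)
    G[1:(m + 1), 1:(m + 1)] <- G0
    G[1:(m + 1), (m + 2):(2 * m + 1)] <- GL[, -1]
    G[(m + 2):(2 * m + 1), 1:(m + 1)] <- t(GL[, -1])
    G[(m + 2):(2 * m + 1), (m + 2):(2 * m + 1)] <- GL[-1, -1]
    gy <- c(g0, gL[-1])
  } else {
    G <- G0
    gy <- g0
  }
  list(G = G, gy = gy, yy = sum(y^2), n = n, ybar = mean(y),
       tss = sum((y - mean(y))^2), width_grid = width_grid, m = m,
       has_loc = has_loc)
}

# Candidate search + OLS readout from precomputed cross-products.
fit_dog_core <- function(xp, spec, min_width_separation = 15) {
  if (is.character(spec)) spec <- model_spec(spec)
  n <- xp$n
  width_grid <- xp$width_grid
  m <- xp$m
  n_params <- 1L + spec$n_components * (1L + spec$location_interaction)
  if (n <= n_params)
    stop("fewer observations (", n, ") than parameters (", n_params, ")")
  if (spec$location_interaction && !xp$has_loc)
    stop("interaction models need a 'loc' column (0 = random, 1 = fixed)")
  tss <- xp$tss

  if (spec$n_components == 0L) {
    est <- xp$ybar
    se <- sqrt(tss / (n - 1)) / sqrt(n)
    tv <- if (se > 0) est / se else 0
    coefs <- data.frame(term = "(Intercept)", estimate = est, se = se,
                        t = tv, p = 2 * stats::pt(-abs(tv), n - 1),
                        stringsAsFactors = FALSE)
    return(new_dog_fit(spec, numeric(0), coefs, 0, tss, n, 1L))
  }

  G <- xp$G; gy <- xp$gy; yy <- xp$yy
  idx_for <- function(ws) {
    j <- match(ws, width_grid)
    idx <- c(1L, 1L + j)
    if (spec$location_interaction) idx <- c(idx, 1L + m + j)
    idx
  }
  rss_for <- function(idx) {
    b <- tryCatch(solve(G[idx, idx, drop = FALSE], gy[idx]),
                  error = function(e) NULL)
    if (is.null(b)) return(Inf)
    max(yy - sum(b * gy[idx]), 0)
  }

  if (spec$n_components == 1L) {
    cand <- lapply(width_grid, function(w) w)
  } else {
    cand <- list()
    k <- 0L
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (width_grid[j] - width_grid[i] < min_width_separation) next
      k <- k + 1L
      cand[[k]] <- c(width_grid[i], width_grid[j])
    }
    if (!length(cand))
      stop("width_grid spans less than min_width_separation; ",
           "no admissible width pair")
  }
  rss_all <- vapply(cand, function(ws) rss_for(idx_for(ws)), numeric(1))
  if (all(!is.finite(rss_all)))
    stop("all width assignments gave singular designs")
  best <- which.min(rss_all)  # first minimum: smaller w1, then smaller w2
  widths <- cand[[best]]
  idx <- idx_for(widths)

  XtX <- G[idx, idx, drop = FALSE]
  beta <- solve(XtX, gy[idx])
  rss <- max(yy - sum(beta * gy[idx]), 0)
  sigma2 <- rss / (n - length(idx))
  se <- sqrt(diag(solve(XtX)) * sigma2)
  terms <- c("(Intercept)", paste0("dog", seq_len(spec$n_components)))
  if (spec$location_interaction)
    terms <- c(terms, paste0("dog", seq_len(spec$n_components), ":loc"))
  tval <- ifelse(se > 0, beta / se, 0)
  coefs <- data.frame(term = terms, estimate = beta, se = se, t = tval,
                      p = 2 * stats::pt(-abs(tval), n - length(idx)),
                      stringsAsFactors = FALSE)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  names(widths) <- paste0("dog", seq_len(spec$n_components))
  new_dog_fit(spec, widths, coefs, r2, rss, n, length(idx))
}

new_dog_fit <- function(spec, widths, coefs, r2, rss, n, k) {
  rownames(coefs) <- NULL
  bic <- if (rss > 0) bic_gaussian(rss, n, k) else NA_real_
  structure(list(spec = spec, widths = widths, coefficients = coefs,
                 r_squared = r2, rss = rss, n_obs = n, n_params = k,
                 bic = bic),
            class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, ...) {
  cat(sprintf("DoG model '%s': n = %d, r^2 = %.4g, BIC = %.2f\n",
              x$spec$name, x$n_obs, x$r_squared, x$bic))
  if (length(x$widths))
    cat("  widths (deg):", paste(sprintf("%s = %g", names(x$widths), x$widths),
                                 collapse = ", "), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Compare fitted models by BIC
#'
#' BIC differences are reported on the conventional evidence scale with the
#' worst model at 0 and larger values indicating better models
#' (`delta_bic = max(BIC) - BIC`); differences of at least 2 count as
#' positive and at least 6 as strong evidence.
#'
#' @param fits A (preferably named) list of `dog_fit` objects fit to the
#'   same observations.
#' @return A `dog_comparison`: a data frame with one row per model
#'   (`model`, `widths`, `r_squared`, `n_params`, `bic`, `delta_bic`,
#'   `evidence_vs_worst`), with attribute `best_model` (smallest BIC,
#'   largest delta_bic).
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) stop("compare_models(): need at least 2 fits")
  if (!all(vapply(fits, inherits, logical(1), "dog_fit")))
    stop("compare_models(): all elements must be dog_fit objects")
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1)
    stop("compare_models(): fits use different numbers of observations; ",
         "BIC values are not comparable")
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$spec$name, character(1))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  delta_bic <- max(bic) - bic
  evidence <- ifelse(delta_bic >= 6, "strong",
                     ifelse(delta_bic >= 2, "positive", "weak"))
  tab <- data.frame(
    model = names(fits),
    widths = vapply(fits, function(f)
      paste(round(f$widths, 1), collapse = "/"), character(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    bic = bic, delta_bic = delta_bic, evidence_vs_worst = evidence,
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(tab, best_model = tab$model[which.min(bic)],
            class = c("dog_comparison", "data.frame"))
}

#' @export
print.dog_comparison <- function(x, ...) {
  cat("Model comparison (delta BIC: worst model = 0, larger = better)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat("best model:", attr(x, "best_model"), "\n")
  invisible(x)
}

#' Peak bias of a fitted kernel component
#'
#' Converts a regression coefficient on the raw [dog_basis()] into the
#' extremum of the fitted bias curve `b * dog_basis(delta, w)`:
#' the peak lies at `delta = width` and equals
#' `coefficient * width * exp(-1/2)` degrees. Positive peaks are attractive
#' under the package's sign convention, negative peaks repulsive.
#'
#' @param coefficient Fitted coefficient on the raw basis.
#' @param width Kernel width in degrees, > 0.
#' @return A list with `peak` (degrees of bias) and `location` (degrees of
#'   delta at which the extremum occurs).
#' @export
peak_bias <- function(coefficient, width) {
  if (!is.numeric(width) || any(width <= 0)) stop("peak_bias(): width must be positive")
  list(peak = coefficient * width * exp(-0.5), location = width)
}

#' Peak biases of every kernel component of a fit
#'
#' @param fit A `dog_fit`.
#' @return A data frame with one row per component: `term`, `width`,
#'   `peak`, `location`.
#' @export
peak_biases <- function(fit) {
  if (!inherits(fit, "dog_fit")) stop("fit must be a dog_fit")
  if (!length(fit$widths))
    return(data.frame(term = character(0), width = numeric(0),
                      peak = numeric(0), location = numeric(0)))
  terms <- names(fit$widths)
  b <- fit$coefficients$estimate[match(terms, fit$coefficients$term)]
  pk <- peak_bias(b, unname(fit$widths))
  data.frame(term = terms, width = unname(fit$widths),
             peak = pk$peak, location = pk$location,
             stringsAsFactors = FALSE)
}

#' z-test comparing one coefficient between two independent fits
#'
#' `z = (b_a - b_b) / sqrt(se_a^2 + se_b^2)` with a two-sided p-value from
#' the standard normal; used to contrast kernel amplitudes between
#' independently fitted data subsets (e.g. the similarity split).
#'
#' @param fit_a,fit_b `dog_fit` objects containing the term.
#' @param term Coefficient name, e.g. `"dog1"` or `"dog2"`.
#' @return A list with `z`, `p`, and the two estimates and standard errors.
#' @export
compare_coefficients <- function(fit_a, fit_b, term) {
  get <- function(f, who) {
    i <- match(term, f$coefficients$term)
    if (is.na(i)) stop("term '", term, "' not present in ", who)
    f$coefficients[i, c("estimate", "se")]
  }
  a <- get(fit_a, "fit_a"); b <- get(fit_b, "fit_b")
  z <- (a$estimate - b$estimate) / sqrt(a$se^2 + b$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       estimate_a = a$estimate, se_a = a$se,
       estimate_b = b$estimate, se_b = b$se)
}

#' Split trials by previous-probe/distractor similarity
#'
#' Partitions distractor-present trials into those where the previous probe
#' and the current distractor had similar orientations
#' (`|prev_probe_distractor_delta| < threshold`) and dissimilar ones
#' (`>= threshold`).
#'
#' @param trials Annotated trial table.
#' @param threshold Similarity threshold in degrees (default 45).
#' @return A list with data frames `similar` and `dissimilar`; trials
#'   without a defined `prev_probe_distractor_delta` are dropped.
#' @export
split_by_similarity <- function(trials, threshold = 45) {
  if (!"prev_probe_distractor_delta" %in% names(trials))
    stop("trials must be annotated (missing prev_probe_distractor_delta)")
  eligible <- trials[is.finite(trials$prev_probe_distractor_delta), , drop = FALSE]
  sim <- abs(eligible$prev_probe_distractor_delta) < threshold
  out <- list(similar = eligible[sim, , drop = FALSE],
              dissimilar = eligible[!sim, , drop = FALSE])
  if (any(vapply(out, nrow, integer(1)) == 0))
    warning("split_by_similarity(): one subset is empty")
  out
}

#' Moving-average bias curve for plotting
#'
#' Mean and SD of adjustment errors within a moving window over delta,
#' evaluated at integer-degree centers (delta space is 180-degree periodic,
#' so the window wraps across the +/-90 boundary). For display only: models
#' are fit to the unsmoothed single-trial data.
#'
#' @param delta Orientation differences in degrees, in (-90, 90].
#' @param errors Adjustment errors in degrees.
#' @param window Window width in degrees (odd; default 21, i.e. +/-10).
#' @return A data frame with columns `delta`, `mean`, `sd`, `n`; centers
#'   with no data are omitted.
#' @export
smooth_curve <- function(delta, errors, window = 21) {
  if (window < 1 || window %% 2 != 1) stop("window must be a positive odd width")
  keep <- is.finite(delta) & is.finite(errors)
  delta <- delta[keep]; errors <- errors[keep]
  half <- (window - 1) / 2
  centers <- seq(-89, 90)
  rows <- lapply(centers, function(ctr) {
    sel <- abs(wrap_diff(delta, ctr)) <= half
    if (!any(sel)) return(NULL)
    data.frame(delta = ctr, mean = mean(errors[sel]),
               sd = if (sum(sel) > 1) stats::sd(errors[sel]) else 0,
               n = sum(sel))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
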