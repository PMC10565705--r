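# Discrimination-task reaction-time analyses: attentional capture and the
# inverse-Gaussian mixed-effects regression.

#' Attentional capture effect per participant and location condition
#'
#' RT(distractor present) - RT(distractor absent) in ms, computed on
#' correct-response trials per participant within each location condition,
#' with a group summary (mean and normal-approximation 95% CI).
#'
#' @param trials Preprocessed trial table (correct responses are selected
#'   internally).
#' @return A list with `per_participant` (participant, location_condition,
#'   rt_present, rt_absent, capture) and `group` (location_condition, mean,
#'   se, lower, upper, n). Participants lacking a cell are omitted with a
#'   warning.
#' @export
capture_effect <- function(trials) {
  d <- trials[trials$discrimination_correct, , drop = FALSE]
  if (nrow(d) == 0) stop("capture_effect(): no correct-response trials")
  rows <- list(); dropped <- character(0)
  for (p in unique(d$participant_id)) for (lc in c("random", "fixed")) {
    sel <- d$participant_id == p & d$location_condition == lc
    pres <- d$discrimination_rt[sel & d$distractor_present]
    abs_ <- d$discrimination_rt[sel & !d$distractor_present]
    if (!length(pres) || !length(abs_)) {
      dropped <- c(dropped, paste0(p, "/", lc)); next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = p, location_condition = lc,
      rt_present = mean(pres), rt_absent = mean(abs_),
      capture = mean(pres) - mean(abs_), stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("capture_effect(): cells missing, omitted: ",
            paste(dropped, collapse = ", "))
  pp <- do.call(rbind, rows)
  grp <- do.call(rbind, lapply(c("random", "fixed"), function(lc) {
    x <- pp$capture[pp$location_condition == lc]
    se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    data.frame(location_condition = lc, mean = mean(x), se = se,
               lower = mean(x) - 1.96 * se, upper = mean(x) + 1.96 * se,
               n = length(x), stringsAsFactors = FALSE)
  }))
  list(per_participant = pp, group = grp)
}

# log-density of the inverse Gaussian with mean mu and shape lambda
ig_logdens <- function(y, mu, lambda) {
  0.5 * log(lambda / (2 * pi * y^3)) - lambda * (y - mu)^2 / (2 * mu^2 * y)
}

# Marginal negative log-likelihood of the inverse-Gaussian identity-link
# random-intercept model, evaluated on per-participant cell means by
# adaptive Gauss-Hermite quadrature. The cell-mean reduction is exact for
# the mean structure: the mu-dependent part of the IG log-likelihood of a
# cell's trials depends on the data only through the cell sum, and the mean
# of n iid IG(mu, lambda) variables is IG(mu, n*lambda).
igmm_nll <- function(par, ybar, w, X, id_index, gh) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  lambda <- exp(par[p + 1])
  tau <- exp(par[p + 2])
  eta <- drop(X %*% beta)
  total <- 0
  for (cells in id_index) {
    e <- eta[cells]; yb <- ybar[cells]; lam <- w[cells] * lambda
    logf <- function(u) {
      mu <- outer(e, u, "+")
      cs <- colSums(ig_logdens(yb, mu, lam))
      # large finite penalty keeps optimize()/quadrature NA-free when a
      # candidate random effect drives a cell mean non-positive
      cs[apply(mu <= 0, 2, any)] <- -1e12
      cs + stats::dnorm(u, 0, tau, log = TRUE)
    }
    opt <- stats::optimize(function(u) -logf(u),
                           interval = c(-8 * tau - 1, 8 * tau + 1))
    uhat <- opt$minimum
    h <- max(1e-3, 1e-4 * tau)
    d2 <- (logf(uhat + h) - 2 * logf(uhat) + logf(uhat - h)) / h^2
    s_post <- 1 / sqrt(max(-d2, 1e-10))
    nodes <- uhat + sqrt(2) * s_post * gh$x
    lg <- logf(nodes) + gh$x^2 + log(gh$w) + 0.5 * log(2) + log(s_post)
    mx <- max(lg)
    if (!is.finite(mx)) return(1e10)
    total <- total + mx + log(sum(exp(lg - mx)))
  }
  -total
}

#' Mixed-effects inverse-Gaussian regression of discrimination RT
#'
#' Fits RT (correct-response trials only) with an inverse-Gaussian response
#' distribution, identity link, fixed effects for the location condition
#' (binary, random = 0), distractor presence (binary, absent = 0) and their
#' interaction, and a participant-level random intercept, by maximum
#' likelihood with adaptive Gauss-Hermite quadrature over the random
#' effect. The likelihood is evaluated on per-participant condition-cell
#' means with trial counts as weights, an exact sufficient-statistic
#' reduction for this mean structure.
#'
#' With a single participant the random intercept is not identifiable and a
#' plain inverse-Gaussian GLM ([stats::glm()]) is fitted instead; the
#' `method` field records which route was taken.
#'
#' @param trials Preprocessed trial table.
#' @param nq Number of quadrature nodes.
#' @return An `rt_model` object: `coefficients` (term, estimate (ms), se,
#'   t, df, p, lower, upper 95% CI), `lambda` (IG shape),
#'   `ranef_sd` (random-intercept SD, ms), `n_obs`, `method`. Degrees of
#'   freedom are residual (`n_obs` - 4); CIs are estimate +/- 1.96 se.
#' @export
fit_rt_model <- function(trials, nq = 15) {
  d <- trials[trials$discrimination_correct, , drop = FALSE]
  if (nrow(d) < 8) stop("fit_rt_model(): too few correct-response trials")
  loc <- as.numeric(d$location_condition == "fixed")
  dis <- as.numeric(d$distractor_present)
  terms <- c("(Intercept)", "location", "distractor", "interaction")
  n_obs <- nrow(d)
  df <- n_obs - 4L

  finish <- function(est, se, lambda, tau, method) {
    tval <- est / se
    coefs <- data.frame(term = terms, estimate = est, se = se, t = tval,
                        df = df, p = 2 * stats::pt(-abs(tval), df),
                        lower = est - 1.96 * se, upper = est + 1.96 * se,
                        stringsAsFactors = FALSE)
    rownames(coefs) <- NULL
    structure(list(coefficients = coefs, lambda = lambda, ranef_sd = tau,
                   n_obs = n_obs, method = method), class = "rt_model")
  }

  ids <- unique(d$participant_id)
  if (length(ids) == 1L) {
    if (stats::var(d$discrimination_rt) == 0) {
      # fully degenerate: constant RT
      est <- c(mean(d$discrimination_rt), 0, 0, 0)
      return(finish(est, rep(NA_real_, 4), NA_real_, 0, "glm_degenerate"))
    }
    g <- stats::glm(d$discrimination_rt ~ loc * dis,
                    family = stats::inverse.gaussian(link = "identity"),
                    start = c(mean(d$discrimination_rt), 0, 0, 0))
    s <- summary(g)$coefficients
    return(finish(s[, 1], s[, 2], 1 / summary(g)$dispersion, 0, "glm_single_participant"))
  }

  key <- paste(d$participant_id, loc, dis, sep = "\r")
  first <- !duplicated(key)
  cells <- data.frame(id = d$participant_id[first], loc = loc[first],
                      dis = dis[first], stringsAsFactors = FALSE)
  cells$ybar <- as.numeric(tapply(d$discrimination_rt, key, mean)[key[first]])
  cells$n <- as.numeric(tapply(d$discrimination_rt, key, length)[key[first]])
  X <- cbind(1, cells$loc, cells$dis, cells$loc * cells$dis)
  id_index <- split(seq_len(nrow(cells)), cells$id)

  gh <- pracma::gaussHermite(nq)
  # starting values: cell-mean OLS for beta, moments for lambda and tau
  b0 <- stats::lm.fit(X, cells$ybar)$coefficients
  pm <- vapply(id_index, function(i) mean(cells$ybar[i]), numeric(1))
  tau0 <- max(stats::sd(pm), 1)
  lam0 <- mean(cells$ybar)^3 / max(stats::var(d$discrimination_rt), 1)
  start <- c(b0, log(lam0), log(tau0))
  fit <- stats::nlminb(start, igmm_nll, ybar = cells$ybar, w = cells$n,
                       X = X, id_index = id_index, gh = gh,
                       control = list(iter.max = 400, eval.max = 600))
  if (fit$convergence != 0 && !is.finite(fit$objective))
    stop("fit_rt_model(): optimizer failed to converge (code ",
         fit$convergence, "): ", fit$message)
  H <- stats::optimHess(fit$par, igmm_nll, ybar = cells$ybar, w = cells$n,
                        X = X, id_index = id_index, gh = gh)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 6, 6))
  se <- sqrt(pmax(diag(V)[1:4], 0))
  finish(fit$par[1:4], se, exp(fit$par[5]), exp(fit$par[6]),
         "agq_inverse_gaussian")
}

#' @export
print.rt_model <- function(x, ...) {
  cat(sprintf("Inverse-Gaussian RT mixed model (%s), n = %d\n",
              x$method, x$n_obs))
  print(x$coefficients, digits = 4)
  cat(sprintf("  random-intercept SD: %.2f ms, IG shape lambda: %.0f\n",
              x$ranef_sd, x$lambda))
  invisible(x)
}
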