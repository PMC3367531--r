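# Analytic rate surface: ln k(A->B) = ln k_max
#   - ln(1 + exp(+alpha_HB * dE_HB)) - ln(1 + exp(-alpha_c * dN_c)) + ln G(q)
# with dE_HB = E_HB^B - E_HB^A, dN_c = N_c^B - N_c^A and G a symmetric
# logistic factor in the shared-contact fraction q, normalized to G(1) = 1.
# With both sigmoid midpoints pinned at 0 the log-ratio factorizes exactly,
#   ln k_AB - ln k_BA = -alpha_HB * dE_HB + alpha_c * dN_c,
# so the family obeys detailed balance with equilibrium probabilities
#   P_X proportional to exp(-alpha_HB * E_HB^X + alpha_c * N_c^X).

#' Rate-surface parameters
#'
#' @param log_k_max Log of the plateau (maximum) rate.
#' @param alpha_HB Hydrogen-bond sensitivity (> 0, per reduced energy unit):
#'   jumps towards more hydrogen bonds (`dE_HB < 0`) are fast.
#' @param alpha_c Contact-count sensitivity (> 0, per contact): jumps towards
#'   more compact structures (`dN_c > 0`) are fast.
#' @param alpha_q,q_mid Common-contact factor steepness and midpoint;
#'   `G(q) = g_scale / (1 + exp(-alpha_q (q - q_mid)))` with `g_scale` fixed
#'   by `G(1) = 1`. `alpha_q = 0` disables the factor (`G == 1`).
#' @return A `rate_surface_params` list (with the implied `g_scale`).
#' @export
rate_surface_params <- function(log_k_max = 0, alpha_HB = 1, alpha_c = 1,
                                alpha_q = 0, q_mid = 0.5) {
  if (alpha_HB <= 0 || alpha_c <= 0)
    stop("alpha_HB and alpha_c must be positive", call. = FALSE)
  g_scale <- 1 + exp(-alpha_q * (1 - q_mid))
  structure(list(log_k_max = log_k_max, alpha_HB = alpha_HB,
                 alpha_c = alpha_c, alpha_q = alpha_q, q_mid = q_mid,
                 g_scale = g_scale),
            class = "rate_surface_params")
}

#' @export
print.rate_surface_params <- function(x, ...) {
  cat(sprintf(
    "rate surface: ln k_max = %.4g, alpha_HB = %.4g, alpha_c = %.4g, G(q): alpha_q = %.4g, q_mid = %.4g\n",
    x$log_k_max, x$alpha_HB, x$alpha_c, x$alpha_q, x$q_mid))
  invisible(x)
}

log_G <- function(q, params) {
  if (params$alpha_q == 0) return(rep(0, length(q)))
  log(params$g_scale) - log1p(exp(-params$alpha_q * (q - params$q_mid)))
}

#' Evaluate the analytic rate surface
#'
#' @param params A [rate_surface_params()].
#' @param dE_HB Hydrogen-bond energy difference `E_HB^B - E_HB^A`.
#' @param dN_c Contact-count difference `N_c^B - N_c^A`.
#' @param q Shared-contact fraction of the pair (symmetric).
#' @param log If `TRUE` return `ln k`.
#' @return Rate `k(A -> B)` (units of the mutation-rate prefactor).
#' @export
rate_surface <- function(params, dE_HB, dN_c, q = 1, log = FALSE) {
  lk <- params$log_k_max -
    log1p(exp(params$alpha_HB * dE_HB)) -
    log1p(exp(-params$alpha_c * dN_c)) +
    log_G(q, params)
  if (log) lk else exp(lk)
}

check_observations <- function(obs) {
  need <- c("dE_HB", "dN_c", "q", "k_AB", "k_BA")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("observations missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  obs
}

# one row per direction: forward rows as-is, reverse rows with flipped signs
stack_directions <- function(obs) {
  data.frame(
    dE_HB = c(obs$dE_HB, -obs$dE_HB),
    dN_c = c(obs$dN_c, -obs$dN_c),
    q = c(obs$q, obs$q),
    k = c(obs$k_AB, obs$k_BA),
    se = if (all(c("se_AB", "se_BA") %in% names(obs)))
      c(obs$se_AB, obs$se_BA) else rep(NA_real_, 2 * nrow(obs)))
}

#' Fit the analytic rate surface to observed rates
#'
#' Weighted least squares on `ln k` of the midpoint-0 double-logistic family
#' (optionally with the common-contact factor), using both directions of
#' every pair. Initialized from the detailed-balance plane fit of the
#' log-ratios; weights are inverse relative variances `(k / se)^2` when
#' bootstrap errors are available.
#'
#' @param obs Data frame with columns `dE_HB`, `dN_c`, `q`, `k_AB`, `k_BA`
#'   (optionally `se_AB`, `se_BA`), one row per structure pair with the
#'   `A -> B` sign convention.
#' @param fit_q If `TRUE`, fit the common-contact factor jointly; requires
#'   spread in `q`.
#' @param method `"balance"` (default) estimates the alphas from the paired
#'   log-ratios `ln k_AB - ln k_BA` -- for the midpoint-0 family this
#'   difference equals `-alpha_HB dE_HB + alpha_c dN_c` exactly, and the
#'   within-pair differencing cancels every pair-level nuisance factor
#'   (including `G(q)` and the specific identity of the differing contacts)
#'   -- then fits the plateau and `G(q)` to the rate magnitudes with the
#'   alphas held fixed. `"joint"` fits everything at once to the magnitudes;
#'   it is statistically less robust when pair-level scatter is large.
#' @return List with `params` ([rate_surface_params()]), `se` (parameter
#'   standard errors; from the plane fit for the alphas under
#'   `"balance"`, from the Hessian of the weighted least-squares objective
#'   otherwise), `residual_rms` on `ln k`, `n_used`, `convergence`.
#' @export
fit_rate_surface <- function(obs, fit_q = FALSE,
                             method = c("balance", "joint")) {
  method <- match.arg(method)
  obs <- check_observations(obs)
  if (nrow(obs) < 3L) stop("need at least 3 pairs (6 directed rates)", call. = FALSE)
  d <- stack_directions(obs)
  keep <- d$k > 0
  d <- d[keep, , drop = FALSE]
  for (ax in c("dE_HB", "dN_c")) {
    if (all(d[[ax]] >= 0) || all(d[[ax]] <= 0))
      stop("observations span only one sign of ", ax,
           "; the sigmoid along that axis is unidentifiable", call. = FALSE)
  }
  d$y <- log(d$k)
  # inverse-variance weights on the log scale, var(ln k) ~ (se/k)^2, with a
  # variance floor so saturated estimates (se -> 0) cannot dominate the fit
  w <- if (all(is.finite(d$se))) 1 / ((d$se / d$k)^2 + 0.01) else rep(1, nrow(d))
  if (fit_q && diff(range(d$q)) < 0.05)
    stop("insufficient spread in q to fit the common-contact factor",
         call. = FALSE)
  model <- function(p) {
    lk <- p[1] - log1p(exp(p[2] * d$dE_HB)) - log1p(exp(-p[3] * d$dN_c))
    if (fit_q) lk <- lk + log1p(exp(-p[4] * (1 - p[5]))) -
        log1p(exp(-p[4] * (d$q - p[5])))
    lk
  }
  pl <- plane_fit_log_ratio(obs)
  a_hb0 <- max(abs(pl$c_HB), 1e-3)
  a_c0 <- max(abs(pl$c_c), 1e-3)

  fixed <- if (method == "balance") c(ahb = a_hb0, ac = a_c0) else NULL
  obj <- function(pfree) {
    p <- if (is.null(fixed)) pfree else
      c(pfree[1], fixed[["ahb"]], fixed[["ac"]], pfree[-1])
    sum(w * (d$y - model(p))^2)
  }
  p0 <- if (is.null(fixed))
    c(lkm = max(d$y), ahb = a_hb0, ac = a_c0) else c(lkm = max(d$y))
  lower <- if (is.null(fixed)) c(-Inf, 1e-4, 1e-4) else -Inf
  upper <- if (is.null(fixed)) c(Inf, Inf, Inf) else Inf
  if (fit_q) {
    grid <- expand.grid(aq = c(2, 5, 10, 25),
                        qm = unname(quantile(d$q, c(0.25, 0.5, 0.75))))
    vals <- apply(grid, 1L, function(g) obj(c(p0, g[["aq"]], g[["qm"]])))
    g <- grid[which.min(vals), ]
    p0 <- c(p0, aq = unname(g$aq), qm = unname(g$qm))
    lower <- c(lower, 0, 0)
    upper <- c(upper, 200, 1)
  }
  opt <- optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 500), hessian = TRUE)
  cf_free <- opt$par
  cf <- if (is.null(fixed)) cf_free else
    c(lkm = cf_free[[1]], ahb = fixed[["ahb"]], ac = fixed[["ac"]],
      if (fit_q) c(aq = cf_free[[2]], qm = cf_free[[3]]))
  params <- rate_surface_params(
    log_k_max = cf[["lkm"]], alpha_HB = cf[["ahb"]], alpha_c = cf[["ac"]],
    alpha_q = if (fit_q) cf[["aq"]] else 0,
    q_mid = if (fit_q) cf[["qm"]] else 0.5)
  # cov = 2 sigma2 H^{-1} for a weighted SSR objective (H ~ 2 J'WJ)
  sigma2 <- opt$value / max(1, nrow(d) - length(cf_free))
  se_free <- tryCatch(sqrt(pmax(diag(2 * sigma2 * solve(opt$hessian)), 0)),
                      error = function(e) rep(NA_real_, length(cf_free)))
  names(se_free) <- names(p0)
  se <- if (is.null(fixed)) se_free else
    c(lkm = se_free[["lkm"]],
      ahb = unname(pl$se["dE_HB"]), ac = unname(pl$se["dN_c"]),
      if (fit_q) c(aq = se_free[["aq"]], qm = se_free[["qm"]]))
  pfull <- function() {
    if (is.null(fixed)) cf_free else
      c(cf_free[1], fixed[["ahb"]], fixed[["ac"]], cf_free[-1])
  }
  list(params = params, se = se, method = method,
       residual_rms = sqrt(mean((d$y - model(pfull()))^2)),
       n_used = nrow(d), convergence = opt$convergence)
}

#' Fit the common-contact factor given base surface parameters
#'
#' Fits `G(q) = g_scale / (1 + exp(-alpha_q (q - q_mid)))`, normalized so
#' `G(1) = 1`, to the residual `ln k - ln k_base(dE_HB, dN_c)`. Because `q`
#' is symmetric under swapping the pair, `G` cancels exactly in every rate
#' ratio and cannot disturb detailed balance.
#'
#' @param obs Observations as in [fit_rate_surface()].
#' @param base_params A [rate_surface_params()] describing the q-independent
#'   part.
#' @return List with updated `params`, `se`, `fixed` (`TRUE` when `q` spread
#'   was insufficient and `G` was fixed to 1 with a warning).
#' @export
fit_common_contact_factor <- function(obs, base_params) {
  obs <- check_observations(obs)
  d <- stack_directions(obs)
  d <- d[d$k > 0, , drop = FALSE]
  if (diff(range(d$q)) < 0.05) {
    warning("insufficient spread in q; common-contact factor fixed to 1")
    return(list(params = base_params, se = c(aq = NA, qm = NA), fixed = TRUE))
  }
  base <- rate_surface_params(base_params$log_k_max, base_params$alpha_HB,
                              base_params$alpha_c, alpha_q = 0)
  d$y <- log(d$k) - rate_surface(base, d$dE_HB, d$dN_c, log = TRUE)
  model <- function(p) log1p(exp(-p[1] * (1 - p[2]))) -
    log1p(exp(-p[1] * (d$q - p[2])))
  obj <- function(p) sum((d$y - model(p))^2)
  grid <- expand.grid(aq = c(2, 5, 10, 25),
                      qm = quantile(d$q, c(0.25, 0.5, 0.75)))
  vals <- apply(grid, 1L, function(g) obj(c(g[["aq"]], g[["qm"]])))
  g <- grid[which.min(vals), ]
  opt <- optim(c(aq = g$aq, qm = g$qm), obj, method = "L-BFGS-B",
               lower = c(0, 0), upper = c(200, 1),
               control = list(maxit = 500), hessian = TRUE)
  cf <- opt$par
  params <- rate_surface_params(base_params$log_k_max, base_params$alpha_HB,
                                base_params$alpha_c,
                                alpha_q = cf[[1]], q_mid = cf[[2]])
  sigma2 <- opt$value / max(1, nrow(d) - 2L)
  se <- tryCatch(sqrt(pmax(diag(2 * sigma2 * solve(opt$hessian)), 0)),
                 error = function(e) c(NA_real_, NA_real_))
  names(se) <- c("aq", "qm")
  list(params = params, se = se, fixed = FALSE)
}

#' Detailed-balance plane fit of the rate log-ratios
#'
#' Least-squares fit of `ln k_AB - ln k_BA = c_HB * dE_HB + c_c * dN_c`
#' through the origin. Consistency with the fitted surface requires
#' `c_HB = -alpha_HB` and `c_c = +alpha_c`; on data generated exactly from
#' the midpoint-0 family the fit is exact with `R^2 = 1`.
#'
#' @param obs Observations as in [fit_rate_surface()]; pairs with a zero
#'   rate in either direction are excluded (with a message). When bootstrap
#'   errors are present the fit is weighted by the inverse variance of the
#'   log-ratio, `var = (se_AB/k_AB)^2 + (se_BA/k_BA)^2` (with a small
#'   variance floor); unweighted otherwise.
#' @return List with `c_HB`, `c_c`, `se` (named), `r_squared`, `n_used`.
#' @export
plane_fit_log_ratio <- function(obs) {
  obs <- check_observations(obs)
  keep <- obs$k_AB > 0 & obs$k_BA > 0
  if (any(!keep))
    message(sum(!keep), " pair(s) with a zero rate excluded from the plane fit")
  obs <- obs[keep, , drop = FALSE]
  if (!nrow(obs)) stop("no pairs with both rates positive", call. = FALSE)
  y <- log(obs$k_AB) - log(obs$k_BA)
  w <- if (all(c("se_AB", "se_BA") %in% names(obs)) &&
           all(is.finite(obs$se_AB)) && all(is.finite(obs$se_BA))) {
    1 / ((obs$se_AB / obs$k_AB)^2 + (obs$se_BA / obs$k_BA)^2 + 0.01)
  } else rep(1, nrow(obs))
  fit <- lm(y ~ 0 + dE_HB + dN_c, data = obs, weights = w)
  cf <- coef(fit)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum(y^2)  # no-intercept fit: R^2 about the origin
  list(c_HB = unname(cf["dE_HB"]), c_c = unname(cf["dN_c"]),
       se = sqrt(diag(vcov(fit))),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n_used = nrow(obs), fit = fit)
}

#' Total-rate ratios of measured pairs under fitted equilibrium probabilities
#'
#' For each measured pair, `R_AB / R_BA = (k_AB / k_BA) (P_A / P_B)` with the
#' equilibrium probabilities implied by the fitted surface parameters
#' (`P_A / P_B = exp(alpha_HB dE_HB - alpha_c dN_c)`). Under detailed balance
#' the two total rates are equal, so the distribution of this ratio over
#' pairs should be peaked at 1; its spread measures how far the measured
#' rates deviate from the analytic family.
#'
#' @param obs Observations as in [fit_rate_surface()].
#' @param params A [rate_surface_params()].
#' @return Numeric vector of ratios, one per pair with both rates positive.
#' @export
total_rate_ratios <- function(obs, params) {
  obs <- check_observations(obs)
  obs <- obs[obs$k_AB > 0 & obs$k_BA > 0, , drop = FALSE]
  (obs$k_AB / obs$k_BA) *
    exp(params$alpha_HB * obs$dE_HB - params$alpha_c * obs$dN_c)
}

#' Equilibrium probabilities of a structure set under the fitted family
#'
#' `P_X` proportional to `exp(-alpha_HB * E_HB^X + alpha_c * N_c^X)`,
#' normalized over the provided set. This closed form satisfies global
#' balance exactly for rates drawn from the fitted surface, and makes the
#' designability statement quantitative: probability grows with the number
#' of hydrogen bonds (more negative `E_HB`) and with compactness.
#'
#' @param structures List of [ss_structure()] objects.
#' @param params A [rate_surface_params()].
#' @return Named probability vector summing to 1.
#' @export
equilibrium_probabilities <- function(structures, params) {
  if (!length(structures)) stop("empty structure set", call. = FALSE)
  lw <- vapply(structures, function(x)
    -params$alpha_HB * x$e_hb + params$alpha_c * x$n_contacts, numeric(1))
  lw <- lw - max(lw)
  p <- exp(lw) / sum(exp(lw))
  names(p) <- vapply(structures, `[[`, character(1), "id")
  p
}
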