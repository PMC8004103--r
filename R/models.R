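# Models of promoter activity P as a function of summed enhancer activity S:
#   additive     P = alpha * S + beta
#   exponential  P = exp(alpha * S + beta)          (the synergistic model)
#   logistic     P = delta / (1 + exp(-(alpha * S + beta)))
#   logarithmic  P = alpha * log(S + s0) + beta     (negative control)
# Fitted by least squares (normal error model): bounded differential-
# evolution global search seeded with closed-form/heuristic starts, followed
# by local refinement. Exponents are clamped to +-50 during evaluation.

MODEL_NAMES <- c("additive", "exponential", "logistic", "logarithmic")

clamp_exp <- function(x) exp(pmin(pmax(x, -50), 50))

model_predict <- function(model, par, S, s0 = 1) {
  switch(model,
    additive = par[1] * S + par[2],
    exponential = clamp_exp(par[1] * S + par[2]),
    logistic = par[3] / (1 + clamp_exp(-(par[1] * S + par[2]))),
    logarithmic = par[1] * log(S + s0) + par[2],
    abort(sprintf("unknown model '%s'", model))
  )
}

model_k <- function(model) if (model == "logistic") 3L else 2L

# scale-aware optimizer bounds; exponent-scale models bound alpha so the
# exponent stays within the +-50 evaluation clamp
model_bounds <- function(model, S, P, s0 = 1) {
  smax <- max(abs(S), 1e-9)
  pmax_ <- max(abs(P), 1e-9)
  switch(model,
    additive = list(lower = c(-10 * pmax_ / smax, -10 * pmax_),
                    upper = c(10 * pmax_ / smax, 10 * pmax_)),
    exponential = list(lower = c(-50 / smax, -50), upper = c(50 / smax, 50)),
    logistic = list(lower = c(-50 / smax, -50, 1e-9),
                    upper = c(50 / smax, 50, 2 * pmax_)),
    logarithmic = {
      lmax <- max(abs(log(S + s0)), 1e-9)
      list(lower = c(-10 * pmax_ / lmax, -10 * pmax_),
           upper = c(10 * pmax_ / lmax, 10 * pmax_))
    }
  )
}

# closed-form / transformed-linear starting values, clipped into bounds
model_heuristic_start <- function(model, S, P, bounds, s0 = 1) {
  start <- switch(model,
    additive = unname(coef(lm(P ~ S)))[c(2, 1)],
    exponential = unname(coef(lm(log(pmax(P, 1e-9)) ~ S)))[c(2, 1)],
    logistic = {
      d0 <- 1.05 * max(P)
      y <- pmin(pmax(P / d0, 0.01), 0.99)
      ab <- unname(coef(lm(stats::qlogis(y) ~ S)))[c(2, 1)]
      c(ab, d0)
    },
    logarithmic = {
      L <- log(S + s0)
      unname(coef(lm(P ~ L)))[c(2, 1)]
    }
  )
  start[!is.finite(start)] <- 0
  pmin(pmax(start, bounds$lower), bounds$upper)
}

#' Closed-form least-squares fit of the additive model
#'
#' Ordinary least squares for P = alpha * S + beta; used to initialize the
#' global optimizer and as an equivalence oracle for it.
#'
#' @param S,P Numeric vectors of equal length >= 3; `S` non-constant.
#' @return List with `alpha`, `beta`, `rss`.
#' @examples
#' ols_additive(c(1, 2, 3), c(3, 5, 7))  # alpha 2, beta 1, rss 0
#' @export
ols_additive <- function(S, P) {
  if (length(S) != length(P) || length(S) < 3) {
    abort("S and P must have equal length >= 3")
  }
  if (length(unique(S)) == 1L) {
    abort("degenerate input: S is constant")
  }
  fit <- lm(P ~ S)
  list(alpha = unname(coef(fit))[2], beta = unname(coef(fit))[1],
       rss = sum(stats::residuals(fit)^2))
}

#' Fit one cooperation model by bounded global least squares
#'
#' Minimizes the residual sum of squares of the chosen model by a bounded
#' differential-evolution search (population 10 per parameter, 100
#' generations, seeded and deterministic) whose initial population includes
#' a closed-form or transformed-linear starting point, followed by local
#' refinement with `nlminb` from both the evolutionary optimum and the
#' heuristic start. Exponents are clamped to +-50 during evaluation.
#'
#' @param S Summed enhancer activity per time point.
#' @param P Promoter activity per time point (same length, 6 or 7 points in
#'   routine use; >= 4 required).
#' @param model One of `"additive"`, `"exponential"`, `"logistic"`,
#'   `"logarithmic"`.
#' @param bounds Optional list `lower`, `upper` overriding the scale-aware
#'   default bounds.
#' @param seed Integer seed for the evolutionary search.
#' @param s0 Offset of the logarithmic model (default 1).
#' @param itermax,np_factor Differential-evolution budget (generations and
#'   population size per parameter).
#' @return An object of class `encoop_model_fit`: list with `model`,
#'   `params` (`alpha`, `beta`, `delta`), `rss`, `n`, `k`, `bic`.
#' @examples
#' fit <- fit_cooperation_model(1:7, 2 * (1:7) + 1, "additive", seed = 1)
#' fit$params$alpha
#' @export
fit_cooperation_model <- function(S, P, model = MODEL_NAMES, bounds = NULL,
                                  seed = 1L, s0 = 1, itermax = 100,
                                  np_factor = 10) {
  model <- match.arg(model)
  if (length(S) != length(P) || length(S) < 4) {
    abort("S and P must have equal length >= 4")
  }
  if (!all(is.finite(S)) || !all(is.finite(P))) {
    abort("domain error: non-finite values in S or P")
  }
  if (length(unique(S)) == 1L) {
    abort("unfittable signal: S is constant")
  }
  if (model == "logarithmic" && any(S + s0 <= 0)) {
    abort(sprintf("domain error: S + %g must be > 0 for the logarithmic model",
                  s0))
  }
  if (is.null(bounds)) bounds <- model_bounds(model, S, P, s0)
  d <- length(bounds$lower)
  obj <- function(par) {
    r <- sum((P - model_predict(model, par, S, s0))^2)
    if (!is.finite(r)) 1e300 else r
  }

  set.seed(seed)
  np <- max(np_factor * d, 20L)
  pop <- matrix(runif(np * d, rep(bounds$lower, each = np),
                      rep(bounds$upper, each = np)), nrow = np)
  start <- model_heuristic_start(model, S, P, bounds, s0)
  pop[1, ] <- start
  de <- DEoptim::DEoptim(
    obj, lower = bounds$lower, upper = bounds$upper,
    control = DEoptim::DEoptim.control(NP = np, itermax = itermax, F = 0.8,
                                       CR = 0.9, trace = FALSE,
                                       initialpop = pop))
  cands <- list(de$optim$bestmem, start)
  best <- NULL
  for (p0 in cands) {
    ref <- tryCatch(
      nlminb(p0, obj, lower = bounds$lower, upper = bounds$upper),
      error = function(e) list(par = p0, objective = obj(p0)))
    if (is.null(best) || ref$objective < best$objective) best <- ref
  }
  par <- pmin(pmax(best$par, bounds$lower), bounds$upper)
  rss <- obj(par)
  n <- length(S)
  k <- model_k(model)
  structure(
    list(model = model,
         params = list(alpha = unname(par[1]), beta = unname(par[2]),
                       delta = if (model == "logistic") unname(par[3])
                               else NA_real_),
         rss = rss, n = n, k = k, s0 = s0,
         bic = compute_bic(rss, n, k)),
    class = "encoop_model_fit")
}

#' Bayesian information criterion for a least-squares fit
#'
#' `n * ln(max(rss, eps) / n) + (k + 1) * ln(n)`, counting the error
#' variance as one parameter (the `+ 1`); `eps = 1e-12` floors a zero RSS.
#' Constant offsets of the Gaussian likelihood cancel in relative BIC, so
#' this convention fixes them at zero.
#'
#' @param rss Residual sum of squares.
#' @param n Number of points (>= 3).
#' @param k_params Number of model parameters (2, or 3 for logistic).
#' @param eps RSS floor.
#' @return BIC value.
#' @examples
#' compute_bic(7, 7, 2)  # 3 * log(7)
#' @export
compute_bic <- function(rss, n, k_params, eps = 1e-12) {
  if (n < 3) abort("n must be >= 3")
  n * log(max(rss, eps) / n) + (k_params + 1) * log(n)
}

#' @export
print.encoop_model_fit <- function(x, ...) {
  cat(sprintf("<encoop_model_fit> %s: alpha=%.4g beta=%.4g%s rss=%.4g bic=%.4g (n=%d)\n",
              x$model, x$params$alpha, x$params$beta,
              if (!is.na(x$params$delta)) sprintf(" delta=%.4g", x$params$delta)
              else "",
              x$rss, x$bic, x$n))
  invisible(x)
}

#' @method tidy encoop_model_fit
#' @export
tidy.encoop_model_fit <- function(x, ...) {
  tibble(model = x$model,
         term = c("alpha", "beta", "delta"),
         estimate = c(x$params$alpha, x$params$beta, x$params$delta)) |>
    filter(!is.na(.data$estimate))
}

#' @method glance encoop_model_fit
#' @export
glance.encoop_model_fit <- function(x, ...) {
  tibble(model = x$model, rss = x$rss, bic = x$bic, n = x$n, k = x$k)
}
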