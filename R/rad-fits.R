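#' Least-squares rank-abundance distribution fit
#'
#' Fits one model family to a descending abundance vector by minimizing the
#' sum of squared errors on the *untransformed* abundances (matching
#' spreadsheet-style least squares on a rank-abundance plot; fitting in log
#' space would change both the optimum and the SSE-based model ranking).
#' Model forms over ranks `r = 1..S`:
#' \describe{
#'   \item{power}{\eqn{f(r) = a r^{-b}}}
#'   \item{exponential}{\eqn{f(r) = a e^{-k r}}}
#'   \item{lognormal (quantile form, default)}{\eqn{f(r) = \exp(\mu + \sigma
#'     \Phi^{-1}(1 - (r - 0.5)/S))}, the abundance at the standard-normal
#'     quantile of the rank's plotting position}
#'   \item{lognormal (gaussian-in-logrank form)}{\eqn{f(r) = a \exp(-(\ln r -
#'     \mu)^2 / (2\sigma^2))}}
#' }
#' Optimization is multi-start nonlinear least squares: a log-linear
#' regression seed plus perturbed restarts, each polished with BFGS and
#' Nelder-Mead; shape parameters are optimized on the log scale so they stay
#' positive. The returned SSE is never above the SSE of any start.
#'
#' @param y A [rank_abundance()] object or positive descending numeric
#'   vector (it is sorted if needed; zeros dropped; *not* renormalized, so
#'   fits on raw profiles recover the raw intercept).
#' @param model `"power"`, `"exponential"` or `"lognormal"`.
#' @param lognormal_form `"quantile"` (default) or `"gaussian_logrank"`.
#' @param n_starts Number of perturbed restarts around the seed (default 3).
#' @return A list of class `rad_fit`: `model`, `params` (named), `sse`,
#'   `converged`, `n_points`, `sample_id`.
#' @export
#' @examples
#' fit_rad(0.5 * (1:20)^-1, "power")  # recovers a = 0.5, b = 1
fit_rad <- function(y, model = c("power", "exponential", "lognormal"),
                    lognormal_form = c("quantile", "gaussian_logrank"),
                    n_starts = 3) {
  model <- match.arg(model)
  lognormal_form <- match.arg(lognormal_form)
  sample_id <- attr(y, "sample_id")
  y <- as.numeric(y)
  y <- y[y > 0]
  y <- sort(y, decreasing = TRUE)
  s <- length(y)
  n_par <- if (model == "lognormal" && lognormal_form == "gaussian_logrank")
    3L else 2L
  if (s < n_par + 1L)
    stopf("need at least %d nonzero ranks to fit a %d-parameter model, got %d",
          n_par + 1L, n_par, s)
  r <- seq_len(s)

  spec <- rad_model_spec(model, lognormal_form, r, s, y)
  sse_fun <- function(theta) {
    pred <- spec$predict(theta)
    sum((y - pred)^2)
  }
  starts <- lapply(spec$starts(n_starts), unname)
  best <- NULL
  for (st in starts) {
    fit1 <- tryCatch(
      stats::optim(st, sse_fun, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    par0 <- if (is.null(fit1)) st else fit1$par
    fit2 <- tryCatch(
      stats::optim(par0, sse_fun, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    cand <- Filter(Negate(is.null), list(fit2, fit1))
    if (length(cand) == 0) next
    cand <- cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best))
    return(structure(list(model = model, params = spec$unpack(starts[[1]]),
                          sse = NA_real_, converged = FALSE, n_points = s,
                          sample_id = sample_id), class = "rad_fit"))
  structure(list(model = model, params = spec$unpack(best$par),
                 sse = best$value, converged = best$convergence == 0,
                 n_points = s, sample_id = sample_id),
            class = "rad_fit")
}

# Prediction function, seed construction and parameter unpacking for each
# model family. theta holds unconstrained coordinates (log scale for the
# positive shape parameters).
rad_model_spec <- function(model, lognormal_form, r, s, y) {
  ly <- log(y)
  jitter_starts <- function(seed, n_starts, shape_idx) {
    fac <- c(1, 0.5, 2, 0.25, 4)[seq_len(max(1, n_starts))]
    lapply(fac, function(f) {
      st <- seed
      st[shape_idx] <- st[shape_idx] + log(f)
      st
    })
  }
  if (model == "power") {
    lr <- log(r)
    list(
      predict = function(th) exp(th[1] - exp(th[2]) * lr),
      starts = function(n) {
        cf <- stats::coef(stats::lm(ly ~ lr))
        b0 <- max(-cf[2], 1e-3)
        jitter_starts(c(cf[1], log(b0)), n, 2L)
      },
      unpack = function(th) c(a = exp(th[1]), b = exp(th[2])))
  } else if (model == "exponential") {
    list(
      predict = function(th) exp(th[1] - exp(th[2]) * r),
      starts = function(n) {
        cf <- stats::coef(stats::lm(ly ~ r))
        k0 <- max(-cf[2], 1e-4)
        jitter_starts(c(cf[1], log(k0)), n, 2L)
      },
      unpack = function(th) c(a = exp(th[1]), k = exp(th[2])))
  } else if (lognormal_form == "quantile") {
    z <- stats::qnorm(1 - (r - 0.5) / s)
    list(
      predict = function(th) exp(th[1] + exp(th[2]) * z),
      starts = function(n) {
        cf <- stats::coef(stats::lm(ly ~ z))
        sig0 <- max(cf[2], 1e-3)
        jitter_starts(c(cf[1], log(sig0)), n, 2L)
      },
      unpack = function(th) c(mu = th[1], sigma = exp(th[2])))
  } else {
    lr <- log(r)
    list(
      predict = function(th) {
        sig <- exp(th[3])
        exp(th[1] - (lr - th[2])^2 / (2 * sig^2))
      },
      starts = function(n) {
        cf <- stats::coef(stats::lm(ly ~ lr + I(lr^2)))
        if (is.na(cf[3]) || cf[3] >= 0) {
          seed <- c(max(ly), 0, 0)
        } else {
          sig0 <- sqrt(-1 / (2 * cf[3]))
          mu0 <- cf[2] * sig0^2
          la0 <- cf[1] + mu0^2 / (2 * sig0^2)
          seed <- c(la0, mu0, log(sig0))
        }
        jitter_starts(seed, n, 3L)
      },
      unpack = function(th) c(a = exp(th[1]), mu = th[2], sigma = exp(th[3])))
  }
}

#' @export
print.rad_fit <- function(x, ...) {
  cat(sprintf("rad_fit [%s]%s: %s; sse = %.4g; converged = %s; n = %d\n",
              x$model,
              if (is.null(x$sample_id)) "" else paste0(" ", x$sample_id),
              paste(sprintf("%s = %.5g", names(x$params), x$params),
                    collapse = ", "),
              x$sse, x$converged, x$n_points))
  invisible(x)
}

#' Lowest-SSE model among the three fits of one sample
#'
#' @param fits A list of three `rad_fit` objects (one per family) for the
#'   same sample.
#' @param tie_tol SSE ties closer than this are broken by the fixed order
#'   power < exponential < lognormal.
#' @return Model name, or `NA` (with a warning) if any fit failed to
#'   converge.
#' @export
best_model <- function(fits, tie_tol = 1e-12) {
  stopifnot(all(vapply(fits, inherits, logical(1), "rad_fit")))
  models <- vapply(fits, `[[`, character(1), "model")
  need <- c("power", "exponential", "lognormal")
  if (!setequal(models, need))
    stopf("best_model needs exactly one fit per family (power, exponential, lognormal)")
  if (!all(vapply(fits, `[[`, logical(1), "converged"))) {
    warnf("best_model withheld: unconverged fit(s) for sample %s",
          fits[[1]]$sample_id %||% "<unnamed>")
    return(NA_character_)
  }
  ord <- match(need, models)
  sse <- vapply(fits[ord], `[[`, numeric(1), "sse")
  need[which(sse <= min(sse) + tie_tol)[1]]
}

#' Fit all three model families to every sample
#'
#' @param x An [otu_table()].
#' @param ... Passed to [fit_rad()].
#' @return A `data.frame` with one row per sample x model: `sample_id`,
#'   `model`, `param1`, `param2` (the shape parameter `b`, `k` or `sigma`
#'   also copied into `shape`), `sse`, `converged`, `best`.
#' @export
fit_rad_all <- function(x, ...) {
  stopifnot(inherits(x, "otu_table"))
  rel <- relative_abundance(x)
  rows <- lapply(rownames(rel), function(id) {
    ra <- rank_abundance(rel[id, ], sample_id = id)
    fits <- lapply(c("power", "exponential", "lognormal"),
                   function(m) fit_rad(ra, m, ...))
    best <- tryCatch(best_model(fits), warning = function(w) NA_character_)
    do.call(rbind, lapply(fits, function(f) {
      shape <- switch(f$model, power = f$params[["b"]],
                      exponential = f$params[["k"]],
                      lognormal = f$params[["sigma"]])
      data.frame(sample_id = id, model = f$model,
                 param1 = unname(f$params[1]), param2 = unname(f$params[2]),
                 shape = shape, sse = f$sse, converged = f$converged,
                 best = identical(best, f$model), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Cross-sample correlation of the power and exponential decay parameters
#'
#' Pearson correlation between the fitted power-law exponent `b` and the
#' exponential rate `k` over samples where both fits converged. Both
#' parameters measure how fast the rank-abundance curve falls, so steeply
#' dominated sample sets show a strong positive correlation.
#'
#' @param fits The data frame from [fit_rad_all()], or a list of `rad_fit`
#'   objects.
#' @return A list with `r` (Pearson correlation, `NA` with a warning if
#'   either parameter has zero variance), `n`, and `sample_ids`.
#' @export
parameter_correlation <- function(fits) {
  if (!is.data.frame(fits)) {
    stopifnot(all(vapply(fits, inherits, logical(1), "rad_fit")))
    fits <- do.call(rbind, lapply(fits, function(f) data.frame(
      sample_id = f$sample_id %||% NA_character_, model = f$model,
      shape = switch(f$model, power = f$params[["b"]],
                     exponential = f$params[["k"]], NA_real_),
      converged = f$converged, stringsAsFactors = FALSE)))
  }
  pw <- fits[fits$model == "power" & fits$converged, c("sample_id", "shape")]
  ex <- fits[fits$model == "exponential" & fits$converged,
             c("sample_id", "shape")]
  merged <- merge(pw, ex, by = "sample_id", suffixes = c("_b", "_k"))
  if (nrow(merged) < 3)
    stopf("need at least 3 samples with converged power and exponential fits, got %d",
          nrow(merged))
  if (stats::sd(merged$shape_b) == 0 || stats::sd(merged$shape_k) == 0) {
    warnf("parameter_correlation: zero variance in b or k; correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(merged$shape_b, merged$shape_k)
  }
  list(r = r, n = nrow(merged), sample_ids = merged$sample_id)
}
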