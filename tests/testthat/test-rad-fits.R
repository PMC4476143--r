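test_that("exact power-law data is recovered to machine precision", {
  fit <- fit_rad(0.5 * (1:20)^(-1), "power")
  expect_true(fit$converged)
  expect_equal(unname(fit$params["a"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(fit$params["b"]), 1.0, tolerance = 1e-6)
  expect_lte(fit$sse, 1e-12)
})

test_that("exact exponential data recovers its rate", {
  fit <- fit_rad(0.8 * exp(-0.3 * (1:30)), "exponential")
  expect_true(fit$converged)
  expect_equal(unname(fit$params["k"]), 0.3, tolerance = 1e-6)
  expect_lte(fit$sse, 1e-12)
})

test_that("lognormal quantile form recovers (mu, sigma) and beats the others", {
  s <- 100
  y <- exp(-4 + 1.2 * qnorm(1 - ((1:s) - 0.5) / s))
  ln <- fit_rad(y, "lognormal")
  expect_true(ln$converged)
  expect_equal(unname(ln$params["mu"]), -4, tolerance = 1e-3)
  expect_equal(unname(ln$params["sigma"]), 1.2, tolerance = 1e-3)
  pw <- fit_rad(y, "power")
  ex <- fit_rad(y, "exponential")
  expect_gt(pw$sse, ln$sse)
  expect_gt(ex$sse, ln$sse)
})

test_that("gaussian-in-logrank alternative form is self-consistent", {
  # mu = 0 keeps the curve monotone decreasing over ranks >= 1, as a
  # rank-abundance profile must be
  y <- 0.3 * exp(-log(1:50)^2 / (2 * 0.8^2))
  fit <- fit_rad(y, "lognormal", lognormal_form = "gaussian_logrank")
  expect_true(fit$converged)
  expect_lte(fit$sse, 1e-10)
  expect_equal(unname(fit$params["sigma"]), 0.8, tolerance = 1e-3)
})

test_that("fits are permutation-invariant and never climb above their seeds", {
  set.seed(31)
  y <- as.numeric(rmultinom(1, 3000, 0.4 * (1:40)^(-1.2) /
                              sum(0.4 * (1:40)^(-1.2))))
  y <- y[y > 0] / sum(y)
  f1 <- fit_rad(y, "power")
  f2 <- fit_rad(sample(y), "power")
  expect_equal(f1$params, f2$params, tolerance = 1e-9)
  # seed SSE from the log-linear regression is an upper bound on the optimum
  r <- seq_along(sort(y, decreasing = TRUE))
  ys <- sort(y, decreasing = TRUE)
  cf <- coef(lm(log(ys) ~ log(r)))
  seed_sse <- sum((ys - exp(cf[1]) * r^(cf[2]))^2)
  expect_lte(f1$sse, seed_sse + 1e-15)
})

test_that("undersized inputs are rejected", {
  expect_error(fit_rad(c(0.6, 0.4), "power"), "at least 3")
  expect_error(fit_rad(c(0.4, 0.3, 0.3), "lognormal",
                       lognormal_form = "gaussian_logrank"), "at least 4")
})

test_that("best_model selects minimal SSE with fixed tie order", {
  mk <- function(model, sse, converged = TRUE)
    structure(list(model = model, params = c(a = 1, b = 1), sse = sse,
                   converged = converged, n_points = 10, sample_id = "S"),
              class = "rad_fit")
  fits <- list(mk("power", 1e-3), mk("exponential", 2e-3),
               mk("lognormal", 5e-4))
  expect_identical(best_model(fits), "lognormal")
  tie <- list(mk("power", 1e-3), mk("exponential", 1e-3),
              mk("lognormal", 1e-3))
  expect_identical(best_model(tie), "power")
  expect_warning(res <- best_model(list(mk("power", 1, FALSE),
                                        mk("exponential", 1),
                                        mk("lognormal", 1))), "unconverged")
  expect_identical(res, NA_character_)
  y <- 0.5 * (1:20)^(-1)
  fits <- lapply(c("power", "exponential", "lognormal"),
                 function(m) fit_rad(y, m))
  expect_identical(best_model(fits), "power")
})

test_that("model-winner tally over bank communities is non-degenerate", {
  set.seed(17)
  wins <- table(vapply(1:40, function(i) {
    ra <- bank_community(bank_model_params(s_bank = 80), seed = i)
    best_model(lapply(c("power", "exponential", "lognormal"),
                      function(m) fit_rad(ra, m)))
  }, character(1)))
  expect_gte(length(wins), 2)  # no single family wins everything
})

test_that("parameter_correlation behaves on constructed inputs", {
  mk <- function(id, model, shape)
    data.frame(sample_id = id, model = model, shape = shape,
               converged = TRUE, stringsAsFactors = FALSE)
  fits <- rbind(mk(c("a", "b", "c", "d"), "power", c(1, 2, 3, 4)),
                mk(c("a", "b", "c", "d"), "exponential", c(2, 4, 6, 8)))
  res <- parameter_correlation(fits)
  expect_equal(res$r, 1.0, tolerance = 1e-12)
  expect_identical(res$n, 4L)
  expect_error(parameter_correlation(fits[c(1, 2, 5, 6), ]), "at least 3")
  flat <- rbind(mk(c("a", "b", "c"), "power", c(1, 1, 1)),
                mk(c("a", "b", "c"), "exponential", c(2, 4, 6)))
  expect_warning(res0 <- parameter_correlation(flat), "zero variance")
  expect_true(is.na(res0$r))
  # samples built with jointly increasing steepness correlate positively
  fits_real <- do.call(rbind, lapply(1:6, function(i) {
    b <- 0.6 + 0.2 * i
    y <- (1:60)^(-b); y <- y / sum(y)
    f <- lapply(c("power", "exponential"), function(m) fit_rad(y, m))
    data.frame(sample_id = paste0("S", i),
               model = c("power", "exponential"),
               shape = c(f[[1]]$params["b"], f[[2]]$params["k"]),
               converged = c(f[[1]]$converged, f[[2]]$converged))
  }))
  expect_gt(parameter_correlation(fits_real)$r, 0)
})

test_that("fit_rad_all produces the per-sample x model table", {
  tab <- random_table(3, 25, seed = 8)
  fits <- fit_rad_all(tab)
  expect_equal(nrow(fits), 9)
  expect_true(all(fits$sse >= 0))
  expect_equal(sum(fits$best), 3)  # one winner per sample
})
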