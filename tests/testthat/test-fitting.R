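# Nonlinear least-squares estimation: recovery on synthetic truth,
# weighting and equivariance properties, model comparison.

test_that("noiseless unconstrained data refits to the generating truth", {
  pr <- simulate_3c_profile(seq(2, 60, 2), K = 1, L = 9.70, S = 2.7)
  fit <- fit_unconstrained(pr, L = 9.70)
  expect_true(fit$converged)
  expect_equal(fit$params[["K"]], 1, tolerance = 1e-6)
  expect_equal(fit$params[["S"]], 2.7, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("scaling all frequencies scales K and leaves S unchanged", {
  pr <- simulate_3c_profile(seq(2, 60, 2), K = 1, L = 9.70, S = 2.7)
  pr10 <- contact_profile(pr$separation_kb, pr$frequency * 10)
  f1 <- fit_unconstrained(pr, L = 9.70)
  f10 <- fit_unconstrained(pr10, L = 9.70)
  expect_equal(f10$params[["K"]], 10 * f1$params[["K"]], tolerance = 1e-8)
  expect_equal(f10$params[["S"]], f1$params[["S"]], tolerance = 1e-8)
})

test_that("free-L fits recover S and the identifiable amplitude", {
  # K and L enter only through K*(L*S)^-3, so compare S and amplitude.
  truth <- c(K = 1.5e-9, L = 10.6, S = 4.9)
  s <- seq(5, 70, 5)
  pr <- simulate_3c_profile(s, K = truth[["K"]], L = truth[["L"]],
                            S = truth[["S"]])
  fit <- fit_unconstrained(pr, L = "free")
  expect_true(fit$converged)
  expect_equal(fit$params[["S"]], truth[["S"]], tolerance = 1e-2)
  amp_hat <- fit$params[["K"]] *
    (fit$params[["L"]] * fit$params[["S"]])^(-3)
  amp_true <- truth[["K"]] * (truth[["L"]] * truth[["S"]])^(-3)
  expect_equal(amp_hat, amp_true, tolerance = 1e-2)
  expect_true(is.na(fit$stderr[["L"]])) # degenerate direction flagged
})

test_that("noiseless helix data refits to the generating truth", {
  truth <- c(K = 1.07e3, S = 2.7, D = 255, P = 201)
  pr <- simulate_3c_profile(seq(5, 250, 10), K = truth[["K"]], L = 9.70,
                            S = truth[["S"]], D = truth[["D"]],
                            P = truth[["P"]])
  fit <- fit_helix(pr, L = 9.70)
  expect_true(fit$converged)
  expect_equal(unname(fit$params[names(truth)]), unname(truth),
               tolerance = 1e-3)
  expect_equal(fit$sh_kb,
               helix_turn_length(fit$params[["D"]], fit$params[["P"]], 9.70))
})

test_that("helix fit nests the unconstrained fit (D = 0 truth)", {
  pr <- simulate_3c_profile(seq(5, 150, 5), K = 500, L = 9.45, S = 3.1)
  fu <- fit_unconstrained(pr, L = 9.45)
  fh <- fit_helix(pr, L = 9.45)
  slack <- 1e-12 * sum(pr$frequency^2)
  expect_lte(fh$ssr, fu$ssr * (1 + 1e-8) + slack)
  # the helix either collapses (D ~ 0) or hides its diameter in a
  # sub-resolution modulation; the fitted curves must agree
  expect_equal(fh$fitted, fu$fitted, tolerance = 1e-4)
})

test_that("nested-model dominance holds on noisy profiles", {
  pr <- simulate_3c_profile(seq(5, 250, 5), K = 1.07e3, L = 9.70, S = 2.7,
                            D = 255, P = 201, noise = noise_spec(0.15),
                            seed = 7)
  fu <- fit_unconstrained(pr, L = 9.70)
  fh <- fit_helix(pr, L = 9.70)
  slack <- 1e-12 * sum(pr$frequency^2)
  expect_lte(fh$ssr, fu$ssr * (1 + 1e-8) + slack)
  expect_gte(fh$r_squared, fu$r_squared - 1e-8)
})

test_that("doubling every SEM leaves point estimates unchanged", {
  pr <- simulate_3c_profile(seq(5, 250, 5), K = 1.07e3, L = 9.70, S = 2.7,
                            D = 255, P = 201, noise = noise_spec(0.1),
                            seed = 21)
  pr2 <- contact_profile(pr$separation_kb, pr$frequency, sem = 2 * pr$sem)
  f1 <- fit_helix(pr, L = 9.70, weights = "sem")
  f2 <- fit_helix(pr2, L = 9.70, weights = "sem")
  expect_equal(f1$params, f2$params, tolerance = 1e-6)
})

test_that("fits are deterministic given identical input and options", {
  pr <- simulate_3c_profile(seq(5, 250, 5), K = 1.07e3, L = 9.70, S = 2.7,
                            D = 255, P = 201, noise = noise_spec(0.1),
                            seed = 3)
  f1 <- fit_helix(pr, L = 9.70)
  f2 <- fit_helix(pr, L = 9.70)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$ssr, f2$ssr)
})

test_that("power-law fits recover exact generating exponents", {
  s <- seq(4, 200, 4)
  f1 <- fit_powerlaw(contact_profile(s, powerlaw_frequency(s, 5, -1)))
  expect_equal(unname(f1$params), c(5, -1), tolerance = 1e-6)
  f2 <- fit_powerlaw(contact_profile(s, powerlaw_frequency(s, 2, -1.5)))
  expect_equal(f2$params[["alpha"]], -1.5, tolerance = 1e-6)
})

test_that("profiles with too few observations are rejected", {
  pr <- contact_profile(c(5, 10, 15), c(3, 2, 1))
  expect_error(fit_unconstrained(pr, L = 10), "at least 4")
  expect_error(fit_helix(contact_profile(c(5, 10, 15, 20), c(4, 3, 2, 1)),
                         L = 10), "at least 5")
  expect_error(fit_powerlaw(contact_profile(c(5, 10), c(2, 1))),
               "at least 3")
})

test_that("r_squared matches hand-computed values and guards edge cases", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_lt(r_squared(c(1, 2, 3), c(9, 9, 9)), 0)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("compare_fits orders by R^2 with a stable model-id tie-break", {
  s <- seq(5, 250, 5)
  pr <- simulate_3c_profile(s, K = 1.07e3, L = 9.70, S = 2.7, D = 255,
                            P = 201, noise = noise_spec(0.1), seed = 5)
  fits <- list(fit_unconstrained(pr, L = 9.70), fit_helix(pr, L = 9.70),
               fit_powerlaw(pr))
  tab <- compare_fits(fits)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$r_squared) <= 0))
  expect_equal(tab$model_id[1], "helix") # modulation favours the helix
  one <- compare_fits(fits[[1]])
  expect_equal(nrow(one), 1)
  # exact R^2 ties fall back to alphabetical model ids
  f <- fits[[1]]
  g <- fits[[1]]
  g$model_id <- "zzz"
  tied <- compare_fits(list(g, f))
  expect_equal(tied$model_id, c("unconstrained", "zzz"))
})
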