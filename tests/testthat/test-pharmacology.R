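test_that("the 4PL response has the analytic midpoint and asymptotes", {
  expect_equal(hill_response(1e-5, bottom = 10, top = 90, ec50 = 1e-5,
                             hill = 2), 50)
  expect_equal(hill_response(1e-12, bottom = 10, top = 90, ec50 = 1e-5,
                             hill = 1), 10, tolerance = 1e-4)
  expect_equal(hill_response(1e2, bottom = 10, top = 90, ec50 = 1e-5,
                             hill = 1), 90, tolerance = 1e-4)
  expect_equal(hill_response(1e-4, bottom = 0, top = 1, ec50 = 1e-5,
                             hill = 1), 10 / 11)
  expect_error(hill_response(0, bottom = 0, top = 1, ec50 = 1e-5), "positive")
})

test_that("normalization divides by the matched control mean", {
  conc <- rep(10^(-7:-4), each = 2)
  ctrl <- data.frame(concentration = conc, response = 100)
  cur <- dose_response_curve("r", "l", conc, rep(c(100, 250), 4),
                             control = ctrl)
  norm <- normalize_responses(cur)
  expect_equal(sort(unique(norm$response)), c(1, 2.5))

  flat <- dose_response_curve("r", "l", conc, rep(100, 8), control = ctrl)
  expect_equal(normalize_responses(flat)$response, rep(1, 8))

  # missing control at one concentration drops those points with a warning
  ctrl2 <- ctrl[ctrl$concentration != 1e-4, ]
  cur2 <- dose_response_curve("r", "l", conc, rep(100, 8), control = ctrl2)
  expect_warning(norm2 <- normalize_responses(cur2), "dropped")
  expect_equal(nrow(norm2), 6)

  bad <- dose_response_curve("r", "l", conc, rep(100, 8),
                             control = data.frame(concentration = conc,
                                                  response = -1))
  expect_error(normalize_responses(bad), "control")
})

test_that("noise-free curves are recovered to optimizer tolerance", {
  conc <- 10^seq(-8, -3, length.out = 8)
  truth <- data.frame(receptor = "r", ligand = "l", bottom = 5, top = 120,
                      ec50 = 3e-6, hill = 1.4)
  sa <- simulate_assay(truth, concentrations = conc, noise_frac = 0,
                       seed = 1)
  fit <- fit_dose_response(sa$curves[[1]])
  p <- coef(fit)
  expect_true(fit$flags$converged)
  expect_equal(p[["bottom"]], 5, tolerance = 1e-5)
  expect_equal(p[["top"]], 120, tolerance = 1e-5)
  expect_equal(log10(p[["ec50"]]), log10(3e-6), tolerance = 1e-5)
  expect_equal(p[["hill"]], 1.4, tolerance = 1e-4)
  expect_false(fit$flags$degenerate)
  expect_false(fit$flags$extrapolated)
})

test_that("fitting validates input and flags degenerate data", {
  cur <- dose_response_curve("r", "l", rep(10^(-6:-4), each = 2),
                             rnorm(6, 50, 1))
  expect_error(fit_dose_response(cur), "4 distinct")

  set.seed(1)
  conc <- rep(10^seq(-8, -3, length.out = 8), each = 3)
  flat <- dose_response_curve("r", "l", conc, rnorm(24, 100, 2))
  ffit <- fit_dose_response(flat)
  expect_true(ffit$flags$degenerate)

  # monotone-decreasing data under hill > 0 cannot give top > bottom
  dec <- dose_response_curve("r", "l", conc,
                             100 - hill_response(conc, 0, 80, 1e-5, 1))
  dfit <- fit_dose_response(dec)
  expect_true(dfit$flags$degenerate)
})

test_that("the fit is scale-equivariant and deterministic", {
  conc <- rep(10^seq(-8, -3, length.out = 8), each = 3)
  set.seed(7)
  resp <- hill_response(conc, 2, 100, 1e-5, 1) + rnorm(length(conc), 0, 4)
  f1 <- fit_dose_response(dose_response_curve("r", "l", conc, resp))
  f2 <- fit_dose_response(dose_response_curve("r", "l", conc, resp * 7))
  expect_equal(coef(f2)[["bottom"]], 7 * coef(f1)[["bottom"]],
               tolerance = 1e-3)
  expect_equal(coef(f2)[["top"]], 7 * coef(f1)[["top"]], tolerance = 1e-3)
  expect_equal(coef(f2)[["ec50"]], coef(f1)[["ec50"]], tolerance = 1e-3)
  expect_equal(coef(f2)[["hill"]], coef(f1)[["hill"]], tolerance = 1e-3)
  f1b <- fit_dose_response(dose_response_curve("r", "l", conc, resp))
  expect_identical(coef(f1), coef(f1b))
})

test_that("simulating from a fit reproduces the data to residual noise", {
  conc <- rep(10^seq(-8, -3, length.out = 8), each = 3)
  set.seed(21)
  resp <- hill_response(conc, 0, 100, 1e-5, 1) + rnorm(length(conc), 0, 5)
  fit <- fit_dose_response(dose_response_curve("r", "l", conc, resp))
  sims <- simulate(fit, nsim = 50, seed = 1)
  dev <- vapply(sims, function(s) sd(s - fit$fitted.values), numeric(1))
  expect_equal(mean(dev), fit$sigma, tolerance = 0.15)
})

test_that("relative potency is the EC50 ratio with a propagated interval", {
  mk <- function(ec50) {
    conc <- rep(10^seq(log10(ec50) - 2.5, log10(ec50) + 2.5,
                       length.out = 8), each = 3)
    set.seed(3)
    resp <- hill_response(conc, 0, 100, ec50, 1) + rnorm(length(conc), 0, 2)
    fit_dose_response(dose_response_curve("r", "l", conc, resp))
  }
  fa <- mk(1e-3); fb <- mk(1e-6)
  rp <- relative_potency(fa, fb)
  expect_equal(as.numeric(rp), 1000, tolerance = 0.15)
  expect_equal(as.numeric(relative_potency(fa, fa)), 1)
  ci <- attr(rp, "ci")
  expect_true(ci[1] < 1000 && 1000 < ci[2])
  expect_false(attr(rp, "flagged"))
})

test_that("a planted 3000-fold potency difference is recovered within CI", {
  truth <- data.frame(receptor = c("wt", "mut"), ligand = "diaminopropane",
                      bottom = 0, top = 100, ec50 = c(1e-7, 3e-4), hill = 1)
  sa <- simulate_assay(truth,
                       concentrations = 10^seq(-9, -2, length.out = 10),
                       noise_frac = 0.05, seed = 17)
  f_wt <- fit_dose_response(sa$curves[["wt/diaminopropane"]])
  f_mut <- fit_dose_response(sa$curves[["mut/diaminopropane"]])
  rp <- relative_potency(f_mut, f_wt)
  ci <- attr(rp, "ci")
  expect_true(ci[1] <= 3000 && 3000 <= ci[2])
})

test_that("screen hits deconvolve to the union of hit-pool members", {
  design <- default_mixture_design()
  expect_length(design$mixes, 11)
  got <- deconvolve_mixture_hits(design, "mix3")
  expect_setequal(got$candidates,
                  c("hexylamine", "isoamylamine", "isobutylamine",
                    "isopropylamine", "indole", "cadaverine"))
  expect_equal(deconvolve_mixture_hits(design, character(0))$candidates,
               character(0))
  expect_error(deconvolve_mixture_hits(design, "mix99"), "mix99")

  # monotone: adding a hit pool never removes candidates
  one <- deconvolve_mixture_hits(design, "mix3")$candidates
  two <- deconvolve_mixture_hits(design, c("mix3", "mix10"))$candidates
  expect_true(all(one %in% two))

  # follow-up partitions a mix-5 hit into confirmed and rejected
  fu <- c("2-phenylethylamine" = TRUE, hexanal = FALSE,
          "ethyl butyrate" = FALSE, tryptamine = FALSE, histamine = FALSE,
          trimethylamine = FALSE)
  part <- deconvolve_mixture_hits(design, "mix5", followup = fu)
  expect_equal(part$confirmed, "2-phenylethylamine")
  expect_setequal(part$rejected, setdiff(design$mixes$mix5,
                                         "2-phenylethylamine"))
  expect_length(part$untested, 0)
})

test_that("hit calling compares pool responses to no-receptor controls", {
  tab <- data.frame(
    receptor = c(rep("r1", 4), rep(NA, 4)),
    mix_id = c("mix1", "mix1", "mix2", "mix2", NA, NA, NA, NA),
    response = c(300, 320, 110, 95, 100, 95, 105, 100),
    is_control = c(rep(FALSE, 4), rep(TRUE, 4))
  )
  hits <- call_screen_hits(tab, threshold = 2)
  expect_equal(hits$hit, c(TRUE, FALSE))
  expect_equal(hits$fold[1], mean(c(300, 320)) / 100, tolerance = 1e-9)
})
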