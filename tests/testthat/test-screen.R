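test_that("percent effect anchors 0 at the neutral and 100 at the stimulator median", {
  neutral <- c(98, 100, 102, 101)
  stim <- c(995, 1000, 1005)
  expect_equal(percent_effect(median(neutral), neutral, stim), 0)
  expect_equal(percent_effect(median(stim), neutral, stim), 100)
  mid <- (median(neutral) + median(stim)) / 2
  expect_equal(percent_effect(mid, neutral, stim), 50)
  # affine invariance: positive affine rescaling changes nothing
  f <- function(x) 3.7 * x + 42
  raw <- c(150, 400, 900)
  expect_equal(percent_effect(f(raw), f(neutral), f(stim)),
               percent_effect(raw, neutral, stim), tolerance = 1e-12)
  expect_error(percent_effect(1, c(5, 5), c(5, 5)), "equal")
  expect_error(percent_effect(1, 5, c(1, 2)), "at least 2 wells")
})

test_that("hit calling uses a strict >50% rule in at least one readout", {
  eff <- data.frame(compound = c("a", "b", "c", "d", "e"),
                    effect_prolif = c(55, 49, 50, 10, NA),
                    effect_ifng = c(10, 49, 50, 51, 60))
  h <- call_hits(eff)
  expect_equal(h$hit, c(TRUE, FALSE, FALSE, TRUE, FALSE))  # (50,50) is not a hit
  expect_equal(h$untestable, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # hit set monotone nonincreasing in the threshold
  prev <- sum(call_hits(eff, 0)$hit)
  for (thr in c(10, 30, 50, 70, 90)) {
    cur <- sum(call_hits(eff, thr)$hit)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("the counter screen validates only hits inactive on T cells alone", {
  eff <- data.frame(compound = c("a", "b", "c", "d"),
                    effect_prolif = c(80, 70, 20, 90),
                    effect_ifng = c(10, 10, 10, 10))
  h <- call_hits(eff)
  counter <- data.frame(compound = c("a", "b", "c"),
                        effect_prolif = c(5, 60, 1),
                        effect_ifng = c(3, 5, 1))
  v <- suppressMessages(counter_screen_filter(h, counter))
  expect_true(v$validated[v$compound == "a"])    # counter effects (5, 3)
  expect_false(v$validated[v$compound == "b"])   # direct T-cell effect (60, 5)
  expect_false(v$validated[v$compound == "c"])   # a non-hit is never validated
  expect_true(is.na(v$validated[v$compound == "d"]))  # no counter data: excluded
})

test_that("the 4PL fit recovers noise-free parameters on the secondary-screen ladder", {
  doses <- secondary_screen_ladder()
  y <- fourpl(doses, bottom = 0, top = 100, ec50 = 2.6e-6, hill = 1)
  fit <- fit_dose_response(doses, y)
  expect_true(fit$converged && fit$active)
  p <- coef(fit)
  expect_equal(p[["ec50"]], 2.6e-6, tolerance = 1e-6)
  expect_equal(p[["bottom"]], 0, tolerance = 1e-4)
  expect_equal(p[["top"]], 100, tolerance = 1e-6)
  expect_equal(p[["hill"]], 1, tolerance = 1e-6)
  expect_equal(fit$ec50_relative, fit$ec50)
  expect_false(fit$extrapolated)
  # flat response: inactive classification
  flat <- fit_dose_response(doses, rnorm(10, 0, 1))
  expect_false(flat$active)
  # monotone-decreasing data: negative slope allowed, EC50 still reported
  dec <- fit_dose_response(doses, fourpl(doses, 100, 0, 1e-6, 1))
  expect_true(dec$converged)
  expect_lt(coef(dec)[["hill"]], 0)
  expect_equal(dec$ec50, 1e-6, tolerance = 1e-4)
  expect_error(fit_dose_response(c(1e-6, 2e-6, 3e-6), c(1, 2, 3)), "4 distinct")
})

test_that("donor effects bin into none/mild/strong with a closed boundary at 40", {
  b <- bin_donor_effects(c(-5, 10, 45))
  expect_equal(unname(c(b$counts)), c(1L, 1L, 1L))
  expect_equal(unname(c(bin_donor_effects(rep(0, 4))$counts)), c(4L, 0L, 0L))
  expect_equal(as.character(bin_donor_effects(40)$category), "mild")
  expect_equal(as.character(bin_donor_effects(40.0001)$category), "strong")
})

test_that("noise-free simulated plates round-trip true percent effects exactly", {
  te <- data.frame(compound = sprintf("C%02d", 1:6),
                   effect_prolif = c(55, -10, 0, 100, 23.5, 51),
                   effect_ifng = c(5, 80, 0, 40, 50, 49))
  sim <- gen_plate(plate_sim_config(n_compounds = 6, plate_noise_sd = 0,
                                    true_effects = te, seed = 4))
  eff <- normalize_plate(sim$plate)
  ord <- match(te$compound, eff$compound)
  expect_equal(eff$effect_prolif[ord], te$effect_prolif, tolerance = 1e-12)
  expect_equal(eff$effect_ifng[ord], te$effect_ifng, tolerance = 1e-12)
  h <- call_hits(eff)
  expect_equal(sort(h$compound[h$hit]), c("C01", "C02", "C04", "C06"))
  # with noise, per-compound bias stays small relative to the noise level
  sim2 <- gen_plate(plate_sim_config(n_compounds = 200, plate_noise_sd = 5, seed = 8))
  eff2 <- normalize_plate(sim2$plate)
  bias <- mean(eff2$effect_prolif[match(sim2$truth$compound, eff2$compound)] -
                 sim2$truth$effect_prolif)
  expect_lt(abs(bias), 5 / sqrt(16) * 3)
})
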