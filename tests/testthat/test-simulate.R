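test_that("all generators are bit-reproducible under a fixed seed", {
  cfgs <- list(
    profile = function() gen_tmt_profile(profile_sim_config(n_proteins = 50, seed = 5)),
    plate = function() gen_plate(plate_sim_config(n_compounds = 8, seed = 5)),
    pulldown = function() gen_pulldown_series(pulldown_sim_config(n_proteins = 6, seed = 5)),
    sip = function() gen_solvent_profiles(sip_sim_config(n_proteins = 40, seed = 5)))
  for (f in cfgs) expect_identical(f(), f())
  # and a different seed changes the data
  expect_false(identical(
    gen_tmt_profile(profile_sim_config(n_proteins = 50, seed = 5)),
    gen_tmt_profile(profile_sim_config(n_proteins = 50, seed = 6))))
})

test_that("profile ground truth flags exactly the requested regulated fraction", {
  sim <- gen_tmt_profile(profile_sim_config(n_proteins = 1000, frac_regulated = 0.1,
                                            seed = 1))
  expect_equal(sum(sim$truth$regulated), 100L)
  expect_true(all(sim$truth$true_log2fc[!sim$truth$regulated] == 0))
  expect_true(all(sim$truth$true_log2fc[sim$truth$regulated] != 0))
  # invalid configs rejected
  expect_error(profile_sim_config(n_proteins = NaN), "n_proteins")
  expect_error(profile_sim_config(frac_regulated = 1.2), "frac_regulated")
  expect_error(profile_sim_config(noise_sd_log2 = -1), "noise_sd_log2")
})

test_that("noise-free profiles reproduce the true effects exactly and bridges carry the reference", {
  sim <- gen_tmt_profile(profile_sim_config(
    n_proteins = 200, channels_per_group = 3, n_plexes = 2, bridge = TRUE,
    noise_sd_log2 = 0, missing_rate = 0, batch_factor_log2 = c(0, 1), seed = 2))
  ch <- channel_meta(sim$matrix)
  expect_equal(sum(ch$bridge), 2L)
  L <- log2(intensities(sim$matrix))
  # empirical log2 FC within one plex equals the true effect exactly
  a1 <- which(ch$condition == "A" & ch$plex == 1)
  b1 <- which(ch$condition == "B" & ch$plex == 1)
  fc <- rowMeans(L[, b1, drop = FALSE]) - rowMeans(L[, a1, drop = FALSE])
  expect_equal(unname(fc), sim$truth$true_log2fc, tolerance = 1e-12)
  # the plex-2 batch factor is one log2 unit on every plex-2 channel
  a2 <- which(ch$condition == "A" & ch$plex == 2)
  expect_equal(unname(L[, a2[1]] - L[, a1[1]]), rep(1, 200), tolerance = 1e-12)
  # the bridge channel equals the untreated (A) profile within its plex
  br1 <- which(ch$bridge & ch$plex == 1)
  expect_equal(unname(L[, br1]), unname(L[, a1[1]]), tolerance = 1e-12)
  # bridge normalization then removes the batch factor entirely
  plex_list <- lapply(1:2, function(p) {
    sel <- which(ch$plex == p)
    y <- sim$matrix[, sel]
    y$channels$label[y$channels$bridge] <- "bridge"
    y
  })
  j <- bridge_normalize(plex_list, "bridge")
  jc <- channel_meta(j)
  la <- log2(intensities(j))
  expect_equal(unname(la[, which(jc$condition == "A")[1]]),
               unname(la[, which(jc$condition == "A" & grepl("plex2", jc$label))[1]]),
               tolerance = 1e-12)
  # missing values injected at the requested rate
  sim2 <- gen_tmt_profile(profile_sim_config(n_proteins = 500, missing_rate = 0.1, seed = 3))
  expect_equal(mean(is.na(intensities(sim2$matrix))), 0.1, tolerance = 0.01)
})

test_that("pulldown series follow the depletion-corrected binding law", {
  # put c = Kd_eff = true_kd / cf = 200 nM on the ladder: binding is exactly 1/2
  cfg <- pulldown_sim_config(n_proteins = 4, n_targets = 2, true_kd = 1e-7,
                             depletion_cf = 0.5, noise_cv = 0, seed = 3,
                             dose_ladder = c(0, 10, 100, 200, 1000, 30000) * 1e-9)
  sim <- gen_pulldown_series(cfg)
  s <- sim$series[[1]]
  r <- relative_binding(s)
  expect_equal(r[which.min(abs(s$doses - 2e-7))], 0.5, tolerance = 1e-12)
  # PDPD/PD equals the true cf exactly without noise
  expect_equal(s$pdpd / s$pd, 0.5, tolerance = 1e-12)
  # non-target: ratios all 1, no depletion
  nt <- sim$series[[3]]
  expect_equal(relative_binding(nt), rep(1, length(s$doses)))
  expect_equal(nt$pdpd / nt$pd, 1, tolerance = 1e-12)
  # cf outside (0,1] rejected; default ladder matches the eight-dose design
  expect_error(pulldown_sim_config(depletion_cf = 0), "0, 1")
  expect_error(pulldown_sim_config(depletion_cf = 1.5), "0, 1")
  expect_equal(pulldown_sim_config()$dose_ladder,
               c(0, 10, 30, 100, 300, 1000, 3000, 30000) * 1e-9)
})

test_that("plate generator honours roles, control counts and the effect scale", {
  sim <- gen_plate(plate_sim_config(n_compounds = 0, n_neutral = 4,
                                    n_stimulator = 4, seed = 1))
  expect_equal(nrow(sim$plate), 8L)
  expect_setequal(unique(sim$plate$role), c("neutral", "stimulator"))
  expect_equal(anyDuplicated(sim$plate$well), 0L)
  expect_error(plate_sim_config(n_neutral = 1), "n_neutral")
})

test_that("solvent profiles respond to the midpoint shift as the survival model predicts", {
  # no shift: active and inactive conditions generated identically (noise-free)
  sim0 <- gen_solvent_profiles(sip_sim_config(n_proteins = 60, n_stabilized = 5,
                                              midpoint_shift = 0, noise_sd_log2 = 0,
                                              seed = 4))
  ch <- channel_meta(sim0$matrix)
  m0 <- intensities(sim0$matrix)
  expect_equal(m0[, ch$condition == "cmpd2_10x"], m0[, ch$condition == "cmpd3_10uM"],
               ignore_attr = TRUE)
  # positive shift: pooled intensity strictly larger under the active compound
  simp <- gen_solvent_profiles(sip_sim_config(n_proteins = 60, n_stabilized = 5,
                                              midpoint_shift = 2, noise_sd_log2 = 0,
                                              seed = 4))
  mp <- intensities(simp$matrix)
  chp <- channel_meta(simp$matrix)
  stab <- simp$truth$stabilized
  act <- mp[, chp$condition == "cmpd2_10x"][, 1]
  inact <- mp[, chp$condition == "cmpd3_10uM"][, 1]
  expect_true(all(act[stab] > inact[stab]))
  expect_equal(act[!stab], inact[!stab], tolerance = 1e-12, ignore_attr = TRUE)
  # survival ~ 1 over the whole grid: pooled intensity equals the baseline
  expect_warning(
    cfg_hi <- sip_sim_config(n_proteins = 20, n_stabilized = 0,
                             midpoint_range = c(80, 80), noise_sd_log2 = 0, seed = 4),
    "beyond the solvent grid")
  sim_hi <- gen_solvent_profiles(cfg_hi)
  surv <- 1 / (1 + exp((c(8, 10, 12, 14, 16, 18, 20, 22) - 80) / 1.5))
  expect_equal(mean(surv), 1, tolerance = 1e-9)  # full survival over the grid
  mhi <- intensities(sim_hi$matrix)
  # so every sample reports the undiminished baseline (columns all identical)
  expect_lt(max(abs(mhi - mhi[, 1])), 1e-6 * max(mhi))
})

test_that("phosphosite profiles separate site-level from protein-level regulation", {
  # a quiescent proteome with unequal channel loading: after normalizing the
  # sites by the proteome total-sum factors, site FCs center on 0
  prot <- gen_tmt_profile(profile_sim_config(
    n_proteins = 300, frac_regulated = 0, noise_sd_log2 = 0.1,
    missing_rate = 0, loading_sd_log2 = 0.3, seed = 8))
  scfg <- profile_sim_config(n_proteins = 1000, frac_regulated = 0,
                             noise_sd_log2 = 0.1, seed = 8)
  sites <- gen_phospho_profile(scfg, prot)
  rep_ <- total_sum_normalize(prot$matrix)$report
  norm_sites <- normalize_phospho_by_proteome(sites$matrix, rep_)
  ch <- channel_meta(sites$matrix)
  L <- log2(intensities(norm_sites))
  fc <- rowMeans(L[, ch$condition == "B"]) - rowMeans(L[, ch$condition == "A"])
  expect_lt(abs(median(fc)), 0.05)
  # without the loading correction the raw site FCs are offset by the loading
  Lraw <- log2(intensities(sites$matrix))
  fc_raw <- rowMeans(Lraw[, ch$condition == "B"]) - rowMeans(Lraw[, ch$condition == "A"])
  expect_gt(abs(median(fc_raw) - median(fc)), 0.01)
  # a site-level effect of +2 on a flat protein shows up as a site FC of ~2
  prot0 <- gen_tmt_profile(profile_sim_config(n_proteins = 50, frac_regulated = 0,
                                              noise_sd_log2 = 0, missing_rate = 0,
                                              seed = 9))
  scfg2 <- profile_sim_config(n_proteins = 200, frac_regulated = 0.2,
                              effect_log2 = 2, effect_sd = 0, noise_sd_log2 = 0,
                              seed = 9)
  sites2 <- gen_phospho_profile(scfg2, prot0)
  ch2 <- channel_meta(sites2$matrix)
  L2 <- log2(intensities(sites2$matrix))
  fc2 <- rowMeans(L2[, ch2$condition == "B"]) - rowMeans(L2[, ch2$condition == "A"])
  reg <- sites2$truth$site_regulated
  expect_equal(abs(fc2[reg]), rep(2, sum(reg)), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fc2[!reg], rep(0, sum(!reg)), tolerance = 1e-10, ignore_attr = TRUE)
  # determinism and the absent-parent guard
  expect_identical(gen_phospho_profile(scfg2, prot0), sites2)
  expect_error(gen_phospho_profile(scfg2, prot0, parent = rep("NOPE", 200)),
               "absent from the proteome")
})
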