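#' Configuration for the TMT profiling simulator
#'
#' Defaults emulate the two-state proteome profiling design: a single
#' 10-channel plex with five replicates per state (five independent MDSC
#' differentiations vs progenitors), ten percent regulated proteins with a
#' mean absolute effect of 1 log2 unit, and typical TMT replicate noise.
#'
#' @param n_proteins number of protein rows.
#' @param channels_per_group replicates per state (total samples =
#'   `2 * channels_per_group`).
#' @param n_plexes number of TMT plexes the samples are split across
#'   (round-robin).
#' @param bridge add a common bridge channel (untreated reference) to every
#'   plex.
#' @param frac_regulated fraction of proteins regulated between the states.
#' @param effect_log2 mean true log2 fold change of regulated proteins (the
#'   sign is drawn at random per protein).
#' @param effect_sd SD of the true effects around `effect_log2`.
#' @param noise_sd_log2 per-measurement log2 noise SD.
#' @param missing_rate fraction of values set missing.
#' @param batch_factor_log2 per-plex multiplicative batch factor on the log2
#'   scale (scalar recycled, or one value per plex).
#' @param loading_sd_log2 SD of per-channel loading offsets (log2); models
#'   unequal sample amounts that total-sum normalization removes.
#' @param missing_mode `"mcar"` (completely at random, default) or
#'   `"intensity"` (missingness enriched in low-intensity values).
#' @param seed integer seed.
#' @return A `profile_sim_config` list.
#' @export
profile_sim_config <- function(n_proteins = 4000L, channels_per_group = 5L,
                               n_plexes = 1L, bridge = FALSE,
                               frac_regulated = 0.1, effect_log2 = 1,
                               effect_sd = 0.25, noise_sd_log2 = 0.2,
                               missing_rate = 0.05, batch_factor_log2 = 0,
                               loading_sd_log2 = 0, missing_mode = c("mcar", "intensity"),
                               seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(
    n_proteins = .check_count(n_proteins, "n_proteins", min = 1L),
    channels_per_group = .check_count(channels_per_group, "channels_per_group", min = 1L),
    n_plexes = .check_count(n_plexes, "n_plexes", min = 1L),
    bridge = isTRUE(bridge),
    frac_regulated = .check_fraction(frac_regulated, "frac_regulated"),
    effect_log2 = .check_num(effect_log2, "effect_log2"),
    effect_sd = .check_num(effect_sd, "effect_sd", min = 0),
    noise_sd_log2 = .check_num(noise_sd_log2, "noise_sd_log2", min = 0),
    missing_rate = .check_fraction(missing_rate, "missing_rate"),
    batch_factor_log2 = if (length(batch_factor_log2) == 1L)
      rep(.check_num(batch_factor_log2, "batch_factor_log2"), n_plexes)
    else .check_num(batch_factor_log2, "batch_factor_log2", len = as.integer(n_plexes)),
    loading_sd_log2 = .check_num(loading_sd_log2, "loading_sd_log2", min = 0),
    missing_mode = missing_mode,
    seed = .check_count(seed, "seed"))
  structure(cfg, class = "profile_sim_config")
}

#' Simulate a two-state TMT profiling experiment
#'
#' Log-normal baseline abundances; a seeded subset of proteins carries a true
#' log2 effect (random sign, magnitude `effect_log2 +/- effect_sd`) in the
#' second state; per-plex batch factors and per-channel loading offsets are
#' applied multiplicatively; when `bridge = TRUE` every plex gains a bridge
#' channel carrying the untreated reference (state A) profile; missing values
#' are injected at `missing_rate`. Identical seeds reproduce identical
#' output.
#'
#' @param config a [profile_sim_config()].
#' @return List with `matrix` (a [reporter_matrix]) and `truth` (data frame
#'   with `id`, `regulated`, `true_log2fc`).
#' @export
gen_tmt_profile <- function(config = profile_sim_config()) {
  stopifnot(inherits(config, "profile_sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  npg <- config$channels_per_group
  ids <- sprintf("P%05d", seq_len(n))
  base_log2 <- rnorm(n, mean = 20, sd = 1.5)
  n_reg <- round(config$frac_regulated * n)
  reg_idx <- if (n_reg > 0) sort(sample.int(n, n_reg)) else integer(0)
  effects <- numeric(n)
  if (n_reg > 0)
    effects[reg_idx] <- sample(c(-1, 1), n_reg, replace = TRUE) *
      rnorm(n_reg, config$effect_log2, config$effect_sd)

  # round-robin assignment of samples to plexes (balanced across conditions)
  samples <- data.frame(
    label = c(sprintf("A%d", seq_len(npg)), sprintf("B%d", seq_len(npg))),
    condition = rep(c("A", "B"), each = npg),
    plex = rep_len(seq_len(config$n_plexes), 2L * npg),
    stringsAsFactors = FALSE)
  samples$bridge <- FALSE
  samples$role <- "sample"
  if (config$bridge) {
    br <- data.frame(label = sprintf("bridge_p%d", seq_len(config$n_plexes)),
                     condition = "bridge", plex = seq_len(config$n_plexes),
                     bridge = TRUE, role = "bridge", stringsAsFactors = FALSE)
    samples <- rbind(samples, br)
  }
  loading <- rnorm(nrow(samples), 0, config$loading_sd_log2)
  L <- matrix(base_log2, n, nrow(samples))
  for (k in seq_len(nrow(samples))) {
    eff <- if (samples$condition[k] == "B") effects else 0
    L[, k] <- base_log2 + eff + config$batch_factor_log2[samples$plex[k]] +
      loading[k] + rnorm(n, 0, config$noise_sd_log2)
  }
  M <- 2^L
  if (config$missing_rate > 0) {
    n_miss <- round(config$missing_rate * length(M))
    if (config$missing_mode == "mcar") {
      miss <- sample.int(length(M), n_miss)
    } else {
      w <- 1 / rank(M)           # low intensities more likely missing
      miss <- sample.int(length(M), n_miss, prob = w)
    }
    M[miss] <- NA_real_
  }
  rownames(M) <- ids
  colnames(M) <- samples$label
  # true effect reported as log2(B) - log2(A)
  truth <- data.frame(id = ids, regulated = seq_len(n) %in% reg_idx,
                      true_log2fc = effects, stringsAsFactors = FALSE)
  list(matrix = reporter_matrix(M, channels = samples), truth = truth)
}

#' Configuration for the phosphosite simulator
#'
#' Reuses [profile_sim_config()] semantics: `n_proteins` is the number of
#' phosphosites, `frac_regulated` the fraction with a *site-level* effect on
#' top of their parent protein's behavior.
#'
#' @param config a [profile_sim_config()] describing the site layer.
#' @param proteome the `gen_tmt_profile()` output (list with `matrix` and
#'   `truth`) the sites hang off.
#' @param parent optional character vector assigning each site a parent
#'   protein id; defaults to a seeded random assignment. Ids absent from the
#'   proteome are rejected.
#' @return List with `matrix` (site [reporter_matrix], same channels as the
#'   proteome) and `truth` (site id, parent, site-level and parent-level
#'   regulation flags and effects).
#' @export
gen_phospho_profile <- function(config, proteome, parent = NULL) {
  stopifnot(inherits(config, "profile_sim_config"))
  pm <- proteome$matrix
  stopifnot(inherits(pm, "reporter_matrix"))
  set.seed(config$seed + 1L)
  n <- config$n_proteins
  prot_ids <- pm$rows$id
  if (is.null(parent)) {
    parent <- sample(prot_ids, n, replace = TRUE)
  } else {
    bad <- setdiff(unique(parent), prot_ids)
    if (length(bad)) .stopf("site parent(s) absent from the proteome: %s",
                            paste(head(bad, 5L), collapse = ", "))
    stopifnot(length(parent) == n)
  }
  pos <- sample.int(2000L, n, replace = TRUE)
  ids <- sprintf("%s_S%d___1", parent, pos)
  ids <- make.unique(ids, sep = "#")
  n_reg <- round(config$frac_regulated * n)
  reg_idx <- if (n_reg > 0) sort(sample.int(n, n_reg)) else integer(0)
  effects <- numeric(n)
  if (n_reg > 0)
    effects[reg_idx] <- sample(c(-1, 1), n_reg, replace = TRUE) *
      rnorm(n_reg, config$effect_log2, config$effect_sd)
  stoich <- runif(n, -3, 0)  # log2 site stoichiometry factor
  P <- pm$intensity[parent, , drop = FALSE]
  isB <- pm$channels$condition == "B"
  L <- log2(P) + stoich +
    matrix(rnorm(n * ncol(P), 0, config$noise_sd_log2), n, ncol(P))
  L[, isB] <- L[, isB] + effects
  M <- 2^L
  rownames(M) <- ids
  ptruth <- proteome$truth[match(parent, proteome$truth$id), ]
  truth <- data.frame(id = ids, parent = parent,
                      site_regulated = seq_len(n) %in% reg_idx,
                      site_effect = effects,
                      parent_regulated = ptruth$regulated,
                      parent_effect = ptruth$true_log2fc,
                      stringsAsFactors = FALSE)
  list(matrix = reporter_matrix(M, channels = pm$channels), truth = truth)
}

#' Configuration for the competition-pulldown simulator
#'
#' The default dose ladder is the eight-dose design: DMSO vehicle, 10 nM,
#' 30 nM, 100 nM, 300 nM, 1000 nM, 3000 nM and 30,000 nM.
#'
#' @param n_proteins total proteins (targets first).
#' @param n_targets number of true targets.
#' @param dose_ladder concentrations in molar; first entry 0 (vehicle), then
#'   strictly increasing.
#' @param true_kd true dissociation constant(s) in molar (recycled across
#'   targets).
#' @param hill_slope Hill slope of the binding curves (positive).
#' @param depletion_cf bead-depletion correction factor(s) in (0, 1]
#'   (recycled across targets).
#' @param noise_cv multiplicative intensity noise (coefficient of
#'   variation).
#' @param seed integer seed.
#' @return A `pulldown_sim_config` list.
#' @export
pulldown_sim_config <- function(n_proteins = 100L, n_targets = 5L,
                                dose_ladder = c(0, 10, 30, 100, 300, 1000, 3000, 30000) * 1e-9,
                                true_kd = c(2e-8, 5e-8, 1e-7, 5e-7, 2e-6),
                                hill_slope = 1, depletion_cf = 0.5,
                                noise_cv = 0.1, seed = 1L) {
  n_targets <- .check_count(n_targets, "n_targets")
  if (dose_ladder[1L] != 0 || any(diff(dose_ladder[-1L]) <= 0))
    .stopf("dose ladder must start at 0 (vehicle) and then increase strictly")
  if (any(depletion_cf <= 0 | depletion_cf > 1))
    .stopf("depletion_cf must lie in (0, 1]")
  structure(list(
    n_proteins = .check_count(n_proteins, "n_proteins", min = 1L),
    n_targets = n_targets,
    dose_ladder = as.numeric(dose_ladder),
    true_kd = rep_len(.check_num(true_kd, "true_kd", min = 0, len = length(true_kd)),
                      max(n_targets, 1L)),
    hill_slope = .check_num(hill_slope, "hill_slope", min = .Machine$double.xmin),
    depletion_cf = rep_len(as.numeric(depletion_cf), max(n_targets, 1L)),
    noise_cv = .check_num(noise_cv, "noise_cv", min = 0),
    seed = .check_count(seed, "seed")), class = "pulldown_sim_config")
}

.cv_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate competition-pulldown dose series
#'
#' Target proteins follow the residual-binding law
#' `r(c) = 1 / (1 + (c / Kd_eff)^hill)` with `Kd_eff = true_kd /
#' depletion_cf`, so that a fitted EC50 multiplied by the correction factor
#' recovers the true Kd. Non-targets have dose-independent ratios of 1 (up to
#' noise) and no bead depletion (cf = 1). The vehicle PD intensity is the
#' series baseline; the consecutive-pulldown PDPD intensity equals
#' `PD * depletion_cf`. All intensities carry multiplicative log-normal noise
#' of the given coefficient of variation.
#'
#' @param config a [pulldown_sim_config()].
#' @return List with `series` (list of [pulldown_series]) and `truth`
#'   (protein, is_target, true_kd, true_cf).
#' @export
gen_pulldown_series <- function(config = pulldown_sim_config()) {
  stopifnot(inherits(config, "pulldown_sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins; nt <- config$n_targets
  doses <- config$dose_ladder
  ids <- sprintf("T%03d", seq_len(n))
  is_target <- seq_len(n) <= nt
  kd <- ifelse(is_target, rep_len(config$true_kd, n), NA_real_)
  cf <- ifelse(is_target, rep_len(config$depletion_cf, n), 1)
  base <- 2^rnorm(n, 21, 1.2)
  up <- ifelse(is_target, sample(5:30, n, replace = TRUE),
               sample(c(1:4, 5:20), n, replace = TRUE))
  series <- vector("list", n)
  for (i in seq_len(n)) {
    r <- if (is_target[i]) {
      kd_eff <- kd[i] / cf[i]
      1 / (1 + (doses / kd_eff)^config$hill_slope)
    } else rep(1, length(doses))
    ints <- base[i] * r * .cv_noise(length(doses), config$noise_cv)
    pd <- base[i] * .cv_noise(1L, config$noise_cv)
    pdpd <- pd * cf[i] * .cv_noise(1L, config$noise_cv)
    series[[i]] <- pulldown_series(ids[i], doses, ints, pd = pd, pdpd = pdpd,
                                   unique_peptides = up[i],
                                   msms = up[i] * sample(2:6, 1L))
  }
  truth <- data.frame(protein = ids, is_target = is_target, true_kd = kd,
                      true_cf = ifelse(is_target, cf, NA_real_),
                      stringsAsFactors = FALSE)
  list(series = series, truth = truth)
}

#' Configuration for the coculture-plate simulator
#'
#' Defaults emulate a 384-well coculture screen plate with 16 neutral (DMSO)
#' and 16 stimulator (mIL-2) control wells.
#'
#' @param n_compounds number of compound wells (one compound each).
#' @param n_neutral,n_stimulator control well counts (at least 2 each).
#' @param true_effects `data.frame(compound, effect_prolif, effect_ifng)` of
#'   true percent effects, or `NULL` to draw them (mostly inactive, a few
#'   strong actives).
#' @param plate_noise_sd well noise SD in percent-effect units.
#' @param seed integer seed.
#' @return A `plate_sim_config` list.
#' @export
plate_sim_config <- function(n_compounds = 352L, n_neutral = 16L,
                             n_stimulator = 16L, true_effects = NULL,
                             plate_noise_sd = 5, seed = 1L) {
  n_neutral <- .check_count(n_neutral, "n_neutral", min = 2L)
  n_stimulator <- .check_count(n_stimulator, "n_stimulator", min = 2L)
  structure(list(
    n_compounds = .check_count(n_compounds, "n_compounds"),
    n_neutral = n_neutral, n_stimulator = n_stimulator,
    true_effects = true_effects,
    plate_noise_sd = .check_num(plate_noise_sd, "plate_noise_sd", min = 0),
    seed = .check_count(seed, "seed")), class = "plate_sim_config")
}

#' Simulate a coculture screen plate
#'
#' Control wells are drawn around their role means (neutral = suppressed
#' T-cell activity, stimulator = full activity); compound wells sit at their
#' true percent effect on the control-defined scale plus noise. Both readouts
#' (proliferation and IFN-gamma) are generated.
#'
#' @param config a [plate_sim_config()].
#' @return List with `plate` (data frame: well, role, compound, prolif, ifng)
#'   and `truth` (the true percent effects).
#' @export
gen_plate <- function(config = plate_sim_config()) {
  stopifnot(inherits(config, "plate_sim_config"))
  set.seed(config$seed)
  nc <- config$n_compounds
  te <- config$true_effects
  if (is.null(te)) {
    eff <- function(n) {
      e <- rnorm(n, 0, 8)
      act <- runif(n) < 0.03
      e[act] <- runif(sum(act), 55, 100)
      e
    }
    te <- data.frame(compound = sprintf("CPD%04d", seq_len(nc)),
                     effect_prolif = eff(nc), effect_ifng = eff(nc),
                     stringsAsFactors = FALSE)
  } else {
    stopifnot(nrow(te) == nc)
  }
  scales <- list(prolif = c(neutral = 2000, stim = 20000),
                 ifng = c(neutral = 500, stim = 8000))
  n_wells <- nc + config$n_neutral + config$n_stimulator
  role <- c(rep("neutral", config$n_neutral), rep("stimulator", config$n_stimulator),
            rep("compound", nc))
  plate <- data.frame(well = sprintf("W%03d", seq_len(n_wells)), role = role,
                      compound = c(rep(NA_character_, config$n_neutral + config$n_stimulator),
                                   te$compound), stringsAsFactors = FALSE)
  for (ro in c("prolif", "ifng")) {
    sc <- scales[[ro]]
    span <- sc[["stim"]] - sc[["neutral"]]
    noise <- rnorm(n_wells, 0, config$plate_noise_sd / 100 * span)
    raw <- numeric(n_wells)
    raw[role == "neutral"] <- sc[["neutral"]]
    raw[role == "stimulator"] <- sc[["stim"]]
    raw[role == "compound"] <- sc[["neutral"]] +
      te[[paste0("effect_", ro)]] / 100 * span
    plate[[ro]] <- raw + noise
  }
  list(plate = plate, truth = te)
}

#' Configuration for the SIP solvent-gradient simulator
#'
#' Defaults emulate the 15-channel SIP design: five conditions (vehicle, two
#' active-compound doses, two inactive-analog doses) in three replicates,
#' pooled in silico over the eight-step solvent gradient 8-22%.
#'
#' @param n_proteins number of proteins.
#' @param n_stabilized number of proteins stabilized by the active compound.
#' @param solvent_grid solvent percentages of the denaturation gradient.
#' @param midpoint_range interval the per-protein precipitation midpoints are
#'   drawn from (percent solvent); a range outside the grid span triggers a
#'   warning.
#' @param midpoint_shift midpoint shift (percentage points) of stabilized
#'   proteins at the full active dose; scaled by each condition's
#'   `shift_weight`.
#' @param n_replicates replicates per condition.
#' @param conditions `data.frame(name, shift_weight)`; defaults to vehicle,
#'   cmpd2 at 3x and 10x EC50 (weights 0.5 and 1) and cmpd3 at two doses
#'   (weight 0, inactive).
#' @param noise_sd_log2 replicate noise SD on log2 pooled intensity.
#' @param transition_width logistic width of the precipitation transition
#'   (percent solvent).
#' @param seed integer seed.
#' @return A `sip_sim_config` list.
#' @export
sip_sim_config <- function(n_proteins = 1000L, n_stabilized = 5L,
                           solvent_grid = c(8, 10, 12, 14, 16, 18, 20, 22),
                           midpoint_range = c(10, 20), midpoint_shift = 2,
                           n_replicates = 3L, conditions = NULL,
                           noise_sd_log2 = 0.05, transition_width = 1.5,
                           seed = 1L) {
  if (is.null(conditions))
    conditions <- data.frame(
      name = c("vehicle", "cmpd2_3x", "cmpd2_10x", "cmpd3_10uM", "cmpd3_26uM"),
      shift_weight = c(0, 0.5, 1, 0, 0), stringsAsFactors = FALSE)
  stopifnot(all(c("name", "shift_weight") %in% names(conditions)))
  if (any(diff(solvent_grid) <= 0)) .stopf("solvent grid must be strictly increasing")
  if (midpoint_range[1L] < min(solvent_grid) - 2 || midpoint_range[2L] > max(solvent_grid) + 2)
    .warnf("midpoint_range extends well beyond the solvent grid span")
  structure(list(
    n_proteins = .check_count(n_proteins, "n_proteins", min = 1L),
    n_stabilized = .check_count(n_stabilized, "n_stabilized"),
    solvent_grid = as.numeric(solvent_grid),
    midpoint_range = .check_num(midpoint_range, "midpoint_range", len = 2L),
    midpoint_shift = .check_num(midpoint_shift, "midpoint_shift"),
    n_replicates = .check_count(n_replicates, "n_replicates", min = 1L),
    conditions = conditions,
    noise_sd_log2 = .check_num(noise_sd_log2, "noise_sd_log2", min = 0),
    transition_width = .check_num(transition_width, "transition_width",
                                  min = .Machine$double.xmin),
    seed = .check_count(seed, "seed")), class = "sip_sim_config")
}

# Descending logistic survival of the soluble fraction vs solvent percentage.
.sip_survival <- function(solvent, midpoint, width) {
  1 / (1 + exp((solvent - midpoint) / width))
}

#' Simulate pooled SIP solvent-gradient profiles
#'
#' Per-protein soluble-fraction survival follows a descending logistic in
#' solvent percentage with a per-protein midpoint drawn from
#' `midpoint_range`. Under conditions with a positive `shift_weight`
#' (active compound), stabilized proteins have their midpoint shifted right
#' by `midpoint_shift * shift_weight`. The reported intensity per sample is
#' `baseline x mean survival over the solvent grid` (in-silico equal-amount
#' pooling); replicates add log-normal noise.
#'
#' @param config a [sip_sim_config()].
#' @return List with `matrix` (a [reporter_matrix], channels labeled by
#'   condition and replicate) and `truth` (protein, stabilized, midpoint).
#' @export
gen_solvent_profiles <- function(config = sip_sim_config()) {
  stopifnot(inherits(config, "sip_sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("S%05d", seq_len(n))
  stab <- seq_len(n) %in% sample.int(n, config$n_stabilized)
  mid <- runif(n, config$midpoint_range[1L], config$midpoint_range[2L])
  base <- 2^rnorm(n, 20, 1.5)
  conds <- config$conditions
  nrep <- config$n_replicates
  labels <- as.vector(t(outer(conds$name, seq_len(nrep), paste, sep = "_r")))
  condition <- rep(conds$name, each = nrep)
  M <- matrix(NA_real_, n, length(labels))
  for (j in seq_along(conds$name)) {
    shift <- ifelse(stab, config$midpoint_shift * conds$shift_weight[j], 0)
    pooled <- vapply(seq_len(n), function(i)
      mean(.sip_survival(config$solvent_grid, mid[i] + shift[i],
                         config$transition_width)), numeric(1))
    for (r in seq_len(nrep)) {
      k <- (j - 1L) * nrep + r
      M[, k] <- base * pooled * 2^rnorm(n, 0, config$noise_sd_log2)
    }
  }
  rownames(M) <- ids
  colnames(M) <- labels
  channels <- data.frame(label = labels, condition = condition,
                         plex = 1L, bridge = FALSE, role = "sample",
                         stringsAsFactors = FALSE)
  rows <- data.frame(id = ids, gene = NA_character_,
                     unique_peptides = sample(2:30, n, replace = TRUE),
                     msms = sample(2:200, n, replace = TRUE),
                     contaminant = FALSE, reverse = FALSE, only_by_site = FALSE,
                     stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, stabilized = stab, midpoint = mid,
                      stringsAsFactors = FALSE)
  list(matrix = reporter_matrix(M, rows = rows, channels = channels), truth = truth)
}

#' Read a simulator configuration from YAML or JSON
#'
#' @param path path to a `.yml`/`.yaml`/`.json` file whose top-level keys are
#'   arguments of the corresponding `*_sim_config()` constructor.
#' @param type one of `"profile"`, `"pulldown"`, `"plate"`, `"sip"`.
#' @return The corresponding config object.
#' @export
read_sim_config <- function(path, type = c("profile", "pulldown", "plate", "sip")) {
  type <- match.arg(type)
  args <- yaml::read_yaml(path)  # yaml is a superset of json for this use
  ctor <- switch(type, profile = profile_sim_config,
                 pulldown = pulldown_sim_config,
                 plate = plate_sim_config, sip = sip_sim_config)
  if (type == "sip" && !is.null(args$conditions))
    args$conditions <- as.data.frame(do.call(rbind, lapply(args$conditions, as.data.frame)))
  do.call(ctor, args)
}
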