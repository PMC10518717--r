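#' Run the analysis pipeline from a configuration
#'
#' Thin orchestration layer wiring the package's stages. The configuration is
#' a named list (or path to a YAML file) with elements `seed`, `outdir`, and
#' `stages`, itself a named list selecting among:
#'
#' * `simulate_profile`: arguments of [profile_sim_config()]; writes the
#'   simulated reporter matrix and ground truth.
#' * `diffexp`: arguments of [test_config()] plus optional `input` (a TSV
#'   written by a previous `simulate_profile` run; default: the in-memory
#'   result of that stage); writes the differential-expression table.
#' * `simulate_plate` / `screen`: [plate_sim_config()] arguments and hit
#'   calling with `threshold`.
#' * `simulate_pulldown` / `pulldown`: [pulldown_sim_config()] arguments and
#'   [fit_pulldown()].
#' * `simulate_sip` / `sip`: [sip_sim_config()] arguments and
#'   [stabilization_analysis()] with `reference`.
#'
#' Stages are executed in dependency order; every output file carries a
#' provenance header (`# mdscreen <version>; seed=<seed>; config=<hash>`);
#' the log records row counts after every filter. The first failing stage
#' aborts with an error naming the stage.
#'
#' @param config named list or path to a YAML config file.
#' @param dry_run if `TRUE`, print the resolved plan and write nothing.
#' @return Invisibly, a named list of written file paths (empty for a dry
#'   run).
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  seed <- .check_count(config$seed %||% 1L, "seed")
  outdir <- config$outdir %||% "."
  stages <- config$stages %||% list()
  if (!length(stages)) .stopf("config selects no stages")
  order_all <- c("simulate_profile", "diffexp", "simulate_plate", "screen",
                 "simulate_pulldown", "pulldown", "simulate_sip", "sip")
  unknown <- setdiff(names(stages), order_all)
  if (length(unknown)) .stopf("unknown stage(s): %s", paste(unknown, collapse = ", "))
  plan <- order_all[order_all %in% names(stages)]
  chash <- .config_hash(config)
  if (dry_run) {
    cat(sprintf("pipeline plan (seed %d, outdir %s, config %s):\n", seed, outdir, chash))
    for (st in plan) cat(" -", st, "\n")
    return(invisible(list()))
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outputs <- list()
  state <- new.env(parent = emptyenv())
  for (st in plan) {
    args <- stages[[st]]
    args <- if (is.list(args)) args else list()
    outputs[[st]] <- tryCatch(
      .run_stage(st, args, seed, outdir, chash, state),
      error = function(e) .stopf("stage '%s' failed: %s", st, conditionMessage(e)))
  }
  invisible(outputs)
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(config), collapse = ""), tf)
  unname(substr(tools::md5sum(tf), 1, 8))
}

.write_tsv <- function(df, path, seed, chash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mdscreen %s; seed=%d; config=%s",
                     as.character(utils::packageVersion("mdscreen")), seed, chash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a pipeline output TSV (skipping the provenance header)
#'
#' @param path file written by [run_pipeline()].
#' @return A data frame.
#' @export
read_pipeline_tsv <- function(path) {
  if (!file.exists(path)) .stopf("input path not found: %s", path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, check.names = FALSE)
}

.run_stage <- function(st, args, seed, outdir, chash, state) {
  p <- function(f) file.path(outdir, f)
  switch(st,
    simulate_profile = {
      args$seed <- args$seed %||% seed
      sim <- gen_tmt_profile(do.call(profile_sim_config, args))
      state$profile <- sim
      long <- data.frame(id = sim$matrix$rows$id, sim$matrix$intensity,
                         check.names = FALSE)
      c(matrix = .write_tsv(long, p("profile_matrix.tsv"), seed, chash),
        truth = .write_tsv(sim$truth, p("profile_truth.tsv"), seed, chash))
    },
    diffexp = {
      if (!is.null(args$input)) {
        if (!file.exists(args$input)) .stopf("input path not found: %s", args$input)
        tab <- read_pipeline_tsv(args$input)
        M <- as.matrix(tab[, -1, drop = FALSE]); rownames(M) <- tab[[1L]]
        labels <- args$labels %||% sub("[0-9]+$", "", colnames(M))
      } else {
        if (is.null(state$profile)) .stopf("no profile available; run simulate_profile or give 'input'")
        M <- state$profile$matrix$intensity
        labels <- state$profile$matrix$channels$condition
      }
      cfgargs <- args[names(args) %in% c("alpha", "s0", "n_permutations", "correction")]
      cfgargs$seed <- args$seed %||% seed
      res <- differential_expression(log2(M), labels, do.call(test_config, cfgargs))
      message(sprintf("diffexp: %d rows tested, %d significant",
                      nrow(res), sum(res$significant, na.rm = TRUE)))
      c(result = .write_tsv(as.data.frame(res), p("diffexp.tsv"), seed, chash))
    },
    simulate_plate = {
      args$seed <- args$seed %||% seed
      sim <- gen_plate(do.call(plate_sim_config, args))
      state$plate <- sim
      c(plate = .write_tsv(sim$plate, p("plate.tsv"), seed, chash),
        truth = .write_tsv(sim$truth, p("plate_truth.tsv"), seed, chash))
    },
    screen = {
      plate <- if (!is.null(args$input)) {
        if (!file.exists(args$input)) .stopf("input path not found: %s", args$input)
        read_pipeline_tsv(args$input)
      } else {
        if (is.null(state$plate)) .stopf("no plate available; run simulate_plate or give 'input'")
        state$plate$plate
      }
      eff <- normalize_plate(plate)
      hits <- call_hits(eff, threshold = args$threshold %||% 50)
      message(sprintf("screen: %d compounds, %d hits", nrow(hits), sum(hits$hit)))
      c(hits = .write_tsv(hits, p("screen_hits.tsv"), seed, chash))
    },
    simulate_pulldown = {
      args$seed <- args$seed %||% seed
      sim <- gen_pulldown_series(do.call(pulldown_sim_config, args))
      state$pulldown <- sim
      flat <- do.call(rbind, lapply(sim$series, function(s)
        data.frame(protein = s$protein, dose = s$doses, intensity = s$intensities,
                   pd = s$pd, pdpd = s$pdpd, unique_peptides = s$unique_peptides,
                   stringsAsFactors = FALSE)))
      c(series = .write_tsv(flat, p("pulldown_series.tsv"), seed, chash),
        truth = .write_tsv(sim$truth, p("pulldown_truth.tsv"), seed, chash))
    },
    pulldown = {
      if (is.null(state$pulldown)) .stopf("no pulldown series available; run simulate_pulldown")
      res <- fit_pulldown(state$pulldown$series)
      message(sprintf("pulldown: %d proteins fit, %d annotated targets",
                      nrow(res), sum(res$target)))
      c(result = .write_tsv(as.data.frame(res), p("pulldown_fits.tsv"), seed, chash))
    },
    simulate_sip = {
      args$seed <- args$seed %||% seed
      sim <- gen_solvent_profiles(do.call(sip_sim_config, args))
      state$sip <- sim
      long <- data.frame(id = sim$matrix$rows$id, sim$matrix$intensity,
                         check.names = FALSE)
      c(matrix = .write_tsv(long, p("sip_matrix.tsv"), seed, chash),
        truth = .write_tsv(sim$truth, p("sip_truth.tsv"), seed, chash))
    },
    sip = {
      if (is.null(state$sip)) .stopf("no SIP matrix available; run simulate_sip")
      x <- state$sip$matrix
      x <- filter_entries(x, filter_rules(min_unique_peptides = 2L))
      x <- median_center(x)$matrix
      res <- stabilization_analysis(x, reference = args$reference %||% "vehicle",
                                    alpha = args$alpha %||% 0.05)
      message(sprintf("sip: %d tests, %d significant", nrow(res),
                      sum(res$significant, na.rm = TRUE)))
      c(result = .write_tsv(as.data.frame(res), p("sip_results.tsv"), seed, chash))
    },
    .stopf("unhandled stage '%s'", st))
}
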