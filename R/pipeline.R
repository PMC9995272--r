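default_run_config <- function() {
  list(
    outdir = "polwave_out",
    stages = c("simulate", "pausing", "halflife", "wave", "velocity"),
    seed = 1L,
    sim = list(),
    paths = list(genes = NULL, samples = NULL, tracks_dir = NULL),
    pausing = list(promoter_window = c(-50, 300), body_offset = 300),
    halflife = list(window = c(0, 300), rpkm_min = 1, sigma_max = 0.05),
    wave = list(region_kb = 120, trim_fraction = 0.1, grid_bp = 100,
                exclusion_kb = 2, rpm_min = 100, anchor_kb = 10.3),
    velocity = list(n_bins = 100, body_offset = 300)
  )
}

known_stages <- c("simulate", "pausing", "halflife", "wave", "velocity")

#' Validate and resolve a pipeline configuration
#'
#' Accepts a named list or a YAML file path, merges it over the package
#' defaults, and reports unknown keys (warnings - forward compatible),
#' out-of-range values and missing inputs (errors). Defaults mirror the
#' analysis settings used throughout: 300-bp promoter window, RPKM > 1,
#' sigma < 0.05, 100 rpm, 10-kb anchoring, triptolide 0/5/10/20/40 min and
#' DRB release 0/10/20/30 min.
#'
#' @param config named list or path to a YAML file.
#' @return list with `config` (fully resolved, defaults materialized) and
#'   `issues` (`data.frame` with `level`, `key`, `message`; empty when
#'   clean). Unknown keys produce `"warning"` rows, invalid values
#'   `"error"` rows.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) stop("unparseable config: ",
                                                conditionMessage(e)))
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- default_run_config()
  issues <- data.frame(level = character(), key = character(),
                       message = character())
  note <- function(level, key, message)
    rbind(issues, data.frame(level = level, key = key, message = message))

  sim_keys <- setdiff(names(formals(sim_config)), "")
  known <- list(sim = sim_keys, paths = names(defaults$paths),
                pausing = names(defaults$pausing),
                halflife = names(defaults$halflife),
                wave = names(defaults$wave),
                velocity = names(defaults$velocity))
  for (k in names(config)) {
    if (!k %in% names(defaults)) {
      issues <- note("warning", k, "unknown top-level key (ignored)")
    } else if (k %in% names(known) && is.list(config[[k]])) {
      for (kk in setdiff(names(config[[k]]), known[[k]]))
        issues <- note("warning", paste(k, kk, sep = "."),
                       "unknown key (ignored)")
    }
  }
  cfg <- utils::modifyList(defaults, config[names(config) %in%
                                              names(defaults)])
  bad_stage <- setdiff(cfg$stages, known_stages)
  if (length(bad_stage))
    issues <- note("error", "stages",
                   paste("unknown stage(s):", paste(bad_stage, collapse = ", ")))
  if (cfg$wave$trim_fraction >= 0.5 || cfg$wave$trim_fraction < 0)
    issues <- note("error", "wave.trim_fraction", "must be in [0, 0.5)")
  if (cfg$halflife$sigma_max <= 0)
    issues <- note("error", "halflife.sigma_max", "must be > 0")
  if (!"simulate" %in% cfg$stages) {
    for (p in c("genes", "samples", "tracks_dir")) {
      v <- cfg$paths[[p]]
      if (is.null(v))
        issues <- note("error", paste0("paths.", p),
                       "required when the simulate stage is not run")
      else if (!file.exists(v))
        issues <- note("error", paste0("paths.", p),
                       paste("path does not exist:", v))
    }
  }
  simcfg <- tryCatch(do.call(sim_config,
                             c(cfg$sim[names(cfg$sim) %in% sim_keys],
                               list(seed = cfg$seed))),
                     error = function(e) e)
  if (inherits(simcfg, "error"))
    issues <- note("error", "sim", conditionMessage(simcfg))
  list(config = cfg, issues = issues)
}

ppmsg <- function(...) message("[polwave] ", sprintf(...))

#' Run the analysis pipeline from one configuration
#'
#' Executes the requested stages in dependency order - simulate (fixture
#' generation), pausing, halflife, wave, velocity - and writes a run
#' manifest (`manifest.json`) recording the resolved parameters, package
#' version and an MD5 checksum of every output file. With the same
#' configuration and seed, reruns produce byte-identical manifests.
#'
#' When the simulate stage is not requested, `paths$genes` (BED12),
#' `paths$samples` (sample sheet TSV) and `paths$tracks_dir` (bedGraph
#' pairs) supply the inputs.
#'
#' @param config named list or YAML path (see [validate_config()]).
#' @param stages optional character vector overriding `config$stages`.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), stages = NULL) {
  vc <- validate_config(config)
  errs <- vc$issues[vc$issues$level == "error", ]
  if (nrow(errs))
    stop("invalid configuration:\n",
         paste(sprintf("  %s: %s", errs$key, errs$message), collapse = "\n"))
  cfg <- vc$config
  if (!is.null(stages)) cfg$stages <- stages
  cfg$stages <- known_stages[known_stages %in% cfg$stages]
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  add_out <- function(paths) outputs <<- c(outputs, unname(paths))

  sim_keys <- setdiff(names(formals(sim_config)), "")
  simcfg <- do.call(sim_config, c(cfg$sim[names(cfg$sim) %in% sim_keys],
                                  list(seed = cfg$seed)))

  fixture_dir <- file.path(outdir, "fixture")
  genes <- truth <- NULL
  mnet_tracks <- tt_tracks <- ss_tracks <- list()

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", function() {
      ppmsg("simulate: %d genes, seed %d", simcfg$n_genes, simcfg$seed)
      sim <- simulate_genome(simcfg)
      genes <<- sim$genes; truth <<- sim$truth
      mnet_tracks <<- simulate_triptolide_timecourse(genes, truth, simcfg)
      tt_tracks <<- simulate_drb_release(genes, truth, simcfg)
      ss_tracks <<- lapply(seq_len(simcfg$replicates), function(r)
        simulate_steady_state_tt(genes, truth, simcfg, replicate = r))
      write_fixture(fixture_dir, genes, truth,
                    c(mnet_tracks, tt_tracks, ss_tracks))
      add_out(c(file.path(fixture_dir, c("genes.bed", "truth.tsv",
                                         "samples.tsv")),
                list.files(fixture_dir, "bedgraph$", full.names = TRUE)))
    })
  } else {
    run_stage("load", function() {
      genes <<- read_gene_models(cfg$paths$genes, "bed12")
      sheet <- read_sample_sheet(cfg$paths$samples)
      all_tracks <- load_tracks(cfg$paths$tracks_dir, sheet)
      mnet_tracks <<- all_tracks[sheet$assay == "mnet"]
      ss <- grepl("_ss_", sheet$sample)
      tt_tracks <<- all_tracks[sheet$assay == "ttseq" & !ss]
      ss_tracks <<- all_tracks[sheet$assay == "ttseq" & ss]
    })
  }

  need_mnet <- any(c("pausing", "halflife", "velocity") %in% cfg$stages)
  if (need_mnet && length(mnet_tracks)) {
    ref <- names(mnet_tracks)[vapply(mnet_tracks, function(tr)
      tr$timepoint_min == 0 & tr$replicate == 1, logical(1))][1]
    mnet_tracks <- apply_scale_factors(
      mnet_tracks, spikein_scale_factors(mnet_tracks, ref))
  }

  if ("pausing" %in% cfg$stages) run_stage("pausing", function() {
    t0 <- mnet_tracks[vapply(mnet_tracks, function(tr) tr$timepoint_min == 0,
                             logical(1))]
    if (!length(t0)) stop("no t = 0 mNET track available")
    tab <- do.call(rbind, lapply(t0, function(tr)
      pausing_index_table(tr, genes,
                          promoter_window = cfg$pausing$promoter_window,
                          body_offset = cfg$pausing$body_offset)))
    path <- file.path(outdir, "pausing_index.tsv")
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    add_out(path)
    ppmsg("pausing: %d records", nrow(tab))
  })

  if ("halflife" %in% cfg$stages) run_stage("halflife", function() {
    if (!length(mnet_tracks)) stop("no mNET time-course tracks available")
    check_timecourse_completeness(mnet_tracks)
    fits <- halflife_table(mnet_tracks, genes,
                           window = cfg$halflife$window,
                           rpkm_min = cfg$halflife$rpkm_min,
                           sigma_max = cfg$halflife$sigma_max)
    path <- file.path(outdir, "halflife.tsv")
    write.table(fits, path, sep = "\t", quote = FALSE, row.names = FALSE)
    add_out(path)
    smry <- halflife_summary(fits)
    spath <- file.path(outdir, "halflife_summary.json")
    jsonlite::write_json(smry$per_condition, spath, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    add_out(spath)
    ppmsg("halflife: %d/%d genes pass filters, mean %.3g min",
          smry$per_condition$n[1], nrow(fits),
          smry$per_condition$mean_half_life_min[1])
  })

  if ("wave" %in% cfg$stages) run_stage("wave", function() {
    if (!length(tt_tracks)) stop("no DRB-release TT tracks available")
    ref <- names(tt_tracks)[vapply(tt_tracks, function(tr)
      tr$timepoint_min == 0 & tr$replicate == 1, logical(1))][1]
    tts <- apply_scale_factors(tt_tracks,
                               spikein_scale_factors(tt_tracks, ref))
    rg <- select_rate_genes(genes)
    if (!nrow(rg)) stop("no genes pass the wave-analysis selection")
    mg <- metagene_rate(tts, rg, region_kb = cfg$wave$region_kb,
                        trim_fraction = cfg$wave$trim_fraction,
                        grid_bp = cfg$wave$grid_bp,
                        exclusion_kb = cfg$wave$exclusion_kb)
    prof <- do.call(rbind, lapply(mg$profiles, function(p)
      data.frame(timepoint_min = p$timepoint_min, offset_bp = p$offsets,
                 raw = p$raw, smooth = p$smooth)))
    ppath <- file.path(outdir, "metagene_profiles.tsv")
    write.table(prof, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
    spath <- file.path(outdir, "wave_peaks.tsv")
    write.table(as.data.frame(mg$series), spath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    rates <- gene_wave_rates(tts, rg, grid_bp = cfg$wave$grid_bp,
                             exclusion_kb = cfg$wave$exclusion_kb,
                             rpm_min = cfg$wave$rpm_min,
                             anchor_kb = cfg$wave$anchor_kb)
    gpath <- file.path(outdir, "gene_rates.tsv")
    write.table(rates, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
    add_out(c(ppath, spath, gpath))
    if (!is.null(mg$fit))
      ppmsg("wave: metagene rate %.3g kb/min; %d/%d genes eligible",
            mg$fit$rate_kb_min, sum(rates$eligible), nrow(rates))
  })

  if ("velocity" %in% cfg$stages) run_stage("velocity", function() {
    if (!length(ss_tracks)) stop("no steady-state TT track available")
    tt <- ss_tracks[[1]]
    mn0 <- mnet_tracks[vapply(mnet_tracks, function(tr)
      tr$timepoint_min == 0 & tr$replicate == 1, logical(1))]
    if (!length(mn0)) stop("no t = 0 mNET track available")
    vt <- velocity_table(tt, mn0[[1]], genes,
                         n_bins = cfg$velocity$n_bins,
                         body_offset = cfg$velocity$body_offset)
    vpath <- file.path(outdir, "velocity.tsv")
    write.table(vt$table, vpath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    rpath <- file.path(outdir, "velocity_ratios.tsv")
    write.table(vt$ratios, rpath, sep = "\t", quote = FALSE,
                row.names = TRUE, col.names = NA)
    add_out(c(vpath, rpath))
    ppmsg("velocity: %d genes", sum(!vt$table$skipped))
  })

  manifest <- list(
    package = "polwave",
    version = as.character(utils::packageVersion("polwave")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg[c("sim", "pausing", "halflife", "wave", "velocity")],
    inputs = cfg$paths,
    outputs = as.list(setNames(
      unname(tools::md5sum(outputs)),
      sub("^/", "", sub(outdir, "", outputs, fixed = TRUE))))
  )
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  ppmsg("manifest written to %s", mpath)
  invisible(manifest)
}

# fail fast on incomplete time-course designs (every timepoint x replicate
# combination must be present)
check_timecourse_completeness <- function(tracks) {
  times <- sort(unique(vapply(tracks, `[[`, numeric(1), "timepoint_min")))
  reps <- sort(unique(vapply(tracks, `[[`, integer(1), "replicate")))
  have <- vapply(tracks, function(tr) paste(tr$timepoint_min, tr$replicate),
                 character(1))
  wanted <- as.vector(outer(times, reps, paste))
  gaps <- setdiff(wanted, have)
  if (length(gaps))
    stop("incomplete time course; missing timepoint x replicate: ",
         paste(gaps, collapse = "; "))
  invisible(TRUE)
}
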