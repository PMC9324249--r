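#' Default end-to-end run configuration
#'
#' Flat list of every knob of the pipeline: cohort design, denoising
#' band, thresholding rule and analysis flags.  Values mirror the
#' defaults of [cohort_spec()], [threshold_spec()] and
#' [hemispheric_analysis()].
#'
#' @param master_seed integer master seed.
#' @return named list (class `run_config`).
#' @export
default_run_config <- function(master_seed = 1L) {
  structure(list(
    n_roi = 136L,
    n_hc = 20L, n_lgg = 30L, n_hgg = 30L,
    n_volumes = 160L, TR = 2.5,
    base_r_within_lobe = 0.45, base_r_within_hemi = 0.06,
    base_r_homotopic = 0.30, base_r_background = 0.02,
    ar_coeff = 0.3,
    lgg_delta_left_global = 0.08, lgg_delta_local = -0.33,
    hgg_delta_right = -0.10,
    low_hz = 0.01, high_hz = 0.1,
    z_stat_threshold = 2, p_threshold = 0.05, positive_only = TRUE,
    alpha_normality = 0.05, paired_lr = TRUE, welch = FALSE,
    master_seed = as.integer(master_seed)
  ), class = "run_config")
}

#' Read / write a flat key = value run configuration file
#'
#' One `key = value` (or `key: value`) pair per line; `#` starts a
#' comment.  Unknown keys are rejected; missing keys keep their
#' defaults.
#'
#' @param path file path.
#' @param config `run_config` list.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) != 2) stop("cannot parse config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
    cfg[[key]] <- if (is.logical(cfg[[key]])) as.logical(val)
                  else if (is.integer(cfg[[key]])) as.integer(val)
                  else as.numeric(val)
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, "")), path)
  invisible(path)
}

#' @noRd
config_cohort_spec <- function(config) {
  cohort_spec(
    n_per_group = c(HC = config$n_hc, LGG = config$n_lgg,
                    HGG = config$n_hgg),
    n_volumes = config$n_volumes, TR = config$TR,
    base_r_within_lobe = config$base_r_within_lobe,
    base_r_within_hemi = config$base_r_within_hemi,
    base_r_homotopic = config$base_r_homotopic,
    base_r_background = config$base_r_background,
    ar_coeff = config$ar_coeff,
    master_seed = config$master_seed
  )
}

#' @noRd
config_effects <- function(config) {
  list(
    HC = effect_spec("HC"),
    LGG = effect_spec("LGG",
                      delta_left_global = config$lgg_delta_left_global,
                      delta_local = config$lgg_delta_local),
    HGG = effect_spec("HGG", delta_right = config$hgg_delta_right)
  )
}

#' @noRd
require_stage <- function(dir, what, path) {
  if (!file.exists(file.path(dir, path))) {
    stop(sprintf("missing input for stage '%s': %s not found; run the previous stage first",
                 what, file.path(dir, path)), call. = FALSE)
  }
}

#' Pipeline stage: simulate the cohort
#'
#' @param config `run_config`.
#' @param dir run directory.
#' @return invisibly, the stage's output directory.
#' @export
stage_simulate <- function(config, dir) {
  parc <- make_parcellation(config$n_roi)
  cohort <- generate_cohort(parc, config_cohort_spec(config),
                            config_effects(config))
  write_cohort(cohort, dir)
  invisible(dir)
}

#' Pipeline stage: connectivity matrices
#'
#' @inheritParams stage_simulate
#' @export
stage_connect <- function(config, dir) {
  require_stage(dir, "connect", "manifest.tsv")
  cohort <- read_cohort(dir)
  out <- file.path(dir, "connectivity")
  dir.create(out, showWarnings = FALSE)
  for (s in cohort$subjects) {
    conn <- connectivity_pipeline(s$data, TR = config$TR,
                                  low_hz = config$low_hz,
                                  high_hz = config$high_hz,
                                  subject_id = s$subject_id)
    write_conn_matrix(conn, file.path(out, paste0(s$subject_id, ".tsv")))
  }
  invisible(out)
}

#' Pipeline stage: graphs and nodal metrics
#'
#' @inheritParams stage_simulate
#' @export
stage_graph <- function(config, dir) {
  require_stage(dir, "graph", "connectivity")
  man <- read_tsv(file.path(dir, "manifest.tsv"))
  tspec <- threshold_spec(config$z_stat_threshold, config$p_threshold,
                          config$positive_only)
  gdir <- file.path(dir, "graphs"); mdir <- file.path(dir, "metrics")
  dir.create(gdir, showWarnings = FALSE)
  dir.create(mdir, showWarnings = FALSE)
  for (sid in man$subject_id) {
    conn <- read_conn_matrix(file.path(dir, "connectivity",
                                       paste0(sid, ".tsv")))
    g <- threshold_graph(conn, tspec)
    write_graph_tsv(g, file.path(gdir, paste0(sid, "_adjacency.tsv")))
    write_tsv(nodal_metrics(g), file.path(mdir, paste0(sid, "_metrics.tsv")))
  }
  invisible(gdir)
}

#' Pipeline stage: group analyses
#'
#' @inheritParams stage_simulate
#' @export
stage_analyze <- function(config, dir) {
  require_stage(dir, "analyze", "graphs")
  require_stage(dir, "analyze", "metrics")
  parc <- read_parcellation(file.path(dir, "parcellation.tsv"))
  man <- read_tsv(file.path(dir, "manifest.tsv"))
  graphs <- lapply(man$subject_id, function(sid) {
    read_graph_tsv(file.path(dir, "graphs", paste0(sid, "_adjacency.tsv")))
  })
  names(graphs) <- man$subject_id
  nodal <- lapply(man$subject_id, function(sid) {
    read_tsv(file.path(dir, "metrics", paste0(sid, "_metrics.tsv")))
  })
  names(nodal) <- man$subject_id

  sm <- cohort_scope_means(graphs, parc)
  hemi <- hemispheric_analysis(sm, man,
                               alpha_normality = config$alpha_normality,
                               paired_lr = config$paired_lr,
                               welch = config$welch)
  lob <- lobar_analysis(nodal, man, parc,
                        alpha_normality = config$alpha_normality,
                        welch = config$welch)
  screen <- confound_screen(sm, man)

  adir <- file.path(dir, "analysis")
  dir.create(adir, showWarnings = FALSE)
  write_tsv(sm, file.path(adir, "scope_means.tsv"))
  write_tsv(hemi, file.path(adir, "hemispheric.tsv"))
  write_tsv(lob, file.path(adir, "lobar.tsv"))
  write_tsv(lobar_direction_table(lob), file.path(adir, "lobar_directions.tsv"))
  write_tsv(screen, file.path(adir, "confound_screen.tsv"))
  invisible(adir)
}

#' Run the full pipeline end to end
#'
#' simulate -> connect -> graph -> analyze, all driven by one flat
#' configuration and one master seed.  Every output file is listed in
#' `run_manifest.json` with an MD5 content hash, alongside a
#' provenance block (configuration, seed, package version).  Stages
#' can be re-run individually with the `stage_*` functions; a stage
#' whose inputs are missing aborts naming the missing input.
#'
#' @param config `run_config` list (see [default_run_config()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the parsed run manifest (list).
#' @export
run_all <- function(config = default_run_config(), dir) {
  stopifnot(!missing(dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(simulate = function() stage_simulate(config, dir),
                 connect = function() stage_connect(config, dir),
                 graph = function() stage_graph(config, dir),
                 analyze = function() stage_analyze(config, dir))
  for (nm in names(stages)) {
    gc_log("stage %s ...", nm)
    tryCatch(stages[[nm]](), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE)
    })
  }
  files <- list.files(dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "run_manifest.json")
  hashes <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    provenance = list(package = "gliomaconn",
                      version = as.character(packageVersion("gliomaconn")),
                      master_seed = config$master_seed,
                      config = config[order(names(config))]),
    files = data.frame(file = files, md5 = unname(hashes),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' In-memory cohort analysis without file round-trips
#'
#' Convenience wrapper used by simulation studies: generates a cohort,
#' runs the connectivity and graph stages in memory and returns the
#' hemispheric analysis together with the intermediate objects.
#'
#' @param config `run_config`.
#' @param keep_conns keep per-subject connectivity matrices in the
#'   result (needed for connectograms).
#' @return list: `parcellation`, `manifest`, `scope_means`,
#'   `hemispheric`, and optionally `conns`, `graphs`, `nodal`.
#' @export
run_cohort_analysis <- function(config = default_run_config(),
                                keep_conns = FALSE) {
  parc <- make_parcellation(config$n_roi)
  cohort <- generate_cohort(parc, config_cohort_spec(config),
                            config_effects(config))
  man <- cohort_manifest(cohort)
  tspec <- threshold_spec(config$z_stat_threshold, config$p_threshold,
                          config$positive_only)
  conns <- lapply(cohort$subjects, function(s) {
    connectivity_pipeline(s$data, TR = config$TR, low_hz = config$low_hz,
                          high_hz = config$high_hz,
                          subject_id = s$subject_id)
  })
  graphs <- lapply(conns, threshold_graph, spec = tspec)
  sm <- cohort_scope_means(graphs, parc)
  hemi <- hemispheric_analysis(sm, man,
                               alpha_normality = config$alpha_normality,
                               paired_lr = config$paired_lr,
                               welch = config$welch)
  out <- list(parcellation = parc, manifest = man, scope_means = sm,
              hemispheric = hemi, graphs = graphs)
  if (keep_conns) out$conns <- conns
  out
}
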