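#' Run configuration
#'
#' Assembles and validates the configuration for the scripted pipeline
#' (`run_synth()` -> `run_metrics()` -> `run_pam()` -> `run_stats()`).
#' Any field can be overridden; unknown fields are rejected, which is the
#' schema check for configs read from JSON.
#'
#' @param out_dir output directory (created if missing).
#' @param seed global integer seed; component substreams derive from it.
#' @param sigma homogeneous conductivity, S/m.
#' @param contact_radius equivalent contact radius for voltage-to-current
#'   conversion, mm.
#' @param metric list: `step_mm`, `aggregator`, `magnitude_threshold`,
#'   `projection_threshold`.
#' @param pam list: `d_min`, `d_max`, `n_samples`, `dt_ms`, `onset_ms`,
#'   `prob_cutoff`.
#' @param stats list: `prob_cutoff`, `min_frac`, `top_k`.
#' @param cohort list passed to [synthetic_cohort_spec()] (minus seed).
#' @param atlas list passed to [synthetic_atlas_spec()] (minus seed).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = "axonmetrics-out", seed = 42, sigma = 0.1,
                       contact_radius = 0.635,
                       metric = list(), pam = list(), stats = list(),
                       cohort = list(), atlas = list()) {
  def <- list(
    metric = list(step_mm = 0.5, aggregator = "peak",
                  magnitude_threshold = 200, projection_threshold = 125),
    pam = list(d_min = 1, d_max = 4, n_samples = 10, dt_ms = 0.005,
               onset_ms = 0.1, prob_cutoff = 0.5),
    stats = list(prob_cutoff = 0.5, min_frac = 0.2, top_k = 100),
    cohort = list(), atlas = list())
  merge1 <- function(base, user, what) {
    bad <- setdiff(names(user), c(names(base), switch(what,
      cohort = names(formals(synthetic_cohort_spec)),
      atlas = names(formals(synthetic_atlas_spec)), character(0))))
    if (length(bad) > 0) {
      abort(paste0("unknown config key(s) in ", what, ": ",
                   paste(bad, collapse = ", ")))
    }
    utils::modifyList(base, user)
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), sigma = sigma,
    contact_radius = contact_radius,
    metric = merge1(def$metric, metric, "metric"),
    pam = merge1(def$pam, pam, "pam"),
    stats = merge1(def$stats, stats, "stats"),
    cohort = cohort, atlas = atlas),
    class = "run_config")
}

#' @rdname run_config
#' @param path JSON file holding the fields of `run_config()`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j)
}

cfg_path <- function(config, ...) file.path(config$out_dir, ...)

write_csv9 <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) fmt_num(x))
  readr::write_csv(df, path)
  path
}

#' Generate the synthetic study inputs
#'
#' Writes the atlas (native format), the mirror map, the per-stimulation
#' protocols, the reference electrode, and the cohort table under the
#' configured output directory.  Fully deterministic under the config
#' seed.
#'
#' @param config a [run_config()].
#' @return the config, invisibly; files land in `config$out_dir`.
#' @export
run_synth <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  aspec <- do.call(synthetic_atlas_spec,
                   utils::modifyList(config$atlas,
                                     list(seed = substream(config$seed, "atlas-spec"))))
  electrode <- make_electrode(tip = aspec$lead_tip, axis = aspec$lead_axis)
  atlas <- make_synthetic_atlas(aspec, electrode)
  cspec <- do.call(synthetic_cohort_spec,
                   utils::modifyList(config$cohort,
                                     list(seed = substream(config$seed, "cohort-spec"))))
  coh <- make_cohort(cspec, atlas, electrode, sigma = config$sigma)

  write_fibers(atlas, cfg_path(config, "atlas"))
  write_csv9(attr(atlas, "mirror_map"), cfg_path(config, "mirror_map.csv"))
  jsonlite::write_json(
    list(tip = electrode$tip, axis = electrode$axis,
         radius = electrode$radius,
         contacts = purrr::pmap(electrode$contacts, function(id, x, y, z)
           list(id = id, position_mm = c(x, y, z)))),
    cfg_path(config, "electrode.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  dir.create(cfg_path(config, "protocols"), showWarnings = FALSE)
  for (sid in names(coh$protocols)) {
    write_protocol(coh$protocols[[sid]],
                   cfg_path(config, "protocols", paste0(sid, ".json")))
  }
  write_csv9(coh$cohort, cfg_path(config, "cohort.csv"))
  jsonlite::write_json(
    list(seed = config$seed, n_stimulations = nrow(coh$cohort),
         n_fibers = length(unique(atlas$fiber_id)),
         effect_pathway = cspec$effect_pathway),
    cfg_path(config, "synth_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(config)
}

load_run_inputs <- function(config) {
  atlas <- read_fibers(cfg_path(config, "atlas.fib.tsv"))
  cohort <- readr::read_csv(cfg_path(config, "cohort.csv"),
                            show_col_types = FALSE)
  proto_files <- list.files(cfg_path(config, "protocols"),
                            full.names = TRUE, pattern = "\\.json$")
  protocols <- lapply(proto_files, read_protocol)
  names(protocols) <- sub("\\.json$", "", basename(proto_files))
  mirror_map <- NULL
  mm_path <- cfg_path(config, "mirror_map.csv")
  if (file.exists(mm_path)) {
    mirror_map <- readr::read_csv(mm_path, show_col_types = FALSE)
  }
  list(atlas = atlas, cohort = cohort, protocols = protocols,
       mirror_map = mirror_map)
}

stim_field <- function(config, protocol) {
  point_source_field(
    protocol_sources(protocol, config$sigma, config$contact_radius),
    config$sigma)
}

stim_hemisphere <- function(protocol) {
  if (mean(protocol$contacts$x) < 0) "left" else "right"
}

#' Field-metric stage: per-stimulation fibre metric tables
#'
#' For every stimulation protocol, computes the fibre-wise magnitude and
#' projection metrics (value, sigmoid probability, binary call) over the
#' fibres of the stimulated hemisphere and writes one CSV per stimulation
#' under `out_dir/metrics/`.
#'
#' @param config a [run_config()]; `run_synth()` outputs must exist.
#' @return the config, invisibly.
#' @export
run_metrics <- function(config) {
  inp <- load_run_inputs(config)
  dir.create(cfg_path(config, "metrics"), showWarnings = FALSE)
  m <- config$metric
  for (sid in names(inp$protocols)) {
    proto <- inp$protocols[[sid]]
    field <- stim_field(config, proto)
    hemi <- stim_hemisphere(proto)
    sub <- inp$atlas[inp$atlas$hemisphere == hemi, ]
    # fibres intersecting this stimulation's lead are not sampled; they
    # receive verdicts from the Euclidean flagged-fibre rule instead
    sub <- flag_fibers(sub, electrode_from_protocol(proto))
    nf <- sub[!sub$flagged, ]
    ac <- proto$contacts[match(proto$roles$id, proto$contacts$id),
                         c("x", "y", "z")]
    tabs <- lapply(c("magnitude", "projection"), function(met) {
      cfgm <- metric_config(met, m$aggregator,
                           threshold = if (met == "magnitude")
                             m$magnitude_threshold else m$projection_threshold,
                           step_mm = m$step_mm)
      fm <- fiber_metrics(nf, field, cfgm)
      fv <- flagged_fiber_rule(sub, fm$fiber_id[fm$binary], ac)
      if (nrow(fv) > 0) {
        info <- fiber_info(sub)
        fm <- dplyr::bind_rows(fm, tibble::tibble(
          fiber_id = fv$fiber_id,
          pathway = info$pathway[match(fv$fiber_id, info$fiber_id)],
          metric = cfgm$metric, aggregator = cfgm$aggregator,
          value = NA_real_, probability = as.numeric(fv$activated),
          binary = fv$activated))
      }
      fm
    })
    out <- dplyr::bind_rows(tabs)
    out$stim_id <- sid
    write_csv9(out[, c("stim_id", "fiber_id", "pathway", "metric",
                       "aggregator", "value", "probability", "binary")],
               cfg_path(config, "metrics", paste0(sid, ".csv")))
  }
  invisible(config)
}

#' Pathway-activation-model stage: per-stimulation pPAM tables
#'
#' Runs the probabilistic cable model over the sampled diameter grid for
#' every non-flagged fibre of the stimulated hemisphere, applies the
#' Euclidean flagged-fibre rule, and writes one CSV per stimulation under
#' `out_dir/pam/` (activation bitstring per fibre, p(A), flag columns).
#'
#' @param config a [run_config()].
#' @return the config, invisibly.
#' @export
run_pam <- function(config) {
  inp <- load_run_inputs(config)
  dir.create(cfg_path(config, "pam"), showWarnings = FALSE)
  p <- config$pam
  for (sid in names(inp$protocols)) {
    proto <- inp$protocols[[sid]]
    field <- stim_field(config, proto)
    hemi <- stim_hemisphere(proto)
    sub <- inp$atlas[inp$atlas$hemisphere == hemi, ]
    sub <- flag_fibers(sub, electrode_from_protocol(proto))
    wf <- pulse_waveform(proto$pulse_width_us, onset_ms = p$onset_ms)
    driven <- proto$roles
    ac <- proto$contacts[match(driven$id, proto$contacts$id),
                         c("x", "y", "z")]
    res <- ppam_atlas(sub, field, wf, prob_cutoff = p$prob_cutoff,
                      active_contacts = ac,
                      d_min = p$d_min, d_max = p$d_max,
                      n_samples = p$n_samples, dt_ms = p$dt_ms)
    res$stim_id <- sid
    res$activation_bits <- vapply(res$activations, function(a)
      paste(as.integer(a), collapse = ""), character(1))
    write_csv9(res[, c("stim_id", "fiber_id", "pathway", "n_samples",
                       "n_activated", "p_a", "activation_bits", "flagged",
                       "flag_rule_applied")],
               cfg_path(config, "pam", paste0(sid, ".csv")))
  }
  invisible(config)
}

read_stage <- function(config, stage) {
  files <- list.files(cfg_path(config, stage), full.names = TRUE,
                      pattern = "\\.csv$")
  dplyr::bind_rows(lapply(files, readr::read_csv, show_col_types = FALSE))
}

#' Group-statistics stage
#'
#' Pools both hemispheres by mirroring left stimulations onto the
#' right-hemisphere fibres, then for each activation metric (thresholded
#' magnitude, thresholded projection, PAM) applies the prevalence filter,
#' the pooled fibre-wise t-test (binary) and its probability-weighted
#' version, and the top-k pathway distribution.  Per-stimulation pathway
#' activation profiles and their pairwise Spearman comparisons across
#' metrics are also written.
#'
#' Outputs under `out_dir`: `fiber_stats.csv`, `profiles.json`,
#' `comparisons.json`, `top_k.json`.
#'
#' @param config a [run_config()].
#' @return the config, invisibly.
#' @export
run_stats <- function(config) {
  inp <- load_run_inputs(config)
  if (is.null(inp$mirror_map)) abort("run_stats needs mirror_map.csv")
  metrics <- read_stage(config, "metrics")
  pam <- read_stage(config, "pam")
  cohort <- inp$cohort
  sc <- config$stats

  long <- list(
    magnitude = metrics |>
      dplyr::filter(.data$metric == "magnitude") |>
      dplyr::transmute(.data$stim_id, .data$fiber_id,
                       p_a = as.numeric(.data$binary), prob = .data$probability),
    projection = metrics |>
      dplyr::filter(.data$metric == "projection") |>
      dplyr::transmute(.data$stim_id, .data$fiber_id,
                       p_a = as.numeric(.data$binary), prob = .data$probability),
    pam = pam |>
      dplyr::filter(!is.na(.data$p_a)) |>
      dplyr::transmute(.data$stim_id, .data$fiber_id, p_a = .data$p_a,
                       prob = .data$p_a))

  # per-stimulation pathway profiles (native hemisphere, before mirroring)
  hemis <- setNames(cohort$hemisphere, cohort$stim_id)
  profiles <- lapply(long, function(df) {
    lapply(split(df, df$stim_id), function(one) {
      hemi <- hemis[[one$stim_id[1]]]
      sub <- inp$atlas[inp$atlas$hemisphere == hemi, ]
      pr <- pathway_profile(sub, one, prob_cutoff = sc$prob_cutoff)
      setNames(pr$pct_activated, pr$pathway)
    })
  })

  stim_ids <- sort(unique(cohort$stim_id))
  pairs <- list(c("magnitude", "pam"), c("projection", "pam"),
                c("magnitude", "projection"))
  comparisons <- lapply(pairs, function(pr) {
    rhos <- vapply(stim_ids, function(sid) {
      a <- profiles[[pr[1]]][[sid]]; b <- profiles[[pr[2]]][[sid]]
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      stats::cor(a, b[names(a)], method = "spearman")
    }, numeric(1))
    ps <- vapply(stim_ids, function(sid) {
      a <- profiles[[pr[1]]][[sid]]; b <- profiles[[pr[2]]][[sid]]
      out <- tryCatch(
        compare_profiles_spearman(
          tibble::tibble(pathway = names(a), pct_activated = unname(a)),
          tibble::tibble(pathway = names(b), pct_activated = unname(b)))$p_value,
        error = function(e) NA_real_)
      out
    }, numeric(1))
    list(pair = paste(pr, collapse = "_vs_"),
         rho = unname(rhos), p = unname(ps),
         mean_rho = mean(rhos, na.rm = TRUE),
         n_significant = sum(ps < 0.05, na.rm = TRUE))
  })
  # paired comparison: are the two field metrics equally similar to PAM?
  ok <- is.finite(comparisons[[1]]$rho) & is.finite(comparisons[[2]]$rho)
  paired <- compare_correlation_sets(comparisons[[1]]$rho[ok],
                                     comparisons[[2]]$rho[ok], clamp = TRUE)

  # fibre filtering on mirrored stimulations
  mirrored <- lapply(long, function(df)
    mirror_stimulations(df, cohort, inp$mirror_map))
  outcomes_for <- function(m) {
    ids <- sort(unique(m$stim_id))
    cohort$outcome_percent[match(ids, cohort$stim_id)]
  }
  right_atlas <- inp$atlas[inp$atlas$hemisphere == "right", ]
  fiber_stats <- list(); top_k <- list()
  for (met in names(mirrored)) {
    df <- mirrored[[met]]
    mat_bin <- activation_matrix(df)
    mat_bin <- (mat_bin >= sc$prob_cutoff) * 1
    y <- outcomes_for(df)
    filt <- prevalence_filter(mat_bin, min_frac = sc$min_frac,
                              prob_cutoff = 0.5)
    keep <- filt$fiber_id[filt$included]
    mat_use <- mat_bin[, as.character(keep), drop = FALSE]
    st <- fiber_ttest(mat_use, y)
    matw <- activation_matrix(
      df |> dplyr::transmute(.data$stim_id, .data$fiber_id, p_a = .data$prob))
    stw <- weighted_fiber_ttest(matw[, as.character(keep), drop = FALSE], y)
    st$weighted <- FALSE; stw$weighted <- TRUE
    st$metric <- met; stw$metric <- met
    fiber_stats[[met]] <- dplyr::bind_rows(st, stw)
    top_k[[met]] <- list(
      binary = as.list(setNames(
        top_fiber_distribution(st, right_atlas, k = sc$top_k)$n_fibers,
        top_fiber_distribution(st, right_atlas, k = sc$top_k)$pathway)),
      weighted = as.list(setNames(
        top_fiber_distribution(stw, right_atlas, k = sc$top_k)$n_fibers,
        top_fiber_distribution(stw, right_atlas, k = sc$top_k)$pathway)))
  }
  fs <- dplyr::bind_rows(fiber_stats)
  write_csv9(fs[, c("metric", "weighted", "fiber_id", "t",
                    "n_act", "n_nonact")],
             cfg_path(config, "fiber_stats.csv"))
  jsonlite::write_json(profiles, cfg_path(config, "profiles.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 9)
  jsonlite::write_json(
    list(pairwise = comparisons,
         paired_field_metrics_vs_pam = as.list(paired)),
    cfg_path(config, "comparisons.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = 9)
  jsonlite::write_json(top_k, cfg_path(config, "top_k.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config)
}

#' Full pipeline with manifest
#'
#' `run_synth()` + `run_metrics()` + `run_pam()` + `run_stats()`, then a
#' manifest recording the tool version, the config, and an MD5 content
#' hash and record count for every output file.  The manifest carries no
#' wall-clock timestamp so a rerun with the same seed is byte-identical.
#'
#' @param config a [run_config()].
#' @return the manifest path, invisibly.
#' @export
run_all <- function(config) {
  run_synth(config)
  run_metrics(config)
  run_pam(config)
  run_stats(config)
  files <- sort(setdiff(
    list.files(config$out_dir, recursive = TRUE),
    "manifest.json"))
  paths <- file.path(config$out_dir, files)
  hashes <- tools::md5sum(paths)
  counts <- vapply(paths, function(p) {
    if (grepl("\\.(csv|tsv)$", p)) length(readLines(p)) - 1L else NA_integer_
  }, integer(1))
  jsonlite::write_json(
    list(tool = "axonmetrics",
         version = as.character(utils::packageVersion("axonmetrics")),
         seed = config$seed,
         config_hash = unname(tools::md5sum(write_json_tmp(
           unclass(config)[setdiff(names(config), "out_dir")]))),
         files = purrr::map2(unname(hashes), unname(counts), function(h, n)
           list(md5 = h, records = if (is.na(n)) NULL else n)) |>
           setNames(files)),
    cfg_path(config, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg_path(config, "manifest.json"))
}

write_json_tmp <- function(x) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(x), tmp, auto_unbox = TRUE, digits = NA)
  tmp
}
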