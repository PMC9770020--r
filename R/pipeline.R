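# End-to-end orchestration: preprocess -> per-band connectivity -> spikes ->
# distances -> pair table -> decay fits -> group statistics, with a
# reproducible run manifest.

#' Build a validated pipeline run configuration
#'
#' @param bands named list of [band_spec()]s (default [default_bands()]).
#' @param event_threshold event-detection threshold in uV (default 0.1).
#' @param spike_z robust z threshold of the spike detector (default 6).
#' @param spike_min_isi_ms spike refractory period (default 50 ms).
#' @param mains_hz notch center frequency (default 60).
#' @param mains_guard frequency interval that no analysis band may overlap
#'   (default `c(55, 65)`, the omitted band around 60 Hz mains).
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest and used by any
#'   stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(bands = default_bands(),
                       event_threshold = 0.1,
                       spike_z = 6, spike_min_isi_ms = 50,
                       mains_hz = 60, mains_guard = c(55, 65),
                       out_dir = tempfile("eventconn_run_"),
                       seed = 1) {
  for (b in bands) {
    if (!is.null(mains_guard) &&
        b$fmin < mains_guard[2] && b$fmax > mains_guard[1])
      stop(sprintf("band %s (%g-%g Hz) overlaps the %g-%g Hz guard band",
                   b$name, b$fmin, b$fmax, mains_guard[1], mains_guard[2]))
  }
  nm <- names(bands)
  for (a in seq_along(bands)) for (b in seq_along(bands)) {
    if (a < b && bands[[a]]$fmax > bands[[b]]$fmin &&
        bands[[b]]$fmax > bands[[a]]$fmin)
      stop("analysis bands ", nm[a], " and ", nm[b], " overlap")
  }
  structure(
    list(bands = bands, event_threshold = event_threshold,
         spike_z = spike_z, spike_min_isi_ms = spike_min_isi_ms,
         mains_hz = mains_hz, mains_guard = mains_guard,
         out_dir = out_dir, seed = seed),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline over a set of patients
#'
#' For each patient: harmonize to 1 kHz, notch mains, band-pass each analysis
#' band, compute windowed pairwise connectivity and its across-window mean,
#' detect spikes and build the coupling-rate matrix, compute inter-contact
#' distances, assemble the pair table, and fit the distance-decay model per
#' band. With two or more patients and both outcome groups present, the
#' mixed-model statistics stage runs on the pooled pair table. All artifacts
#' are written under `config$out_dir` together with a JSON manifest (package
#' version, seed, config hash), making a run reproducible.
#'
#' @param patients list of per-patient lists with elements `recording`
#'   (an `ieeg_recording`), `metadata` (channel table), `patient` (id) and
#'   `outcome` ("SF"/"NSF") — the shape returned by [make_study()].
#' @param config a [run_config()].
#' @return list with `pair_table`, `decay_fits`, `connectivity` (per patient
#'   per band), `spikes`, `stats` (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(patients, config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  all_pairs <- list(); decay_rows <- list()
  conn_out <- list(); spikes_out <- list()

  for (pt in patients) {
    pid <- pt$patient %||% "P01"
    rec <- stage("load", {
      r <- pt$recording
      meta <- validate_channel_metadata(pt$metadata)
      keep <- meta$label[meta$gray_matter == 1L & meta$noise_free == 1L]
      select_channels(r, intersect(r$channel_labels, keep))
    })
    rec <- stage("resample", resample_to_1khz(rec))
    rec <- stage("notch", notch_mains(rec, config$mains_hz))

    conn <- list()
    for (bn in names(config$bands)) {
      band <- config$bands[[bn]]
      conn[[bn]] <- stage(paste0("connectivity:", bn), {
        filtered <- bandpass(rec, band)
        mean_connectivity(
          window_connectivity(filtered, band, config$event_threshold))
      })
      write_labeled_matrix(conn[[bn]]$h,
        file.path(config$out_dir, sprintf("conn_%s_%s.tsv", pid, bn)))
    }
    conn_out[[pid]] <- conn

    spikes <- stage("spikes", {
      trains <- lapply(stats::setNames(seq_len(n_channels(rec)),
                                       rec$channel_labels), function(ch)
        detect_spikes(whiten(rec$data[ch, ]), config$spike_z,
                      config$spike_min_isi_ms))
      spike_coupling_matrix(trains, duration_s(rec))
    })
    spikes_out[[pid]] <- spikes
    spike_df <- do.call(rbind, lapply(names(spikes$counts), function(ch)
      if (spikes$counts[[ch]] > 0)
        data.frame(channel = ch, time_ms = detect_spikes(
          whiten(rec$data[ch, ]), config$spike_z, config$spike_min_isi_ms))))
    if (!is.null(spike_df))
      utils::write.table(spike_df,
        file.path(config$out_dir, sprintf("spikes_%s.tsv", pid)),
        sep = "\t", quote = FALSE, row.names = FALSE)

    meta <- pt$metadata[match(rec$channel_labels, pt$metadata$label), ]
    dmat <- stage("distances", distance_matrix(meta))
    write_labeled_matrix(dmat,
      file.path(config$out_dir, sprintf("distances_%s.tsv", pid)))

    ptab <- stage("pair_table",
      build_pair_table(conn, spikes, dmat, meta, pid,
                       outcome = pt$outcome %||% "SF"))
    all_pairs[[pid]] <- ptab

    for (bn in names(conn)) {
      fit <- try(fit_decay(ptab[[paste0("h_", bn)]], ptab$distance_mm),
                 silent = TRUE)
      if (!inherits(fit, "try-error"))
        decay_rows[[paste(pid, bn)]] <- data.frame(
          patient = pid, band = bn, A = fit$A, tau = fit$tau,
          n_pairs = fit$n_pairs, rmse = fit$rmse)
    }
  }

  pair_table <- tibble::as_tibble(do.call(rbind, all_pairs))
  write_pair_table(pair_table, file.path(config$out_dir, "pair_table.tsv"))
  decay_fits <- if (length(decay_rows))
    tibble::as_tibble(do.call(rbind, decay_rows)) else NULL
  if (!is.null(decay_fits))
    utils::write.table(decay_fits, file.path(config$out_dir, "decay_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  stats_res <- NULL
  if (length(unique(pair_table$patient)) >= 2) {
    stats_res <- tryCatch({
      fit <- fit_mixed_model(pair_table, dependent = "h_high_gamma")
      cons <- marginal_contrasts(fit)
      utils::write.table(cons, file.path(config$out_dir, "stats_contrasts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(fit = fit, contrasts = cons)
    }, error = function(e) {
      warning("statistics stage skipped: ", conditionMessage(e))
      NULL
    })
  }

  manifest <- list(
    package = "eventconn",
    version = as.character(utils::packageVersion("eventconn")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    n_patients = length(patients),
    bands = lapply(config$bands, function(b)
      list(name = b$name, fmin = b$fmin, fmax = b$fmax,
           window_length_s = b$window_length_s)),
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(pair_table = pair_table, decay_fits = decay_fits,
       connectivity = conn_out, spikes = spikes_out,
       stats = stats_res, manifest = manifest)
}

config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg)), tmp)
  unname(tools::md5sum(tmp))
}
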