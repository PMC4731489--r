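#' Write an events table (tab-separated)
#'
#' Serialises a schedule or a simulated recording as a BIDS-inspired
#' events table: one row per event (trial onset, visual stimulus onset,
#' tone onsets, responses), UTF-8, tab-separated, '.' decimal, onsets in
#' ms from run start, deterministic column order.
#'
#' @param x an `erp_schedule` or `erp_recording`.
#' @param path output file.
#' @return the written data frame, invisibly.
#' @export
write_events_tsv <- function(x, path) {
  df <- events_table(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(df)
}

#' Events table of a schedule or recording
#'
#' The in-memory form of the serialised events TSV: one row per event in
#' deterministic order.
#'
#' @param x an `erp_schedule` or `erp_recording`.
#' @return data frame with columns `onset_ms`, `duration_ms`, `level`,
#'   `block`, `trial`, `event_type`, `marker_code` (plus `sample` for
#'   recordings).
#' @export
events_table <- function(x) {
  if (inherits(x, "erp_recording")) {
    ev <- x$events
    df <- data.frame(onset_ms = ev$ms, duration_ms = ev$duration_ms,
                     level = ev$level, block = ev$block, trial = ev$trial,
                     event_type = ev$event_type, marker_code = ev$marker_code,
                     sample = ev$sample, stringsAsFactors = FALSE)
    return(df[order(df$onset_ms, df$event_type), ])
  }
  abort_if(!inherits(x, "erp_schedule"), "cannot serialise object of class %s",
           paste(class(x), collapse = "/"))
  tr <- x$trials
  cfg <- x$config
  rows <- list(
    data.frame(onset_ms = tr$onset_ms, duration_ms = tr$duration_ms,
               level = tr$level, block = tr$block, trial = tr$trial,
               event_type = "trial_onset", marker_code = tr$marker_code,
               stringsAsFactors = FALSE)
  )
  stim <- tr[tr$kind == "stimulus", ]
  rows <- c(rows, list(
    data.frame(onset_ms = stim$onset_ms + cfg$pre_mask_ms,
               duration_ms = cfg$stim_duration_ms, level = stim$level,
               block = stim$block, trial = stim$trial, event_type = "stimulus",
               marker_code = stim$marker_code, stringsAsFactors = FALSE)
  ))
  tone <- stim[stim$tone_slot & stim$tone_pair_type != "silent", ]
  if (nrow(tone) > 0) {
    s1 <- tone$onset_ms + cfg$pre_mask_ms + tone$tone_offset_ms
    rows <- c(rows, list(
      data.frame(onset_ms = s1, duration_ms = cfg$tone_duration_ms,
                 level = tone$level, block = tone$block, trial = tone$trial,
                 event_type = "tone_s1", marker_code = tone$marker_code,
                 stringsAsFactors = FALSE),
      data.frame(onset_ms = s1 + cfg$s1_s2_gap_ms, duration_ms = cfg$tone_duration_ms,
                 level = tone$level, block = tone$block, trial = tone$trial,
                 event_type = "tone_s2", marker_code = tone$marker_code,
                 stringsAsFactors = FALSE)
    ))
  }
  df <- do.call(rbind, rows)
  df[order(df$onset_ms, df$event_type, df$trial), ]
}

#' Read an events table
#'
#' @param path file written by [write_events_tsv()].
#' @return data frame of events.
#' @export
read_events_tsv <- function(path) {
  abort_if(!file.exists(path), "data error: no such file: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("parse error: line %d has %d fields (expected %d)",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_ms", "duration_ms", "level", "block", "trial",
            "event_type", "marker_code")
  missing_cols <- setdiff(need, names(df))
  abort_if(length(missing_cols) > 0, "parse error: missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  df
}

#' Rebuild a schedule from an events table
#'
#' Inverts [write_events_tsv()] for schedule-level tables: trial rows are
#' reconstructed from the `trial_onset` events and their structured marker
#' codes, which carry the full condition tuple.
#'
#' @param events data frame from [read_events_tsv()].
#' @param config the [paradigm_config()] the schedule was generated with.
#' @return an `erp_schedule` (seed `NA`: provenance is the file).
#' @export
schedule_from_events <- function(events, config = paradigm_config()) {
  on <- events[events$event_type == "trial_onset", ]
  on <- on[order(on$onset_ms), ]
  abort_if(nrow(on) == 0, "data error: no trial_onset events in table")
  m <- decode_event_marker(on$marker_code)
  tone_parts <- strsplit(m$tone, "@", fixed = TRUE)
  tr <- data.frame(
    level = m$level, block = m$block, block_mode = m$block_mode,
    trial_in_block = stats::ave(m$block, m$block, FUN = seq_along),
    kind = ifelse(m$image == "none", "baseline", "stimulus"),
    image = m$image, side = m$side, category = m$category,
    distractor = m$distractor,
    trial = seq_len(nrow(on)),
    tone_slot = m$tone != "none",
    tone_offset_ms = vapply(tone_parts, function(p)
      if (length(p) == 2) as.integer(p[2]) else NA_integer_, integer(1)),
    tone_pair_type = vapply(tone_parts, function(p) p[1], character(1)),
    jitter_ms = on$duration_ms - (config$pre_mask_ms + config$stim_duration_ms +
                                  config$response_window_ms + config$end_baseline_min_ms),
    duration_ms = on$duration_ms,
    onset_ms = on$onset_ms,
    stringsAsFactors = FALSE
  )
  level <- tr$level[1]
  tr$expected_button <- "none"
  stim <- tr$kind == "stimulus"
  tr$expected_button[stim] <- response_rule(level, tr$block_mode[stim], tr$kind[stim],
                                            tr$image[stim], tr$side[stim])
  tr$marker_code <- on$marker_code
  blocks <- do.call(rbind, lapply(split(tr[stim, ], tr$block[stim]), function(tb) {
    freq_img <- tb$image[tb$category == "frequent"][1]
    rare_imgs <- unique(tb$image[tb$category == "rare"])
    data.frame(index = tb$block[1], level = level, mode = tb$block_mode[1],
               frequent_image = freq_img,
               frequent_side = tb$side[tb$category == "frequent"][1],
               rare_image_1 = rare_imgs[1],
               rare_image_2 = if (length(rare_imgs) > 1) rare_imgs[2] else NA,
               n_rare_1 = sum(tb$image == rare_imgs[1] & tb$category == "rare"),
               stringsAsFactors = FALSE)
  }))
  rownames(blocks) <- NULL
  structure(list(trials = tr, blocks = blocks, level = level, seed = NA_integer_,
                 config = config),
            class = "erp_schedule")
}

#' Persist a recording (flat binary + JSON sidecar + events TSV)
#'
#' The signal is written as little-endian float32, channel index varying
#' fastest (R column-major order of the channels x samples matrix); the
#' sidecar documents layout, sampling rate, channel names and units; the
#' events table gains a `sample` column.
#'
#' @param recording an `erp_recording`.
#' @param prefix output path prefix (writes `<prefix>.bin`,
#'   `<prefix>.json`, `<prefix>_events.tsv`).
#' @return named character vector of the written paths, invisibly.
#' @export
write_recording <- function(recording, prefix) {
  paths <- c(bin = paste0(prefix, ".bin"), sidecar = paste0(prefix, ".json"),
             events = paste0(prefix, "_events.tsv"))
  con <- file(paths["bin"], "wb")
  writeBin(as.numeric(recording$signal), con, size = 4, endian = "little")
  close(con)
  sidecar <- list(
    srate_hz = recording$srate,
    n_channels = nrow(recording$signal),
    n_samples = ncol(recording$signal),
    channels = recording$channels,
    units = "uV",
    dtype = "float32",
    byte_order = "little",
    layout = "channels_fastest",
    sample_alignment = "sample column is 1-based; onset_ms = (sample - 1) / srate * 1000",
    level = recording$level,
    seed = recording$seed
  )
  jsonlite::write_json(sidecar, paths["sidecar"], auto_unbox = TRUE, pretty = TRUE)
  write_events_tsv(recording, paths["events"])
  invisible(paths)
}

#' Load a recording written by [write_recording()]
#'
#' @param prefix path prefix used at write time.
#' @return an `erp_recording`.
#' @export
read_recording <- function(prefix) {
  sidecar_path <- paste0(prefix, ".json")
  abort_if(!file.exists(sidecar_path), "data error: no sidecar at %s", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(prefix, ".bin"), "rb")
  raw <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  close(con)
  abort_if(length(raw) != n, "data error: binary payload truncated")
  events <- read_events_tsv(paste0(prefix, "_events.tsv"))
  ev <- events
  names(ev)[names(ev) == "onset_ms"] <- "ms"
  # recover condition fields from the marker codes
  m <- decode_event_marker(ev$marker_code)
  tone_parts <- strsplit(m$tone, "@", fixed = TRUE)
  ev$block_mode <- m$block_mode
  ev$image <- m$image; ev$side <- m$side; ev$category <- m$category
  ev$distractor <- m$distractor; ev$button <- m$button; ev$accuracy <- m$accuracy
  ev$tone_pair_type <- vapply(tone_parts, function(p) p[1], character(1))
  ev$tone_offset_ms <- vapply(tone_parts, function(p)
    if (length(p) == 2) as.integer(p[2]) else NA_integer_, integer(1))
  montage <- default_montage()
  if (!setequal(montage$channel, meta$channels))
    montage <- data.frame(channel = meta$channels, x = NA_real_, y = NA_real_)
  structure(list(signal = matrix(raw, nrow = meta$n_channels),
                 srate = meta$srate_hz, channels = meta$channels,
                 events = ev, montage = montage, level = meta$level,
                 seed = meta$seed),
            class = "erp_recording")
}

#' Write a paradigm configuration to JSON
#'
#' @param config a [paradigm_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(config, path) {
  vals <- unclass(config)
  vals$tone_pair_mix <- as.list(vals$tone_pair_mix)  # keep the names in JSON
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a paradigm configuration from JSON
#'
#' Unknown keys are rejected; missing keys fall back to the defaults, so a
#' config file may override only the fields it cares about.
#'
#' @param path JSON file as written by [write_config_json()] (or
#'   hand-written with the same keys).
#' @return a validated [paradigm_config()].
#' @export
read_config_json <- function(path) {
  abort_if(!file.exists(path), "data error: no such config file: %s", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(paradigm_config))
  unknown <- setdiff(names(vals), known)
  abort_if(length(unknown) > 0, "configuration error: unknown key(s): %s",
           paste(unknown, collapse = ", "))
  if (!is.null(vals$tone_pair_mix)) vals$tone_pair_mix <- unlist(vals$tone_pair_mix)
  do.call(paradigm_config, vals)
}

#' Build and write a run manifest
#'
#' Records the configuration hash, seeds, file paths and tool version so a
#' run can be reproduced bit-for-bit for its deterministic stages.
#'
#' @param config a [paradigm_config()].
#' @param seeds named list/vector of the seeds used.
#' @param files named character vector of produced files (must exist).
#' @param path optional output JSON path.
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(config, seeds, files, path = NULL) {
  abort_if(!all(file.exists(files)), "manifest error: missing file(s): %s",
           paste(files[!file.exists(files)], collapse = ", "))
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(config_md5 = hash, seeds = as.list(seeds),
                   files = as.list(files),
                   tool_version = as.character(utils::packageVersion("multierp")),
                   created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
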