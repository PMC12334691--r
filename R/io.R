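#' Write / read a stimulus protocol as JSON
#'
#' Round-trip faithful serialization of a `stim_protocol`.
#'
#' @param protocol A `stim_protocol`.
#' @param path Output JSON path.
#' @return `path`, invisibly (writer); a `stim_protocol` (reader).
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("kind", "frame_rate", "time", "lum_contra", "lum_ipsi",
           "onsets", "conditions", "baseline_lux")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    stop("protocol JSON missing field(s): ", paste(miss, collapse = ", "))
  }
  structure(x, class = "stim_protocol")
}

#' Write / read a pupil trace as CSV
#'
#' Long-format CSV with columns `time`, `area`, `eye`.
#'
#' @param trace A [pupil_trace()].
#' @param path CSV path.
#' @return `path`, invisibly (writer); a `pupil_trace` (reader).
#' @export
write_pupil_csv <- function(trace, path) {
  stopifnot(inherits(trace, "pupil_trace"))
  utils::write.csv(data.frame(time = trace$time, area = trace$area,
                              eye = trace$eye),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pupil_csv
#' @export
read_pupil_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time", "area", "eye")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("pupil CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  pupil_trace(df$time, df$area, eye = df$eye[1])
}

#' Write / read bouton traces as long-format CSV
#'
#' Columns `bouton`, `frame`, `f_raw`, `f_neuropil`; trial sync is stored
#' in a companion JSON manifest next to the CSV.
#'
#' @param traces A `bouton_traces`.
#' @param path CSV path; the sync manifest goes to `<path>.json`.
#' @return `path`, invisibly (writer); a `bouton_traces` (reader).
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "bouton_traces"))
  n_b <- nrow(traces$F_raw); n_f <- ncol(traces$F_raw)
  df <- data.frame(bouton = rep(seq_len(n_b), each = n_f),
                   frame = rep(seq_len(n_f), times = n_b),
                   f_raw = as.vector(t(traces$F_raw)),
                   f_neuropil = as.vector(t(traces$F_neuropil)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(frame_rate = traces$frame_rate,
                            onsets = traces$onsets,
                            conditions = traces$conditions,
                            stim_duration_s = traces$stim_duration_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("bouton", "frame", "f_raw", "f_neuropil")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("trace CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  sync <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ids <- sort(unique(df$bouton))
  n_f <- max(df$frame)
  Fr <- matrix(NA_real_, length(ids), n_f)
  Fn <- matrix(NA_real_, length(ids), n_f)
  for (i in seq_along(ids)) {
    sub <- df[df$bouton == ids[i], ]
    sub <- sub[order(sub$frame), ]
    Fr[i, ] <- sub$f_raw
    Fn[i, ] <- sub$f_neuropil
  }
  structure(list(F_raw = Fr, F_neuropil = Fn,
                 frame_rate = sync$frame_rate, onsets = sync$onsets,
                 conditions = sync$conditions,
                 stim_duration_s = sync$stim_duration_s,
                 bouton_ids = ids, meta = NULL),
            class = "bouton_traces")
}

#' Write / read a pupil-mask stack as multi-page TIFF
#'
#' @param masks `height x width x frames` 0/1 array.
#' @param path TIFF path.
#' @return `path`, invisibly (writer); the array (reader).
#' @export
write_masks_tiff <- function(masks, path) {
  stopifnot(length(dim(masks)) == 3)
  pages <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_masks_tiff
#' @export
read_masks_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , i] <- (p > 0.5) * 1L
  }
  arr
}

#' Run the full simulate -> process -> analyze pipeline
#'
#' Executes the end-to-end analysis on simulated data: builds the flash
#' protocol, simulates pupil and bouton traces, computes per-trial dF/F,
#' filters by RQI, computes the RMI per kept bouton with shuffle-null
#' significance, and writes results plus a manifest to `out_dir`.
#'
#' @param config Named list (or path to a YAML/JSON file) overriding the
#'   defaults: `seed`, `level`, `duration_s`, `n_rep`, `pharmacology`,
#'   `background_mode`, `rqi_threshold`, `n_shuffles`, `axons_per_type`,
#'   `boutons_per_axon`, `noise_sd`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the manifest and the RMI results table.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("plr_run_")) {
  if (is.character(config)) {
    config <- if (grepl("[.]ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML config requires the 'yaml' package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(seed = 1, level = 20, duration_s = 3, n_rep = 6,
                   pharmacology = "NONE", background_mode = "GRAY",
                   rqi_threshold = 0.3, n_shuffles = 200,
                   axons_per_type = 3, boutons_per_axon = 2,
                   noise_sd = 0.05)
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf(...))

  log_stage("stage: simulate (seed %d)", cfg$seed)
  proto <- make_protocol("FLASH", level = cfg$level,
                         duration_s = cfg$duration_s, n_rep = cfg$n_rep,
                         pharmacology = cfg$pharmacology,
                         background_mode = cfg$background_mode,
                         seed = cfg$seed)
  plr <- plr_params("mouse")
  pupil <- simulate_pupil(proto, plr, noise_sd = cfg$noise_sd,
                          seed = cfg$seed + 1)
  traces <- simulate_boutons(proto, pupil,
                             axons_per_type = cfg$axons_per_type,
                             boutons_per_axon = cfg$boutons_per_axon,
                             seed = cfg$seed + 2)
  write_protocol(proto, file.path(out_dir, "protocol.json"))
  write_pupil_csv(pupil$contra, file.path(out_dir, "pupil_contra.csv"))

  log_stage("stage: process (dF/F + RQI)")
  set <- process_traces(traces)
  rq <- rqi_table(set)
  kept <- threshold_boutons(rq, cfg$rqi_threshold)
  utils::write.csv(rq, file.path(out_dir, "rqi.csv"), row.names = FALSE)
  log_stage("  %d/%d boutons pass RQI >= %.2f", length(kept), nrow(rq),
            cfg$rqi_threshold)

  log_stage("stage: binocular analysis")
  window <- c(0, cfg$duration_s)
  res <- rmi_significance(
    set$tensors[["BOTH"]][, , kept, drop = FALSE],
    set$tensors[["CONTRA"]][, , kept, drop = FALSE],
    set$time, window, n_shuffles = cfg$n_shuffles, seed = cfg$seed + 3)
  res$bouton <- kept
  utils::write.csv(res, file.path(out_dir, "rmi.csv"), row.names = FALSE)

  manifest <- list(
    config = cfg,
    created = format(t0),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    n_boutons = nrow(rq), n_kept = length(kept),
    n_excluded_trials = nrow(set$excluded),
    files = c("protocol.json", "pupil_contra.csv", "rqi.csv", "rmi.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, rmi = res, out_dir = out_dir))
}
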