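#' Read a 3D TIFF volume
#'
#' Reads a single-channel TIFF z-stack (z-major page order) into an
#' `image_stack`. Plain TIFF carries no z spacing, so the spacing comes
#' from, in order of precedence: the `spacing` argument, or a YAML sidecar
#' `<path>.yaml` with a `spacing:` entry (written by [write_stack()]).
#' 8-bit data are returned on the 0-255 scale.
#'
#' @param path TIFF file path.
#' @param spacing voxel spacing (um) override.
#' @param channel channel label.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, spacing = NULL, channel = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    stop("not a 3D stack: TIFF has a single page")
  if (length(dim(pages[[1]])) != 2)
    stop("expected single-channel grayscale pages")
  if (is.null(spacing)) {
    sidecar <- paste0(path, ".yaml")
    if (file.exists(sidecar)) {
      meta <- yaml::read_yaml(sidecar)
      spacing <- as.numeric(meta$spacing)
    }
  }
  if (is.null(spacing))
    stop("voxel spacing unavailable: supply `spacing` or provide a sidecar ",
         path, ".yaml")
  # readTIFF returns row-major matrices (y rows, x cols) scaled to [0, 1]
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
  image_stack(round(arr * 255), spacing, channel)
}

#' Write a 3D volume as an 8-bit TIFF (with spacing sidecar)
#'
#' @param img image_stack (values on the 0-255 scale).
#' @param path output TIFF path; a `<path>.yaml` sidecar records the
#'   spacing so [read_stack()] can round-trip it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(img, path) {
  stopifnot(inherits(img, "image_stack"))
  v <- pmin(pmax(img$values, 0), 255) / 255
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  yaml::write_yaml(list(spacing = as.numeric(img$spacing),
                        channel = img$channel), paste0(path, ".yaml"))
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the analysis chain with their defaults; the
#' configuration round-trips through YAML unchanged.
#'
#' @param n_nuclei number of phantoms to simulate (simulation mode).
#' @param seed base seed; phantom i uses seed + i.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(n_nuclei = 2L, seed = 1L) {
  structure(list(
    n_nuclei = as.integer(n_nuclei),
    seed = as.integer(seed),
    stage = "2-cell",
    phantom = list(),              # overrides for phantom_spec()
    nucseg = list(method = "otsu", min_volume = 200, max_border_fraction = 0.3,
                  preprocess = c("median(1)", "gray_hole_fill")),
    spotseg = list(sigma = 0.15, tophat_radius = 1.0, min_volume = 0.05,
                   threshold_fraction = 0.25),
    radial = list(n_fractions = 1000L, mode = "intensity"),
    polarity = list(n_sim = 500L, method = "t"),
    npb = list(min_volume = 1, min_sphericity = 0.6, gap = 0.5)
  ), class = "run_config")
}

#' Read / write a pipeline configuration
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  known <- names(cfg)
  for (k in names(raw)) {
    if (!k %in% known) stop(sprintf("unknown configuration key: '%s'", k))
    if (is.list(cfg[[k]])) {
      for (k2 in names(raw[[k]])) {
        if (k != "phantom" && !k2 %in% names(cfg[[k]]))
          stop(sprintf("unknown configuration key: '%s.%s'", k, k2))
        cfg[[k]][[k2]] <- raw[[k]][[k2]]
      }
    } else cfg[[k]] <- raw[[k]]
  }
  cfg$n_nuclei <- as.integer(cfg$n_nuclei)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Analyze one multi-channel nucleus stack
#'
#' The per-nucleus analysis chain: nucleus segmentation on the DNA
#' channel, spot segmentation per signal channel, EVF radial profile and
#' d_max, polarity test, NPB detection and association, and the assembled
#' record. When a ground-truth mask is supplied (phantom mode with
#' `use_truth_mask = TRUE`) segmentation is still run but the analysis
#' uses the segmented mask; the ground truth is only used by callers for
#' validation.
#'
#' @param channels named list of `image_stack`: `dna` plus signal
#'   channels.
#' @param config a `run_config`.
#' @param stage,nucleus_id,embryo_id record identifiers.
#' @param seed seed for the polarity null.
#' @return List: `record` (one-row data.frame), `nucleus` (label_mask),
#'   `spots`, `profiles`, `polarity`, `npbs`.
#' @export
analyze_nucleus <- function(channels, config = default_config(),
                            stage = NA_character_, nucleus_id = 1L,
                            embryo_id = NA_character_, seed = 1L) {
  stopifnot("dna" %in% names(channels))
  dna <- channels$dna
  # smoothing + hole filling for the nuclear threshold only: NPB voids must
  # not punch holes into the mask, but NPB detection needs the raw voids
  pre <- preprocess(dna, config$nucseg$preprocess)
  nuc <- segment_nuclei(pre, method = config$nucseg$method,
                        min_volume = config$nucseg$min_volume,
                        max_border_fraction = config$nucseg$max_border_fraction)
  if (n_labels(nuc) == 0)
    stop(sprintf("nucseg: no nucleus found (nucleus %s)", nucleus_id))
  # largest nucleus in the field
  main <- which.max(nuc$counts)
  mask <- new_label_mask(array(as.integer(nuc$labels == main),
                               dim = dim(nuc$labels)), nuc$spacing)
  ev <- evf_map(mask)
  fractions <- equal_volume_fractions(ev, config$radial$n_fractions)
  signal_names <- setdiff(names(channels), "dna")
  spots <- profiles <- pol <- list()
  for (ch in signal_names) {
    den <- denoise_spots(channels[[ch]], sigma = config$spotseg$sigma,
                         tophat_radius = config$spotseg$tophat_radius)
    spots[[ch]] <- segment_spots(den, mask,
                                 min_volume = config$spotseg$min_volume,
                                 threshold_fraction = config$spotseg$threshold_fraction,
                                 nucleus_id = nucleus_id, channel = ch)
    profiles[[ch]] <- radial_profile(fractions, channels[[ch]],
                                     mode = config$radial$mode)
    if (nrow(spots[[ch]]$table) > 0)
      pol[[ch]] <- polarity_test(mask, spots[[ch]],
                                 n_sim = config$polarity$n_sim,
                                 seed = seed, method = config$polarity$method)
  }
  npbs <- segment_npbs(dna, mask, min_volume = config$npb$min_volume,
                       min_sphericity = config$npb$min_sphericity)
  for (ch in signal_names)
    npbs <- associate(npbs, spots[[ch]], gap = config$npb$gap, channel = ch)
  rec <- measure_nucleus(mask, spots = spots, radial = profiles,
                         polarity = pol, npbs = npbs, stage = stage,
                         nucleus_id = nucleus_id, embryo_id = embryo_id)
  list(record = rec, nucleus = mask, spots = spots, profiles = profiles,
       polarity = pol, npbs = npbs)
}

#' Run the simulate-segment-analyze pipeline
#'
#' Simulates `n_nuclei` phantoms (seeded seed + 1 ... seed + n) and runs
#' the full per-nucleus analysis on each; optionally writes the record
#' table, per-spot tables and configuration echo under `output_dir`.
#' Rerunning with the same configuration reproduces every table exactly.
#'
#' @param config a `run_config`.
#' @param output_dir optional output directory for CSV/YAML artifacts.
#' @return List: `records` (data.frame, one row per nucleus), `results`
#'   (per-nucleus analysis bundles), `config`.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  records <- list()
  results <- list()
  for (i in seq_len(config$n_nuclei)) {
    spec <- do.call(phantom_spec,
                    c(config$phantom, list(seed = config$seed + i)))
    ph <- simulate_phantom(spec)
    res <- analyze_nucleus(ph$channels, config, stage = config$stage,
                           nucleus_id = i, embryo_id = sprintf("phantom-%d", i),
                           seed = config$seed + 5000L + i)
    res$truth <- ph
    records[[i]] <- res$record
    results[[i]] <- res
  }
  records <- do.call(rbind, records)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(output_dir, "nucleus_records.csv"),
              row.names = FALSE)
    spot_tables <- do.call(rbind, lapply(results, function(r)
      do.call(rbind, lapply(names(r$spots), function(ch) {
        tb <- r$spots[[ch]]$table
        if (nrow(tb) == 0) return(NULL)
        cbind(nucleus_id = r$record$nucleus_id, channel = ch, tb)
      }))))
    if (!is.null(spot_tables))
      write.csv(spot_tables, file.path(output_dir, "spots.csv"),
                row.names = FALSE)
    write_config(config, file.path(output_dir, "config.yaml"))
  }
  list(records = records, results = results, config = config)
}
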