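#' Series specification for batch processing
#'
#' Describes a time series experiment: where frames live, which frame range
#' to process, where outputs go, and the per-stage parameter blocks. Frame
#' file names follow a fixed zero-padded pattern, e.g. \code{gray_0003.tif}.
#'
#' @param output_root directory receiving all stage outputs (one
#'   sub-directory per stage) and manifests.
#' @param frames strictly increasing integer frame indices.
#' @param input_root directory holding the input grayscale frames (only
#'   needed when the series does not start from the \code{synth} stage).
#' @param params named list of per-stage parameter blocks (see
#'   \code{\link{run_stage}} for the recognized names).
#' @param seed master seed for the synthetic stages.
#' @return object of class \code{"series_spec"}.
#' @export
series_spec <- function(output_root, frames = 0:2, input_root = NULL,
                        params = list(), seed = 1L) {
  frames <- as.integer(frames)
  if (any(diff(frames) <= 0)) stop("frames must be strictly increasing")
  structure(list(output_root = output_root, frames = frames,
                 input_root = input_root, params = params,
                 seed = as.integer(seed)),
            class = "series_spec")
}

#' Read a series specification from a YAML config file
#'
#' The file holds the \code{\link{series_spec}} fields: \code{output_root},
#' \code{frames} (either a list or \code{first}/\code{last}),
#' \code{input_root}, \code{seed} and a \code{params} block keyed by stage
#' name.
#'
#' @param path YAML file.
#' @return a \code{\link{series_spec}}.
#' @export
read_series_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  frames <- if (!is.null(cfg$frames$first))
    seq(cfg$frames$first, cfg$frames$last) else unlist(cfg$frames)
  series_spec(output_root = cfg$output_root, frames = frames,
              input_root = cfg$input_root,
              params = if (is.null(cfg$params)) list() else cfg$params,
              seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}

stage_dir <- function(series, stage) {
  d <- file.path(series$output_root, stage)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

frame_file <- function(dir, prefix, frame, ext = "tif")
  file.path(dir, sprintf("%s_%04d.%s", prefix, frame, ext))

stage_params <- function(series, stage, defaults) {
  p <- series$params[[stage]]
  utils::modifyList(defaults, if (is.null(p)) list() else p)
}

# manifest bookkeeping: one JSON per stage listing parameters and per-frame
# status; frames whose outputs exist under identical parameters are skipped
read_manifest <- function(series, stage) {
  f <- file.path(series$output_root, paste0("manifest_", stage, ".json"))
  if (file.exists(f)) jsonlite::read_json(f, simplifyVector = TRUE) else NULL
}

write_manifest <- function(series, stage, params, entries) {
  # store outputs relative to output_root so runs are relocatable and
  # byte-comparable across directories
  root <- paste0(series$output_root, "/")
  entries <- lapply(entries, function(e) {
    e$outputs <- vapply(e$outputs, function(p) {
      if (startsWith(p, root)) substring(p, nchar(root) + 1L) else p
    }, character(1), USE.NAMES = FALSE)
    e
  })
  f <- file.path(series$output_root, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(list(stage = stage, params = params,
                            entries = entries),
                       f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(f)
}

#' Run one pipeline stage over a frame series
#'
#' Executes a named stage of the quantification pipeline for every frame (or
#' frame pair, for the pairwise stages) of the series, writing one artifact
#' per frame with deterministic names and a JSON manifest recording
#' parameters and per-frame status. Frames whose outputs already exist under
#' identical parameters are skipped unless \code{force}; a missing input
#' frame is recorded as a per-frame failure and the batch continues.
#'
#' Stages and their parameter blocks (all parameters optional):
#' \describe{
#'   \item{synth}{generate a drifting synthetic foam series; params are the
#'     \code{\link{foam_spec}} fields plus \code{arrangement}, \code{jitter},
#'     and the rendering levels/noise. Writes gray, phase and label stacks
#'     plus ground-truth tables.}
#'   \item{process}{grayscale to clean labels: \code{bg_scale} (0 disables
#'     background removal), \code{method}, \code{min_size_liquid},
#'     \code{min_size_gas}, \code{h}, \code{min_volume},
#'     \code{drop_edge}.}
#'   \item{structure}{region tables per frame plus one liquid-fraction and
#'     radius-statistics summary row per frame.}
#'   \item{contacts}{pair and topology tables per frame; params
#'     \code{dilation}.}
#'   \item{mechanics}{texture and interfacial-stress tables per frame;
#'     params \code{Gamma}, \code{voxel_size}, \code{smooth_sigma}.}
#'   \item{track}{pairwise track tables; params \code{search_radius},
#'     \code{vol_tol}.}
#'   \item{plasticity}{lost/new contacts and T1 tables per frame pair.}
#'   \item{fields}{gridded averages of the track displacements; params
#'     \code{cell_shape}, \code{min_count}.}
#'   \item{report}{one JSON summary across frames.}
#' }
#'
#' @param stage stage name.
#' @param series a \code{\link{series_spec}}.
#' @param force recompute even when outputs exist.
#' @return the manifest entries, invisibly.
#' @export
run_stage <- function(stage, series, force = FALSE) {
  stopifnot(inherits(series, "series_spec"))
  stages <- c("synth", "process", "structure", "contacts", "mechanics",
              "track", "plasticity", "fields", "report")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; stages: ", paste(stages, collapse = ", "))
  fun <- get(paste0("stage_", stage), mode = "function")
  fun(series, force)
}

#' Run several pipeline stages in order
#'
#' @param series a \code{\link{series_spec}}.
#' @param stages character vector of stage names, executed in the given
#'   order.
#' @param force recompute even when outputs exist.
#' @return invisibly, a named list of manifest entries per stage.
#' @export
run_pipeline <- function(series,
                         stages = c("synth", "process", "structure",
                                    "contacts", "track", "plasticity"),
                         force = FALSE) {
  out <- lapply(stages, run_stage, series = series, force = force)
  names(out) <- stages
  invisible(out)
}

# ---- individual stages ----------------------------------------------------

stage_synth <- function(series, force) {
  p <- stage_params(series, "synth", list(
    box_shape = c(48, 48, 48), n_bubbles = 12L, radius_law = "constant",
    radius = 6, film_thickness = 1, drift = c(1, 0, 0),
    arrangement = "random", jitter = 0.3, gas_level = 50,
    liquid_level = 200, blur_sigma = 1, noise_sigma = 5))
  dir <- stage_dir(series, "synth")
  man <- read_manifest(series, "synth")
  spec <- foam_spec(box_shape = unlist(p$box_shape), n_bubbles = p$n_bubbles,
                    radius_law = p$radius_law, radius = p$radius,
                    film_thickness = p$film_thickness, seed = series$seed,
                    drift = unlist(p$drift))
  entries <- list()
  outputs_of <- function(f) c(frame_file(dir, "gray", f),
                              frame_file(dir, "phase", f),
                              frame_file(dir, "labels", f))
  pjson <- function(x) as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                     digits = NA))
  done <- !force && !is.null(man) && identical(pjson(man$params), pjson(p)) &&
    all(file.exists(unlist(lapply(series$frames, outputs_of))))
  if (done) {
    entries <- lapply(series$frames, function(f)
      list(frame = f, status = "skipped", outputs = outputs_of(f)))
  } else {
    pk <- make_packing(spec, arrangement = p$arrangement, jitter = p$jitter)
    frames <- deform_sequence(pk$labels, translation = unlist(p$drift),
                              n_frames = length(series$frames))
    write_table_csv(data.frame(label = seq_along(pk$truth$radii),
                               z = pk$truth$centroids[, 1],
                               y = pk$truth$centroids[, 2],
                               x = pk$truth$centroids[, 3],
                               radius = pk$truth$radii,
                               volume = pk$truth$volumes),
                    file.path(dir, "truth_bubbles.csv"))
    write_table_csv(as.data.frame(pk$truth$adjacency),
                    file.path(dir, "truth_adjacency.csv"))
    for (k in seq_along(series$frames)) {
      f <- series$frames[k]
      lab <- frames[[k]]
      ph <- array(0L, dim = dim(lab)); ph[lab == 0L] <- 1L
      gray <- render_tomogram(ph, p$gas_level, p$liquid_level,
                              p$blur_sigma, p$noise_sigma,
                              seed = series$seed + k)
      write_gray_tiff(gray, frame_file(dir, "gray", f))
      write_label_tiff(ph, frame_file(dir, "phase", f))
      write_label_tiff(lab, frame_file(dir, "labels", f))
      entries[[k]] <- list(frame = f, status = "done",
                           outputs = outputs_of(f))
    }
  }
  write_manifest(series, "synth", p, entries)
  invisible(entries)
}

stage_process <- function(series, force) {
  p <- stage_params(series, "process", list(
    bg_scale = 0, method = "otsu", min_size_liquid = 4L, min_size_gas = 4L,
    h = 2, min_volume = 10L, drop_edge = FALSE))
  sdir <- stage_dir(series, "synth")
  dir <- stage_dir(series, "process")
  entries <- list()
  for (f in series$frames) {
    inp <- if (is.null(series$input_root)) frame_file(sdir, "gray", f)
           else frame_file(series$input_root, "gray", f)
    out <- frame_file(dir, "labels", f)
    if (!file.exists(inp)) {
      entries[[length(entries) + 1L]] <-
        list(frame = f, status = "missing-input", outputs = character())
      next
    }
    if (!force && file.exists(out)) {
      entries[[length(entries) + 1L]] <-
        list(frame = f, status = "skipped", outputs = out)
      next
    }
    vol <- read_gray_tiff(inp)
    if (p$bg_scale > 0) vol <- remove_background(vol, p$bg_scale)
    phase <- segment_phase(vol, method = p$method)
    phase <- remove_speckles(phase, p$min_size_liquid, p$min_size_gas)
    labels <- segment_bubbles(phase, h = p$h, min_volume = p$min_volume)
    if (isTRUE(p$drop_edge)) labels <- remove_edge_bubbles(labels)
    write_label_tiff(labels, out)
    entries[[length(entries) + 1L]] <-
      list(frame = f, status = "done", outputs = out)
  }
  write_manifest(series, "process", p, entries)
  invisible(entries)
}

labels_path <- function(series, f) {
  pdir <- file.path(series$output_root, "process")
  frame_file(pdir, "labels", f)
}

stage_structure <- function(series, force) {
  dir <- stage_dir(series, "structure")
  entries <- list(); summary_rows <- list()
  for (f in series$frames) {
    inp <- labels_path(series, f)
    out <- frame_file(dir, "regions", f, "csv")
    if (!file.exists(inp)) {
      entries[[length(entries) + 1L]] <-
        list(frame = f, status = "missing-input", outputs = character())
      next
    }
    labels <- read_label_tiff(inp)
    reg <- region_properties(labels)
    write_table_csv(reg, out)
    phase <- array(0L, dim = dim(labels)); phase[labels == 0L] <- 1L
    rs <- radius_statistics(reg)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      frame = f, liquid_fraction = liquid_fraction(phase),
      n_bubbles = nrow(reg), mean_R = rs$mean_R, R32 = rs$R32, p32 = rs$p32)
    entries[[length(entries) + 1L]] <-
      list(frame = f, status = "done", outputs = out)
  }
  if (length(summary_rows))
    write_table_csv(do.call(rbind, summary_rows),
                    file.path(dir, "summary.csv"))
  write_manifest(series, "structure", list(), entries)
  invisible(entries)
}

stage_contacts <- function(series, force) {
  p <- stage_params(series, "contacts", list(dilation = 1L))
  dir <- stage_dir(series, "contacts")
  entries <- list()
  for (f in series$frames) {
    inp <- labels_path(series, f)
    outs <- c(frame_file(dir, "pairs", f, "csv"),
              frame_file(dir, "topology", f, "csv"))
    if (!file.exists(inp)) {
      entries[[length(entries) + 1L]] <-
        list(frame = f, status = "missing-input", outputs = character())
      next
    }
    net <- get_contacts(read_label_tiff(inp), dilation = p$dilation)
    write_table_csv(net$pairs, outs[1])
    write_table_csv(net$topology, outs[2])
    entries[[length(entries) + 1L]] <-
      list(frame = f, status = "done", outputs = outs)
  }
  write_manifest(series, "contacts", p, entries)
  invisible(entries)
}

stage_mechanics <- function(series, force) {
  p <- stage_params(series, "mechanics", list(
    Gamma = 1, voxel_size = 1, smooth_sigma = 1, dilation = 1L))
  dir <- stage_dir(series, "mechanics")
  entries <- list()
  for (f in series$frames) {
    inp <- labels_path(series, f)
    outs <- c(frame_file(dir, "stress", f, "csv"),
              frame_file(dir, "texture", f, "csv"))
    if (!file.exists(inp)) {
      entries[[length(entries) + 1L]] <-
        list(frame = f, status = "missing-input", outputs = character())
      next
    }
    labels <- read_label_tiff(inp)
    write_table_csv(batchelor_stress_all(labels, p$Gamma, p$voxel_size,
                                         p$smooth_sigma), outs[1])
    reg <- region_properties(labels)
    net <- get_contacts(labels, dilation = p$dilation)
    write_table_csv(texture_table(reg, net), outs[2])
    entries[[length(entries) + 1L]] <-
      list(frame = f, status = "done", outputs = outs)
  }
  jsonlite::write_json(list(Gamma = p$Gamma, voxel_size = p$voxel_size),
                       file.path(dir, "units.json"), auto_unbox = TRUE)
  write_manifest(series, "mechanics", p, entries)
  invisible(entries)
}

stage_track <- function(series, force) {
  p <- stage_params(series, "track", list(search_radius = NULL,
                                          vol_tol = 0.3))
  dir <- stage_dir(series, "track")
  entries <- list()
  fr <- series$frames
  for (k in seq_len(length(fr) - 1L)) {
    inps <- c(labels_path(series, fr[k]), labels_path(series, fr[k + 1]))
    out <- file.path(dir, sprintf("track_%04d_%04d.csv", fr[k], fr[k + 1]))
    if (!all(file.exists(inps))) {
      entries[[length(entries) + 1L]] <-
        list(frame = fr[k], status = "missing-input", outputs = character())
      next
    }
    rt <- region_properties(read_label_tiff(inps[1]))
    r1 <- region_properties(read_label_tiff(inps[2]))
    tt <- track_labels(rt, r1, search_radius = p$search_radius,
                       vol_tol = p$vol_tol)
    write_table_csv(tt, out)
    entries[[length(entries) + 1L]] <-
      list(frame = fr[k], status = "done", outputs = out)
  }
  write_manifest(series, "track", p, entries)
  invisible(entries)
}

stage_plasticity <- function(series, force) {
  dir <- stage_dir(series, "plasticity")
  cdir <- file.path(series$output_root, "contacts")
  tdir <- file.path(series$output_root, "track")
  entries <- list()
  fr <- series$frames
  for (k in seq_len(length(fr) - 1L)) {
    pf <- frame_file(cdir, "pairs", fr[k], "csv")
    pf1 <- frame_file(cdir, "pairs", fr[k + 1], "csv")
    tf <- file.path(tdir, sprintf("track_%04d_%04d.csv", fr[k], fr[k + 1]))
    out <- file.path(dir, sprintf("t1_%04d_%04d.csv", fr[k], fr[k + 1]))
    if (!all(file.exists(c(pf, pf1, tf)))) {
      entries[[length(entries) + 1L]] <-
        list(frame = fr[k], status = "missing-input", outputs = character())
      next
    }
    pairs_t <- read.csv(pf); pairs_t1 <- read.csv(pf1)
    tracks <- read.csv(tf)
    tr <- translate_pairs(pairs_t, tracks)
    ln <- lost_new(tr, pairs_t1)
    t1 <- detect_t1(ln$lost, ln$new, tr, pairs_t1)
    write_table_csv(as.data.frame(t1), out)
    write_table_csv(ln$lost, file.path(dir, sprintf("lost_%04d_%04d.csv",
                                                    fr[k], fr[k + 1])))
    write_table_csv(ln$new, file.path(dir, sprintf("new_%04d_%04d.csv",
                                                   fr[k], fr[k + 1])))
    entries[[length(entries) + 1L]] <-
      list(frame = fr[k], status = "done", outputs = out)
  }
  write_manifest(series, "plasticity", list(), entries)
  invisible(entries)
}

stage_fields <- function(series, force) {
  p <- stage_params(series, "fields", list(cell_shape = 16L, min_count = 1L))
  dir <- stage_dir(series, "fields")
  tdir <- file.path(series$output_root, "track")
  entries <- list()
  fr <- series$frames
  for (k in seq_len(length(fr) - 1L)) {
    tf <- file.path(tdir, sprintf("track_%04d_%04d.csv", fr[k], fr[k + 1]))
    out <- file.path(dir, sprintf("flow_%04d_%04d.csv", fr[k], fr[k + 1]))
    if (!file.exists(tf)) {
      entries[[length(entries) + 1L]] <-
        list(frame = fr[k], status = "missing-input", outputs = character())
      next
    }
    tt <- read.csv(tf)
    tt <- tt[tt$status == "matched", ]
    lab <- read_label_tiff(labels_path(series, fr[k]))
    ga <- grid_average(as.matrix(tt[, c("z_t", "y_t", "x_t")]),
                       as.matrix(tt[, c("dz", "dy", "dx")]),
                       grid_spec(unlist(p$cell_shape)), dim(lab),
                       min_count = p$min_count)
    write_table_csv(data.frame(ga$cell_index, count = ga$count,
                               dz = ga$mean[, 1], dy = ga$mean[, 2],
                               dx = ga$mean[, 3]), out)
    entries[[length(entries) + 1L]] <-
      list(frame = fr[k], status = "done", outputs = out)
  }
  write_manifest(series, "fields", p, entries)
  invisible(entries)
}

stage_report <- function(series, force) {
  sdir <- file.path(series$output_root, "structure")
  out <- file.path(series$output_root, "report.json")
  summary_file <- file.path(sdir, "summary.csv")
  rep <- list(frames = series$frames)
  if (file.exists(summary_file)) {
    s <- read.csv(summary_file)
    rep$liquid_fraction <- mean(s$liquid_fraction)
    rep$mean_R <- mean(s$mean_R)
    rep$R32 <- mean(s$R32)
    rep$p32 <- mean(s$p32)
    rep$n_bubbles <- mean(s$n_bubbles)
  }
  jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  entries <- list(list(frame = NA, status = "done", outputs = out))
  write_manifest(series, "report", list(), entries)
  invisible(entries)
}
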