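#' Channel-dimension sweep configuration
#'
#' Defines the channel experiment: the montage fixed over the fold crown,
#' channel shapes crossed with shaft diameters, plus the channel-free
#' reference configuration.
#'
#' @param shapes Channel shapes to sweep, subset of `c("I", "T")`.
#' @param diameters Shaft diameters (mm), default `c(1, 3, 5, 7, 9)`.
#' @param include_none Include the channel-free reference, default TRUE.
#' @param head A [head_params()].
#' @param spacing Grid spacing (mm), default 0.5.
#' @param montage A [montage_spec()].
#' @param sigma Conductivities, see [default_conductivities()].
#' @param solver A [solver_config()].
#' @param roi A [roi_spec()].
#' @param membrane A [membrane_params()].
#' @param kinds Neuron kinds to simulate, default `c("L5", "L3")`.
#' @param morph A [morph_params()].
#' @return Object of class `sweep_config`.
#' @export
channel_sweep_config <- function(shapes = c("I", "T"),
                                 diameters = c(1, 3, 5, 7, 9),
                                 include_none = TRUE,
                                 head = head_params(), spacing = 0.5,
                                 montage = montage_spec(),
                                 sigma = default_conductivities(),
                                 solver = solver_config(),
                                 roi = roi_spec(),
                                 membrane = membrane_params(),
                                 kinds = c("L5", "L3"),
                                 morph = morph_params()) {
  stopifnot(all(shapes %in% c("I", "T")))
  configs <- data.frame(shape = character(0), diameter = numeric(0),
                        disp_x = numeric(0), disp_y = numeric(0))
  if (include_none)
    configs <- rbind(configs, data.frame(shape = "NONE", diameter = NA_real_,
                                         disp_x = 0, disp_y = 0))
  for (s in shapes) for (d in diameters)
    configs <- rbind(configs, data.frame(shape = s, diameter = d,
                                         disp_x = 0, disp_y = 0))
  if (nrow(configs) == 0) stop("sweep has no configurations")
  configs$label <- ifelse(configs$shape == "NONE", "none",
                          sprintf("%s%g", configs$shape, configs$diameter))
  structure(list(type = "channel", configs = configs, head = head,
                 spacing = spacing, montage = montage, sigma = sigma,
                 solver = solver, roi = roi, membrane = membrane,
                 kinds = kinds, morph = morph),
            class = "sweep_config")
}

#' Electrode-displacement sweep configuration
#'
#' The transcranial channel stays implanted over the target while the whole
#' five-electrode montage is displaced rigidly in the scalp plane. The
#' default direction is +x: in-plane and perpendicular to the gyral ridge.
#'
#' @param displacements Displacement magnitudes (mm), default
#'   `c(0, 5, 10, 15, 20)`.
#' @param channel The fixed [channel_spec()] (default T-shaped, 7 mm).
#' @param direction Unit 2-vector of the displacement direction.
#' @param spacing Grid spacing (mm), default 1.
#' @inheritParams channel_sweep_config
#' @details The default head is laterally wider than for the channel sweep
#'   (126 mm) so the displaced montage stays on the scalp at the largest
#'   displacement.
#' @return Object of class `sweep_config`.
#' @export
displacement_sweep_config <- function(displacements = c(0, 5, 10, 15, 20),
                                      channel = channel_spec("T", 7),
                                      direction = c(1, 0),
                                      head = head_params(lateral_extent = 126),
                                      spacing = 1,
                                      montage = montage_spec(),
                                      sigma = default_conductivities(),
                                      solver = solver_config(),
                                      roi = roi_spec(),
                                      membrane = membrane_params(),
                                      kinds = c("L5", "L3"),
                                      morph = morph_params()) {
  if (length(displacements) == 0) stop("sweep has no configurations")
  direction <- direction / sqrt(sum(direction^2))
  configs <- data.frame(shape = channel$shape, diameter = channel$shaft_diameter,
                        disp_x = displacements * direction[1],
                        disp_y = displacements * direction[2])
  configs$label <- sprintf("disp%g", displacements)
  structure(list(type = "displacement", configs = configs, head = head,
                 spacing = spacing, montage = montage, sigma = sigma,
                 solver = solver, roi = roi, membrane = membrane,
                 kinds = kinds, morph = morph, channel = channel,
                 displacements = displacements),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf("sweep_config (%s): %d configurations at %g mm spacing, kinds %s\n",
              x$type, nrow(x$configs), x$spacing, paste(x$kinds, collapse = "/")))
  print(x$configs[, c("label", "shape", "diameter", "disp_x", "disp_y")],
        row.names = FALSE)
  invisible(x)
}

# channel spec for one config row
config_channel <- function(cfg, row) {
  if (row$shape == "NONE") channel_spec("NONE")
  else channel_spec(row$shape, row$diameter)
}

#' Per-landmark ROI statistics
#'
#' Median, first and third quartile (linear-interpolation convention,
#' `stats::quantile` type 7), minimum and maximum of the polarization at
#' each landmark over a population of profiles.
#'
#' @param profiles List of `polarization_profile` objects with a common
#'   landmark set.
#' @return Data frame: `landmark, median, q1, q3, min, max` (mV).
#' @export
roi_statistics <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles supplied")
  lms <- lapply(profiles, function(p) sort(names(attr(p, "landmarks"))))
  if (length(unique(vapply(lms, paste, character(1), collapse = ","))) != 1)
    stop("profiles have inconsistent landmark sets")
  nm <- names(attr(profiles[[1]], "landmarks"))
  vals <- vapply(profiles, function(p) attr(p, "landmarks")[nm],
                 numeric(length(nm)))
  vals <- matrix(vals, nrow = length(nm))
  data.frame(
    landmark = nm,
    median = apply(vals, 1, median),
    q1 = apply(vals, 1, quantile, probs = 0.25, names = FALSE),
    q3 = apply(vals, 1, quantile, probs = 0.75, names = FALSE),
    min = apply(vals, 1, min),
    max = apply(vals, 1, max)
  )
}

# solve one configuration and measure fields + polarization.
# population: list of kind -> list of placed neurons (shared across configs)
run_one_config <- function(cfg, row, population, normals, x0 = NULL) {
  t0 <- proc.time()[3]
  grid <- build_head_model(head_grid(cfg$head, cfg$spacing), cfg$head)
  grid <- carve_channel(grid, config_channel(cfg, row))
  mont <- cfg$montage
  mont$displacement <- c(row$disp_x, row$disp_y)
  pm <- place_montage(grid, mont)
  t1 <- proc.time()[3]
  pf <- solve_potential(pm, cfg$sigma, cfg$solver, x0 = x0)
  t2 <- proc.time()[3]
  fs <- compute_efield(pf, pm$grid)
  foc <- focality_volumes(fs, "GM")
  pol <- list(); coup <- list(); stats_df <- list()
  for (kind in cfg$kinds) {
    neurons <- population[[kind]]
    profiles <- vector("list", length(neurons))
    ks <- numeric(length(neurons))
    for (q in seq_along(neurons)) {
      ctr <- compartment_centers(neurons[[q]]$morph)
      e_mV <- sample_potential(pf, ctr) * 1000
      profiles[[q]] <- steady_state_polarization(neurons[[q]], e_mV,
                                                 cfg$membrane)
      soma_xyz <- ctr[1, , drop = FALSE]
      localE <- sample_efield(fs, soma_xyz)[1, "mag"]
      ks[q] <- if (localE > 0)
        coupling_constant(profiles[[q]], localE)$k_mm else NA_real_
    }
    st <- roi_statistics(profiles)
    st$kind <- kind
    stats_df[[kind]] <- st
    soma_dv <- vapply(profiles, function(p) attr(p, "landmarks")[["soma"]],
                      numeric(1))
    pol[[kind]] <- list(profiles = profiles,
                        peak_soma_abs = max(abs(soma_dv)),
                        median_soma = median(soma_dv))
    coup[[kind]] <- data.frame(kind = kind, mean_k = mean(ks, na.rm = TRUE),
                               sd_k = sd(ks, na.rm = TRUE),
                               n = sum(!is.na(ks)))
  }
  t3 <- proc.time()[3]
  message(sprintf("[%s] geometry %.1fs, solve %.1fs (%d it), neurons %.1fs; GM peak %.3g V/m",
                  row$label, t1 - t0, t2 - t1, pf$iters, t3 - t2, foc$peak))
  list(label = row$label, phi = pf$phi, focality = foc,
       stats = do.call(rbind, stats_df),
       coupling = do.call(rbind, coup),
       peak_soma = vapply(pol, function(p) p$peak_soma_abs, numeric(1)),
       median_soma = vapply(pol, function(p) p$median_soma, numeric(1)),
       solver = list(iters = pf$iters, relres = pf$relres),
       timing = c(geometry = t1 - t0, solve = t2 - t1, neurons = t3 - t2))
}

#' Run a sweep experiment end-to-end
#'
#' For each configuration: build the head, carve the channel, place the
#' montage, solve the volume-conduction problem, compute field metrics, and
#' polarize the ROI neuron population. The population is placed once on the
#' base geometry (the ROI is anchored to the implanted channel) and reused
#' across configurations. A configuration that fails is recorded with its
#' error and the sweep proceeds.
#'
#' @param cfg A `sweep_config` from [channel_sweep_config()] or
#'   [displacement_sweep_config()].
#' @return Object of class `sweep_result` with elements `focality`
#'   (data frame mirroring the peak-EF/focality table), `polarization`
#'   (per-configuration, per-kind, per-landmark ROI statistics), `coupling`,
#'   `peak_soma` (per-configuration peak somatic |dV|), `retention`
#'   (displacement sweeps: peak somatic |dV| relative to zero
#'   displacement), `errors`, and the resolved `config`.
#' @export
run_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  if (nrow(cfg$configs) == 0) stop("sweep has no configurations")
  base_grid <- build_head_model(head_grid(cfg$head, cfg$spacing), cfg$head)
  if (cfg$type == "displacement")
    base_grid <- carve_channel(base_grid, cfg$channel)
  normals <- surface_normals(base_grid)
  population <- list()
  for (kind in cfg$kinds)
    population[[kind]] <- populate_roi(base_grid, cfg$roi, kind, cfg$morph,
                                       normals = normals)
  message(sprintf("ROI population: %s",
                  paste(sprintf("%s n=%d", names(population),
                                lengths(population)), collapse = ", ")))
  results <- list(); errors <- list()
  prev_phi <- NULL   # warm start: fields vary little between configurations
  for (r in seq_len(nrow(cfg$configs))) {
    row <- cfg$configs[r, ]
    res <- tryCatch(run_one_config(cfg, row, population, normals,
                                   x0 = prev_phi),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[row$label]] <- conditionMessage(res)
      message(sprintf("[%s] FAILED: %s", row$label, conditionMessage(res)))
    } else {
      prev_phi <- res$phi
      res$phi <- NULL
      results[[row$label]] <- res
    }
  }
  if (length(results) == 0) stop("all sweep configurations failed")
  foc <- do.call(rbind, lapply(results, function(x) {
    data.frame(label = x$label, peak_EF = x$focality$peak,
               t(x$focality$volumes))
  }))
  cfgs <- cfg$configs[match(foc$label, cfg$configs$label), ]
  foc <- cbind(cfgs[, c("shape", "diameter", "disp_x", "disp_y")], foc)
  rownames(foc) <- NULL
  polstats <- do.call(rbind, lapply(results, function(x) {
    cbind(label = x$label, x$stats)
  }))
  rownames(polstats) <- NULL
  coupling <- do.call(rbind, lapply(results, function(x) {
    cbind(label = x$label, x$coupling)
  }))
  rownames(coupling) <- NULL
  peak_soma <- do.call(rbind, lapply(results, function(x) {
    data.frame(label = x$label, kind = names(x$peak_soma),
               peak_soma_abs_mV = as.numeric(x$peak_soma),
               median_soma_mV = as.numeric(x$median_soma))
  }))
  rownames(peak_soma) <- NULL
  retention <- NULL
  if (cfg$type == "displacement") {
    ref <- peak_soma[peak_soma$label == cfg$configs$label[1], ]
    retention <- do.call(rbind, lapply(split(peak_soma, peak_soma$kind),
                                       function(d) {
      d <- d[match(cfg$configs$label, d$label), ]
      data.frame(kind = d$kind,
                 displacement = cfg$displacements,
                 label = d$label,
                 peak_soma_abs_mV = d$peak_soma_abs_mV,
                 retention = d$peak_soma_abs_mV /
                   d$peak_soma_abs_mV[1])
    }))
    rownames(retention) <- NULL
  }
  structure(list(type = cfg$type, focality = foc, polarization = polstats,
                 coupling = coupling, peak_soma = peak_soma,
                 retention = retention, errors = errors,
                 population_n = lengths(population),
                 config = cfg,
                 details = results),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result (%s): %d configurations (%d failed)\n",
              x$type, nrow(x$focality), length(x$errors)))
  print(x$focality[, c("label", "peak_EF", "Vol_50", "Vol_60", "Vol_70",
                       "Vol_80")], row.names = FALSE, digits = 4)
  if (!is.null(x$retention)) {
    cat("retention of peak somatic |dV|:\n")
    print(x$retention, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

# deterministic fingerprint of an integer label array (order-sensitive
# polynomial checksum, reported in the run manifest); modulus below 2^26 so
# every double-precision product stays exact
label_checksum <- function(labels) {
  v <- as.double(labels) + 1
  p <- 67108859            # largest prime below 2^26
  chunk <- 4096L
  w <- numeric(chunk)
  w[1] <- 1
  for (q in 2:chunk) w[q] <- (w[q - 1] * 31) %% p
  w_step <- (w[chunk] * 31) %% p
  acc <- 0; mult <- 1
  for (s in seq(1, length(v), by = chunk)) {
    e <- min(s + chunk - 1, length(v))
    seg <- v[s:e]
    partial <- sum((seg * w[seq_along(seg)]) %% p) %% p
    acc <- (acc + mult * partial) %% p
    mult <- (mult * (if (length(seg) == chunk) w_step
                     else (w[length(seg)] * 31) %% p)) %% p
  }
  sprintf("%08.0f", acc)
}

# serialize the resolved sweep configuration to plain lists for the manifest
resolved_config <- function(cfg) {
  strip <- function(x) {
    if (inherits(x, c("head_params", "montage_spec", "solver_config",
                      "roi_spec", "membrane_params", "morph_params",
                      "channel_spec")))
      x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  list(type = cfg$type,
       spacing = cfg$spacing,
       head = strip(cfg$head),
       montage = strip(cfg$montage),
       sigma = as.list(cfg$sigma),
       solver = strip(cfg$solver),
       roi = strip(cfg$roi),
       membrane = strip(cfg$membrane),
       morph = strip(cfg$morph),
       kinds = cfg$kinds,
       configs = cfg$configs)
}

#' Write sweep report files
#'
#' Writes `focality.csv` (one row per configuration: shape, diameter,
#' displacement, peak EF, Vol_50..Vol_80), `polarization_stats.csv`,
#' `coupling.csv`, `retention.csv` (displacement sweeps; the zero-
#' displacement row is exactly 1), and `run_manifest.json` holding the full
#' resolved configuration, package version and a checksum of the base grid
#' labels. Re-running with the same configuration reproduces byte-identical
#' CSVs.
#'
#' @param result A `sweep_result`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, outdir) {
  stopifnot(inherits(result, "sweep_result"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0)
    stop(sprintf("output directory '%s' is not writable", outdir))
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$focality, "focality.csv")
  wr(result$polarization, "polarization_stats.csv")
  wr(result$coupling, "coupling.csv")
  if (!is.null(result$retention)) wr(result$retention, "retention.csv")
  cfg <- result$config
  base_grid <- build_head_model(head_grid(cfg$head, cfg$spacing), cfg$head)
  manifest <- list(
    package = "tcranchan",
    version = as.character(utils::packageVersion("tcranchan")),
    quantile_convention = "type 7 (linear interpolation between order statistics)",
    grid_label_checksum = label_checksum(base_grid$labels),
    config = resolved_config(cfg),
    errors = result$errors
  )
  mp <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, mp)
  invisible(paths)
}

#' Read a sweep run manifest
#'
#' @param path Path to `run_manifest.json`.
#' @return The manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
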