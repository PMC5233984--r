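#' Read a sweep configuration from YAML
#'
#' Parses a single YAML (or JSON) document with sections `head`, `montage`,
#' `channel`, `conductivity`, `solver`, `roi`, `membrane`, `morph` and
#' `sweep`, each optional except `sweep`, and returns the corresponding
#' `sweep_config`. Unknown sections or keys are rejected.
#'
#' The `sweep` section requires `type: channel` (keys `shapes`, `diameters`,
#' `include_none`) or `type: displacement` (keys `displacements`,
#' `direction`; the fixed channel comes from the `channel` section).
#' `spacing` (mm) and `kinds` may be set at the top level.
#'
#' @param path Path to the configuration file.
#' @return A `sweep_config`.
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known_top <- c("head", "montage", "channel", "conductivity", "solver",
                 "roi", "membrane", "morph", "sweep", "spacing", "kinds")
  unknown <- setdiff(names(doc), known_top)
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  take <- function(section, builder) {
    args <- doc[[section]]
    if (is.null(args)) return(builder())
    ok <- names(formals(builder))
    bad <- setdiff(names(args), ok)
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", section,
                   paste(bad, collapse = ", ")))
    do.call(builder, args)
  }
  head <- take("head", head_params)
  montage <- take("montage", montage_spec)
  solver <- take("solver", solver_config)
  roi <- take("roi", roi_spec)
  membrane <- take("membrane", membrane_params)
  morph <- take("morph", morph_params)
  sigma <- default_conductivities()
  if (!is.null(doc$conductivity)) {
    bad <- setdiff(names(doc$conductivity), names(sigma))
    if (length(bad))
      stop("unknown tissue(s) in 'conductivity': ", paste(bad, collapse = ", "))
    for (nm in names(doc$conductivity)) sigma[[nm]] <- doc$conductivity[[nm]]
  }
  kinds <- doc$kinds %||% c("L5", "L3")
  sw <- doc$sweep
  if (is.null(sw) || is.null(sw$type))
    stop("configuration requires a 'sweep' section with a 'type'")
  if (sw$type == "channel") {
    bad <- setdiff(names(sw), c("type", "shapes", "diameters", "include_none"))
    if (length(bad))
      stop("unknown key(s) in 'sweep': ", paste(bad, collapse = ", "))
    channel_sweep_config(
      shapes = unlist(sw$shapes) %||% c("I", "T"),
      diameters = unlist(sw$diameters) %||% c(1, 3, 5, 7, 9),
      include_none = sw$include_none %||% TRUE,
      head = head, spacing = doc$spacing %||% 0.5, montage = montage,
      sigma = sigma, solver = solver, roi = roi, membrane = membrane,
      kinds = kinds, morph = morph)
  } else if (sw$type == "displacement") {
    bad <- setdiff(names(sw), c("type", "displacements", "direction"))
    if (length(bad))
      stop("unknown key(s) in 'sweep': ", paste(bad, collapse = ", "))
    channel <- take("channel", channel_spec)
    displacement_sweep_config(
      displacements = unlist(sw$displacements) %||% c(0, 5, 10, 15, 20),
      channel = channel,
      direction = unlist(sw$direction) %||% c(1, 0),
      head = head, spacing = doc$spacing %||% 1, montage = montage,
      sigma = sigma, solver = solver, roi = roi, membrane = membrane,
      kinds = kinds, morph = morph)
  } else {
    stop("sweep type must be 'channel' or 'displacement'")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
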