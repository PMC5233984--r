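#' Compartmental morphology container
#'
#' A morphology is a rooted tree of cylindrical compartments. Each
#' compartment is the segment from its parent's endpoint to its own endpoint
#' (the root — the soma — is a single compartment whose nominal length equals
#' its diameter). Coordinates are in the local frame with +z toward the pia,
#' in mm; diameters in micrometers.
#'
#' @param df Data frame with columns `id` (0-based), `parent` (-1 for the
#'   root), `part` (one of soma, apical_dendrite, basal_dendrite, iseg,
#'   axon), `x, y, z` (mm), `diam` (um).
#' @param landmarks Named integer vector mapping landmark names to `id`s.
#' @param kind Optional kind tag (`"L5"`, `"L3"`, or other).
#' @return Object of class `morphology`.
#' @export
morphology <- function(df, landmarks = integer(), kind = "custom") {
  need <- c("id", "parent", "part", "x", "y", "z", "diam")
  if (!all(need %in% names(df))) stop("morphology data frame lacks required columns")
  df <- df[order(df$id), need]
  n <- nrow(df)
  if (!identical(as.integer(df$id), seq_len(n) - 1L))
    stop("compartment ids must be 0-based and consecutive")
  if (sum(df$parent == -1L) != 1L || df$parent[1] != -1L)
    stop("morphology must have exactly one root (first compartment)")
  if (any(df$parent[-1] >= df$id[-1]))
    stop("parent must precede child (tree order)")
  if (any(df$parent[-1] < 0L))
    stop("only the root may have parent -1")
  if (any(df$diam <= 0)) stop("diameters must be > 0")
  if (length(landmarks)) {
    if (is.null(names(landmarks)) || any(!nzchar(names(landmarks))))
      stop("landmarks must be named")
    if (any(!(landmarks %in% df$id)))
      stop("landmark refers to a non-existent compartment")
  }
  structure(list(comp = df, landmarks = landmarks, kind = kind),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("morphology (%s): %d compartments, %d landmarks\n",
              x$kind, nrow(x$comp), length(x$landmarks)))
  if (length(x$landmarks))
    cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  parts <- table(x$comp$part)
  cat("  parts:", paste(sprintf("%s (%d)", names(parts), parts), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.morphology <- function(x, ...) {
  comp <- x$comp
  graphics::plot(NA, xlim = range(comp$x), ylim = range(comp$z),
                 xlab = "x (mm)", ylab = "z (mm)", asp = 1,
                 main = sprintf("%s morphology", x$kind), ...)
  for (r in which(comp$parent >= 0)) {
    p <- comp[comp$id == comp$parent[r], ]
    graphics::segments(p$x, p$z, comp$x[r], comp$z[r],
                       lwd = pmax(0.5, comp$diam[r] / 4))
  }
  lm <- x$landmarks
  if (length(lm)) {
    sel <- comp$id %in% lm
    graphics::points(comp$x[sel], comp$z[sel], col = "red", pch = 16)
    graphics::text(comp$x[sel], comp$z[sel], names(lm)[match(comp$id[sel], lm)],
                   pos = 4, col = "red", cex = 0.7)
  }
  invisible(x)
}

#' Parametric morphology parameters
#'
#' @param soma_diameter Soma diameter (um), default 20.
#' @param apical_length Nominal apical trunk length (mm); rescaled at
#'   placement so the tip reaches layer 1.
#' @param basal_radius Lateral extent of the basal arbor (mm).
#' @param axon_length Nominal axon length below the soma (mm); for L5
#'   rescaled at placement so landmark b1 falls on the GM/WM boundary.
#' @param iseg_length Axon initial-segment length (mm).
#' @param flatness Factor in (0, 1] compressing the apical vertical extent,
#'   emulating flat-dendritic-tree variants; default 1 (tall).
#' @param seg_len Build-time compartment length (mm), default 0.025 — well
#'   under a tenth of the electrotonic length constant for all default
#'   diameters.
#' @return Object of class `morph_params`.
#' @export
morph_params <- function(soma_diameter = 20, apical_length = NULL,
                         basal_radius = NULL, axon_length = NULL,
                         iseg_length = 0.05, flatness = 1, seg_len = 0.025) {
  stopifnot(soma_diameter > 0, iseg_length > 0, flatness > 0, seg_len > 0)
  structure(list(soma_diameter = soma_diameter, apical_length = apical_length,
                 basal_radius = basal_radius, axon_length = axon_length,
                 iseg_length = iseg_length, flatness = flatness,
                 seg_len = seg_len),
            class = "morph_params")
}

# fill kind-dependent defaults
resolve_morph_params <- function(kind, p) {
  def <- if (kind == "L5") list(apical_length = 1.2, basal_radius = 0.35,
                                axon_length = 0.8)
  else list(apical_length = 0.8, basal_radius = 0.30, axon_length = 0.9)
  for (nm in names(def)) if (is.null(p[[nm]])) p[[nm]] <- def[[nm]]
  stopifnot(p$apical_length > 0, p$basal_radius > 0, p$axon_length > 0)
  p
}

# internal builder state: grow a chain of compartments from a start point to
# an end point in steps of ~seg_len, returning updated table and the id of
# the chain tip
grow_chain <- function(tab, from_id, from_xyz, to_xyz, part, diam, seg_len) {
  v <- to_xyz - from_xyz
  len <- sqrt(sum(v^2))
  nseg <- max(1L, ceiling(len / seg_len))
  ids <- nrow(tab) - 1L + seq_len(nseg)
  pts <- matrix(from_xyz, nseg, 3, byrow = TRUE) + outer(seq_len(nseg) / nseg, v)
  new <- data.frame(id = ids,
                    parent = c(from_id, ids[-nseg]),
                    part = part,
                    x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    diam = diam)
  list(tab = rbind(tab, new), tip = ids[nseg])
}

#' Build a parametric pyramidal-neuron morphology
#'
#' Constructs a deterministic stand-in layer 5 or layer 3 pyramidal neuron:
#' an apical trunk ascending to a short tuft, oblique and descending basal
#' dendrites, an axon initial segment, and an axon. The L5 axon continues
#' past the prospective GM/WM boundary (landmark `b1`), bends (`b2`) and
#' runs obliquely to its terminal; the L3 axon descends within the gray
#' matter with landmarks `mid` and `terminal`.
#'
#' Landmarks: L5 `d1` (mid apical trunk), `d2` (apical tip), `d3` (oblique
#' basal tip), `d4` (descending basal tip), `soma`, `iseg`, `b1`, `b2`,
#' `terminal`; L3 `d1`, `d2`, `d3` (descending basal tip), `soma`, `iseg`,
#' `mid`, `terminal`.
#'
#' @param kind `"L5"` or `"L3"`.
#' @param params A [morph_params()].
#' @return A [morphology()].
#' @export
build_pn <- function(kind = c("L5", "L3"), params = morph_params()) {
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% c("L5", "L3")))
    stop("unknown neuron kind; must be \"L5\" or \"L3\"")
  p <- resolve_morph_params(kind, params)
  sl <- p$seg_len
  soma_d <- p$soma_diameter
  # flattening compresses the trunk and moves arbor from the vertical
  # continuation into wide, thick lateral tuft branches (span-conserving)
  A <- p$apical_length * (0.5 + 0.5 * p$flatness)
  tab <- data.frame(id = 0L, parent = -1L, part = "soma",
                    x = 0, y = 0, z = 0, diam = soma_d)
  lm <- c(soma = 0L)
  # apical trunk
  g <- grow_chain(tab, 0L, c(0, 0, 0), c(0, 0, A), "apical_dendrite", 3, sl)
  trunk_tip <- g$tip; tab <- g$tab
  mid_z <- A / 2
  trunk_rows <- tab$part == "apical_dendrite"
  lm["d1"] <- tab$id[trunk_rows][which.min(abs(tab$z[trunk_rows] - mid_z))]
  # apical tuft: central continuation (tip = d2) plus four near-horizontal
  # branches whose lateral spread and caliber grow as the tree flattens (a
  # flat dendritic tree conserves its arbor span while losing vertical
  # extent)
  g <- grow_chain(tab, trunk_tip, c(0, 0, A), c(0, 0, A + 0.2 * p$flatness),
                  "apical_dendrite", 1.5, sl)
  lm["d2"] <- g$tip; tab <- g$tab
  spread <- 0.2 / p$flatness^2
  for (dir in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    g <- grow_chain(tab, trunk_tip, c(0, 0, A),
                    c(dir[1] * spread, dir[2] * spread, A + 0.05),
                    "apical_dendrite", 1.8 / p$flatness, sl)
    tab <- g$tab
  }
  # basal arbor: four oblique branches and one descending branch
  obl_tips <- integer(0)
  for (dir in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    g <- grow_chain(tab, 0L, c(0, 0, 0),
                    c(dir[1] * p$basal_radius, dir[2] * p$basal_radius, -0.25),
                    "basal_dendrite", 1.5, sl)
    obl_tips <- c(obl_tips, g$tip); tab <- g$tab
  }
  desc_len <- if (kind == "L5") 0.45 else 0.35
  g <- grow_chain(tab, 0L, c(0, 0, 0), c(0, 0, -desc_len),
                  "basal_dendrite", 2, sl)
  desc_tip <- g$tip; tab <- g$tab
  if (kind == "L5") {
    lm["d3"] <- obl_tips[1]
    lm["d4"] <- desc_tip
  } else {
    lm["d3"] <- desc_tip
  }
  # axon initial segment straight down from the soma
  g <- grow_chain(tab, 0L, c(0, 0, 0), c(0, 0, -p$iseg_length), "iseg", 2, sl)
  iseg_tip <- g$tip; tab <- g$tab
  lm["iseg"] <- iseg_tip
  if (kind == "L5") {
    # axon to the GM/WM boundary (b1), then bend (b2) and oblique run
    g <- grow_chain(tab, iseg_tip, c(0, 0, -p$iseg_length),
                    c(0, 0, -p$axon_length), "axon", 1.2, sl)
    lm["b1"] <- g$tip; tab <- g$tab
    zb <- -p$axon_length
    g <- grow_chain(tab, lm[["b1"]], c(0, 0, zb), c(0.15, 0, zb - 0.15),
                    "axon", 1.2, sl)
    lm["b2"] <- g$tip; tab <- g$tab
    g <- grow_chain(tab, lm[["b2"]], c(0.15, 0, zb - 0.15),
                    c(0.9, 0, zb - 0.3), "axon", 1.2, sl)
    lm["terminal"] <- g$tip; tab <- g$tab
  } else {
    g <- grow_chain(tab, iseg_tip, c(0, 0, -p$iseg_length),
                    c(0, 0, -p$axon_length), "axon", 1.2, sl)
    tab <- g$tab
    ax_rows <- tab$part == "axon"
    lm["mid"] <- tab$id[ax_rows][which.min(abs(tab$z[ax_rows] + p$axon_length / 2))]
    lm["terminal"] <- g$tip
  }
  morphology(tab, lm, kind = kind)
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`).
#' Type codes map to part tags: 1 soma, 2 axon, 3 basal dendrite, 4 apical
#' dendrite, 5 axon initial segment (package extension); other codes are
#' read as axon with a warning. Coordinates are converted from the file unit
#' to mm and radii to diameters in um.
#'
#' @param path File path.
#' @param unit Length unit of the file: `"um"` (SWC convention, default) or
#'   `"mm"`.
#' @return A [morphology()] (no landmarks).
#' @export
read_swc <- function(path, unit = c("um", "mm")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop(sprintf("SWC parse error at line %d: expected 7 columns", lineno[bad[1]]))
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    r <- which(apply(is.na(m), 1, any))[1]
    stop(sprintf("SWC parse error at line %d: non-numeric field", lineno[r]))
  }
  ids <- as.integer(m[, 1]); parents <- as.integer(m[, 7])
  id_map <- match(parents, ids)
  root <- which(parents == -1L)
  if (length(root) != 1L)
    stop("SWC file must contain exactly one root record (parent -1)")
  missing_parent <- which(parents != -1L & is.na(id_map))
  if (length(missing_parent))
    stop(sprintf("SWC parse error at line %d: parent %d not defined",
                 lineno[missing_parent[1]], parents[missing_parent[1]]))
  n <- nrow(m)
  in_order <- parents == -1L | (!is.na(id_map) & id_map < seq_len(n))
  if (all(in_order)) {
    # file already topologically ordered: preserve record order
    order_new <- seq_len(n)
    pos <- seq_len(n)
  } else {
    # breadth-first reordering from the root (also detects cycles)
    order_new <- integer(n); pos <- integer(n)
    placed <- logical(n)
    queue <- root; cnt <- 0L
    children <- split(seq_len(n), factor(id_map, levels = seq_len(n)))
    while (length(queue)) {
      r <- queue[1]; queue <- queue[-1]
      cnt <- cnt + 1L
      order_new[cnt] <- r; pos[r] <- cnt; placed[r] <- TRUE
      kids <- children[[r]]
      if (length(kids)) queue <- c(queue, kids)
    }
    if (cnt != n) {
      r <- which(!placed)[1]
      stop(sprintf("SWC parse error at line %d: record unreachable from root (cyclic or orphaned)",
                   lineno[r]))
    }
    m <- m[order_new, , drop = FALSE]
  }
  parent_new <- ifelse(m[, 7] == -1, -1L, pos[id_map[order_new]] - 1L)
  scale <- if (unit == "um") 1e-3 else 1
  type <- as.integer(m[, 2])
  part <- rep("axon", n)
  part[type == 1L] <- "soma"
  part[type == 3L] <- "basal_dendrite"
  part[type == 4L] <- "apical_dendrite"
  part[type == 5L] <- "iseg"
  if (any(!(type %in% c(1:5))))
    warning("unknown SWC type code(s) read as axon")
  diam_scale <- if (unit == "um") 2 else 2000
  morphology(data.frame(id = seq_len(n) - 1L, parent = as.integer(parent_new),
                        part = part,
                        x = m[, 3] * scale, y = m[, 4] * scale, z = m[, 5] * scale,
                        diam = m[, 6] * diam_scale),
             kind = "swc")
}

#' Write a morphology to SWC
#'
#' Inverse of [read_swc()]: part tags map to type codes 1 (soma), 2 (axon),
#' 3 (basal), 4 (apical), 5 (initial segment). Landmark annotations are not
#' representable in SWC and are dropped.
#'
#' @param m A [morphology()].
#' @param path Output file path.
#' @param unit Length unit to write: `"um"` (default) or `"mm"`.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(m, path, unit = c("um", "mm")) {
  unit <- match.arg(unit)
  stopifnot(inherits(m, "morphology"))
  comp <- m$comp
  type <- match(comp$part, c("soma", "axon", "basal_dendrite",
                             "apical_dendrite", "iseg"))
  type[is.na(type)] <- 2L
  scale <- if (unit == "um") 1e3 else 1
  rscale <- if (unit == "um") 0.5 else 5e-4
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   comp$id + 1L, type,
                   comp$x * scale, comp$y * scale, comp$z * scale,
                   comp$diam * rscale,
                   ifelse(comp$parent < 0, -1L, comp$parent + 1L))
  writeLines(c("# SWC export", lines), path)
  invisible(path)
}

# compartment segment lengths (mm); root uses its diameter as nominal length
compartment_lengths <- function(m) {
  comp <- m$comp
  len <- numeric(nrow(comp))
  has_par <- comp$parent >= 0
  pi_ <- match(comp$parent[has_par], comp$id)
  len[has_par] <- sqrt((comp$x[has_par] - comp$x[pi_])^2 +
                         (comp$y[has_par] - comp$y[pi_])^2 +
                         (comp$z[has_par] - comp$z[pi_])^2)
  len[!has_par] <- comp$diam[!has_par] * 1e-3
  len
}

#' Compartment center points
#'
#' Midpoints of each compartment's segment (the root's center is its own
#' endpoint), where extracellular potentials are sampled.
#'
#' @param m A [morphology()] or placed neuron.
#' @return Matrix (n x 3) of centers (mm).
#' @export
compartment_centers <- function(m) {
  comp <- m$comp
  out <- cbind(comp$x, comp$y, comp$z)
  has_par <- comp$parent >= 0
  pi_ <- match(comp$parent[has_par], comp$id)
  out[has_par, ] <- (out[has_par, , drop = FALSE] +
                       cbind(comp$x[pi_], comp$y[pi_], comp$z[pi_])) / 2
  out
}
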