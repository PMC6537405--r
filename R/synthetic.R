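# Seeded generator of ground-truthed multi-channel 3D scenes.
#
# The renderer emulates what a widefield epifluorescence microscope sees in a
# 3D collagen culture: light adds, so every slice is the SUM of in-focus
# nucleus cross-sections and the defocused halos of cells centered in other
# slices, on top of a center-bright vignetting field and Gaussian read noise.
# Nuclei are rendered as flat-top discs (stain saturation) with a brighter
# chromatin core; cross-sections dim toward the nucleus edge (chord-length
# scaling); beyond the nucleus the appearance decays into a blurred halo
# whose peak is halo_scale x the in-focus level at one nucleus radius of
# defocus. Apopxin (a membrane phosphatidylserine marker) is rendered as a
# ring around the nucleus, partially overlapping it, so that dual-marker
# overlap subtraction is exercised with nonzero, non-total intersections.

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

#' Parameters of a synthetic 3D scene
#'
#' Defaults describe the stated world of the assay scaled to a test-sized
#' stack: a 16-slice 256x256 volume (the paper-scale acquisition is 251
#' slices at 2 um) holding 30 cells — about 1.9 in-focus nuclei per slice,
#' denser than the real acquisitions. Intensities are 16-bit-scale: bright
#' nuclear stain (mean 8000) over a dim background (offset 100, lumped
#' read/autofluorescence noise SD 15), with per-cell brightness varying
#' lognormally (CV 0.10).
#'
#' @param n_cells number of cells in the volume.
#' @param volume_shape integer `(z, y, x)` extents.
#' @param nucleus_radius_px nucleus radius in xy pixels.
#' @param z_step_px z distance between slices, in xy-pixel units (default
#'   half a nucleus radius, i.e. a 2 um step on a ~4 um-radius nucleus).
#' @param fractions list of cell-fate fractions: `dead_ethd`,
#'   `dead_apopxin`, `dead_both` (mutually exclusive fates; their sum is
#'   the kill fraction), `s_phase` (among surviving cells), `gfp_lineage`
#'   (lineage-tag fraction). With `gfp_protected = TRUE` (default) death
#'   fractions apply to the GFP-negative target population only, which is
#'   the drug-insensitive-fibroblast co-culture situation.
#' @param intensity list: `nucleus_mean`, `cv`, `core_boost` (chromatin
#'   core relative brightness), `edge_sigma` (disc edge softness, px),
#'   `halo_scale` (halo peak relative to in-focus at one radius of
#'   defocus), `halo_power` (defocus decay steepness), `z_psf_growth`
#'   (halo blur growth per slice of defocus, px), `background`, `noise_sd`.
#' @param chord_power dimming exponent of near-edge nucleus cross-sections.
#' @param vignetting_strength relative falloff at the plane corners (0-1).
#' @param ring_width,ring_overlap apopxin ring geometry (px outside /
#'   inside the nucleus radius).
#' @param bit_depth 8 or 16.
#' @param truth_level ground-truth masks are the pre-noise, pre-vignetting
#'   render at or above `truth_level * nucleus_mean`.
#' @param gfp_protected see `fractions`.
#' @param z_confine optional `c(lo, hi)` (slice units, 0-based) confining
#'   cell centers in z — e.g. a narrow central band emulates a focal sheet
#'   of cells whose out-of-focus halos dominate the stack extremes.
#' @param seed integer seed; the whole scene (and every rendered byte) is a
#'   pure function of the parameters and this seed.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(n_cells = 30L,
                         volume_shape = c(16L, 256L, 256L),
                         nucleus_radius_px = 6,
                         z_step_px = nucleus_radius_px / 2,
                         fractions = list(),
                         intensity = list(),
                         chord_power = 0.8,
                         vignetting_strength = 0.15,
                         ring_width = 2,
                         ring_overlap = 1,
                         bit_depth = 16L,
                         truth_level = 0.5,
                         gfp_protected = TRUE,
                         z_confine = NULL,
                         seed = 1L) {
  fr <- utils::modifyList(list(dead_ethd = 0, dead_apopxin = 0,
                               dead_both = 0, s_phase = 0,
                               gfp_lineage = 0), fractions)
  it <- utils::modifyList(list(nucleus_mean = 8000, cv = 0.10,
                               core_boost = 0.4, edge_sigma = 0.4,
                               halo_scale = 0.3, halo_power = 2,
                               z_psf_growth = 1.5, background = 100,
                               noise_sd = 15), intensity)
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1L),
            nucleus_radius_px > 0, z_step_px > 0,
            bit_depth %in% c(8L, 16L), truth_level > 0, truth_level <= 1)
  kill <- fr$dead_ethd + fr$dead_apopxin + fr$dead_both
  if (kill > 1 + 1e-12) stop("dead fractions sum to more than 1")
  for (nm in c("s_phase", "gfp_lineage"))
    if (fr[[nm]] < 0 || fr[[nm]] > 1) stop(nm, " fraction outside [0, 1]")
  if (vignetting_strength < 0 || vignetting_strength >= 1)
    stop("vignetting_strength must be in [0, 1)")
  # expected in-focus crowding; pathological densities destabilize
  # histogram thresholding and are no longer the assay's regime
  footprint <- n_cells * pi * nucleus_radius_px^2 *
    (2 * nucleus_radius_px / z_step_px) / prod(volume_shape)
  if (footprint > 0.25)
    stop("infeasible density: expected nucleus overlap too high")
  structure(list(n_cells = as.integer(n_cells),
                 volume_shape = as.integer(volume_shape),
                 nucleus_radius_px = nucleus_radius_px,
                 z_step_px = z_step_px, fractions = fr, intensity = it,
                 chord_power = chord_power,
                 vignetting_strength = vignetting_strength,
                 ring_width = ring_width, ring_overlap = ring_overlap,
                 bit_depth = as.integer(bit_depth),
                 truth_level = truth_level,
                 gfp_protected = isTRUE(gfp_protected),
                 z_confine = z_confine,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Simulate a ground-truth cell list
#'
#' Places `n_cells` uniformly at random in the volume (with margins so each
#' nucleus fits) and draws cell fates: a multinomial draw over
#' alive / EtHd-only / apopxin-only / both-marked per the configured dead
#' fractions, then S-phase among survivors and the GFP lineage tag.
#' Deterministic given `params$seed`.
#'
#' @param params a [scene_params()] object.
#' @return object of class `synthetic_scene`: `cells` (data frame with
#'   columns `x`, `y`, `z` (slice units, 0-based, continuous), `level`,
#'   `fate`, `s_phase`, `gfp`) and `params`.
#' @export
simulate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  nz <- params$volume_shape[1L]
  ny <- params$volume_shape[2L]
  nx <- params$volume_shape[3L]
  r <- params$nucleus_radius_px
  n <- params$n_cells
  zmargin <- r / params$z_step_px + 0.5
  z_lo <- zmargin; z_hi <- nz - 1 - zmargin
  if (!is.null(params$z_confine)) {
    z_lo <- params$z_confine[1L]; z_hi <- params$z_confine[2L]
  }
  if (z_hi < z_lo && n > 0)
    stop("volume too shallow for the nucleus radius")
  fr <- params$fractions
  cells <- with_seed(params$seed, {
    # fixed draw order (x, y, z, level, fate, s_phase, gfp): tests
    # re-derive fate counts by replaying this sequence
    x <- stats::runif(n, r + 2, nx - r - 1)
    y <- stats::runif(n, r + 2, ny - r - 1)
    z <- stats::runif(n, z_lo, z_hi)
    sdlog <- sqrt(log(1 + params$intensity$cv^2))
    level <- stats::rlnorm(n, log(params$intensity$nucleus_mean) -
                             sdlog^2 / 2, sdlog)
    fate <- if (n > 0)
      sample(c("alive", "ethd", "apopxin", "both"), n, replace = TRUE,
             prob = c(1 - fr$dead_ethd - fr$dead_apopxin - fr$dead_both,
                      fr$dead_ethd, fr$dead_apopxin, fr$dead_both))
    else character(0)
    s_phase <- stats::runif(n) < fr$s_phase & fate == "alive"
    gfp <- stats::runif(n) < fr$gfp_lineage
    if (params$gfp_protected && any(gfp)) {
      fate[gfp] <- "alive"
      s_phase[gfp] <- FALSE
    }
    data.frame(x = x, y = y, z = z, level = level, fate = fate,
               s_phase = s_phase, gfp = gfp, stringsAsFactors = FALSE)
  })
  structure(list(cells = cells, params = params),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d cells in %s volume (seed %d)\n",
              nrow(x$cells),
              paste(x$params$volume_shape, collapse = "x"),
              x$params$seed))
  print(table(fate = x$cells$fate))
  invisible(x)
}

# which cells light up in a channel
cells_for_role <- function(scene, role) {
  cl <- scene$cells
  switch(role,
         nuclear = cl,
         dead_membrane = cl[cl$fate %in% c("ethd", "both"), , drop = FALSE],
         dead_apoptotic = cl[cl$fate %in% c("apopxin", "both"), , drop = FALSE],
         proliferation = cl[cl$s_phase, , drop = FALSE],
         lineage_gfp = cl[cl$gfp, , drop = FALSE],
         stop("unknown channel role: ", role))
}

# add one disc (or annulus) appearance to a plane, in place via return
add_blob <- function(plane, cy, cx, level, rad, edge, core_boost,
                     inner = NULL) {
  ny <- nrow(plane); nx <- ncol(plane)
  ext <- ceiling(rad + 4 * edge + 1)
  y0 <- max(1L, floor(cy) - ext); y1 <- min(ny, ceiling(cy) + ext)
  x0 <- max(1L, floor(cx) - ext); x1 <- min(nx, ceiling(cx) + ext)
  if (y0 > y1 || x0 > x1 || rad < 0.5) return(plane)
  dy2 <- ((y0:y1) - cy)^2
  dx2 <- ((x0:x1) - cx)^2
  d <- sqrt(outer(dy2, dx2, "+"))
  prof <- ifelse(d <= rad, 1, exp(-(d - rad)^2 / (2 * edge^2)))
  if (!is.null(inner) && inner > 0) {
    # annulus: cut out the interior with its own soft edge
    prof <- prof * ifelse(d >= inner, 1,
                          exp(-(inner - d)^2 / (2 * edge^2)))
  }
  blob <- level * prof
  if (core_boost > 0)
    blob <- blob * (1 + core_boost * exp(-d^2 / (2 * (rad / 2 + 0.5)^2)))
  plane[y0:y1, x0:x1] <- plane[y0:y1, x0:x1] + blob
  plane
}

vignette_field <- function(ny, nx, strength) {
  if (strength <= 0) return(NULL)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  rho2 <- outer(((1:ny) - cy)^2, ((1:nx) - cx)^2, "+")
  sv2 <- max(rho2) / (-2 * log(1 - strength))
  exp(-rho2 / (2 * sv2))
}

# noiseless, unvignetted photon image of one channel (list of planes)
render_pure <- function(scene, role) {
  p <- scene$params
  nz <- p$volume_shape[1L]; ny <- p$volume_shape[2L]; nx <- p$volume_shape[3L]
  r <- p$nucleus_radius_px
  it <- p$intensity
  ring <- role == "dead_apoptotic"
  cl <- cells_for_role(scene, role)
  planes <- replicate(nz, matrix(0, ny, nx), simplify = FALSE)
  if (nrow(cl) == 0L) return(planes)
  # farthest defocus at which the halo is still rendered (att >= 0.02)
  dz_max <- r * (log(0.02) / log(it$halo_scale))^(1 / it$halo_power)
  for (i in seq_len(nrow(cl))) {
    cy <- cl$y[i]; cx <- cl$x[i]; cz <- cl$z[i]; lv <- cl$level[i]
    k_lo <- max(1L, ceiling(cz - dz_max / p$z_step_px) + 1L)
    k_hi <- min(nz, floor(cz + dz_max / p$z_step_px) + 1L)
    for (k in k_lo:k_hi) {
      dz <- abs((k - 1) - cz) * p$z_step_px
      if (dz < r) {
        rad <- sqrt(r^2 - dz^2)
        level_k <- lv * (rad / r)^p$chord_power
        planes[[k]] <- if (ring)
          add_blob(planes[[k]], cy, cx, level_k, rad + p$ring_width,
                   it$edge_sigma, 0,
                   inner = max(rad - p$ring_overlap, 0))
        else
          add_blob(planes[[k]], cy, cx, level_k, rad, it$edge_sigma,
                   it$core_boost)
      } else {
        att <- it$halo_scale^((dz / r)^it$halo_power)
        if (att < 0.02) next
        edge_k <- it$edge_sigma + it$z_psf_growth * (dz - r) / p$z_step_px
        planes[[k]] <- if (ring)
          add_blob(planes[[k]], cy, cx, att * lv, r + p$ring_width,
                   edge_k, 0, inner = max(r - p$ring_overlap, 0))
        else
          add_blob(planes[[k]], cy, cx, att * lv, r, edge_k, 0)
      }
    }
  }
  planes
}

role_index <- function(role) match(role, CHANNEL_ROLES)

#' Render one channel of a scene as an acquired image stack
#'
#' Sums the in-focus and defocused appearance of every positive cell into
#' each slice, multiplies by the centered vignetting field (1 at the
#' center, `1 - vignetting_strength` at the corners), adds the background
#' offset and Gaussian read noise, rounds, and clips to the bit depth.
#' Bit-identical for a given scene seed and role.
#'
#' @param scene a [simulate_scene()] result.
#' @param role channel role (see [CHANNEL_ROLES]).
#' @param noise,vignetting set `FALSE` for diagnostic noiseless/flat
#'   renders.
#' @param well,position metadata stamped on the returned stack.
#' @return an [image_stack()].
#' @export
render_channel <- function(scene, role, noise = TRUE, vignetting = TRUE,
                           well = "w1", position = 0L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  p <- scene$params
  it <- p$intensity
  planes <- render_pure(scene, role)
  V <- if (vignetting) vignette_field(p$volume_shape[2L],
                                      p$volume_shape[3L],
                                      p$vignetting_strength) else NULL
  maxv <- 2^p$bit_depth - 1
  noise_seed <- (p$seed * 31L + role_index(role) * 101L) %% 2147483647L
  planes <- with_seed(noise_seed, lapply(planes, function(pl) {
    if (!is.null(V)) pl <- pl * V
    pl <- pl + it$background
    if (noise && it$noise_sd > 0)
      pl <- pl + stats::rnorm(length(pl), 0, it$noise_sd)
    pl <- round(pl)
    pl[pl < 0] <- 0
    pl[pl > maxv] <- maxv
    storage.mode(pl) <- "integer"
    pl
  }))
  image_stack(planes, well = well, position = position, channel = role,
              bit_depth = p$bit_depth)
}

#' Ground-truth foreground mask of one channel
#'
#' The pre-noise, pre-vignetting render thresholded at
#' `truth_level * nucleus_mean`: the voxels genuinely occupied by in-focus
#' marker signal (defocus halos fall below the level by construction).
#'
#' @inheritParams render_channel
#' @return list of logical matrices, one per slice.
#' @export
ground_truth_mask <- function(scene, role) {
  stopifnot(inherits(scene, "synthetic_scene"))
  lvl <- scene$params$truth_level * scene$params$intensity$nucleus_mean
  lapply(render_pure(scene, role), function(pl) pl >= lvl)
}

#' @rdname ground_truth_mask
#' @export
ground_truth_count <- function(scene, role) {
  sum(vapply(ground_truth_mask(scene, role), sum, 0L))
}

#' Render several channels of one scene
#'
#' @param scene a [simulate_scene()] result.
#' @param roles channel roles to render (default: the four monoculture
#'   assay channels).
#' @inheritParams render_channel
#' @return named list of [image_stack()]s.
#' @export
render_scene <- function(scene,
                         roles = c("nuclear", "dead_membrane",
                                   "dead_apoptotic", "proliferation"),
                         well = "w1", position = 0L) {
  stats::setNames(lapply(roles, function(ro)
    render_channel(scene, ro, well = well, position = position)), roles)
}

# four-parameter logistic response at dose d
logistic_effect <- function(d, ec50, hill, floor_val, ceil_val) {
  if (d <= 0) return(floor_val)
  frac <- d^hill / (d^hill + ec50^hill)
  floor_val + (ceil_val - floor_val) * frac
}

#' Default filename tokens for the synthetic plate writer
#' @export
DEFAULT_CHANNEL_TOKENS <- c(nuclear = "hoechst", dead_membrane = "ethd",
                            dead_apoptotic = "apopxin",
                            proliferation = "edu", lineage_gfp = "gfp")

#' Simulate a dose-series plate
#'
#' One well per dose (dose 0 is the DMSO vehicle control), `n_positions`
#' imaging positions per well. The planted kill fraction follows a
#' four-parameter logistic of dose (split 45/25/30 between EtHd-only,
#' apopxin-only and both-marked fates) and the S-phase fraction falls from
#' `s_max` to `s_min` likewise; alternatively pass `fractions_by_dose` to
#' plant per-dose fractions directly. With `dir` the plate is written as a
#' TIFF tree (one file per slice per channel, channel identified by a
#' filename token) plus a layout/naming config JSON and a ground-truth
#' CSV; otherwise stacks are returned in memory.
#'
#' @param doses numeric vector including 0 (the control).
#' @param base a [scene_params()] used for every scene (fates overridden
#'   per dose; seeds derived per well/position).
#' @param n_positions imaging positions per well.
#' @param response list: `kill_max`, `viability_ec50`, `viability_hill`,
#'   `s_max`, `s_min`, `prolif_ec50`, `prolif_hill`.
#' @param fractions_by_dose optional data frame with columns `dose`,
#'   `kill_fraction`, `s_phase_fraction` overriding `response`.
#' @param roles channels to render.
#' @param dir optional output directory for the TIFF tree.
#' @param tokens filename tokens per role (for `dir`).
#' @param seed plate seed; per-scene seeds are derived from it.
#' @return list with `layout` ([plate_layout()]), `truth` (data frame),
#'   `scenes` (named list `well/position -> synthetic_scene`), `stacks`
#'   (named list `well/position -> role -> image_stack`, only when `dir`
#'   is `NULL`), `dir`, `config_path` (when written).
#' @export
simulate_plate <- function(doses,
                           base = scene_params(),
                           n_positions = 4L,
                           response = list(kill_max = 0.9,
                                           viability_ec50 = 100,
                                           viability_hill = 1.2,
                                           s_max = 0.4, s_min = 0.05,
                                           prolif_ec50 = 10,
                                           prolif_hill = 1.2),
                           fractions_by_dose = NULL,
                           roles = c("nuclear", "dead_membrane",
                                     "dead_apoptotic", "proliferation"),
                           dir = NULL,
                           tokens = DEFAULT_CHANNEL_TOKENS,
                           seed = base$seed) {
  stopifnot(any(doses == 0))
  doses <- sort(unique(doses))
  wells <- paste0("w", seq_along(doses))
  labels <- ifelse(doses == 0, "DMSO",
                   paste0("dose_", format(doses, trim = TRUE,
                                          scientific = FALSE)))
  layout <- plate_layout(stats::setNames(labels, wells), "DMSO")
  if (!is.null(fractions_by_dose)) {
    stopifnot(all(c("dose", "kill_fraction", "s_phase_fraction") %in%
                    names(fractions_by_dose)))
    kill <- fractions_by_dose$kill_fraction[
      match(doses, fractions_by_dose$dose)]
    sph <- fractions_by_dose$s_phase_fraction[
      match(doses, fractions_by_dose$dose)]
    if (anyNA(kill) || anyNA(sph)) stop("fractions_by_dose misses a dose")
  } else {
    kill <- vapply(doses, logistic_effect, 0, ec50 = response$viability_ec50,
                   hill = response$viability_hill, floor_val = 0,
                   ceil_val = response$kill_max)
    sph <- vapply(doses, logistic_effect, 0, ec50 = response$prolif_ec50,
                  hill = response$prolif_hill, floor_val = response$s_max,
                  ceil_val = response$s_min)
  }
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scenes <- list(); stacks <- list(); truth <- list()
  for (wi in seq_along(doses)) {
    for (pos in seq_len(n_positions) - 1L) {
      sc_seed <- (seed * 104729L + wi * 1009L + pos * 31L) %% 2147483647L
      fr <- base$fractions
      fr$dead_ethd <- 0.45 * kill[wi]
      fr$dead_apopxin <- 0.25 * kill[wi]
      fr$dead_both <- 0.30 * kill[wi]
      fr$s_phase <- sph[wi]
      prm <- base
      prm$fractions <- fr
      prm$seed <- sc_seed
      class(prm) <- "scene_params"
      scene <- simulate_scene(prm)
      key <- paste0(wells[wi], "/", pos)
      scenes[[key]] <- scene
      st <- render_scene(scene, roles, well = wells[wi], position = pos)
      if (is.null(dir)) {
        stacks[[key]] <- st
      } else {
        for (ro in roles) {
          pls <- st[[ro]]$planes
          for (z in seq_along(pls)) {
            fn <- sprintf("%s_p%d_z%03d_%s.tif", wells[wi], pos, z - 1L,
                          tokens[[ro]])
            write_tiff(pls[[z]], file.path(dir, fn),
                       bit_depth = base$bit_depth)
          }
        }
      }
      truth[[key]] <- data.frame(well = wells[wi], position = pos,
                                 dose = doses[wi],
                                 treatment = labels[wi],
                                 kill_fraction = kill[wi],
                                 s_phase_fraction = sph[wi],
                                 seed = sc_seed,
                                 stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  config_path <- NULL
  if (!is.null(dir)) {
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    config_path <- file.path(dir, "layout.json")
    jsonlite::write_json(
      list(channels = as.list(tokens[roles]),
           wells = as.list(layout$assignments),
           control = layout$control_label),
      config_path, auto_unbox = TRUE, pretty = TRUE)
  }
  list(layout = layout, truth = truth, scenes = scenes,
       stacks = if (is.null(dir)) stacks else NULL,
       dir = dir, config_path = config_path)
}
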