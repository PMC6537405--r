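#' Channel roles
#'
#' The roles a fluorescence channel can play in the assay: `nuclear`
#' (Hoechst, all nuclei — mandatory for any scoring run), `dead_membrane`
#' (ethidium homodimer, membrane-compromised dead cells), `dead_apoptotic`
#' (apopxin, externalized phosphatidylserine), `proliferation` (EdU,
#' S-phase DNA synthesis) and `lineage_gfp` (H2B-eGFP lineage tag in
#' co-culture).
#'
#' @export
CHANNEL_ROLES <- c("nuclear", "dead_membrane", "dead_apoptotic",
                   "proliferation", "lineage_gfp")

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "&")

#' Per-position foreground pixel areas and pairwise intersections
#'
#' Sums foreground pixels per channel over all z-slices, and pairwise mask
#' intersections slice-wise in 2D (never via z-projection, which would merge
#' distinct cells). All counts are integers; intersection counts can never
#' exceed either member's area.
#'
#' @param masks named list (names are channel roles); each element a list of
#'   logical matrices, one per z-slice, all the same shape and slice count.
#' @param key optional identifier (e.g. `"well/position"`) carried through.
#' @return an object of class `channel_areas`: `area` (named numeric),
#'   `intersections` (named numeric keyed `"roleA&roleB"` with roles
#'   sorted), `n_slices`, `key`.
#' @export
measure_areas <- function(masks, key = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1L, !is.null(names(masks)))
  roles <- names(masks)
  ns <- vapply(masks, length, 0L)
  if (length(unique(ns)) != 1L)
    stop("channel mask stacks have differing slice counts")
  dims <- lapply(masks, function(mm) dim(mm[[1L]]))
  for (r in roles) for (pl in masks[[r]]) {
    if (!identical(dim(pl), dims[[1L]]))
      stop("mask shape mismatch in channel ", r)
  }
  area <- vapply(masks, function(mm) sum(vapply(mm, sum, 0L)), 0)
  inter <- numeric(0)
  if (length(roles) > 1L) {
    combs <- utils::combn(roles, 2L, simplify = FALSE)
    inter <- vapply(combs, function(ab) {
      sum(vapply(seq_len(ns[[1L]]), function(z)
        sum(masks[[ab[1L]]][[z]] & masks[[ab[2L]]][[z]]), 0L))
    }, 0)
    names(inter) <- vapply(combs, function(ab) pair_key(ab[1L], ab[2L]), "")
  }
  structure(list(area = area, intersections = inter,
                 n_slices = ns[[1L]], key = key),
            class = "channel_areas")
}

#' @export
print.channel_areas <- function(x, ...) {
  cat("<channel_areas>", if (!is.null(x$key)) x$key else "", "\n")
  cat("  areas:", paste(names(x$area), format(x$area), sep = "=",
                        collapse = ", "), "\n")
  if (length(x$intersections))
    cat("  intersections:", paste(names(x$intersections),
                                  format(x$intersections), sep = "=",
                                  collapse = ", "), "\n")
  invisible(x)
}

intersection_of <- function(areas, a, b) {
  v <- areas$intersections[[pair_key(a, b)]]
  if (is.null(v)) 0 else v
}

#' Overlap-corrected dead-cell pixel area
#'
#' Cells in late death can be positive for both dead markers; to avoid
#' counting them twice the overlapping pixel area of the two dead-cell
#' channels is subtracted from their total (inclusion-exclusion):
#' `dead = EtHd + apopxin - EtHd&apopxin`. If only one death channel was
#' configured (e.g. co-culture runs drop apopxin), its area is returned
#' as-is.
#'
#' @param areas a [measure_areas()] result.
#' @return non-negative integer pixel count.
#' @export
dead_area <- function(areas) {
  stopifnot(inherits(areas, "channel_areas"))
  has_e <- "dead_membrane" %in% names(areas$area)
  has_a <- "dead_apoptotic" %in% names(areas$area)
  if (has_e && has_a) {
    areas$area[["dead_membrane"]] + areas$area[["dead_apoptotic"]] -
      intersection_of(areas, "dead_membrane", "dead_apoptotic")
  } else if (has_e) {
    areas$area[["dead_membrane"]]
  } else if (has_a) {
    areas$area[["dead_apoptotic"]]
  } else {
    stop("no death channel measured")
  }
}

#' Co-culture channel arithmetic
#'
#' In melanoma/fibroblast co-cultures the fibroblasts carry an H2B-eGFP
#' nuclear tag. Target-cell (melanoma) pixels are obtained by subtracting
#' the GFP-overlapping pixels from the Hoechst and EtHd totals; the
#' EtHd-GFP intersection itself is the fibroblast death signal. Subtraction
#' uses the mask *intersections* (not raw GFP area) so counts can never go
#' negative when GFP bleeds outside Hoechst.
#'
#' @param areas a [measure_areas()] result including `lineage_gfp`.
#' @param raw_subtraction if `TRUE`, subtract the raw GFP area instead of
#'   the intersection (clamped at zero) — parity mode only.
#' @return an object of class `coculture_areas` with fields
#'   `hoechst_total`, `gfp`, `ethd_total`, `hoechst_target`, `ethd_target`,
#'   `ethd_fibroblast`.
#' @export
coculture_areas <- function(areas, raw_subtraction = FALSE) {
  stopifnot(inherits(areas, "channel_areas"))
  if (!"lineage_gfp" %in% names(areas$area))
    stop("co-culture arithmetic needs a lineage_gfp channel")
  if (!"nuclear" %in% names(areas$area))
    stop("co-culture arithmetic needs the nuclear channel")
  hoechst <- areas$area[["nuclear"]]
  gfp <- areas$area[["lineage_gfp"]]
  ethd <- if ("dead_membrane" %in% names(areas$area))
    areas$area[["dead_membrane"]] else 0
  hg <- intersection_of(areas, "nuclear", "lineage_gfp")
  eg <- intersection_of(areas, "dead_membrane", "lineage_gfp")
  if (raw_subtraction) { hg <- min(gfp, hoechst); eg <- min(gfp, ethd) }
  structure(list(hoechst_total = hoechst, gfp = gfp, ethd_total = ethd,
                 hoechst_target = hoechst - hg,
                 ethd_target = ethd - eg,
                 ethd_fibroblast = eg),
            class = "coculture_areas")
}

#' Colocalization fraction of one channel within another
#'
#' `intersection(a, b) / area(b)` — e.g. the GFP-in-Hoechst fraction used as
#' the co-culture QC bar (expected above 0.8 when GFP and Hoechst label the
#' same nuclei).
#'
#' @param areas a [measure_areas()] result.
#' @param a,b channel roles.
#' @return a number in `[0, 1]`, or `NA` (with a warning) when `area[b]` is
#'   zero.
#' @export
coloc_fraction <- function(areas, a, b) {
  stopifnot(inherits(areas, "channel_areas"))
  if (!b %in% names(areas$area) || areas$area[[b]] == 0) {
    warning("coloc_fraction undefined: zero reference area for ", b)
    return(NA_real_)
  }
  intersection_of(areas, a, b) / areas$area[[b]]
}
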