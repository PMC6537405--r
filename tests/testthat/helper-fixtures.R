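# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; no binary fixtures ship with the package.

# --- independent brute-force oracle for Yen's criterion -------------------
# Direct transcription of the entropic-correlation objective, recomputing
# every sum per cut; deliberately slower and structured differently from
# the package's vectorized implementation.
yen_oracle <- function(hist) {
  p <- hist$counts / sum(hist$counts)
  nb <- length(p)
  tc <- rep(-Inf, nb - 1L)
  for (t in seq_len(nb - 1L)) {
    # both classes must hold at least one pixel (count-based validity)
    if (sum(hist$counts[seq_len(t)]) == 0L) next
    if (sum(hist$counts[(t + 1L):nb]) == 0L) next
    P <- 0; A <- 0
    for (i in seq_len(t)) { P <- P + p[i]; A <- A + p[i]^2 }
    B <- 0
    for (i in (t + 1L):nb) B <- B + p[i]^2
    tc[t] <- -log(max(A * B, .Machine$double.xmin) / (P^2 * (1 - P)^2))
  }
  # same tie rule as the implementation: lowest cut within rounding noise
  top <- max(tc)
  hist$edges[which(tc >= top - 1e-10 * max(1, abs(top)))[1L] + 1L]
}

random_histogram <- function(seed, max_bins = 256L) {
  set.seed(seed)
  nb <- sample(8:max_bins, 1L)
  counts <- rpois(nb, lambda = sample(c(0.5, 5, 50), nb, replace = TRUE))
  # ensure at least two occupied bins
  if (sum(counts > 0) < 2L) counts[c(1L, nb)] <- counts[c(1L, nb)] + 1L
  structure(list(counts = counts,
                 edges = seq(0, sample(50:5000, 1L), length.out = nb + 1L)),
            class = "intensity_histogram")
}

# --- pixel-by-pixel double-loop intersection oracle -----------------------
intersection_oracle <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (a[i, j] && b[i, j]) n <- n + 1L
  n
}

# --- canonical synthetic worlds ------------------------------------------
# Default fixture: the package's stated world (30 cells, 16 x 256 x 256).
default_scene <- function(seed, fractions = list()) {
  simulate_scene(scene_params(fractions = fractions, seed = seed))
}

# Dose-plate world: smaller nuclei at matched areal density pack more cells
# per plane (better fate statistics per CPU second).
plate_params <- function(seed, fractions = list(), n_cells = 70L,
                         nz = 12L, nucleus_mean = 8000) {
  scene_params(n_cells = n_cells, nucleus_radius_px = 4,
               volume_shape = c(nz, 256L, 256L),
               fractions = fractions,
               intensity = list(nucleus_mean = nucleus_mean), seed = seed)
}

# Short synthetic stacks pool 5 of 12 central slices for threshold
# estimation (the production default 0.2 assumes paper-scale 251-slice
# stacks where it already pools ~50 slices).
PLATE_THRESHOLD <- list(central_fraction = 0.42)

SCORE_DEFAULTS <- list(orientation = "edu_over_hoechst", pseudocount = 1L,
                       coculture = FALSE)

# In-memory scoring of a set of rendered positions (exported-API path).
score_stacks_in_memory <- function(stacks_by_key, layout,
                                   threshold = PLATE_THRESHOLD,
                                   coculture = FALSE) {
  rows <- lapply(names(stacks_by_key), function(key) {
    parts <- strsplit(key, "/")[[1L]]
    res <- analyze_stacks(stacks_by_key[[key]], threshold = threshold,
                          key = key)
    areas <- res$areas
    v <- viability_ratio(areas, coculture = coculture)
    row <- data.frame(well = parts[1L], position = as.integer(parts[2L]),
                      metric = "viability", log_ratio = v$log_ratio,
                      nuclear_has_signal = res$decisions$nuclear$has_signal,
                      stringsAsFactors = FALSE)
    if ("proliferation" %in% names(areas$area)) {
      pr <- proliferation_ratio(areas)
      row <- rbind(row, data.frame(well = parts[1L],
                                   position = as.integer(parts[2L]),
                                   metric = "proliferation",
                                   log_ratio = pr$log_ratio,
                                   nuclear_has_signal =
                                     res$decisions$nuclear$has_signal,
                                   stringsAsFactors = FALSE))
    }
    row
  })
  treatment_scores(do.call(rbind, rows), layout)
}

# The 4-dose recovery plate (kill 0/0.2/0.5/0.9, S-phase 0.4 -> 0.05).
RECOVERY_FRACTIONS <- data.frame(dose = c(0, 10, 100, 1000),
                                 kill_fraction = c(0, 0.2, 0.5, 0.9),
                                 s_phase_fraction = c(0.4, 0.26, 0.13, 0.05))

build_recovery_plate <- function(seed, n_positions = 5L) {
  simulate_plate(doses = RECOVERY_FRACTIONS$dose,
                 base = plate_params(seed, nz = 10L),
                 n_positions = n_positions,
                 fractions_by_dose = RECOVERY_FRACTIONS,
                 seed = seed)
}

scores_by_dose <- function(scores, truth, metric) {
  tr <- unique(truth[order(truth$dose), c("treatment", "dose")])
  sub <- scores[scores$metric == metric, , drop = FALSE]
  sub$score[match(tr$treatment, sub$treatment)]
}

# Halo fixture: a band of cells in the stack center; edge slices carry only
# strongly defocused halos (halo_scale 0.3 pinned at one radius of defocus).
halo_fixture_scene <- function(seed) {
  simulate_scene(scene_params(n_cells = 30L, nucleus_radius_px = 6,
                              volume_shape = c(18L, 256L, 256L),
                              z_confine = c(6.5, 10.5), seed = seed))
}
HALO_EDGE_SLICES <- c(1:4, 15:18)   # 1-based, outside the band's focus reach
HALO_NEAR_SLICES <- c(4:5, 14:15)   # halo-only slices nearest the band

# Paired co-culture fixture: one scene rendered with its GFP fibroblasts
# (co-culture) and with them removed (matched melanoma monoculture).
drop_gfp_cells <- function(scene) {
  scene$cells <- scene$cells[!scene$cells$gfp, , drop = FALSE]
  scene
}

build_coculture_pair <- function(seed_base, n_positions = 8L,
                                 kill_ctrl = 0.15, kill_trt = 0.55) {
  layout <- plate_layout(c(w1 = "DMSO", w2 = "treated"), "DMSO")
  co <- list(); mono <- list()
  for (wi in 1:2) for (pos in seq_len(n_positions) - 1L) {
    k <- if (wi == 1L) kill_ctrl else kill_trt
    p <- scene_params(n_cells = 60L, nucleus_radius_px = 4,
                      volume_shape = c(12L, 256L, 256L),
                      fractions = list(dead_ethd = 0.7 * k,
                                       dead_both = 0.3 * k,
                                       gfp_lineage = 0.5),
                      seed = seed_base + wi * 977L + pos * 31L)
    sc <- simulate_scene(p)
    key <- paste0("w", wi, "/", pos)
    co[[key]] <- render_scene(sc, c("nuclear", "dead_membrane",
                                    "lineage_gfp"),
                              well = paste0("w", wi), position = pos)
    mono[[key]] <- render_scene(drop_gfp_cells(sc),
                                c("nuclear", "dead_membrane"),
                                well = paste0("w", wi), position = pos)
  }
  list(co = co, mono = mono, layout = layout)
}

treated_viability <- function(scores) {
  scores$score[scores$treatment == "treated" & scores$metric == "viability"]
}

# Tiny plate for I/O tests: 3 wells x 2 positions x 3 channels x 5 slices.
tiny_plate_params <- function(seed) {
  scene_params(n_cells = 3L, nucleus_radius_px = 2,
               volume_shape = c(5L, 32L, 32L), z_confine = c(2, 2),
               seed = seed)
}

write_tiny_plate <- function(dir, seed = 1L) {
  simulate_plate(doses = c(0, 1, 2), base = tiny_plate_params(seed),
                 n_positions = 2L,
                 fractions_by_dose = data.frame(
                   dose = c(0, 1, 2), kill_fraction = c(0, 0.3, 0.6),
                   s_phase_fraction = c(0, 0, 0)),
                 roles = c("nuclear", "dead_membrane", "dead_apoptotic"),
                 dir = dir, seed = seed)
}
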