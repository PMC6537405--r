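#' One channel's ordered z-stack
#'
#' @param planes list of integer matrices (ascending z), all the same
#'   shape, intensities `>= 0`.
#' @param well,position,channel acquisition metadata.
#' @param bit_depth 8 or 16.
#' @param z_spacing_um optional z step in micrometers.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(planes, well = NA_character_, position = NA_integer_,
                        channel = NA_character_, bit_depth = 16L,
                        z_spacing_um = NULL) {
  stopifnot(is.list(planes), length(planes) >= 1L)
  d1 <- dim(planes[[1L]])
  for (i in seq_along(planes)) {
    if (!is.matrix(planes[[i]]) || !identical(dim(planes[[i]]), d1))
      stop("plane ", i, " has a different shape")
    if (min(planes[[i]]) < 0) stop("negative intensities in plane ", i)
  }
  structure(list(planes = planes,
                 key = list(well = well, position = as.integer(position),
                            channel = channel),
                 bit_depth = as.integer(bit_depth),
                 z_spacing_um = z_spacing_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$planes[[1L]])
  cat(sprintf("<image_stack> %s/p%s [%s]: %d slices of %dx%d (%d-bit)\n",
              x$key$well, x$key$position, x$key$channel,
              length(x$planes), d[1L], d[2L], x$bit_depth))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) {
  c(length(x$planes), dim(x$planes[[1L]]))
}

# last integer run in a file name (before the extension) = z index
parse_z_index <- function(name) {
  stem <- sub("\\.[^.]*$", "", name)
  runs <- regmatches(stem, gregexpr("[0-9]+", stem))[[1L]]
  if (length(runs) == 0L) return(NA_integer_)
  as.integer(runs[length(runs)])
}

parse_stack_fields <- function(name) {
  stem <- sub("\\.[^.]*$", "", name)
  fields <- strsplit(stem, "_", fixed = TRUE)[[1L]]
  pos_field <- grep("^p[0-9]+$", fields, value = TRUE)
  list(well = fields[1L],
       position = if (length(pos_field))
         as.integer(sub("^p", "", pos_field[1L])) else NA_integer_,
       z = parse_z_index(name))
}

#' Discover and group the TIFF slices of a dataset
#'
#' Walks `root_dir` for TIFF files and assigns each to a channel by the
#' unique filename token it contains (case-insensitive, per the
#' NamesAndTypes-style convention of naming each channel distinctively at
#' acquisition time). The well is the leading underscore-delimited field,
#' the position a `p<digits>` field, and the z index the last integer run
#' before the extension. Files matching zero or two-plus tokens, or with
#' unparseable fields, are reported in a rejects table — never silently
#' dropped. Discovery is a pure function of the directory listing and the
#' token map.
#'
#' @param root_dir directory to walk (recursively).
#' @param channel_tokens named character vector `role -> token`; tokens
#'   must not be substrings of one another.
#' @return object of class `dataset_manifest`: `manifest` (data frame
#'   `file`, `well`, `position`, `role`, `z`, sorted), `rejects` (data
#'   frame `file`, `reason`), `root`.
#' @export
discover_dataset <- function(root_dir, channel_tokens) {
  if (!dir.exists(root_dir)) stop("root_dir does not exist: ", root_dir)
  stopifnot(is.character(channel_tokens), length(channel_tokens) >= 1L,
            !is.null(names(channel_tokens)))
  bad_roles <- setdiff(names(channel_tokens), CHANNEL_ROLES)
  if (length(bad_roles))
    stop("unknown channel roles: ", paste(bad_roles, collapse = ", "))
  toks <- tolower(channel_tokens)
  if (anyDuplicated(toks)) stop("duplicate channel tokens")
  for (i in seq_along(toks)) for (j in seq_along(toks)) {
    if (i != j && grepl(toks[i], toks[j], fixed = TRUE))
      stop("channel tokens overlap: '", toks[i], "' is a substring of '",
           toks[j], "'")
  }
  files <- sort(list.files(root_dir, pattern = "\\.tiff?$",
                           recursive = TRUE, ignore.case = TRUE,
                           full.names = TRUE))
  rows <- list(); rejects <- list()
  for (f in files) {
    base <- tolower(basename(f))
    hit <- which(vapply(toks, grepl, FALSE, x = base, fixed = TRUE))
    if (length(hit) == 0L) {
      rejects[[f]] <- "no channel token matches"
    } else if (length(hit) > 1L) {
      rejects[[f]] <- paste("ambiguous channel token match:",
                            paste(names(toks)[hit], collapse = ", "))
    } else {
      fld <- parse_stack_fields(basename(f))
      if (is.na(fld$position) || is.na(fld$z)) {
        rejects[[f]] <- "cannot parse position/z index from file name"
      } else {
        rows[[f]] <- data.frame(file = f, well = fld$well,
                                position = fld$position,
                                role = names(toks)[hit], z = fld$z,
                                stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), well = character(0),
               position = integer(0), role = character(0), z = integer(0))
  rownames(manifest) <- NULL
  if (nrow(manifest) == 0L)
    stop("empty dataset: no TIFF slice matched a channel token under ",
         root_dir)
  dup <- duplicated(manifest[c("well", "position", "role", "z")])
  if (any(dup)) {
    for (f in manifest$file[dup]) rejects[[f]] <- "duplicate z index"
    manifest <- manifest[!dup, , drop = FALSE]
  }
  manifest <- manifest[order(manifest$well, manifest$position,
                             manifest$role, manifest$z), , drop = FALSE]
  rejects <- if (length(rejects))
    data.frame(file = names(rejects),
               reason = unlist(rejects, use.names = FALSE),
               stringsAsFactors = FALSE)
  else data.frame(file = character(0), reason = character(0))
  rownames(rejects) <- NULL
  structure(list(manifest = manifest, rejects = rejects, root = root_dir),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  keys <- unique(x$manifest[c("well", "position", "role")])
  cat(sprintf("<dataset_manifest> %s: %d slices in %d stacks (%d rejects)\n",
              x$root, nrow(x$manifest), nrow(keys), nrow(x$rejects)))
  invisible(x)
}

#' Stack keys present in a manifest
#'
#' @param manifest a [discover_dataset()] result.
#' @return data frame `well`, `position`, `role`, `n_slices`.
#' @export
stack_keys <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  m <- manifest$manifest
  agg <- stats::aggregate(list(n_slices = m$z),
                          m[c("well", "position", "role")], length)
  agg[order(agg$well, agg$position, agg$role), , drop = FALSE]
}

#' Read one channel stack from a manifest
#'
#' Slices are read and returned in ascending z order regardless of listing
#' order; a shape mismatch between slices is a hard error naming the
#' offending file. Bit depth is preserved.
#'
#' @param manifest a [discover_dataset()] result.
#' @param well,position,role the stack key.
#' @return an [image_stack()].
#' @export
read_stack <- function(manifest, well, position, role) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  m <- manifest$manifest
  sel <- m[m$well == well & m$position == position & m$role == role, ,
           drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no slices for ", well, "/p", position, "/", role)
  sel <- sel[order(sel$z), , drop = FALSE]
  planes <- vector("list", nrow(sel))
  bit <- NULL
  for (i in seq_len(nrow(sel))) {
    pl <- read_tiff(sel$file[i])
    if (is.null(bit)) bit <- attr(pl, "bit_depth")
    if (i > 1L && !identical(dim(pl), dim(planes[[1L]])))
      stop("slice shape mismatch at ", sel$file[i])
    attr(pl, "bit_depth") <- NULL
    planes[[i]] <- pl
  }
  image_stack(planes, well = well, position = position, channel = role,
              bit_depth = bit)
}

#' Write the per-treatment score table
#'
#' RFC-4180 CSV with header `treatment, metric, score, sem, n_images,
#' n_positions`, one row per treatment and metric, in deterministic
#' (treatment, then metric, lexicographic) order — the same list permuted
#' writes a byte-identical file.
#'
#' @param scores a [treatment_scores()] data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scores_table <- function(scores, path) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L)
  need <- c("treatment", "metric", "score", "sem", "n_images", "n_positions")
  if (!all(need %in% names(scores)))
    stop("scores must have columns: ", paste(need, collapse = ", "))
  out <- as.data.frame(scores)[need]
  out <- out[order(out$treatment, out$metric), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
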