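# Landmark and specimen-metadata input/output: TPS files, classifier tables,
# slider and module-partition tables, and centroid-size staging.

#' Construct a landmark configuration
#'
#' A landmark configuration holds one specimen's `k x 2` coordinates, an
#' optional digitizing scale factor, and the semilandmark slider triples
#' that define along-curve sliding during superimposition.
#'
#' @param specimen_id Character scalar identifying the specimen.
#' @param coords Numeric `k x 2` matrix of landmark coordinates (length
#'   units, e.g. mm). `k >= 3`, all values finite.
#' @param scale Optional positive scalar (units per pixel). When supplied
#'   at read time coordinates are multiplied by it; stored here only for
#'   provenance.
#' @param sliders Integer `m x 3` matrix of 1-indexed landmark triples
#'   `(before, slider, after)`; the middle landmark slides along the chord
#'   from `before` to `after`. May have zero rows.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, coords, scale = NULL, sliders = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("coords must be a k x 2 matrix")
  k <- nrow(coords)
  if (k < 3L)
    stop("a landmark configuration needs at least 3 landmarks, got ", k)
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in specimen '", specimen_id, "'")
  if (!is.null(scale)) {
    scale <- as.numeric(scale)
    if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
      stop("scale must be a positive scalar")
  }
  if (is.null(sliders)) {
    sliders <- matrix(integer(0), ncol = 3L)
  } else {
    sliders <- as.matrix(sliders)
    storage.mode(sliders) <- "integer"
    if (ncol(sliders) != 3L) stop("sliders must have 3 columns")
  }
  colnames(sliders) <- c("before", "slider", "after")
  validate_sliders(sliders, k)
  structure(list(specimen_id = as.character(specimen_id),
                 coords = unname(coords),
                 scale = scale,
                 sliders = sliders),
            class = "landmark_config")
}

validate_sliders <- function(sliders, k) {
  if (nrow(sliders) == 0L) return(invisible(TRUE))
  if (any(sliders < 1L) || any(sliders > k))
    stop("slider indices must lie in 1..", k)
  bad <- apply(sliders, 1L, function(r) length(unique(r)) != 3L)
  if (any(bad))
    stop("slider triples must have three distinct indices (row ",
         which(bad)[1], ")")
  if (anyDuplicated(sliders[, 2L]))
    stop("a landmark may appear as the sliding (middle) index of at most one triple")
  invisible(TRUE)
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", x$specimen_id, "': ",
      nrow(x$coords), " landmarks, ", nrow(x$sliders),
      " semilandmarks\n", sep = "")
  invisible(x)
}

#' Read landmark configurations from a TPS file
#'
#' Parses the TPS dialect used throughout the package: each record starts
#' with `LM=k` followed by `k` whitespace-separated `x y` lines, then
#' optionally `CURVES=c` with `c` blocks of `POINTS=m` followed by `m`
#' coordinate lines, and the keyword lines `IMAGE=`, `ID=`, `SCALE=`.
#' Curve points are appended after the fixed landmarks; the first and last
#' point of every curve are fixed anchors while interior points are
#' registered as sliding semilandmarks with chord-neighbour slider triples.
#' When `SCALE=` is present all coordinates are multiplied by it.
#'
#' @param path Path to a TPS file.
#' @return A list of [landmark_config()] objects, in file order.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no LM= records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    out[[r]] <- parse_tps_record(rec, r)
  }
  out
}

tps_value <- function(line) sub("^[A-Za-z]+\\s*=\\s*", "", line)

parse_tps_record <- function(rec, record_index) {
  n_lm <- suppressWarnings(as.integer(tps_value(rec[1L])))
  if (is.na(n_lm)) stop("record ", record_index, ": malformed LM= line")
  i <- 2L
  read_points <- function(m, what) {
    if (i + m - 1L > length(rec))
      stop("record ", record_index, ": ", what, " declares ", m,
           " points but the record ends early")
    block <- rec[i:(i + m - 1L)]
    if (any(grepl("=", block, fixed = TRUE)))
      stop("record ", record_index, ": ", what, " declares ", m,
           " points but found only ", sum(!grepl("=", block, fixed = TRUE)),
           " coordinate lines")
    vals <- lapply(strsplit(block, "\\s+"), as.numeric)
    if (any(vapply(vals, length, 1L) != 2L) || anyNA(unlist(vals)))
      stop("record ", record_index, ": non-numeric coordinate line in ", what)
    i <<- i + m
    do.call(rbind, vals)
  }
  fixed <- read_points(n_lm, "LM block")
  curves <- list()
  id <- NULL; scale <- NULL
  while (i <= length(rec)) {
    line <- rec[i]
    if (grepl("^CURVES\\s*=", line, ignore.case = TRUE)) {
      nc <- as.integer(tps_value(line)); i <- i + 1L
      for (ci in seq_len(nc)) {
        if (i > length(rec) || !grepl("^POINTS\\s*=", rec[i], ignore.case = TRUE))
          stop("record ", record_index, ": CURVES=", nc,
               " but POINTS block ", ci, " is missing")
        m <- as.integer(tps_value(rec[i])); i <- i + 1L
        if (m < 3L)
          stop("record ", record_index, ": curve ", ci,
               " needs at least 3 points (two anchors + one slider)")
        curves[[ci]] <- read_points(m, paste0("POINTS block ", ci))
      }
    } else if (grepl("^ID\\s*=", line, ignore.case = TRUE)) {
      id <- tps_value(line); i <- i + 1L
    } else if (grepl("^SCALE\\s*=", line, ignore.case = TRUE)) {
      scale <- as.numeric(tps_value(line)); i <- i + 1L
    } else if (grepl("^IMAGE\\s*=", line, ignore.case = TRUE)) {
      i <- i + 1L  # provenance only
    } else if (grepl("^LM\\s*=", line, ignore.case = TRUE)) {
      stop("record ", record_index,
           ": LM count does not match the number of coordinate lines")
    } else {
      stop("record ", record_index, ": unexpected line '", line, "'")
    }
  }
  coords <- fixed
  sliders <- matrix(integer(0), ncol = 3L)
  for (curve in curves) {
    m <- nrow(curve)
    idx <- nrow(coords) + seq_len(m)
    coords <- rbind(coords, curve)
    interior <- idx[2:(m - 1L)]
    sliders <- rbind(sliders,
                     cbind(idx[seq_len(m - 2L)], interior, idx[3:m]))
  }
  if (is.null(id)) id <- paste0("specimen_", record_index)
  if (!is.null(scale)) coords <- coords * scale
  landmark_config(id, coords, scale = scale, sliders = sliders)
}

#' Write landmark configurations to a TPS file
#'
#' Writes fixed landmarks and slider definitions in the dialect read by
#' [read_tps()]. Configurations are written with all points in the `LM=`
#' block (sliders travel separately, see [write_sliders()]), so a
#' write/read round trip preserves coordinates, order and ids. Coordinates
#' are written at full precision (`%.9g`); `SCALE=` is not re-emitted
#' because stored coordinates already include it.
#'
#' @param configs Non-empty list of [landmark_config()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tps <- function(configs, path) {
  if (length(configs) == 0L) stop("empty dataset: nothing to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    stopifnot(inherits(cfg, "landmark_config"))
    writeLines(paste0("LM=", nrow(cfg$coords)), con)
    writeLines(sprintf("%.9g %.9g", cfg$coords[, 1L], cfg$coords[, 2L]), con)
    writeLines(paste0("ID=", cfg$specimen_id), con)
  }
  invisible(path)
}

#' Read a semilandmark slider table
#'
#' Three-column delimited table (`before`, `slider`, `after`), 1-indexed.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @return Integer `m x 3` matrix.
#' @export
read_sliders <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = guess_sep(path))
  if (ncol(tab) < 3L) stop("slider table needs 3 columns (before, slider, after)")
  m <- as.matrix(tab[, 1:3])
  storage.mode(m) <- "integer"
  colnames(m) <- c("before", "slider", "after")
  m
}

#' Write a semilandmark slider table
#' @param sliders Integer `m x 3` matrix (1-indexed).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sliders <- function(sliders, path) {
  utils::write.csv(as.data.frame(sliders), path, row.names = FALSE)
  invisible(path)
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a specimen classifier table
#'
#' Reads a delimited table with at least the columns `specimen_id`,
#' `species` and `life_stage` (`juvenile` or `adult`); optional columns
#' `ontogenetic_stage` (1-4) and `centroid_size` are carried through.
#'
#' @param path Path to a CSV or TSV file.
#' @return A data frame of specimen metadata with one row per specimen.
#' @export
read_classifiers <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "life_stage")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("classifier table lacks column(s): ", paste(missing_cols, collapse = ", "))
  tab$specimen_id <- as.character(tab$specimen_id)
  dup <- tab$specimen_id[duplicated(tab$specimen_id)]
  if (length(dup))
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "))
  ok <- tab$life_stage %in% c("juvenile", "adult")
  if (!all(ok))
    stop("unknown life_stage token(s): ",
         paste(unique(tab$life_stage[!ok]), collapse = ", "),
         " (allowed: juvenile, adult)")
  if (!is.null(tab$ontogenetic_stage)) {
    s <- tab$ontogenetic_stage
    if (!all(is.na(s) | s %in% 1:4)) stop("ontogenetic_stage must be 1..4")
  }
  tab
}

#' Assign ontogenetic stages from centroid size
#'
#' Adults are stage 4. Within each species, juveniles are binned by their
#' centroid-size percentile among that species' juveniles: stages 1, 2 and
#' 3 correspond to percentiles 1-33, 34-66 and above 66. The percentile of
#' a juvenile is `floor(100 * rank / n_juveniles)` with average ranks for
#' ties, so equal centroid sizes always share a stage and the assignment
#' depends only on the within-species size ordering (any monotone rescaling
#' of centroid size leaves stages unchanged).
#'
#' @param metadata Data frame with columns `species`, `life_stage` and,
#'   for juveniles, `centroid_size`.
#' @return `metadata` with an integer `ontogenetic_stage` column.
#' @export
assign_ontogenetic_stage <- function(metadata) {
  stopifnot(all(c("species", "life_stage") %in% names(metadata)))
  juv <- metadata$life_stage == "juvenile"
  if (any(juv)) {
    if (is.null(metadata$centroid_size) ||
        anyNA(metadata$centroid_size[juv]))
      stop("centroid_size must be populated for all juveniles")
  }
  stage <- rep(NA_integer_, nrow(metadata))
  stage[!juv] <- 4L
  for (sp in unique(metadata$species[juv])) {
    idx <- which(juv & metadata$species == sp)
    n <- length(idx)
    if (n < 3L)
      warning("species '", sp, "' has fewer than 3 juveniles; ",
              "stages assigned by the same percentile rule")
    pct <- floor(100 * rank(metadata$centroid_size[idx]) / n)
    stage[idx] <- ifelse(pct <= 33, 1L, ifelse(pct <= 66, 2L, 3L))
  }
  metadata$ontogenetic_stage <- stage
  metadata
}

#' Read a module-partition table
#'
#' Two-column delimited table (`landmark`, `module`), 1-indexed landmarks.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param k Optional landmark count for validation.
#' @return Character vector of length `k` mapping each landmark to a module
#'   label.
#' @export
read_partition <- function(path, k = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("partition table needs columns landmark, module")
  lm <- as.integer(tab[[1L]])
  if (is.null(k)) k <- max(lm)
  part <- rep(NA_character_, k)
  part[lm] <- as.character(tab[[2L]])
  validate_partition(part)
  part
}

validate_partition <- function(partition) {
  if (anyNA(partition))
    stop("every landmark must be assigned to exactly one module")
  counts <- table(partition)
  if (length(counts) < 2L) stop("a partition needs at least 2 modules")
  if (any(counts < 3L))
    stop("each module needs at least 3 landmarks (violated by: ",
         paste(names(counts)[counts < 3L], collapse = ", "), ")")
  invisible(TRUE)
}

#' Write a module-partition table
#' @param partition Character vector of module labels, one per landmark.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(data.frame(landmark = seq_along(partition),
                              module = partition),
                   path, row.names = FALSE)
  invisible(path)
}
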