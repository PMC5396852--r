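# Readers/writers for the delimited formats (track tables, trajectory logs,
# key-value configs) and JSON run manifests.  All delimited text is
# comma-separated, headered, UTF-8, '.' decimal; coordinates are continuous um
# (pixel (i,j) center = (j-0.5, i-0.5) um at 1 px/um).

#' Write a trajectory log as delimited text plus a JSON run manifest
#'
#' @param log a `trajectory_log`.
#' @param dir output directory (created if needed).
#' @param stem file stem; writes `<stem>.csv` and `<stem>_manifest.json`.
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(log, dir, stem = "trajectory") {
  stopifnot(inherits(log, "trajectory_log"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  write.csv(as.data.frame(log), csv, row.names = FALSE)
  manifest <- run_manifest(config = unclass(log$config),
                           seed = log$config$seed,
                           inputs = character(0), outputs = basename(csv))
  mpath <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, manifest = mpath))
}

#' Read a trajectory log written by [write_trajectory()]
#'
#' @param path CSV path.
#' @param box,periodic geometry metadata (recovered from the manifest when
#'   present next to the CSV).
#' @return A `trajectory_log`.
#' @export
read_trajectory <- function(path, box = NULL, periodic = TRUE) {
  d <- read.csv(path)
  need <- c("frame", "t_min", "cell_id", "x_um", "y_um", "vx", "vy", "phase")
  if (!all(need %in% names(d))) {
    stop("missing column(s): ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  mpath <- sub("\\.csv$", "_manifest.json", path)
  cfg <- NULL
  if (is.null(box) && file.exists(mpath)) {
    m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    box <- m$config$box_length
    periodic <- identical(m$config$boundary, "periodic")
    cfg <- m$config
  }
  frames <- sort(unique(d$frame))
  ids <- sort(unique(d$cell_id))
  shape <- function(col) {
    matrix(d[[col]][order(d$frame, d$cell_id)], length(ids), length(frames))
  }
  phase_code <- match(d$phase[order(d$frame, d$cell_id)],
                      c("quiescent", "firing", "refractory")) - 1L
  log <- list(t = d$t_min[match(frames, d$frame)],
              x = shape("x_um"), y = shape("y_um"),
              vx = shape("vx"), vy = shape("vy"),
              phase = matrix(phase_code, length(ids), length(frames)),
              config = cfg, box = box, periodic = isTRUE(periodic))
  class(log) <- "trajectory_log"
  log
}

#' Read a tracked-cell table
#'
#' Accepts either the long layout with columns `frame, cell_id, x, y`
#' (converted to linked pairs by matching cell ids across consecutive
#' frames), or the legacy linked-pair layout with columns
#' `frame, x, y, x_next, y_next` (a four-column `x, y, x_next, y_next` table
#' per frame).
#'
#' @param path CSV/TSV path (separator sniffed from the header line).
#' @param units `"um"` or `"px"`; defaults to a `# units:` header comment if
#'   present, else `"um"`.
#' @return A data frame with columns `frame, x, y, x_next, y_next` and
#'   attribute `units`.
#' @export
read_tracks <- function(path, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 2)
  if (is.null(units)) {
    m <- regmatches(first[1], regexec("^#\\s*units:\\s*(\\S+)", first[1]))[[1]]
    units <- if (length(m)) m[2] else "um"
  }
  sep <- if (grepl("\t", first[length(first)])) "\t" else ","
  d <- read.csv(path, sep = sep, comment.char = "#")
  long <- all(c("frame", "cell_id", "x", "y") %in% names(d))
  pair <- all(c("frame", "x", "y", "x_next", "y_next") %in% names(d))
  if (!long && !pair) {
    stop("unrecognized track table layout; need (frame, cell_id, x, y) or ",
         "(frame, x, y, x_next, y_next)")
  }
  numcols <- if (pair && !long) c("frame", "x", "y", "x_next", "y_next")
             else c("frame", "cell_id", "x", "y")
  for (col in numcols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("malformed value in column '", col, "' at data line ", bad)
    }
    d[[col]] <- v
  }
  if (pair && !long) {
    out <- d[, c("frame", "x", "y", "x_next", "y_next")]
  } else {
    fr <- split(d, d$frame)
    frames <- as.numeric(names(fr))
    rows <- lapply(seq_len(length(fr) - 1), function(i) {
      a <- fr[[i]]
      b <- fr[[i + 1]]
      j <- match(a$cell_id, b$cell_id)
      ok <- !is.na(j)
      if (!any(ok)) return(NULL)
      data.frame(frame = frames[i], x = a$x[ok], y = a$y[ok],
                 x_next = b$x[j[ok]], y_next = b$y[j[ok]])
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) {
      out <- data.frame(frame = numeric(0), x = numeric(0), y = numeric(0),
                        x_next = numeric(0), y_next = numeric(0))
    }
  }
  attr(out, "units") <- units
  out
}

#' Write a track table
#'
#' @param tracks data frame with columns `frame, x, y, x_next, y_next`.
#' @param path output CSV path.
#' @param units unit tag written as a `# units:` header comment.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path, units = "um") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  write.csv(tracks, con, row.names = FALSE)
  invisible(path)
}

#' Read a key-value simulation config file
#'
#' One `key = value` pair per line (`#` comments allowed); keys must be
#' arguments of [swarm_config()], unknown keys are rejected.  An empty file
#' yields all defaults.
#'
#' @param path config file path.
#' @return A [swarm_config()].
#' @export
read_swarm_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(formals(swarm_config))) {
      stop("unknown config key: '", key, "'")
    }
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (!is.na(num)) num else if (val %in% c("TRUE", "FALSE"))
      as.logical(val) else val
  }
  do.call(swarm_config, args)
}

#' Build a run manifest
#'
#' Every CLI run writes one manifest: config echo, seed, tool version, input
#' hashes and output paths — enough to replay the run.
#'
#' @param config configuration echo (list).
#' @param seed RNG seed used.
#' @param inputs input file paths (hashed by size + first bytes).
#' @param outputs output file paths.
#' @return A list ready for [jsonlite::write_json()].
#' @export
run_manifest <- function(config, seed, inputs = character(0),
                         outputs = character(0)) {
  hashes <- vapply(inputs, function(p) {
    if (!file.exists(p)) return(NA_character_)
    info <- file.info(p)
    head_bytes <- readBin(p, "raw", n = min(4096, info$size))
    sprintf("size:%d;sum:%d", info$size, sum(as.integer(head_bytes)))
  }, character(1))
  list(tool = "dictyoswarm",
       version = as.character(packageVersion("dictyoswarm")),
       seed = seed,
       config = config,
       inputs = as.list(setNames(hashes, inputs)),
       outputs = as.list(outputs),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Read or write images
#'
#' Thin wrappers over EBImage for grayscale TIFF/PNG, returning/accepting
#' plain numeric matrices in `[0, 1]`.
#'
#' @param path image path.
#' @return `read_image()`: a numeric matrix; `write_image()`: `path`,
#'   invisibly.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2) m <- m[, , 1]
  # EBImage stores x (cols) as the first dimension; transpose to row-major
  t(m)
}

#' @rdname read_image
#' @param image numeric matrix.
#' @export
write_image <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(as.matrix(image))), path)
  invisible(path)
}
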