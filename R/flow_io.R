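#' Construct a single-cell event table
#'
#' The central container for flow-cytometry data: one row per acquired event
#' (cell), one column per channel. Values are fluorescence intensities in
#' arbitrary units (a.u.); negative values are permitted because
#' baseline-subtracting instruments emit them.
#'
#' @param intensities Numeric matrix, `n_events x n_channels`, all finite.
#' @param channels Character vector of unique channel names, one per column.
#' @param sample_id Sample identifier.
#' @param panel Named list or character vector mapping channel name to the
#'   stained marker (e.g. `c(PE = "VEGFR1")`). May cover a subset of channels.
#' @return An object of class `event_table` with fields `sample_id`,
#'   `channels`, `intensities`, `panel`, `n_events`.
#' @examples
#' ev <- event_table(matrix(rnorm(20, 100, 5), 10, 2), c("FSC", "PE"))
#' ev$n_events
#' @export
event_table <- function(intensities, channels, sample_id = "sample",
                        panel = list()) {
  if (is.data.frame(intensities)) intensities <- as.matrix(intensities)
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(intensities) < 1L) stop("event table must contain at least one event",
                                   call. = FALSE)
  channels <- as.character(channels)
  if (length(channels) != ncol(intensities)) {
    stop(sprintf("%d channel names for %d intensity columns",
                 length(channels), ncol(intensities)), call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("channel names must be unique: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("intensities must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  dimnames(intensities) <- list(NULL, channels)
  structure(
    list(sample_id = as.character(sample_id)[1], channels = channels,
         intensities = intensities, panel = as.list(panel),
         n_events = nrow(intensities)),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> sample '%s': %d events x %d channels\n",
              x$sample_id, x$n_events, length(x$channels)))
  cat("  channels: ", paste(x$channels, collapse = ", "), "\n", sep = "")
  if (length(x$panel)) {
    cat("  panel:    ",
        paste(sprintf("%s=%s", names(x$panel), unlist(x$panel)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract one channel from an event table
#'
#' @param events An [event_table()].
#' @param channel Channel name.
#' @return Numeric vector of per-event intensities.
#' @export
channel_values <- function(events, channel) {
  stopifnot(inherits(events, "event_table"))
  if (!channel %in% events$channels) {
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(events$channels, collapse = ", ")), call. = FALSE)
  }
  events$intensities[, channel]
}

# ---------------------------------------------------------------------------
# CSV event tables: the canonical, bit-exact interchange format.
# Header row = channel names; body numeric; "." decimal; UTF-8.

#' Read an event table from CSV
#'
#' @param path CSV file with a header row of channel names and a numeric body.
#' @param panel Optional channel-to-marker map (see [event_table()]).
#' @param sample_id Sample identifier; defaults to the file name.
#' @return An [event_table()] preserving the file's column order.
#' @export
read_events_csv <- function(path, panel = list(), sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 1L || is.null(names(df)) || any(!nzchar(names(df)))) {
    stop("missing or empty header row in ", path, call. = FALSE)
  }
  if (nrow(df) < 1L) stop("no events in ", path, call. = FALSE)
  mat <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   df[[j]][bad[1]], bad[1], names(df)[j], path), call. = FALSE)
    }
    mat[, j] <- v
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  event_table(mat, names(df), sample_id = sample_id, panel = panel)
}

#' Write an event table to CSV
#'
#' Full-precision (up to 17 significant digits) so that a read/write round
#' trip is lossless for doubles.
#'
#' @param events An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  df <- as.data.frame(apply(events$intensities, 2, format_full))
  names(df) <- events$channels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shortest decimal representation that round-trips a double
format_full <- function(x) {
  vapply(x, function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

# ---------------------------------------------------------------------------
# FCS 3.0 / 3.1 adapter. List-mode, $DATATYPE F (float32) or I (integer),
# little- or big-endian. FCS 2.0 is rejected.

#' Read an FCS 3.0/3.1 file
#'
#' Supports list-mode files with float (`$DATATYPE F`) or integer
#' (`$DATATYPE I`) data, 1,2,3,4 or 4,3,2,1 byte order. Channel names come
#' from the `$PnN` keywords; the stain names (`$PnS`), when present, populate
#' the panel map. FCS 2.0 files are rejected with an explanatory error.
#'
#' @param path Path to an FCS file with at least one event.
#' @return An [event_table()].
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1, 6)
  if (version == "FCS2.0") {
    stop("FCS 2.0 files are not supported; re-export as FCS 3.0/3.1",
         call. = FALSE)
  }
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("not an FCS 3.0/3.1 file (header version field: '", version, "')",
         call. = FALSE)
  }
  offs <- suppressWarnings(as.integer(c(
    substr(header, 11, 18), substr(header, 19, 26),
    substr(header, 27, 34), substr(header, 35, 42))))
  if (any(is.na(offs[1:2])) || offs[2] <= offs[1]) {
    stop("malformed FCS header: invalid TEXT segment offsets", call. = FALSE)
  }
  seek(con, offs[1])
  text <- rawToChar(readBin(con, "raw", offs[2] - offs[1] + 1L))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop("malformed FCS TEXT segment", call. = FALSE)
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- setNames(as.list(parts[seq(2, length(parts), 2)]),
                 toupper(trimws(parts[seq(1, length(parts), 2)])))
  need <- function(key) {
    v <- kw[[key]]
    if (is.null(v)) stop("malformed FCS file: required keyword ", key,
                         " missing", call. = FALSE)
    v
  }
  tot <- as.integer(need("$TOT"))
  if (is.na(tot)) stop("malformed FCS file: keyword $TOT is not an integer",
                       call. = FALSE)
  if (tot == 0L) stop("FCS file contains zero events ($TOT=0)", call. = FALSE)
  par <- as.integer(need("$PAR"))
  mode <- need("$MODE")
  if (toupper(mode) != "L") {
    stop("only list-mode FCS supported (keyword $MODE='", mode, "')",
         call. = FALSE)
  }
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D", "I")) {
    stop("unsupported $DATATYPE '", dtype, "' (need F, D or I)", call. = FALSE)
  }
  byteord <- need("$BYTEORD")
  endian <- if (grepl("^4,3,2,1", byteord)) "big" else "little"
  bits <- vapply(seq_len(par), function(i)
    as.integer(need(sprintf("$P%dB", i))), integer(1))
  if (dtype == "F" && any(bits != 32L)) {
    stop("malformed FCS file: $DATATYPE F requires $PnB=32 (keyword $P",
         which(bits != 32L)[1], "B)", call. = FALSE)
  }
  chans <- vapply(seq_len(par), function(i) need(sprintf("$P%dN", i)),
                  character(1))
  stains <- vapply(seq_len(par), function(i) {
    v <- kw[[sprintf("$P%dS", i)]]
    if (is.null(v)) NA_character_ else v
  }, character(1))
  dbeg <- as.integer(kw[["$BEGINDATA"]])
  dend <- as.integer(kw[["$ENDDATA"]])
  if (is.na(dbeg) || dbeg == 0L) { dbeg <- offs[3]; dend <- offs[4] }
  if (is.na(dbeg) || is.na(dend) || dend <= dbeg) {
    stop("malformed FCS file: invalid DATA segment offsets ($BEGINDATA)",
         call. = FALSE)
  }
  seek(con, dbeg)
  nvals <- tot * par
  if (dtype == "F") {
    vals <- readBin(con, "numeric", nvals, size = 4L, endian = endian)
  } else if (dtype == "D") {
    vals <- readBin(con, "numeric", nvals, size = 8L, endian = endian)
  } else {
    sz <- bits[1] %/% 8L
    if (any(bits != bits[1])) {
      stop("integer FCS with mixed $PnB widths not supported", call. = FALSE)
    }
    vals <- readBin(con, "integer", nvals, size = sz, endian = endian,
                    signed = sz > 2L)
    vals <- as.numeric(vals)
  }
  if (length(vals) < nvals) {
    stop("malformed FCS file: DATA segment truncated ($TOT x $PAR values ",
         "expected)", call. = FALSE)
  }
  mat <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  panel <- as.list(setNames(stains[!is.na(stains)], chans[!is.na(stains)]))
  event_table(mat, chans,
              sample_id = sub("\\.fcs$", "", basename(path),
                              ignore.case = TRUE),
              panel = panel)
}

#' Write an event table as FCS 3.0
#'
#' Minimal float32 list-mode writer, intended for fixtures and interchange;
#' values round-trip within float32 precision.
#'
#' @param events An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  n <- events$n_events
  p <- length(events$channels)
  d <- "/"
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%DB%", "$ENDDATA", "%DE%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p))
  for (i in seq_len(p)) {
    ch <- events$channels[i]
    kv <- c(kv, sprintf("$P%dN", i), ch, sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0", sprintf("$P%dR", i), "262144")
    if (!is.null(events$panel[[ch]])) {
      kv <- c(kv, sprintf("$P%dS", i), as.character(events$panel[[ch]]))
    }
  }
  # fixed-width offset placeholders keep the TEXT length stable
  text_start <- 58L
  build_text <- function(db, de) {
    paste0(d, paste(rbind(
      kv_sub(kv, c("%DB%" = sprintf("%010d", db), "%DE%" = sprintf("%010d", de))),
      d), collapse = ""))
  }
  text0 <- build_text(0L, 0L)
  data_start <- text_start + nchar(text0, type = "bytes")
  data_end <- data_start + 4L * n * p - 1L
  text <- build_text(data_start, data_end)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + nchar(text, type = "bytes") - 1L,
                    data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(events$intensities)), con, size = 4L,
           endian = "little")
  invisible(path)
}

kv_sub <- function(kv, map) {
  for (k in names(map)) kv[kv == k] <- map[[k]]
  kv
}

# ---------------------------------------------------------------------------
# Pipeline configuration

#' Build a pipeline configuration
#'
#' Collects every tunable of the analysis pipeline with its default:
#' `bins = 500` equally spaced log10 bins for the quadratic-entropy
#' calculation, mixture component range `k_range = c(1, 9)`, and the
#' heterogeneity threshold `qe_threshold = 0.7` separating low from high
#' quadratic entropy.
#'
#' @param panel Named list mapping channel to marker.
#' @param gates A [gate_node()] tree (or nested list convertible to one).
#' @param events Path to the event file (CSV or FCS), optional until run time.
#' @param format `"csv"` or `"fcs"`.
#' @param beads Path to a bead calibration CSV (columns `known_fluorophores`,
#'   `intensity`), or `NULL` when a pre-fitted curve is supplied to the run.
#' @param receptors_per_fluorophore Stoichiometry factor converting
#'   fluorophores to receptors (default 1: one PE per antibody per receptor).
#' @param markers Channels to analyze as receptor read-outs; defaults to all
#'   panel channels.
#' @param bins Bin count for binned distributions (>= 2).
#' @param k_range Two integers in `[1, 9]`: mixture component counts to scan.
#' @param qe_threshold Quadratic-entropy low/high heterogeneity boundary.
#' @param min_cells Minimum population size for mixture/entropy analysis.
#' @param bootstrap Bootstrap resamples for ensemble confidence intervals.
#' @param criteria A [target_criteria()] object.
#' @param reference Optional named list of healthy-reference geometric-mean
#'   receptor concentrations per marker, for specificity fold-changes.
#' @param sample_id Sample identifier.
#' @param seed Non-negative integer seed governing all stochastic steps.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(panel, gates, events = NULL, format = c("csv", "fcs"),
                            beads = NULL, receptors_per_fluorophore = 1,
                            markers = NULL, bins = 500L, k_range = c(1L, 9L),
                            qe_threshold = 0.7, min_cells = 50L,
                            bootstrap = 200L, criteria = target_criteria(),
                            reference = NULL, sample_id = "sample", seed = 0L) {
  format <- match.arg(format)
  cfg <- structure(
    list(panel = as.list(panel), gates = gates, events = events,
         format = format, beads = beads,
         receptors_per_fluorophore = receptors_per_fluorophore,
         markers = if (is.null(markers)) unname(unlist(as.list(panel))) else markers,
         bins = as.integer(bins), k_range = as.integer(k_range),
         qe_threshold = qe_threshold, min_cells = as.integer(min_cells),
         bootstrap = as.integer(bootstrap), criteria = criteria,
         reference = reference, sample_id = sample_id,
         seed = as.integer(seed)),
    class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (!length(cfg$panel)) add("panel: must map at least one channel to a marker")
  if (is.null(cfg$gates)) add("gates: gate tree missing")
  if (!is.numeric(cfg$bins) || is.na(cfg$bins) || cfg$bins < 2)
    add("bins: must be an integer >= 2")
  kr <- cfg$k_range
  if (length(kr) != 2 || any(is.na(kr)) || kr[1] < 1 || kr[2] > 9 || kr[1] > kr[2])
    add("k_range: must be two integers within [1, 9], low <= high")
  if (!is.numeric(cfg$qe_threshold) || cfg$qe_threshold <= 0)
    add("qe_threshold: must be strictly positive")
  if (!is.numeric(cfg$receptors_per_fluorophore) ||
      cfg$receptors_per_fluorophore <= 0)
    add("receptors_per_fluorophore: must be strictly positive")
  if (!is.numeric(cfg$min_cells) || cfg$min_cells < 1)
    add("min_cells: must be a positive integer")
  if (!is.numeric(cfg$seed) || is.na(cfg$seed) || cfg$seed < 0)
    add("seed: must be a non-negative integer")
  crit_problems <- tryCatch({ validate_criteria(cfg$criteria); character(0) },
                            error = function(e) conditionMessage(e))
  problems <- c(problems, crit_problems)
  if (length(problems)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(cfg)
}

#' Load a pipeline configuration from JSON
#'
#' Applies defaults for absent fields (500 bins, component range 1-9,
#' quadratic-entropy threshold 0.7) and validates every field, reporting all
#' violations at once.
#'
#' @param path Path to a JSON configuration document.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  gates <- if (!is.null(raw$gates)) gate_node_from_list(raw$gates) else NULL
  crit <- do.call(target_criteria, lapply(raw$criteria %||% list(), unlist))
  num1 <- function(x) if (is.null(x)) NULL else as.numeric(x)
  pipeline_config(
    panel = raw$panel %||% list(),
    gates = gates,
    events = raw$events,
    format = raw$format %||% "csv",
    beads = raw$beads,
    receptors_per_fluorophore = num1(raw$receptors_per_fluorophore) %||% 1,
    markers = if (!is.null(raw$markers)) unlist(raw$markers),
    bins = num1(raw$bins) %||% 500L,
    k_range = if (!is.null(raw$k_range)) unlist(raw$k_range) else c(1L, 9L),
    qe_threshold = num1(raw$qe_threshold) %||% 0.7,
    min_cells = num1(raw$min_cells) %||% 50L,
    bootstrap = num1(raw$bootstrap) %||% 200L,
    criteria = crit,
    reference = if (!is.null(raw$reference)) lapply(raw$reference, as.numeric),
    sample_id = raw$sample_id %||% "sample",
    seed = num1(raw$seed) %||% 0L)
}

#' Serialize a pipeline configuration to JSON
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- unclass(cfg)
  out$gates <- gate_node_to_list(cfg$gates)
  out$criteria <- unclass(cfg$criteria)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
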