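# Native exchange format: delimited text (or raw binary) with a '#'-prefixed
# key:value header. There is no community standard for binned FCS traces, so
# the format is fully specified here; vendor TCSPC formats are not parsed.

.header_lines <- function(trace) {
  g <- trace$geometry
  c("# isfcs-trace",
    sprintf("# bin_time: %.17g", trace$bin_time),
    sprintf("# channels: %s", paste(colnames(trace$counts), collapse = ",")),
    sprintf("# orbit_radius: %.17g", g$orbit_radius),
    sprintf("# orbit_period: %.17g", g$orbit_period),
    sprintf("# waist_lateral: %.17g", g$waist_lateral),
    sprintf("# waist_axial: %.17g", g$waist_axial),
    sprintf("# scan_enabled: %s", g$scan_enabled),
    sprintf("# origin: %s", trace$origin),
    if (!is.null(trace$seed)) sprintf("# seed: %d", trace$seed))
}

.parse_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    s <- sub("^#\\s*", "", ln)
    if (!grepl(":", s)) next
    key <- trimws(sub(":.*$", "", s))
    val <- trimws(sub("^[^:]*:", "", s))
    kv[[key]] <- val
  }
  kv
}

.geometry_from_header <- function(kv) {
  num <- function(key, default = NA_real_) {
    v <- kv[[key]]
    if (is.null(v) || identical(v, "NA")) default else as.numeric(v)
  }
  scan_geometry(orbit_radius = num("orbit_radius", 0),
                orbit_period = num("orbit_period"),
                waist_lateral = num("waist_lateral", 0.2),
                waist_axial = num("waist_axial", num("waist_lateral", 0.2) * 4),
                scan_enabled = identical(toupper(kv[["scan_enabled"]]), "TRUE"))
}

#' Bin photon arrival timestamps into counts
#'
#' Timestamps are assigned to half-open, left-closed bins
#' \code{[k*dt, (k+1)*dt)}, so a photon at t = 0 lands in the first bin. The
#' number of bins is `floor(max(times)/dt) + 1` unless `duration` says
#' otherwise; photons at or beyond `duration` are dropped.
#'
#' @param times Non-decreasing photon arrival times (s).
#' @param bin_time Target bin width dt (s).
#' @param duration Optional total trace duration (s).
#' @return Integer vector of counts per bin.
#' @export
bin_timestamps <- function(times, bin_time, duration = NULL) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0))
    stop("timestamps must be finite and non-negative")
  if (is.unsorted(times)) stop("timestamps must be non-decreasing")
  if (!is.numeric(bin_time) || bin_time <= 0) stop("bin_time must be > 0")
  n_bins <- if (is.null(duration)) {
    if (length(times) == 0L) stop("no timestamps and no duration given")
    floor(max(times) / bin_time) + 1L
  } else {
    as.integer(floor(duration / bin_time + 1e-9))
  }
  idx <- floor(times / bin_time) + 1L
  keep <- idx >= 1L & idx <= n_bins
  tabulate(idx[keep], nbins = n_bins)
}

#' Read an intensity trace from file
#'
#' Supported formats: `"delimited"` (text columns, one per channel, after a
#' `#` key:value header), `"binary"` (same header, then little-endian unsigned
#' 32-bit counts, column-major), and `"timestamps"` (text: one photon arrival
#' time per row, or `channel<TAB>time`, binned on read). `"auto"` picks by
#' extension: `.fcsbin` is binary, anything else delimited.
#'
#' @param path File to read.
#' @param format One of `"auto"`, `"delimited"`, `"binary"`, `"timestamps"`.
#' @param bin_time Target bin width when binning timestamps; overrides the
#'   header's value.
#' @param duration Optional duration for timestamp binning.
#' @return An [intensity_trace()].
#' @export
read_trace <- function(path, format = c("auto", "delimited", "binary",
                                        "timestamps"),
                       bin_time = NULL, duration = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.fcsbin$", path)) "binary" else "delimited"

  if (format == "binary") {
    raw <- readBin(path, what = "raw", n = file.info(path)$size)
    marker <- charToRaw("# end-header\n")
    pos <- .find_raw(raw, marker)
    if (is.na(pos)) stop("malformed header: missing '# end-header'")
    header <- strsplit(rawToChar(raw[seq_len(pos - 1L)]), "\n", fixed = TRUE)[[1]]
    kv <- .parse_header(header)
    if (is.null(kv$bin_time) || is.null(kv$channels))
      stop("malformed header: bin_time and channels required")
    channels <- strsplit(kv$channels, ",", fixed = TRUE)[[1]]
    body <- raw[(pos + length(marker)):length(raw)]
    # counts are far below 2^31, so the unsigned on-disk words read back
    # losslessly as R's signed 32-bit integers
    vals <- readBin(body, what = "integer", size = 4L,
                    endian = "little", n = length(body) %/% 4L)
    if (length(vals) %% length(channels) != 0L)
      stop("data error: payload not a multiple of channel count")
    counts <- matrix(vals, ncol = length(channels))
    return(intensity_trace(counts, as.numeric(kv$bin_time),
                           .geometry_from_header(kv), channels,
                           origin = if (identical(kv$origin, "simulated"))
                             "simulated" else "measured",
                           seed = if (!is.null(kv$seed)) as.integer(kv$seed)))
  }

  lines <- readLines(path)
  is_h <- startsWith(lines, "#")
  kv <- .parse_header(lines[is_h])
  body <- lines[!is_h]
  body <- body[nzchar(trimws(body))]

  if (format == "timestamps") {
    dt <- bin_time
    if (is.null(dt) && !is.null(kv$bin_time)) dt <- as.numeric(kv$bin_time)
    if (is.null(dt)) stop("malformed header: timestamp input needs bin_time")
    if (is.null(duration) && !is.null(kv$duration))
      duration <- as.numeric(kv$duration)
    tab <- utils::read.table(text = body, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) == 1L) {
      counts <- bin_timestamps(tab[[1]], dt, duration)
      counts <- matrix(counts, ncol = 1)
      channels <- "probe"
    } else {
      channels <- unique(as.character(tab[[1]]))
      dur <- duration
      if (is.null(dur)) dur <- (floor(max(tab[[2]]) / dt) + 1L) * dt
      counts <- sapply(channels, function(ch)
        bin_timestamps(tab[[2]][tab[[1]] == ch], dt, dur))
    }
    return(intensity_trace(counts, dt, .geometry_from_header(kv), channels))
  }

  # delimited
  if (is.null(kv$bin_time)) stop("malformed header: bin_time required")
  header_row <- body[1]
  channels <- strsplit(trimws(header_row), "[,\t ]+")[[1]]
  if (any(grepl("^[0-9.+-]", channels))) {
    # no channel-name row; fall back to header declaration
    if (is.null(kv$channels)) stop("malformed header: channels required")
    channels <- strsplit(kv$channels, ",", fixed = TRUE)[[1]]
    data_rows <- body
  } else data_rows <- body[-1]
  tab <- utils::read.table(text = data_rows, header = FALSE)
  if (ncol(tab) != length(channels))
    stop("data error: column count does not match channels")
  intensity_trace(as.matrix(tab), as.numeric(kv$bin_time),
                  .geometry_from_header(kv), channels,
                  origin = if (identical(kv$origin, "simulated"))
                    "simulated" else "measured",
                  seed = if (!is.null(kv$seed)) as.integer(kv$seed))
}

.find_raw <- function(haystack, needle) {
  idx <- which(haystack == needle[1])
  for (i in idx) {
    if (i + length(needle) - 1L > length(haystack)) next
    if (all(haystack[i:(i + length(needle) - 1L)] == needle)) return(i)
  }
  NA_integer_
}

#' Write an intensity trace to file
#'
#' Delimited text or raw binary, both re-readable bit-exactly by
#' [read_trace()]. The header records bin time, channels, geometry, origin and
#' seed.
#'
#' @param trace An [intensity_trace()].
#' @param path Output file; use extension `.fcsbin` for binary.
#' @param format `"delimited"` or `"binary"` (`"auto"` picks by extension).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("auto", "delimited",
                                                "binary")) {
  stopifnot(inherits(trace, "intensity_trace"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcsbin$", path)) "binary" else "delimited"
  hdr <- .header_lines(trace)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "# end-header"), con, sep = "\n")
    vals <- as.vector(trace$counts)
    writeBin(as.integer(vals), con, size = 4L, endian = "little")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(paste(colnames(trace$counts), collapse = "\t"), con)
    utils::write.table(trace$counts, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write correlation curves and fit results
#'
#' Curves go to a single delimited table (population, lag, G, SE, n_averaged);
#' fit results to JSON with model id, parameters, standard errors, derived
#' quantities, seed and a configuration echo. Numbers are written in full
#' precision so results re-parse to numerically identical values.
#'
#' @param curves Named list of [correlation_curve()] objects (may be empty).
#' @param fits Named list of `fcs_fit` objects (may be empty).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param seed,config Optional metadata echoed into the JSON report.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(curves = list(), fits = list(), dir = ".",
                          prefix = "isfcs", seed = NULL, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (length(curves)) {
    tabs <- lapply(names(curves), function(nm) {
      d <- as.data.frame(curves[[nm]])
      cbind(population = nm, d)
    })
    tab <- do.call(rbind, tabs)
    fp <- file.path(dir, paste0(prefix, "_curves.tsv"))
    con <- file(fp, "w")
    writeLines("# isfcs correlation curves (lag s, G dimensionless)", con)
    utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = NA),
                       con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
    written <- c(written, fp)
  }
  if (length(fits)) {
    rep_one <- function(f) {
      list(model = f$model_id,
           parameters = as.list(f$parameters),
           stderr = as.list(f$stderr),
           derived = as.list(f$derived),
           gof = f$gof,
           converged = f$converged)
    }
    payload <- list(fits = lapply(fits, rep_one), seed = seed, config = config,
                    package_version = as.character(utils::packageVersion("isfcs")))
    fp <- file.path(dir, paste0(prefix, "_fits.json"))
    jsonlite::write_json(payload, fp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <- c(written, fp)
  }
  invisible(written)
}

#' Read back a correlation-curve table written by [write_results()]
#'
#' @param path The `*_curves.tsv` file.
#' @return Named list of [correlation_curve()] objects.
#' @export
read_curves <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$population), function(d) {
    n_avg <- d$n_averaged[1]
    correlation_curve(d$lag, d$G,
                      dispersion = if (n_avg > 1) d$SE else NULL,
                      n_averaged = n_avg)
  })
  out[unique(tab$population)]
}
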