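# File formats: a self-describing text container for synthetic FIDs (CSV of
# quadrature pairs + JSON sidecar of acquisition parameters), a Bruker-style
# binary fid/acqus directory for round-trip testing against vendor-like
# layouts, and a minimal JCAMP-DX reader.

#' Write / read an FID as a self-describing text container
#'
#' The container is `<path>.csv` with columns `re`, `im` (one row per complex
#' point) plus a JSON sidecar `<path>.json` holding the acquisition parameters
#' and the generating seed.  Round-trips exactly at full double precision.
#'
#' @param fid A [new_fid()] object.
#' @param path Base path without extension.
#' @return `write_fid_container()` returns `path` invisibly;
#'   `read_fid_container()` returns a [new_fid()].
#' @export
write_fid_container <- function(fid, path) {
  stopifnot(inherits(fid, "fid"))
  df <- data.frame(re = Re(fid$data), im = Im(fid$data))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  meta <- unclass(fid$acq)
  meta$seed_record <- if (is.null(fid$seed_record)) NA else fid$seed_record
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fid_container
#' @export
read_fid_container <- function(path) {
  df <- utils::read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  acq <- acquisition_params(
    spectrometer_freq = meta$spectrometer_freq,
    spectral_width = meta$spectral_width,
    n_points = meta$n_points,
    n_averages = meta$n_averages,
    recycle_delay = meta$recycle_delay,
    pulse_width = meta$pulse_width,
    flip_angle = meta$flip_angle,
    carrier_ppm = meta$carrier_ppm
  )
  seed <- if (is.null(meta$seed_record) || is.na(meta$seed_record)) NULL
          else meta$seed_record
  new_fid(complex(real = df$re, imaginary = df$im), acq, seed_record = seed)
}

#' Write / read a Bruker-style FID directory
#'
#' Writes a directory containing a binary `fid` file (interleaved real and
#' imaginary points, little-endian float64) and a minimal `acqus` text file
#' with the parameter keys needed to reconstruct the acquisition (`TD`, `SW_h`,
#' `SFO1`, `O1`, `NS`, `D1`).  This mirrors the on-disk layout of a vendor
#' dataset closely enough for reader round-trip tests; it is not a complete
#' TopSpin implementation.
#'
#' @param fid A [new_fid()] object.
#' @param dir Directory to create/write.
#' @return `write_bruker_fid()` returns `dir` invisibly; `read_bruker_fid()`
#'   returns a [new_fid()].
#' @export
write_bruker_fid <- function(fid, dir) {
  stopifnot(inherits(fid, "fid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  interleaved <- as.vector(rbind(Re(fid$data), Im(fid$data)))
  con <- file(file.path(dir, "fid"), "wb")
  on.exit(close(con))
  writeBin(interleaved, con, size = 8, endian = "little")
  acq <- fid$acq
  lines <- c(
    "##TITLE= Parameter file, synthetic Bruker-style export",
    "##JCAMPDX= 5.0",
    sprintf("##$TD= %d", 2L * acq$n_points),
    sprintf("##$SW_h= %.10g", sw_hz(acq)),
    sprintf("##$SFO1= %.10g", acq$spectrometer_freq),
    sprintf("##$O1= %.10g", acq$carrier_ppm * acq$spectrometer_freq),
    sprintf("##$NS= %d", acq$n_averages),
    sprintf("##$D1= %.10g", acq$recycle_delay),
    sprintf("##$P1= %.10g", acq$pulse_width),
    "##$DTYPA= 2",
    "##END="
  )
  writeLines(lines, file.path(dir, "acqus"))
  invisible(dir)
}

# pull a numeric "##$KEY= value" entry out of acqus lines
acqus_value <- function(lines, key) {
  pat <- paste0("^##\\$", key, "= *")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) stop(sprintf("acqus key '%s' not found", key),
                         call. = FALSE)
  as.numeric(sub(pat, "", hit[1]))
}

#' @rdname write_bruker_fid
#' @export
read_bruker_fid <- function(dir) {
  acqus <- readLines(file.path(dir, "acqus"))
  td <- acqus_value(acqus, "TD")
  swh <- acqus_value(acqus, "SW_h")
  sfo1 <- acqus_value(acqus, "SFO1")
  o1 <- acqus_value(acqus, "O1")
  ns <- acqus_value(acqus, "NS")
  d1 <- acqus_value(acqus, "D1")
  n <- as.integer(td / 2)
  con <- file(file.path(dir, "fid"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = td, size = 8, endian = "little")
  acq <- acquisition_params(
    spectrometer_freq = sfo1, spectral_width = swh / sfo1, n_points = n,
    n_averages = ns, recycle_delay = d1, carrier_ppm = o1 / sfo1
  )
  new_fid(complex(real = raw[seq(1, td, 2)], imaginary = raw[seq(2, td, 2)]),
          acq)
}

#' Read a minimal JCAMP-DX spectrum file
#'
#' Parses a single-block JCAMP-DX file whose data section is
#' `##XYDATA= (X++(Y..Y))` in plain AFFN form (space-separated decimal
#' numbers, one abscissa value leading each line).  `XFACTOR`/`YFACTOR`
#' scalings are applied.  Compressed ASDF forms (SQZ/DIF/DUP) and NTUPLES
#' blocks are not supported.
#'
#' @param path Path to the `.jdx`/`.dx` file.
#' @return A list with `x`, `y` and `meta` (named character vector of header
#'   records).
#' @export
read_jcamp_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^##", lines)
  meta <- c()
  data_start <- NA_integer_
  for (i in hdr_idx) {
    kv <- sub("^##", "", lines[i])
    key <- toupper(trimws(sub("=.*$", "", kv)))
    val <- trimws(sub("^[^=]*=", "", kv))
    meta[key] <- val
    if (key == "XYDATA") {
      if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", val)) {
        stop("only XYDATA=(X++(Y..Y)) JCAMP-DX files are supported",
             call. = FALSE)
      }
      data_start <- i + 1L
    }
  }
  if (is.na(data_start)) stop("no ##XYDATA record found", call. = FALSE)
  end_idx <- grep("^##END", lines)
  data_end <- if (length(end_idx)) min(end_idx[end_idx >= data_start]) - 1L
              else length(lines)
  xf <- if (!is.na(meta["XFACTOR"])) as.numeric(meta["XFACTOR"]) else 1
  yf <- if (!is.na(meta["YFACTOR"])) as.numeric(meta["YFACTOR"]) else 1
  xs <- c(); ys <- c()
  for (ln in lines[data_start:data_end]) {
    tokens <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (any(grepl("[A-DF-Za-df-z%@]", tokens))) {
      stop("compressed (ASDF) JCAMP-DX data are not supported", call. = FALSE)
    }
    vals <- as.numeric(tokens)
    if (anyNA(vals) || length(vals) < 2) {
      stop("malformed JCAMP-DX data line", call. = FALSE)
    }
    xs <- c(xs, vals[1])
    ys <- c(ys, vals[-1])
  }
  npt <- length(ys)
  x1 <- as.numeric(meta["FIRSTX"]); x2 <- as.numeric(meta["LASTX"])
  x <- if (!is.na(x1) && !is.na(x2) && npt > 1) {
    seq(x1, x2, length.out = npt)
  } else {
    # reconstruct from per-line leading abscissas
    seq(xs[1] * xf, by = (xs[2] - xs[1]) * xf /
          (length(ys) / length(xs)), length.out = npt)
  }
  list(x = x, y = ys * yf, meta = meta)
}

#' Write a processed spectrum to CSV (+ JSON processing record)
#'
#' Writes `ppm`, `intensity` columns to `<path>.csv` and the ordered
#' processing record (step names and parameters) to `<path>.json`.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param path Base path without extension.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  utils::write.csv(data.frame(ppm = spectrum$ppm,
                              intensity = spectrum$intensity),
                   paste0(path, ".csv"), row.names = FALSE)
  rec <- lapply(spectrum$record, function(s) {
    s$exclude_windows <- NULL   # windows are objects; keep the record JSON-flat
    s
  })
  jsonlite::write_json(rec, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
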