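#' Read a WFDB (PhysioNet) record
#'
#' Minimal reader for WFDB header/signal pairs as distributed by PhysioNet
#' (e.g. abdominal fetal-ECG databases): parses the `.hea` header, decodes
#' the signal file (formats 16 and 212 are supported) and converts samples
#' to physical units using the per-channel gain and baseline. If a binary
#' annotation file `<record>.<annotation_suffix>` exists it is decoded
#' (MIT annotation format, beat codes only) into the fetal R-peak set;
#' a plain-text sidecar `<record>.fqrs.txt` / `<record>.mqrs.txt` with one
#' 1-based index per line is also honoured.
#'
#' @param path record path without extension (e.g. `"data/r01"`).
#' @param annotation_suffix optional suffix of a fetal QRS annotation file
#'   (e.g. `"qrs"` for `r01.qrs`).
#' @return an [ecg_record()]; channel roles come from the header signal
#'   descriptions when they match known roles, else `"abdominal_mixture"`.
#' @export
read_wfdb_record <- function(path, annotation_suffix = NULL) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("missing WFDB header file: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 2L) stop("corrupt WFDB header: ", hea)
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (length(lines) < 1L + nsig) stop("WFDB header declares ", nsig,
                                      " signals but lists fewer: ", hea)
  sig <- lapply(lines[1 + seq_len(nsig)],
                function(l) strsplit(trimws(l), "\\s+")[[1]])
  fname <- vapply(sig, `[`, "", 1)
  if (length(unique(fname)) != 1L)
    stop("multi-file WFDB records are not supported: ", hea)
  fmt <- sub("x.*$", "", vapply(sig, `[`, "", 2))
  if (length(unique(fmt)) != 1L) stop("mixed signal formats not supported")
  fmt <- fmt[1]
  gainfield <- vapply(sig, function(s) if (length(s) >= 3) s[3] else "200", "")
  gain <- as.numeric(sub("^([-0-9.eE+]*).*$", "\\1", gainfield))
  gain[!is.finite(gain) | gain == 0] <- 200
  baseline <- ifelse(grepl("\\(", gainfield),
                     as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainfield)), 0)
  adczero <- vapply(sig, function(s) if (length(s) >= 5) as.numeric(s[5]) else 0,
                    numeric(1))
  baseline <- ifelse(is.finite(baseline), baseline, adczero)
  desc <- vapply(sig, function(s) if (length(s) >= 9)
    paste(s[9:length(s)], collapse = " ") else "", "")

  dat <- file.path(dirname(hea), fname[1])
  if (!file.exists(dat)) stop("missing WFDB signal file: ", dat)
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  adc <- switch(fmt,
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
      matrix(v[seq_len((length(v) %/% nsig) * nsig)], ncol = nsig, byrow = TRUE)
    },
    "212" = {
      n3 <- (length(raw) %/% 3L) * 3L
      b <- as.integer(raw[seq_len(n3)])
      b0 <- b[seq(1, n3, 3)]; b1 <- b[seq(2, n3, 3)]; b2 <- b[seq(3, n3, 3)]
      s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0F), 8)
      s2 <- b2 + bitwShiftL(bitwShiftR(b1, 4), 8)
      s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
      s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
      v <- as.vector(rbind(s1, s2))
      matrix(v[seq_len((length(v) %/% nsig) * nsig)], ncol = nsig, byrow = TRUE)
    },
    stop("unsupported WFDB signal format '", fmt, "'")
  )
  if (!is.na(nsamp) && nrow(adc) != nsamp) {
    if (nrow(adc) < nsamp)
      stop("WFDB signal file shorter than header declares (", nrow(adc),
           " < ", nsamp, " samples): ", dat)
    adc <- adc[seq_len(nsamp), , drop = FALSE]
  }
  phys <- sweep(sweep(adc, 2, baseline, "-"), 2, gain, "/")

  known <- c("abdominal_mixture", "fetal_truth", "maternal_truth",
             "fetal_scalp_reference", "fecg_pred", "mecg_pred")
  roles <- ifelse(desc %in% known, desc, "abdominal_mixture")

  rpf <- read_index_sidecar(paste0(path, ".fqrs.txt"))
  rpm <- read_index_sidecar(paste0(path, ".mqrs.txt"))
  if (!is.null(annotation_suffix)) {
    af <- paste0(path, ".", annotation_suffix)
    if (file.exists(af)) rpf <- read_wfdb_annotation(af)
  }
  ecg_record(phys, fs = fs, channel_roles = roles,
             rpeaks_fetal = rpf, rpeaks_maternal = rpm,
             meta = read_meta_sidecar(paste0(path, ".meta.json")))
}

#' Read a binary MIT-format annotation file
#'
#' Decodes the standard WFDB annotation byte stream (2-byte little-endian
#' words; annotation code in the top 6 bits, time increment in the low 10)
#' including SKIP/NUM/SUB/CHN/AUX pseudo-annotations, and returns the sample
#' indices (1-based) of beat annotations.
#'
#' @param file path to the annotation file.
#' @return integer vector of 1-based R-peak sample indices.
#' @export
read_wfdb_annotation <- function(file) {
  if (!file.exists(file)) stop("missing annotation file: ", file)
  b <- as.integer(readBin(file, "raw", n = file.info(file)$size))
  i <- 1L; t <- 0L; out <- integer()
  while (i + 1L <= length(b)) {
    lo <- b[i]; hi <- b[i + 1L]; i <- i + 2L
    code <- bitwShiftR(hi, 2)
    delta <- bitwShiftL(bitwAnd(hi, 3L), 8) + lo
    if (code == 0L && delta == 0L) break        # end of file
    if (code == 59L) {                           # SKIP: 4-byte interval follows
      if (i + 3L > length(b)) break
      high <- bitwShiftL(bitwAnd(b[i + 1L], 255L), 8) + b[i]
      low <- bitwShiftL(bitwAnd(b[i + 3L], 255L), 8) + b[i + 2L]
      iv <- bitwShiftL(high, 16) + low
      if (iv > 2^31 - 1) iv <- iv - 2^32
      t <- t + iv
      i <- i + 4L
    } else if (code == 63L) {                    # AUX: delta bytes of text
      i <- i + delta + (delta %% 2L)
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN carry fields, no time advance
    } else {
      t <- t + delta
      if (code >= 1L && code <= 49L) out <- c(out, t + 1L)  # beat annotation
    }
  }
  as.integer(out)
}

#' Write an ECG record to disk
#'
#' Two on-disk layouts are supported. `"csv"` writes one header row of
#' channel roles and one column per channel, with annotations in plain-text
#' sidecars (`<base>.fqrs.txt`, `<base>.mqrs.txt`, one 1-based index per
#' line) and the sampling rate plus scalar metadata in `<base>.meta.json`.
#' `"wfdb"` writes a PhysioNet-compatible header/signal pair in format 16
#' with per-channel auto-scaled gain (quantisation error at most
#' `0.5/gain`), plus the same annotation sidecars.
#'
#' @param record an [ecg_record()].
#' @param path output path; the extension is stripped to form the base name.
#' @param format `"csv"` or `"wfdb"`.
#' @return the base path, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb")) {
  validate_record(record)
  format <- match.arg(format)
  base <- sub("\\.(csv|hea|dat)$", "", path)
  dir <- dirname(base)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  if (format == "csv") {
    df <- as.data.frame(record$signals)
    names(df) <- record$channel_roles
    utils::write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  } else {
    n <- nrow(record$signals); nsig <- ncol(record$signals)
    amax <- pmax(apply(abs(record$signals), 2, max), 1e-12)
    gain <- 32000 / amax
    adc <- round(sweep(record$signals, 2, gain, "*"))
    adc[adc > 32767] <- 32767; adc[adc < -32768] <- -32768
    con <- file(paste0(base, ".dat"), "wb")
    writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
    close(con)
    hdr <- c(sprintf("%s %d %g %d", basename(base), nsig, record$fs, n),
             sprintf("%s.dat 16 %.6f(0)/mV 16 0 %d 0 0 %s",
                     basename(base), gain, as.integer(adc[1, ]),
                     record$channel_roles))
    writeLines(hdr, paste0(base, ".hea"))
  }
  write_index_sidecar(paste0(base, ".fqrs.txt"), record$rpeaks_fetal)
  write_index_sidecar(paste0(base, ".mqrs.txt"), record$rpeaks_maternal)
  scalars <- record$meta[vapply(record$meta, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))]
  jsonlite::write_json(c(list(fs = record$fs), scalars),
                       paste0(base, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' Read a record written by [write_record()] in CSV layout
#'
#' @param path path to the `.csv` file (or its base name).
#' @param fs sampling rate override; by default taken from the
#'   `<base>.meta.json` sidecar.
#' @return an [ecg_record()].
#' @export
read_record_csv <- function(path, fs = NULL) {
  base <- sub("\\.csv$", "", path)
  f <- paste0(base, ".csv")
  if (!file.exists(f)) stop("missing CSV record file: ", f)
  df <- utils::read.csv(f, check.names = FALSE)
  meta <- read_meta_sidecar(paste0(base, ".meta.json"))
  if (is.null(fs)) {
    fs <- meta$fs
    if (is.null(fs)) stop("no sampling rate: pass fs= or provide ",
                          base, ".meta.json")
    meta$fs <- NULL
  }
  ecg_record(as.matrix(df), fs = fs, channel_roles = names(df),
             rpeaks_fetal = read_index_sidecar(paste0(base, ".fqrs.txt")),
             rpeaks_maternal = read_index_sidecar(paste0(base, ".mqrs.txt")),
             meta = meta)
}

write_index_sidecar <- function(file, idx) {
  if (length(idx)) writeLines(as.character(as.integer(idx)), file)
  else if (file.exists(file)) unlink(file)
  invisible(file)
}

read_index_sidecar <- function(file) {
  if (!file.exists(file)) return(integer())
  as.integer(readLines(file, warn = FALSE))
}

read_meta_sidecar <- function(file) {
  if (!file.exists(file)) return(list())
  out <- jsonlite::read_json(file, simplifyVector = TRUE)
  as.list(out)
}
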