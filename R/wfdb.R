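# WFDB (.hea/.dat/.atr) support: enough to round-trip the synthetic records
# used in tests and to read standard two-lead arrhythmia-database records
# (signal formats 212 and 16) for the optional real-data workflow.

#' Construct a single-lead ECG signal
#'
#' @param samples numeric vector of voltages (mV), all finite.
#' @param fs sampling rate in Hz (> 0).
#' @param record_id record identifier.
#' @param lead lead name.
#' @return an object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, fs, record_id = "synth", lead = "I") {
  if (!length(samples)) stop_bad("samples must be non-empty")
  if (!all(is.finite(samples))) stop_bad("samples must all be finite")
  assert_scalar_num(fs, "fs", positive = TRUE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         record_id = as.character(record_id), lead = as.character(lead)),
    class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> record %s, lead %s: %d samples @ %g Hz (%.1f s)\n",
              x$record_id, x$lead, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

# standard WFDB annotation code <-> symbol table (codes 1..41)
.atr_symbols <- c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j",
                  "/", "Q", "~", "", "|", "", "s", "T", "*", "D", "\"",
                  "=", "p", "B", "^", "t", "+", "u", "?", "!", "[", "]",
                  "e", "n", "@", "x", "f", "(", ")", "r")

.atr_code_for <- function(symbol) {
  code <- match(symbol, .atr_symbols)
  code[is.na(code)] <- 13L # unknown beats -> Q
  code
}

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop_bad("empty header: ", hea_path)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record <- sub("/.*$", "", top[1])
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  n_samp <- if (length(top) >= 4) as.numeric(top[4]) else NA_real_
  if (length(lines) < 1 + n_sig) stop_bad("header declares ", n_sig,
                                          " signals but lists fewer")
  sig <- lapply(lines[1 + seq_len(n_sig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_field <- f[3]
    units <- if (grepl("/", gain_field)) sub("^[^/]*/", "", gain_field) else "mV"
    gb <- sub("/.*$", "", gain_field)
    baseline <- NA_real_
    if (grepl("\\(", gb)) {
      baseline <- as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gb))
      gb <- sub("\\(.*$", "", gb)
    }
    gain <- as.numeric(gb)
    if (!is.finite(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (!is.finite(baseline)) baseline <- adc_zero
    list(file = f[1], format = as.integer(sub("x.*$", "", f[2])),
         gain = gain, baseline = baseline, units = units,
         description = if (length(f) >= 9)
           paste(f[9:length(f)], collapse = " ") else NA_character_)
  })
  list(record = record, n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sig)
}

decode_dat <- function(raw, format, n_sig) {
  if (format == 212) {
    n3 <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(n3)])
    b0 <- b[seq(1, n3, by = 3)]; b1 <- b[seq(2, n3, by = 3)]
    b2 <- b[seq(3, n3, by = 3)]
    s0 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8)
    s1 <- b2 + bitwShiftL(bitwShiftR(b1, 4), 8)
    s0 <- ifelse(s0 > 2047L, s0 - 4096L, s0)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    v <- as.vector(rbind(s0, s1))
  } else if (format == 16) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
  } else {
    stop_bad("unsupported WFDB signal format: ", format)
  }
  n <- (length(v) %/% n_sig) * n_sig
  matrix(v[seq_len(n)], ncol = n_sig, byrow = TRUE)
}

#' Read one lead of a WFDB record
#'
#' Supports signal formats 212 (packed 12-bit pairs, the arrhythmia-database
#' format) and 16 (little-endian 16-bit).  Samples are converted to physical
#' units via `(adc - baseline) / gain`.
#'
#' @param path record path with or without the `.hea` extension.
#' @param lead lead name (header description field); `NULL` selects the
#'   first signal.
#' @return an [ecg_signal()].
#' @export
read_record <- function(path, lead = NULL) {
  base <- sub("\\.hea$", "", path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) stop_bad("header not found: ", hea_path)
  h <- parse_hea(hea_path)
  descs <- vapply(h$signals, function(s) s$description %||% NA_character_,
                  character(1))
  idx <- if (is.null(lead)) 1L else match(lead, descs)
  if (is.na(idx)) stop_bad("lead '", lead, "' not in record (have: ",
                           paste(descs, collapse = ", "), ")")
  sg <- h$signals[[idx]]
  dat_path <- file.path(dirname(hea_path), sg$file)
  if (!file.exists(dat_path)) stop_bad("signal file not found: ", dat_path)
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  mat <- decode_dat(raw, sg$format, h$n_sig)
  if (is.finite(h$n_samp) && h$n_samp > 0 && nrow(mat) >= h$n_samp)
    mat <- mat[seq_len(h$n_samp), , drop = FALSE]
  ecg_signal((mat[, idx] - sg$baseline) / sg$gain, fs = h$fs,
             record_id = h$record, lead = descs[idx] %||% paste0("sig", idx))
}

#' Write an ECG signal as a WFDB record (format 16)
#'
#' Minimal single-signal writer used by the synthetic-data workflow and the
#' round-trip tests.  Quantization step is `1/gain` mV.
#'
#' @param signal an [ecg_signal()].
#' @param path output path without extension.
#' @param gain ADC units per mV.
#' @param adc_zero ADC zero level.
#' @return `path`, invisibly.
#' @export
write_record <- function(signal, path, gain = 2000, adc_zero = 0) {
  stopifnot(inherits(signal, "ecg_signal"))
  adc <- as.integer(round(signal$samples * gain + adc_zero))
  if (any(adc > 32767L | adc < -32768L))
    stop_bad("signal exceeds 16-bit range at gain ", gain)
  base <- basename(path)
  writeLines(c(
    sprintf("%s 1 %g %d", base, signal$fs, length(adc)),
    sprintf("%s.dat 16 %g(%d)/mV 16 %d %d 0 0 %s",
            base, gain, as.integer(adc_zero), as.integer(adc_zero),
            adc[1], signal$lead)),
    paste0(path, ".hea"))
  writeBin(adc, paste0(path, ".dat"), size = 2L, endian = "little")
  invisible(path)
}

#' Map an annotation symbol to its AAMI four-class group
#'
#' Follows the AAMI EC57 convention behind the N/S/V/F nomenclature:
#' N gets `{N, L, R, e, j}`, S gets `{A, a, J, S}`, V gets `{V, E}`,
#' F gets `{F}`; every other symbol (paced, unknown, and non-beat marks)
#' maps to `"EXCLUDED"`.  Total on any character input.
#'
#' @param symbol character vector of annotation codes.
#' @return character vector over `{N, S, V, F, EXCLUDED}`.
#' @export
map_symbol_to_aami <- function(symbol) {
  groups <- c(N = "N", L = "N", R = "N", e = "N", j = "N",
              A = "S", a = "S", J = "S", S = "S",
              V = "V", E = "V",
              F = "F")
  out <- unname(groups[as.character(symbol)])
  out[is.na(out)] <- "EXCLUDED"
  out
}

#' Read beat annotations
#'
#' Reads either a WFDB binary `.atr`/`.qrs` annotation file or a CSV with
#' columns `r_index` (0-based sample index) and `symbol`.  Returns one row per
#' beat mark, sorted by `r_index`, with the AAMI class attached.
#'
#' @param path annotation file.
#' @return data.frame with columns `r_index`, `symbol`, `aami_class`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_bad("annotation file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("r_index", "symbol") %in% names(df)))
      stop_bad("annotation CSV needs columns r_index, symbol")
    ann <- data.frame(r_index = as.integer(df$r_index),
                      symbol = as.character(df$symbol),
                      stringsAsFactors = FALSE)
  } else {
    ann <- read_atr(path)
  }
  ann <- ann[order(ann$r_index), , drop = FALSE]
  ann$aami_class <- map_symbol_to_aami(ann$symbol)
  rownames(ann) <- NULL
  ann
}

read_atr <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  w <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
               signed = FALSE, endian = "little")
  t_cur <- 0; i <- 1L
  idx <- integer(0); sym <- character(0)
  while (i <= length(w)) {
    code <- bitwShiftR(w[i], 10)
    tfield <- bitwAnd(w[i], 1023L)
    if (code == 0L && tfield == 0L) break            # EOF
    if (code == 59L) {                               # SKIP: 4-byte interval
      if (tfield == 0L) {
        if (i + 2L > length(w)) break
        t_cur <- t_cur + w[i + 1L] * 65536 + w[i + 2L]
        i <- i + 3L
        next
      }
      t_cur <- t_cur + tfield
      i <- i + 1L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { i <- i + 1L; next }   # NUM/SUB/CHN
    if (code == 63L) {                                       # AUX string
      i <- i + 1L + (tfield + tfield %% 2L) %/% 2L
      next
    }
    t_cur <- t_cur + tfield
    if (code >= 1L && code <= length(.atr_symbols) &&
        nzchar(.atr_symbols[code])) {
      idx <- c(idx, t_cur)
      sym <- c(sym, .atr_symbols[code])
    }
    i <- i + 1L
  }
  data.frame(r_index = as.integer(idx), symbol = sym, stringsAsFactors = FALSE)
}

#' Write beat annotations
#'
#' Writes a WFDB `.atr`-style binary stream (extension other than `.csv`)
#' or a plain CSV.  Only beat marks are emitted.
#'
#' @param ann data.frame with `r_index` and `symbol`.
#' @param path output file; `.csv` selects CSV output.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  ann <- ann[order(ann$r_index), , drop = FALSE]
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(ann[, c("r_index", "symbol")], path, row.names = FALSE)
    return(invisible(path))
  }
  codes <- .atr_code_for(ann$symbol)
  words <- integer(0)
  prev <- 0
  for (j in seq_along(codes)) {
    delta <- ann$r_index[j] - prev
    if (delta > 1023) {
      words <- c(words, bitwShiftL(59L, 10),
                 as.integer(delta %/% 65536), as.integer(delta %% 65536))
      delta <- 0L
    }
    words <- c(words, bitwShiftL(codes[j], 10) + as.integer(delta))
    prev <- ann$r_index[j]
  }
  words <- c(words, 0L)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(words, con, size = 2L, endian = "little")
  invisible(path)
}

#' Export a beat table as CSV
#'
#' @param ann annotation data.frame (from [read_annotations()]).
#' @param record_id record identifier column value.
#' @param path output CSV path.
#' @export
write_beat_table <- function(ann, record_id, path) {
  out <- data.frame(record_id = record_id, r_index = ann$r_index,
                    symbol = ann$symbol, aami_class = ann$aami_class,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Random per-class stratified split; within each class the training share is
#' within one observation of `train_frac`.  Classes with fewer than two
#' members go entirely to training, with a warning.
#'
#' @param labels class label per observation.
#' @param train_frac training fraction in (0, 1); default 0.9.
#' @param seed integer seed; the split is reproducible for a fixed seed.
#' @return list with `train_ids`, `test_ids` (1-based indices into `labels`)
#'   and `seed`.
#' @export
split_dataset <- function(labels, train_frac = 0.9, seed = 1L) {
  if (!(train_frac > 0 && train_frac < 1))
    stop_bad("train_frac must be in (0, 1)")
  labels <- as.character(labels)
  train <- integer(0); test <- integer(0)
  with_seed(seed, {
    for (cls in unique(labels)) {
      ids <- which(labels == cls)
      if (length(ids) < 2L) {
        warning("class ", cls, " has < 2 members; all assigned to training")
        train <- c(train, ids)
        next
      }
      n_tr <- round(train_frac * length(ids))
      n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
      tr <- sample(ids, n_tr)
      train <- c(train, tr)
      test <- c(test, setdiff(ids, tr))
    }
  })
  list(train_ids = sort(train), test_ids = sort(test), seed = seed)
}
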