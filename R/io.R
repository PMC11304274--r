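# File formats: a tab-separated text dialect for interchange and an RDS
# binary dialect for lossless round trips; a minimal JCAMP-DX importer for
# externally processed real spectra.

#' Save / load a spectrum
#'
#' The text dialect (`.tsv`) stores `axis_hz` and `value` columns with the
#' normalization factor and sweep width in `#`-comment headers at full
#' precision; the binary dialect (`.rds`) serializes the object. Both round
#' trip losslessly.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param path file path; format inferred from the extension (`.rds` binary,
#'   anything else text) unless `format` is given.
#' @param format `"text"` or `"binary"`.
#' @export
save_spectrum <- function(spectrum, path, format = NULL) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (length(spectrum$values) < 1) stop("refusing to write an empty spectrum")
  format <- format %||% if (grepl("\\.rds$", path)) "binary" else "text"
  if (format == "binary") {
    saveRDS(spectrum, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# nmr_spectrum n_ft=%d", spectrum$n_ft),
                 sprintf("# spectral_width_hz=%.17g", spectrum$spectral_width_hz),
                 sprintf("# norm_factor=%.17g", spectrum$norm_factor),
                 "axis_hz\tvalue"), con)
    writeLines(sprintf("%.17g\t%.17g", spectrum$axis_hz, spectrum$values), con)
  }
  invisible(path)
}

#' @rdname save_spectrum
#' @export
load_spectrum <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||% if (grepl("\\.rds$", path)) "binary" else "text"
  if (format == "binary") {
    sp <- readRDS(path)
    if (!inherits(sp, "nmr_spectrum")) stop(path, " does not hold a spectrum")
    return(sp)
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key) {
    m <- grep(paste0(key, "="), hdr, value = TRUE)
    if (!length(m)) stop("malformed spectrum file ", path, ": missing ", key)
    as.numeric(sub(paste0(".*", key, "="), "", m[1]))
  }
  sw <- get_num("spectral_width_hz")
  nf <- get_num("norm_factor")
  body <- lines[!grepl("^#", lines)][-1]       # drop the column header
  if (!length(body)) stop("spectrum file ", path, " holds no data rows")
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad))
    stop("malformed spectrum file ", path, ": line ",
         bad[1] + length(hdr) + 1, " does not have 2 fields")
  vals <- as.numeric(vapply(parts, `[`, character(1), 2))
  sp <- as_spectrum(vals, spectral_width_hz = sw)
  sp$norm_factor <- nf
  sp$axis_hz <- as.numeric(vapply(parts, `[`, character(1), 1))
  sp
}

#' Save / load a synthetic dataset
#'
#' Binary dialect: RDS of the whole container. Text export: one spectrum per
#' row, inputs then labels, for interchange with other tools.
#'
#' @param dataset a [generate_dataset()] result.
#' @param path file path (`.rds` for the container; [export_dataset_tsv()]
#'   writes the text dialect).
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "psnet_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ds <- readRDS(path)
  if (!inherits(ds, "psnet_dataset")) stop(path, " does not hold a dataset")
  ds
}

#' @rdname save_dataset
#' @param prefix output path prefix; writes `<prefix>.input.tsv` and
#'   `<prefix>.label.tsv`.
#' @export
export_dataset_tsv <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "psnet_dataset"))
  utils::write.table(dataset$input, paste0(prefix, ".input.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$label, paste0(prefix, ".label.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the weights, the full architecture configuration,
#' the batch-norm running statistics, the training history and seeds, so a
#' reload reconstructs identically.
#' @param model a `sepsnet` object.
#' @param path checkpoint path (RDS).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sepsnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- readRDS(path)
  if (!inherits(m, "sepsnet")) stop(path, " does not hold a model checkpoint")
  m
}

#' Minimal JCAMP-DX import of a real 1D spectrum
#'
#' Reads fixed-format / AFFN `XYDATA (X++(Y..Y))` blocks — enough for
#' externally processed real-valued spectra. Compressed (SQZ/DIF/DUP)
#' encodings are not supported.
#'
#' @param path a `.jdx` / `.dx` file.
#' @return an `nmr_spectrum` (values in file order, axis from FIRSTX/LASTX).
#' @export
read_jdx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    m <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(m)) return(NA_real_)
    as.numeric(sub(paste0("^##", key, "=\\s*"), "", m[1]))
  }
  yfac <- get_field("YFACTOR"); if (is.na(yfac)) yfac <- 1
  firstx <- get_field("FIRSTX"); lastx <- get_field("LASTX")
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA= block in ", path)
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  ys <- unlist(lapply(body, function(l) {
    tok <- strsplit(trimws(l), "[ \t]+")[[1]]
    if (length(tok) < 2) return(numeric(0))
    as.numeric(tok[-1])                       # first token is the X value
  }))
  if (!length(ys) || any(is.na(ys)))
    stop("could not parse AFFN XYDATA in ", path,
         " (compressed encodings are unsupported)")
  sw <- if (!is.na(firstx) && !is.na(lastx)) abs(lastx - firstx) else length(ys)
  as_spectrum(ys * yfac, spectral_width_hz = sw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
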