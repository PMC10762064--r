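#' Read spectra from a Mascot generic format (MGF) file
#'
#' One [spectrum()] per `BEGIN IONS`/`END IONS` block. `TITLE` is used as
#' the spectrum id, `PEPMASS` as precursor m/z and `CHARGE` (sign suffix
#' accepted, e.g. `2+`) as precursor charge. Entries missing a precursor
#' field or holding a malformed peak line are rejected individually; the
#' remaining entries are still returned (rejections are reported via
#' warnings naming the entry index).
#'
#' @param path Path to an MGF file.
#' @return List of `seqmend_spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends))
    stop("unbalanced BEGIN IONS/END IONS blocks in ", path)
  out <- vector("list", length(begins))
  ok <- logical(length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    res <- tryCatch(.parse_mgf_block(block, i), error = function(e) {
      warning("MGF entry ", i, " rejected: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      out[[i]] <- res
      ok[i] <- TRUE
    }
  }
  out[ok]
}

.parse_mgf_block <- function(block, idx) {
  block <- block[nzchar(trimws(block))]
  is_header <- grepl("^[A-Za-z]+=", block)
  headers <- block[is_header]
  keys <- toupper(sub("=.*$", "", headers))
  vals <- sub("^[A-Za-z]+=", "", headers)
  title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
    paste0("index=", idx)
  if (!"PEPMASS" %in% keys) stop("missing PEPMASS")
  pepmass <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]),
                                 "\\s+")[[1]][1])
  if (is.na(pepmass)) stop("unreadable PEPMASS")
  if (!"CHARGE" %in% keys) stop("missing CHARGE")
  chg_raw <- trimws(vals[match("CHARGE", keys)])
  chg <- suppressWarnings(as.integer(sub("\\+$", "", chg_raw)))
  if (grepl("-$", chg_raw)) chg <- -chg
  if (is.na(chg)) stop("unreadable CHARGE '", chg_raw, "'")
  peak_lines <- trimws(block[!is_header])
  mz <- numeric(0); inten <- numeric(0)
  if (length(peak_lines)) {
    fields <- strsplit(peak_lines, "[ \t]+")
    if (any(lengths(fields) < 2L)) stop("malformed peak line")
    mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
    inten <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    if (anyNA(mz) || anyNA(inten)) stop("malformed peak line")
  }
  spectrum(title, mz, inten, pepmass, chg)
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()] up to float formatting (m/z written with 5
#' decimals, intensities with 6 significant digits).
#'
#' @param spectra List of `seqmend_spectrum` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    paste(c("BEGIN IONS",
            paste0("TITLE=", s$spectrum_id),
            sprintf("PEPMASS=%.5f", s$precursor_mz),
            sprintf("CHARGE=%d+", s$precursor_charge),
            sprintf("%.5f %.6g", s$mz, s$intensity),
            "END IONS"), collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Export peak lists as a TSV table
#'
#' @param spectra List of `seqmend_spectrum` objects.
#' @param path Output path; the table holds spectrum_id, mz, intensity.
#' @export
write_peaks_tsv <- function(spectra, path) {
  df <- do.call(rbind, lapply(spectra, function(s)
    data.frame(spectrum_id = s$spectrum_id, mz = s$mz,
               intensity = s$intensity)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
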