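#' Write / read a spectral dataset as CSV
#'
#' Matrix dialect: the header row holds the wavenumber axis and each
#' subsequent row is one spectrum. Labels travel in a sidecar manifest CSV
#' (`sample_id`, label columns), aligned by row order.
#'
#' @param ds An [ev_dataset()].
#' @param path Spectrum matrix CSV path.
#' @param manifest_path Manifest CSV path (default: `path` with a
#'   `_manifest.csv` suffix).
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path,
                              manifest_path = sub("\\.csv$", "_manifest.csv", path)) {
  m <- ev_intensities(ds)
  wn <- ev_wavenumbers(ds)
  utils::write.table(rbind(wn, m), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- ds[setdiff(names(ds), "spectra")]
  utils::write.csv(meta, manifest_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @param check_ragged Validate that every row has the same field count.
#' @export
read_spectra_csv <- function(path, manifest_path = sub("\\.csv$", "_manifest.csv", path),
                             check_ragged = TRUE) {
  if (check_ragged) {
    nf <- utils::count.fields(path, sep = ",")
    bad <- which(nf != nf[1])
    if (length(bad) > 0) {
      stop("malformed spectrum CSV '", path, "': row ", bad[1], " has ",
           nf[bad[1]], " fields, expected ", nf[1], call. = FALSE)
    }
  }
  raw <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  wn <- as.numeric(raw[1, ])
  if (any(!is.finite(wn)) || any(diff(wn) <= 0)) {
    stop("malformed spectrum CSV '", path,
         "': header row is not a strictly increasing wavenumber axis", call. = FALSE)
  }
  m <- raw[-1, , drop = FALSE]
  storage.mode(m) <- "double"
  meta <- if (file.exists(manifest_path)) {
    tibble::as_tibble(utils::read.csv(manifest_path, stringsAsFactors = FALSE))
  } else NULL
  ev_dataset(m, wn, meta)
}

#' Read a directory of two-column spectrum files
#'
#' Alternative input dialect: one whitespace- or comma-delimited two-column
#' (wavenumber, intensity) text file per spectrum, with a manifest CSV
#' giving `sample_id` (and optionally `file`) plus label columns. All files
#' must share one axis.
#'
#' @param dir Directory of spectrum files.
#' @param manifest_path Manifest CSV; `file` defaults to `<sample_id>.txt`.
#' @return An [ev_dataset()].
#' @export
read_spectra_dir <- function(dir, manifest_path = file.path(dir, "manifest.csv")) {
  if (!file.exists(manifest_path)) {
    stop("missing manifest: ", manifest_path, call. = FALSE)
  }
  meta <- tibble::as_tibble(utils::read.csv(manifest_path, stringsAsFactors = FALSE))
  if (!"sample_id" %in% names(meta)) stop("manifest lacks sample_id", call. = FALSE)
  files <- if ("file" %in% names(meta)) meta$file else paste0(meta$sample_id, ".txt")
  wn <- NULL
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    tab <- utils::read.table(file.path(dir, files[i]), header = FALSE,
                             sep = "", comment.char = "#")
    if (ncol(tab) == 1) tab <- utils::read.table(file.path(dir, files[i]), sep = ",")
    if (ncol(tab) < 2) {
      stop("spectrum file '", files[i], "' is not two-column", call. = FALSE)
    }
    if (is.null(wn)) wn <- tab[[1]]
    if (!isTRUE(all.equal(wn, tab[[1]]))) {
      stop("spectrum file '", files[i], "' is on a different axis", call. = FALSE)
    }
    rows[[i]] <- tab[[2]]
  }
  ev_dataset(do.call(rbind, rows), wn, meta[setdiff(names(meta), "file")])
}

#' Write / read particle diameter tables
#'
#' @param particles Tibble with `label`, `diameter_nm` (extra columns kept).
#' @param path CSV path.
#' @return `path` invisibly, or the tibble.
#' @export
write_particles_csv <- function(particles, path) {
  utils::write.csv(tibble::as_tibble(particles), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_particles_csv
#' @export
read_particles_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("label", "diameter_nm") %in% names(out))) {
    stop("particle CSV needs label and diameter_nm columns", call. = FALSE)
  }
  out
}
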