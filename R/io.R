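#' Read a stability curve from CSV
#'
#' Expects a header `generation,fraction` (or `generation,percent` with
#' `percent = TRUE`, in which case values are divided by 100). Rows are
#' validated — unsorted generations, out-of-range fractions or malformed
#' values raise an error naming the offending row.
#'
#' @param path File path.
#' @param percent If `TRUE`, the second column holds percentages.
#' @param label Curve label (defaults to the file name).
#' @return A [stability_curve()].
#' @export
read_stability_csv <- function(path, percent = FALSE, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  value_col <- if (percent) "percent" else "fraction"
  if (!all(c("generation", value_col) %in% names(tbl))) {
    stop(sprintf("expected header `generation,%s` in %s", value_col, path),
         call. = FALSE)
  }
  gen <- suppressWarnings(as.numeric(tbl$generation))
  val <- suppressWarnings(as.numeric(tbl[[value_col]]))
  bad <- which(!is.finite(gen) | !is.finite(val))
  if (length(bad)) {
    stop(sprintf("malformed value in row %d of %s", bad[1], path), call. = FALSE)
  }
  if (percent) val <- val / 100
  bad <- which(val < 0 | val > 1)
  if (length(bad)) {
    stop(sprintf("fraction out of [0, 1] in row %d of %s", bad[1], path),
         call. = FALSE)
  }
  if (any(gen < 0)) {
    stop(sprintf("negative generation in row %d of %s", which(gen < 0)[1], path),
         call. = FALSE)
  }
  if (is.unsorted(gen, strictly = TRUE)) {
    bad <- which(diff(gen) <= 0)[1] + 1L
    stop(sprintf("generations not strictly increasing at row %d of %s",
                 bad, path), call. = FALSE)
  }
  stability_curve(gen, val, label = label)
}

#' Write a stability curve to CSV
#'
#' @param curve A [stability_curve()].
#' @param path Output file.
#' @export
write_stability_csv <- function(curve, path) {
  readr::write_csv(
    tibble::tibble(generation = curve$generation, fraction = curve$fraction),
    path
  )
  invisible(path)
}

#' Read a densitometry lane profile from CSV
#'
#' Expects a header `position,intensity`; positions must be increasing and
#' intensities finite and non-negative.
#'
#' @param path File path.
#' @return A tibble with columns `position`, `intensity`.
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    position = readr::col_double(), intensity = readr::col_double()
  ))
  if (any(!is.finite(tbl$intensity)) || any(tbl$intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (is.unsorted(tbl$position)) {
    stop("profile positions must be increasing", call. = FALSE)
  }
  tibble::as_tibble(tbl)
}

#' @param profile A profile tibble to write.
#' @rdname read_profile_csv
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(profile[c("position", "intensity")], path)
  invisible(path)
}
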