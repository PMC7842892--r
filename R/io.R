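# CSV import/export of the tabular artifacts. Schemas are fixed and
# validated on read; malformed rows are reported with their line numbers.

#' Write a radial profile to CSV
#'
#' Columns: `r_mm`, `layer`, `E_vertical`, `E_radial`, `E_mean`,
#' `J_vertical`, `J_radial`, `J_mean`.
#'
#' @param profile A `radial_profile` from [layer_profiles()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profile, path) {
  cols <- c("r_mm", "layer", "E_vertical", "E_radial", "E_mean",
            "J_vertical", "J_radial", "J_mean")
  readr::write_csv(tibble::as_tibble(profile)[, cols], path)
  invisible(path)
}

#' Read a radial profile CSV
#'
#' @param path Path to a CSV written by [write_profiles()].
#' @return A tibble with the profile columns.
#' @export
read_profiles <- function(path) {
  need <- c("r_mm", "layer", "E_vertical", "E_radial", "E_mean",
            "J_vertical", "J_radial", "J_mean")
  tab <- .read_checked_csv(path, need, numeric_cols = setdiff(need, "layer"))
  tab
}

#' Write an exposure profile to CSV
#'
#' Columns: `r_mm`, `V_m_V`, `I_cell_A`.
#'
#' @param exposure An `exposure_profile` from [membrane_exposure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exposure <- function(exposure, path) {
  out <- tibble::tibble(r_mm = exposure$r_mm,
                        V_m_V = exposure$V_m,
                        I_cell_A = exposure$I_cell)
  readr::write_csv(out, path)
  invisible(path)
}

.read_checked_csv <- function(path, need, numeric_cols) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    suppressWarnings(readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)),
    error = function(e) stop("missing header: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!nrow(raw) && !ncol(raw)) stop("missing header", call. = FALSE)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (col in numeric_cols) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at data row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (anyNA(num))
      stop("missing ", col, " at data row(s): ",
           paste(which(is.na(num)), collapse = ", "), call. = FALSE)
    raw[[col]] <- num
  }
  raw
}

#' Read a transfection-efficiency profile from CSV
#'
#' Expects a header row with columns `r_mm` and `eta`. Rows must be numeric
#' with strictly increasing radii and non-negative efficiencies; violations
#' are reported with their data row numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble of class `efficiency_profile` with `r_mm` and `eta`.
#' @export
read_efficiency <- function(path) {
  tab <- .read_checked_csv(path, c("r_mm", "eta"),
                           numeric_cols = c("r_mm", "eta"))
  dr <- diff(tab$r_mm)
  if (any(dr <= 0))
    stop("non-increasing radii at data row(s): ",
         paste(which(dr <= 0) + 1, collapse = ", "), call. = FALSE)
  if (any(tab$eta < 0))
    stop("negative eta at data row(s): ",
         paste(which(tab$eta < 0), collapse = ", "), call. = FALSE)
  out <- tibble::tibble(r_mm = tab$r_mm, eta = tab$eta)
  class(out) <- c("efficiency_profile", class(out))
  out
}

#' Write an efficiency profile to CSV
#'
#' @param efficiency An `efficiency_profile` (e.g. [synth_efficiency()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_efficiency <- function(efficiency, path) {
  readr::write_csv(tibble::tibble(r_mm = efficiency$r_mm,
                                  eta = efficiency$eta), path)
  invisible(path)
}
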