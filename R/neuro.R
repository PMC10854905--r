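# Optic-nerve subarachnoid space width (ONSASW) and trans-lamina cribrosa
# pressure difference (TLCPD) from tabular MRI/clinical measurements.
# ONSASW is the CSF-filled gap between nerve and sheath:
# (mean ONSD - mean OND) / 2, measured at 3, 9 and 15 mm behind the globe;
# TLCPD = IOP - CSFP.

.onsas_stations <- c(3, 9, 15)

#' Optic nerve subarachnoid space width
#'
#' Half the difference between the optic nerve sheath diameter (ONSD) and
#' the optic nerve diameter (OND), each averaged over its horizontal and
#' vertical section; by linearity this equals the mean of the per-axis
#' half-differences.
#'
#' @param ond_h,ond_v optic nerve diameter, horizontal/vertical, mm.
#' @param onsd_h,onsd_v optic nerve sheath diameter, horizontal/vertical,
#'   mm.
#' @return ONSASW in mm (vectorized).
#' @examples
#' compute_onsasw(2.2, 2.2, 4.2, 4.2)  # 1.0 mm
#' @export
compute_onsasw <- function(ond_h, ond_v, onsd_h, onsd_v) {
  if (any(onsd_h < ond_h | onsd_v < ond_v)) {
    stop("sheath narrower than nerve: ONSD must be >= OND on each axis",
         call. = FALSE)
  }
  ((onsd_h + onsd_v) / 2 - (ond_h + ond_v) / 2) / 2
}

#' Trans-lamina cribrosa pressure difference
#'
#' @param iop intraocular pressure, mmHg (>= 0).
#' @param csfp cerebrospinal fluid pressure, mmHg (>= 0); supplied by the
#'   user (e.g. from lumbar puncture or an external estimate) — the package
#'   does not estimate CSFP.
#' @return TLCPD = IOP - CSFP in mmHg; negative values are allowed and
#'   flagged with a `"negative"` attribute.
#' @export
compute_tlcpd <- function(iop, csfp) {
  check_that(all(iop >= 0), "iop", "must be >= 0")
  check_that(all(csfp >= 0), "csfp", "must be >= 0")
  out <- iop - csfp
  attr(out, "negative") <- out < 0
  out
}

#' Load retrobulbar MRI measurements from CSV
#'
#' Expected columns: `subject`, `eye`, `distance_mm` (3, 9 or 15),
#' `ond_h_mm`, `ond_v_mm`, `onsd_h_mm`, `onsd_v_mm`.  Rows violating the
#' measurement invariants are rejected with row-numbered messages.
#'
#' @param path CSV file path.
#' @return data.frame of validated records with an `onsasw_mm` column
#'   appended.
#' @export
load_mri_measurements <- function(path) {
  cols <- c("subject", "eye", "distance_mm", "ond_h_mm", "ond_v_mm",
            "onsd_h_mm", "onsd_v_mm")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty measurement file: ", path)
    out <- df[, intersect(cols, names(df)), drop = FALSE]
    out$onsasw_mm <- numeric(0)
    return(out)
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(cols, c("subject", "eye"))
  errs <- character(0)
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) | is.na(df[[cc]]))
    if (length(bad)) {
      errs <- c(errs, sprintf("row %d: non-numeric %s", bad, cc))
    }
    df[[cc]] <- v
  }
  if (!length(errs)) {
    bad_station <- which(!(df$distance_mm %in% .onsas_stations))
    if (length(bad_station)) {
      errs <- c(errs, sprintf(
        "row %d: distance_mm must be one of the retrobulbar stations 3, 9, 15 mm",
        bad_station))
    }
    bad_axis <- which(df$onsd_h_mm < df$ond_h_mm | df$onsd_v_mm < df$ond_v_mm)
    if (length(bad_axis)) {
      errs <- c(errs, sprintf("row %d: sheath narrower than nerve", bad_axis))
    }
  }
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  df$onsasw_mm <- compute_onsasw(df$ond_h_mm, df$ond_v_mm,
                                 df$onsd_h_mm, df$onsd_v_mm)
  df
}
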