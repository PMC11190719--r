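#' Standard cumulative-DVH threshold grid
#'
#' Dose thresholds (Gy) at which structure volumes are summarised:
#' 0.5, 1, 2 and 5 to 55 Gy in 5-Gy steps.
#'
#' @return Numeric vector of thresholds in Gy.
#' @export
dvh_grid <- function() c(0.5, 1, 2, seq(5, 55, by = 5))

#' Names of the Vx columns of a wide DVH table
#' @return Character vector, e.g. `"V0.5"`, `"V1"`, ..., `"V55"`.
#' @export
vx_cols <- function() paste0("V", dvh_grid())

dvh_metric_names <- function() c("Dmin", "Dmax", "Dmean", vx_cols())

dvh_structures <- function() c("lungs_sum", "heart", "body")

.record_vx <- function(record) {
  unlist(record[vx_cols()], use.names = FALSE)
}

#' Validate a cumulative-DVH record
#'
#' Checks the physical consistency of one structure's cDVH summary:
#' volumes within \[0, 100\]%, Vx non-increasing in the dose threshold,
#' non-negative doses, and `Dmin <= Dmean <= Dmax`. The validator reports
#' issues and never throws.
#'
#' @param record A one-row data frame or named list with `d_min`, `d_max`,
#'   `d_mean` (Gy) and the Vx columns of [vx_cols()] (% volume).
#' @param tol Numerical slack for the monotonicity check.
#' @return Character vector of issues; empty when the record is valid.
#' @examples
#' rec <- as.list(setNames(rep(0, length(vx_cols())), vx_cols()))
#' rec$d_min <- 0; rec$d_mean <- 0; rec$d_max <- 0
#' validate_cdvh(rec)
#' @export
validate_cdvh <- function(record, tol = 1e-9) {
  issues <- character()
  grid <- dvh_grid()
  v <- suppressWarnings(as.numeric(.record_vx(record)))
  if (anyNA(v)) {
    return("missing or non-numeric Vx values")
  }
  bad <- which(v < -tol | v > 100 + tol)
  for (i in bad) {
    issues <- c(issues, sprintf("volume out of range at %g Gy", grid[i]))
  }
  inc <- which(diff(v) > tol)
  for (i in inc) {
    issues <- c(issues, sprintf("non-monotone Vx at %g Gy", grid[i + 1]))
  }
  d <- c(d_min = record$d_min, d_mean = record$d_mean, d_max = record$d_max)
  if (anyNA(d)) {
    issues <- c(issues, "missing dose summary")
    return(issues)
  }
  if (any(d < -tol)) issues <- c(issues, "negative dose")
  if (d[["d_mean"]] > d[["d_max"]] + tol) issues <- c(issues, "mean exceeds max")
  if (d[["d_mean"]] < d[["d_min"]] - tol) issues <- c(issues, "mean below min")
  issues
}

#' Validate every record of a wide DVH table
#'
#' @param dvh Wide DVH table: one row per patient x structure with columns
#'   `patient_id`, `structure`, `d_min`, `d_max`, `d_mean` and [vx_cols()].
#' @return Data frame of issues (`patient_id`, `structure`, `issue`); zero
#'   rows when everything is valid.
#' @export
validate_cdvh_table <- function(dvh) {
  out <- lapply(seq_len(nrow(dvh)), function(i) {
    iss <- validate_cdvh(dvh[i, , drop = FALSE])
    if (length(iss) == 0) return(NULL)
    data.frame(patient_id = dvh$patient_id[i], structure = dvh$structure[i],
               issue = iss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), structure = character(),
                      issue = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Equivalent dose in 2-Gy fractions (EQD2)
#'
#' Linear-quadratic conversion `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)`
#' with dose per fraction `d = D / n_fractions`. With `alpha/beta = 10 Gy`
#' (the convention for lymphotoxicity endpoints) a 2-Gy-per-fraction course
#' maps to itself.
#'
#' @param total_dose Total (cumulative) dose D in Gy; vectorised.
#' @param n_fractions Number of fractions, at least 1.
#' @param alpha_beta Tissue alpha/beta ratio in Gy (default 10).
#' @return EQD2 in Gy.
#' @examples
#' eqd2(66, 33)  # 2 Gy/fraction: unchanged
#' eqd2(60, 20)  # 3 Gy/fraction: 65 Gy
#' @export
eqd2 <- function(total_dose, n_fractions, alpha_beta = 10) {
  if (any(!is.finite(n_fractions)) || any(n_fractions < 1)) {
    stop(ril_error("ril_domain_error", "n_fractions must be >= 1"))
  }
  if (any(!is.finite(total_dose)) || any(total_dose < 0)) {
    stop(ril_error("ril_domain_error", "total_dose must be non-negative"))
  }
  d <- total_dose / n_fractions
  total_dose * (d + alpha_beta) / (2 + alpha_beta)
}

.eqd2_transform_record <- function(record, n_fractions, alpha_beta = 10) {
  issues <- validate_cdvh(record)
  if (length(issues) > 0) {
    stop(ril_error("ril_validation_error",
                   paste0("invalid cDVH record: ",
                          paste(issues, collapse = "; "))))
  }
  grid <- dvh_grid()
  v <- .record_vx(record)
  new_x <- eqd2(grid, n_fractions, alpha_beta)
  # resample onto the standard grid: polyline anchored at (0 Gy, 100 %),
  # zero volume beyond the highest transformed threshold
  res <- stats::approx(x = c(0, new_x), y = c(100, v), xout = grid,
                       rule = 1)$y
  res[is.na(res)] <- 0
  out <- record
  out[vx_cols()] <- as.list(res)
  out$d_min <- eqd2(record$d_min, n_fractions, alpha_beta)
  out$d_mean <- eqd2(record$d_mean, n_fractions, alpha_beta)
  out$d_max <- eqd2(record$d_max, n_fractions, alpha_beta)
  out
}

#' EQD2-transform cumulative DVH records
#'
#' Converts the dose axis of each cDVH record to EQD2 point-wise (each
#' threshold or dose summary D is assumed delivered in `n_fractions` equal
#' fractions of `D / n_fractions` Gy) and re-samples the volumes back onto
#' the standard grid by monotone linear interpolation. Monotonicity and
#' volume bounds are preserved.
#'
#' @param dvh A wide DVH table (see [validate_cdvh_table()]) or a single
#'   record as a named list.
#' @param n_fractions Either a single fraction number or a data frame
#'   `patient_id`, `n_fractions` joined by patient.
#' @param alpha_beta Tissue alpha/beta ratio in Gy (default 10).
#' @return The transformed table (or record) in the same shape.
#' @export
eqd2_transform_dvh <- function(dvh, n_fractions, alpha_beta = 10) {
  if (!is.data.frame(dvh)) {
    stopifnot(length(n_fractions) == 1)
    return(.eqd2_transform_record(dvh, n_fractions, alpha_beta))
  }
  if (is.data.frame(n_fractions)) {
    nfx <- n_fractions$n_fractions[match(dvh$patient_id,
                                         n_fractions$patient_id)]
    if (anyNA(nfx)) {
      stop(ril_error("ril_schema_error",
                     "n_fractions missing for some patients in the DVH table"))
    }
  } else {
    nfx <- rep_len(n_fractions, nrow(dvh))
  }
  out <- dvh
  for (i in seq_len(nrow(dvh))) {
    rec <- .eqd2_transform_record(as.list(dvh[i, , drop = FALSE]), nfx[i],
                                  alpha_beta)
    out[i, c("d_min", "d_mean", "d_max", vx_cols())] <-
      rec[c("d_min", "d_mean", "d_max", vx_cols())]
  }
  out
}

#' Effective dose of radiation to circulating immune cells (EDRIC)
#'
#' Weighted combination of mean lung dose (MLD), mean heart dose (MHD) and
#' mean body dose (MBD), with the body weight growing with the number of
#' fractions (longer courses expose more of the recirculating blood pool):
#' `EDRIC = 0.12*MLD + 0.08*MHD + (0.45 + 0.35 * 0.85 * n/45) * MBD`.
#'
#' @param mld,mhd,mbd Mean doses in Gy (non-negative; vectorised).
#' @param n_fractions Number of fractions, at least 1.
#' @return EDRIC in Gy.
#' @examples
#' edric(10, 5, 2, 30)
#' @export
edric <- function(mld, mhd, mbd, n_fractions) {
  if (any(!is.finite(c(mld, mhd, mbd))) || any(c(mld, mhd, mbd) < 0)) {
    stop(ril_error("ril_domain_error", "mean doses must be non-negative"))
  }
  if (any(!is.finite(n_fractions)) || any(n_fractions < 1)) {
    stop(ril_error("ril_domain_error", "n_fractions must be >= 1"))
  }
  0.12 * mld + 0.08 * mhd + (0.45 + 0.35 * 0.85 * (n_fractions / 45)) * mbd
}

#' Per-patient EDRIC from a DVH table and clinical fractionation
#'
#' Extracts the mean lung (sum), heart and whole-body doses from a wide
#' (physical-dose) DVH table and combines them with each patient's number
#' of fractions.
#'
#' @param dvh Wide DVH table with rows for structures `lungs_sum`, `heart`
#'   and `body`.
#' @param clinical Clinical table with `patient_id` and `n_fractions`.
#' @return Data frame `patient_id`, `mld`, `mhd`, `mbd`, `n_fractions`,
#'   `edric`.
#' @export
edric_table <- function(dvh, clinical) {
  need <- dvh_structures()
  means <- lapply(need, function(s) {
    d <- dvh[dvh$structure == s, c("patient_id", "d_mean")]
    names(d)[2] <- s
    d
  })
  m <- Reduce(function(x, y) merge(x, y, by = "patient_id"), means)
  m <- merge(m, clinical[, c("patient_id", "n_fractions")], by = "patient_id")
  data.frame(patient_id = m$patient_id,
             mld = m$lungs_sum, mhd = m$heart, mbd = m$body,
             n_fractions = m$n_fractions,
             edric = edric(m$lungs_sum, m$heart, m$body, m$n_fractions),
             stringsAsFactors = FALSE)
}
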