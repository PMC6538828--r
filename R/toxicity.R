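## Dioxin/furan toxic equivalency and regulatory threshold screening.

#' Toxic equivalency (TEQ) of a dioxin/furan congener profile
#'
#' TEF-weighted sum of congener concentrations:
#' `TEQ = sum_i C_i * TEF_i`, in ng TEQ per kg when concentrations are in
#' ng/kg.
#'
#' @param congener_concs named numeric vector, congener id -> concentration
#'   (ng/kg).
#' @param tefs toxic equivalency factor table: either a named numeric
#'   vector or a data.frame with columns `congener` and `tef` (see
#'   [hsw_fixture()] for the packaged WHO-2005 factors).
#' @return TEQ in ng/kg.
#' @export
teq <- function(congener_concs, tefs) {
  if (length(congener_concs) == 0) return(0)
  if (is.null(names(congener_concs)) || any(names(congener_concs) == ""))
    abort("congener concentrations must be named")
  if (is.data.frame(tefs)) tefs <- stats::setNames(tefs$tef, tefs$congener)
  if (any(tefs < 0, na.rm = TRUE)) abort("TEF values must be nonnegative")
  missing <- setdiff(names(congener_concs), names(tefs))
  if (length(missing))
    abort("no TEF for congener(s): ", paste(missing, collapse = ", "))
  sum(congener_concs * tefs[names(congener_concs)])
}

#' Percent margin of a measured value below a regulatory threshold
#'
#' `100 * (threshold - value) / threshold`: positive when below the limit,
#' zero at the limit, negative when exceeding.
#'
#' @param value measured concentration.
#' @param threshold regulatory maximum, > 0, same unit as `value`.
#' @return percent margin (at most 100).
#' @export
margin_to_threshold <- function(value, threshold) {
  if (any(threshold <= 0, na.rm = TRUE)) abort("threshold must be positive")
  100 * (threshold - value) / threshold
}

#' Screen an amendment against a regulatory threshold set
#'
#' Compares every analyte present in both the record and the threshold set.
#' Exceedance is strict (`value > threshold`); a value equal to the limit
#' passes, since regulatory limits are stated as maxima.
#'
#' @param record one-row amendment table in internal units (mg/kg for
#'   metals, ug/kg for PAH/PCB totals, ng/kg for dioxin TEQ), as produced
#'   by [read_amendments()] or [hsw_fixture()].
#' @param thresholds data.frame with columns `regulation`, `analyte`,
#'   `limit`, `unit` — one regulation's limits (filter the packaged table
#'   first if it holds several).
#' @return `screen_report` data.frame: one row per analyte with `measured`,
#'   `threshold`, `regulation`, `status` ("pass"/"exceed") and
#'   `margin_percent`.
#' @export
screen_amendment <- function(record, thresholds) {
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(record) != 1) abort("screen one amendment record at a time")
  stopifnot(all(c("regulation", "analyte", "limit") %in% names(thresholds)))
  if (length(unique(thresholds$regulation)) > 1)
    abort("thresholds must belong to a single regulation; filter first")
  if (any(thresholds$limit <= 0, na.rm = TRUE))
    abort("threshold limits must be positive")
  # analyte names in threshold tables match internal record columns; the
  # internal unit convention makes units commensurate by construction.
  expected_unit <- c(cd = "mg/kg", cr = "mg/kg", cu = "mg/kg", ni = "mg/kg",
                     pb = "mg/kg", zn = "mg/kg", pah_total = "ug/kg",
                     pcb_total = "ug/kg", pcddf_teq = "ng/kg")
  rows <- list()
  for (i in seq_len(nrow(thresholds))) {
    an <- thresholds$analyte[i]
    if (!an %in% names(record)) next
    val <- record[[an]][1]
    if (is.na(val)) next
    if ("unit" %in% names(thresholds) && an %in% names(expected_unit) &&
        !is.na(thresholds$unit[i]) && thresholds$unit[i] != expected_unit[[an]])
      abort("unit mismatch for analyte '", an, "': threshold in ",
            thresholds$unit[i], ", record in ", expected_unit[[an]])
    lim <- thresholds$limit[i]
    rows[[length(rows) + 1L]] <- data.frame(
      analyte = an, measured = val, threshold = lim,
      regulation = thresholds$regulation[i],
      status = if (val > lim) "exceed" else "pass",
      margin_percent = margin_to_threshold(val, lim),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(analyte = character(), measured = numeric(),
               threshold = numeric(), regulation = character(),
               status = character(), margin_percent = numeric(),
               stringsAsFactors = FALSE)
  class(out) <- c("screen_report", class(out))
  out
}

#' Screen every amendment against every packaged regulation
#'
#' Convenience wrapper over [screen_amendment()]: one combined report with
#' `treatment_id` and `regulation` columns.
#'
#' @param records amendment table (several rows allowed).
#' @param thresholds full threshold table (several regulations allowed).
#' @return combined `screen_report` data.frame.
#' @export
screen_all <- function(records, thresholds) {
  parts <- list()
  for (i in seq_len(nrow(records))) {
    for (reg in unique(thresholds$regulation)) {
      rep1 <- screen_amendment(records[i, , drop = FALSE],
                               thresholds[thresholds$regulation == reg, ,
                                          drop = FALSE])
      if (nrow(rep1))
        parts[[length(parts) + 1L]] <-
          cbind(treatment_id = records$treatment_id[i], rep1)
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("screen_report", "data.frame")
  out
}
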