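## Amendment composition tables: schema, validation, readers/writers.
##
## Internal unit convention (one unit per quantity, everywhere in the
## package): concentrations in mg/kg dry amendment, CEC in mmol_c/kg,
## CaCO3 equivalency in % w/w, elemental inventories (H, C) as mass
## fractions, PAH/PCB totals in ug/kg, dioxin/furan TEQ in ng/kg, mass
## yield as a dry-mass fraction of feedstock in (0, 1]. Absent values are
## NA, never zero.

# field registry: internal column name, mandatory flag, and the accepted
# CSV column spellings with their to-internal conversion factors. The
# first spelling is canonical and is what write_amendments() emits.
.amendment_fields <- function() {
  f <- function(internal, mandatory, csv, factor) {
    list(internal = internal, mandatory = mandatory,
         csv = csv, factor = factor)
  }
  list(
    f("treatment_id", TRUE,  "treatment_id", NA),
    f("hht_celsius",  TRUE,  "hht_celsius", 1),
    f("available_n",  FALSE, c("available_n_mg_kg", "available_n_g_kg"), c(1, 1000)),
    f("p",            FALSE, c("p_mg_kg", "p_g_kg"), c(1, 1000)),
    f("k",            FALSE, c("k_mg_kg", "k_g_kg"), c(1, 1000)),
    f("ca",           FALSE, c("ca_mg_kg", "ca_g_kg"), c(1, 1000)),
    f("mg",           FALSE, c("mg_mg_kg", "mg_g_kg"), c(1, 1000)),
    f("s",            FALSE, c("s_mg_kg", "s_g_kg"), c(1, 1000)),
    f("micronutrients", FALSE, c("micronutrients_mg_kg", "micronutrients_g_kg"), c(1, 1000)),
    f("cec",          FALSE, "cec_mmolc_kg", 1),
    f("cec_cations",  FALSE, c("cec_cations_g_kg", "cec_cations_mg_kg"), c(1, 1e-3)),
    f("caco3_equiv",  FALSE, "caco3_equiv_pct", 1),
    f("h_total",      FALSE, "h_total_frac", 1),
    f("c_total",      FALSE, "c_total_frac", 1),
    f("c_inorg",      FALSE, "c_inorg_frac", 1),
    f("bc100",        FALSE, "bc100_pct", 1),
    f("mass_yield",   FALSE, "mass_yield", 1),
    f("cd",           FALSE, "cd_mg_kg", 1),
    f("cr",           FALSE, "cr_mg_kg", 1),
    f("cu",           FALSE, "cu_mg_kg", 1),
    f("ni",           FALSE, "ni_mg_kg", 1),
    f("pb",           FALSE, "pb_mg_kg", 1),
    f("zn",           FALSE, "zn_mg_kg", 1),
    f("pah_total",    FALSE, "pah_total_ug_kg", 1),
    f("pcb_total",    FALSE, "pcb_total_ug_kg", 1),
    f("pcddf_teq",    FALSE, "pcddf_teq_ng_kg", 1)
  )
}

.amendment_colnames <- function() {
  vapply(.amendment_fields(), `[[`, "", "internal")
}

#' Validate an amendment composition table
#'
#' Checks the structural invariants of an amendment table in internal
#' units: all concentrations nonnegative, mass fractions in \[0, 1\],
#' inorganic carbon not exceeding total carbon, mass yield in (0, 1\], and
#' BC+100 in \[0, 100\]. Absent values (NA) are permitted everywhere except
#' `treatment_id` and `hht_celsius`.
#'
#' @param x data.frame with columns named per the internal convention (see
#'   [read_amendments()]).
#' @return `x`, invisibly, if valid; otherwise an error naming the
#'   offending row and field.
#' @export
validate_amendments <- function(x) {
  if (!is.data.frame(x) || nrow(x) == 0)
    abort("amendment table must be a data.frame with at least one row")
  for (m in c("treatment_id", "hht_celsius")) {
    if (!m %in% names(x)) abort("missing mandatory column: ", m)
    if (anyNA(x[[m]])) abort("mandatory column '", m, "' contains NA")
  }
  if (anyDuplicated(x$treatment_id))
    abort("duplicate treatment_id values")
  num <- setdiff(intersect(names(x), .amendment_colnames()), "treatment_id")
  for (cn in num) {
    v <- x[[cn]]
    bad <- which(!is.na(v) & v < 0 & cn != "hht_celsius")
    if (length(bad))
      abort("negative value in column '", cn, "', row ", bad[1],
            " (treatment ", x$treatment_id[bad[1]], ")")
  }
  frac <- c("h_total", "c_total", "c_inorg", "mass_yield")
  for (cn in intersect(frac, names(x))) {
    v <- x[[cn]]
    bad <- which(!is.na(v) & v > 1)
    if (length(bad))
      abort("'", cn, "' must be a mass fraction in [0, 1]: row ", bad[1])
  }
  if ("mass_yield" %in% names(x)) {
    bad <- which(!is.na(x$mass_yield) & x$mass_yield <= 0)
    if (length(bad)) abort("mass_yield must lie in (0, 1]: row ", bad[1])
  }
  if (all(c("c_total", "c_inorg") %in% names(x))) {
    both <- !is.na(x$c_total) & !is.na(x$c_inorg)
    bad <- which(both & x$c_inorg > x$c_total + 1e-12)
    if (length(bad))
      abort("c_inorg exceeds c_total in row ", bad[1],
            " (treatment ", x$treatment_id[bad[1]], ")")
  }
  if ("bc100" %in% names(x)) {
    bad <- which(!is.na(x$bc100) & (x$bc100 < 0 | x$bc100 > 100))
    if (length(bad)) abort("bc100 must lie in [0, 100]: row ", bad[1])
  }
  invisible(x)
}

#' Read an amendment composition table from CSV
#'
#' Reads a comma-separated, UTF-8, dot-decimal table with one header row.
#' Column names carry their unit (e.g. `p_g_kg` or `p_mg_kg`); values are
#' converted to the internal convention (mg/kg for concentrations,
#' mmol_c/kg for CEC, mass fractions for H/C) on read. Unknown columns are
#' rejected, missing mandatory columns are fatal, and blank cells become
#' NA absent-value markers.
#'
#' @param path path to a CSV file following the documented schema (see
#'   `system.file("extdata", "schema.md", package = "hswvalue")`).
#' @return data.frame in internal units, one row per treatment, validated
#'   by [validate_amendments()].
#' @export
read_amendments <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         encoding = "UTF-8", check.names = FALSE)
  fields <- .amendment_fields()
  known <- unlist(lapply(fields, `[[`, "csv"))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort("unknown column(s) in ", path, ": ",
          paste(unknown, collapse = ", "))
  out <- list()
  for (fl in fields) {
    hit <- which(fl$csv %in% names(raw))
    if (length(hit) > 1)
      abort("column '", fl$internal, "' given in more than one unit in ", path)
    if (length(hit) == 1) {
      v <- raw[[fl$csv[hit]]]
      if (fl$internal != "treatment_id") {
        if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
        v <- v * fl$factor[hit]
      } else {
        v <- as.character(v)
      }
      out[[fl$internal]] <- v
    } else if (fl$mandatory) {
      abort("missing mandatory column: ", fl$csv[1], " in ", path)
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  validate_amendments(out)
  out
}

#' Write an amendment composition table to CSV
#'
#' Emits the canonical schema (internal units, unit-suffixed column names)
#' at full double precision so that
#' `read_amendments(write_amendments(x, f))` reproduces `x` exactly.
#'
#' @param x validated amendment table in internal units.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_amendments <- function(x, path) {
  if (nrow(x) > 0) validate_amendments(x)
  fields <- .amendment_fields()
  cols <- list()
  for (fl in fields) {
    if (fl$internal %in% names(x)) {
      v <- x[[fl$internal]]
      if (fl$internal == "treatment_id") {
        cols[[fl$csv[1]]] <- v
      } else {
        # canonical spelling has factor 1: write internal value verbatim
        cols[[fl$csv[1]]] <- vapply(v, function(z) {
          if (is.na(z)) "" else sprintf("%.17g", z)
        }, "")
      }
    }
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) abort("cannot open for writing: ", path))
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
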