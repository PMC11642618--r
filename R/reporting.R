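# Machine-readable reporting standard: manifests mirroring the minimal
# acquisition (2D X-ray / 3D uCT) and analysis reporting parameter tables,
# a compliance checker, and unit normalization. All rows are treated as
# required for a passing report; `lenient = TRUE` demotes the strain / sex /
# controls rows to warnings.

report_schema <- function(type = c("acquisition", "analysis")) {
  type <- match.arg(type)
  path <- system.file("extdata", "schemas", paste0(type, "_schema.json"),
                      package = "finmorph")
  if (!nzchar(path))
    stop("schema file not found; is the package installed?", call. = FALSE)
  jsonlite::read_json(path)
}

field_ok <- function(fd, value) {
  if (is.null(value) || (is.atomic(value) && !length(value))) return(FALSE)
  switch(fd$type,
    text = is.character(value) && length(value) == 1L && nzchar(trimws(value)),
    boolean = is.logical(value) && length(value) == 1L && !is.na(value),
    number = is.numeric(value) && length(value) == 1L && is.finite(value),
    integer = is.numeric(value) && length(value) == 1L && is.finite(value) &&
      value == round(value),
    enum = is.character(value) && length(value) == 1L &&
      value %in% unlist(fd$values),
    subset = is.character(unlist(value)) &&
      all(unlist(value) %in% unlist(fd$values)),
    threshold = is.list(value) &&
      (("global_mgHA_cm3" %in% names(value) &&
          is.numeric(value$global_mgHA_cm3)) ||
         ("algorithm" %in% names(value) &&
            is.character(value$algorithm) && nzchar(value$algorithm))),
    FALSE)
}

condition_met <- function(cond, manifest) {
  if (is.null(cond)) return(TRUE)
  v <- manifest[[cond$field]]
  if (!is.null(cond$equals)) return(isTRUE(v == cond$equals))
  if (!is.null(cond$contains)) return(cond$contains %in% unlist(v))
  TRUE
}

#' Check a reporting manifest for completeness
#'
#' Validates a parsed manifest (a named list, typically from JSON) against
#' the reporting schema: every required field must be present and well
#' typed. Conditional rows apply only when triggered (e.g. the filter type
#' only when filtering was used; the BMD ROI description only when BMD is
#' among the examined density measures). Acquisition manifests declare
#' their `modality` (`"xray2d"` or `"uct3d"`), which selects the
#' modality-specific detector rows.
#'
#' @param manifest named list, or a JSON file path.
#' @param type `"auto"` (acquisition iff a `modality` field is present),
#'   `"acquisition"` or `"analysis"`.
#' @param lenient demote the strain/sex/controls rows to warnings.
#' @return A `compliance_report` list: `type`, `violations` (data.frame
#'   field/row/problem), `warnings`, `n_required`, `n_present`,
#'   `completeness`, `passed`.
#' @export
check_manifest <- function(manifest, type = c("auto", "acquisition", "analysis"),
                           lenient = FALSE) {
  type <- match.arg(type)
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- tryCatch(jsonlite::read_json(manifest, simplifyVector = FALSE),
                         error = function(e)
                           stop("malformed JSON manifest: ", conditionMessage(e),
                                call. = FALSE))
  }
  if (!is.list(manifest)) stop("manifest must be a named list", call. = FALSE)
  if (type == "auto")
    type <- if ("modality" %in% names(manifest)) "acquisition" else "analysis"
  schema <- report_schema(type)
  modality <- if (type == "acquisition") manifest$modality else NULL
  viol <- list(); warns <- list()
  n_required <- 0L; n_present <- 0L
  for (fd in schema$fields) {
    if (type == "acquisition" && fd$modality != "both" &&
        !is.null(modality) && fd$modality != modality) next
    if (!condition_met(fd$required_if, manifest)) next
    is_lenient_row <- lenient && isTRUE(fd$lenient)
    if (!is_lenient_row) n_required <- n_required + 1L
    ok <- field_ok(fd, manifest[[fd$field]])
    if (ok && !is_lenient_row) n_present <- n_present + 1L
    if (!ok) {
      problem <- if (is.null(manifest[[fd$field]])) "missing" else "ill-typed"
      entry <- data.frame(field = fd$field, row = fd$row, problem = problem,
                          stringsAsFactors = FALSE)
      if (is_lenient_row) warns[[length(warns) + 1L]] <- entry
      else viol[[length(viol) + 1L]] <- entry
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(field = character(0), row = character(0),
               problem = character(0), stringsAsFactors = FALSE)
  warnings_df <- if (length(warns)) do.call(rbind, warns) else
    data.frame(field = character(0), row = character(0),
               problem = character(0), stringsAsFactors = FALSE)
  structure(list(type = type, violations = violations,
                 warnings = warnings_df, n_required = n_required,
                 n_present = n_present,
                 completeness = n_present / n_required,
                 passed = nrow(violations) == 0L),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report:%s> %s (completeness %.2f, %d/%d)\n",
              x$type, if (x$passed) "PASS" else "INCOMPLETE",
              x$completeness, x$n_present, x$n_required))
  if (nrow(x$violations))
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  %s [%s]: %s\n", x$violations$problem[i],
                  x$violations$field[i], x$violations$row[i]))
  if (nrow(x$warnings))
    for (i in seq_len(nrow(x$warnings)))
      cat(sprintf("  warning [%s]: %s\n", x$warnings$field[i],
                  x$warnings$row[i]))
  invisible(x)
}

UNIT_TABLES <- list(
  kV = c(kv = 1, v = 1e-3, kvp = 1),
  uA = c(ua = 1, ma = 1e3, a = 1e6),
  ms = c(ms = 1, s = 1e3),
  s = c(s = 1, ms = 1e-3),
  um = c(um = 1, mm = 1e3, cm = 1e4, m = 1e6),
  mm = c(mm = 1, cm = 10, um = 1e-3, m = 1e3),
  cm = c(cm = 1, mm = 0.1, m = 100),
  "mgHA/cm3" = c("mgha/cm3" = 1, "mg/cm3" = 1, "mg.cm-3" = 1,
                 "gha/cm3" = 1e3, "g/cm3" = 1e3, "g.cm-3" = 1e3)
)

FIELD_UNITS <- c(tube_potential_kv = "kV", tube_current_ua = "uA",
                 integration_ms = "ms", exposure_s = "s",
                 pixel_or_voxel_size_um = "um", voxel_size_um = "um",
                 standard_length_mm = "mm", source_distance_cm = "cm",
                 threshold_mgHA_cm3 = "mgHA/cm3", density_mgHA_cm3 = "mgHA/cm3")

clean_unit <- function(u) {
  u <- tolower(trimws(u))
  u <- gsub("µ|μ", "u", u)  # micro signs -> u
  u <- gsub("\\s+", "", u)
  u <- gsub("\\^", "", u)             # g.cm^-3 -> g.cm-3
  u
}

#' Normalize a reported value to its field's canonical unit
#'
#' Parses strings like `"45 kV"`, `"0.2 mA"`, `"10 s"`, `"0.75 g.cm^-3"`
#' and converts to the canonical reporting unit of the field (kV, uA, ms,
#' s, um, mm, cm, or mg HA/cm3). Unknown or dimensionally wrong units are
#' errors.
#'
#' @param field manifest field name (see `names(finmorph:::FIELD_UNITS)`).
#' @param value_string `"<number> <unit>"`, or a bare number already in the
#'   canonical unit.
#' @return Numeric value in the canonical unit, with attribute `unit`.
#' @export
normalize_units <- function(field, value_string) {
  if (!field %in% names(FIELD_UNITS))
    stop(sprintf("unknown field '%s'", field), call. = FALSE)
  canon <- FIELD_UNITS[[field]]
  if (is.numeric(value_string))
    return(structure(as.numeric(value_string), unit = canon))
  m <- regmatches(value_string,
                  regexec("^\\s*([-+0-9.eE]+)\\s*(.*)$", value_string))[[1]]
  if (length(m) != 3 || !nzchar(m[2]))
    stop(sprintf("cannot parse value '%s'", value_string), call. = FALSE)
  num <- as.numeric(m[2])
  if (is.na(num)) stop(sprintf("cannot parse number in '%s'", value_string),
                       call. = FALSE)
  unit <- clean_unit(m[3])
  if (!nzchar(unit)) return(structure(num, unit = canon))
  tab <- UNIT_TABLES[[canon]]
  if (!unit %in% names(tab))
    stop(sprintf("unit '%s' not valid for field '%s' (canonical %s)",
                 m[3], field, canon), call. = FALSE)
  structure(num * unname(tab[[unit]]), unit = canon)
}

#' Format a canonical value back to a reporting string
#'
#' Inverse of [normalize_units()] for round-tripping: the canonical value
#' with its canonical unit symbol.
#'
#' @param field manifest field name.
#' @param value numeric value in the canonical unit.
#' @return String `"<value> <unit>"`.
#' @export
format_units <- function(field, value) {
  if (!field %in% names(FIELD_UNITS))
    stop(sprintf("unknown field '%s'", field), call. = FALSE)
  canon <- FIELD_UNITS[[field]]
  sprintf("%.15g %s", value, canon)
}

#' A complete example uCT acquisition manifest
#'
#' A golden manifest that passes [check_manifest()] with completeness 1;
#' parameter values are typical for adult zebrafish scanning.
#'
#' @return Named list.
#' @export
example_acquisition_manifest <- function() {
  list(modality = "uct3d",
       sample_preparation = "fixed in 4% PFA, stored in 70% ethanol",
       in_vivo = FALSE, whole_animal = TRUE, medium = "air",
       multiplexed = TRUE, n_multiplexed = 4L,
       tube_potential_kv = 55, tube_current_ua = 145,
       filter_used = TRUE, filter_type = "0.5 mm aluminum",
       integration_ms = 500, frames_averaged = 3L,
       projections_per_revolution = 1000L,
       pixel_or_voxel_size_um = 10.5,
       calibration_method = "two CaHA phantoms, 250 and 750 mg HA/cm3",
       machine_make_model = "example scanner")
}

#' A complete example analysis manifest
#'
#' @return Named list passing [check_manifest()] with completeness 1.
#' @export
example_analysis_manifest <- function() {
  list(density_measures = list("BMD", "TMD"),
       bmd_roi_description = "box ROI spanning centrum v16, endplate to endplate",
       morphometry_mode = list("landmark", "segmentation"),
       landmark_details = "manual placement on MIPs; endplate centers and spine tips",
       segmentation_details = "global threshold; thickness by maximal inscribed spheres",
       software_versions = "finmorph 0.1.0",
       roi_method = "geometric",
       roi_description = "cylinder aligned to the centrum axis, radius CH/2",
       threshold = list(global_mgHA_cm3 = 300),
       age = "6 months", standard_length_mm = 30,
       strain = "AB wild-type", sex = "mixed",
       controls = "clutch mate controls",
       normalization = "power-law SL normalization, alpha fitted",
       image_presentation = "max intensity projection, anterior left, dorsal up")
}
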