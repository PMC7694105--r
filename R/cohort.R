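# Cohort table schema, record validation and simple indices.
#
# A cohort is a plain data frame with one row per athlete. Stature is stored
# in cm everywhere; any operation needing metres converts internally.

#' Cohort CSV schema
#'
#' Column names of the standard per-athlete cohort table: identifiers, the ten
#' Heath-Carter body dimensions, 50 kHz whole-body impedance, and playing
#' position. All equations in the package are male-specific; an optional `sex`
#' column is accepted on ingest but any value other than `"male"` is refused.
#'
#' @return character vector of required column names.
#' @export
cohort_columns <- function() {
  c("athlete_id", "age", "weight_kg", "stature_cm",
    "triceps_mm", "subscapular_mm", "supraspinal_mm", "medial_calf_mm",
    "arm_girth_cm", "calf_girth_cm", "humerus_cm", "femur_cm",
    "resistance_ohm", "reactance_ohm", "position")
}

#' Playing positions recognised in the cohort schema
#' @return character vector of the four position labels.
#' @export
position_levels <- function() {
  c("goalkeeper", "defender", "midfielder", "forward")
}

#' Body mass index
#'
#' Ratio of body mass to stature squared, kg/m^2. Stature is taken in cm (the
#' package-wide convention) and converted to metres internally.
#'
#' @param weight_kg body mass, kg.
#' @param stature_cm stature, cm.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' body_mass_index(79.5, 183.8)  # 23.5 to 1 d.p.
body_mass_index <- function(weight_kg, stature_cm) {
  check_positive(weight_kg, "weight_kg")
  check_positive(stature_cm, "stature_cm")
  weight_kg / (stature_cm / 100)^2
}

# per-field physiological invariants; each entry: function(row) -> TRUE/FALSE,
# plus a human-readable rule. Checks are total: NA/non-finite fails the rule
# rather than erroring.
cohort_rules <- function() {
  ok <- function(x) is.finite(x)
  sf <- function(x) ok(x) & x > 0 & x < 60
  list(
    weight_kg      = list(rule = "weight > 0",            fun = function(r) ok(r$weight_kg) & r$weight_kg > 0),
    stature_cm     = list(rule = "100 <= stature <= 230", fun = function(r) ok(r$stature_cm) & r$stature_cm >= 100 & r$stature_cm <= 230),
    triceps_mm     = list(rule = "0 < skinfold < 60",     fun = function(r) sf(r$triceps_mm)),
    subscapular_mm = list(rule = "0 < skinfold < 60",     fun = function(r) sf(r$subscapular_mm)),
    supraspinal_mm = list(rule = "0 < skinfold < 60",     fun = function(r) sf(r$supraspinal_mm)),
    medial_calf_mm = list(rule = "0 < skinfold < 60",     fun = function(r) sf(r$medial_calf_mm)),
    arm_girth_cm   = list(rule = "girth > 0",             fun = function(r) ok(r$arm_girth_cm) & r$arm_girth_cm > 0),
    calf_girth_cm  = list(rule = "girth > 0",             fun = function(r) ok(r$calf_girth_cm) & r$calf_girth_cm > 0),
    humerus_cm     = list(rule = "breadth > 0",           fun = function(r) ok(r$humerus_cm) & r$humerus_cm > 0),
    femur_cm       = list(rule = "breadth > 0",           fun = function(r) ok(r$femur_cm) & r$femur_cm > 0),
    resistance_ohm = list(rule = "R > 0",                 fun = function(r) ok(r$resistance_ohm) & r$resistance_ohm > 0),
    reactance_ohm  = list(rule = "Xc >= 0",               fun = function(r) ok(r$reactance_ohm) & r$reactance_ohm >= 0),
    xc_lt_r        = list(rule = "Xc < R",                fun = function(r) {
      both <- ok(r$reactance_ohm) & ok(r$resistance_ohm)
      # only meaningful when both present; absent halves are caught above
      !both | r$reactance_ohm < r$resistance_ohm
    })
  )
}

#' Validate a cohort table against the physiological invariants
#'
#' Checks every row against the record invariants (positive weight, stature in
#' 100-230 cm, skinfolds in (0, 60) mm, positive girths and breadths, R > 0,
#' 0 <= Xc < R), uniqueness of `athlete_id`, allowed `position` labels, and
#' the male-only restriction when a `sex` column is present. Violations are
#' returned as data, never raised: the function is total on finite and
#' non-finite numeric input alike.
#'
#' @param cohort cohort data frame (see [cohort_columns()]); columns that are
#'   absent are skipped rather than flagged (use [read_cohort_csv()] for
#'   strict schema checking).
#' @return data frame with one row per violation: `row`, `athlete_id`,
#'   `field`, `value`, `rule`. Zero rows when the cohort is fully valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  viol <- list()
  add <- function(rows, field, value, rule) {
    if (!length(rows)) return()
    ids <- if ("athlete_id" %in% names(cohort)) {
      as.character(cohort$athlete_id[rows])
    } else NA_character_
    viol[[length(viol) + 1L]] <<- data.frame(
      row = rows, athlete_id = ids, field = field,
      value = as.character(value), rule = rule)
  }
  n <- nrow(cohort)
  if (n) {
    for (field in names(cohort_rules())) {
      r <- cohort_rules()[[field]]
      cols <- if (field == "xc_lt_r") c("resistance_ohm", "reactance_ohm") else field
      if (!all(cols %in% names(cohort))) next
      pass <- r$fun(cohort)
      pass[is.na(pass)] <- FALSE
      bad <- which(!pass)
      val <- if (field == "xc_lt_r") {
        paste0("Xc=", cohort$reactance_ohm[bad], ", R=", cohort$resistance_ohm[bad])
      } else cohort[[field]][bad]
      add(bad, if (field == "xc_lt_r") "reactance_ohm" else field, val, r$rule)
    }
    if ("athlete_id" %in% names(cohort)) {
      dup <- which(duplicated(cohort$athlete_id))
      add(dup, "athlete_id", cohort$athlete_id[dup], "athlete_id unique")
    }
    if ("position" %in% names(cohort)) {
      bad <- which(!(is.na(cohort$position) |
                       cohort$position %in% position_levels()))
      add(bad, "position", cohort$position[bad],
          paste("position in {", paste(position_levels(), collapse = ", "), "}"))
    }
    if ("sex" %in% names(cohort)) {
      bad <- which(!is.na(cohort$sex) & cohort$sex != "male")
      add(bad, "sex", cohort$sex[bad],
          "sex must be 'male': all bundled equations are male-specific")
    }
  }
  if (!length(viol)) {
    return(data.frame(row = integer(), athlete_id = character(),
                      field = character(), value = character(),
                      rule = character()))
  }
  out <- do.call(rbind, viol)
  out[order(out$row), , drop = FALSE]
}

#' Read a cohort CSV
#'
#' Strict reader for the standard cohort schema (comma delimiter, dot decimal,
#' UTF-8; see [cohort_columns()]). The header must contain exactly the schema
#' columns (an optional `sex` column is also accepted); missing or unknown
#' columns raise a schema error naming them, and a semicolon-delimited file is
#' rejected with an actionable message. Rows violating the physiological
#' invariants are dropped with a warning; the violation table is attached as
#' attribute `"violations"`.
#'
#' @param path file path.
#' @return validated cohort data frame with attribute `violations`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 10L, encoding = "UTF-8")
  header <- header[!startsWith(header, "#")][1]
  if (is.na(header)) stop("empty file: no header line found", call. = FALSE)
  if (!grepl(",", header, fixed = TRUE) && grepl(";", header, fixed = TRUE)) {
    stop("file appears to be semicolon-delimited; the cohort schema requires ",
         "comma delimiter and dot decimal (export with sep=',', dec='.')",
         call. = FALSE)
  }
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                            fileEncoding = "UTF-8")
  required <- cohort_columns()
  missing <- setdiff(required, names(cohort))
  unknown <- setdiff(names(cohort), c(required, "sex"))
  if (length(missing) || length(unknown)) {
    stop(sprintf("cohort schema error: missing columns [%s]; unknown columns [%s]",
                 paste(missing, collapse = ", "),
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  num_cols <- setdiff(required, c("athlete_id", "position"))
  for (cl in num_cols) {
    if (!is.numeric(cohort[[cl]])) {
      suppressWarnings(cohort[[cl]] <- as.numeric(cohort[[cl]]))
    }
  }
  incomplete <- which(apply(is.na(cohort[num_cols]), 1L, any))
  v <- validate_cohort(cohort)
  bad_rows <- sort(unique(c(v$row, incomplete)))
  if (length(bad_rows)) {
    warning(sprintf("%d row(s) dropped for invariant violations or missing fields (rows: %s)",
                    length(bad_rows), paste(bad_rows, collapse = ", ")),
            call. = FALSE)
    cohort <- cohort[-bad_rows, , drop = FALSE]
    rownames(cohort) <- NULL
  }
  attr(cohort, "violations") <- v
  cohort
}

#' Write a cohort CSV
#'
#' Writes the standard cohort table with an optional `#`-prefixed metadata
#' comment line (equation-set id, package version, seed) which
#' [read_cohort_csv()] skips on re-read.
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @param metadata optional named character vector written as a comment line.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, metadata = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(paste0("# ", paste(names(metadata), unname(metadata),
                                  sep = ": ", collapse = "; ")), con)
  }
  utils::write.csv(cohort, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
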