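## Typed CSV readers/writers and bundled study fixtures.
##
## Every tabular input is a plain comma-separated UTF-8 file with a mandatory
## header, "." decimal separator and ASCII minus signs (U+2212 from copied
## sources is normalized on read). Missing activity cells may be written as an
## empty cell or "---"; in memory they are NA, never 0.

.schemas <- list(
  quantum = list(
    required = c("compound", "phase", "e_total_au", "dipole_D",
                 "e_homo_au", "e_lumo_au"),
    optional = "suspect",
    numeric  = c("e_total_au", "dipole_D", "e_homo_au", "e_lumo_au")
  ),
  physchem = list(
    required = c("compound", "logp", "mw_da", "hbd", "hba", "n_rotb",
                 "psa_A2", "logd74"),
    optional = c("pol_A3", "mr_A3", "vol_A3", "sag_A2", "he_kcalmol"),
    numeric  = c("logp", "mw_da", "hbd", "hba", "n_rotb", "psa_A2", "logd74",
                 "pol_A3", "mr_A3", "vol_A3", "sag_A2", "he_kcalmol")
  ),
  sar = list(
    required = c("compound", "pol_A3", "mr_A3", "vol_A3", "sag_A2",
                 "he_kcalmol"),
    optional = character(),
    numeric  = c("pol_A3", "mr_A3", "vol_A3", "sag_A2", "he_kcalmol")
  ),
  activity = list(
    required = c("compound", "cell_line", "ic50_uM"),
    optional = character(),
    numeric  = "ic50_uM"
  ),
  docking = list(
    required = c("compound", "target", "dg_kcalmol", "ki_nM", "n_hbonds"),
    optional = character(),
    numeric  = c("dg_kcalmol", "ki_nM", "n_hbonds")
  ),
  bondlengths = list(
    required = c("parameter", "experimental"),
    optional = NULL,                      # any further columns = method columns
    numeric  = "experimental"
  )
)

.fixtures <- list(
  bondlengths_tu    = list(file = "bondlengths_tu.csv",    schema = "bondlengths"),
  energies_dipoles  = list(file = "energies_dipoles.csv",  schema = "quantum"),
  reactivity_inputs = list(file = "reactivity_inputs.csv", schema = "quantum"),
  physchem          = list(file = "physchem.csv",          schema = "physchem"),
  sar_properties    = list(file = "sar_properties.csv",    schema = "sar"),
  activities        = list(file = "activities.csv",        schema = "activity"),
  docking_alpha     = list(file = "docking_alpha.csv",     schema = "docking"),
  docking_beta      = list(file = "docking_beta.csv",      schema = "docking")
)

.normalize_cell <- function(x) {
  x <- gsub("\u2212", "-", x, fixed = TRUE)   # typeset minus -> ASCII
  x <- trimws(x)
  x[x == "" | x == "---"] <- NA_character_
  x
}

.as_numeric_col <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop_parse(sprintf(
      "non-numeric value '%s' in column '%s', row %d", x[bad[1]], col, bad[1]))
  }
  out
}

.validate_rows <- function(df, schema) {
  ok_compound <- function() {
    if (any(is.na(df$compound) | df$compound == ""))
      stop_validation("compound_id must be non-empty")
  }
  if (schema == "quantum") {
    ok_compound()
    bad <- setdiff(unique(df$phase), c("gas", "aqueous"))
    if (length(bad) > 0)
      stop_validation(sprintf("phase must be 'gas' or 'aqueous', got '%s'", bad[1]))
    both <- !is.na(df$e_homo_au) & !is.na(df$e_lumo_au)
    if (any(both & df$e_homo_au >= df$e_lumo_au))
      stop_validation("e_homo must be strictly below e_lumo")
  } else if (schema == "physchem") {
    ok_compound()
    for (col in c("hbd", "hba", "n_rotb")) {
      v <- df[[col]]
      if (any(is.na(v)) || !is_count(v))
        stop_validation(sprintf("%s must be a non-negative integer count", col))
    }
    if (any(is.na(df$mw_da) | df$mw_da <= 0))
      stop_validation("mw_da must be > 0")
    if (any(is.na(df$psa_A2) | df$psa_A2 < 0))
      stop_validation("psa_A2 must be >= 0")
  } else if (schema == "sar") {
    ok_compound()
  } else if (schema == "activity") {
    ok_compound()
    if (any(is.na(df$cell_line) | df$cell_line == ""))
      stop_validation("cell_line must be non-empty")
    present <- !is.na(df$ic50_uM)
    if (any(present & df$ic50_uM <= 0))
      stop_validation("ic50_uM must be > 0 when present")
  } else if (schema == "docking") {
    ok_compound()
    bad <- setdiff(unique(df$target), c("topo2a", "topo2b"))
    if (length(bad) > 0)
      stop_validation(sprintf("target must be 'topo2a' or 'topo2b', got '%s'", bad[1]))
    if (any(is.na(df$dg_kcalmol) | df$dg_kcalmol >= 0))
      stop_validation("binding energy dg_kcalmol must be < 0")
    if (any(is.na(df$ki_nM) | df$ki_nM <= 0))
      stop_validation("ki_nM must be > 0")
    if (any(is.na(df$n_hbonds)) || !is_count(df$n_hbonds))
      stop_validation("n_hbonds must be a non-negative integer count")
  } else if (schema == "bondlengths") {
    num <- df[setdiff(names(df), "parameter")]
    if (any(vapply(num, function(v) any(is.na(v) | v <= 0), logical(1))))
      stop_validation("all bond lengths must be present and > 0")
  }
  invisible(df)
}

#' Load a typed table from CSV
#'
#' Reads one of the package's tabular input kinds, validates its header against
#' the documented schema, coerces numeric columns (reporting the offending
#' row/column on failure) and checks record invariants. Empty cells and
#' `"---"` become `NA`; row order is preserved.
#'
#' Schemas (exact headers, optional columns in brackets):
#' \describe{
#'   \item{quantum}{`compound,phase,e_total_au,dipole_D,e_homo_au,e_lumo_au[,suspect]`
#'     -- per-compound, per-phase total electronic energy (hartree), dipole
#'     moment (debye) and frontier-orbital energies (hartree). Any of the four
#'     numeric columns may be empty; `e_homo_au < e_lumo_au` is enforced when
#'     both are present. Rows flagged `suspect` are dropped unless
#'     `skip_suspect = FALSE`.}
#'   \item{physchem}{`compound,logp,mw_da,hbd,hba,n_rotb,psa_A2,logd74[,pol_A3,mr_A3,vol_A3,sag_A2,he_kcalmol]`}
#'   \item{sar}{`compound,pol_A3,mr_A3,vol_A3,sag_A2,he_kcalmol`}
#'   \item{activity}{`compound,cell_line,ic50_uM` -- missing IC50 written as an
#'     empty cell or `"---"`.}
#'   \item{docking}{`compound,target,dg_kcalmol,ki_nM,n_hbonds` with target one
#'     of `topo2a`/`topo2b`.}
#'   \item{bondlengths}{`parameter,experimental,<one column per method>`.}
#' }
#'
#' @param path path to a CSV file.
#' @param schema one of `"quantum"`, `"physchem"`, `"sar"`, `"activity"`,
#'   `"docking"`, `"bondlengths"`.
#' @param skip_suspect drop rows whose optional `suspect` column is TRUE
#'   (quantum schema only). Default TRUE.
#' @return a validated `data.frame` with a `"deskqsar_schema"` attribute.
#' @export
#' @examples
#' acts <- load_table(fixture_path("activities"), "activity")
#' sum(!is.na(acts$ic50_uM))
load_table <- function(path, schema, skip_suspect = TRUE) {
  schema <- match.arg(schema, names(.schemas))
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  spec <- .schemas[[schema]]

  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(spec$required, names(raw))
  if (length(missing_cols) > 0) {
    stop_schema(sprintf("header for schema '%s' is missing column(s): %s",
                        schema, paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(spec$optional)) {
    extra <- setdiff(names(raw), c(spec$required, spec$optional))
    if (length(extra) > 0) {
      stop_schema(sprintf("unknown column(s) for schema '%s': %s",
                          schema, paste(extra, collapse = ", ")))
    }
  }

  df <- as.data.frame(lapply(raw, .normalize_cell),
                      optional = TRUE, stringsAsFactors = FALSE)
  names(df) <- names(raw)

  if (schema == "bondlengths") {
    method_cols <- setdiff(names(df), c("parameter"))
    for (col in method_cols) df[[col]] <- .as_numeric_col(df[[col]], col)
  } else {
    for (col in intersect(spec$numeric, names(df))) {
      df[[col]] <- .as_numeric_col(df[[col]], col)
    }
  }
  if (schema == "quantum" && "suspect" %in% names(df)) {
    df$suspect <- toupper(df$suspect) %in% c("TRUE", "T", "1", "YES")
    if (skip_suspect) {
      df <- df[!df$suspect, , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  if (nrow(df) > 0) .validate_rows(df, schema)
  attr(df, "deskqsar_schema") <- schema
  df
}

#' Path to a bundled fixture file
#'
#' @param name fixture name; see [bundled_fixture()].
#' @return absolute path to the installed CSV file.
#' @export
fixture_path <- function(name) {
  if (!name %in% names(.fixtures)) {
    stop_lookup(sprintf("unknown fixture '%s'; valid names: %s",
                        name, paste(names(.fixtures), collapse = ", ")))
  }
  system.file("extdata", .fixtures[[name]]$file,
              package = "deskqsar", mustWork = TRUE)
}

#' Load a bundled study table
#'
#' The package ships cell-for-cell transcriptions of the study's printed data
#' tables: the thiouracil bond-length benchmark, total energies and dipoles,
#' frontier-orbital energies, physicochemical/ADME descriptors, SAR properties,
#' antiproliferative IC50 values, and the two topoisomerase docking tables.
#'
#' The frontier-orbital table contains one row flagged `suspect`: the source
#' prints two aqueous-phase rows for compound 9H, the first a verbatim
#' duplicate of the 7H aqueous row, so the 9H gas-phase values are not
#' recoverable. Suspect rows are dropped by default.
#'
#' @param name one of `"bondlengths_tu"`, `"energies_dipoles"`,
#'   `"reactivity_inputs"`, `"physchem"`, `"sar_properties"`, `"activities"`,
#'   `"docking_alpha"`, `"docking_beta"`.
#' @param skip_suspect drop suspect-flagged rows (default TRUE).
#' @return a validated `data.frame`; see [load_table()] for schemas.
#' @export
#' @examples
#' bundled_fixture("docking_beta")
bundled_fixture <- function(name, skip_suspect = TRUE) {
  path <- fixture_path(name)
  load_table(path, .fixtures[[name]]$schema, skip_suspect = skip_suspect)
}

#' Write a result table to CSV or JSON
#'
#' CSV output round-trips: loading a written table with the same schema
#' reproduces it field for field (missing values become empty cells). JSON
#' output is an array of one object per row with field names as keys.
#'
#' @param x a data.frame (typically from [load_table()] or a report builder).
#' @param path destination file.
#' @param format `"csv"` or `"json"`.
#' @return `invisible(path)`.
#' @export
write_report <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(x)) stop_validation("x must be a data.frame")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(sprintf("directory does not exist: %s", dir))
  if (format == "csv") {
    ok <- try(utils::write.csv(x, path, row.names = FALSE, na = "",
                               fileEncoding = "UTF-8"), silent = TRUE)
    if (inherits(ok, "try-error")) stop_io(sprintf("cannot write %s", path))
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' MD5 digests of the bundled fixtures
#'
#' Used by the test suite to guard against transcription drift.
#'
#' @return named character vector of MD5 hex digests, one per fixture.
#' @export
fixture_checksums <- function() {
  vapply(names(.fixtures), function(nm) {
    unname(tools::md5sum(fixture_path(nm)))
  }, character(1))
}
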