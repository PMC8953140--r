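#' Claims-table model: domain containers, code sets, readers and writers
#'
#' The pipeline consumes three delimited tables mirroring a national
#' sample-cohort claims layout:
#'
#' * qualification: `person_id, sex, year, age_group, income_rank` — one row
#'   per person-year; `age_group` is the 5-year band index (0 = age 0,
#'   1 = 1-4, 2 = 5-9, ..., 18 = 85+); `income_rank` is 0-10
#'   (0 = medical aid, 1-10 = income deciles).
#' * statement: `person_id, claim_no, visit_date, principal_dx, additional_dx`.
#' * disease: `claim_no, visit_date, dx` — extra diagnoses attached to a claim.
#'
#' Reading fans the statement's principal and additional diagnoses and the
#' disease-table rows out into one claim stream (one row per non-empty
#' diagnosis), distinguishable only by a `source` column.
#'
#' @name claims_model
NULL

#' Default diagnosis code sets
#'
#' Delivery-mode, abortion and stillbirth sets are fixed by the study design;
#' the pregnancy, jaundice, preterm and multiple-gestation sets are
#' dictionary-dependent and configurable (see [load_code_config()]). Prefixes
#' match on dot-normalized code strings, so `"O84.2"` also covers `"O842"`.
#'
#' @return A named list of character vectors of code prefixes, class
#'   `code_sets`.
#' @export
default_code_sets <- function() {
  structure(list(
    pregnancy          = c("Z32", "Z33", "Z34", "Z35", "Z36"),
    delivery_vaginal   = c("O80", "O81", "O83", "O84.0", "O84.1"),
    delivery_cesarean  = c("O82", "O84.2"),
    jaundice           = c("P58", "P59"),
    preterm            = c("O60"),
    multiple_gestation = c("O30", "O31"),
    abortion           = sprintf("O%02d", 0:8),
    stillbirth         = c("O36.4", "Z37.1", "Z37.4", "Z37.7"),
    # ANC-context codes never tabulated as exposures in the antenatal study:
    # the whole pregnancy/childbirth/puerperium chapter plus Z32-Z39
    pregnancy_related_exclusion = c("O", sprintf("Z3%d", 2:9))
  ), class = "code_sets")
}

validate_code_sets <- function(cs) {
  required <- names(default_code_sets())
  missing <- setdiff(required, names(cs))
  if (length(missing)) stop("code_sets missing: ", paste(missing, collapse = ", "))
  if (any(!vapply(cs[required], length, 0L) > 0))
    stop("every code set must be non-empty")
  overlap <- intersect(strip_dot(cs$delivery_cesarean),
                       strip_dot(cs$delivery_vaginal))
  if (length(overlap))
    stop("cesarean and vaginal delivery sets overlap: ",
         paste(overlap, collapse = ", "))
  structure(cs[required], class = "code_sets")
}

#' Default analysis windows (days)
#'
#' Week-based rules convert at 7 days/week and years at 365 days:
#' 4 wk = 28 d (delivery-adjacent flags, minimum delivery-to-next-pregnancy
#' gap), 24 wk = 168 d (minimum inter-delivery gap), 44 wk = 308 d (maximum
#' pregnancy-diagnosis-to-delivery span), 1 yr = 365 d (pre-conception
#' window).
#' @export
default_windows <- function() {
  list(flag_days = 28L, min_delivery_gap = 168L, max_gestation = 308L,
       preconception_days = 365L)
}

default_dialect <- function() {
  list(delim = "\t", date_format = "%Y-%m-%d")
}

#' Load code-set / window / dialect configuration from YAML
#'
#' Recognized top-level sections: `code_sets`, `windows`, `dialect`; any
#' omitted entry falls back to its default. Overlapping cesarean/vaginal
#' delivery sets are an error.
#'
#' @param path path to a YAML file.
#' @return list with elements `code_sets` (class `code_sets`), `windows`,
#'   `dialect`.
#' @export
load_code_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cs <- utils::modifyList(unclass(default_code_sets()),
                          lapply(cfg$code_sets %||% list(), as.character))
  list(code_sets = validate_code_sets(cs),
       windows = utils::modifyList(default_windows(), cfg$windows %||% list()),
       dialect = utils::modifyList(default_dialect(), cfg$dialect %||% list()))
}

#' Truncate a diagnosis code to its 3-character category
#'
#' @param code character vector of diagnosis codes.
#' @return the first three characters, uppercased. Codes shorter than 3
#'   characters (after dropping a dot in position 4, which cannot affect the
#'   first three) are an error.
#' @examples truncate_code(c("K29.1", "O840", "a53")) # "K29" "O84" "A53"
#' @export
truncate_code <- function(code) {
  code <- trimws(code)
  if (any(nchar(strip_dot(code)) < 3L))
    stop("diagnosis code shorter than 3 characters: ",
         paste(code[nchar(strip_dot(code)) < 3L], collapse = ", "))
  toupper(substr(code, 1L, 3L))
}

new_claims_bundle <- function(qualifications, claims) {
  qualifications <- as.data.table(qualifications)
  claims <- as.data.table(claims)
  stray <- setdiff(claims$person_id, qualifications$person_id)
  if (length(stray))
    stop("claims reference persons absent from the qualification table: ",
         paste(utils::head(stray, 5), collapse = ", "))
  structure(list(qualifications = qualifications, claims = claims),
            class = "claims_bundle")
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat(sprintf("claims_bundle: %d persons, %d person-years, %d claim records\n",
              length(unique(x$qualifications$person_id)),
              nrow(x$qualifications), nrow(x$claims)))
  invisible(x)
}

.parse_dates <- function(x, fmt, what) {
  d <- as.Date(as.character(x), format = fmt)
  bad <- is.na(d) & !is.na(x) & nzchar(as.character(x))
  if (any(bad))
    warning(sprintf("%s: dropped %d row(s) with malformed visit_date", what,
                    sum(bad)), call. = FALSE)
  list(dates = d, keep = !bad & !is.na(d))
}

#' Read the three claims tables into one bundle
#'
#' @param qual_path,statement_path,disease_path file paths; `disease_path`
#'   may be `NULL` when there is no disease table.
#' @param dialect list with `delim` and `date_format` (see
#'   [load_code_config()]); defaults to tab-delimited ISO-8601 dates.
#' @return a `claims_bundle`. Rows with malformed dates are dropped with a
#'   warning; claims naming a person absent from the qualification table are
#'   an error.
#' @export
read_claims_tables <- function(qual_path, statement_path, disease_path = NULL,
                               dialect = default_dialect()) {
  dialect <- utils::modifyList(default_dialect(), dialect)
  qual <- fread(qual_path, sep = dialect$delim, colClasses = list(
    character = "person_id"))
  need <- c("person_id", "sex", "year", "age_group", "income_rank")
  if (!all(need %in% names(qual)))
    stop("qualification table must have columns: ", paste(need, collapse = ", "))

  stmt <- fread(statement_path, sep = dialect$delim,
                colClasses = list(character = c("person_id", "claim_no",
                                                "principal_dx", "additional_dx")))
  pd <- .parse_dates(stmt$visit_date, dialect$date_format, "statement")
  stmt <- stmt[pd$keep][, visit_date := pd$dates[pd$keep]]

  fan <- function(col, src) stmt[
    nzchar(get(col)),
    .(person_id, claim_no, visit_date, code = get(col), source = src)]
  claims <- rbindlist(list(fan("principal_dx", "principal"),
                           fan("additional_dx", "additional")))

  if (!is.null(disease_path)) {
    dis <- fread(disease_path, sep = dialect$delim,
                 colClasses = list(character = c("claim_no", "dx")))
    pd <- .parse_dates(dis$visit_date, dialect$date_format, "disease")
    dis <- dis[pd$keep][, visit_date := pd$dates[pd$keep]]
    owner <- unique(stmt[, .(claim_no, person_id)])
    dis <- owner[dis, on = "claim_no"]
    if (anyNA(dis$person_id))
      stop("disease-table rows reference claim numbers absent from the ",
           "statement table")
    claims <- rbindlist(list(
      claims,
      dis[nzchar(dx), .(person_id, claim_no, visit_date, code = dx,
                        source = "disease_table")]))
  }
  setorder(claims, person_id, visit_date, claim_no, code)
  new_claims_bundle(qual, claims)
}

#' Write a claims bundle back to the three-table layout
#'
#' The inverse of [read_claims_tables()]: principal/additional rows return to
#' the statement table (one statement row per claim; first principal and first
#' additional code kept per (claim, date); extra rows go to the disease
#' table).
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @param dialect delimiter/date-format list.
#' @return invisibly, the three file paths.
#' @export
write_claims_tables <- function(bundle, dir, dialect = default_dialect()) {
  dialect <- utils::modifyList(default_dialect(), dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c(qualification = "qualification.tsv",
                            statement = "statement.tsv",
                            disease = "disease.tsv"))
  fwrite(bundle$qualifications, paths[1], sep = dialect$delim)

  cl <- copy(bundle$claims)
  cl[, visit_date := format(visit_date, dialect$date_format)]
  stmt <- data.table::dcast(
    cl[source %in% c("principal", "additional")],
    person_id + claim_no + visit_date ~ source,
    value.var = "code", fun.aggregate = function(x) x[1], fill = "")
  for (col in c("principal", "additional"))
    if (!col %in% names(stmt)) stmt[, (col) := ""]
  setnames(stmt, c("principal", "additional"),
           c("principal_dx", "additional_dx"))
  fwrite(stmt[, .(person_id, claim_no, visit_date, principal_dx,
                  additional_dx)], paths[2], sep = dialect$delim)

  dis <- cl[source == "disease_table",
            .(claim_no, visit_date, dx = code)]
  fwrite(dis, paths[3], sep = dialect$delim)
  invisible(paths)
}
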