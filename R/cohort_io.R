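#' Cohort container
#'
#' A validated two-table representation of a pregnancy-weight cohort:
#' \code{women} (one row per woman: id, pre-pregnancy weight in kg, height
#' in m, four logical complication flags with NA = unknown) and \code{obs}
#' (one row per weight observation: id, gestational age in decimal weeks,
#' weight in kg). The implied week-0 observation (weight = pre-pregnancy
#' weight at gestational age 0) is always materialized.
#'
#' @param women data.frame with columns \code{woman_id},
#'   \code{prepregnancy_weight}, \code{height_m}, \code{hypertensive},
#'   \code{diabetic}, \code{preterm}, \code{sga_lga}.
#' @param obs data.frame with columns \code{woman_id}, \code{ga_weeks},
#'   \code{weight_kg}.
#' @param provenance free-text label for the table's origin.
#' @param rejections data.frame(reason, n) tallying rows/women rejected
#'   during loading.
#' @return object of class \code{"cohort_table"}.
#' @export
cohort_table <- function(women, obs, provenance = "unspecified",
                         rejections = data.frame(reason = character(0), n = integer(0))) {
  need_w <- c("woman_id", "prepregnancy_weight", "height_m",
              "hypertensive", "diabetic", "preterm", "sga_lga")
  need_o <- c("woman_id", "ga_weeks", "weight_kg")
  if (!all(need_w %in% names(women)))
    stop("women table lacks column(s): ",
         paste(setdiff(need_w, names(women)), collapse = ", "))
  if (!all(need_o %in% names(obs)))
    stop("obs table lacks column(s): ",
         paste(setdiff(need_o, names(obs)), collapse = ", "))
  if (anyDuplicated(women$woman_id))
    stop("woman_id must be unique within a cohort table")
  structure(list(women = women[, need_w, drop = FALSE],
                 obs = obs[, need_o, drop = FALSE],
                 provenance = provenance,
                 rejections = rejections),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$women), " women, ", nrow(x$obs),
      " observations (", x$provenance, ")\n", sep = "")
  if (nrow(x$rejections) > 0) {
    cat("rejections:\n")
    print(x$rejections, row.names = FALSE)
  }
  invisible(x)
}

.default_schema <- function() {
  c(woman_id = "woman_id", prepregnancy_weight = "prepregnancy_weight_kg",
    height_m = "height_m", ga_weeks = "ga_weeks", weight_kg = "weight_kg",
    hypertensive = "hypertensive", diabetic = "diabetic",
    preterm = "preterm", sga_lga = "sga_lga")
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(ifelse(is.na(x), NA, x != 0))
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  out
}

#' Read a long-format cohort CSV
#'
#' One row per (woman, observation); comma-separated, UTF-8, header row,
#' decimal point. Units are fixed at kg / m / decimal weeks. Mandatory
#' columns (or their \code{schema_config} mappings): woman_id,
#' prepregnancy_weight_kg, height_m, ga_weeks, weight_kg; the four
#' complication-flag columns are optional (absent flag = unknown).
#'
#' Women without a pre-pregnancy weight are excluded (inclusion rule) and
#' counted; observations failing the plausibility screens (gestational age
#' outside 0-45 weeks, weight outside 25-250 kg) are collected into the
#' rejection tally, never silently dropped. Week-0 rows are materialized
#' from the pre-pregnancy weight for every retained woman.
#'
#' @param path CSV file path.
#' @param schema_config named character vector mapping internal field names
#'   to the file's column names; defaults to the canonical names.
#' @return a [cohort_table()]; \code{$rejections} carries the per-reason
#'   tally and \code{attr(, "excluded_women")} the no-pre-pregnancy-weight
#'   exclusion count.
#' @export
read_cohort_csv <- function(path, schema_config = NULL) {
  schema <- .default_schema()
  if (!is.null(schema_config)) schema[names(schema_config)] <- schema_config
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("empty cohort file: ", path)
    empty_w <- data.frame(woman_id = character(0), prepregnancy_weight = numeric(0),
                          height_m = numeric(0), hypertensive = logical(0),
                          diabetic = logical(0), preterm = logical(0),
                          sga_lga = logical(0))
    empty_o <- data.frame(woman_id = character(0), ga_weeks = numeric(0),
                          weight_kg = numeric(0))
    return(cohort_table(empty_w, empty_o, provenance = path))
  }
  mandatory <- c("woman_id", "prepregnancy_weight", "height_m", "ga_weeks", "weight_kg")
  for (f in mandatory)
    if (!schema[[f]] %in% names(raw))
      stop("mandatory column '", schema[[f]], "' (field ", f, ") missing in ", path)

  id <- as.character(raw[[schema[["woman_id"]]]])
  pre <- as.numeric(raw[[schema[["prepregnancy_weight"]]]])
  ht <- as.numeric(raw[[schema[["height_m"]]]])
  ga <- as.numeric(raw[[schema[["ga_weeks"]]]])
  wt <- as.numeric(raw[[schema[["weight_kg"]]]])
  flags <- lapply(c("hypertensive", "diabetic", "preterm", "sga_lga"), function(f) {
    col <- schema[[f]]
    if (col %in% names(raw)) .as_flag(raw[[col]]) else rep(NA, nrow(raw))
  })
  names(flags) <- c("hypertensive", "diabetic", "preterm", "sga_lga")

  # plausibility screens on observation rows
  bad_ga <- !is.na(ga) & (ga < 0 | ga > 45)
  bad_wt <- !is.na(wt) & (wt <= 25 | wt >= 250)
  keep_obs <- !is.na(ga) & !is.na(wt) & !bad_ga & !bad_wt & ga > 0

  first <- !duplicated(id)
  women <- data.frame(woman_id = id[first], prepregnancy_weight = pre[first],
                      height_m = ht[first],
                      hypertensive = flags$hypertensive[first],
                      diabetic = flags$diabetic[first],
                      preterm = flags$preterm[first],
                      sga_lga = flags$sga_lga[first],
                      stringsAsFactors = FALSE)
  has_pre <- is.finite(women$prepregnancy_weight) & women$prepregnancy_weight > 0
  excluded_women <- sum(!has_pre)
  women <- women[has_pre, , drop = FALSE]

  obs <- data.frame(woman_id = id[keep_obs], ga_weeks = ga[keep_obs],
                    weight_kg = wt[keep_obs], stringsAsFactors = FALSE)
  obs <- obs[obs$woman_id %in% women$woman_id, , drop = FALSE]
  # materialize the implied week-0 observation per retained woman
  week0 <- data.frame(woman_id = women$woman_id, ga_weeks = 0,
                      weight_kg = women$prepregnancy_weight,
                      stringsAsFactors = FALSE)
  obs <- rbind(week0, obs)
  rownames(obs) <- rownames(women) <- NULL

  rejections <- data.frame(
    reason = c("gestational_age_outside_0_45", "weight_outside_25_250",
               "missing_ga_or_weight", "woman_without_prepregnancy_weight"),
    n = c(sum(bad_ga), sum(bad_wt & !bad_ga),
          sum((is.na(ga) | is.na(wt)) & !(ga <= 0) %in% TRUE),
          excluded_women))
  out <- cohort_table(women, obs, provenance = path, rejections = rejections)
  attr(out, "excluded_women") <- excluded_women
  out
}

#' Write a cohort to the canonical CSV schema
#'
#' Inverse of [read_cohort_csv()] (modulo row order): one row per
#' in-pregnancy observation with the woman-level columns repeated. Week-0
#' rows are not written (they are implied by prepregnancy_weight_kg and
#' re-materialized on read). Deterministic output: same table, same bytes.
#'
#' @param cohort a [cohort_table()].
#' @param path output CSV path.
#' @return invisibly, the written data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  obs <- cohort$obs[cohort$obs$ga_weeks > 0, , drop = FALSE]
  m <- match(obs$woman_id, cohort$women$woman_id)
  w <- cohort$women[m, , drop = FALSE]
  df <- data.frame(woman_id = obs$woman_id,
                   prepregnancy_weight_kg = w$prepregnancy_weight,
                   height_m = w$height_m,
                   ga_weeks = obs$ga_weeks,
                   weight_kg = obs$weight_kg,
                   hypertensive = as.integer(w$hypertensive),
                   diabetic = as.integer(w$diabetic),
                   preterm = as.integer(w$preterm),
                   sga_lga = as.integer(w$sga_lga))
  df <- df[order(df$woman_id, df$ga_weeks), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Week-indexed BCT parameter grids on disk
#'
#' A parameter grid is the exchange format between a fitted chart and the
#' z-score calculator: one row per integer gestational week with the four
#' BCT parameters. On disk it is a CSV with columns
#' \code{week,mu,sigma,nu,tau}, one BMI group per file, the group named in
#' a leading comment line \code{# group: <label>}. Values are stored at
#' full precision; \code{read(write(g))} is an identity.
#'
#' @param grid a \code{parameter_grid} (see [export_parameter_grid()]), or
#'   any data.frame with the five columns and a \code{bmi_group} attribute.
#' @param path CSV path.
#' @return \code{read_parameter_grid}: the grid; \code{write_parameter_grid}:
#'   invisibly the path.
#' @export
write_parameter_grid <- function(grid, path) {
  need <- c("week", "mu", "sigma", "nu", "tau")
  stopifnot(all(need %in% names(grid)))
  if (any(diff(grid$week) <= 0)) stop("grid weeks must be strictly increasing")
  if (any(grid$week != round(grid$week))) stop("grid weeks must be integers")
  grp <- attr(grid, "bmi_group")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# group: ", if (is.null(grp)) "unspecified" else grp), con)
  utils::write.csv(format(grid[, need], digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parameter_grid
#' @export
read_parameter_grid <- function(path) {
  header <- readLines(path, n = 1)
  grp <- if (startsWith(header, "#")) sub("^#\\s*group:\\s*", "", header) else NULL
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("week", "mu", "sigma", "nu", "tau")
  if (!all(need %in% names(df)))
    stop("parameter grid lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$week)) stop("duplicate week rows in parameter grid")
  if (any(diff(df$week) <= 0)) stop("grid weeks must be strictly increasing")
  if (any(df$sigma <= 0)) stop("sigma must be > 0 throughout the grid")
  if (any(df$tau <= 0)) stop("tau must be > 0 throughout the grid")
  if (any(df$mu <= 0)) stop("mu must be > 0 throughout the grid")
  structure(df[, need], bmi_group = grp, class = c("parameter_grid", "data.frame"))
}
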