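#' Supported endpoint labels
#'
#' The six genetic toxicology endpoints handled by the package: DNA adduct
#' frequency (continuous, adducts per 1e8 nucleotides), lacZ transgene mutant
#' frequency (mutant pfu / total pfu), Pig-a mutant phenotype frequency in
#' reticulocytes and total red blood cells (mutant cells per 1e6 cells), and
#' micronucleated reticulocyte / normochromatic erythrocyte frequency
#' (% micronucleated cells).
#'
#' @format character vector of endpoint ids.
#' @export
bmd_endpoints <- c(
  "dna_adducts", "lacz_mf", "piga_mf_ret", "piga_mf_rbc", "mn_ret", "mn_nce"
)

# reporting-unit scale for count endpoints: response = count/denominator * scale
endpoint_unit_scale <- c(
  lacz_mf = 1e5, piga_mf_ret = 1e6, piga_mf_rbc = 1e6, mn_ret = 100, mn_nce = 100
)

endpoint_default_units <- c(
  dna_adducts = "adducts per 10^8 nucleotides",
  lacz_mf = "mutants per 10^5 pfu",
  piga_mf_ret = "mutants per 10^6 RET",
  piga_mf_rbc = "mutants per 10^6 RBC",
  mn_ret = "% micronucleated RET",
  mn_nce = "% micronucleated NCE"
)

#' Construct an animal-level dose-response dataset
#'
#' A dataset holds the per-animal measurements for one tissue x endpoint
#' combination.  Records are either continuous (column `response`, strictly
#' positive, e.g. DNA adducts per 1e8 nucleotides) or count-type (columns
#' `count` and `denominator`, e.g. mutant pfu out of total pfu) -- uniformly
#' within a dataset.
#'
#' Validation enforces the design assumptions of downstream modelling: all
#' doses non-negative, at least one vehicle-control record at dose 0, at
#' least three distinct dose levels, `0 <= count <= denominator` with
#' `denominator > 0`, and `response > 0` (required by the log-normal error
#' model).
#'
#' @param records data frame with columns `animal_id`, `dose`, and either
#'   `response` or `count` + `denominator`.
#' @param tissue tissue label (e.g. `"bone_marrow"`).
#' @param endpoint endpoint id; one of [bmd_endpoints].
#' @param dose_units dose unit label; default `"mg/kg BW/day"`.
#' @param response_units response unit label; defaults to the endpoint's
#'   conventional reporting unit.
#' @return an object of class `dr_dataset`.
#' @export
#' @examples
#' ds <- dr_dataset(
#'   data.frame(animal_id = 1:9, dose = rep(c(0, 1, 10), each = 3),
#'              response = c(1.1, 0.9, 1.2, 2.3, 1.8, 2.6, 7.9, 8.8, 9.4)),
#'   tissue = "liver", endpoint = "dna_adducts"
#' )
#' ds
dr_dataset <- function(records, tissue, endpoint,
                       dose_units = "mg/kg BW/day", response_units = NULL) {
  if (!is.data.frame(records)) contract_error("`records` must be a data frame")
  if (!is.character(tissue) || length(tissue) != 1L || !nzchar(tissue)) {
    contract_error("`tissue` must be a non-empty label")
  }
  if (!endpoint %in% bmd_endpoints) {
    contract_error(sprintf(
      "unknown endpoint '%s'; expected one of %s",
      endpoint, paste(bmd_endpoints, collapse = ", ")
    ))
  }
  if (!all(c("animal_id", "dose") %in% names(records))) {
    validation_error("records need columns `animal_id` and `dose`")
  }
  has_resp <- "response" %in% names(records) && !all(is.na(records$response))
  has_count <- all(c("count", "denominator") %in% names(records)) &&
    !all(is.na(records$count))
  if (has_resp == has_count) {
    validation_error(
      "records must contain exactly one of `response` or `count` + `denominator`"
    )
  }
  kind <- if (has_resp) "continuous" else "count"
  cols <- c("animal_id", "dose",
            if (kind == "continuous") "response" else c("count", "denominator"))
  records <- records[, cols, drop = FALSE]
  records$animal_id <- as.character(records$animal_id)
  records$dose <- as.numeric(records$dose)
  rownames(records) <- NULL

  ds <- structure(
    list(
      tissue = tissue,
      endpoint = endpoint,
      kind = kind,
      records = records,
      dose_units = dose_units,
      response_units = response_units %||%
        unname(endpoint_default_units[endpoint])
    ),
    class = "dr_dataset"
  )
  validate_dr_dataset(ds)
}

#' Validate a dose-response dataset
#'
#' @param ds a [dr_dataset()].
#' @return `ds`, invisibly classed, if valid; otherwise a validation error
#'   listing the offending rows.
#' @export
validate_dr_dataset <- function(ds) {
  r <- ds$records
  bad <- which(!is.finite(r$dose) | r$dose < 0)
  if (length(bad) > 0) {
    validation_error(paste0("negative or missing dose in rows: ",
                            paste(bad, collapse = ", ")))
  }
  if (!any(r$dose == 0)) {
    validation_error("no vehicle-control records (dose 0) present")
  }
  if (length(unique(r$dose)) < 3) {
    validation_error("at least 3 distinct dose levels are required for modelling")
  }
  if (ds$kind == "continuous") {
    bad <- which(!is.finite(r$response) | r$response <= 0)
    if (length(bad) > 0) {
      validation_error(paste0(
        "non-positive response (invalid under the log-normal error model) ",
        "in rows: ", paste(bad, collapse = ", ")
      ))
    }
  } else {
    bad <- which(!is.finite(r$denominator) | r$denominator <= 0)
    if (length(bad) > 0) {
      validation_error(paste0("non-positive denominator in rows: ",
                              paste(bad, collapse = ", ")))
    }
    bad <- which(!is.finite(r$count) | r$count < 0 | r$count != round(r$count))
    if (length(bad) > 0) {
      validation_error(paste0("counts must be non-negative integers; rows: ",
                              paste(bad, collapse = ", ")))
    }
    bad <- which(r$count > r$denominator)
    if (length(bad) > 0) {
      validation_error(paste0("count exceeds denominator in rows: ",
                              paste(bad, collapse = ", ")))
    }
  }
  ds
}

#' @export
print.dr_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("<dr_dataset> %s / %s (%s)\n", x$tissue, x$endpoint, x$kind))
  cat(sprintf("  %d animals, %d dose levels (%s): %s\n",
              nrow(r), length(unique(r$dose)), x$dose_units,
              paste(sort(unique(r$dose)), collapse = ", ")))
  cat(sprintf("  response units: %s\n", x$response_units))
  invisible(x)
}

#' Read dose-response datasets from CSV
#'
#' Expects a comma-separated, UTF-8, header-first file with columns
#' `animal_id`, `dose`, and either `response` or `count` + `denominator`.
#' `tissue` and `endpoint` may be columns of the file or supplied as
#' arguments (arguments are used when the columns are absent).  Rows are
#' grouped into one dataset per tissue x endpoint combination.
#'
#' @param path path to a CSV file.
#' @param tissue,endpoint labels used when the file has no such columns.
#' @param drop if `TRUE` (default) and the file holds a single tissue x
#'   endpoint combination, return that `dr_dataset` directly instead of a
#'   length-one list.
#' @return a `dr_dataset`, or a named list of them (names `tissue.endpoint`).
#' @export
read_dr_csv <- function(path, tissue = NULL, endpoint = NULL, drop = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  value_cols <- intersect(c("response", "count", "denominator"), names(df))
  need <- c("animal_id", "dose")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0 ||
      !("response" %in% value_cols ||
        all(c("count", "denominator") %in% value_cols))) {
    validation_error(paste0(
      "CSV schema error in '", path, "': need columns animal_id, dose and ",
      "either response or count + denominator",
      if (length(missing) > 0) paste0(" (missing: ",
                                      paste(missing, collapse = ", "), ")")
    ))
  }
  if (!"tissue" %in% names(df)) {
    if (is.null(tissue)) validation_error("no `tissue` column and none supplied")
    df$tissue <- tissue
  }
  if (!"endpoint" %in% names(df)) {
    if (is.null(endpoint)) validation_error("no `endpoint` column and none supplied")
    df$endpoint <- endpoint
  }
  key <- interaction(df$tissue, df$endpoint, drop = TRUE, sep = ".")
  out <- lapply(split(df, key), function(g) {
    dr_dataset(g[, c("animal_id", "dose", value_cols), drop = FALSE],
               tissue = g$tissue[1], endpoint = g$endpoint[1])
  })
  if (drop && length(out) == 1L) out[[1]] else out
}

#' Write dose-response datasets to CSV
#'
#' The inverse of [read_dr_csv()]: numeric values are written with 17
#' significant digits so that a write/read round trip reproduces labels
#' bit-exactly, integers exactly and reals to better than 1e-12 relative.
#'
#' @param x a `dr_dataset` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dr_csv <- function(x, path) {
  if (inherits(x, "dr_dataset")) x <- list(x)
  rows <- lapply(x, function(ds) {
    r <- ds$records
    r$tissue <- ds$tissue
    r$endpoint <- ds$endpoint
    r
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[, all_cols, drop = FALSE]
  })
  df <- do.call(rbind, rows)
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Convert a dataset to the per-animal positive response series used for
#' benchmark-dose modelling
#'
#' Continuous endpoints pass through unchanged.  Count endpoints are
#' converted to rates on the endpoint's conventional reporting scale
#' (`count / denominator * scale`; e.g. mutants per 1e5 pfu for lacZ).
#' Zero counts -- which are incompatible with log-scale modelling -- are
#' handled by `zero_rule`:
#'
#' * `"half_minimum"` (default): replace zero with half the smallest
#'   non-zero per-animal value in the same dataset;
#' * `"exclude"`: drop zero-count animals (an error if this empties a whole
#'   dose group).
#'
#' @param ds a [dr_dataset()].
#' @param zero_rule `"half_minimum"` or `"exclude"`.
#' @return data frame with columns `animal_id`, `dose`, `response`
#'   (all responses strictly positive).
#' @export
to_modelling_response <- function(ds, zero_rule = c("half_minimum", "exclude")) {
  zero_rule <- match.arg(zero_rule)
  stopifnot(inherits(ds, "dr_dataset"))
  r <- ds$records
  if (ds$kind == "continuous") {
    return(data.frame(animal_id = r$animal_id, dose = r$dose,
                      response = r$response))
  }
  scale <- unname(endpoint_unit_scale[ds$endpoint])
  y <- r$count / r$denominator * scale
  zero <- y == 0
  if (all(zero)) {
    validation_error("all counts are zero: no response signal to model")
  }
  if (any(zero)) {
    if (zero_rule == "half_minimum") {
      y[zero] <- min(y[!zero]) / 2
    } else {
      keep <- !zero
      lost <- setdiff(unique(r$dose), unique(r$dose[keep]))
      if (length(lost) > 0) {
        validation_error(paste0(
          "zero-rule 'exclude' removes every animal at dose(s) ",
          paste(lost, collapse = ", "),
          "; consider the 'half_minimum' rule instead"
        ))
      }
      r <- r[keep, , drop = FALSE]
      y <- y[keep]
    }
  }
  data.frame(animal_id = r$animal_id, dose = r$dose, response = y)
}
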