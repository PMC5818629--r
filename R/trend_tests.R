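#' Poisson-regression trend testing with per-dose contrasts
#'
#' @description
#' [trend_test()] screens a dataset for an overall dose effect and compares
#' each dose group with the vehicle control:
#'
#' * the overall test is a likelihood-ratio chi-square comparing a Poisson
#'   regression with dose as a categorical factor (and the log denominator
#'   as offset) against the intercept-only model; its degrees of freedom are
#'   the number of dose levels minus one (the "Type 3" treatment-effect test
#'   for a single factor);
#' * each per-dose contrast is the likelihood-ratio statistic (df = 1) from
#'   constraining that dose group's rate to equal the control rate, with the
#'   p-value mapped to the significance tiers `a` (p < 0.0001), `b`
#'   (p < 0.001), `c` (p < 0.01), `d` (p < 0.05) or `ns`.
#'
#' Count endpoints are tested on their raw counts and denominators.
#' Continuous DNA adduct responses, which are reported per 1e8 nucleotides,
#' are converted to integer adduct counts by rounding (denominator one unit
#' of 1e8 nucleotides) so the same Poisson machinery applies to every
#' endpoint.  No multiplicity adjustment is applied across contrasts; the
#' raw tiered p-values per dose are reported.
#'
#' @name trend_tests
NULL

# per-animal (count, denominator) pairs for Poisson testing
.count_frame <- function(ds) {
  stopifnot(inherits(ds, "dr_dataset"))
  r <- ds$records
  if (ds$kind == "count") {
    data.frame(dose = r$dose, count = r$count, denom = r$denominator)
  } else {
    # continuous responses are on a per-1e8-nucleotide scale already
    data.frame(dose = r$dose, count = round(r$response), denom = 1)
  }
}

.poisson_ll <- function(fit) as.numeric(logLik(fit))

#' Overall dose-effect and per-dose contrast tests
#'
#' @param ds a [dr_dataset()].
#' @return an object of class `trend_test`: list with `overall_stat`,
#'   `overall_df`, `overall_p`, `contrasts` (data frame: `dose`, `lr_stat`,
#'   `p`, `tier`, one row per non-zero dose), `logel` (lowest dose whose
#'   contrast reaches p < 0.05; `NA` if none), `tissue`, `endpoint`.
#' @export
#' @examples
#' ds <- generate_preset("lacz_bone_marrow", seed = 1)
#' trend_test(ds)
trend_test <- function(ds) {
  cf <- .count_frame(ds)
  totals <- tapply(cf$denom, cf$dose, sum)
  if (any(totals <= 0)) {
    contract_error("a dose group has zero total denominator")
  }
  f <- factor(cf$dose)
  full <- glm(count ~ f, offset = log(denom), family = poisson(), data = cf)
  null <- glm(count ~ 1, offset = log(denom), family = poisson(), data = cf)
  stat <- max(0, 2 * (.poisson_ll(full) - .poisson_ll(null)))
  df <- nlevels(f) - 1L
  p <- pchisq(stat, df = df, lower.tail = FALSE)

  doses <- sort(unique(cf$dose[cf$dose > 0]))
  contr <- lapply(doses, function(d0) .dose_contrast(cf, full, d0))
  contrasts <- do.call(rbind, contr)
  sig <- contrasts$p < 0.05
  structure(
    list(
      overall_stat = stat, overall_df = df, overall_p = p,
      contrasts = contrasts,
      logel = if (any(sig)) min(contrasts$dose[sig]) else NA_real_,
      tissue = ds$tissue, endpoint = ds$endpoint
    ),
    class = "trend_test"
  )
}

.dose_contrast <- function(cf, full, d0) {
  # constrain the rate of dose group d0 to the control rate by merging the
  # factor levels, then compare with the full categorical model
  merged <- factor(ifelse(cf$dose == d0, 0, cf$dose))
  constrained <- glm(count ~ merged, offset = log(denom), family = poisson(),
                     data = cf)
  stat <- max(0, 2 * (.poisson_ll(full) - .poisson_ll(constrained)))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  data.frame(dose = d0, lr_stat = stat, p = p, tier = p_tier(p),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio contrast of one dose group against control
#'
#' @param ds a [dr_dataset()].
#' @param dose a non-zero dose level present in `ds`.
#' @return list with `lr_stat`, `p` and `tier`.
#' @export
dose_vs_control_contrast <- function(ds, dose) {
  cf <- .count_frame(ds)
  if (!dose %in% cf$dose || dose == 0) {
    contract_error(sprintf("dose %g is not a non-zero level of the dataset", dose))
  }
  f <- factor(cf$dose)
  full <- glm(count ~ f, offset = log(denom), family = poisson(), data = cf)
  row <- .dose_contrast(cf, full, dose)
  list(lr_stat = row$lr_stat, p = row$p, tier = row$tier)
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf(
    "<trend_test> %s / %s: overall LR chi-square = %.3f (df = %d, p = %.3g)\n",
    x$tissue, x$endpoint, x$overall_stat, x$overall_df, x$overall_p
  ))
  cat(sprintf("  LOGEL: %s\n",
              if (is.na(x$logel)) "none" else format(x$logel)))
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}
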