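#' Configuration for a full analysis run
#'
#' @param ces benchmark response as fractional increase over background
#'   (default 1: a two-fold increase).
#' @param ci_level two-sided confidence level for BMD intervals (default 0.90).
#' @param lrt_alpha significance level of the model-selection likelihood
#'   ratio steps (default 0.05).
#' @param zero_rule zero-count handling rule (`"half_minimum"` or
#'   `"exclude"`).
#' @param seed integer seed controlling every stochastic step of a run
#'   (fit multi-starts and, when presets are analysed, data generation).
#' @param out_dir optional directory; when set, result tables (CSV/JSON)
#'   and a run log are written there.
#' @param plots also write forest / proportionality plots (requires
#'   `out_dir`).
#' @return a `run_config` list.
#' @export
run_config <- function(ces = 1, ci_level = 0.90, lrt_alpha = 0.05,
                       zero_rule = "half_minimum", seed = 1,
                       out_dir = NULL, plots = FALSE) {
  if (ces <= 0) contract_error("`ces` must be > 0")
  if (ci_level <= 0 || ci_level >= 1) contract_error("`ci_level` must be in (0, 1)")
  if (lrt_alpha <= 0 || lrt_alpha >= 1) contract_error("`lrt_alpha` must be in (0, 1)")
  zero_rule <- match.arg(zero_rule, c("half_minimum", "exclude"))
  structure(list(ces = ces, ci_level = ci_level, lrt_alpha = lrt_alpha,
                 zero_rule = zero_rule, seed = as.integer(seed),
                 out_dir = out_dir, plots = plots),
            class = "run_config")
}

#' Run the full benchmark-dose analysis pipeline
#'
#' For every dataset: model selection, BMD estimation with profile CI, and
#' the Poisson trend test with per-dose contrasts.  Across datasets:
#' CI-overlap sensitivity ranking per endpoint, cross-endpoint comparison
#' per tissue measured under several endpoints, and unity-slope
#' proportionality for each configured endpoint pair.  Datasets that fail
#' validation or estimation are skipped with a logged reason; the run fails
#' only if every dataset fails.
#'
#' @param datasets a list of [dr_dataset()]s, or a character vector of
#'   preset names (datasets are then generated with seeds derived from
#'   `config$seed`).
#' @param config a [run_config()].
#' @param proportionality_pairs list of endpoint-id pairs to analyse for
#'   proportionality when both endpoints cover >= 3 shared tissues
#'   (default: DNA adducts vs lacZ mutant frequency).
#' @return an object of class `bmd_report`: list with `bmd_table` (one row
#'   per dataset), `estimates`, `selections`, `trends`, `rankings` (per
#'   endpoint), `cross_endpoint` (per multi-endpoint tissue),
#'   `proportionality`, `skipped` and `config`.  If `config$out_dir` is set
#'   the tables are also written as CSV/JSON together with a run log.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(c("lacz_bone_marrow", "lacz_spleen",
#'                       "lacz_small_intestine"))
#' rep$bmd_table
#' }
run_pipeline <- function(datasets, config = run_config(),
                         proportionality_pairs = list(c("dna_adducts", "lacz_mf"))) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(datasets)) {
    names <- datasets
    datasets <- lapply(seq_along(names), function(i) {
      generate_preset(names[i], seed = config$seed + i)
    })
  }
  if (length(datasets) == 0) contract_error("no datasets supplied")

  estimates <- list()
  selections <- list()
  trends <- list()
  skipped <- list()
  for (ds in datasets) {
    key <- paste(ds$tissue, ds$endpoint, sep = ".")
    res <- tryCatch({
      ds <- validate_dr_dataset(ds)
      sel <- select_model(ds, alpha = config$lrt_alpha,
                          zero_rule = config$zero_rule, seed = config$seed)
      est <- estimate_bmd(sel, ds, ces = config$ces, level = config$ci_level,
                          zero_rule = config$zero_rule)
      tt <- trend_test(ds)
      list(sel = sel, est = est, tt = tt)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[key]] <- conditionMessage(res)
    } else {
      selections[[key]] <- res$sel
      estimates[[key]] <- res$est
      trends[[key]] <- res$tt
    }
  }
  if (length(estimates) == 0) {
    contract_error(paste0(
      "every dataset failed: ",
      paste(sprintf("%s (%s)", names(skipped), unlist(skipped)),
            collapse = "; ")
    ))
  }

  bmd_table <- do.call(rbind, lapply(names(estimates), function(k) {
    e <- estimates[[k]]
    t <- trends[[k]]
    data.frame(
      tissue = e$tissue, endpoint = e$endpoint, status = e$status,
      model_id = e$model_id, bmd = e$bmd, bmdl = e$bmdl, bmdu = e$bmdu,
      precision_ratio = e$precision_ratio, midpoint = e$midpoint,
      bmdu_unbounded = e$bmdu_unbounded,
      trend_stat = t$overall_stat, trend_p = t$overall_p, logel = t$logel,
      stringsAsFactors = FALSE
    )
  }))
  rownames(bmd_table) <- NULL

  ok <- vapply(estimates, function(e) e$status == "ok", logical(1))
  rankings <- list()
  for (ep in unique(bmd_table$endpoint)) {
    es <- estimates[ok & vapply(estimates, function(e) e$endpoint == ep,
                                logical(1))]
    if (length(es) >= 2) rankings[[ep]] <- rank_tissues(unname(es))
  }

  cross_endpoint <- list()
  tissues <- unique(bmd_table$tissue)
  for (tt in tissues) {
    es <- estimates[ok & vapply(estimates, function(e) e$tissue == tt,
                                logical(1))]
    if (length(es) >= 2) cross_endpoint[[tt]] <- compare_endpoints(unname(es))
  }

  props <- list()
  for (pair in proportionality_pairs) {
    ex <- estimates[ok & vapply(estimates, function(e) e$endpoint == pair[1],
                                logical(1))]
    ey <- estimates[ok & vapply(estimates, function(e) e$endpoint == pair[2],
                                logical(1))]
    shared <- intersect(vapply(ex, function(e) e$tissue, character(1)),
                        vapply(ey, function(e) e$tissue, character(1)))
    if (length(shared) >= 3) {
      tx <- vapply(ex, function(e) e$tissue, character(1))
      ty <- vapply(ey, function(e) e$tissue, character(1))
      props[[paste(pair, collapse = "_vs_")]] <-
        proportionality(unname(ex[tx %in% shared]), unname(ey[ty %in% shared]))
    }
  }

  trend_table <- do.call(rbind, lapply(names(trends), function(k) {
    t <- trends[[k]]
    cbind(data.frame(tissue = t$tissue, endpoint = t$endpoint,
                     stringsAsFactors = FALSE),
          t$contrasts)
  }))

  report <- structure(
    list(bmd_table = bmd_table, estimates = estimates,
         selections = selections, trends = trends,
         trend_table = trend_table,
         rankings = rankings, cross_endpoint = cross_endpoint,
         proportionality = props, skipped = skipped, config = config),
    class = "bmd_report"
  )
  if (!is.null(config$out_dir)) .write_report(report, config)
  report
}

.num_fmt <- function(df) {
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
  }
  df
}

.write_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write.csv(.num_fmt(report$bmd_table), out("bmd_table.csv"),
            row.names = FALSE)
  write.csv(.num_fmt(report$trend_table), out("trend_tests.csv"),
            row.names = FALSE)
  if (length(report$rankings) > 0) {
    rank_tab <- do.call(rbind, lapply(report$rankings, function(r) r$table))
    write.csv(.num_fmt(rank_tab), out("rankings.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(report$selections, function(s) {
      jsonlite::fromJSON(selection_to_json(s), simplifyVector = TRUE)
    }),
    out("selections.json"), auto_unbox = TRUE, digits = NA
  )
  if (length(report$proportionality) > 0) {
    jsonlite::write_json(
      lapply(report$proportionality, function(p) p[setdiff(names(p), "pairs")]),
      out("proportionality.json"), auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(
    list(
      config = unclass(config)[c("ces", "ci_level", "lrt_alpha", "zero_rule",
                                 "seed")],
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("bmdrank")),
      skipped = report$skipped,
      ladders = lapply(report$selections, function(s) s$ladder)
    ),
    out("run_log.json"), auto_unbox = TRUE, digits = NA
  )
  if (isTRUE(config$plots)) {
    for (ep in names(report$rankings)) {
      ggplot2::ggsave(out(paste0("forest_", ep, ".svg")),
                      plot_bmd_forest(report$rankings[[ep]]),
                      width = 7, height = 4.5)
    }
    for (nm in names(report$proportionality)) {
      ggplot2::ggsave(out(paste0("proportionality_", nm, ".svg")),
                      plot_proportionality(report$proportionality[[nm]]),
                      width = 5.5, height = 5)
    }
  }
  invisible(report)
}

#' @export
print.bmd_report <- function(x, ...) {
  cat(sprintf("<bmd_report> %d dataset(s), %d skipped\n",
              nrow(x$bmd_table), length(x$skipped)))
  print(x$bmd_table, row.names = FALSE, digits = 4)
  invisible(x)
}
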