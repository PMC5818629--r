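#' BMD comparison: CI-overlap ranking, cross-endpoint summaries,
#' proportionality and proliferation correlation
#'
#' @description
#' These operations turn per-tissue BMD estimates into the comparative
#' results a genotoxicity study reports:
#'
#' * [rank_tissues()] orders tissues by the geometric midpoint of their
#'   BMDL-BMDU interval and declares two tissues distinguishable exactly
#'   when their confidence intervals do not overlap; tissues are grouped by
#'   the transitive closure of adjacent-CI overlap in midpoint order.
#' * [compare_endpoints()] lines up BMD midpoints, CI ranges and the fitted
#'   maximum-response parameter `c` across endpoints for one tissue or
#'   compartment.
#' * [proportionality()] quantifies the unity-slope (double-log)
#'   relationship between tissue-matched BMDs of two endpoints.
#' * [ki67_correlation()] correlates a tissue proliferation index with the
#'   per-tissue ratio of two endpoint BMDs.
#'
#' @name compare_rank
NULL

.check_estimates <- function(estimates, min_n = 2) {
  if (inherits(estimates, "bmd_estimate")) estimates <- list(estimates)
  ok <- vapply(estimates, inherits, logical(1), what = "bmd_estimate")
  if (!all(ok)) contract_error("all elements must be bmd_estimate objects")
  usable <- vapply(estimates, function(e) e$status == "ok", logical(1))
  if (any(!usable)) {
    contract_error(paste0(
      "estimate(s) without a BMD cannot be compared: ",
      paste(vapply(estimates[!usable], function(e) e$tissue, character(1)),
            collapse = ", ")
    ))
  }
  if (length(estimates) < min_n) {
    contract_error(sprintf("at least %d estimates are required", min_n))
  }
  estimates
}

#' Rank tissues by BMD with CI-overlap distinguishability
#'
#' @param estimates list of [bmd_estimate()]s for a single endpoint
#'   (>= 2; estimates with a capped/unbounded BMDU are ranked last and
#'   flagged).
#' @return an object of class `bmd_ranking`: list with `table` (data frame
#'   sorted ascending by midpoint, with a `group` index), `distinguishable`
#'   (symmetric logical matrix, `TRUE` where the two CIs are disjoint) and
#'   `groups` (list of tissue-name vectors, in midpoint order).
#' @export
#' @examples
#' e1 <- bmd_estimate("si", "lacz_mf", 1.5, 1, 2)
#' e2 <- bmd_estimate("bm", "lacz_mf", 3.5, 3, 4)
#' rank_tissues(list(e1, e2))
rank_tissues <- function(estimates) {
  estimates <- .check_estimates(estimates, min_n = 2)
  eps <- vapply(estimates, function(e) e$endpoint, character(1))
  if (length(unique(eps)) != 1L) {
    contract_error(sprintf("mixed endpoints in ranking: %s",
                           paste(unique(eps), collapse = ", ")))
  }
  tab <- data.frame(
    tissue = vapply(estimates, function(e) e$tissue, character(1)),
    endpoint = eps,
    model_id = vapply(estimates, function(e) e$model_id, character(1)),
    bmd = vapply(estimates, function(e) e$bmd, numeric(1)),
    bmdl = vapply(estimates, function(e) e$bmdl, numeric(1)),
    bmdu = vapply(estimates, function(e) e$bmdu, numeric(1)),
    precision_ratio = vapply(estimates, function(e) e$precision_ratio, numeric(1)),
    midpoint = vapply(estimates, function(e) e$midpoint, numeric(1)),
    bmdu_unbounded = vapply(estimates, function(e) e$bmdu_unbounded, logical(1)),
    stringsAsFactors = FALSE
  )
  # unbounded upper intervals are ordered after all bounded ones
  ord <- order(tab$bmdu_unbounded, tab$midpoint)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  n <- nrow(tab)
  dist <- matrix(FALSE, n, n, dimnames = list(tab$tissue, tab$tissue))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        dist[i, j] <- tab$bmdu[i] < tab$bmdl[j] || tab$bmdu[j] < tab$bmdl[i]
      }
    }
  }
  group <- integer(n)
  group[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      group[i] <- if (dist[i - 1, i]) group[i - 1] + 1L else group[i - 1]
    }
  }
  tab$group <- group
  structure(
    list(table = tab, distinguishable = dist,
         groups = split(tab$tissue, group), endpoint = eps[1]),
    class = "bmd_ranking"
  )
}

#' @export
print.bmd_ranking <- function(x, ...) {
  cat(sprintf("<bmd_ranking> %s: %d tissues, %d CI-overlap group(s)\n",
              x$endpoint, nrow(x$table), length(x$groups)))
  print(x$table[, c("tissue", "bmd", "bmdl", "bmdu", "midpoint", "group")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare BMDs across endpoints for one tissue or compartment
#'
#' @param estimates list of [bmd_estimate()]s, one per endpoint, sharing a
#'   tissue/compartment.
#' @return data frame (class `endpoint_comparison`) sorted ascending by CI
#'   midpoint, with the selected model's maximum-response parameter `c`
#'   (`NA` for models without an asymptote, i.e. `m2`/`m3`).
#' @export
compare_endpoints <- function(estimates) {
  estimates <- .check_estimates(estimates, min_n = 2)
  cs <- vapply(estimates, function(e) {
    if (!is.null(e$params) && !is.null(e$params$c)) e$params$c else NA_real_
  }, numeric(1))
  tab <- data.frame(
    endpoint = vapply(estimates, function(e) e$endpoint, character(1)),
    tissue = vapply(estimates, function(e) e$tissue, character(1)),
    model_id = vapply(estimates, function(e) e$model_id, character(1)),
    bmd = vapply(estimates, function(e) e$bmd, numeric(1)),
    bmdl = vapply(estimates, function(e) e$bmdl, numeric(1)),
    bmdu = vapply(estimates, function(e) e$bmdu, numeric(1)),
    midpoint = vapply(estimates, function(e) e$midpoint, numeric(1)),
    max_response_c = cs,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$midpoint), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("endpoint_comparison", "data.frame")
  tab
}

.match_pairs <- function(estimates_x, estimates_y, min_n = 3) {
  estimates_x <- .check_estimates(estimates_x, min_n = 1)
  estimates_y <- .check_estimates(estimates_y, min_n = 1)
  tx <- vapply(estimates_x, function(e) e$tissue, character(1))
  ty <- vapply(estimates_y, function(e) e$tissue, character(1))
  if (anyDuplicated(tx) || anyDuplicated(ty)) {
    contract_error("duplicate tissues within one estimate list")
  }
  only_x <- setdiff(tx, ty)
  only_y <- setdiff(ty, tx)
  shared <- intersect(tx, ty)
  if (length(shared) < min_n) {
    contract_error(sprintf(
      "need >= %d tissue-matched pairs; unmatched tissues: %s",
      min_n,
      paste(c(only_x, only_y), collapse = ", ")
    ))
  }
  ex <- estimates_x[match(shared, tx)]
  ey <- estimates_y[match(shared, ty)]
  data.frame(
    tissue = shared,
    bmd_x = vapply(ex, function(e) e$bmd, numeric(1)),
    bmdl_x = vapply(ex, function(e) e$bmdl, numeric(1)),
    bmdu_x = vapply(ex, function(e) e$bmdu, numeric(1)),
    bmd_y = vapply(ey, function(e) e$bmd, numeric(1)),
    bmdl_y = vapply(ey, function(e) e$bmdl, numeric(1)),
    bmdu_y = vapply(ey, function(e) e$bmdu, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Unity-slope proportionality analysis between two endpoints' BMDs
#'
#' On a double-log plot a line of slope one corresponds to a proportional
#' relationship between the two endpoints' BMDs.  The proportionality
#' constant is estimated as `10^mean(log10(bmd_y) - log10(bmd_x))` over
#' tissue-matched pairs (the one-parameter least-squares offset of the
#' unity line).  Adequacy of the unity slope is assessed by comparing the
#' residual sum of squares of the slope-1 fit against the free-slope
#' least-squares fit with an F-test at the 0.05 level -- a formalization of
#' the visual criterion customarily applied to such plots.  Pairs are
#' unweighted by default; `weighted = TRUE` weights them by the inverse
#' squared combined log-width of the two CIs.
#'
#' @param estimates_x,estimates_y lists of [bmd_estimate()]s; tissues must
#'   match (>= 3 shared tissues).
#' @param weighted use CI-width weights (default `FALSE`).
#' @return an object of class `bmd_proportionality`: list with `pairs`
#'   (the matched table), `log10_offset`, `proportionality_constant`,
#'   `slope_free`, `f_stat`, `p_unity` and `unity_adequate`.
#' @export
proportionality <- function(estimates_x, estimates_y, weighted = FALSE) {
  pairs <- .match_pairs(estimates_x, estimates_y, min_n = 3)
  lx <- log10(pairs$bmd_x)
  ly <- log10(pairs$bmd_y)
  w <- if (weighted) {
    width <- (log10(pairs$bmdu_x) - log10(pairs$bmdl_x)) +
      (log10(pairs$bmdu_y) - log10(pairs$bmdl_y))
    1 / pmax(width, 1e-6)^2
  } else {
    rep(1, length(lx))
  }
  n <- length(lx)
  # slope fixed at one: offset is the (weighted) mean paired difference
  offset <- sum(w * (ly - lx)) / sum(w)
  rss1 <- sum(w * (ly - lx - offset)^2)
  free <- lm(ly ~ lx, weights = w)
  rss2 <- sum(w * free$residuals^2)
  slope_free <- unname(coef(free)[2])
  if (rss2 < 1e-12 || rss1 - rss2 < 1e-12) {
    f_stat <- 0
    p_unity <- 1
  } else {
    f_stat <- (rss1 - rss2) / (rss2 / (n - 2))
    p_unity <- pf(f_stat, 1, n - 2, lower.tail = FALSE)
  }
  structure(
    list(
      pairs = pairs,
      log10_offset = offset,
      proportionality_constant = 10^offset,
      slope_free = slope_free,
      f_stat = f_stat,
      p_unity = p_unity,
      unity_adequate = p_unity >= 0.05,
      weighted = weighted
    ),
    class = "bmd_proportionality"
  )
}

#' @export
print.bmd_proportionality <- function(x, ...) {
  cat(sprintf(
    "<bmd_proportionality> %d tissues: constant = %.4g (log10 offset %.4g)\n",
    nrow(x$pairs), x$proportionality_constant, x$log10_offset
  ))
  cat(sprintf("  free slope = %.4g; unity slope %s (F = %.3g, p = %.3g)\n",
              x$slope_free,
              if (x$unity_adequate) "adequate" else "rejected",
              x$f_stat, x$p_unity))
  invisible(x)
}

#' Correlate a proliferation index with the ratio of two endpoints' BMDs
#'
#' Pearson correlation of a per-tissue Ki-67 proliferation index against
#' the per-tissue ratio `bmd_x / bmd_y` (e.g. DNA adduct BMD over mutant
#' frequency BMD).  With the minimum of three tissues the correlation is
#' supported by very few points; the returned object carries an explicit
#' small-sample caveat.
#'
#' @param ki67 named numeric vector of Ki-67 indices; names are tissues.
#' @param estimates_x,estimates_y lists of [bmd_estimate()]s (tissues must
#'   cover the names of `ki67`; >= 3 matched tissues).
#' @param log_scale correlate against `log10` of the ratio instead of the
#'   raw ratio (default `FALSE`).
#' @return list with `r` (Pearson correlation; `NA` with `degenerate = TRUE`
#'   when either variable is constant), `n`, `table` and `caveat`.
#' @export
ki67_correlation <- function(ki67, estimates_x, estimates_y,
                             log_scale = FALSE) {
  if (is.null(names(ki67)) || any(!nzchar(names(ki67)))) {
    contract_error("`ki67` must be a named vector (names = tissues)")
  }
  pairs <- .match_pairs(estimates_x, estimates_y, min_n = 1)
  shared <- intersect(names(ki67), pairs$tissue)
  if (length(shared) < 3) {
    contract_error("at least 3 tissues with both a Ki-67 index and BMDs are required")
  }
  pairs <- pairs[match(shared, pairs$tissue), , drop = FALSE]
  ratio <- pairs$bmd_x / pairs$bmd_y
  if (log_scale) ratio <- log10(ratio)
  ki <- unname(ki67[shared])
  degenerate <- sd(ratio) == 0 || sd(ki) == 0
  r <- if (degenerate) NA_real_ else cor(ki, ratio)
  list(
    r = r,
    n = length(shared),
    degenerate = degenerate,
    table = data.frame(tissue = shared, ki67 = ki, bmd_ratio = ratio,
                       stringsAsFactors = FALSE),
    caveat = paste0(
      "correlation based on only ", length(shared),
      " tissues; interpret as supporting evidence, not a formal test"
    )
  )
}
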