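#' Maximum-likelihood fitting of the nested exponential family
#'
#' @description
#' [fit_exp_model()] fits one family member to a dataset by maximum
#' likelihood under the log-normal error model.  Two parameters are profiled
#' analytically: the log background `log(a)` (a linear location on the log
#' scale) and the residual SD `sigma` (root-mean-square log residual), so the
#' numerical search runs only over the remaining one to three parameters on
#' transformed, unconstrained scales (`log b` with free sign for `m2`/`m3`,
#' `log(c - 1)`, and a scaled logit for `d` in `[1, 4]`).  The search is
#' multi-start: a moment-based heuristic start, the solution of the nested
#' simpler model (which guarantees the likelihood ladder is monotone up to
#' optimizer tolerance), and Latin-hypercube draws over a bounded box in the
#' transformed parameters, all under a fixed seed so fits are deterministic.
#'
#' [select_model()] runs the nested likelihood-ratio ladder used for model
#' selection: `m2` is tested against `m1` (df = 1); if accepted, `m3` and
#' `m4` are each tested against `m2` (df = 1) and the better-supported
#' accepted candidate is carried (ties favour `m4`); finally `m5` is tested
#' against the carried three-parameter model (df = 1).  A step is accepted
#' when twice the log-likelihood gain exceeds the chi-square critical value
#' (3.841 at alpha = 0.05 for df = 1), and the selected model is the most
#' complex accepted one.
#'
#' @name fit_select
NULL

# extract (dose, log response) from a dr_dataset or a data.frame
.model_frame <- function(data, zero_rule = "half_minimum") {
  if (inherits(data, "dr_dataset")) {
    data <- to_modelling_response(data, zero_rule = zero_rule)
  }
  if (!is.data.frame(data) || !all(c("dose", "response") %in% names(data))) {
    contract_error("`data` must be a dr_dataset or a data frame with dose, response")
  }
  if (any(data$response <= 0)) {
    contract_error("responses must be strictly positive")
  }
  list(x = as.numeric(data$dose), ly = log(as.numeric(data$response)),
       n = nrow(data))
}

# variance floor: sigma-hat is floored at 1e-6 so that noiseless data keep a
# finite likelihood
SIGMA2_FLOOR <- 1e-12

# concentrated -2/n objective pieces ------------------------------------------

# given the log mean curve with a = 1, profile log(a) and return the
# mean squared log residual
.prof_s2 <- function(lnf0, ly) {
  r <- ly - lnf0
  r <- r - sum(r) / length(r)
  sum(r * r) / length(r)
}

.prof_la <- function(lnf0, ly) {
  r <- ly - lnf0
  sum(r) / length(r)
}

.ll_from_s2 <- function(s2, n, ly) {
  s2f <- s2 + SIGMA2_FLOOR
  -n / 2 * (log(2 * pi * s2f) + 1) - sum(ly)
}

# model-specific fitters -------------------------------------------------------

.fit_m1 <- function(x, ly, n) {
  la <- mean(ly)
  s2 <- mean((ly - la)^2)
  list(params = list(a = exp(la), sigma = sqrt(s2 + SIGMA2_FLOOR)),
       loglik = .ll_from_s2(s2, n, ly), converged = TRUE)
}

.ols_bz <- function(z, ly) {
  zc <- z - mean(z)
  vz <- sum(zc^2)
  b <- if (vz == 0) 0 else sum(zc * (ly - mean(ly))) / vz
  la <- mean(ly) - b * mean(z)
  r <- ly - la - b * z
  list(b = b, la = la, s2 = mean(r^2))
}

.fit_m2 <- function(x, ly, n) {
  o <- .ols_bz(x, ly)
  list(params = list(a = exp(o$la), b = o$b,
                     sigma = sqrt(o$s2 + SIGMA2_FLOOR)),
       loglik = .ll_from_s2(o$s2, n, ly), converged = TRUE)
}

.fit_m3 <- function(x, ly, n) {
  s2_of_d <- function(d) .ols_bz(.xpow(x, d), ly)$s2
  grid <- seq(D_BOUNDS[1], D_BOUNDS[2], length.out = 25)
  vals <- vapply(grid, s2_of_d, numeric(1))
  i <- which.min(vals)
  lo <- max(D_BOUNDS[1], grid[i] - 0.2)
  hi <- min(D_BOUNDS[2], grid[i] + 0.2)
  opt <- optimize(s2_of_d, c(lo, hi), tol = 1e-9)
  d <- if (opt$objective < vals[i]) opt$minimum else grid[i]
  o <- .ols_bz(.xpow(x, d), ly)
  list(params = list(a = exp(o$la), b = o$b, d = d,
                     sigma = sqrt(o$s2 + SIGMA2_FLOOR)),
       loglik = .ll_from_s2(o$s2, n, ly), converged = TRUE)
}

.d_from_t <- function(t) 1 + 3 / (1 + exp(-t))
.t_from_d <- function(d) {
  p <- (d - D_BOUNDS[1]) / diff(D_BOUNDS)
  p <- min(max(p, 1e-6), 1 - 1e-6)
  stats::qlogis(p)
}

# objective factories over the transformed free parameters
.obj_m4 <- function(x, ly) {
  n <- length(ly)
  function(th) {
    b <- exp(th[1]); cc <- 1 + exp(th[2])
    r <- ly - log(cc - (cc - 1) * exp(-b * x))
    r <- r - sum(r) / n
    sum(r * r) / n
  }
}

.obj_m5 <- function(x, ly) {
  n <- length(ly)
  xpos <- x > 0
  function(th) {
    b <- exp(th[1]); cc <- 1 + exp(th[2]); d <- 1 + 3 / (1 + exp(-th[3]))
    z <- numeric(n)
    z[xpos] <- x[xpos]^d
    r <- ly - log(cc - (cc - 1) * exp(-b * z))
    r <- r - sum(r) / n
    sum(r * r) / n
  }
}

# heuristic scales used to centre the multi-start boxes
.start_info <- function(x, ly) {
  xp <- sort(unique(x[x > 0]))
  top <- max(x)
  fold <- exp(mean(ly[x == top]) - mean(ly[x == 0]))
  list(
    xp = xp,
    b0 = log(2) / stats::median(xp),
    lb_box = c(log(log(2) / (50 * max(xp))), log(log(2) / (0.02 * min(xp)))),
    fold = fold,
    lc_box = c(log(0.1), log(max(5 * max(fold, 1.2), 20)))
  )
}

.run_nm <- function(obj, starts, maxit) {
  vals <- vapply(starts, obj, numeric(1))
  ord <- order(vals)
  best <- NULL
  for (i in ord[seq_len(min(3, length(ord)))]) {
    fit <- optim(starts[[i]], obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = maxit))
    # Nelder-Mead that runs out of iterations on a flat likelihood ridge is
    # restarted from its own endpoint (fresh simplex) before being declared
    # unconverged
    tries <- 0
    while (fit$convergence != 0 && tries < 3) {
      fit <- optim(fit$par, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = maxit))
      tries <- tries + 1
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

.fit_m4 <- function(x, ly, n, n_starts, seed) {
  info <- .start_info(x, ly)
  obj <- .obj_m4(x, ly)
  starts <- list(
    c(log(info$b0), log(max(info$fold, 1.5) - 1 + 0.1)),
    c(log(info$b0), -12) # near the m1 boundary (c -> 1)
  )
  lh <- with_seed(seed, lhs::randomLHS(n_starts, 2))
  for (i in seq_len(n_starts)) {
    starts[[length(starts) + 1]] <- c(
      info$lb_box[1] + lh[i, 1] * diff(info$lb_box),
      info$lc_box[1] + lh[i, 2] * diff(info$lc_box)
    )
  }
  best <- .run_nm(obj, starts, maxit = 1500)
  b <- exp(best$par[1]); cc <- 1 + exp(best$par[2])
  lnf0 <- log(cc - (cc - 1) * exp(-b * x))
  s2 <- .prof_s2(lnf0, ly)
  list(params = list(a = exp(.prof_la(lnf0, ly)), b = b, c = cc,
                     sigma = sqrt(s2 + SIGMA2_FLOOR)),
       loglik = .ll_from_s2(s2, n, ly), converged = best$convergence == 0)
}

.fit_m5 <- function(x, ly, n, n_starts, seed, m4_fit = NULL, m3_fit = NULL) {
  info <- .start_info(x, ly)
  obj <- .obj_m5(x, ly)
  clamp <- function(th) pmin(pmax(th, -25), 25)
  starts <- list()
  if (!is.null(m4_fit)) {
    starts[[1]] <- clamp(c(log(m4_fit$params$b), log(m4_fit$params$c - 1), -8))
  }
  if (!is.null(m3_fit) && m3_fit$params$b > 0) {
    starts[[length(starts) + 1]] <- clamp(c(
      log(m3_fit$params$b), log(max(5 * info$fold, 20)),
      .t_from_d(m3_fit$params$d)
    ))
  }
  starts[[length(starts) + 1]] <-
    c(log(info$b0), log(max(info$fold, 1.5) - 1 + 0.1), 0)
  lh <- with_seed(seed + 1L, lhs::randomLHS(n_starts, 3))
  for (i in seq_len(n_starts)) {
    starts[[length(starts) + 1]] <- c(
      info$lb_box[1] + lh[i, 1] * diff(info$lb_box),
      info$lc_box[1] + lh[i, 2] * diff(info$lc_box),
      -6 + 12 * lh[i, 3]
    )
  }
  best <- .run_nm(obj, starts, maxit = 2000)
  b <- exp(best$par[1]); cc <- 1 + exp(best$par[2]); d <- .d_from_t(best$par[3])
  lnf0 <- log(cc - (cc - 1) * exp(-b * .xpow(x, d)))
  s2 <- .prof_s2(lnf0, ly)
  list(params = list(a = exp(.prof_la(lnf0, ly)), b = b, c = cc, d = d,
                     sigma = sqrt(s2 + SIGMA2_FLOOR)),
       loglik = .ll_from_s2(s2, n, ly), converged = best$convergence == 0)
}

#' Fit one nested exponential model by maximum likelihood
#'
#' @param model model id (`"m1"`..`"m5"`).
#' @param data a [dr_dataset()] or a data frame with columns `dose` and
#'   `response` (responses strictly positive).
#' @param zero_rule zero-count handling rule passed to
#'   [to_modelling_response()] when `data` is a dataset.
#' @param n_starts number of Latin-hypercube starting points for the
#'   numerical search (models `m4`/`m5`).
#' @param seed seed for the (deterministic) start draws.
#' @return an object of class `exp_fit`: list with `model_id`, `params`
#'   (including the profiled `sigma`), `loglik` (exact log-normal
#'   log-likelihood including the Jacobian term), `converged` and `n_obs`.
#' @seealso [select_model()]
#' @export
#' @examples
#' d <- data.frame(dose = rep(c(0, 1, 5, 25), each = 3),
#'                 response = exp_mean("m4", list(a = 1, b = 0.4, c = 8),
#'                                     rep(c(0, 1, 5, 25), each = 3)))
#' fit_exp_model("m4", d)
fit_exp_model <- function(model, data, zero_rule = "half_minimum",
                          n_starts = 10, seed = 1) {
  .check_model_id(model)
  mf <- .model_frame(data, zero_rule)
  fit <- switch(model,
    m1 = .fit_m1(mf$x, mf$ly, mf$n),
    m2 = .fit_m2(mf$x, mf$ly, mf$n),
    m3 = .fit_m3(mf$x, mf$ly, mf$n),
    m4 = .fit_m4(mf$x, mf$ly, mf$n, n_starts, seed),
    m5 = {
      m4f <- .fit_m4(mf$x, mf$ly, mf$n, n_starts, seed)
      m3f <- .fit_m3(mf$x, mf$ly, mf$n)
      .fit_m5(mf$x, mf$ly, mf$n, n_starts, seed, m4_fit = m4f, m3_fit = m3f)
    }
  )
  structure(
    list(model_id = model, params = fit$params, loglik = fit$loglik,
         converged = fit$converged, n_obs = mf$n),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  pars <- x$params
  cat(sprintf("<exp_fit> %s  logLik = %.4f  (n = %d%s)\n",
              x$model_id, x$loglik, x$n_obs,
              if (x$converged) "" else ", NOT converged"))
  cat("  ", paste(sprintf("%s = %.5g", names(pars), unlist(pars)),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Select a nested exponential model by likelihood-ratio ladder
#'
#' @inheritParams fit_exp_model
#' @param alpha significance level of each likelihood-ratio step
#'   (default 0.05, i.e. a critical value of 3.841 for df = 1).
#' @return an object of class `exp_selection`: list with `fits` (named list
#'   of [fit_exp_model()] results for `m1`..`m5`), `selected` (model id),
#'   `ladder` (data frame tracing every comparison: statistic `2 * dLL`,
#'   df, critical value, accepted flag) and `alpha`.
#' @details Fits that fail to converge are pruned from the ladder with a
#'   warning.  The ladder is invariant to row order and animal relabelling.
#' @export
select_model <- function(data, alpha = 0.05, zero_rule = "half_minimum",
                         n_starts = 10, seed = 1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    contract_error("`alpha` must lie in (0, 1)")
  }
  mf <- .model_frame(data, zero_rule)
  fits <- list(
    m1 = .fit_m1(mf$x, mf$ly, mf$n),
    m2 = .fit_m2(mf$x, mf$ly, mf$n),
    m3 = .fit_m3(mf$x, mf$ly, mf$n),
    m4 = .fit_m4(mf$x, mf$ly, mf$n, n_starts, seed)
  )
  fits$m5 <- .fit_m5(mf$x, mf$ly, mf$n, n_starts, seed,
                     m4_fit = fits$m4, m3_fit = fits$m3)
  fits <- lapply(names(fits), function(id) {
    structure(list(model_id = id, params = fits[[id]]$params,
                   loglik = fits[[id]]$loglik,
                   converged = fits[[id]]$converged, n_obs = mf$n),
              class = "exp_fit")
  })
  names(fits) <- exp_model_ids

  usable <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(usable)) {
    warning("fit(s) excluded from selection (no convergence): ",
            paste(names(fits)[!usable], collapse = ", "))
  }
  ll <- function(id) fits[[id]]$loglik
  ladder <- data.frame(comparison = character(), stat = numeric(),
                       df = integer(), crit = numeric(), accepted = logical(),
                       stringsAsFactors = FALSE)
  add_step <- function(ladder, wide, narrow, df = 1L) {
    stat <- 2 * (ll(wide) - ll(narrow))
    crit <- qchisq(1 - alpha, df = df)
    acc <- usable[[wide]] && stat > crit
    rbind(ladder, data.frame(
      comparison = paste(wide, "vs", narrow), stat = stat, df = df,
      crit = crit, accepted = acc, stringsAsFactors = FALSE
    ))
  }

  selected <- "m1"
  ladder <- add_step(ladder, "m2", "m1")
  if (ladder$accepted[nrow(ladder)]) {
    selected <- "m2"
    ladder <- add_step(ladder, "m3", "m2")
    m3_ok <- ladder$accepted[nrow(ladder)]
    ladder <- add_step(ladder, "m4", "m2")
    m4_ok <- ladder$accepted[nrow(ladder)]
    carried <- NULL
    if (m4_ok && (!m3_ok || ll("m4") >= ll("m3"))) {
      carried <- "m4" # tie-break prefers the saturating model
    } else if (m3_ok) {
      carried <- "m3"
    }
    if (!is.null(carried)) {
      selected <- carried
      ladder <- add_step(ladder, "m5", carried)
      if (ladder$accepted[nrow(ladder)]) selected <- "m5"
    } else {
      # neither single added parameter helps on its own, but the pair may be
      # needed jointly (superlinear onset with saturation), so m5 gets a
      # two-degree-of-freedom test against m2
      ladder <- add_step(ladder, "m5", "m2", df = 2L)
      if (ladder$accepted[nrow(ladder)]) selected <- "m5"
    }
  }

  structure(
    list(fits = fits, selected = selected, ladder = ladder, alpha = alpha,
         n_obs = mf$n),
    class = "exp_selection"
  )
}

#' @export
print.exp_selection <- function(x, ...) {
  cat(sprintf("<exp_selection> selected: %s (alpha = %g, n = %d)\n",
              x$selected, x$alpha, x$n_obs))
  print(x$ladder, row.names = FALSE)
  invisible(x)
}

#' Serialize a model selection (including its ladder trace) to JSON
#'
#' @param sel an [select_model()] result.
#' @return a JSON string.
#' @export
selection_to_json <- function(sel) {
  stopifnot(inherits(sel, "exp_selection"))
  jsonlite::toJSON(list(
    selected = sel$selected,
    alpha = sel$alpha,
    n_obs = sel$n_obs,
    fits = lapply(sel$fits, function(f) {
      list(model_id = f$model_id, params = f$params, loglik = f$loglik,
           converged = f$converged)
    }),
    ladder = sel$ladder
  ), auto_unbox = TRUE, digits = NA)
}
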