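#' Benchmark dose estimates with profile-likelihood confidence intervals
#'
#' @description
#' [estimate_bmd()] takes a model selection and returns the benchmark dose
#' (BMD) at a stated benchmark response together with its two-sided
#' profile-likelihood confidence interval (BMDL, BMDU; default level 90%).
#'
#' The selected model is reparameterized so that the BMD is an explicit
#' parameter (the rate `b` is expressed in terms of the BMD and the other
#' parameters), the remaining parameters -- background `a`, maximum-response
#' multiple `c`, shape `d`, and residual SD `sigma` -- are maximized out at
#' each fixed BMD value, and the interval bounds are the doses where twice
#' the profile log-likelihood drop equals the chi-square quantile with one
#' degree of freedom (2.7055 at the 90% level), located by bisection with
#' bracket expansion on each side of the maximum-likelihood BMD.
#'
#' @name profile_ci
NULL

#' Construct a benchmark-dose estimate object
#'
#' Used by [estimate_bmd()] and available directly for building fixtures or
#' importing externally computed BMD tables.
#'
#' @param tissue,endpoint labels.
#' @param bmd,bmdl,bmdu benchmark dose and its confidence bounds
#'   (`0 < bmdl <= bmd <= bmdu`).
#' @param ces benchmark response (fractional increase over background).
#' @param level confidence level of `[bmdl, bmdu]`.
#' @param model_id id of the model the estimate derives from (or `NA`).
#' @param params fitted model parameters (or `NULL`).
#' @param bmdu_unbounded flag: the upper bound hit the search cap without
#'   the profile crossing the cutoff.
#' @param status `"ok"`, or a reason why no BMD exists
#'   (`"no_dose_response"`, `"no_increasing_trend"`, `"bmr_unreachable"`).
#' @return an object of class `bmd_estimate` with derived fields
#'   `precision_ratio` (`bmdu / bmdl`) and `midpoint`
#'   (`sqrt(bmdl * bmdu)`, the geometric midpoint used for ranking).
#' @export
bmd_estimate <- function(tissue, endpoint, bmd, bmdl, bmdu, ces = 1,
                         level = 0.90, model_id = NA_character_,
                         params = NULL, bmdu_unbounded = FALSE,
                         status = "ok") {
  if (status == "ok") {
    if (!(is.finite(bmdl) && is.finite(bmd) && is.finite(bmdu))) {
      contract_error("bmd, bmdl, bmdu must be finite for status 'ok'")
    }
    if (!(bmdl > 0 && bmdl <= bmd && bmd <= bmdu)) {
      contract_error("interval ordering 0 < bmdl <= bmd <= bmdu violated")
    }
  }
  structure(
    list(
      tissue = tissue, endpoint = endpoint,
      bmd = bmd, bmdl = bmdl, bmdu = bmdu,
      ces = ces, level = level, model_id = model_id, params = params,
      precision_ratio = bmdu / bmdl,
      midpoint = sqrt(bmdl * bmdu),
      bmdu_unbounded = isTRUE(bmdu_unbounded),
      status = status
    ),
    class = "bmd_estimate"
  )
}

#' @export
print.bmd_estimate <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<bmd_estimate> %s / %s: no BMD (%s)\n",
                x$tissue, x$endpoint, x$status))
    return(invisible(x))
  }
  cat(sprintf(
    "<bmd_estimate> %s / %s (%s, CES = %g)\n  BMD = %.4g  [%.4g, %.4g] %d%% CI%s  (BMDU/BMDL = %.3g)\n",
    x$tissue, x$endpoint, x$model_id, x$ces, x$bmd, x$bmdl, x$bmdu,
    round(100 * x$level), if (x$bmdu_unbounded) " (upper bound capped)" else "",
    x$precision_ratio
  ))
  invisible(x)
}

# profile log-likelihood at a fixed BMD value ---------------------------------
# returns a function(B) -> maximized log-likelihood, for the selected model
.profiler <- function(model, x, ly, n, ces, init_params) {
  q <- log(1 + ces)
  if (model == "m2") {
    function(B) {
      b <- q / B
      .ll_from_s2(.prof_s2(b * x, ly), n, ly)
    }
  } else if (model == "m3") {
    function(B) {
      s2_of_d <- function(d) .prof_s2((q / B^d) * .xpow(x, d), ly)
      grid <- seq(D_BOUNDS[1], D_BOUNDS[2], length.out = 13)
      vals <- vapply(grid, s2_of_d, numeric(1))
      i <- which.min(vals)
      opt <- optimize(s2_of_d,
                      c(max(D_BOUNDS[1], grid[i] - 0.3),
                        min(D_BOUNDS[2], grid[i] + 0.3)), tol = 1e-7)
      .ll_from_s2(min(opt$objective, vals[i]), n, ly)
    }
  } else if (model == "m4") {
    t_box <- c(-18, 22)
    grid <- seq(t_box[1], t_box[2], length.out = 9)
    step <- grid[2] - grid[1]
    function(B) {
      s2_of_t <- function(t) {
        cc <- 1 + ces + exp(t)
        b <- log((cc - 1) / (cc - 1 - ces)) / B
        r <- ly - log(cc - (cc - 1) * exp(-b * x))
        r <- r - sum(r) / n
        sum(r * r) / n
      }
      vals <- vapply(grid, s2_of_t, numeric(1))
      i <- which.min(vals)
      opt <- optimize(s2_of_t,
                      c(max(t_box[1], grid[i] - step),
                        min(t_box[2], grid[i] + step)), tol = 1e-6)
      .ll_from_s2(min(opt$objective, vals[i]), n, ly)
    }
  } else if (model == "m5") {
    # nested 1-d searches: for each candidate shape d the maximum-response
    # direction t = log(c - 1 - ces) is profiled over a wide box (the
    # optimum can sit at the c -> 1 + ces boundary), and d itself is then
    # profiled over [1, 4] by grid plus local refinement -- deterministic
    # and robust to isolated evaluations far from the MLE
    t_box <- c(-18, 22)
    t_grid <- seq(t_box[1], t_box[2], length.out = 9)
    t_step <- t_grid[2] - t_grid[1]
    xpos <- x > 0
    function(B) {
      s2_of_td <- function(t, d, z) {
        cc <- 1 + ces + exp(t)
        b <- log((cc - 1) / (cc - 1 - ces)) / B^d
        r <- ly - log(cc - (cc - 1) * exp(-b * z))
        r <- r - sum(r) / n
        sum(r * r) / n
      }
      s2_of_d <- function(d) {
        z <- numeric(n)
        z[xpos] <- x[xpos]^d
        vals <- vapply(t_grid, s2_of_td, numeric(1), d = d, z = z)
        i <- which.min(vals)
        opt <- optimize(s2_of_td,
                        c(max(t_box[1], t_grid[i] - t_step),
                          min(t_box[2], t_grid[i] + t_step)),
                        d = d, z = z, tol = 1e-6)
        min(opt$objective, vals[i])
      }
      d_grid <- seq(D_BOUNDS[1], D_BOUNDS[2], length.out = 7)
      dv <- vapply(d_grid, s2_of_d, numeric(1))
      j <- which.min(dv)
      opt_d <- optimize(s2_of_d,
                        c(max(D_BOUNDS[1], d_grid[j] - 0.5),
                          min(D_BOUNDS[2], d_grid[j] + 0.5)), tol = 1e-5)
      .ll_from_s2(min(opt_d$objective, dv[j]), n, ly)
    }
  } else {
    contract_error("profiling is undefined for m1")
  }
}

#' Estimate the benchmark dose with a profile-likelihood confidence interval
#'
#' @param selection an [select_model()] result (or a single `exp_fit`).
#' @param data the dataset the selection was computed on (a [dr_dataset()]
#'   or data frame with `dose`, `response`).
#' @param ces benchmark response as fractional increase over background
#'   (default 1: a two-fold increase, the BMD(100) convention).
#' @param level two-sided confidence level (default 0.90).
#' @param cap_mult upper search cap for the BMDU, as a multiple of the top
#'   dose (default 100); a profile that never crosses the cutoff below the
#'   cap yields a capped, flagged BMDU.
#' @param zero_rule passed to [to_modelling_response()].
#' @return a [bmd_estimate()].  When the selected model is `m1` (or shows a
#'   non-increasing trend) the result carries status `"no_dose_response"` /
#'   `"no_increasing_trend"` instead of an interval; this is a result
#'   object, not an error, so pipelines can report it.
#' @export
estimate_bmd <- function(selection, data, ces = 1, level = 0.90,
                         cap_mult = 100, zero_rule = "half_minimum") {
  if (inherits(selection, "exp_selection")) {
    fit <- selection$fits[[selection$selected]]
  } else if (inherits(selection, "exp_fit")) {
    fit <- selection
  } else {
    contract_error("`selection` must be an exp_selection or exp_fit")
  }
  if (!is.finite(level) || level <= 0 || level >= 1) {
    contract_error("`level` must lie in (0, 1)")
  }
  mf <- .model_frame(data, zero_rule)
  tissue <- if (inherits(data, "dr_dataset")) data$tissue else NA_character_
  endpoint <- if (inherits(data, "dr_dataset")) data$endpoint else NA_character_
  model <- fit$model_id
  no_bmd <- function(status) {
    bmd_estimate(tissue, endpoint, NA_real_, NA_real_, NA_real_, ces = ces,
                 level = level, model_id = model, params = fit$params,
                 status = status)
  }
  if (model == "m1") return(no_bmd("no_dose_response"))
  if (model %in% c("m2", "m3") && fit$params$b <= 0) {
    return(no_bmd("no_increasing_trend"))
  }
  bmd <- tryCatch(bmd_exp(model, fit$params, ces = ces),
                  error = function(e) NA_real_)
  if (!is.finite(bmd)) return(no_bmd("bmr_unreachable"))

  prof <- .profiler(model, mf$x, mf$ly, mf$n, ces, fit$params)
  ll_max <- fit$loglik
  ll_at_bmd <- prof(bmd)
  # the reparameterized fit must reproduce the unconstrained optimum; if the
  # profile finds a better point, adopt it as the reference
  if (ll_at_bmd > ll_max) ll_max <- ll_at_bmd
  cutoff <- qchisq(level, df = 1)
  h <- function(B) 2 * (ll_max - prof(B)) - cutoff

  # Brent root finding on the log-dose scale after bracket expansion
  solve_bound <- function(lo, hi, f_lo, f_hi) {
    r <- uniroot(function(w) h(exp(w)), c(log(lo), log(hi)),
                 f.lower = f_lo, f.upper = f_hi, tol = 1e-8)
    exp(r$root)
  }

  # lower bound
  lo <- bmd
  f_hi <- -cutoff
  lower_hit <- FALSE
  for (i in 1:60) {
    cand <- lo / 2
    hc <- h(cand)
    if (hc > 0) {
      bmdl <- solve_bound(cand, lo, hc, f_hi)
      lower_hit <- TRUE
      break
    }
    lo <- cand
    f_hi <- hc
  }
  if (!lower_hit) bmdl <- lo

  # upper bound
  cap <- cap_mult * max(mf$x)
  hi <- bmd
  f_lo <- -cutoff
  upper_hit <- FALSE
  for (i in 1:80) {
    cand <- min(hi * 2, cap)
    hc <- h(cand)
    if (hc > 0) {
      bmdu <- solve_bound(hi, cand, f_lo, hc)
      upper_hit <- TRUE
      break
    }
    hi <- cand
    f_lo <- hc
    if (hi >= cap) break
  }
  if (!upper_hit) bmdu <- cap

  bmd_estimate(tissue, endpoint,
               bmd = bmd, bmdl = min(bmdl, bmd), bmdu = max(bmdu, bmd),
               ces = ces, level = level, model_id = model,
               params = fit$params, bmdu_unbounded = !upper_hit,
               status = "ok")
}

#' Profile log-likelihood of the BMD over a dose grid
#'
#' Diagnostic companion to [estimate_bmd()]: evaluates the profile
#' log-likelihood (all nuisance parameters maximized out) at each grid dose.
#'
#' @inheritParams estimate_bmd
#' @param bmd_grid strictly positive doses at which to evaluate the profile;
#'   must lie below `cap_mult` times the top dose.
#' @return data frame with columns `bmd` and `loglik`.
#' @export
profile_curve <- function(selection, data, bmd_grid, ces = 1,
                          cap_mult = 100, zero_rule = "half_minimum") {
  if (inherits(selection, "exp_selection")) {
    fit <- selection$fits[[selection$selected]]
  } else {
    fit <- selection
  }
  mf <- .model_frame(data, zero_rule)
  cap <- cap_mult * max(mf$x)
  if (any(!is.finite(bmd_grid)) || any(bmd_grid <= 0) || any(bmd_grid >= cap)) {
    contract_error(sprintf("`bmd_grid` must lie in (0, %g)", cap))
  }
  if (fit$model_id == "m1") contract_error("no profile exists for m1")
  prof <- .profiler(fit$model_id, mf$x, mf$ly, mf$n, ces, fit$params)
  data.frame(bmd = bmd_grid,
             loglik = vapply(bmd_grid, prof, numeric(1)))
}
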