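#' The nested exponential dose-response model family
#'
#' Five nested models for a positive continuous response `y` as a function of
#' dose `x` (Slob's exponential family, the standard choice for continuous
#' dose-response data in regulatory benchmark-dose work):
#'
#' * `m1`: `y = a` (no dose effect)
#' * `m2`: `y = a * exp(b * x)`
#' * `m3`: `y = a * exp(b * x^d)`
#' * `m4`: `y = a * (c - (c - 1) * exp(-b * x))`
#' * `m5`: `y = a * (c - (c - 1) * exp(-b * x^d))`
#'
#' `a > 0` is the background response at dose zero (`f(0) = a` for every
#' member), `b` the rate parameter, `c > 1` the maximum response expressed as
#' a multiple of background (`m4`/`m5` plateau at `a * c`), and `d` a shape
#' exponent restricted to `[1, 4]`.  Errors are modelled as log-normal:
#' `log(y) ~ Normal(log f(x), sigma^2)` with a single `sigma` shared across
#' dose groups.
#'
#' For the unbounded members `m2`/`m3` the sign of `b` is left free so that
#' the no-effect hypothesis can be tested two-sided during model selection;
#' benchmark-dose inversion additionally requires an increasing trend
#' (`b > 0`).
#'
#' @name exp_family
#' @keywords internal
NULL

exp_model_ids <- c("m1", "m2", "m3", "m4", "m5")

exp_model_npar <- c(m1 = 1L, m2 = 2L, m3 = 3L, m4 = 3L, m5 = 4L)

# parameter names used by each member (besides sigma)
exp_model_parnames <- list(
  m1 = "a",
  m2 = c("a", "b"),
  m3 = c("a", "b", "d"),
  m4 = c("a", "b", "c"),
  m5 = c("a", "b", "c", "d")
)

# shape-exponent bounds; the lower bound avoids infinite slope at dose zero
D_BOUNDS <- c(1, 4)

.check_model_id <- function(model) {
  if (!is.character(model) || length(model) != 1L || !model %in% exp_model_ids) {
    contract_error(sprintf(
      "`model` must be one of %s", paste(exp_model_ids, collapse = ", ")
    ))
  }
  model
}

.check_exp_params <- function(model, params, require_sigma = FALSE) {
  .check_model_id(model)
  need <- exp_model_parnames[[model]]
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    contract_error(sprintf(
      "model %s requires parameter(s) %s", model, paste(missing, collapse = ", ")
    ))
  }
  a <- params[["a"]]
  if (!is.finite(a) || a <= 0) contract_error("background `a` must be > 0")
  if ("b" %in% need && !is.finite(params[["b"]])) {
    contract_error("rate `b` must be finite")
  }
  if (model %in% c("m4", "m5")) {
    if (params[["b"]] <= 0) contract_error("rate `b` must be > 0 for m4/m5")
    cc <- params[["c"]]
    # c = 1 is admitted as the no-effect boundary (m4/m5 collapse to m1)
    if (!is.finite(cc) || cc < 1) {
      contract_error("maximum-response multiple `c` must be >= 1")
    }
  }
  if ("d" %in% need) {
    d <- params[["d"]]
    if (!is.finite(d) || d < D_BOUNDS[1] || d > D_BOUNDS[2]) {
      contract_error(sprintf(
        "shape `d` must lie in [%g, %g]", D_BOUNDS[1], D_BOUNDS[2]
      ))
    }
  }
  if (require_sigma) {
    s <- params[["sigma"]]
    if (is.null(s) || !is.finite(s) || s <= 0) {
      contract_error("`sigma` (log-scale residual SD) must be > 0")
    }
  }
  invisible(params)
}

# log mean response, computed on the log scale throughout so that extreme
# rate parameters cannot overflow
exp_log_mean <- function(model, a, b = NULL, c = NULL, d = NULL, x) {
  la <- log(a)
  switch(model,
    m1 = rep(la, length(x)),
    m2 = la + b * x,
    m3 = la + b * .xpow(x, d),
    m4 = la + log(c - (c - 1) * exp(-b * x)),
    m5 = la + log(c - (c - 1) * exp(-b * .xpow(x, d)))
  )
}

# x^d with the convention 0^d = 0 (d >= 1 here, so this is the limit value)
.xpow <- function(x, d) {
  z <- x^d
  z[x == 0] <- 0
  z
}

#' Evaluate the expected response of a nested exponential model
#'
#' @param model model id, one of `"m1"`..`"m5"`.
#' @param params named list (or vector) of parameters; which of `a`, `b`,
#'   `c`, `d` are required depends on `model`.
#' @param x numeric vector of doses (>= 0).
#' @return numeric vector of expected responses; `exp_mean(model, params, 0)`
#'   equals `a` for every model.
#' @export
#' @examples
#' exp_mean("m4", list(a = 2, b = 1, c = 5), c(0, 1, 100))
exp_mean <- function(model, params, x) {
  params <- as.list(params)
  .check_exp_params(model, params)
  if (any(!is.finite(x)) || any(x < 0)) contract_error("doses `x` must be >= 0")
  exp(exp_log_mean(model, params$a, params$b, params$c, params$d, x))
}

#' Closed-form benchmark dose for a nested exponential model
#'
#' Inverts the mean curve at the benchmark response `a * (1 + ces)`, i.e. a
#' fractional increase of `ces` over background (`ces = 1` is a 100%, or
#' two-fold, increase -- the BMD(100) convention for genotoxicity data).
#'
#' Closed forms: `m2`: `log(1 + ces) / b`; `m3`: `(log(1 + ces) / b)^(1/d)`;
#' `m4`: `-(1/b) * log((c - 1 - ces) / (c - 1))`; `m5`: the `m4` quantity
#' raised to `1/d`.
#'
#' @inheritParams exp_mean
#' @param ces benchmark response as a fractional increase over background
#'   (> 0; default 1, a two-fold increase).
#' @return the benchmark dose (a single positive number).
#' @export
#' @examples
#' bmd_exp("m2", list(a = 1, b = log(2)), ces = 1) # exactly 1
bmd_exp <- function(model, params, ces = 1) {
  params <- as.list(params)
  .check_exp_params(model, params)
  if (!is.finite(ces) || ces <= 0) contract_error("`ces` must be > 0")
  if (model == "m1") {
    contract_error("m1 has no dose dependence: no benchmark dose exists")
  }
  if (model %in% c("m2", "m3") && params$b <= 0) {
    contract_error("no increasing dose-response (b <= 0): benchmark dose undefined")
  }
  q <- log(1 + ces)
  if (model %in% c("m4", "m5")) {
    cc <- params$c
    if (cc <= 1 + ces) {
      contract_error(sprintf(
        "benchmark response unreachable: asymptote a*c = %g does not exceed a*(1+ces) = %g",
        params$a * cc, params$a * (1 + ces)
      ))
    }
    core <- -log((cc - 1 - ces) / (cc - 1)) / params$b
  } else {
    core <- q / params$b
  }
  if (model %in% c("m3", "m5")) core^(1 / params$d) else core
}

#' Log-normal log-likelihood of a nested exponential model
#'
#' Exact log density of the observed responses under
#' `log(y) ~ Normal(log f(x), sigma^2)`, including the `-sum(log y)` Jacobian
#' of the log transform.  The Jacobian is constant across models fitted to
#' the same data, so likelihood-ratio statistics are unaffected by it.
#'
#' @inheritParams exp_mean
#' @param params named list of parameters, including `sigma` (> 0).
#' @param dose numeric vector of doses.
#' @param response numeric vector of strictly positive responses.
#' @return the log-likelihood (a single number).
#' @export
loglik_lognormal <- function(model, params, dose, response) {
  params <- as.list(params)
  .check_exp_params(model, params, require_sigma = TRUE)
  if (length(dose) != length(response)) {
    contract_error("`dose` and `response` must have equal length")
  }
  if (any(!is.finite(response)) || any(response <= 0)) {
    contract_error("responses must be strictly positive for log-normal modelling")
  }
  if (any(!is.finite(dose)) || any(dose < 0)) contract_error("doses must be >= 0")
  lnf <- exp_log_mean(model, params$a, params$b, params$c, params$d, dose)
  sum(dnorm(log(response), mean = lnf, sd = params$sigma, log = TRUE)) -
    sum(log(response))
}
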