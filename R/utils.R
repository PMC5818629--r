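# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

geomean <- function(x) exp(mean(log(x)))

#' Evaluate code under a temporary, seeded RNG state
#'
#' Runs `code` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state so library calls never disturb a user's
#' simulation stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Map a p-value to the study's significance tier letters
#'
#' Tiers follow the convention used in dose-group contrast reporting:
#' `a` for p < 0.0001, `b` for p < 0.001, `c` for p < 0.01, `d` for p < 0.05
#' and `ns` otherwise.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of tiers.
#' @export
#' @examples
#' p_tier(c(0.3, 0.03, 0.0003))
p_tier <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p < 0.05] <- "d"
  out[p < 0.01] <- "c"
  out[p < 0.001] <- "b"
  out[p < 0.0001] <- "a"
  out[is.na(p)] <- NA_character_
  out
}

# stop() with a class so callers can distinguish contract violations
contract_error <- function(msg, class = "bmdrank_contract_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(msg) {
  contract_error(msg, class = c("bmdrank_validation_error", "bmdrank_contract_error"))
}
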