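# independent oracles and small fixture builders used across test files

# numeric benchmark-dose oracle: bisection (uniroot) on the mean curve,
# independent of the closed-form inversion
bmd_by_bisection <- function(model, params, ces = 1) {
  target <- params$a * (1 + ces)
  f <- function(x) exp_mean(model, params, x) - target
  hi <- 1
  for (i in 1:200) {
    if (f(hi) > 0) break
    hi <- hi * 2
  }
  stopifnot(f(hi) > 0)
  uniroot(f, c(0, hi), tol = 1e-13 * hi)$root
}

# brute-force Poisson likelihood maximization: each group's rate maximized
# by 1-d numeric search (groups are separable), never via glm
pois_group_ll <- function(y, D) {
  nll <- function(lr) -sum(dpois(y, exp(lr) * D, log = TRUE))
  opt <- optimize(nll, c(-40, 10), tol = 1e-12)
  -opt$objective
}

pois_brute_overall_lr <- function(dose, y, D) {
  ll_full <- sum(vapply(split(seq_along(y), dose), function(i) {
    pois_group_ll(y[i], D[i])
  }, numeric(1)))
  ll_null <- pois_group_ll(y, D)
  2 * (ll_full - ll_null)
}

pois_brute_contrast_lr <- function(dose, y, D, d0) {
  merged <- ifelse(dose == d0, 0, dose)
  ll_full <- sum(vapply(split(seq_along(y), dose), function(i) {
    pois_group_ll(y[i], D[i])
  }, numeric(1)))
  ll_con <- sum(vapply(split(seq_along(y), merged), function(i) {
    pois_group_ll(y[i], D[i])
  }, numeric(1)))
  2 * (ll_full - ll_con)
}

# continuous dataset straight from a mean curve plus log-normal noise
make_continuous_ds <- function(model, params, sigma = 0, seed = 1,
                               doses = c(0, 0.1, 0.2, 0.39, 0.78, 1.56, 3.13,
                                         6.25, 12.5, 25, 50),
                               n_per = 7, n_control = 14,
                               tissue = "liver", endpoint = "dna_adducts") {
  em <- endpoint_model(endpoint, kind = "continuous_lognormal",
                       model_id = model, params = params, sigma = sigma)
  generate_dataset(study_design(doses, n_per, n_control), em, seed = seed,
                   tissue = tissue)
}

# count-type dataset with fully specified rows (3 dose levels minimum)
make_count_ds <- function(dose, count, denominator, endpoint = "lacz_mf",
                          tissue = "bone_marrow") {
  dr_dataset(
    data.frame(animal_id = seq_along(dose), dose = dose, count = count,
               denominator = denominator),
    tissue = tissue, endpoint = endpoint
  )
}

# synthetic BMD estimate with a chosen interval (for ranking/proportionality
# fixtures)
fake_estimate <- function(tissue, bmdl, bmdu, endpoint = "lacz_mf",
                          bmd = sqrt(bmdl * bmdu), model_id = "m4",
                          params = NULL) {
  bmd_estimate(tissue, endpoint, bmd = bmd, bmdl = bmdl, bmdu = bmdu,
               model_id = model_id, params = params)
}
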