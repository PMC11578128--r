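## Shared fixtures for the test suite.  Everything is generated in code.

ref_params <- function() lamivudine_params()
ref_model <- function() lamivudine_model()
q24 <- function() dose_regimen(300, 24)
q12 <- function() dose_regimen(150, 12)

## A small, fast study for estimation tests: morning-style rich sampling,
## both matrices, no sample loss.
small_design <- function(n = 8L) {
  study_design(n_q12 = 0L, n_q24 = n, n_morning = n, missingness = 0)
}

small_study <- function(seed, n = 8L, model = ref_model()) {
  simulate_study(small_design(n), model, seed = seed)
}

## Loosened outer tolerance for throwaway fits in tests.
fast_control <- list(rel.tol = 1e-6, iter.max = 200L)

## Independent scalar re-implementation of the per-subject joint -2LL used
## as a dual-implementation oracle: plain loops, calling the public scalar
## concentration functions, no shared code with the vectorised likelihood.
naive_joint_neg2ll <- function(table, theta, omega, sigma2, eta) {
  p <- individual_params(theta, eta)
  total <- 0
  for (r in seq_len(nrow(table))) {
    row <- table[r, ]
    if (!row$MATRIX %in% c("plasma", "milk") || row$MDV != 0 ||
        row$BLQ != 0) next
    reg <- dose_regimen(row$DOSE, row$TAU)
    f <- if (row$MATRIX == "plasma") plasma_conc(p, reg, row$TIME) / 1000
         else milk_conc(p, reg, row$TIME) / 1000
    sdf <- max(sqrt(sigma2[[row$MATRIX]]) * f, 1e-6)
    y <- row$DV / 1000
    total <- total + log(2 * pi) + 2 * log(sdf) + ((y - f) / sdf)^2
  }
  total + 3 * log(2 * pi) +
    determinant(omega, logarithm = TRUE)$modulus[1] +
    drop(t(eta) %*% solve(omega) %*% eta)
}
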