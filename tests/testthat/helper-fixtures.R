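## Shared small fixtures, built in code at test time.

## small cohort cache so expensive fixtures are built once per run
.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(name = "default", builder = NULL) {
  if (!exists(name, .fixture_env)) {
    co <- if (is.null(builder)) {
      simulate_cohort(simulation_config(n_patients = 400, n_snps = 60,
                                        seed = 20260912))
    } else builder()
    assign(name, co, .fixture_env)
  }
  get(name, .fixture_env)
}

## deterministic dosage matrix with a planted effect-free structure
toy_dosage <- function(n = 200, m = 6, seed = 42, maf = 0.3) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, maf), n, m,
              dimnames = list(sprintf("P%03d", 1:n),
                              sprintf("s%02d", 1:m)))
  d
}

toy_covariates <- function(n = 200, seed = 43) {
  set.seed(seed)
  data.frame(PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
             PC4 = rnorm(n), PC5 = rnorm(n), age = rnorm(n, 65, 7),
             pga = rbeta(n, 2, 20), snv_density = rlnorm(n, 0, 0.5),
             ISUP_GG = sample(1:5, n, TRUE),
             T_category = sample(c("T2", "T3"), n, TRUE),
             PSA = rlnorm(n, 2, 0.5), row.names = sprintf("P%03d", 1:n))
}
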