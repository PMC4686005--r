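# Lazily built, memoised phantom fixtures shared across test files. Heavy
# objects (48^3 cohorts and their pairwise-LNCC caches) are built at most
# once per test run.

.vx_fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .vx_fixtures, inherits = FALSE))
    assign(name, builder(), envir = .vx_fixtures)
  get(name, envir = .vx_fixtures, inherits = FALSE)
}

# Tiny 24^3 cohort for structural/contract tests.
tiny_cohort <- function() fixture("tiny_cohort", function() {
  spec <- phantom_spec(grid = c(24, 24, 24))
  generate_cohort(spec, c(normal = 2, switch_a = 2, switch_b = 2), seed = 42)
})

# Default-spec 48^3 cohort, 10 per condition: the leave-one-out comparison
# cohort.
loocv_cohort <- function() fixture("loocv_cohort", function() {
  generate_cohort(phantom_spec(),
                  c(normal = 10, switch_a = 10, switch_b = 10), seed = 101)
})

loocv_cache <- function() fixture("loocv_cache", function() {
  build_lncc_cache(loocv_cohort(), sigma_g = 2)
})

# 11-per-condition cohort for the size sweep (sizes up to 10 need N-1 >= 10)
# and the imbalance study.
sweep_cohort <- function() fixture("sweep_cohort", function() {
  generate_cohort(phantom_spec(),
                  c(normal = 11, switch_a = 11, switch_b = 11), seed = 202)
})

sweep_cache <- function() fixture("sweep_cache", function() {
  build_lncc_cache(sweep_cohort(), sigma_g = 2)
})

# LOOCV cohort extended with four novel-morphology subjects for the
# missing-pathology probe.
missing_cohort <- function() fixture("missing_cohort", function() {
  spec <- phantom_spec(conditions = c("normal", "switch_a", "switch_b",
                                      "fallot"))
  generate_cohort(spec, c(normal = 10, switch_a = 10, switch_b = 10,
                          fallot = 4), seed = 101)
})

missing_cache <- function() fixture("missing_cache", function() {
  build_lncc_cache(missing_cohort(), sigma_g = 2)
})
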