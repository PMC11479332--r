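# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

quiet_participant <- function(seed = 3, ...) {
  args <- utils::modifyList(list(mass = 70, noise_sd = 0,
                                 cardiac_amplitude = 0, seed = seed),
                            list(...))
  do.call(virtual_participant, args)
}

# corner forces that place the combined CoM exactly at (x, y): the inverse
# of the moment balance, used as an independent construction in tests
forces_for_com <- function(x, y, bed, total = 1000) {
  a <- 2 * x / bed$width_w
  b <- 2 * y / bed$length_l
  data.frame(LH = total * (1 + a + b) / 4, RH = total * (1 - a + b) / 4,
             LF = total * (1 + a - b) / 4, RF = total * (1 - a - b) / 4)
}

# small low-noise cohort shared by the heavier classifier tests
small_cohort_features <- function() {
  cached("small_cohort_features", function() {
    coh <- generate_cohort(6, master_seed = 42, noise_sd = 0.05,
                           pose_duration = 90)
    # 30-s intermediate holds of the scaled protocol are sub-window and skipped
    suppressWarnings(extract_cohort_features(coh))
  })
}
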