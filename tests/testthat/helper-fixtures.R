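# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env()

memo <- function(key, fn) {
  key <- paste0("memo_", key)
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, fn(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env, inherits = FALSE)
}

# one clean 20-s record (HR 60, light noise) plus its preprocessed window
clean_window <- function() {
  memo("clean_window", function() {
    rec <- generate_record(
      subject_profile(hr_bpm = 60,
                      noise_sd = c(ppg = 0.01, ecg = 0.01, abp = 0.3)),
      duration_s = 20, fs = 125, seed = 42)
    list(rec = rec, pre = preprocess_window(rec), truth = attr(rec, "truth"))
  })
}

# small feature table extracted from a 10-subject cohort
small_cohort_features <- function() {
  memo("small_cohort_features", function() {
    recs <- generate_cohort(10, seed = 7,
                            noise_sd = c(ppg = 0.01, ecg = 0.01, abp = 0.5))
    list(recs = recs, features = records_to_features(recs))
  })
}

# one synthetic PPG-like pulse sampled on [0, 1] s at fs
synth_pulse <- function(fs = 125) {
  u <- seq(0, 1, length.out = fs + 1)
  exp(-(u - 0.30)^2 / (2 * 0.095^2)) + 0.35 * exp(-(u - 0.62)^2 / (2 * 0.12^2))
}
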