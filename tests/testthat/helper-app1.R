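# Location of the Application 1 supplementary diary data, when a user has
# packaged it.  The study's diary CSV (25 smoking college students in
# 12-step recovery; daily tobacco use, negative affect and substance
# craving) is distributed as supplementary material of the source study
# and is not redistributed here; to run the real-data acceptance checks,
# export it to inst/extdata/app1/diary.csv in the package's long format
# (columns patient_id, day, tobacco, negaff, craving, optionally gender
# and age) and reinstall.
app1_csv_path <- function() {
  p <- system.file("extdata", "app1", "diary.csv", package = "bhvar")
  if (nzchar(p)) p else NA_character_
}

app1_schema <- list(patient_id = "patient_id", day = "day",
                    variables = c("tobacco", "negaff", "craving"))

# Study preprocessing: flank-mean imputation of missing days, log(x + 1)
# (tobacco is recorded on a 0-5 scale so a unit offset precedes the log),
# standardization to mean 0 / variance 1, linear detrending on the day
# index.
app1_preprocess <- function(panel) {
  preprocess(panel, preprocess_config(imputation = "flank_mean",
                                      log_transform = TRUE, log_offset = 1,
                                      standardize = TRUE, detrend = TRUE))
}
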