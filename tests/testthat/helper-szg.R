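# Shared fixtures, all built in code.

# a small random recording with labelled channels
make_recording <- function(n_ch = 4, rate = 32, dur = 10, seed = 1,
                           labels = paste0("C", seq_len(n_ch))) {
  set.seed(seed)
  sig <- matrix(rnorm(n_ch * rate * dur, sd = 30), n_ch)
  recording(sig, rate, labels)
}

# one annotated seizure
make_ann <- function(onset = 700, dur = 60, side = "right",
                     category = "simultaneous", scalp_onset = NULL) {
  seizure_annotation(onset, onset + dur, side, category, scalp_onset)
}

# tiny low-rate generator config: full-length recordings (the 10-min
# horizon fixes the time axis) but cheap in samples
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_patients = 2L, n_unilateral = 1L,
                                 rate = 32L, seed = 5L), list(...))
  do.call(generator_config, args)
}

# heavyweight shared objects for the acceptance suite, built once per
# test run: one simulation of the 19-patient strong cohort yields both
# the iEEG three-class and the scalp four-class datasets
.szg_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.szg_cache[[name]])) .szg_cache[[name]] <- builder()
  .szg_cache[[name]]
}

strong_datasets <- function() {
  cached("strong_datasets", function() {
    simulate_datasets(
      szg_preset("strong_separation", seed = 42),
      list(ieeg3 = list(view = "ieeg", metric = "waxman"),
           scalp4 = list(view = "scalp", metric = "waxman",
                         scheme = "four_class")),
      seed = 1)
  })
}

# the reference classifier configuration used across acceptance checks
accept_cnn_spec <- function(input_dim, n_classes = 3L, epochs = 5L) {
  classifier_spec("cnn", k = 1L, n_classes = n_classes,
                  input_dim = input_dim, seed = 1, epochs = epochs,
                  batch_size = 64, pool_widths = c(4L, 2L))
}
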