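# shared fixtures, built in code and memoised per test run

.fx <- new.env(parent = emptyenv())

fx_sched <- function() {
  if (is.null(.fx$sched)) .fx$sched <- make_frame_schedule(default_frame_spec())
  .fx$sched
}

fx_ref <- function() {
  if (is.null(.fx$ref)) .fx$ref <- simulate_reference_tac()
  .fx$ref
}

fx_basis <- function() {
  if (is.null(.fx$basis)) .fx$basis <- srtm_basis(fx_ref(), fx_sched())
  .fx$basis
}

fx_phantom <- function() {
  if (is.null(.fx$phantom)) .fx$phantom <- make_phantom()
  .fx$phantom
}

# single-region cohort config used across recovery tests
fx_config <- function(...) {
  cohort_config(
    regions = data.frame(region = "striatum", bp0 = 2.5, volume_ml = 42.6,
                         stringsAsFactors = FALSE),
    ...)
}
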