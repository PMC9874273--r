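# The default-configuration wake run takes a few minutes, so it is
# simulated once per test session and shared by every test that needs it.
.wake_cache <- new.env(parent = emptyenv())

default_wake <- function() {
  if (is.null(.wake_cache$field)) {
    .wake_cache$field <- simulate_wake(wake_config())
  }
  .wake_cache$field
}

# small, fast shedding run for qualitative solver tests
small_wake <- function() {
  if (is.null(.wake_cache$small)) {
    .wake_cache$small <- simulate_wake(
      wake_config(resolution = 10, n_periods = 20, sample_every = 100,
                  field_every = 1000)
    )
  }
  .wake_cache$small
}
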