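# fixtures shared across test files; everything generated in code

# a small block of valid logger records
make_records <- function(n = 10, chamber_id = 1L, t0 = 0, co2_sample = 395,
                         mode = "measure") {
  tibble::tibble(
    timestamp = t0 + seq_len(n) - 1,
    chamber_id = as.integer(chamber_id),
    co2_ref = 400,
    co2_sample = co2_sample,
    h2o_ref = 10,
    h2o_sample = 12,
    flow_velocity = 0.83,
    temp_chamber = 25,
    pressure = 101300,
    ppfd_set = 1000,
    ppfd_transmitted = 1000,
    mode = mode
  )
}

# random valid records for round-trip tests
random_records <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    timestamp = cumsum(runif(n, 0.5, 2)),
    chamber_id = sample(1:12, n, replace = TRUE),
    co2_ref = runif(n, 380, 420),
    co2_sample = runif(n, 380, 420),
    h2o_ref = runif(n, 5, 15),
    h2o_sample = runif(n, 5, 15),
    flow_velocity = runif(n, 0.5, 2.7),
    temp_chamber = runif(n, 18, 30),
    pressure = runif(n, 95000, 105000),
    ppfd_set = runif(n, 0, 1500),
    ppfd_transmitted = runif(n, 0, 1500),
    mode = "measure"
  )
}

# default transient parameters used across model tests
default_params <- function(...) {
  args <- list(...)
  do.call(transient_params,
          utils::modifyList(list(F_mol = 0.34, V = 19.3, S0 = 0, Sx = 3),
                            args))
}
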