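# One structured config drives the whole cross-stage experiment. The config
# is a plain nested list, round-trippable through YAML, and every stochastic
# stage derives its seed from the single master seed.

#' Default experiment configuration
#'
#' Nested list mirroring the recorded study's conditions: stimulus set over
#' {L+M, L-M} x temporal frequencies 1-20 Hz plus a blank, 666 ms stimuli
#' with 166 ms contrast ramps, contrasts at behavioral threshold (clipped at
#' the display gamut caps 0.86 / 0.19), magno and parvo LNP neurons with
#' ~100 ms latency, and the population and cone model defaults documented in
#' [population_model()] and [cone_mosaic_model()].
#'
#' @param seed master seed.
#' @return a named list (the config).
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    stimulus = list(
      directions = c("L_plus_M", "L_minus_M"),
      frequencies = c(1, 2, 5, 10, 20),
      duration = 0.666, ramp = 0.166,
      eccentricity = 5, aperture_sigma = 0.4),
    tcsf = NULL,          # NULL = tcsf_model() defaults
    behavior = list(pc = 0.82, criterion = NULL),  # NULL = pc_to_dprime(pc)
    neurons = list(n_magno = 4, n_parvo = 4, latency = 0.1,
                   surround_delay = 0.010),
    trials = list(n_per_condition = 40, dt = 0.001, pad = 0.3),
    snr = list(bootstrap_B = 500,
               sweep_offsets = seq(0, 0.2, by = 0.04)),
    population = NULL,    # NULL = population_model() defaults
    cones = NULL          # NULL = cone_mosaic_model() defaults
  )
}

#' Read / write an experiment config as YAML
#' @param path file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param config a config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate an experiment config
#'
#' Schema check: required sections and fields must be present with sane
#' values; violations report the offending field path. Missing optional
#' sections are filled with defaults.
#'
#' @param config a config list.
#' @return the validated, default-completed config.
#' @export
validate_config <- function(config) {
  config <- modifyList(default_config(), config)
  fail <- function(path, why)
    stop_lgnsnr(sprintf("config error at %s: %s", path, why),
                "lgnsnr_config_error")
  if (is.null(config$seed) || !is.finite(config$seed))
    fail("seed", "must be a finite integer")
  st <- config$stimulus
  if (length(st$frequencies) > 0 && any(st$frequencies <= 0))
    fail("stimulus.frequencies", "must be > 0")
  if (2 * st$ramp > st$duration)
    fail("stimulus.ramp", "2*ramp exceeds duration")
  if (st$eccentricity < 0) fail("stimulus.eccentricity", "must be >= 0")
  bh <- config$behavior
  if (!is.null(bh$pc) && (bh$pc <= 0.5 || bh$pc >= 1))
    fail("behavior.pc", "must lie in (0.5, 1)")
  if (config$trials$n_per_condition < 2)
    fail("trials.n_per_condition", "need at least 2 trials")
  if (config$trials$dt <= 0) fail("trials.dt", "must be > 0")
  config
}
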