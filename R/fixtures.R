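#' Registry of reference parameter sets
#'
#' Named parameter sets for the worked examples shipped with the package:
#' single-cell Hill (`n = 11, k_H = 0.136`) and protein-sequestration
#' (`A = 0.0659, k_d = 1e-5`) oscillators, their identical- and
#' nonidentical-cell coupled versions at `s = 20`, and the simulation
#' settings used for the waveform comparison at `alpha = 0.60139`.
#'
#' @param key Fixture key; see [list_fixtures()].
#' @return `fixture()`: a list with `key`, `family`, `params` (flat named
#'   list) and `note`. `fixture_model()`: the corresponding `cell_model`.
#'   `list_fixtures()`: a data.frame of keys, families and notes.
#' @examples
#' list_fixtures()
#' m <- fixture_model("ex4.1.1-HT")
#' @name fixtures
NULL

.fixture_registry <- list(
  "ex3.1" = list(
    family = "single_cell", repression = "HT",
    params = list(n = 11, k_H = 0.136, alpha = 1),
    note = "single-cell Hill oscillator; Hopf at alpha ~ 0.545174"),
  "ex3.2" = list(
    family = "single_cell", repression = "PS",
    params = list(A = 0.0659, k_d = 1e-5, alpha = 1),
    note = "single-cell protein-sequestration oscillator; Hopf at alpha ~ 0.533809"),
  "ex4.1.1-HT" = list(
    family = "coupled_identical", repression = "HT",
    params = list(n = 11, k_H = 0.136, alpha = 0.4742, coupling = 0.05, s = 20, N = 2),
    note = "two identical Hill cells at the (0.05, 0.4742) bifurcation value"),
  "ex4.1.1-PS" = list(
    family = "coupled_identical", repression = "PS",
    params = list(A = 0.0659, k_d = 1e-5, alpha = 0.4766, coupling = 0.05, s = 20, N = 2),
    note = "two identical protein-sequestration cells at (0.05, 0.4766)"),
  "ex4.2-HT" = list(
    family = "coupled_nonidentical", repression = "HT",
    params = list(n = 11, k_H = 0.136, alpha = 0.5165, coupling = 0.05,
                  s = 20, sigma = 1.05),
    note = "nonidentical Hill pair (sigma = 1.05) at (0.05, 0.5165)"),
  "ex4.2-PS" = list(
    family = "coupled_nonidentical", repression = "PS",
    params = list(A = 0.0659, k_d = 1e-5, alpha = 0.5043, coupling = 0.038,
                  s = 20, sigma = 1.05),
    note = "nonidentical protein-sequestration pair at (0.038, 0.5043)"),
  "remark2-HT" = list(
    family = "single_cell", repression = "HT",
    params = list(n = 11, k_H = 0.04, alpha = 1),
    note = "Hill oscillator with the narrow-threshold half-saturation 0.04 at alpha = 1"),
  "fig4" = list(
    family = "single_cell", repression = "HT",
    params = list(n = 11, k_H = 0.136, alpha = 0.60139,
                  x0_1 = 0.1, x0_2 = 0.1, x0_3 = 0.1),
    note = "Hill waveform run matched to the protein-sequestration waveform at alpha = 0.60139")
)

#' @rdname fixtures
#' @export
fixture <- function(key) {
  fx <- .fixture_registry[[key]]
  if (is.null(fx)) stop("unknown fixture '", key, "'; see list_fixtures()")
  c(list(key = key), fx)
}

#' @rdname fixtures
#' @export
list_fixtures <- function() {
  data.frame(key = names(.fixture_registry),
             family = vapply(.fixture_registry, `[[`, "", "family"),
             repression = vapply(.fixture_registry, `[[`, "", "repression"),
             note = vapply(.fixture_registry, `[[`, "", "note"),
             row.names = NULL)
}

#' @rdname fixtures
#' @export
fixture_spec <- function(key) {
  fx <- fixture(key)
  if (fx$repression == "HT")
    hill_repression(fx$params$n, fx$params$k_H)
  else
    seq_repression(fx$params$A, fx$params$k_d)
}

#' @rdname fixtures
#' @export
fixture_model <- function(key) {
  fx <- fixture(key)
  spec <- fixture_spec(key)
  p <- fx$params
  switch(fx$family,
    single_cell = single_cell_model(spec, p$alpha),
    coupled_identical = coupled_identical_model(spec, p$alpha, p$coupling,
                                                p$s, p$N),
    coupled_nonidentical = coupled_nonidentical_model(spec, p$alpha,
                                                      p$coupling, p$s,
                                                      p$sigma),
    stop("unsupported fixture family"))
}

#' @rdname fixtures
#' @export
fixture_initial_state <- function(key) {
  p <- fixture(key)$params
  ks <- grep("^x0_", names(p), value = TRUE)
  if (length(ks)) unlist(p[ks], use.names = FALSE) else NULL
}

#' Flat key-value parameter configs
#'
#' Round-trips a flat named list of scalars to a JSON file, for scripting
#' parameter sweeps from the command line.
#'
#' @param params Flat named list of numeric/character scalars.
#' @param path File path.
#' @return `read_model_config()` returns the named list.
#' @export
write_model_config <- function(params, path) {
  stopifnot(is.list(params), !is.null(names(params)))
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Representative segmentation-clock parameter set
#'
#' A synthetic parameter set for the zebrafish segmentation-clock pair
#' chosen by this package to exercise the numeric bifurcation machinery:
#' rates are balanced so every variable is bounded (saturating degradation
#' rates exceed maximal production), the repressor equilibrium sits on the
#' steep flank of its Hill term, and the isolated cell undergoes a Hopf
#' bifurcation in the transcription rate `nu1` near 0.245. It is not a
#' published calibration; see the methods vignette for the construction.
#'
#' @param nu1 Basal transcription rate (the bifurcation parameter).
#' @param nu_c Coupling strength.
#' @param sigma Timescale factor of the second cell.
#' @return A `cell_model` of family `segclock_pair`.
#' @export
segclock_example_model <- function(nu1 = 0.25, nu_c = 0, sigma = 1) {
  segclock_model(nu1 = nu1, nu2 = 0.2, nu3 = 0.5, nu4 = 0.2, nu5 = 0.2,
                 nu6 = 0.2, nu7 = 0.2, nu8 = 0.3,
                 k1 = 0.1, k2 = 0.03, k4 = 0.05, k6 = 0.02, k7 = 0.3,
                 k8 = 0.1, n = 2, h = 3, nu_c = nu_c, sigma = sigma)
}
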