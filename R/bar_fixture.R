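#' Stimulus scenarios for the cardiac beta1-adrenergic network
#'
#' The five standard perturbation scenarios used to exercise the
#' 25-variable beta1-adrenergic signalling model and its reductions, each
#' a 400 s transient application followed by 400 s of washout:
#' `iso_1uM` (1 µM isoproterenol, the reference/reduction condition),
#' `iso_0p05uM` (20-fold lower agonist dose), `fsk_10uM` (10 µM forskolin,
#' direct adenylate-cyclase activation), `ibmx_100uM` (100 µM IBMX,
#' phosphodiesterase inhibition) and `pp1_knockout` (total protein
#' phosphatase-1 transiently set to 0). Parameter names follow the
#' total-concentration convention of the published model (`Ltot`,
#' `Fsktot`, `IBMXtot`, `PP1tot`).
#'
#' @param model optional loaded model; when given, the `pp1_knockout`
#'   scenario's washout value is taken from the model's `PP1tot`
#'   parameter (the knockout is transient, so PP1 returns to its resting
#'   total after the window).
#' @param t_off,t_end,n_out protocol timing (defaults 400 s + 400 s).
#' @return named list of five [scenario()]s.
#' @export
bar_scenarios <- function(model = NULL, t_off = 400, t_end = 800,
                          n_out = 2000) {
  pp1_rest <- if (!is.null(model) && "PP1tot" %in% names(model$params)) {
    model$params[["PP1tot"]]
  } else {
    NA_real_
  }
  proto <- function(parameter, on, off = 0) {
    stimulus_protocol(parameter, on_value = on, off_value = off,
                      t_on = 0, t_off = t_off, t_end = t_end, n_out = n_out)
  }
  list(
    iso_1uM = scenario("iso_1uM", proto("Ltot", 1)),
    iso_0p05uM = scenario("iso_0p05uM", proto("Ltot", 0.05)),
    fsk_10uM = scenario("fsk_10uM", proto("Fsktot", 10)),
    ibmx_100uM = scenario("ibmx_100uM", proto("IBMXtot", 100)),
    pp1_knockout = scenario("pp1_knockout", proto("PP1tot", 0, pp1_rest)))
}

bar_variant_files <- c(full25 = "bar_full25.model",
                       reduced6 = "bar_reduced6.model",
                       reduced4 = "bar_reduced4.model")

#' Load the beta1-adrenergic model fixture
#'
#' Loads one of the three declarative transcriptions of the cardiac
#' beta1-adrenergic signalling model: the original 25-state
#' differential-algebraic system (12 ODEs + 13 implicit algebraic
#' equations) or its 6- and 4-ODE reductions. The transcription must be
#' prepared from the published model definition (the full equations and
#' parameter/initial-condition tables are distributed with the original
#' publications, not reprinted here) either as a declarative model file
#' (see [read_model_file()]) or as CellML. This package does not bundle a
#' transcription; when none is found at `path`, loading signals an
#' explicit `phaseloop_fixture_unavailable` condition — never a silent
#' fallback — and the synthetic cascade generator is the supported
#' testbed instead.
#'
#' @param variant `"full25"`, `"reduced6"` or `"reduced4"`.
#' @param path path to the transcription (`.model` declarative file or
#'   `.cellml`); defaults to `bar_<variant>.model` under the package's
#'   `extdata` directory.
#' @return a [network_model()]; the structural counts of the requested
#'   variant are validated (full25: 25 states, 12 ode + 13 implicit;
#'   reduced6: 6 ode; reduced4: 4 ode).
#' @export
load_bar_model <- function(variant = c("full25", "reduced6", "reduced4"),
                           path = NULL) {
  variant <- match.arg(variant)
  if (is.null(path)) {
    path <- system.file("extdata", bar_variant_files[[variant]],
                        package = "phaseloop")
  }
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    stop(errorCondition(
      sprintf(paste0(
        "beta-adrenergic fixture unavailable: no transcription found for variant '%s'.\n",
        "Transcribe the published model (equations + parameter/initial-condition tables)\n",
        "to a declarative model file and pass its path, or place it at inst/extdata/%s.\n",
        "Synthetic cascades (generate_cascade) cover the analysis pipeline without it."),
        variant, bar_variant_files[[variant]]),
      class = c("phaseloop_fixture_unavailable", "phaseloop_error")))
  }
  m <- if (tolower(tools::file_ext(path)) == "cellml") {
    import_cellml(path)
  } else {
    read_model_file(path)
  }
  n_ode <- sum(m$kind == "ode")
  n_imp <- sum(m$kind == "implicit_algebraic")
  ok <- switch(variant,
               full25 = length(m$states) == 25 && n_ode == 12 && n_imp == 13,
               reduced6 = n_ode == 6,
               reduced4 = n_ode == 4)
  if (!ok) {
    stop_phaseloop(sprintf(
      "transcription at '%s' does not match variant '%s' (found %d states, %d ode, %d implicit)",
      path, variant, length(m$states), n_ode, n_imp),
      "phaseloop_fixture_error")
  }
  m
}

#' Accuracy table of the 6- and 4-variable reductions
#'
#' Simulates the full and both reduced beta1-adrenergic models under the
#' reference transient (1 µM isoproterenol, 400 s + 400 s), scores each
#' reduction with [score_reduction()] and returns the pair of error
#' reports. Species fixed under the protocol (forskolin, IBMX,
#' phosphodiesterase) and species removed by the reductions (free
#' receptor, Gs-alpha-GDP, Gs-beta-gamma) are excluded from the overall
#' mean, matching the reduced models' accounting.
#'
#' @param paths optional named list/vector with elements `full25`,
#'   `reduced6`, `reduced4` giving transcription paths (see
#'   [load_bar_model()]).
#' @param excluded species excluded from scoring.
#' @param n_out output samples for the scoring protocol.
#' @return list with `report6` and `report4` (both `error_report`s) and
#'   the scenario used. Signals `phaseloop_fixture_unavailable` when the
#'   transcriptions are absent.
#' @export
reproduce_table1 <- function(paths = NULL,
                             excluded = c("Fsk", "IBMX", "PDE",
                                          "b1AR_free", "Gsa_gdp", "Gsbg"),
                             n_out = 2000) {
  getp <- function(v) if (!is.null(paths) && v %in% names(paths)) paths[[v]] else NULL
  full <- load_bar_model("full25", getp("full25"))
  red6 <- load_bar_model("reduced6", getp("reduced6"))
  red4 <- load_bar_model("reduced4", getp("reduced4"))
  sc <- bar_scenarios(full, n_out = n_out)$iso_1uM
  report6 <- score_reduction(full, red6, sc$protocol,
                             overrides = sc$overrides, excluded = excluded)
  report4 <- score_reduction(full, red4, sc$protocol,
                             overrides = sc$overrides, excluded = excluded)
  list(report6 = report6, report4 = report4, scenario = sc$name)
}
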