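#' Describe a substance for simulation and measurement
#'
#' A substance spec carries what the GC and the receptor need to know about
#' one chemical: where it elutes, how wide its elution peak is, how strongly
#' the flame ionization detector responds per unit headspace amount, and how
#' the recorded receptor channel responds to it.
#'
#' @param name Text label, e.g. `"ethyl_acetate"`.
#' @param retention_time Elution apex time in seconds (> 0).
#' @param elution_width Gaussian sigma of the elution peak in seconds (> 0).
#' @param fid_response_factor FID signal units per unit headspace amount
#'   (>= 0).
#' @param receptor_model A receptor model built with [receptor_excitatory()],
#'   [receptor_inhibitory()] or [receptor_inert()].
#' @return A list of class `substance_spec`.
#' @export
#' @examples
#' ea <- substance_spec("ethyl_acetate", 100, 3,
#'   receptor_model = receptor_excitatory(Rmax = 0.4, EC50 = -5, h = 1.5))
substance_spec <- function(name, retention_time, elution_width = 3,
                           fid_response_factor = 1e4,
                           receptor_model = receptor_inert()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (retention_time <= 0) stop("retention_time must be > 0", call. = FALSE)
  if (elution_width <= 0) stop("elution_width must be > 0", call. = FALSE)
  if (fid_response_factor < 0) {
    stop("fid_response_factor must be >= 0", call. = FALSE)
  }
  structure(
    list(name = name, retention_time = retention_time,
         elution_width = elution_width,
         fid_response_factor = fid_response_factor,
         receptor_model = receptor_model),
    class = "substance_spec"
  )
}

#' Receptor response models
#'
#' A receptor model maps a delivered log10 amount to a signed peak
#' \eqn{\Delta F/F} amplitude, plus the response kinetics. Excitatory
#' responses follow the logistic dose-response curve
#' \eqn{R = R_{max} / (1 + e^{-h (c - EC_{50})})} on the log10-dilution
#' axis; inhibitory responses are the negated curve (calcium decreases);
#' inert substances elicit nothing.
#'
#' Kinetics: the response kernel rises instantaneously at odor arrival and
#' decays exponentially; above the saturation amplitude `sat` the decay time
#' constant stretches (responses "tail to the right" at high concentration).
#'
#' @param Rmax Maximum response asymptote, \eqn{\Delta F/F} units (> 0).
#' @param EC50 Half-effective log10 dilution.
#' @param h Steepness per log10 unit (> 0).
#' @param tau Baseline decay time constant, seconds.
#' @param sat Saturation amplitude above which `tau` stretches.
#' @return A list of class `receptor_model`.
#' @export
receptor_excitatory <- function(Rmax, EC50, h, tau = 8, sat = 0.3) {
  stopifnot(Rmax > 0, h > 0, tau > 0, sat > 0)
  structure(list(kind = "excitatory", Rmax = Rmax, EC50 = EC50, h = h,
                 tau = tau, sat = sat),
            class = "receptor_model")
}

#' @rdname receptor_excitatory
#' @export
receptor_inhibitory <- function(Rmax, EC50, h, tau = 8, sat = 0.3) {
  stopifnot(Rmax > 0, h > 0, tau > 0, sat > 0)
  structure(list(kind = "inhibitory", Rmax = Rmax, EC50 = EC50, h = h,
                 tau = tau, sat = sat),
            class = "receptor_model")
}

#' @rdname receptor_excitatory
#' @export
receptor_inert <- function() {
  structure(list(kind = "inert", tau = 8, sat = 0.3),
            class = "receptor_model")
}

#' Signed peak amplitude of a receptor model at a delivered amount
#'
#' @param model A `receptor_model`.
#' @param c_log10 Delivered amount as log10 of the dilution fraction.
#' @return Signed \eqn{\Delta F/F} amplitude (0 for inert).
#' @export
receptor_amplitude <- function(model, c_log10) {
  stopifnot(inherits(model, "receptor_model"))
  if (model$kind == "inert") return(rep(0, length(c_log10)))
  a <- model$Rmax / (1 + exp(-model$h * (c_log10 - model$EC50)))
  if (model$kind == "inhibitory") -a else a
}

#' Describe an odorant sample: main substance, dilution, contaminants
#'
#' A contaminant co-dilutes with the sample: its delivered headspace amount
#' is `relative_fraction * dilution`, so diluting the sample by one decadic
#' step lowers the contaminant's apparent concentration by the same step.
#'
#' @param main_substance A `substance_spec`.
#' @param dilution Dimensionless dilution fraction in (0, 1].
#' @param contaminants A list of `list(substance = <substance_spec>,
#'   relative_fraction = <fraction in [0, 1)>)`.
#' @return A list of class `sample_spec`.
#' @export
sample_spec <- function(main_substance, dilution, contaminants = list()) {
  stopifnot(inherits(main_substance, "substance_spec"))
  if (dilution <= 0 || dilution > 1) {
    stop("dilution must be in (0, 1]", call. = FALSE)
  }
  for (ct in contaminants) {
    stopifnot(inherits(ct$substance, "substance_spec"))
    if (ct$relative_fraction < 0 || ct$relative_fraction >= 1) {
      stop("relative_fraction must be in [0, 1)", call. = FALSE)
    }
  }
  structure(list(main_substance = main_substance, dilution = dilution,
                 contaminants = contaminants),
            class = "sample_spec")
}

#' Delivered headspace amounts of every substance in a sample
#'
#' @param sample A `sample_spec`.
#' @return A tibble with columns `name`, `amount` (linear fraction),
#'   `substance` (list column of specs).
#' @export
sample_amounts <- function(sample) {
  stopifnot(inherits(sample, "sample_spec"))
  subs <- c(list(list(substance = sample$main_substance,
                      relative_fraction = 1)),
            sample$contaminants)
  tibble::tibble(
    name = purrr::map_chr(subs, ~ .x$substance$name),
    amount = purrr::map_dbl(subs, ~ .x$relative_fraction * sample$dilution),
    substance = purrr::map(subs, "substance")
  )
}

#' Acquisition settings for a simulated recording
#'
#' Defaults follow the two protocols used throughout: GC-coupled antennal
#' imaging at 1 Hz for 9 min, and direct double-pulse stimulation recorded
#' at 4 Hz for 20 s. Photobleaching follows `A * exp(-t/B) + C` in raw
#' fluorescence counts; `gc_transit` is the travel time of the eluate from
#' the column split to the antenna, and `stim_delay` the autosampler/flow
#' delay in direct mode (~750 ms).
#'
#' @param mode `"gc_coupled"` or `"direct_stim"`.
#' @param duration Recording length, seconds.
#' @param rate Sampling rate, Hz (> 0).
#' @param bleach Numeric `c(A, B, C)` of the decay model, raw counts/seconds.
#' @param noise_sd Additive Gaussian noise SD in \eqn{\Delta F/F} units
#'   (>= 0). The default gives the ethyl butyrate reference peak a
#'   signal-to-noise ratio of about 20.
#' @param fid_noise_sd Additive noise SD on the FID channel, signal units.
#' @param animal_gain Multiplicative factor on response amplitudes.
#' @param gc_transit Column-to-antenna transit, seconds (gc_coupled mode).
#' @param stim_delay Injection-to-antenna delay, seconds (direct_stim mode).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(mode = c("gc_coupled", "direct_stim"),
                             duration = NULL, rate = NULL,
                             bleach = c(A = 250, B = 180, C = 750),
                             noise_sd = 0.006, fid_noise_sd = 0.05,
                             animal_gain = 1, gc_transit = 2,
                             stim_delay = 0.75, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(duration)) duration <- if (mode == "gc_coupled") 540 else 20
  if (is.null(rate)) rate <- if (mode == "gc_coupled") 1 else 4
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  bleach <- stats::setNames(as.numeric(bleach), c("A", "B", "C"))
  if (bleach[["B"]] <= 0) stop("bleach B must be > 0", call. = FALSE)
  structure(
    list(mode = mode, duration = duration, rate = rate, bleach = bleach,
         noise_sd = noise_sd, fid_noise_sd = fid_noise_sd,
         animal_gain = animal_gain, gc_transit = gc_transit,
         stim_delay = stim_delay, seed = seed),
    class = "acquisition_spec"
  )
}

#' Time grid of an acquisition
#' @keywords internal
acq_times <- function(acq) {
  seq(0, acq$duration, by = 1 / acq$rate)
}

#' Stimulus onset times at the antenna
#'
#' Injection happens at the autosampler; the stimulus arrives at the antenna
#' after the transit delay of the delivery line. The standard double-pulse
#' protocol injects at 6 and 8.5 s with a 0.75 s delay, so stimuli arrive at
#' 6.75 and 9.25 s.
#'
#' @param injection_times Numeric vector of injection times, seconds.
#' @param transit_delay Delivery delay, seconds. Default 0.75.
#' @return Numeric vector of onset times at the antenna.
#' @export
#' @examples
#' stimulus_onsets() # 6.75 9.25
stimulus_onsets <- function(injection_times = c(6, 8.5),
                            transit_delay = 0.75) {
  stopifnot(is.numeric(injection_times), transit_delay >= 0)
  injection_times + transit_delay
}

#' Default substance library
#'
#' Retention times are anchored on the two landmarks used throughout
#' (ethyl acetate ~100 s, benzaldehyde ~240 s); the esters between them are
#' spaced by volatility. Receptor models emulate an Or42b-like channel:
#' strongly excitatory to short esters, inhibited by benzaldehyde (both
#' isotopomers identically -- isotopic substitution does not change the
#' modelled receptor).
#'
#' @return A named list of `substance_spec` objects.
#' @export
substance_library <- function() {
  ea_model <- receptor_excitatory(Rmax = 0.4, EC50 = -5.0, h = 1.5, tau = 8,
                                  sat = 0.3)
  bza_model <- receptor_inhibitory(Rmax = 0.2, EC50 = -3.0, h = 1.0,
                                   tau = 10, sat = 0.3)
  list(
    ethyl_acetate = substance_spec("ethyl_acetate", 100, 3,
                                   receptor_model = ea_model),
    ethyl_propionate = substance_spec(
      "ethyl_propionate", 140, 3,
      receptor_model = receptor_excitatory(Rmax = 0.35, EC50 = -4.5, h = 1.5)
    ),
    propyl_acetate = substance_spec(
      "propyl_acetate", 155, 3,
      receptor_model = receptor_excitatory(Rmax = 0.3, EC50 = -4.3, h = 1.5)
    ),
    ethyl_butyrate = substance_spec(
      "ethyl_butyrate", 180, 3,
      receptor_model = receptor_excitatory(Rmax = 0.45, EC50 = -4.2, h = 1.5)
    ),
    unknown_impurity = substance_spec(
      "unknown_impurity", 162, 3,
      receptor_model = receptor_excitatory(Rmax = 0.2, EC50 = -4.0, h = 1.5)
    ),
    benzaldehyde_h = substance_spec("benzaldehyde_h", 240, 4,
                                    receptor_model = bza_model),
    benzaldehyde_d5 = substance_spec("benzaldehyde_d5", 240, 4,
                                     receptor_model = bza_model),
    methyl_acetate = substance_spec("methyl_acetate", 80, 3,
                                    receptor_model = receptor_inert())
  )
}

#' Default tuning map for the recorded channel
#'
#' Maps substance name to the receptor model used when simulating imaging
#' traces. Substances missing from the map are treated as inert.
#'
#' @param library A substance library, see [substance_library()].
#' @return Named list of `receptor_model` objects.
#' @export
or42b_tuning <- function(library = substance_library()) {
  purrr::map(library, "receptor_model")
}

#' Canonical samples used in the experiments
#'
#' * `reference_sample()`: ethyl butyrate at `10^-2` carrying an ethyl
#'   acetate contamination of relative fraction `10^-3.6`, so that the first
#'   response peak (the calibration reference) corresponds to `10^-5.6`
#'   ethyl acetate. Two further trace contaminants give the
#'   characteristic four-peak response.
#' * `contaminated_sample()`: benzaldehyde-d5 carrying ethyl acetate at a
#'   known relative fraction (default `10^-5.2`).
#'
#' @param dilution Sample dilution fraction.
#' @param library Substance library.
#' @return A `sample_spec`.
#' @export
reference_sample <- function(dilution = 1e-2, library = substance_library()) {
  sample_spec(
    library$ethyl_butyrate, dilution,
    contaminants = list(
      list(substance = library$ethyl_acetate, relative_fraction = 10^-3.6),
      list(substance = library$ethyl_propionate, relative_fraction = 10^-3.8),
      list(substance = library$unknown_impurity, relative_fraction = 10^-3.5)
    )
  )
}

#' @rdname reference_sample
#' @param fraction Contaminant relative fraction (linear), default `10^-5.2`.
#' @export
contaminated_sample <- function(dilution = 1e-2, fraction = 10^-5.2,
                                library = substance_library()) {
  sample_spec(
    library$benzaldehyde_d5, dilution,
    contaminants = list(
      list(substance = library$ethyl_acetate, relative_fraction = fraction)
    )
  )
}
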