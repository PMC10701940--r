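#' Volumetric dilution
#'
#' Concentration after transferring `taken` mL into a flask filled to
#' `final` mL: `c_out = c_in * taken / final`.
#'
#' @param conc Input concentration (ug/mL).
#' @param taken Transferred volume (mL), positive and at most `final`.
#' @param final Final volume (mL).
#' @return Diluted concentration (ug/mL).
#' @export
#' @examples
#' dilute(5000, 2.5, 100)   # 125
dilute <- function(conc, taken, final) {
  if (taken <= 0 || final <= 0 || taken > final)
    stop("need 0 < taken <= final")
  conc * taken / final
}

#' Apply a chain of dilution steps
#'
#' @param conc Starting concentration (ug/mL).
#' @param steps List of `c(taken, final)` pairs, applied in order.
#' @return Final concentration; composition is exact:
#'   `c * prod(taken_i / final_i)`.
#' @export
#' @examples
#' dilution_chain(5000, list(c(2.5, 100), c(1, 25)))   # 5
dilution_chain <- function(conc, steps) {
  for (s in steps) conc <- dilute(conc, s[1], s[2])
  conc
}

#' Label-claim percentage
#'
#' `100 * found / nominal`.
#'
#' @param found Found concentration or amount.
#' @param nominal Declared (nominal) concentration or amount.
#' @return Percent of label claim.
#' @export
label_claim_percent <- function(found, nominal) {
  if (any(nominal <= 0)) stop("nominal must be positive")
  100 * found / nominal
}

#' Tablet assay plan for the PAR/HYO combination product
#'
#' Encodes the dosage-form work-up: tablets declared at 500.00 mg PAR and
#' 10.00 mg HYO; a stock solution of 5000.00 ug/mL PAR and 100.00 ug/mL
#' HYO; dilution 2.5 mL to 100 mL (working solution, 125.00 / 2.50
#' ug/mL), then 1 mL to 25 mL (assay solution, 5.00 / 0.10 ug/mL); and a
#' standard spike of 16.00 ug/mL HYO added to the assay solution.  The
#' spike lifts HYO from far below its calibrated range (16-24 ug/mL) to
#' just inside it, and is subtracted from the prediction afterwards.
#'
#' @return List with `label_claim_mg`, `stock_conc`, `steps`,
#'   `spike_hyo`, and the derived `nominal_assay_conc` (ug/mL in the
#'   final flask).
#' @export
assay_plan <- function() {
  steps <- list(c(2.5, 100), c(1, 25))
  stock <- c(PAR = 5000, HYO = 100)
  nominal <- vapply(stock, dilution_chain, 0, steps = steps)
  list(label_claim_mg = c(PAR = 500, HYO = 10),
       stock_conc = stock,
       steps = steps,
       spike_hyo = 16,
       nominal_assay_conc = nominal)
}

#' Predict a spiked dosage-form sample and remove the spike
#'
#' Predicts all six analytes from the sample spectrum with the supplied
#' calibration model, then subtracts the known spiked HYO concentration
#' from the HYO prediction; other analytes are untouched.  A corrected
#' HYO below `-tolerance` is flagged as failed spike accounting.
#'
#' @param model A [calibrate()] fit (or `mcr_quantify`-style predictor
#'   via `predict_fun`).
#' @param spectra Sample spectra (`spectra_matrix`, matrix or single
#'   spectrum vector).
#' @param spike_conc Spiked HYO concentration (ug/mL), non-negative.
#' @param analyte Name of the spiked analyte column (default `"HYO"`).
#' @param tolerance Negativity tolerance for the corrected value
#'   (default 1e-6 ug/mL).
#' @return List with `predictions` (spike-corrected, samples x analytes)
#'   and `flag` (`TRUE` if spike accounting failed).
#' @export
spike_corrected_predict <- function(model, spectra, spike_conc,
                                    analyte = "HYO", tolerance = 1e-6) {
  if (spike_conc < 0) stop("spike_conc must be non-negative")
  pred <- predict(model, spectra)
  if (!analyte %in% colnames(pred))
    stop("model does not predict analyte ", analyte)
  pred[, analyte] <- pred[, analyte] - spike_conc
  flag <- any(pred[, analyte] < -tolerance)
  if (flag)
    warning("corrected ", analyte, " concentration is negative beyond tolerance: ",
            "spike accounting failed")
  list(predictions = pred, flag = flag)
}

#' Simulate a spiked tablet-assay sample
#'
#' Builds the six-analyte concentration vector of the final assay flask
#' (PAR and HYO at their nominal assay levels, impurities absent, HYO
#' spike added) and simulates its spectrum under the bilinear model.
#'
#' @param plan An [assay_plan()].
#' @param library Pure-spectrum library.
#' @param noise_sd,seed Passed to [simulate_spectra()].
#' @param par_conc,hyo_conc Optional overrides of the nominal assay
#'   concentrations (ug/mL).
#' @return List with `spectra` (`spectra_matrix`, one sample), `true_conc`
#'   (pre-spike), `spiked_conc` (as measured).
#' @export
simulate_tablet_sample <- function(plan = assay_plan(),
                                   library = pure_spectra_library(),
                                   noise_sd = 0.002, seed = NULL,
                                   par_conc = NULL, hyo_conc = NULL) {
  nominal <- plan$nominal_assay_conc
  if (is.null(par_conc)) par_conc <- nominal[["PAR"]]
  if (is.null(hyo_conc)) hyo_conc <- nominal[["HYO"]]
  true_conc <- c(PAR = par_conc, HYO = hyo_conc, PNP = 0, PCA = 0,
                 TRO = 0, PAP = 0)
  spiked <- true_conc
  spiked["HYO"] <- spiked["HYO"] + plan$spike_hyo
  sp <- simulate_spectra(matrix(spiked, nrow = 1,
                                dimnames = list("tablet", names(spiked))),
                         library = library, noise_sd = noise_sd, seed = seed)
  list(spectra = sp, true_conc = true_conc, spiked_conc = spiked)
}

#' Full dosage-form assay
#'
#' Simulated or measured spiked sample in, label-claim percentages out:
#' predict with the model, subtract the HYO spike, and express PAR and
#' HYO against their nominal assay concentrations.
#'
#' @param model A [calibrate()] fit.
#' @param sample A [simulate_tablet_sample()] result or a
#'   `spectra_matrix` of spiked assay samples.
#' @param plan An [assay_plan()].
#' @return List with `found` (ug/mL, spike-corrected), `label_claim`
#'   (percent, PAR and HYO columns) and `flag`.
#' @export
#' @examples
#' d <- default_design()
#' sp <- simulate_spectra(d, noise_sd = 0, seed = 3)
#' fit <- calibrate(sp$absorbance[d$calibration_ids, ],
#'                  calibration_set(d), method = "pcr", ncomp = 6)
#' smp <- simulate_tablet_sample(noise_sd = 0, seed = 4)
#' assay_tablet(fit, smp)$label_claim
assay_tablet <- function(model, sample, plan = assay_plan()) {
  spectra <- if (is.list(sample) && !inherits(sample, "spectra_matrix"))
    sample$spectra else sample
  corr <- spike_corrected_predict(model, spectra, plan$spike_hyo)
  found <- corr$predictions
  nominal <- plan$nominal_assay_conc
  claim <- cbind(PAR = label_claim_percent(found[, "PAR"], nominal[["PAR"]]),
                 HYO = label_claim_percent(found[, "HYO"], nominal[["HYO"]]))
  list(found = found, label_claim = claim, flag = corr$flag)
}
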