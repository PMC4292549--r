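# Published VDAC1 gating parameters at -10 mV for the five experimental
# conditions: wild-type purified channel (WT), nitrosated channel at 25 and
# 100 uM of the NO donor PAPA NONOate (PPN25, PPN100), recombinant
# un-phosphorylated channel (rVDAC), and the S137E phosphomimetic mutant.
# Rates are in s^-1; thresholds are current magnitudes in pA (the larger
# magnitude separates the fully open level, the smaller the closed level).
.vdac_conditions <- list(
  WT = list(
    rates_s = c("S1->S3" = 141.6, "S3->S1" = 9.79,
                "S1->S5" = 177.3, "S5->S1" = 148.1,
                "S3->S4" = 253.3, "S4->S3" = 0.24,
                "S2->S4" = 332.6, "S4->S2" = 0.4),
    open_mag = 20, closed_mag = 15
  ),
  PPN25 = list(
    rates_s = c("S1->S3" = 230, "S3->S1" = 3,
                "S1->S5" = 95, "S5->S1" = 220,
                "S3->S4" = 110, "S4->S3" = 0.12,
                "S2->S4" = 0.46, "S4->S2" = 0.048),
    open_mag = 9, closed_mag = 6.7
  ),
  PPN100 = list(
    rates_s = c("S1->S3" = 120, "S3->S1" = 0.66,
                "S1->S5" = 139, "S5->S1" = 118,
                "S3->S4" = 157, "S4->S3" = 0.094,
                "S2->S4" = 165, "S4->S2" = 0.075),
    open_mag = 38, closed_mag = 34
  ),
  rVDAC = list(
    rates_s = c("S1->S3" = 130.3, "S3->S1" = 47.5,
                "S1->S5" = 118.6, "S5->S1" = 161.2,
                "S3->S4" = 237.2, "S4->S3" = 0.36,
                "S2->S4" = 296.1, "S4->S2" = 3.6),
    open_mag = 21.5, closed_mag = 14.5
  ),
  S137E = list(
    rates_s = c("S1->S3" = 135.3, "S3->S1" = 1.26,
                "S1->S5" = 152.2, "S5->S1" = 137.4,
                "S3->S4" = 169.9, "S4->S3" = 0.61,
                "S2->S4" = 143.8, "S4->S2" = 0.83),
    open_mag = 20, closed_mag = 15
  )
)

#' Five-state VDAC gating model
#'
#' The open-loop five-state topology S5 - S1 - S3 - S4 - S2 that describes
#' VDAC gating with three conductance classes: S3 is the maximally open
#' conformation (class `"O"`), S2 the minimally open / closed conformation
#' (class `"C"`), and S1, S4, S5 share the sub-conductance level (class
#' `"O_S"`).  Rates default to the published estimates for the requested
#' experimental condition, converted from s^-1 to the internal ms^-1.
#'
#' @param condition One of `"WT"`, `"PPN25"`, `"PPN100"`, `"rVDAC"`,
#'   `"S137E"`.
#' @return A [gating_model()] with 5 states and 4 edges.
#' @examples
#' m <- vdac_model("WT")
#' stationary_distribution(build_generator(m))
#' @export
vdac_model <- function(condition = c("WT", "PPN25", "PPN100",
                                     "rVDAC", "S137E")) {
  condition <- match.arg(condition)
  cond <- .vdac_conditions[[condition]]
  gating_model(
    states  = paste0("S", 1:5),
    classes = c(S1 = "O_S", S2 = "C", S3 = "O", S4 = "O_S", S5 = "O_S"),
    edges   = rbind(c("S1", "S3"), c("S1", "S5"),
                    c("S3", "S4"), c("S2", "S4")),
    rates   = cond$rates_s / 1000,
    acyclic = TRUE
  )
}

#' Published idealization thresholds per condition
#'
#' Current-magnitude thresholds (pA) separating the three conductance
#' classes for each experimental condition, as a [threshold_spec()].
#'
#' @inheritParams vdac_model
#' @return A [threshold_spec()].
#' @export
vdac_thresholds <- function(condition = c("WT", "PPN25", "PPN100",
                                          "rVDAC", "S137E")) {
  condition <- match.arg(condition)
  cond <- .vdac_conditions[[condition]]
  threshold_spec(cond$open_mag, cond$closed_mag)
}
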