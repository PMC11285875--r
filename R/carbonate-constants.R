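#' Equilibrium constants of the seawater CO2 system
#'
#' Evaluates the thermodynamic constants needed to speciate the seawater
#' carbonate system and to drive the buffered CO2-release model: the CO2
#' solubility `K0` (Weiss 1974), the carbonic acid dissociation constants
#' `K1`/`K2`, the borate acidity constant `KB` (Dickson 1990), the ion
#' product of water `Kw` (Millero 1995) and total boron `TB` (Uppstrom
#' 1974, 0.000416 * S/35). Sulfate and fluoride association constants are
#' evaluated as well because they define the conversions between pH scales.
#'
#' All constants are returned on the **total** hydrogen-ion scale in
#' mol/kg-seawater (`K0` in mol/kg/atm, `Kw` in mol^2/kg^2). Three K1/K2
#' formulations are available:
#' \describe{
#'   \item{`"lueker2000"`}{Lueker, Dickson & Keeling (2000) refit of the
#'     Mehrbach constants, reported directly on the total scale (default).}
#'   \item{`"dickson_millero1987"`}{Dickson & Millero (1987) refit of
#'     Mehrbach, seawater scale, converted to total internally.}
#'   \item{`"roy1993"`}{Roy et al. (1993), total scale.}
#' }
#'
#' @param temperature Water temperature, degrees C (valid -2 to 40).
#' @param salinity Practical salinity (valid 0 to 45; the K1/K2 fits are
#'   calibrated for roughly 19-43).
#' @param formulation K1/K2 formulation tag (see Details).
#'
#' @return An object of class `carb_constants`: a list with elements `K0`,
#'   `K1`, `K2`, `KB`, `Kw`, `TB`, `KS`, `TS`, `KF`, `TF`, the pH-scale
#'   conversion factors `sws_per_tot` (\[H\]sws / \[H\]tot),
#'   `free_per_tot`, `fH` (NBS activity factor, Takahashi et al. 1982),
#'   plus `temperature`, `salinity`, `formulation` and
#'   `ph_scale = "total"`. Use [tidy()] for a one-row tibble.
#'
#' @examples
#' k <- carb_constants(15, 35)
#' k$K1 > k$K2
#' tidy(k)
#' @export
carb_constants <- function(temperature, salinity, formulation = "lueker2000") {
  check_scalar_number(temperature, "temperature", -2, 40)
  check_scalar_number(salinity, "salinity", 0, 45)
  formulation <- arg_match(formulation,
                           c("lueker2000", "dickson_millero1987", "roy1993"))
  TK <- temperature + 273.15
  S <- salinity
  lnTK <- log(TK)

  # ionic strength and conservative totals (mol/kg-SW)
  I <- 19.924 * S / (1000 - 1.005 * S)
  TS <- 0.14 / 96.062 * S / 1.80655
  TF <- 0.000067 / 18.998 * S / 1.80655

  # bisulfate (Dickson 1990a, free scale) and fluoride (Dickson & Riley
  # 1979, free scale) -- needed only for pH-scale conversions
  KS <- exp(-4276.1 / TK + 141.328 - 23.093 * lnTK +
              (-13856 / TK + 324.57 - 47.986 * lnTK) * sqrt(I) +
              (35474 / TK - 771.54 + 114.723 * lnTK) * I -
              2698 / TK * I^1.5 + 1776 / TK * I^2 + log(1 - 0.001005 * S))
  KF <- exp(1590.2 / TK - 12.641 + 1.525 * sqrt(I) + log(1 - 0.001005 * S))

  sws_per_tot <- if (S > 0) (1 + TS / KS + TF / KF) / (1 + TS / KS) else 1
  free_per_tot <- if (S > 0) 1 / (1 + TS / KS) else 1
  fH <- 1.2948 - 0.002036 * TK + (0.0004607 - 0.000001475 * TK) * S^2

  K0 <- exp(-60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
              S * (0.023517 - 0.023656 * (TK / 100) +
                     0.0047036 * (TK / 100)^2))

  if (formulation == "lueker2000") {
    K1 <- 10^-(3633.86 / TK - 61.2172 + 9.67770 * lnTK -
                 0.011555 * S + 0.0001152 * S^2)
    K2 <- 10^-(471.78 / TK + 25.929 - 3.16967 * lnTK -
                 0.01781 * S + 0.0001122 * S^2)
  } else if (formulation == "dickson_millero1987") {
    K1 <- 10^-(3670.7 / TK - 62.008 + 9.7944 * lnTK -
                 0.0118 * S + 0.000116 * S^2) / sws_per_tot
    K2 <- 10^-(1394.7 / TK + 4.777 - 0.0184 * S + 0.000118 * S^2) /
      sws_per_tot
  } else {
    K1 <- exp(2.83655 - 2307.1266 / TK - 1.5529413 * lnTK +
                (-0.20760841 - 4.0484 / TK) * sqrt(S) + 0.08468345 * S -
                0.00654208 * S^1.5 + log(1 - 0.001005 * S))
    K2 <- exp(-9.226508 - 3351.6106 / TK - 0.2005743 * lnTK +
                (-0.106901773 - 23.9722 / TK) * sqrt(S) + 0.1130822 * S -
                0.00846934 * S^1.5 + log(1 - 0.001005 * S))
  }

  KB <- exp((-8966.90 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 -
               0.0996 * S^2) / TK +
              148.0248 + 137.1942 * sqrt(S) + 1.62142 * S -
              (24.4344 + 25.085 * sqrt(S) + 0.2474 * S) * lnTK +
              0.053105 * sqrt(S) * TK)
  Kw <- exp(148.9802 - 13847.26 / TK - 23.6521 * lnTK +
              (-5.977 + 118.67 / TK + 1.0495 * lnTK) * sqrt(S) -
              0.01615 * S) / sws_per_tot
  TB <- 0.000416 * S / 35

  structure(
    list(K0 = K0, K1 = K1, K2 = K2, KB = KB, Kw = Kw, TB = TB,
         KS = KS, TS = TS, KF = KF, TF = TF,
         sws_per_tot = sws_per_tot, free_per_tot = free_per_tot, fH = fH,
         temperature = temperature, salinity = salinity,
         formulation = formulation, ph_scale = "total"),
    class = "carb_constants"
  )
}

#' @export
print.carb_constants <- function(x, ...) {
  cat(sprintf("<carb_constants> %s at %.2f degC, S %.2f (total scale)\n",
              x$formulation, x$temperature, x$salinity))
  cat(sprintf("  pK1 %.4f  pK2 %.4f  pKB %.4f  pKw %.4f  K0 %.5f  TB %.3e\n",
              -log10(x$K1), -log10(x$K2), -log10(x$KB), -log10(x$Kw),
              x$K0, x$TB))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.carb_constants <- function(x, ...) {
  tibble(
    temperature = x$temperature, salinity = x$salinity,
    formulation = x$formulation, ph_scale = x$ph_scale,
    K0 = x$K0, K1 = x$K1, K2 = x$K2, KB = x$KB, Kw = x$Kw, TB = x$TB
  )
}

# Convert a pH reported on `scale` into a total-scale hydrogen-ion
# concentration (mol/kg). NBS pH goes through the Takahashi activity factor
# fH (NBS -> seawater scale) and then to total.
ph_to_h_total <- function(ph, scale, constants) {
  scale <- arg_match(scale, c("total", "NBS", "sws", "free"))
  h <- 10^-ph
  switch(scale,
    total = h,
    sws = h / constants$sws_per_tot,
    free = h / constants$free_per_tot,
    NBS = (h / constants$fH) / constants$sws_per_tot
  )
}

# Inverse of ph_to_h_total.
h_total_to_ph <- function(h, scale, constants) {
  scale <- arg_match(scale, c("total", "NBS", "sws", "free"))
  hh <- switch(scale,
    total = h,
    sws = h * constants$sws_per_tot,
    free = h * constants$free_per_tot,
    NBS = h * constants$sws_per_tot * constants$fH
  )
  -log10(hh)
}
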