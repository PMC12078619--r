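#!/usr/bin/env Rscript
# Stage 1 — densities to apparent molar volumes, Masson fits, taste class and
# hydration numbers for gabapentin in the three aqueous betaine-based media.
#
# Findings this script prints and saves:
#  * the printed-intercept route reproduces the reference hydration column to
#    the third decimal for all nine systems;
#  * refitting the rounded densities works for the internally consistent
#    blocks (betaine 0.01, all IL) and exposes the DES blocks' density/volume
#    inconsistency as wildly shifted intercepts.

library(soluthermo)

dir.create("results", showWarnings = FALSE)
GBP_M <- 171.237
GBP_DCRYST <- 1.257

rep <- run_pipeline(list(
  stages = "volumetric",
  solute = list(name = "gabapentin", M = GBP_M, d_cryst = GBP_DCRYST),
  inputs = list(volumetric = fixture_series("density")),
  options = list(min_molality = 0.002)
))

chain <- do.call(rbind, lapply(names(rep$volumetric), function(nm) {
  r <- rep$volumetric[[nm]]
  data.frame(series = nm, Vphi0_refit = r$Vphi0, Sv_refit = r$Sv,
             nH_refit = r$hydration$n_H, taste = r$taste)
}))

ms <- st_fixture("masson")
hyd <- st_fixture("hydration")
ref <- hydration_number(ms$vphi0, GBP_M, GBP_DCRYST)
tab <- cbind(chain,
             Vphi0_printed = ms$vphi0, Sv_printed = ms$sv,
             nH_from_printed_Vphi0 = ref$n_H, nH_printed = hyd$nh)
write.csv(tab, "results/volumetric_summary.csv", row.names = FALSE)

cat("Hydration numbers, printed-intercept route vs reference column:\n")
print(data.frame(series = tab$series,
                 computed = round(tab$nH_from_printed_Vphi0, 3),
                 printed = tab$nH_printed,
                 diff = round(tab$nH_from_printed_Vphi0 - tab$nH_printed, 4)),
      row.names = FALSE)
cat(sprintf("\nmax |diff| = %.4f (all within last-digit rounding)\n",
            max(abs(tab$nH_from_printed_Vphi0 - tab$nH_printed))))
cat("\nRefit-from-densities intercepts (rounded data, floor 0.002 mol/kg):\n")
print(data.frame(series = tab$series, refit = round(tab$Vphi0_refit, 3),
                 printed = tab$Vphi0_printed), row.names = FALSE)
cat("note: DES blocks diverge because their printed density columns are\n",
    "inconsistent with their own printed molar volumes.\n")

# apparent specific volumes from the printed molar volumes, with taste calls
dens <- st_fixture("densities")
dens <- dens[dens$m > 0, ]
asv <- apparent_specific_volume(dens$vphi_printed, GBP_M)
taste <- classify_taste(asv)
write.csv(data.frame(dens[c("system", "solvent_molality_nominal", "m")],
                     asv = round(asv, 3), taste = taste$taste,
                     sweet_window = taste$sweet_window),
          "results/asv_taste.csv", row.names = FALSE)
cat(sprintf("\nASV range %.3f-%.3f cm^3/g; sweetness window (0.5-0.7) never entered.\n",
            min(asv), max(asv)))
cat(sprintf("Nearest-reference labels: %d 'bitter', %d 'sweet' (the sweet calls sit\n",
            sum(taste$taste == "bitter"), sum(taste$taste == "sweet")))
cat("just below the 0.825 sweet/bitter midpoint - far outside the true\n")
cat("sweetness window, so the drug reads as bitter-leaning in every medium,\n")
cat("most markedly in the DES where ASV runs highest.\n")
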