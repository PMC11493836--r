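#!/usr/bin/env Rscript
# Build the default scheduled MRM panel (84 analytes + 4 internal standards
# over 14 glycosphingolipid classes) and export the transition lists.
suppressPackageStartupMessages(library(gslquant))
dir.create("results", showWarnings = FALSE)

panel <- build_panel(default_panel_config())
write_transition_list(panel, "results/transition_list.csv")
write_transition_list(panel, "results/transition_list_skyline.csv",
                      dialect = "skyline")

analytes <- panel[panel$role == "analyte", ]
cat("analyte transitions:", nrow(analytes), "\n")
print(table(analytes$polarity))
cat("\nScheduled windows span",
    sprintf("%.2f-%.2f min", min(panel$rt_min) - 0.5, max(panel$rt_min) + 0.5),
    "of the 15-min gradient.\n")
cat("Elution order check (class base RTs, min):\n")
print(sort(rt_model()$base_min))
cat("\nQuantifier ions: sialylated ->",
    round(quantifier_fragment_mz("GM3"), 1), " neutral ->",
    round(quantifier_fragment_mz("GlcCer"), 1), "\n")
cat("wrote results/transition_list.csv and results/transition_list_skyline.csv\n")
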