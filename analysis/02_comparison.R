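#!/usr/bin/env Rscript
# Three-way cost comparison: absolute and relative savings of each
# intervention against total thyroidectomy (and against hemithyroidectomy),
# under the societal and the opportunity-cost perspective.
#
# Writes results/comparison_<perspective>.csv and prints the tables.

suppressPackageStartupMessages(library(thyrocost))
dir.create("results", showWarnings = FALSE)

ds <- bundled_datasets()
for (p in c("societal", "opportunity_cost_societal")) {
  br <- lapply(ds, intervention_total, perspective(p), "fidelity")
  cmp_tt <- compare_interventions(br, "total_thyroidectomy")
  cmp_hemi <- compare_interventions(br, "hemithyroidectomy")
  out <- rbind(as.data.frame(cmp_tt), as.data.frame(cmp_hemi))
  write.csv(out, sprintf("results/comparison_%s.csv", p), row.names = FALSE)
  cat(render_comparison(br, "total_thyroidectomy",
                        report_config(perspective(p))), "\n\n", sep = "")
}

# headline: ablation saves ~70% vs total thyroidectomy, >60% vs
# hemithyroidectomy (societal, fidelity)
br <- lapply(ds, intervention_total)
cmp <- compare_interventions(br, "total_thyroidectomy")
abl <- cmp[cmp$comparator == "thermal_ablation", ]
cat(sprintf("thermal ablation vs total thyroidectomy: %.1f%% saving\n",
            100 * abl$relative_saving))
cmp2 <- compare_interventions(br, "hemithyroidectomy")
abl2 <- cmp2[cmp2$comparator == "thermal_ablation", ]
cat(sprintf("thermal ablation vs hemithyroidectomy:   %.1f%% saving\n",
            100 * abl2$relative_saving))
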