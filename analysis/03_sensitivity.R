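#!/usr/bin/env Rscript
# Step 3 — sensitivity of the combined endgame projection to the policy
# effect sizes.
#
# One-way: every effect size of one MPOWER family (P, O, W, E, R) scaled by
# -50% .. +50%; the price family dominates and the cessation-support family
# has no leverage (its level does not change between the status quo and the
# strengthened scenario). Probabilistic: 1000 draws of independent mean-1
# beta scale factors per family, 95% CI by bias-corrected percentiles.
#
# Outputs (results/): one_way_grid.csv, psa_summary.csv, psa_draws.csv

suppressMessages(library(endgamesim))
if (!dir.exists("results/baseline")) {
  stop("run analysis/01_calibrate_baseline.R first")
}
bl <- load_baseline("results/baseline")
scen <- build_scenario("POWE+TFG+R8000+R10%")

message("One-way sensitivity grid (prevalence %, 2030 and 2050):")
grid <- one_way_grid(bl, scen)
grid[c("male", "female", "total")] <-
  lapply(grid[c("male", "female", "total")], round_half_up)
print(grid, row.names = FALSE)
write.csv(grid, "results/one_way_grid.csv", row.names = FALSE)

spread <- vapply(split(grid, grid$component), function(d) {
  max(abs(d$total[d$year == 2050] - d$total[d$year == 2050 & d$delta == 0]))
}, numeric(1))
message("\n2050 total-prevalence spread by family (%p): ",
        paste(sprintf("%s=%.2f", names(spread), spread), collapse = ", "))

message("\nProbabilistic sensitivity analysis (1000 draws) ...")
p <- psa(bl, scen, n_draws = 1000, seed = 42)
print(p)
write.csv(p$summary, "results/psa_summary.csv", row.names = FALSE)
write.csv(as.data.frame(p$draws), "results/psa_draws.csv", row.names = FALSE)
message("Wrote results/one_way_grid.csv, results/psa_summary.csv, results/psa_draws.csv")
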