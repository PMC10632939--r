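#!/usr/bin/env Rscript
# Step 2 — project the seven policy scenarios, 2022-2050.
#
# Scenarios: status quo; full-strength non-price policies (POWE); POWE plus
# a one-time cigarette-price jump to KRW 8000 (R8000); plus 10% annual
# nominal price growth (R10%); and the tobacco-free-generation sales ban
# (TFG, birth cohorts after 2003) in combination.
#
# Outputs (results/):
#   scenario_table_{male,female,total}.csv   scenario x year prevalence (%)
#   projections.csv                          tidy full-precision series

suppressMessages(library(endgamesim))
if (!dir.exists("results/baseline")) {
  stop("run analysis/01_calibrate_baseline.R first")
}
bl <- load_baseline("results/baseline")

series <- lapply(scenario_names(), function(n) run_scenario(bl, build_scenario(n)))

for (sex in c("male", "female", "total")) {
  tab <- render_scenario_table(series, sex = sex)
  write.csv(tab, sprintf("results/scenario_table_%s.csv", sex), row.names = FALSE)
  message(toupper(sex), " adult smoking prevalence (%):")
  print(tab, row.names = FALSE)
  message("")
}
write_projection_csv(series, "results/projections.csv")

comb <- series[[match("POWE+TFG+R8000+R10%", scenario_names())]]
message(sprintf(
  paste0("Under the combined endgame scenario the 2050 prevalence is %.1f%% ",
         "overall (%.1f%% male / %.1f%% female): the <5%% endgame target is %s."),
  round_half_up(comb$total[comb$year == 2050]),
  round_half_up(comb$male[comb$year == 2050]),
  round_half_up(comb$female[comb$year == 2050]),
  if (comb$total[comb$year == 2050] < 5) "met" else "missed"))
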