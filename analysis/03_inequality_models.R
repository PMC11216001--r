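#!/usr/bin/env Rscript
## Stage 3: inequalities in typology membership (weighted multinomial ORs
## vs the parents/friends/family reference, adjusted for ethnicity) and
## the typology -> raised-TD association (modified-Poisson risk ratios at
## three adjustment levels).

suppressPackageStartupMessages(library(careseq))

cohort <- read_cohort("results/cohort_typed.csv")

tab2 <- fit_weighted_multinomial(
  cohort, model_spec("typology", c("education", "ethnicity")))
cat("Typology membership odds ratios (vs Degree, vs Parents/friends/family):\n")
print(tab2)
write.csv(as.data.frame(tab2), "results/table2_inequalities.csv",
          row.names = FALSE)

tab3 <- do.call(rbind, lapply(c("unadjusted", "partial", "full"), function(adj) {
  fit <- fit_modified_poisson_rr(
    cohort, model_spec("outcome_raised_td", "typology", adjustment = adj))
  typ <- fit[grepl("^typology", fit$term), ]
  cbind(adjustment = adj, as.data.frame(typ))
}))
cat("\nRisk of raised TD by typology (risk ratios vs Parents/friends/family):\n")
print(tab3, row.names = FALSE)
write.csv(tab3, "results/table3_rr.csv", row.names = FALSE)
cat("wrote results/table2_inequalities.csv and results/table3_rr.csv\n")
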