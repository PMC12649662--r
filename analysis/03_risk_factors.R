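#!/usr/bin/env Rscript
# Stage 3: score vascular risk by exploratory factor analysis.
#
# Horn's parallel analysis fixes the number of factors; principal-axis
# extraction with direct oblimin rotation yields the loading pattern; each
# subject's risk scores are loading-weighted averages of the standardized
# indicators.

library(shrf)
SEED <- 1
cohort <- read.csv("results/cohort.csv")

indicator_cols <- c("resting_metabolism", "visceral_fat",
                    "abdominal_circumference", "body_fat", "bmi",
                    "physical_activity", "gait_speed", "arterial_stiffness",
                    "high_cholesterol", "hypertension", "diabetes",
                    "family_history_diabetes", "obesity")
ind <- as.matrix(cohort[, indicator_cols])
ind <- ind[, apply(ind, 2, sd) > 0, drop = FALSE]

n_retained <- parallel_analysis(ind, n_iterations = 1000, seed = SEED + 2)
cat(sprintf("parallel analysis retained %d factor(s) from %d indicators\n",
            n_retained, ncol(ind)))
n_use <- max(n_retained, 3L) # extract 3 for comparability across stages
sol <- efa_oblimin(ind, n_use)
cat(sprintf("EFA (%d factors): %.1f%% of variance explained\n",
            n_use, 100 * sol$proportion_variance))
phi <- sol$factor_correlations[upper.tri(sol$factor_correlations)]
cat(sprintf("inter-factor correlations: %s\n",
            paste(round(phi, 2), collapse = ", ")))

scores <- factor_scores(sol, ind)
write.csv(cbind(indicator = rownames(sol$loadings),
                as.data.frame(round(sol$loadings, 3))),
          "results/factor_loadings.csv", row.names = FALSE)
write.csv(data.frame(component = seq_along(sol$eigenvalues),
                     eigenvalue = sol$eigenvalues),
          "results/eigenvalues.csv", row.names = FALSE)
write.csv(cbind(subject_id = cohort$subject_id, as.data.frame(scores)),
          "results/factor_scores.csv", row.names = FALSE)

for (f in seq_len(ncol(sol$loadings))) {
  lead <- order(-abs(sol$loadings[, f]))[1:3]
  cat(sprintf("factor %d leads: %s\n", f,
              paste(sprintf("%s (%.2f)", rownames(sol$loadings)[lead],
                            sol$loadings[lead, f]), collapse = ", ")))
}
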