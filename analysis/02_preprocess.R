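#!/usr/bin/env Rscript
# Stage 2: the dietary preprocessing chain, demonstrated end to end on
# synthetic recall data: two 24-hour recalls per person are averaged,
# eligibility filters applied, amounts categorized into the 4-level coding
# by population tertiles of positive consumption, risk-factor flags derived,
# and survey-weighted descriptives computed.
#
# (Stage 3 fits the model to the categorical data from stage 1, which is
# generated directly at the food-group level; this stage documents and
# exercises the amount-to-level pipeline that real recall data would pass
# through.)

library(rpclust)
set.seed(77)

dir.create("results/preprocess", recursive = TRUE, showWarnings = FALSE)

## synthetic recall days: zero-inflated lognormal amounts for 6 food groups
n <- 400
foods <- c("refined_grains", "whole_grains", "fruit", "vegetables",
           "added_sugars", "cured_meats")
one_day <- function() {
  amt <- matrix(rlnorm(n * 6, meanlog = rep(c(0.4, -0.6, 0, 0.2, 0.8, -1),
                                            each = n), sdlog = 0.6), n, 6)
  amt * matrix(rbinom(n * 6, 1, rep(c(0.95, 0.5, 0.7, 0.9, 0.97, 0.4),
                                    each = n)), n, 6)
}
recalls <- rbind(
  data.frame(person_id = 1:n, day_index = 1L, one_day()),
  data.frame(person_id = 1:n, day_index = 2L, one_day()))
names(recalls)[-(1:2)] <- foods
# ~8% of second days are incomplete
drop2 <- sample(n, 32)
recalls <- recalls[!(recalls$person_id %in% drop2 & recalls$day_index == 2L), ]

avg <- average_recalls(recalls)
cat("Averaged recalls:", nrow(avg$amounts), "persons (",
    nrow(avg$excluded), "excluded with no complete recall)\n")

## eligibility on a synthetic covariate table
cov <- data.frame(
  id = 1:n, sex = "Female",
  age = round(runif(n, 18, 85)),
  race = sample(c("Mexican", "OtherHispanic", "NHWhite", "NHBlack",
                  "NHAsian"), n, TRUE, prob = c(.18, .13, .34, .28, .07)),
  income_ratio = round(runif(n, 0.3, 2.5), 2),
  pregnant = rbinom(n, 1, 0.03) == 1,
  n_recalls = 1L + !(1:n %in% drop2))
elig <- apply_eligibility(cov, eligibility_criteria())
cat("Eligibility: retained", length(elig$ids), "of", n, "- exclusions:\n")
print(elig$tally)

keep <- intersect(as.character(elig$ids), rownames(avg$amounts))
amounts <- avg$amounts[keep, ]
subgroup <- factor(cov$race[match(as.integer(keep), cov$id)],
                   levels = c("Mexican", "OtherHispanic", "NHWhite",
                              "NHBlack", "NHAsian"))

## 4-level coding by population tertiles of positive consumption
rule <- fit_categorization(amounts)
cm <- categorize(amounts, rule, subgroup = subgroup)
write_rule(rule, "results/preprocess/rule.csv")
write_consumption(cm, "results/preprocess/categorized.csv")
cat("\nCutpoints (positive-consumption tertiles):\n")
print(rule)
cat("Level frequencies after categorization:\n")
print(round(prop.table(table(cm$y)), 3))

## risk flags and weighted descriptives
bio <- data.frame(
  total_chol = rnorm(length(keep), 195, 35),
  ldl = rnorm(length(keep), 120, 30),
  chol_meds = rbinom(length(keep), 1, 0.15) == 1,
  bmi = rnorm(length(keep), 30, 6),
  sbp = rnorm(length(keep), 128, 18), dbp = rnorm(length(keep), 78, 10),
  bp_meds = rbinom(length(keep), 1, 0.2) == 1,
  glucose = rnorm(length(keep), 105, 22),
  diabetes_meds = rbinom(length(keep), 1, 0.1) == 1,
  smoker = rbinom(length(keep), 1, 0.25) == 1)
flags <- derive_risk_flags(bio)
weights <- runif(length(keep), 0.5, 3)  # stand-in survey weights
desc <- weighted_descriptives(flags, weights, strata = subgroup,
                              n_boot = 200, seed = 7)
write.csv(desc, "results/preprocess/weighted_descriptives.csv",
          row.names = FALSE)
cat("\nWeighted risk-factor prevalence (% with bootstrap SE), overall:\n")
ov <- desc[desc$stratum == "overall", ]
print(data.frame(flag = ov$variable, pct = round(100 * ov$estimate, 1),
                 se = round(100 * ov$se, 1)), row.names = FALSE)
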