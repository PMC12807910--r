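#!/usr/bin/env Rscript
# Behavioral analyses preceding the model fits: categorization contingency
# tables (by color; by color x ratio difficulty), careless-responder
# exclusion for experiment 2, and "show again later" usage.

library(tvatoj)

trials1 <- read_trials("results/exp1_trials.csv")
trials2 <- read_trials("results/exp2_trials.csv")

tab_color <- contingency_tables(trials1, by = "color")
tab_full <- contingency_tables(trials1, by = "color_difficulty")
write.csv(tab_color, "results/contingency_by_color.csv", row.names = FALSE)
write.csv(tab_full, "results/contingency_by_color_difficulty.csv",
          row.names = FALSE)
cat("categorization accuracy by color (%):\n")
print(tab_color, row.names = FALSE)

excl <- exclude_careless(trials2)
flags <- flagged_participants(excl)
write.csv(as.data.frame(excl), "results/exclusion_per_soa.csv",
          row.names = FALSE)
write.csv(attr(excl, "flags"), "results/exclusion_flags.csv",
          row.names = FALSE)
cat(sprintf("\ncareless exclusion: %d of %d participants flagged (%s)\n",
            length(flags), length(unique(trials2$participant)),
            paste(flags, collapse = ", ")))

keep <- trials2[!(trials2$participant %in% flags), ]
write_trials(keep, "results/exp2_trials_clean.csv")

s <- sal_usage_summary(trials2)
cat(sprintf("deferral usage: %d users, mean %.2f uses (range %d-%d of ~%d)\n",
            s$n_users, s$mean_uses, s$min_uses, s$max_uses,
            s$opportunities))
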