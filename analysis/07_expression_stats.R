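#!/usr/bin/env Rscript
# Relative expression (2^-ddCt) of the stored Ct table and the group
# comparison layer applied to the resulting fold changes.

suppressMessages(library(cardioquant))

q <- read.csv("results/data/qpcr_Nppb.csv")
truth <- read_ground_truth("results/data/qpcr_Nppb.truth.json")
dd <- ddct(q, housekeeping = "Gapdh", control = "CTRL")
write.csv(dd, "results/qpcr_fold_changes.csv", row.names = FALSE)
gm <- tapply(dd$fold, dd$group, function(x) exp(mean(log(x))))
for (g in names(gm)) {
  message(sprintf("  %-8s geometric-mean fold %.3f (true %.3f)", g, gm[[g]],
                  truth$fold_changes[[g]]))
}

r <- compare_groups(data.frame(group = dd$group, value = dd$fold),
                    design = "auto")
message(sprintf("group comparison (%s, design %s): omnibus p = %.3g",
                r$method, r$design, r$p_value))
print(r$pairwise)
jsonlite::write_json(list(method = r$method, p_value = r$p_value,
                          pairwise = r$pairwise),
                     "results/qpcr_stats.json", auto_unbox = TRUE, digits = NA)
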