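#!/usr/bin/env Rscript
# Stage 5: figures. One per-animal pair (epoch activity + intensity trace),
# the full-herd stacked line graph, and the five contiguous sub-group stacks.
# Every figure gets a tidy CSV sidecar of exactly what was drawn.

library(herdrhythm)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

panel <- read_panel_csv("results/panel.csv")
ids <- included_ids(panel)

# representative animal: epochs + trace
id <- ids[1]
es <- read_epoch_csv(file.path("results/epochs", paste0(id, ".csv")))
tr <- read_trace_csv(file.path("results/traces", paste0(id, ".csv")))
plot_animal(es, tr, out_path = file.path("results/figures", paste0(id, ".png")))

# whole herd, then the overlapping contiguous sub-groups
plot_stacked(panel, out_path = "results/figures/herd_stacked.png",
             title = sprintf("Stacked 24 h periodicity intensities, %d animals",
                             length(ids)))
sg <- suppressMessages(subgroup_check(panel, "contiguous-ranges"))
for (g in seq_along(sg$groups)) {
  nm <- gsub("[^0-9]+", "-", names(sg$groups)[g])
  plot_stacked(panel, subset = sg$groups[[g]],
               out_path = file.path("results/figures",
                                    sprintf("subgroup%s_stacked.png", nm)),
               title = paste("Stacked intensities,", names(sg$groups)[g]))
}
cat(sprintf("figures in results/figures: %d files\n",
            length(list.files("results/figures"))))
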