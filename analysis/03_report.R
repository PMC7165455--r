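#!/usr/bin/env Rscript

# Render the Markdown report for the pipeline run (provenance, component
# counts, PCA variance, permutational MANOVA, PC1-PC2 scatter) and print
# where the group difference shows up on the head surface.
#
# Requires analysis/02_pipeline.R to have been run first.

suppressMessages(library(trabmap))

run <- readRDS("results/run/run_record.rds")
path <- make_report(run)
cat("report written to", path, "\n")

# which landmarks carry the group contrast: top PC1 loadings
res <- run$results
tpl <- build_template(run$config$n_curve, run$config$n_surf,
                      run$config$n_divider)
l1 <- res$pca$loadings[, 1]
top <- order(abs(l1), decreasing = TRUE)[1:10]
cat("\nlandmarks with the strongest PC1 loadings (template frame):\n")
print(data.frame(landmark = top, role = tpl$role[top],
                 quarter = tpl$quarter[top],
                 x = round(tpl$points[top, 1], 2),
                 y = round(tpl$points[top, 2], 2),
                 z = round(tpl$points[top, 3], 2),
                 loading = round(l1[top], 3)))
cat("\n(+x medial, +y anterior, +z superior on the unit head)\n")
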