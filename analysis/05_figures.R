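#!/usr/bin/env Rscript

# Step 5: count-plot data.
#
# Cross-tabulates exacerbation counts and SABA prescription counts against
# the six ICS adherence categories (the data behind the study's count
# plots) and writes them as CSV. Pass --plot to also render bar charts
# (requires ggplot2).

suppressPackageStartupMessages({
  library(optparse)
  library(asthmaCMA)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--in", type = "character", default = "results/analysis_dataset.csv",
              dest = "input"),
  make_option("--out", type = "character", default = "results"),
  make_option("--plot", action = "store_true", default = FALSE)
)))

d <- readr::read_csv(opts$input, show_col_types = FALSE)
d$adherence_cat <- factor(d$adherence_cat,
                          c("<=50", "51-60", "61-70", "71-80", "81-90", "91-100"))
d$saba_cat <- factor(d$saba_cat, c("0", "1-2", "3-6", "7-12", ">=13"))
d$exac_cat <- factor(d$exac_cat, c("0", "1", "2", "3", ">=4"))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

fig3 <- countplot_data(d, "adherence_cat", "exac_cat")
fig4 <- countplot_data(d, "adherence_cat", "saba_cat")
readr::write_csv(fig3, file.path(opts$out, "fig3_exacerbations_by_adherence.csv"))
readr::write_csv(fig4, file.path(opts$out, "fig4_saba_by_adherence.csv"))
message("wrote fig3/fig4 cross-tabs; counts per table: ",
        sum(fig3$n), " / ", sum(fig4$n))

if (opts$plot) {
  library(ggplot2)
  p3 <- ggplot(fig3, aes(adherence_cat, n, fill = exac_cat)) +
    geom_col(position = "dodge") +
    labs(x = "ICS adherence category (CMA7)", y = "patients",
         fill = "exacerbations")
  ggsave(file.path(opts$out, "fig3.png"), p3, width = 8, height = 4, dpi = 150)
  p4 <- ggplot(fig4, aes(adherence_cat, n, fill = saba_cat)) +
    geom_col(position = "dodge") +
    labs(x = "ICS adherence category (CMA7)", y = "patients",
         fill = "SABA prescriptions")
  ggsave(file.path(opts$out, "fig4.png"), p4, width = 8, height = 4, dpi = 150)
  message("rendered fig3.png / fig4.png")
}
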