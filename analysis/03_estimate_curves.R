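#!/usr/bin/env Rscript

# Step 3 — estimate the weekly return curves from the late-episode set:
# discrete hazard of return, CDF of return (one minus the product-limit
# survival), and Greenwood-variance 95% bands. With no interior censoring
# the product-limit CDF equals the plain cumulative fraction, which keeps
# every number spreadsheet-checkable.

library(latereturn)

episodes <- readr::read_csv(
  "results/episodes.csv",
  col_types = readr::cols(
    patient_id = readr::col_character(),
    index_visit_date = readr::col_date(),
    expected_return_date = readr::col_date(),
    supply_weeks = readr::col_integer(),
    days_late = readr::col_integer(),
    returned = readr::col_logical(),
    return_week = readr::col_integer()
  )
)

wt <- weekly_table(episodes)
write_weekly_table(wt, "results/weekly_table.csv")

cat(sprintf(
  "By 4 weeks late %.1f%% of late episodes had returned; by 9 weeks %.1f%%; by 26 weeks %.1f%%.\n",
  100 * wt$cdf[4], 100 * wt$cdf[9], 100 * wt$cdf[26]
))
cat(sprintf(
  "Hazard spikes at the refill cycles: week 4 = %.1f%%, week 8 = %.1f%% (neighbouring weeks %.1f%%/%.1f%% and %.1f%%/%.1f%%).\n",
  100 * wt$hazard[4], 100 * wt$hazard[8],
  100 * wt$hazard[3], 100 * wt$hazard[5],
  100 * wt$hazard[7], 100 * wt$hazard[9]
))
cat(sprintf(
  "Of late patients still out at week 4 who will eventually return, %.1f%% return that week.\n",
  100 * conditional_return_proportion(wt, 4)
))

cut <- select_cutoff(wt)
save_ok <- TRUE
for (nm in c("cdf", "hazard")) {
  p <- if (nm == "cdf") plot_cdf(wt, cut) else plot_hazard(wt, cut)
  for (ext in c("png", "svg")) {
    dev <- if (ext == "svg") grDevices::svg else NULL
    tryCatch(
      suppressMessages(ggplot2::ggsave(
        sprintf("results/%s.%s", nm, ext), p,
        device = dev, width = 7, height = 4.5, dpi = 150
      )),
      error = function(e) save_ok <<- FALSE
    )
  }
}
cat(if (save_ok) "Wrote CDF and hazard plots to results/.\n" else "Plot rendering unavailable on this system.\n")
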