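#!/usr/bin/env Rscript

# Step 2 — read the cohort back through the file interface, validate it,
# and apply the inclusion filters: adults (>= 15y) initiating ART in the
# study window, no known death/transfer/stop, expected return at least 12
# months before study end, and >= 7 days late at the return. What survives
# is the analyzable set of late follow-up episodes.

library(latereturn)

patients <- read_patient_table("results/data/patients.csv")
visits <- read_visit_table("results/data/visits.csv")
print(validate_cohort(patients, visits))

built <- build_late_episodes(patients, visits, lateness_config())

readr::write_csv(built$episodes, "results/episodes.csv", progress = FALSE)
readr::write_csv(built$filter_log, "results/filter_log.csv", progress = FALSE)

per_patient <- as.integer(table(built$episodes$patient_id))
cat(sprintf(
  "%d of %d candidate visits remain as late episodes (%d patients; median %d, max %d episodes each).\n",
  nrow(built$episodes), built$n_candidate_visits,
  length(per_patient), stats::median(per_patient), max(per_patient)
))
cat("Visits removed, by filter:\n")
print(as.data.frame(built$filter_log))
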