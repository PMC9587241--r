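#!/usr/bin/env Rscript

# Step 1: generate the synthetic primary-care EHR.
#
# Emits the four routine-care tables (patient registry, diagnosis episodes,
# prescriptions, ACQ records) for a practice-nested asthma cohort, plus the
# ground truth used by later steps to check recovery. The default here is a
# mid-size cohort (~60 practices, ~4,100 patients) so the whole workflow
# runs in a few minutes; pass --full for the full study-scale cohort
# (~200 practices, ~13,750 patients).

suppressPackageStartupMessages({
  library(optparse)
  library(asthmaCMA)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 2016L),
  make_option("--full", action = "store_true", default = FALSE),
  make_option("--out", type = "character", default = "results/synthetic_ehr")
)))

cfg <- if (opts$full) generator_config() else {
  generator_config(n_practices = 60L, mean_patients = 68.8)
}
message(sprintf("generating %d practices (mean %.0f patients each), seed %d",
                cfg$n_practices, cfg$mean_patients, opts$seed))
ehr <- generate_ehr(cfg, seed = opts$seed)
write_ehr(ehr, opts$out)

message(sprintf("wrote %s: %d patients (%d decoys), %d prescriptions, %d ACQ records",
                opts$out, nrow(ehr$patients), sum(!is.na(ehr$truth$decoy)),
                nrow(ehr$prescriptions), nrow(ehr$acq)))
message(sprintf("ground truth: %.1f%% with >=1 exacerbation; %.1f%% ACQ coverage",
                100 * mean(ehr$truth$any_exacerbation, na.rm = TRUE),
                100 * mean(ehr$truth$acq_available, na.rm = TRUE)))
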