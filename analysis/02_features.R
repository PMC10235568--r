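#!/usr/bin/env Rscript
# Extract the univariate linear feature bank in 5-second windows for the
# demonstration patient: relative band powers, spectral edge, moments,
# Hjorth parameters and decorrelation time per channel. (The pairwise
# band ratios and wavelet energies are part of the bank too; they are
# omitted here only to keep the demonstration table compact.)
# Writes the labelled feature matrix to results/.

library(seizecast)

record <- read_record("results/patient_demo")
ann <- read_annotations("results/patient_demo_seizures.csv")

fm <- extract_features(record, ann, preictal_min = 40,
                       features = c("relpower", "sef", "moments",
                                    "hjorth", "decorr"))
print(fm)
cat(sprintf("windows: %d, features: %d, excluded (ictal): %d\n",
            nrow(fm$values), ncol(fm$values), sum(fm$excluded)))

write_features(fm, "results/patient_demo_features.csv")
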