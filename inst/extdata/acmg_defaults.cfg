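# ACMG evaluation thresholds (key <TAB> value); guideline-cited defaults.
# af_ba1: stand-alone common-variant allele-frequency cutoff (BA1)
# af_bs1: allele frequency greater than expected for disorder (BS1)
# af_pm2: "absent/extremely rare in population databases" cutoff (PM2)
# predictor_deleterious: per-predictor score >= this calls deleterious
# predictor_benign: per-predictor score <= this calls benign
# predictor_consensus: fraction of available predictors required (PP3/BP4)
af_ba1	0.05
af_bs1	0.01
af_pm2	0.0001
predictor_deleterious	0.7
predictor_benign	0.3
predictor_consensus	0.75
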