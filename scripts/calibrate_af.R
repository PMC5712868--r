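#!/usr/bin/env Rscript
# One-off calibration of the AF sample-entropy threshold theta_AF stored in
# af_config(). Generates 20 synthetic AF and 20 sinus 5-minute beat windows
# under the generator's default laws (AF RR ~ uniform(0.35, 1.0) s; sinus
# 70 bpm with 30 ms jitter), computes each window's word-value sample
# entropy, and reports the separating threshold (midpoint of the group gap).
#
#   Rscript scripts/calibrate_af.R

library(ecgwatch)

af <- vapply(1:20, function(k)
  detect_af_window(synth_beats("AF", seed = k))$sampen, numeric(1))
sinus <- vapply(1:20, function(k)
  detect_af_window(synth_beats("SINUS", seed = 100 + k))$sampen, numeric(1))

theta <- calibrate_af_threshold(af, sinus)
cat(sprintf("AF SampEn:    min %.4f  max %.4f\n", min(af), max(af)))
cat(sprintf("sinus SampEn: min %.4f  max %.4f\n", min(sinus), max(sinus)))
cat(sprintf("calibrated theta_AF: %.4f (af_config() stores %.2f)\n",
            theta, af_config()$theta_af))
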