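# One-time calibration of the synthetic-cohort defaults.
#
# The generator's defaults (shift_params() and cohort_config()) encode the
# study conditions: cohort-mean D95 ratios 0.9821 overall / 0.9703 island,
# recalculated V100 ~91.4%, Rx/Dmax ratio 0.823/0.830, CI ratio 1.07/1.15.
# This script reruns the calibration diagnostics: it generates cohorts over
# a small seed panel and prints the realized arm means next to the targets,
# so a change to the generator can be re-checked. The frozen defaults in
# R/synthetic.R were fixed from this output once and are not seed-tuned.
#
# Usage: Rscript tools/calibrate_shift.R

suppressMessages(devtools::load_all(file.path(dirname(sub(
  "--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "..")))

targets <- c(d95 = 98.21, d95_island = 97.03, v100 = 91.4,
             rxdmax_ratio = 0.823 / 0.830, ci_ratio = 1.07 / 1.15,
             r50p_ratio = 0.892 / 0.899, dmin_ratio = 88.4 / 90.5)

res <- NULL
for (sd in 1:3) {
  tab <- generate_cohort(cohort_config(seed = sd),
                         arms = c("plan", "recalculated"))
  p <- tab[tab$arm == "plan", ]
  r <- tab[tab$arm == "recalculated", ]
  res <- rbind(res, c(
    d95 = mean(r$d95_pct),
    d95_island = mean(r$d95_pct[r$island]),
    v100 = mean(r$v100_pct),
    rxdmax_ratio = mean(r$rx_over_dmax) / mean(p$rx_over_dmax),
    ci_ratio = mean(r$ci) / mean(p$ci),
    r50p_ratio = mean(r$r50_prime) / mean(p$r50_prime),
    dmin_ratio = mean(r$dmin_pct) / mean(p$dmin_pct)))
}
out <- rbind(realized = colMeans(res),
             target = targets[colnames(res)])
print(round(out, 4))
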