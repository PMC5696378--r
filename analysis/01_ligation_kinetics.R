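#!/usr/bin/env Rscript
# Compare one-step and two-step proximity-ligation kinetics.
#
# Evaluates both closed-form solutions at the inferred rates (p0 = 0.05,
# p1 = 1, p2 = 0.025; N = beta = 1), cross-checks them against fixed-step
# RK4 integration, and tabulates the signal-to-noise ratio y/z over time.
# Writes results/kinetics_trajectories.tsv and
# results/kinetics_signal_noise.tsv.

suppressMessages(library(bridgepet))
dir.create("results", showWarnings = FALSE)

p <- kinetics_params(N = 1, beta = 1, p0 = 0.05, p1 = 1, p2 = 0.025)
grid <- seq(0, 50, by = 0.1)

one <- one_step_closed_form(p, grid)
two <- two_step_closed_form(p, grid)
traj <- rbind(cbind(model = "one-step", one),
              cbind(model = "two-step", two))
write.table(traj, "results/kinetics_trajectories.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# integrator agreement (sanity of both routes)
for (model in c("one-step", "two-step")) {
  tr <- integrate_kinetics(p, model, t_end = 50, n_steps = 50000)
  cf <- if (model == "one-step") one_step_closed_form(p, tr$states$t) else
    two_step_closed_form(p, tr$states$t)
  rel <- abs(as.matrix(tr$states[, -1]) - as.matrix(cf[, -1])) /
    pmax(abs(as.matrix(cf[, -1])), 1e-300)
  rel[as.matrix(cf[, -1]) == 0] <- 0
  cat(sprintf("%s: RK4 vs closed form, max relative deviation %.2e\n",
              model, max(rel)))
}

sn <- merge(signal_noise_curve(one), signal_noise_curve(two), by = "t",
            suffixes = c("_one_step", "_two_step"))
write.table(sn, "results/kinetics_signal_noise.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("small-t signal/noise limit (both models): %.1f\n",
            signal_noise_limit0(p)))
cat(sprintf("t = 1: y/z one-step %.2f, two-step %.2f\n",
            sn$ratio_one_step[sn$t == 1], sn$ratio_two_step[sn$t == 1]))
cat(sprintf("asymptotic y: one-step %.4f, two-step %.4f (alpha = %.4f)\n",
            one$y[length(grid)], two$y[length(grid)], two_step_alpha(p)))
cat(sprintf("asymptotic z (identical by construction): %.6f vs %.6f\n",
            one_step_closed_form(p, 5000)$z, two_step_closed_form(p, 5000)$z))
cat("Signal products saturate more slowly under two-step ligation (the\n")
cat("linker step delays all ligation), while the noise asymptote is\n")
cat("identical; the models are compared per time point, not by endpoint.\n")
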