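#!/usr/bin/env Rscript
# Step 5 -- Three-phase segmentation, the delamination front, and the
# interface/bulk merge prediction.
#
# The tracked trace is segmented into sqrt-t, linear and artifact-jump
# phases.  The constant delamination lag Delta is then estimated from
# changepoint consistency: the delamination front d = X - Delta becomes
# positive exactly when phase II starts, so Delta = alpha_hat *
# sqrt(t1); the membrane relation v2 = D C0 / (S Delta) in turn gives
# the effective interface transport strength D C0 / S = v2 * Delta.
# Finally the merge-time predictor compares the composite interface
# route against bulk diffusion through the droplet cover.

library(corrfront)

cfg <- jsonlite::read_json("results/simulation/config.json",
                           simplifyVector = TRUE)
trace <- read_front_trace("results/tracking/trace.csv")
seg <- segment_phases(trace)
print(seg)

mm_per_px <- cfg$generator$scene$mm_per_px
delta_px <- if (!is.na(seg$t1)) seg$alpha_hat * sqrt(seg$t1) else NA
DC0_S_px2min <- if (!is.na(seg$t1)) seg$v2_hat * delta_px else NA
cat(sprintf("estimated delamination lag Delta = %.1f px (%.2f mm)\n",
            delta_px, delta_px * mm_per_px))
cat(sprintf("implied interface transport D*C0/S = %.3g px^2/min (%.3g mm^2/min)\n",
            DC0_S_px2min, DC0_S_px2min * mm_per_px^2))

# delamination front along the observed trajectory (px units)
X_px <- trace$s
dl <- delamination_front(X_px, delta = delta_px, t = trace$t)
annotated <- data.frame(t_min = trace$t, s_px = trace$s,
                        d_px = dl$d, phase = seg$phase)
dir.create("results/phases", showWarnings = FALSE, recursive = TRUE)
write.csv(annotated, "results/phases/annotated_trace.csv",
          row.names = FALSE)

# merge prediction in CGS: interface transport from the fit, bulk route
# from the cuvette estimate, droplet radius and cover from the scene
bulk <- jsonlite::read_json("results/bulk/estimate.json",
                            simplifyVector = TRUE)
alpha_cm_s <- seg$alpha_hat * (mm_per_px / 10) / sqrt(60)
delta_cm <- delta_px * mm_per_px / 10
DC0_S_cm2_s <- DC0_S_px2min * (mm_per_px / 10)^2 / 60
# represent the fitted interface transport with unit C0/S ratio scaled in
p <- stefan_params(D = DC0_S_cm2_s, C0 = 1, S = 1)
r0_cm <- cfg$generator$scene$droplet_radius_px * mm_per_px / 10
pred <- predict_merge(p, D_bulk = bulk$D_bar_cm2_s,
                      cover_thickness = 0.1, r0 = r0_cm,
                      delta = delta_cm)
print(pred)
jsonlite::write_json(
  list(t1_min = seg$t1, t2_min = seg$t2, alpha_hat_px = seg$alpha_hat,
       v2_hat_px_min = seg$v2_hat, delta_mm = delta_px * mm_per_px,
       t_interface_min = pred$t_interface / 60,
       t_bulk_min = pred$t_bulk / 60, mode = pred$mode),
  "results/phases/segmentation.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/phases/annotated_trace.csv and segmentation.json\n")
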