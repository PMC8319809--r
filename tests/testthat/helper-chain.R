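# Full simulate -> align -> correct -> segment -> quantify chain on a
# phantom scene, with a per-session cache so several test files can share
# one expensive run.

.chain_cache <- new.env(parent = emptyenv())

phantom_chain <- function(preset = "ah-ns-medium", cell_kind = "coccus",
                          interactions = c("penetration", "deformation", "none"),
                          seed = 7, drift_sd_px = 2, noise_sd = 10,
                          texture_sd = 5, tilt_deg = 52, cache = TRUE) {
  key <- paste(preset, cell_kind, paste(unlist(interactions), collapse = "+"),
               seed, drift_sd_px, noise_sd, texture_sd, tilt_deg)
  if (cache && !is.null(.chain_cache[[key]])) return(.chain_cache[[key]])
  sc <- phantom_scene(preset = preset, cell_kind = cell_kind,
                      interactions = interactions, seed = seed)
  acq <- acquisition_params(tilt_deg = tilt_deg,
                            slice_thickness_nm = sc$volume$spacing_nm[3],
                            pixel_size_nm = sc$volume$spacing_nm[1],
                            drift_sd_px = drift_sd_px, noise_sd = noise_sd,
                            texture_sd = texture_sd)
  sim <- simulate_acquisition(sc$volume, acq, seed = seed + 1,
                              ground_truth = sc$ground_truth)
  al <- align_stack(sim$stack)
  st <- correct_foreshortening(crop_canvas(al$stack))
  seg <- segment_labels(st, denoise = noise_sd > 0)
  res <- quantify_volume(seg, ground_truth = sim$ground_truth)
  cmp <- compare_to_ground_truth(res, sim$ground_truth)
  out <- list(scene = sc, acq = acq, sim = sim, alignment = al$alignment,
              stack = st, seg = seg, res = res, cmp = cmp)
  if (cache) .chain_cache[[key]] <- out
  out
}
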