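# A small but feasible two-group pipeline configuration used by the
# pipeline and determinism tests (256 px field, 2 scenes per group).
tiny_pipeline_config <- function(dir, seed = 7) {
  ov <- list(image_size = 256L, n_osteocytes = 4,
             body_axes_px = c(8, 12), deadend_rate = 8)
  pipeline_config(
    seed = seed, output_dir = dir, n_per_group = 2,
    scene_a = ov,
    scene_b = utils::modifyList(ov, list(deadend_rate = 10)))
}
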