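# build a small manifest of saved full-co-location scenes and run the
# pipeline over it
run_fixture_pipeline <- function(out_dir, n_scenes = 3) {
  img_dir <- file.path(tempdir(), "pipe_imgs")
  dir.create(img_dir, showWarnings = FALSE)
  files <- character(n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- small_scene_spec(coloc_fraction = 1, seed = 200 + i,
                           time_min = 30, condition = "EGF",
                           cell_id = sprintf("cell%02d", i))
    sc <- simulate_scene(sp)
    files[i] <- file.path(img_dir, sprintf("scene%02d.tif", i))
    save_stack(sc$stack, files[i])
  }
  manifest <- file.path(img_dir, "manifest.csv")
  write.csv(data.frame(file = files), manifest, row.names = FALSE)
  run_pipeline(list(), manifest, out_dir)
  out_dir
}
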