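# Shared fixtures built in code.

# a small deterministic figure sequence
fixture_walker <- function(n_frames = 20L) {
  generate_action(action_presets()$walk, n_frames = n_frames,
                  frame_duration_s = 0.05, seed = 7L)
}

# single-dot sequence following explicit positions (n x 2 matrix)
fixture_path_sequence <- function(xy, frame_duration_s = 0.05) {
  pos <- array(NA_real_, c(nrow(xy), 1, 2))
  pos[, 1, ] <- xy
  pl_sequence(pos, frame_duration_s, dot_labels = "dot", action_name = "path")
}

# per-dot frame-to-frame displacement array (T-1 x D x 2)
displacements <- function(seq) {
  Tn <- dim(seq$positions)[1]
  seq$positions[-1L, , , drop = FALSE] - seq$positions[-Tn, , , drop = FALSE]
}
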