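# shared fixtures, built in code

# a small two-condition dataset for fast unit tests
tiny_dataset <- function(seed = 11L, n_videos = 2L, n_groups = 2L,
                         n_tracks = 6L) {
  simulate_experiment(experiment_design(
    n_videos_per_condition = n_videos,
    n_groups_per_video = n_groups,
    n_tracks_per_group = n_tracks,
    observation_frames = 40L,
    track_length = list(mean = 15, sd = 8),
    seed = seed))
}

# reduced-input backbone: same architecture, 3x3x256 tap, fast to run
small_spec <- function(seed = 42L) backbone_spec(input_size = 67L,
                                                 seed = seed)

# straight-line track along +x at speed v
line_track <- function(n = 10L, v = 2, t0 = 0L) {
  data.frame(frame = seq.int(t0, length.out = n),
             x = v * (seq_len(n) - 1L), y = rep(0, n))
}
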