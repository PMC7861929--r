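# shared fixtures built in code

ref_path <- function(file) system.file("extdata", file, package = "stackbeat")

ref_confusion <- function(block) {
  df <- read.csv(ref_path("ref_confusions.csv"), stringsAsFactors = FALSE)
  df <- df[df$block == block, ]
  m <- as.matrix(df[match(c("N", "S", "V", "F"), df$true),
                    c("n", "s", "v", "f")])
  dimnames(m) <- list(true = c("N", "S", "V", "F"),
                      pred = c("n", "s", "v", "f"))
  m
}

ref_metric_blocks <- function() read.csv(ref_path("ref_metrics.csv"),
                                         stringsAsFactors = FALSE)

# small mixed-class synthetic record shared by several tests
mixed_record <- function(n_beats = 40, seed = 3, noise_sd = 0.02,
                         baseline_amp = 0.1, rr_jitter_sd = 0) {
  synth_ecg(synth_ecg_config(
    n_beats = n_beats, class_sequence = c("N", "N", "S", "V", "F"),
    noise_sd = noise_sd, baseline_amp = baseline_amp,
    rr_jitter_sd = rr_jitter_sd, seed = seed))
}
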