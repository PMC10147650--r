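# Shared fixtures, independent oracles and lazily cached benchmark
# studies (built once per test session).

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

# classification benchmark study (40 drugs, planted excitatory rule at
# d = 1) with its extracted feature rows; the expensive shared fixture
classification_fixture <- function() {
  cached("classification", function() {
    study <- planted_benchmark_study("classification", master_seed = 101)
    rows <- extract_study_features(study)
    list(study = study, rows = rows)
  })
}

network_fixture <- function() {
  cached("network", function() {
    study <- planted_benchmark_study("network", master_seed = 202)
    rows <- extract_study_features(study)
    list(study = study, rows = rows)
  })
}

# independent O(n^2) brute-force sample-entropy oracle (kept deliberately
# naive; the implementation under test is compiled)
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  A <- 0; B <- 0
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (j <= i) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(0)
  if (A == 0) return(log(B * (B - 1) + 1))
  -log(A / B)
}

# closed-form pooled-variance Student t-test p-value (selection oracle)
pooled_t_p <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  sp2 <- ((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2)
  tv <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  2 * pt(-abs(tv), df = n1 + n0 - 2)
}

# grid recording built from explicit per-wave, per-channel pulse delays
# (bypasses the simulator; used for propagation-pattern constructions)
pulse_recording <- function(delays_per_wave, period = 5, fs = 10,
                            dur = 300, amp = 100, tissue = "ileum") {
  n <- dur * fs
  tt <- (seq_len(n) - 1) / fs
  sig <- matrix(0, 64, n)
  for (k in seq_along(delays_per_wave)) {
    tk <- k * period
    for (c_i in 1:64) {
      tc <- tk + delays_per_wave[[k]][c_i]
      sig[c_i, ] <- sig[c_i, ] + amp * exp(-0.5 * ((tt - tc) /
                                                     (period / 8))^2)
    }
  }
  mea_recording(sig, fs, tissue, 8, 8)
}

grid_x_um <- function() {
  pos <- expand.grid(col = 1:8, row = 1:8)
  pos <- pos[order(pos$row, pos$col), ]
  (pos$col - 1) * 300
}

grid_y_um <- function() {
  pos <- expand.grid(col = 1:8, row = 1:8)
  pos <- pos[order(pos$row, pos$col), ]
  (pos$row - 1) * 300
}

# toy learning dataset with a planted mean shift d on the first
# p_features feature columns
planted_ds <- function(n = 50, d = 2, p_features = 4, seed = 51,
                       kind = "tissue_split(stomach)") {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n)
  feats <- matrix(rnorm(2 * n * 24), 2 * n,
                  dimnames = list(NULL, ef_feature_names()))
  feats[y == 1, seq_len(p_features)] <-
    feats[y == 1, seq_len(p_features)] + d
  # four rows per synthetic drug (labels are drug-consistent) so that a
  # half split keeps nearly every drug covered
  drug <- sprintf("d%s_%03d", c("neg", "pos")[y + 1],
                  (seq_len(2 * n) - 1) %% n %/% 4 + 1)
  ds <- list(features = feats, labels = y,
             meta = data.frame(drug_id = drug,
                               dose = 1e-5,
                               tissue = "stomach",
                               repeat_idx = 1L),
             kind = kind, ae = "toy_ae", ratio = 0.5)
  class(ds) <- "learning_dataset"
  ds
}

# single-drug profile with hand-set multipliers on one tissue
profile_with <- function(tissue, param, value) {
  eff <- data.frame(tissue = gi_tissues, freq_mult = 1, amp_mult = 1,
                    slope_mult = 1, velocity_mult = 1,
                    irregularity_add = 0)
  eff[eff$tissue == tissue, param] <- value
  structure(list(drug_id = "toy", receptor_class = "toy", effects = eff,
                 dose_scaling = 1), class = "drug_profile")
}

# small complete ef_vector with every feature set to `base` except named
# overrides (for normalization arithmetic tests)
ef_vec <- function(base = 10, ...) {
  v <- setNames(rep(base, 24), ef_feature_names())
  over <- list(...)
  v[names(over)] <- unlist(over)
  v
}
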