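# Shared fixtures. Everything is generated in code; the expensive trained
# model used by the recovery/fingerprinting checks is built once per test
# run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

# A tiny deterministic volume_grid pair on an 8^3 grid.
tiny_grid <- function(seed = 1, dims = c(8, 8, 8), hemisphere = "LH") {
  set.seed(seed)
  mask <- hemispec:::ellipsoid_mask(dims, 0.45)
  v <- array(runif(prod(dims), 0.1, 0.9), dims)
  v[!mask] <- 0
  volume_grid(v, mask, hemisphere)
}

tiny_pair <- function(seed = 1, dims = c(8, 8, 8)) {
  hemisphere_pair("toy", tiny_grid(seed, dims, "LH"),
                  tiny_grid(seed + 100, dims, "RH"),
                  covariates = list(age = 30, sex = 1))
}

# A generator whose output is constant regardless of the input: all decoder
# output-layer weights zeroed, so the sigmoid emits 0.5 everywhere.
constant_output_model <- function(dims = c(16, 16, 16), base = 4) {
  m <- build_ce_model(ce_config(in_shape = dims, base_channels = base,
                                use_critic = FALSE), seed = 1)
  ilast <- max(which(vapply(m$gen, function(l) l$type == "tconv", TRUE)))
  m$gen[[ilast]]$W[] <- 0
  m$gen[[ilast]]$b[] <- 0
  m
}

# Replace a model's critic with a hand-set linear critic D(x) = w.x + b.
linear_critic_model <- function(model, w, b = 0) {
  model$critic <- list(list(type = "linear", n_in = length(w), w = w, b = b))
  model
}

# The study-condition training fixture: 60 subjects at 32^3 with planted
# specific components of amplitude 0.3, LH->RH model trained on the first
# 40 subjects for a fixed desk-scale budget (reconstruction-only: 200
# epochs, lr 1e-3 decaying 1%/epoch, batch 8, weight decay 5e-4,
# 128-channel bottleneck); 20 subjects held out.
trained_fixture <- function() {
  if (!is.null(.fixture_env$trained)) return(.fixture_env$trained)
  coh <- generate_cohort(synth_config(grid_shape = c(32, 32, 32),
                                      n_subjects = 60,
                                      specific_amplitude = 0.3, seed = 101))
  model <- build_ce_model(ce_config(in_shape = c(32, 32, 32),
                                    base_channels = 8,
                                    bottleneck_channels = 128,
                                    use_critic = FALSE),
                          seed = 11)
  cfg <- train_config(lambda_rec = 1, lambda_adv = 0, learning_rate = 1e-3,
                      lr_decay = 0.99, batch_size = 8, epochs = 200,
                      weight_decay = 5e-4, seed = 11)
  fit <- train_ce(model, coh$pairs[1:40], cfg)
  .fixture_env$trained <- list(cohort = coh, fit = fit,
                               train_idx = 1:40, test_idx = 41:60)
  .fixture_env$trained
}
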