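#' End-to-end validation experiment on synthetic pairs
#'
#' The package's reference protocol: generate cross-source low-overlap
#' pairs (overlap drawn from 1.3-4.3 %, per-axis rotations up to 170
#' degrees, translations up to 115 mm, intra-operative density twice
#' the pre-operative, optional noise), train the matcher at reduced
#' scale on their cropped counterparts, then register every pair
#' coarse-to-fine and report the error summary. All randomness derives
#' from `seed`.
#'
#' @param n_pairs number of synthetic pairs.
#' @param seed master seed; pair seeds, training and RANSAC seeds are
#'   derived from it.
#' @param n_preop pre-operative cloud size per pair.
#' @param density_ratio intra-/pre-operative sampling density ratio.
#' @param noise_sigma_mm Gaussian noise applied to the intra-operative
#'   clouds (mm).
#' @param epochs training epochs (reduced-scale schedule).
#' @param mode region-selection mode, `"oracle"` or `"blind"`.
#' @param enc_cfg an [encoder_config()].
#' @param verbose print progress.
#' @return list with `report` (an `experiment_report`), `model`, and
#'   `pairs`.
#' @export
validation_experiment <- function(n_pairs = 40L, seed = 1L,
                                  n_preop = 16384L, density_ratio = 2,
                                  noise_sigma_mm = 0, epochs = 20L,
                                  mode = "oracle",
                                  enc_cfg = encoder_config(),
                                  verbose = FALSE) {
  seed <- as.integer(seed)
  pairs <- lapply(seq_len(n_pairs), function(i) {
    make_pair(pair_spec(n_preop = n_preop, density_ratio = density_ratio,
                        noise_sigma_mm = noise_sigma_mm,
                        seed = (seed %% 10000L) * 100000L + i))
  })
  if (verbose) message("generated ", n_pairs, " pairs")
  tp <- training_pairs_from_synthetic(pairs)
  tr_cfg <- training_config(epochs = epochs, batch_size = 2L,
                            learning_rate = 1e-2, temperature_init = 0.1,
                            correspondence_radius = 2.5, seed = seed)
  model <- train_matcher(tp, enc_cfg, tr_cfg, verbose = verbose)
  if (verbose) message("training done; registering")
  cfg <- pipeline_config(seed = seed)
  report <- run_experiment(pairs, model, cfg, mode = mode,
                           verbose = verbose)
  list(report = report, model = model, pairs = pairs)
}
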