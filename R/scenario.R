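#' Run a named simulation scenario end to end
#'
#' The default scenario (`"s1-default"`) is the package's standard test
#' bed: a 400 x 400 x 150 um skin volume with a 3-level vessel tree (7
#' bifurcations), 30 collagen fibers and 6 cells; EM processing applies 5%
#' global shrinkage about the centroid plus 3 smooth displacement bumps
#' (amplitude up to 8 um per axis, width 120 um); 12 bifurcation/crossing
#' landmarks are retained for pairing and observed in each modality with
#' 2 um localization noise and 10% dropout.
#'
#' @param scenario scenario name; only `"s1-default"` is built in.
#' @param seed integer seed controlling every random draw.
#' @param n_landmarks number of landmarks retained for pairing.
#' @return list of class `clem_scenario`: `tissue`, `model`, `processed`
#'   ([apply_em_processing()] result), `lm_observed` / `em_observed`
#'   (noisy [landmark_set()]s), `pairing` (ground-truth-id pairing of the
#'   observed sets), `roi` (first cell centroid, LM frame), `roi_truth`
#'   (its true EM-frame position), `seed`.
#' @export
simulate_scenario <- function(scenario = "s1-default", seed = 1L,
                              n_landmarks = 12L) {
  if (!identical(scenario, "s1-default")) {
    stop("unknown scenario: ", scenario, call. = FALSE)
  }
  seed <- as.integer(seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  params <- tissue_params()
  tissue <- generate_tissue(params, seed = seed)
  # separate stream for deformation + observation so it does not replay
  # the tissue stream (offset wrapped to stay a valid 32-bit seed)
  set.seed(as.integer((as.numeric(seed) + 1000003) %% 2147483647))
  model <- default_deformation(extent = params$extent)
  processed <- apply_em_processing(tissue, model)

  truth <- true_landmarks(tissue,
                          classes = c("VESSEL_BIFURCATION",
                                      "FIBER_CROSSING"))
  sel <- select_spread_landmarks(truth, n_landmarks)
  lm_true <- landmark_set(truth$landmarks[truth$landmarks$id %in% sel, ,
                                          drop = FALSE],
                          name = "LM frame (true)", min_separation = 0)
  co <- processed$correspondence
  em_rows <- co[co$id %in% sel, , drop = FALSE]
  em_true <- landmark_set(
    data.frame(id = em_rows$id, x = em_rows$em_x, y = em_rows$em_y,
               z = em_rows$em_z, feature_class = em_rows$feature_class,
               stringsAsFactors = FALSE),
    name = "EM frame (true)", min_separation = 0)

  lm_obs <- observe_landmarks(lm_true, model)
  em_obs <- observe_landmarks(em_true, model)
  pairing <- pair_by_id(lm_obs, em_obs)

  roi <- region_of_interest(tissue$cells$id[1],
                            as.matrix(tissue$cells[1, c("x", "y", "z")]))
  roi_truth <- deform_points(model, roi$points, processed$center)

  structure(list(tissue = tissue, model = model, processed = processed,
                 lm_true = lm_true, em_true = em_true,
                 lm_observed = lm_obs, em_observed = em_obs,
                 pairing = pairing, roi = roi, roi_truth = roi_truth,
                 seed = seed),
            class = "clem_scenario")
}

# Pick n landmarks with good spatial spread: all vessel bifurcations
# first, then greedy farthest-point selection among the fiber crossings.
select_spread_landmarks <- function(truth, n) {
  lm <- truth$landmarks
  bif <- lm$id[lm$feature_class == "VESSEL_BIFURCATION"]
  if (length(bif) >= n) return(bif[seq_len(n)])
  chosen <- bif
  pool <- lm$id[lm$feature_class == "FIBER_CROSSING"]
  xyz <- as.matrix(lm[, c("x", "y", "z")])
  rownames(xyz) <- lm$id
  while (length(chosen) < n && length(pool) > 0L) {
    d_min <- vapply(pool, function(id) {
      min(sqrt(rowSums(sweep(xyz[chosen, , drop = FALSE], 2,
                             xyz[id, ])^2)))
    }, numeric(1))
    pick <- pool[which.max(d_min)]
    chosen <- c(chosen, pick)
    pool <- setdiff(pool, pick)
  }
  chosen
}
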