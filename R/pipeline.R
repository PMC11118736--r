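# End-to-end orchestration: phantom generation, localizer training and
# evaluation, first-to-last lung slice range selection, segmenter training
# and evaluation, and the eight-configuration ablation sweep. Every random
# operation derives from the run seed; a JSON manifest records the
# configuration, seeds, numerical conventions and per-stage metrics so a
# run is auditable and repeatable.

#' Select the lung slice range from per-slice class probabilities
#'
#' The predicted first lung slice is the slice with the highest
#' first-class probability, the predicted last the one with the highest
#' last-class probability (ties break toward the smaller index). If the
#' pair comes out inverted it is swapped, with a warning, so the returned
#' range is always valid.
#'
#' @param volume_predictions Numeric matrix, one row per slice, columns =
#'   class probabilities (first, other, last). Row `i` corresponds to
#'   slice index `indices[i]`.
#' @param indices 0-based slice indices for the rows (default
#'   `0:(nrow-1)`).
#' @return List with `fl` and `ll`, the inclusive 0-based slice range fed
#'   to segmentation.
#' @export
select_lung_range <- function(volume_predictions, indices = NULL) {
  if (is.null(dim(volume_predictions)) ||
      nrow(volume_predictions) < 1L || ncol(volume_predictions) != 3L) {
    stop("volume_predictions must be a non-empty n x 3 probability matrix")
  }
  if (is.null(indices)) indices <- seq_len(nrow(volume_predictions)) - 1L
  fl <- indices[which.max(volume_predictions[, 1])]
  ll <- indices[which.max(volume_predictions[, 3])]
  if (fl > ll) {
    warning(sprintf("inverted lung range (fl %d > ll %d); swapping", fl, ll))
    tmp <- fl
    fl <- ll
    ll <- tmp
  }
  list(fl = fl, ll = ll)
}

#' Pipeline configuration
#'
#' @param out_dir Run directory for checkpoints, metrics and the manifest.
#' @param n_volumes Phantom volumes to generate (train + held-out).
#' @param n_test Volumes held out for evaluation.
#' @param n_slices,image_size,noise_sd,spacing_mm Phantom geometry, see
#'   [phantom_spec()].
#' @param localizer A [localizer_config()].
#' @param segmenter A [unet_config()].
#' @param loss A [loss_config()].
#' @param loc_epochs,loc_lr Localizer optimizer settings.
#' @param seg_epochs,seg_lr,seg_dice_target Segmenter optimizer settings.
#' @param val_fraction Fraction of training windows held out for
#'   validation (training:validation = 8:2 by default).
#' @param folds Folds for [run_cross_validation()].
#' @param seed Master seed; every stage derives its stream from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("lungfat_run"),
                            n_volumes = 8L, n_test = 3L, n_slices = 14L,
                            image_size = 64L, noise_sd = 50,
                            spacing_mm = 2.5,
                            localizer = localizer_config(),
                            segmenter = unet_config(use_mr = TRUE,
                                                    use_attn = TRUE),
                            loss = loss_config(),
                            loc_epochs = 15L, loc_lr = 0.05,
                            seg_epochs = 40L, seg_lr = 0.3,
                            seg_dice_target = 0.9,
                            val_fraction = 0.2, folds = 4L, seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must be in (0, 1)")
  }
  if (n_test >= n_volumes) stop("n_test must be smaller than n_volumes")
  structure(as.list(environment()), class = "pipeline_config")
}

# deterministic disjoint train/validation split of indices
split_train_val <- function(n, val_fraction, seed) {
  with_seed(seed, {
    idx <- sample(n)
    n_val <- max(1L, round(n * val_fraction))
    list(val = sort(idx[seq_len(n_val)]),
         train = sort(idx[(n_val + 1L):n]))
  })
}

#' Partition indices into cross-validation folds
#'
#' @param n Number of items.
#' @param k Number of folds (>= 2).
#' @param seed Seed for the shuffled assignment.
#' @return List of `k` disjoint index vectors that exactly partition
#'   `1:n`.
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (k < 2L) stop("cross-validation needs k >= 2")
  if (k > n) stop("more folds than items")
  with_seed(seed, {
    idx <- sample(n)
    lapply(seq_len(k), function(f) sort(idx[seq(f, n, by = k)]))
  })
}

#' Run the full localize / range-select / segment pipeline on phantoms
#'
#' Generates seeded phantom volumes, trains the localizer on balanced
#' windows from the training volumes, selects each held-out volume's lung
#' range from the localizer's probabilities, trains SAT and VAT segmenters
#' on the training volumes' lung ranges, and evaluates segmentation on the
#' held-out volumes within their *predicted* ranges. All stage outputs,
#' the numerical conventions in effect (normalization, natural-log class
#' weights, binarization threshold), and per-stage metrics are written to
#' `manifest.json` in the run directory.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `manifest` (path), `localizer`,
#'   `segmenters`, `metrics`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "run.log")
  logline <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", sep = "",
        file = log_file, append = TRUE)
    message(msg)
  }
  manifest <- list(
    seed = config$seed,
    conventions = list(
      normalization = config$localizer$normalization,
      class_weight_log = "natural",
      alpha = config$loss$alpha,
      kappa = config$loss$kappa,
      binarization_threshold = 0.5,
      momentum_beta = 0.9
    ),
    stages = list()
  )
  persist <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  on.exit(persist())

  logline("stage phantom: generating %d volumes (%dx%d, %d slices)",
          config$n_volumes, config$image_size, config$image_size,
          config$n_slices)
  vols <- generate_phantom_batch(config$n_volumes,
                                 n_slices = config$n_slices,
                                 image_size = config$image_size,
                                 spacing_mm = config$spacing_mm,
                                 noise_sd = config$noise_sd,
                                 seed = config$seed)
  test_idx <- seq_len(config$n_test)
  train_vols <- vols[-test_idx]
  test_vols <- vols[test_idx]
  manifest$stages$phantom <- list(n_train = length(train_vols),
                                  n_test = length(test_vols))

  logline("stage localize: building windows (L = %d)",
          config$localizer$window_length)
  wins <- unlist(lapply(seq_along(train_vols), function(i) {
    make_windows(train_vols[[i]]$slices, train_vols[[i]]$loc_labels,
                 config$localizer$window_length,
                 volume_id = paste0("train", i))
  }), recursive = FALSE)
  sv <- split_train_val(length(wins), config$val_fraction,
                        seed = config$seed + 11L)
  labels <- vapply(wins, function(w) w$label, integer(1))
  cw <- compute_class_weights(pmax(tabulate(labels + 1L, 3L), 1L),
                              alpha = config$loss$alpha)
  n_pos <- sum(labels != LBL_OTHER)
  train_wins <- wins[sv$train]
  tp <- max(1L, (n_pos * 2L) %/% 9L) # ~ balanced thirds of training positives
  bal <- tryCatch(
    balance_subsets(train_wins, n_subsets = 3L, target_positive = tp,
                    subset_size = max(2L * tp + tp %/% 5L, tp + 1L),
                    seed = config$seed + 13L),
    error = function(e) NULL
  )
  loc_train <- if (is.null(bal)) train_wins else unlist(bal,
                                                        recursive = FALSE)
  logline("stage localize: training on %d windows (%d epochs)",
          length(loc_train), config$loc_epochs)
  loc_model <- train_localizer(loc_train, config$localizer,
                               epochs = config$loc_epochs,
                               lr = config$loc_lr, class_weights = cw,
                               seed = config$seed + 17L)
  val_acc <- {
    vw <- wins[sv$val]
    mean(vapply(vw, function(w) {
      which.max(classify_window(w, loc_model)) - 1L == w$label
    }, logical(1)))
  }
  loc_eval <- evaluate_localizer(loc_model, test_vols)
  utils::write.csv(loc_eval$per_volume,
                   file.path(config$out_dir, "localization.csv"),
                   row.names = FALSE)
  saveRDS(loc_model, file.path(config$out_dir, "localizer.rds"))
  manifest$stages$localize <- list(
    n_train_windows = length(loc_train), val_accuracy = val_acc,
    md_mm = loc_eval$md_mm,
    final_train_accuracy = utils::tail(loc_model$history$accuracy, 1))
  persist()
  logline("stage localize: MD %.2f mm, val accuracy %.2f",
          loc_eval$md_mm, val_acc)

  logline("stage range-select")
  ranges <- lapply(seq_along(test_vols), function(i) {
    vol <- test_vols[[i]]
    wins_i <- make_windows(vol$slices, vol$loc_labels,
                           config$localizer$window_length)
    probs <- t(vapply(wins_i, classify_window, numeric(3),
                      model = loc_model))
    centers <- vapply(wins_i, function(w) w$center_index, integer(1))
    rg <- select_lung_range(probs, centers)
    true_fl <- which(vol$loc_labels == LBL_FIRST) - 1L
    true_ll <- which(vol$loc_labels == LBL_LAST) - 1L
    covered <- length(intersect(seq(rg$fl, rg$ll),
                                seq(true_fl, true_ll)))
    list(fl = rg$fl, ll = rg$ll, true_fl = true_fl, true_ll = true_ll,
         coverage = covered / (true_ll - true_fl + 1L))
  })
  manifest$stages$range_select <- list(
    ranges = lapply(ranges, function(r) r[c("fl", "ll")]),
    mean_coverage = mean(vapply(ranges, function(r) r$coverage,
                                numeric(1))))
  persist()

  metrics <- list()
  segmenters <- list()
  for (tissue in c("SAT", "VAT")) {
    logline("stage segment %s: training", tissue)
    train_samples <- unlist(lapply(train_vols, make_seg_samples,
                                   tissue = tissue), recursive = FALSE)
    seg_model <- train_segmenter(train_samples, config$segmenter,
                                 loss = config$loss,
                                 epochs = config$seg_epochs,
                                 lr = config$seg_lr,
                                 dice_target = config$seg_dice_target,
                                 seed = config$seed + 29L)
    saveRDS(seg_model, file.path(config$out_dir,
                                 sprintf("segmenter_%s.rds", tolower(tissue))))
    test_samples <- unlist(lapply(seq_along(test_vols), function(i) {
      make_seg_samples(test_vols[[i]], tissue = tissue,
                       range = c(ranges[[i]]$fl, ranges[[i]]$ll))
    }), recursive = FALSE)
    rep <- evaluate_segmenter(seg_model, test_samples)
    metrics[[tissue]] <- rep
    segmenters[[tissue]] <- seg_model
    manifest$stages[[paste0("segment_", tolower(tissue))]] <- list(
      n_train = length(train_samples), n_test = length(test_samples),
      train_epochs = nrow(seg_model$history),
      train_dice = utils::tail(seg_model$history$dice, 1),
      test = rep[c("dice", "f1", "precision", "recall")])
    persist()
    logline("stage segment %s: test dice %.3f", tissue, rep$dice)
  }
  manifest$complete <- TRUE
  persist()
  logline("pipeline complete: %s", config$out_dir)
  invisible(list(manifest = file.path(config$out_dir, "manifest.json"),
                 localizer = loc_model, segmenters = segmenters,
                 metrics = metrics, ranges = ranges))
}

#' Ablation sweep over the eight block combinations
#'
#' Trains one segmenter per `{MR, CP, ATTN}` combination on the same
#' samples and seed and evaluates each on the same held-out samples,
#' emitting a comparison table (which combination wins is a property of
#' the data, not asserted here).
#'
#' @param train_samples,test_samples Lists of `seg_sample` objects.
#' @param depth,base_channels Backbone shape shared by all runs.
#' @param loss A [loss_config()].
#' @param epochs,lr,dice_target Training settings shared by all runs.
#' @param seed Shared seed (same initialization scale per run).
#' @param out_csv Optional path for the table.
#' @param verbose Log one line per configuration.
#' @return Data frame: `model`, `use_mr`, `use_cp`, `use_attn`, `dice`,
#'   `f1`, `precision`, `recall`, `train_dice`, `epochs`.
#' @export
run_ablation <- function(train_samples, test_samples, depth = 4L,
                         base_channels = 16L, loss = loss_config(),
                         epochs = 30L, lr = 0.3, dice_target = NULL,
                         seed = 1L, out_csv = NULL, verbose = FALSE) {
  combos <- expand.grid(use_mr = c(FALSE, TRUE), use_cp = c(FALSE, TRUE),
                        use_attn = c(FALSE, TRUE))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cmb <- combos[i, ]
    cfg <- unet_config(use_mr = cmb$use_mr, use_cp = cmb$use_cp,
                       use_attn = cmb$use_attn, depth = depth,
                       base_channels = base_channels)
    blocks <- c("MR", "CP", "ATTN")[c(cmb$use_mr, cmb$use_cp, cmb$use_attn)]
    name <- if (length(blocks)) {
      paste0("UNet+", paste(blocks, collapse = "+"))
    } else {
      "UNet"
    }
    if (verbose) message("ablation: ", name)
    m <- train_segmenter(train_samples, cfg, loss = loss, epochs = epochs,
                         lr = lr, dice_target = dice_target, seed = seed)
    rep <- evaluate_segmenter(m, test_samples)
    data.frame(model = name, use_mr = cmb$use_mr, use_cp = cmb$use_cp,
               use_attn = cmb$use_attn, dice = rep$dice, f1 = rep$f1,
               precision = rep$precision, recall = rep$recall,
               train_dice = utils::tail(m$history$dice, 1),
               epochs = nrow(m$history))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' K-fold cross-validation for one segmenter configuration
#'
#' @param samples List of `seg_sample` objects.
#' @param config A [unet_config()].
#' @param k Number of folds.
#' @param ... Passed to [train_segmenter()].
#' @param seed Seed for the fold partition and training.
#' @return List with `per_fold` (list of `metrics_report`) and `summary`
#'   (from [aggregate_folds()]).
#' @export
run_cross_validation <- function(samples, config, k = 4L, ..., seed = 1L) {
  folds <- make_folds(length(samples), k, seed = seed)
  reports <- lapply(seq_len(k), function(f) {
    test_i <- folds[[f]]
    m <- train_segmenter(samples[-test_i], config, seed = seed + f, ...)
    evaluate_segmenter(m, samples[test_i])
  })
  list(per_fold = reports, summary = aggregate_folds(reports))
}
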