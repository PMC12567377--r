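# Evaluation protocol: clip-wise stratified folds, leave-one-subject-out
# splits, metrics, paired t-tests, attention attribution, and the
# experiment driver comparing fusion against unimodal and baseline fusion
# heads.

#' Stratified clip-wise cross-validation folds
#'
#' Assigns whole clips to folds so that every fold holds exactly
#' `clips_per_emotion / k` clips of each emotion per subject (one, in the
#' canonical 5-clip / 5-fold design); all windows of a clip share its
#' fold, which rules out window-level leakage between training and
#' validation.
#'
#' @param manifest Data.frame with columns subject, clip, emotion, window.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for the assignment.
#' @return A `fold_split`: clip-level table (subject, clip, emotion, fold).
#' @export
make_clip_folds <- function(manifest, k = 5, seed = 1) {
  clips <- unique(manifest[, c("subject", "clip", "emotion")])
  cnt <- table(clips$subject, clips$emotion)
  abort_if(any(cnt %% k != 0),
           "clips per emotion (", paste(unique(cnt), collapse = ","),
           ") not divisible by k = ", k)
  with_seed(seed, {
    clips$fold <- NA_integer_
    for (s in unique(clips$subject)) {
      for (e in unique(clips$emotion)) {
        idx <- which(clips$subject == s & clips$emotion == e)
        per <- length(idx) %/% k
        clips$fold[sample(idx)] <- rep(seq_len(k), each = per)
      }
    }
  })
  structure(list(assignment = clips, k = k, seed = seed),
            class = "fold_split")
}

#' Train/validation window indices for one fold
#'
#' @param split A `fold_split`.
#' @param manifest The window manifest the split was built from.
#' @param fold Validation fold index.
#' @return List with integer window row indices `train` and `val`.
#' @export
fold_windows <- function(split, manifest, fold) {
  a <- split$assignment
  key <- paste(manifest$subject, manifest$clip)
  vkey <- paste(a$subject, a$clip)[a$fold == fold]
  val <- which(key %in% vkey)
  list(train = setdiff(seq_len(nrow(manifest)), val), val = val)
}

#' Verify clip-level split integrity
#'
#' Asserts that no clip contributes windows to both sides of any fold.
#' Run automatically by the experiment driver.
#'
#' @param split A `fold_split`.
#' @param manifest Window manifest.
#' @return TRUE invisibly; errors on leakage.
#' @export
check_fold_integrity <- function(split, manifest) {
  for (f in seq_len(split$k)) {
    w <- fold_windows(split, manifest, f)
    tr <- unique(paste(manifest$subject[w$train], manifest$clip[w$train]))
    va <- unique(paste(manifest$subject[w$val], manifest$clip[w$val]))
    abort_if(length(intersect(tr, va)) > 0, "clip leakage in fold ", f)
  }
  invisible(TRUE)
}

#' Leave-one-subject-out splits
#'
#' @param manifest Window manifest with a subject column.
#' @return List of splits, each `list(train_subjects, test_subject)`.
#' @export
make_loso_splits <- function(manifest) {
  subs <- sort(unique(manifest$subject))
  abort_if(length(subs) < 2, "LOSO requires at least 2 subjects")
  lapply(subs, function(s) {
    list(train_subjects = setdiff(subs, s), test_subject = s)
  })
}

#' Evaluate predictions into an accuracy/confusion report
#'
#' @param model A trained `mmha_model`, or a precomputed factor of
#'   predicted labels.
#' @param data Prepared tensors with true labels `y` (and `subject`).
#' @return An `eval_report`: overall accuracy (%), row-normalized 4 x 4
#'   confusion matrix, and per-subject accuracy.
#' @export
evaluate <- function(model, data) {
  abort_if(length(data$y) == 0, "empty evaluation set")
  pred <- if (inherits(model, "mmha_model")) {
    predict(model, data)
  } else {
    factor(model, levels = EMOTIONS)
  }
  truth <- factor(EMOTIONS[data$y], levels = EMOTIONS)
  acc <- 100 * mean(pred == truth)
  cm <- table(truth = truth, pred = pred)
  cm_norm <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
  per_subject <- if (!is.null(data$subject)) {
    vapply(split(pred == truth, data$subject), function(z) 100 * mean(z), 0)
  } else {
    NULL
  }
  structure(list(accuracy = acc, confusion = cm_norm,
                 per_subject = per_subject, n = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%% on %d windows\n", x$accuracy, x$n))
  print(round(x$confusion, 3))
  invisible(x)
}

#' Paired two-sided t-test on per-subject accuracies
#'
#' @param acc_a,acc_b Equal-length paired accuracy vectors (%).
#' @return List with `t`, `p`, `df`, `mean_diff`.  Zero-variance non-zero
#'   differences are flagged (`t = NA`) with a warning; identical vectors
#'   give `t = 0, p = 1`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  abort_if(length(acc_a) != length(acc_b), "paired samples must match")
  abort_if(length(acc_a) < 2, "need n >= 2 pairs")
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0))
    }
    warning("zero-variance non-zero differences; t statistic undefined")
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d))
}

# ---------------------------------------------------------------------------
# Attention attribution

#' Facial region masks over the face-token grid
#'
#' Partitions the `gh x gw` token grid of the face encoder into forehead,
#' eyes, cheeks, mouth and other, by normalized grid position.
#'
#' @param gh,gw Token grid height and width.
#' @return Integer assignment vector (token order: grid rows fastest)
#'   with levels eyes/mouth/cheeks/forehead/other.
#' @export
face_region_masks <- function(gh, gw) {
  regions <- c("eyes", "mouth", "cheeks", "forehead", "other")
  assign_one <- function(h, w) {
    u <- (h - 0.5) / gh # 0 = top
    v <- (w - 0.5) / gw
    if (u < 0.28) return("forehead")
    if (u < 0.50) return("eyes")
    if (u < 0.72) { if (v < 0.33 || v > 0.67) return("cheeks") else return("other") }
    if (v >= 0.25 && v <= 0.75) return("mouth")
    "other"
  }
  out <- character(gh * gw)
  t <- 1L
  for (w in seq_len(gw)) {
    for (h in seq_len(gh)) {
      out[t] <- assign_one(h, w)
      t <- t + 1L
    }
  }
  factor(out, levels = regions)
}

#' Attention attribution over EEG bands and facial regions
#'
#' Reads the class-token attention row of the last Transformer block,
#' averaged over heads and windows, sums the mass inside each EEG band
#' token group and each facial region group, and renormalizes within the
#' two groups separately.
#'
#' @param model A trained `"mmha"` `mmha_model`.
#' @param data Prepared tensors.
#' @param region_masks Face-token region assignment (default from the
#'   model's token grid); must partition the grid.
#' @param batch_size Forward batch size.
#' @return An `attribution_report`: `band_weights` (5, summing to 1) and
#'   `face_weights` (5 regions, summing to 1).
#' @export
attention_attribution <- function(model, data, region_masks = NULL,
                                  batch_size = 64) {
  abort_if(!inherits(model, "mmha_model") || model$method != "mmha",
           "attribution requires a trained fusion (mmha) model")
  net <- model$network
  Ts <- net$tokens_per_band
  gh <- net$face_grid[1]; gw <- net$face_grid[2]
  if (is.null(region_masks)) region_masks <- face_region_masks(gh, gw)
  abort_if(length(region_masks) != gh * gw || anyNA(region_masks),
           "region masks must partition the ", gh, "x", gw, " token grid")
  n <- dim(data$topo)[4]
  Te <- 5 * Ts
  acc_tok <- NULL
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    st <- model_step(net, "mmha",
                     data$topo[, , , idx, drop = FALSE],
                     data$faces[, , , idx, drop = FALSE], train = FALSE)
    A <- st$attn[[length(st$attn)]] # T x T x heads x N, last block
    cls_row <- A[1, , , , drop = FALSE]
    m <- apply(cls_row, 2, mean) # mean over heads and windows
    acc_tok <- if (is.null(acc_tok)) m * length(idx) else acc_tok + m * length(idx)
  }
  tok_mass <- acc_tok / n
  eeg_mass <- tok_mass[1 + seq_len(Te)]
  face_mass <- tok_mass[1 + Te + seq_len(gh * gw)]
  band_groups <- rep(seq_len(5), each = Ts)
  band_w <- vapply(1:5, function(b) sum(eeg_mass[band_groups == b]), 0)
  band_w <- band_w / sum(band_w)
  names(band_w) <- BAND_NAMES
  face_w <- vapply(levels(region_masks),
                   function(r) sum(face_mass[region_masks == r]), 0)
  face_w <- face_w / sum(face_w)
  structure(list(band_weights = band_w, face_weights = face_w,
                 token_mass = tok_mass, n_windows = n),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report> mean class-token attention\n")
  cat("  EEG bands: ",
      paste(sprintf("%s %.3f", names(x$band_weights), x$band_weights),
            collapse = "  "), "\n")
  cat("  Face regions: ",
      paste(sprintf("%s %.3f", names(x$face_weights), x$face_weights),
            collapse = "  "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Data preparation and the experiment driver

#' Prepare network input tensors from a synthetic (or loaded) dataset
#'
#' Extracts differential-entropy features per clip, rasterizes per-window
#' band stacks, normalizes face frames per subject, and aligns everything
#' by the manifest.
#'
#' @param ds A `synth_dataset` (or compatible list).
#' @param layout Electrode layout.
#' @param map_size Topographic raster size (224 reference, 64 desk scale).
#' @param floor Clamp floor in nats for sentinel handling.
#' @param verbose Print progress.
#' @return List with `topo` (map_size x map_size x 5 x N), `faces`
#'   (H x W x 3 x N), `y` (integer classes), `subject`, `clip`, `window`,
#'   `manifest`.
#' @export
prepare_model_data <- function(ds, layout = default_layout(), map_size = 64,
                               floor = -10, verbose = FALSE) {
  man <- ds$manifest
  n <- nrow(man)
  fs <- dim(ds$faces[[1]]$pixels)[1]
  topo <- array(0, c(map_size, map_size, 5, n))
  faces <- array(0, c(fs, fs, 3, n))
  norm_frames <- normalize_faces(ds$faces)
  frame_key <- paste(vapply(norm_frames, function(f) f$subject_id, 1),
                     vapply(norm_frames, function(f) f$clip_id, 1),
                     vapply(norm_frames, function(f) f$window, 1))
  row_of_frame <- match(paste(man$subject, man$clip, man$window), frame_key)
  abort_if(anyNA(row_of_frame), "manifest rows without a matching face frame")
  for (i in seq_len(n)) faces[, , , i] <- norm_frames[[row_of_frame[i]]]$pixels
  for (r in seq_along(ds$eeg)) {
    rec <- ds$eeg[[r]]
    de <- extract_de_features(rec)
    rows <- which(man$subject == rec$subject_id & man$clip == rec$clip_id)
    abort_if(length(rows) != dim(de)[1], "manifest/window count mismatch")
    for (w in seq_along(rows)) {
      topo[, , , rows[w]] <- stack_bands(de[w, , ], layout, map_size, floor)
    }
    if (verbose && r %% 10 == 0) message("  featurized clip ", r, "/", length(ds$eeg))
  }
  list(topo = topo, faces = faces,
       y = match(man$emotion, EMOTIONS),
       subject = man$subject, clip = man$clip, window = man$window,
       manifest = man)
}

subset_data <- function(data, idx) {
  list(topo = data$topo[, , , idx, drop = FALSE],
       faces = data$faces[, , , idx, drop = FALSE],
       y = data$y[idx], subject = data$subject[idx],
       clip = data$clip[idx], window = data$window[idx],
       manifest = data$manifest[idx, , drop = FALSE])
}

#' Run a comparative fusion experiment
#'
#' Trains the Transformer fusion model, the two unimodal encoders and the
#' concatenation baseline on clip-wise folds, derives decision-level
#' fusion from the trained unimodal models, and reports accuracy per
#' method with paired t-tests of the fusion model against each baseline.
#' Split integrity is asserted on every run.
#'
#' @param data Prepared tensors from [prepare_model_data()].
#' @param cfg A `model_config`.
#' @param k Number of folds (default 5).
#' @param folds Which folds to run (default 1; the full protocol uses
#'   `1:k`).
#' @param epochs,batch_size,lr Training hyperparameters.
#' @param seed Seed controlling fold assignment, initialization, batches.
#' @param methods Methods to train.
#' @param verbose Print progress.
#' @return An `mmha_experiment`: per-fold accuracy table, summary
#'   (mean and STD per method), confusions, t-tests, trained models of the
#'   last fold.
#' @export
run_experiment <- function(data, cfg = desk_model_config(), k = 5, folds = 1,
                           epochs = 10, batch_size = 32, lr = 1e-3, seed = 1,
                           methods = c("efem", "fefem", "mmha", "concat"),
                           verbose = FALSE) {
  split <- make_clip_folds(data$manifest, k = k, seed = seed)
  check_fold_integrity(split, data$manifest)
  res <- list()
  confusions <- list()
  models <- list()
  per_subject <- list()
  for (f in folds) {
    w <- fold_windows(split, data$manifest, f)
    tr <- subset_data(data, w$train)
    va <- subset_data(data, w$val)
    preds <- list()
    for (m in methods) {
      if (verbose) message("fold ", f, ": training ", m)
      fit <- mmha_train(tr, method = m, cfg = cfg, epochs = epochs,
                        batch_size = batch_size, lr = lr,
                        seed = seed + 17 * f, verbose = verbose)
      ev <- evaluate(fit, va)
      res[[length(res) + 1]] <- data.frame(method = m, fold = f,
                                           accuracy = ev$accuracy)
      confusions[[paste(m, f)]] <- ev$confusion
      per_subject[[paste(m, f)]] <- ev$per_subject
      models[[m]] <- fit
      preds[[m]] <- predict(fit, va, type = "prob")
    }
    if (all(c("efem", "fefem") %in% methods)) {
      pd <- fuse_decision(preds$efem, preds$fefem)
      lab <- factor(EMOTIONS[max.col(pd, "first")], levels = EMOTIONS)
      ev <- evaluate(lab, va)
      res[[length(res) + 1]] <- data.frame(method = "decision", fold = f,
                                           accuracy = ev$accuracy)
      confusions[[paste("decision", f)]] <- ev$confusion
      per_subject[[paste("decision", f)]] <- ev$per_subject
    }
  }
  res <- do.call(rbind, res)
  summary_tab <- do.call(rbind, lapply(split(res, res$method), function(d) {
    data.frame(method = d$method[1], mean = mean(d$accuracy),
               sd = if (nrow(d) > 1) stats::sd(d$accuracy) else NA_real_,
               n_folds = nrow(d))
  }))
  # paired t-tests (per-subject accuracies, last fold) of fusion vs rest
  ttests <- list()
  if ("mmha" %in% methods) {
    for (m in setdiff(unique(res$method), "mmha")) {
      a <- per_subject[[paste("mmha", folds[length(folds)])]]
      b <- per_subject[[paste(m, folds[length(folds)])]]
      if (!is.null(a) && !is.null(b) && length(a) == length(b) &&
          length(a) >= 2 && stats::sd(a - b) > 0) {
        ttests[[m]] <- paired_ttest(a, b)
      }
    }
  }
  structure(list(results = res, summary = summary_tab,
                 confusions = confusions, ttests = ttests,
                 per_subject = per_subject, models = models,
                 split = split, folds = folds, seed = seed),
            class = "mmha_experiment")
}

#' Run a leave-one-subject-out evaluation
#'
#' For every subject, trains on all other subjects' windows and evaluates
#' on the held-out subject — the subject-independent counterpart of the
#' clip-wise protocol.  Subject-level split integrity is asserted on every
#' split.
#'
#' @param data Prepared tensors from [prepare_model_data()].
#' @param cfg A `model_config`.
#' @param method Model variant to train per split.
#' @param epochs,batch_size,lr Training hyperparameters.
#' @param seed Seed controlling initialization and batch order.
#' @param subjects Which held-out subjects to run (default all).
#' @param verbose Print progress.
#' @return A data.frame with one row per held-out subject (subject,
#'   accuracy, n windows) plus a `summary` attribute (mean, sd).
#' @export
run_loso <- function(data, cfg = desk_model_config(), method = "mmha",
                     epochs = 10, batch_size = 32, lr = 1e-3, seed = 1,
                     subjects = NULL, verbose = FALSE) {
  splits <- make_loso_splits(data$manifest)
  if (!is.null(subjects)) {
    splits <- Filter(function(s) s$test_subject %in% subjects, splits)
  }
  rows <- list()
  for (sp in splits) {
    tr_idx <- which(data$subject %in% sp$train_subjects)
    te_idx <- which(data$subject == sp$test_subject)
    abort_if(length(intersect(tr_idx, te_idx)) > 0, "subject leakage")
    if (verbose) message("LOSO: held-out subject ", sp$test_subject)
    fit <- mmha_train(subset_data(data, tr_idx), method = method, cfg = cfg,
                      epochs = epochs, batch_size = batch_size, lr = lr,
                      seed = seed + sp$test_subject, verbose = verbose)
    ev <- evaluate(fit, subset_data(data, te_idx))
    rows[[length(rows) + 1]] <- data.frame(subject = sp$test_subject,
                                           accuracy = ev$accuracy,
                                           n = ev$n)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(mean = mean(out$accuracy),
                            sd = stats::sd(out$accuracy))
  out
}

#' @export
print.mmha_experiment <- function(x, ...) {
  cat("<mmha_experiment> accuracy (%) by method\n")
  tab <- x$summary
  tab$mean <- sprintf("%.2f", tab$mean)
  tab$sd <- ifelse(is.na(tab$sd), "-", sprintf("(+/-%.2f)", as.numeric(tab$sd)))
  print(tab, row.names = FALSE)
  if (length(x$ttests) > 0) {
    cat("paired t-tests, fusion vs:\n")
    for (m in names(x$ttests)) {
      tt <- x$ttests[[m]]
      cat(sprintf("  %-9s t = %.3f, p = %.4f\n", m, tt$t, tt$p))
    }
  }
  invisible(x)
}
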