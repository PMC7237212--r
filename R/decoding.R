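#' Novelty labels of a protocol
#'
#' A trial is novel (label 1) iff no earlier trial presented a stimulus at
#' the same grid location.
#'
#' @param protocol a [protocol()] (typically random-loom).
#' @return integer vector of 0/1 labels, one per trial.
#' @export
novelty_labels <- function(protocol) {
  key <- paste(round(protocol$events$x, 6), round(protocol$events$y, 6))
  as.integer(!duplicated(key))
}

#' Assemble a decoding dataset from a trial table
#'
#' Builds the trials x neurons matrix of stimulus-period spike counts with
#' the location (1-25) and novelty labels of each trial, and the layer
#' group of each neuron.
#'
#' @param trial_table a [build_trial_table()] table.
#' @param neurons the neuron metadata table (for receptive-field centers
#'   used by [augment_population()]).
#' @param grid the stimulus grid (a [loom_grid()]).
#' @return an object of class `decoding_dataset`: list with `X`,
#'   `y_location`, `y_novelty`, `repeat_idx`, `groups`, `neurons`, `grid`.
#' @export
decoding_dataset <- function(trial_table, neurons, grid = loom_grid()) {
  ids <- unique(trial_table$neuron)
  one <- trial_table[trial_table$neuron == ids[1], ]
  ord <- order(one$trial)
  one <- one[ord, ]
  X <- vapply(ids, function(id) {
    rows <- trial_table[trial_table$neuron == id, ]
    rows$count[order(rows$trial)]
  }, numeric(nrow(one)))
  colnames(X) <- ids
  groups <- neurons$layer[match(ids, neurons$id)]
  structure(list(X = X, y_location = one$location,
                 y_novelty = as.integer(one$novel),
                 repeat_idx = one$repeat_idx,
                 groups = groups,
                 neurons = neurons[match(ids, neurons$id), ],
                 grid = grid),
            class = "decoding_dataset")
}

grid_row_col <- function(idx, grid) {
  cbind(col = (idx - 1) %% grid$ncol + 1, row = (idx - 1) %/% grid$ncol + 1)
}

grid_index <- function(col, row, grid) (row - 1) * grid$ncol + col

#' Augment a population with spatially shifted virtual neurons
#'
#' Each neuron contributes up to nine copies (the original plus the eight
#' shifts of a 3 x 3 neighborhood on the stimulus grid): a copy's response
#' profile is the source profile translated by the shift vector, so its
#' response to a trial at location `l` is the source neuron's recorded
#' response at location `l - shift` — counts are relabeled, never
#' resampled. Repeat structure is preserved by matching the per-location
#' repeat index (capped at the number of occurrences available at the
#' source location). Copies whose shifted profile center falls outside the
#' stimulus presentation area are discarded. Trials whose mapped source
#' location lies off the grid take the source's response at the in-grid
#' location farthest from its receptive field — a location where the
#' source profile is at its background.
#'
#' @param dataset a [decoding_dataset()].
#' @param bounds presentation-area bounds, `list(x=, y=)`; defaults to the
#'   stimulus grid extent plus half a spacing.
#' @return a `decoding_dataset` whose `X` has one column per retained
#'   copy and whose `copies` table records (source, shift_x, shift_y).
#' @export
augment_population <- function(dataset, bounds = NULL) {
  grid <- dataset$grid
  sp <- grid$spacing
  if (is.null(bounds)) {
    bounds <- list(
      x = range(grid$centers[, 1]) + c(-sp, sp) / 2,
      y = range(grid$centers[, 2]) + c(-sp, sp) / 2)
  }
  rc <- grid_row_col(dataset$y_location, grid)
  n_trials <- nrow(dataset$X)
  # index of the trial holding (location, capped repeat) for fast lookup
  occ <- split(seq_len(n_trials), dataset$y_location)
  shifts <- expand.grid(sx = -1:1, sy = -1:1)
  cols <- list()
  copies <- list()
  for (j in seq_len(ncol(dataset$X))) {
    nr <- dataset$neurons[j, ]
    # fallback: in-grid location farthest from the source receptive field
    d_far <- sqrt((grid$centers[, 1] - nr$rf_x)^2 +
                    (grid$centers[, 2] - nr$rf_y)^2)
    far_loc <- which.max(d_far)
    for (s in seq_len(nrow(shifts))) {
      sx <- shifts$sx[s]
      sy <- shifts$sy[s]
      px <- nr$rf_x + sx * sp
      py <- nr$rf_y + sy * sp
      if (px < bounds$x[1] || px > bounds$x[2] ||
          py < bounds$y[1] || py > bounds$y[2]) next
      if (sx == 0 && sy == 0) {
        v <- dataset$X[, j]
      } else {
        src_col <- rc[, "col"] - sx
        src_row <- rc[, "row"] - sy
        ok <- src_col >= 1 & src_col <= grid$ncol &
          src_row >= 1 & src_row <= grid$nrow
        src_loc <- ifelse(ok, grid_index(src_col, src_row, grid), far_loc)
        v <- vapply(seq_len(n_trials), function(t) {
          trials_at <- occ[[as.character(src_loc[t])]]
          if (is.null(trials_at)) return(dataset$X[t, j])
          k <- min(dataset$repeat_idx[t], length(trials_at))
          dataset$X[trials_at[k], j]
        }, numeric(1))
      }
      cols[[length(cols) + 1L]] <- v
      copies[[length(copies) + 1L]] <- data.frame(
        source = colnames(dataset$X)[j], group = dataset$groups[j],
        shift_x = sx, shift_y = sy)
    }
  }
  X <- do.call(cbind, cols)
  copies <- do.call(rbind, copies)
  colnames(X) <- paste0(copies$source, "_s", copies$shift_x, copies$shift_y)
  out <- dataset
  out$X <- X
  out$groups <- copies$group
  out$copies <- copies
  out
}

#' Chance level of a decoding task
#'
#' Location: the most frequent location's share of trials,
#' `max_i n_i / sum_j n_j`. Novelty: the fraction of non-novel trials.
#'
#' @param task `"location"` or `"novelty"`.
#' @param labels label vector (location indices, or 0/1 novelty).
#' @return probability in `[0, 1]`.
#' @export
chance_level <- function(task, labels) {
  stopifnot(length(labels) > 0)
  if (task == "location") {
    max(table(labels)) / length(labels)
  } else if (task == "novelty") {
    mean(labels == 0)
  } else {
    stop("unknown task: ", task)
  }
}

make_stratified_folds <- function(y, folds, seed) {
  for (try in 0:19) {
    fold_of <- integer(length(y))
    with_seed(seed + try * 7919, {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold_of[idx] <- (seq_along(idx) + sample.int(folds, 1)) %% folds + 1
      }
    })
    # every class that occurs at least twice must reach every training set;
    # singleton classes unavoidably miss the training set of their own fold
    multi <- names(which(table(y) >= 2))
    ok <- all(vapply(seq_len(folds), function(f) {
      all(multi %in% unique(y[fold_of != f])) && sum(fold_of == f) > 0
    }, logical(1)))
    if (ok) return(fold_of)
  }
  warning("could not build folds with every class in every training set")
  fold_of
}

#' Cross-validated linear decoder accuracy
#'
#' L2-regularized logistic regression (multinomial softmax for the
#' location task, binomial for novelty) on raw spike counts, with inverse
#' regularization strength `C = 1` and stratified, seeded fold assignment.
#' Fits use `glmnet` with `lambda = 1 / (C * n_train)`, the exact
#' correspondence to the per-sample-averaged penalized likelihood, no
#' feature standardization, unpenalized intercept.
#'
#' @param X trials x neurons count matrix.
#' @param y label vector.
#' @param folds number of cross-validation folds (default 4).
#' @param seed RNG seed for fold assignment.
#' @param C inverse regularization strength.
#' @return mean accuracy over folds.
#' @export
fit_decoder <- function(X, y, folds = 4, seed = 1, C = 1.0) {
  y <- factor(y)
  stopifnot(nlevels(y) >= 2, nrow(X) == length(y))
  fold_of <- make_stratified_folds(y, folds, seed)
  fam <- if (nlevels(y) > 2) "multinomial" else "binomial"
  acc <- vapply(seq_len(folds), function(f) {
    tr <- which(fold_of != f)
    # classes with a single training trial cannot be fit; their test
    # trials remain in the fold and count as errors
    cnt <- table(y[tr])
    tr <- tr[y[tr] %in% names(cnt)[cnt >= 2]]
    lam <- 1 / (C * length(tr))
    # coordinate descent needs a gradual path from the data-driven lambda_max
    # down to the target lambda; the advisory about rare classes is expected
    quiet_glmnet <- function(...) {
      withCallingHandlers(
        glmnet::glmnet(..., family = fam, alpha = 0, standardize = FALSE),
        warning = function(w) {
          # rare-class advisories, and path truncation on (near-)rank-
          # degenerate subsamples — handled by clamping s to the smallest
          # lambda the solver reached
          if (grepl("fewer than 8|dangerous|Convergence for",
                    conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    }
    xtr <- X[tr, , drop = FALSE]
    ytr <- droplevels(y[tr])
    # probe fit only for the data-driven lambda_max; its own convergence
    # is irrelevant
    f0 <- suppressWarnings(quiet_glmnet(xtr, ytr, nlambda = 3))
    lmax <- max(f0$lambda[1], lam * 10)
    fit <- quiet_glmnet(xtr, ytr,
                        lambda = exp(seq(log(lmax), log(lam),
                                         length.out = 30)),
                        maxit = 1e6, thresh = 1e-7)
    te <- which(fold_of == f)
    s_use <- max(lam, min(fit$lambda))
    pred <- withCallingHandlers(
      stats::predict(fit, X[te, , drop = FALSE], s = s_use,
                     type = "class"),
      warning = function(w) {
        # tied path knots after truncation; interpolation result unaffected
        if (grepl("collapsing to unique", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    mean(pred == as.character(y[te]))
  }, numeric(1))
  mean(acc)
}

#' Decoder accuracy versus population size
#'
#' For each layer group and requested size, repeatedly subsamples that many
#' (possibly virtual) neurons and reports the mean and standard deviation
#' of the cross-validated decoder accuracy for the location and novelty
#' tasks, alongside the chance levels.
#'
#' @param dataset an (augmented) [decoding_dataset()].
#' @param sizes subsample sizes (the standard ladder by default).
#' @param reps number of random subsamples per size.
#' @param seed master seed.
#' @param tasks which tasks to decode.
#' @param folds cross-validation folds.
#' @return data frame (group, task, size, mean, sd, chance, reps); sizes
#'   exceeding a group's pool are skipped with a warning.
#' @export
subsample_curve <- function(dataset, sizes = c(5, 10, 30, 70, 150, 300),
                            reps = 100, seed = 1,
                            tasks = c("location", "novelty"), folds = 4) {
  out <- list()
  for (grp in unique(dataset$groups)) {
    pool <- which(dataset$groups == grp)
    for (sz in sizes) {
      if (length(pool) < sz) {
        warning(sprintf("group %s has %d neurons < size %d; skipped",
                        grp, length(pool), sz))
        next
      }
      accs <- matrix(NA_real_, reps, length(tasks),
                     dimnames = list(NULL, tasks))
      for (rep_i in seq_len(reps)) {
        sub_seed <- derive_seed(seed, paste(grp, sz, rep_i))
        cols <- with_seed(sub_seed, sample(pool, sz))
        for (task in tasks) {
          yy <- if (task == "location") dataset$y_location else
            dataset$y_novelty
          accs[rep_i, task] <- fit_decoder(
            dataset$X[, cols, drop = FALSE], yy, folds = folds,
            seed = sub_seed)
        }
      }
      for (task in tasks) {
        yy <- if (task == "location") dataset$y_location else
          dataset$y_novelty
        out[[length(out) + 1L]] <- data.frame(
          group = grp, task = task, size = sz,
          mean = mean(accs[, task]),
          sd = if (reps > 1) stats::sd(accs[, task]) else 0,
          chance = chance_level(task, yy), reps = reps)
      }
    }
  }
  do.call(rbind, out)
}
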