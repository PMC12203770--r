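#' Trim a session's trials and hold out the final block
#'
#' Unsuccessful trials are removed first; the remainder is trimmed to its
#' middle `n_keep` trials (centered window, `floor((n - n_keep)/2)` leading
#' trials dropped); the final `n_holdout` of the kept block, in original
#' order, become the holdout never seen in training or validation.
#'
#' @param trials a trial table (data.frame with `outcome`).
#' @param n_keep trials retained after trimming (default 600).
#' @param n_holdout trailing trials held out (default 100).
#' @return list with `kept` (the middle `n_keep` trial row indices into
#'   `trials`), `train_pool` (kept minus holdout) and `holdout`.
#' @export
trim_and_holdout <- function(trials, n_keep = 600, n_holdout = 100) {
  ok <- which(trials$outcome == "success")
  if (length(ok) < n_keep) {
    stop(sprintf(
      "trim_and_holdout: %d successful trials, need >= %d (pass a smaller n_keep for a reduced protocol)",
      length(ok), n_keep))
  }
  lead <- floor((length(ok) - n_keep) / 2)
  kept <- ok[lead + seq_len(n_keep)]
  holdout <- kept[(n_keep - n_holdout + 1):n_keep]
  list(kept = kept, train_pool = kept[seq_len(n_keep - n_holdout)],
       holdout = holdout)
}

#' Build the five-fold trial-level split
#'
#' The training pool is shuffled once with the given seed and partitioned
#' into five equal blocks; fold i uses block i as validation and the other
#' four as training, so every trial appears in exactly four of the five
#' training sets. Shuffling is trial-level only; bins within a trial stay
#' contiguous.
#'
#' @param kept vector of trial indices (length divisible by 5).
#' @param seed shuffle seed.
#' @param n_folds number of folds (default 5).
#' @return a `fold_split`: list with `folds` (list of `list(train, validation)`),
#'   `shuffled`, `seed`.
#' @export
make_folds <- function(kept, seed = 1L, n_folds = 5) {
  n <- length(kept)
  if (n %% n_folds != 0) {
    stop(sprintf("make_folds: %d trials not divisible into %d folds", n, n_folds))
  }
  k <- n / n_folds
  shuffled <- with_seed(seed, sample(kept))
  blocks <- split(shuffled, rep(seq_len(n_folds), each = k))
  folds <- lapply(seq_len(n_folds), function(i) {
    list(train = unlist(blocks[-i], use.names = FALSE),
         validation = blocks[[i]])
  })
  structure(list(folds = folds, shuffled = shuffled, seed = as.integer(seed),
                 n_folds = n_folds), class = "fold_split")
}

#' Assemble multi-context training sets
#'
#' "full" concatenates the complete training fold from every context
#' (4 x 400 = 1600 trials by default). "mixed" takes the first 25\% of each
#' context's already-shuffled training fold, sampled sequentially (the first
#' quarter of the first context, the next quarter of the second, etc.), so
#' its size matches a single-context training fold with equal counts per
#' context.
#'
#' @param folds_by_context named list mapping context -> [make_folds()] result.
#' @param fold_id which fold to draw from (1-based).
#' @param kind "full" or "mixed".
#' @return list with `kind`, `fold_id`, `indices` (trial indices), and
#'   `per_context` (named list of the contributing indices).
#' @export
make_multi_context <- function(folds_by_context, fold_id,
                               kind = c("full", "mixed")) {
  kind <- match.arg(kind)
  contexts <- names(folds_by_context)
  sizes <- vapply(folds_by_context,
                  function(f) length(f$folds[[fold_id]]$train), integer(1))
  if (length(unique(sizes)) != 1) {
    stop("make_multi_context: contexts have differing fold geometry")
  }
  n_train <- sizes[[1]]
  per_context <- vector("list", length(contexts))
  names(per_context) <- contexts
  for (i in seq_along(contexts)) {
    tr <- folds_by_context[[contexts[i]]]$folds[[fold_id]]$train
    per_context[[i]] <- if (kind == "full") {
      tr
    } else {
      # sequential quarter: context i contributes its i-th 25% slice
      q <- n_train / length(contexts)
      tr[((i - 1) * q + 1):(i * q)]
    }
  }
  list(kind = kind, fold_id = fold_id,
       indices = unlist(per_context, use.names = FALSE),
       per_context = per_context)
}

#' Filter a contiguous trial block before trial-metric computation
#'
#' Drops the first `n_exclude` trials of the block (familiarization), then
#' optionally keeps only the middle 100 trials of the remainder (or all of
#' them if fewer than 100 remain).
#'
#' @param trial_ids vector of trial identifiers in block order.
#' @param middle_100 if TRUE, keep only the middle 100 post-exclusion trials.
#' @param n_exclude leading trials to drop (default 5).
#' @return filtered trial ids; empty (with a warning) if the block is shorter
#'   than the exclusion.
#' @export
prepare_trial_block <- function(trial_ids, middle_100 = FALSE, n_exclude = 5) {
  if (length(trial_ids) <= n_exclude) {
    warning("prepare_trial_block: block shorter than the exclusion; empty result")
    return(trial_ids[0])
  }
  rest <- trial_ids[-seq_len(n_exclude)]
  if (middle_100 && length(rest) > 100) {
    lead <- floor((length(rest) - 100) / 2)
    rest <- rest[lead + seq_len(100)]
  }
  rest
}
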