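#' Write a binned session to a plain-text container
#'
#' The container is a directory holding `sbp.csv` (T x C), `position.csv`
#' and `velocity.csv` (T x 2), `trials.csv`, and `meta.json` (bin width,
#' seeds, schema version, prebinned flag). Real recordings supplied already
#' binned use the same layout with `prebinned: true`, bypassing the SBP
#' extraction chain.
#'
#' @param session a `binned_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$sbp, file.path(path, "sbp.csv"), row.names = FALSE)
  utils::write.csv(session$kinematics$position,
                   file.path(path, "position.csv"), row.names = FALSE)
  utils::write.csv(session$kinematics$velocity,
                   file.path(path, "velocity.csv"), row.names = FALSE)
  utils::write.csv(session$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  jsonlite::write_json(session$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binned session from a plain-text container
#'
#' @param path directory written by [write_session()].
#' @return a `binned_session`.
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  session <- list(
    sbp = as.matrix(utils::read.csv(file.path(path, "sbp.csv"))),
    kinematics = list(
      position = as.matrix(utils::read.csv(file.path(path, "position.csv"))),
      velocity = as.matrix(utils::read.csv(file.path(path, "velocity.csv"))),
      bin_ms = meta$bin_ms),
    trials = utils::read.csv(file.path(path, "trials.csv"),
                             stringsAsFactors = FALSE),
    meta = meta)
  dimnames(session$sbp) <- NULL
  dimnames(session$kinematics$position) <- NULL
  dimnames(session$kinematics$velocity) <- NULL
  class(session) <- "binned_session"
  validate_session(session)
  session
}

#' Serialize a fold split to JSON
#'
#' Stores the trial indices, shuffle seed, and a provenance tag so a split
#' can be reproduced and audited against its session.
#'
#' @param split a `fold_split`.
#' @param path output file.
#' @param provenance free-form provenance string (e.g. session digest).
#' @return `path`, invisibly.
#' @export
write_fold_split <- function(split, path, provenance = "") {
  jsonlite::write_json(
    list(seed = split$seed, n_folds = split$n_folds,
         shuffled = split$shuffled,
         folds = lapply(split$folds, function(f)
           list(train = f$train, validation = f$validation)),
         provenance = provenance, schema_version = 1L),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fold split from JSON
#'
#' @param path file written by [write_fold_split()].
#' @return a `fold_split`.
#' @export
read_fold_split <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite simplifies the fold list to a data.frame of list-columns
  folds <- lapply(seq_along(j$folds$train), function(i)
    list(train = j$folds$train[[i]], validation = j$folds$validation[[i]]))
  structure(list(folds = folds, shuffled = j$shuffled, seed = j$seed,
                 n_folds = j$n_folds), class = "fold_split")
}
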