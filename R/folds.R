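#' Configuration-level fold assignment (Stage 2)
#'
#' Randomly partitions configuration identifiers into `k` folds whose sizes
#' differ by at most one. The unit of partitioning is the synapse
#' configuration: all sample points of one configuration share its fold, so
#' no configuration can contribute to both the training and test side of
#' the same fold (the leakage guard behind the cross-validation design).
#'
#' @param config_ids vector of configuration identifiers (unique).
#' @param k number of folds (default 10).
#' @param seed integer RNG seed.
#' @return named integer vector mapping `config_id` to fold index 1..k,
#'   class `fold_assignment`.
#' @export
make_folds <- function(config_ids, k = 10L, seed = 1L) {
  stopifnot(k >= 2)
  if (anyDuplicated(config_ids))
    stop("config_ids must be unique", call. = FALSE)
  n <- length(config_ids)
  if (k > n)
    stop(sprintf("cannot make %d folds from %d configurations", k, n),
         call. = FALSE)
  set.seed(seed)
  fold <- rep(seq_len(k), length.out = n)[sample.int(n)]
  structure(setNames(as.integer(fold), as.character(config_ids)),
            class = "fold_assignment", k = as.integer(k))
}
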