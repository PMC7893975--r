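#' Aggregate attention weights over repeated training runs
#'
#' Trains `R` independent models with seeds `base_seed .. base_seed+R-1`
#' (different random initializations) and sums, elementwise per herb, the
#' second-layer attention weights each model assigns to every positive
#' prescription. Summing and averaging induce the same herb ranking; the
#' default follows the summed form, `average = TRUE` divides by `R`.
#'
#' @param dataset output of [build_balanced_dataset()].
#' @param vocabulary a [herb_vocabulary()] covering the corpus.
#' @param runs number of independent training runs R (default 10).
#' @param base_seed integer; run r uses seed `base_seed + r - 1`.
#' @param hyper a [hann_hyper()].
#' @param average return mean instead of summed weights.
#' @return list of class `aggregated_weights`: `weights` (named list,
#'   prescription id -> numeric vector named by herb), `runs`,
#'   `averaged`.
#' @export
multi_run_attention <- function(dataset, vocabulary, runs = 10L,
                                base_seed = 1L, hyper = hann_hyper(),
                                average = FALSE) {
  stopifnot(runs >= 1L)
  pos_idx <- which(dataset$labels == 1L)
  pos <- dataset$prescriptions[pos_idx]
  pos_ids <- lapply(pos, function(p) herb_id(vocabulary, p$herbs))
  agg <- lapply(pos, function(p) {
    w <- numeric(length(p$herbs))
    names(w) <- p$herbs
    w
  })
  names(agg) <- vapply(pos, function(p) p$id, character(1))
  for (r in seq_len(runs)) {
    fit <- hann_train(dataset, vocabulary, hyper = hyper,
                      seed = as.integer(base_seed) + r - 1L)
    for (i in seq_along(pos)) {
      alpha <- hann_forward(pos_ids[[i]], fit$params)$alpha
      agg[[i]] <- agg[[i]] + alpha
    }
  }
  if (average) agg <- lapply(agg, function(w) w / runs)
  structure(list(weights = agg, runs = as.integer(runs),
                 averaged = isTRUE(average)),
            class = "aggregated_weights")
}

#' Distill a prescription to its essential herbs
#'
#' `top_n` mode ranks herbs by descending weight — ties broken by original
#' prescription position, earlier first — and keeps the first
#' `min(N, k)`. `threshold` mode keeps herbs whose weight is at least
#' `tau`; if none survive, the single best herb is kept with a warning.
#' The output preserves the original relative herb order and is always a
#' subset of the input.
#'
#' @param p a [prescription()].
#' @param weights numeric vector of per-herb weights, aligned with
#'   `p$herbs`.
#' @param mode `"top_n"` (default) or `"threshold"`.
#' @param n herbs to retain in `top_n` mode (default 8).
#' @param tau minimum weight in `threshold` mode (no default; required).
#' @return the distilled [prescription()].
#' @export
distill_prescription <- function(p, weights, mode = c("top_n", "threshold"),
                                 n = 8L, tau = NULL) {
  mode <- match.arg(mode)
  k <- length(p$herbs)
  if (length(weights) != k) {
    stop("weights length (", length(weights), ") != herb count (", k,
         ") for prescription '", p$id, "'")
  }
  if (mode == "top_n") {
    if (is.null(n) || n < 1L) stop("top_n mode requires n >= 1")
    # order() is stable, so equal weights fall back to original position
    keep_rank <- order(-weights)[seq_len(min(n, k))]
  } else {
    if (is.null(tau) || tau < 0) stop("threshold mode requires tau >= 0")
    keep_rank <- which(weights >= tau)
    if (length(keep_rank) == 0L) {
      warning("no herb reaches tau = ", tau, " in prescription '", p$id,
              "'; keeping the single top herb")
      keep_rank <- order(-weights)[1L]
    }
  }
  keep <- sort(keep_rank)  # original relative order
  prescription(p$id, p$herbs[keep], p$efficacies)
}

#' Distill every positive prescription of a balanced dataset
#'
#' @param dataset output of [build_balanced_dataset()].
#' @param aggregated an [multi_run_attention()] result for `dataset`.
#' @param mode,n,tau passed to [distill_prescription()].
#' @return list of distilled positive prescriptions, in dataset order.
#' @export
distill_positives <- function(dataset, aggregated,
                              mode = c("top_n", "threshold"),
                              n = 8L, tau = NULL) {
  mode <- match.arg(mode)
  pos <- dataset$prescriptions[dataset$labels == 1L]
  lapply(pos, function(p) {
    w <- aggregated$weights[[p$id]]
    if (is.null(w)) stop("no aggregated weights for prescription '", p$id, "'")
    distill_prescription(p, w, mode = mode, n = n, tau = tau)
  })
}
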