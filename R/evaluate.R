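#' Correctness of one mined herbal group against the gold standard
#'
#' Greedy alignment: the mined group is matched to whichever gold group
#' maximizes the Dice coefficient `2|hg ∩ hg'| / (|hg| + |hg'|)`.
#' Alignment is independent per mined group (with replacement): several
#' mined groups may align to the same gold group.
#'
#' @param hg character vector, the mined herb set (non-empty).
#' @param s_e list of character vectors, the efficacy's gold groups
#'   (non-empty).
#' @return value in `[0, 1]`; 1 iff `hg` equals some gold group.
#' @export
correctness <- function(hg, s_e) {
  hg <- unique(as.character(hg))
  if (length(hg) == 0L) stop("empty mined group")
  if (length(s_e) == 0L) stop("empty gold standard for the efficacy")
  max(vapply(s_e, function(g) {
    g <- unique(as.character(g))
    2 * length(intersect(hg, g)) / (length(hg) + length(g))
  }, numeric(1)))
}

#' Per-efficacy identification accuracy
#'
#' Soft mode (default): the mean Correctness of the mined groups, i.e.
#' partial overlaps earn partial credit. Strict mode: the fraction of
#' mined groups exactly equal (as sets) to some gold group. An empty
#' mined set scores 0 with a warning.
#'
#' @param a_e list of character vectors, the mined groups.
#' @param s_e list of character vectors, the gold groups.
#' @param mode `"soft"` or `"strict"`.
#' @return accuracy in `[0, 1]`.
#' @export
acc_e <- function(a_e, s_e, mode = c("soft", "strict")) {
  mode <- match.arg(mode)
  if (length(a_e) == 0L) {
    warning("no mined groups; accuracy is 0")
    return(0)
  }
  if (mode == "soft") {
    mean(vapply(a_e, correctness, numeric(1), s_e = s_e))
  } else {
    gold_keys <- vapply(s_e, function(g) paste(sort(unique(g)), collapse = "\r"),
                        character(1))
    mean(vapply(a_e, function(hg) {
      paste(sort(unique(hg)), collapse = "\r") %in% gold_keys
    }, logical(1)))
  }
}

#' Overall accuracy across efficacies
#'
#' The unweighted arithmetic mean of the per-efficacy accuracies.
#'
#' @param per_efficacy numeric vector of per-efficacy accuracies.
#' @return mean accuracy.
#' @export
overall_accuracy <- function(per_efficacy) {
  if (length(per_efficacy) == 0L) stop("no per-efficacy accuracies")
  mean(as.numeric(per_efficacy))
}

#' Average precision of a ranked herb list
#'
#' With `n_p` annotated essential herbs, `AP = (1/n_p) * sum_i
#' i / position(i)`, where `position(i)` is the 1-based rank of the i-th
#' essential herb when the essential herbs are taken in rank order. Every
#' term is at most 1, so `AP <= 1`, with equality iff the essential herbs
#' occupy the top `n_p` ranks.
#'
#' @param ranking character vector of herb names in descending score
#'   order (each herb once).
#' @param essential character vector (subset of `ranking`) of annotated
#'   essential herbs; non-empty.
#' @return AP in `(0, 1]`.
#' @export
average_precision <- function(ranking, essential) {
  essential <- unique(as.character(essential))
  if (length(essential) == 0L) stop("no essential herbs given")
  pos <- match(essential, ranking)
  if (anyNA(pos)) {
    stop("essential herb(s) absent from the ranking: ",
         paste(essential[is.na(pos)], collapse = ", "))
  }
  pos <- sort(pos)
  mean(seq_along(pos) / pos)
}

#' Mean average precision over an efficacy's prescriptions
#'
#' @param aps numeric vector of per-prescription AP values.
#' @return their arithmetic mean.
#' @export
map_e <- function(aps) {
  if (length(aps) == 0L) stop("no AP values")
  mean(as.numeric(aps))
}

#' Expected MAP of uniformly random herb rankings
#'
#' Monte-Carlo estimate: for each prescription the herb order is permuted
#' uniformly and the AP against its essential set recomputed; the mean
#' over permutations and prescriptions estimates the chance-level MAP
#' that a trained ranking must beat.
#'
#' @param prescriptions list of [prescription()] objects.
#' @param essential named list: prescription id -> character vector of
#'   essential herbs.
#' @param n_perm permutations per prescription (default 1000).
#' @param seed integer seed.
#' @return expected MAP under random ranking.
#' @export
random_ranking_map <- function(prescriptions, essential, n_perm = 1000L,
                               seed = 1L) {
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  aps <- vapply(prescriptions, function(p) {
    ess <- essential[[p$id]]
    if (is.null(ess) || length(ess) == 0L) return(NA_real_)
    mean(vapply(seq_len(n_perm), function(i) {
      average_precision(sample(p$herbs), ess)
    }, numeric(1)))
  }, numeric(1))
  map_e(aps[!is.na(aps)])
}

#' Two-stage pipeline for one efficacy
#'
#' Balanced dataset, `runs` training runs with aggregated attention,
#' top-N distillation, Apriori mining, and soft/strict accuracy against
#' the gold standard.
#'
#' @param corpus a [prescription_corpus()].
#' @param gold gold standard (named list efficacy -> list of groups).
#' @param efficacy target efficacy label.
#' @param K itemset size for mining.
#' @param M rank for the M-th-largest-support rule (or `NULL`).
#' @param min_sup explicit support threshold (used when `M` is `NULL`).
#' @param n top-N herbs retained per distilled prescription.
#' @param runs training runs aggregated into the attention weights.
#' @param seed integer seed for the balanced sample and run seeds.
#' @param hyper a [hann_hyper()].
#' @param mode accuracy mode, `"soft"` or `"strict"`.
#' @return list with `acc` (distilled two-stage accuracy), `raw_acc`
#'   (raw-Apriori baseline on undistilled positives at the same
#'   settings), `groups`, `raw_groups`, `aggregated`, `dataset`.
#' @export
run_efficacy_pipeline <- function(corpus, gold, efficacy, K = 2L, M = 8L,
                                  min_sup = NULL, n = 8L, runs = 10L,
                                  seed = 1L, hyper = hann_hyper(),
                                  mode = "soft") {
  dataset <- build_balanced_dataset(corpus, efficacy, seed = seed)
  raw_pos <- dataset$prescriptions[dataset$labels == 1L]
  raw_groups <- detect_eshgs(raw_pos, K = K, M = M, min_sup = min_sup)
  agg <- multi_run_attention(dataset, corpus$vocabulary, runs = runs,
                             base_seed = seed, hyper = hyper)
  distilled <- distill_positives(dataset, agg, mode = "top_n", n = n)
  groups <- detect_eshgs(distilled, K = K, M = M, min_sup = min_sup)
  list(acc = acc_e(groups, gold[[efficacy]], mode = mode),
       raw_acc = acc_e(raw_groups, gold[[efficacy]], mode = mode),
       groups = groups, raw_groups = raw_groups,
       aggregated = agg, dataset = dataset)
}

#' Distilled-versus-raw comparison harness
#'
#' Repeats the two-stage pipeline `repeats` times per efficacy with
#' distinct seeds and compares against the deterministic raw-Apriori
#' baseline, reporting per-efficacy mean accuracy with a 95% normal
#' confidence half-width (`1.96 * sd / sqrt(repeats)`; 0 when
#' `repeats = 1`) and the overall means.
#'
#' @inheritParams run_efficacy_pipeline
#' @param efficacies efficacy labels to evaluate (default: all in
#'   `gold`).
#' @param repeats pipeline repetitions per efficacy.
#' @param base_seed integer; repetition j of efficacy i derives its seed
#'   deterministically from it.
#' @return object of class `eshg_report`: a data.frame with one row per
#'   efficacy plus an overall row, and settings in attributes.
#' @export
compare_harness <- function(corpus, gold, efficacies = names(gold),
                            K = 2L, M = 8L, min_sup = NULL, n = 8L,
                            runs = 10L, repeats = 10L, base_seed = 1L,
                            hyper = hann_hyper(), mode = "soft") {
  stopifnot(repeats >= 1L)
  rows <- list()
  for (i in seq_along(efficacies)) {
    eff <- efficacies[[i]]
    accs <- numeric(repeats)
    raw_acc <- NA_real_
    for (j in seq_len(repeats)) {
      seed_ij <- as.integer(base_seed) + 1000L * (i - 1L) +
        100L * (j - 1L)
      res <- run_efficacy_pipeline(corpus, gold, eff, K = K, M = M,
                                   min_sup = min_sup, n = n, runs = runs,
                                   seed = seed_ij, hyper = hyper,
                                   mode = mode)
      accs[j] <- res$acc
      if (j == 1L) raw_acc <- res$raw_acc
    }
    half <- if (repeats > 1L) 1.96 * stats::sd(accs) / sqrt(repeats) else 0
    rows[[i]] <- data.frame(efficacy = eff, raw_acc = raw_acc,
                            distilled_acc = mean(accs), ci95 = half,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  overall <- data.frame(efficacy = "overall",
                        raw_acc = overall_accuracy(tab$raw_acc),
                        distilled_acc = overall_accuracy(tab$distilled_acc),
                        ci95 = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(tab, overall)
  attr(out, "settings") <- list(K = K, M = M, min_sup = min_sup, n = n,
                                runs = runs, repeats = repeats,
                                mode = mode)
  class(out) <- c("eshg_report", class(out))
  out
}
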