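# Coerce transactions (prescriptions or character vectors) to canonical
# sorted unique item vectors.
as_transactions <- function(transactions) {
  lapply(transactions, function(t) {
    items <- if (inherits(t, "prescription")) t$herbs else as.character(t)
    sort(unique(items))
  })
}

itemset_key <- function(ids) paste(ids, collapse = "\r")

# Tally, over all transactions, every l-subset that actually occurs.
# Returns a named integer vector keyed by itemset_key of sorted item ids.
occurring_subset_counts <- function(tx_ids, l, keep = NULL) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (t in tx_ids) {
    if (length(t) < l) next
    subs <- utils::combn(t, l)
    for (j in seq_len(ncol(subs))) {
      key <- itemset_key(subs[, j])
      if (!is.null(keep) && !exists(key, envir = keep, inherits = FALSE)) next
      cur <- if (exists(key, envir = env, inherits = FALSE)) {
        get(key, envir = env)
      } else 0L
      assign(key, cur + 1L, envir = env)
    }
  }
  keys <- ls(env, sorted = FALSE)
  counts <- vapply(keys, function(k) get(k, envir = env), integer(1))
  names(counts) <- keys
  counts
}

key_to_ids <- function(key) as.integer(strsplit(key, "\r", fixed = TRUE)[[1]])

# Classic F_{l-1} x F_{l-1} candidate generation with subset pruning.
# `freq_prev` is a list of sorted integer vectors; returns an environment
# whose keys are the candidate itemset keys.
apriori_candidates <- function(freq_prev, l) {
  keep <- new.env(hash = TRUE, parent = emptyenv())
  if (length(freq_prev) == 0L) return(keep)
  prev_env <- new.env(hash = TRUE, parent = emptyenv())
  for (f in freq_prev) assign(itemset_key(f), TRUE, envir = prev_env)
  prefix <- vapply(freq_prev, function(f) itemset_key(f[-length(f)]),
                   character(1))
  last <- vapply(freq_prev, function(f) f[length(f)], integer(1))
  for (grp in split(seq_along(freq_prev), prefix)) {
    if (length(grp) < 2L) next
    grp <- grp[order(last[grp])]
    for (a in seq_len(length(grp) - 1L)) {
      for (b in seq((a + 1L), length(grp))) {
        cand <- c(freq_prev[[grp[a]]], last[grp[b]])
        # prune: every (l-1)-subset must be frequent
        ok <- TRUE
        for (drop in seq_len(l)) {
          if (!exists(itemset_key(cand[-drop]), envir = prev_env,
                      inherits = FALSE)) {
            ok <- FALSE
            break
          }
        }
        if (ok) assign(itemset_key(cand), TRUE, envir = keep)
      }
    }
  }
  keep
}

#' Frequent K-itemsets by the Apriori algorithm
#'
#' Level-wise candidate generation with the standard anti-monotonicity
#' pruning, exact transaction-count supports, and a final report of the
#' itemsets of exactly size `K`. `min_sup = 0` is treated as "every
#' K-itemset occurring at least once" — support-0 itemsets are never
#' enumerated.
#'
#' @param transactions list of prescriptions or character vectors; each
#'   transaction is a set (duplicates collapse).
#' @param K itemset size (>= 1).
#' @param min_sup absolute support threshold (transaction count, >= 0).
#' @return object of class `frequent_itemsets`: list with `K`, `min_sup`
#'   (effective threshold used), and `itemsets`, a data.frame with
#'   list-column `itemset` (sorted herb names) and integer `support`,
#'   sorted by descending support then lexicographic herbs.
#' @export
apriori_k_itemsets <- function(transactions, K, min_sup) {
  stopifnot(K >= 1L, min_sup >= 0, length(transactions) > 0L)
  K <- as.integer(K)
  tx <- as_transactions(transactions)
  min_sup_eff <- max(as.integer(min_sup), 1L)
  universe <- sort(unique(unlist(tx, use.names = FALSE)))
  tx_ids <- lapply(tx, function(t) match(t, universe))

  # level 1
  counts1 <- table(factor(unlist(tx_ids, use.names = FALSE),
                          levels = seq_along(universe)))
  freq <- lapply(which(as.integer(counts1) >= min_sup_eff), function(i) i)
  supports <- as.integer(counts1)[vapply(freq, identity, integer(1))]
  level <- 1L
  while (level < K && length(freq) > 0L) {
    level <- level + 1L
    cand <- apriori_candidates(freq, level)
    counts <- occurring_subset_counts(tx_ids, level, keep = cand)
    keep <- counts >= min_sup_eff
    freq <- lapply(names(counts)[keep], key_to_ids)
    supports <- unname(counts[keep])
  }
  if (level < K) {
    freq <- list()
    supports <- integer()
  }
  sets <- lapply(freq, function(ids) universe[ids])
  res <- data.frame(support = as.integer(supports))
  res$itemset <- sets
  if (nrow(res) > 0L) {
    lex <- vapply(sets, function(s) paste(s, collapse = "\r"), character(1))
    ord <- order(-res$support, lex)
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(list(K = K, min_sup = min_sup_eff,
                 itemsets = res[, c("itemset", "support")]),
            class = "frequent_itemsets")
}

#' @export
print.frequent_itemsets <- function(x, ...) {
  cat("<frequent_itemsets> K=", x$K, " min_sup=", x$min_sup, ": ",
      nrow(x$itemsets), " itemsets\n", sep = "")
  invisible(x)
}

#' Support multiset of all occurring K-itemsets
#'
#' @param transactions list of prescriptions or character vectors.
#' @param K itemset size.
#' @return named integer vector: tab-joined sorted herb names ->
#'   transaction count, for every K-itemset occurring at least once.
#' @export
itemset_supports <- function(transactions, K) {
  tx <- as_transactions(transactions)
  universe <- sort(unique(unlist(tx, use.names = FALSE)))
  tx_ids <- lapply(tx, function(t) match(t, universe))
  counts <- occurring_subset_counts(tx_ids, as.integer(K))
  if (length(counts) == 0L) return(stats::setNames(integer(), character()))
  nm <- vapply(names(counts), function(k) {
    paste(universe[key_to_ids(k)], collapse = "\t")
  }, character(1))
  stats::setNames(as.integer(counts), nm)
}

#' M-th largest support among occurring K-itemsets
#'
#' Supports of all occurring K-itemsets are sorted in descending order as
#' a multiset (duplicate values kept) and the M-th entry is returned; when
#' fewer than M itemsets occur, the smallest occurring support is returned
#' with a warning. Used as the data-driven `min_sup` rule.
#'
#' @param transactions list of prescriptions or character vectors.
#' @param K itemset size.
#' @param M rank (>= 1) into the descending support multiset.
#' @return absolute support count.
#' @export
mth_largest_support <- function(transactions, K, M) {
  stopifnot(M >= 1L)
  sup <- itemset_supports(transactions, K)
  if (length(sup) == 0L) {
    stop("no ", K, "-itemset occurs in the transactions")
  }
  sorted <- sort(as.integer(sup), decreasing = TRUE)
  if (length(sorted) < M) {
    warning("only ", length(sorted), " ", K, "-itemsets occur; using the ",
            "smallest occurring support")
    return(sorted[length(sorted)])
  }
  sorted[as.integer(M)]
}

#' Detect candidate efficacy-specific herbal groups
#'
#' Computes the support threshold (from the M-th-largest rule when `M` is
#' given, otherwise the explicit `min_sup`), mines the frequent
#' K-itemsets, and returns them as herbal groups.
#'
#' @param transactions (distilled) positive prescriptions for one
#'   efficacy.
#' @param K itemset size.
#' @param M rank for [mth_largest_support()]; exactly one of `M` and
#'   `min_sup` must be given.
#' @param min_sup explicit absolute support threshold.
#' @return list of sorted herb-name vectors (the candidate groups), with
#'   attributes `min_sup` and `supports` (integer vector aligned with the
#'   groups).
#' @export
detect_eshgs <- function(transactions, K, M = NULL, min_sup = NULL) {
  if (is.null(M) == is.null(min_sup)) {
    stop("give exactly one of M and min_sup")
  }
  if (!is.null(M)) {
    min_sup <- mth_largest_support(transactions, K, M)
  }
  res <- apriori_k_itemsets(transactions, K, min_sup)
  groups <- res$itemsets$itemset
  attr(groups, "min_sup") <- res$min_sup
  attr(groups, "supports") <- res$itemsets$support
  groups
}
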