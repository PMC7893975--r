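#' Configuration for the synthetic prescription corpus
#'
#' The generator emulates the statistical structure the two-stage pipeline
#' assumes: each efficacy owns a small set of planted herbal groups drawn
#' from a reserved herb pool; positive prescriptions contain at least one
#' complete planted group of their efficacy, padded with background herbs
#' whose usage frequencies follow a Zipf law; negative prescriptions are
#' background-only. The gap between the planted groups' support among
#' positives and any background itemset's support is the signal the miner
#' must exploit.
#'
#' @param n_herbs vocabulary size (canonical herbs, before synonyms).
#' @param n_efficacies number of efficacy labels.
#' @param groups_per_efficacy planted groups per efficacy.
#' @param group_size_range integer `c(min, max)` group sizes, min >= 2.
#' @param n_pos_per_efficacy positive prescriptions per efficacy.
#' @param n_neg_per_efficacy background-only prescriptions per efficacy.
#' @param rx_len_range integer `c(min, max)` prescription lengths;
#'   min must be at least the minimum group size.
#' @param noise_rate fraction in `[0, 1]`: probability that each padded
#'   slot of a positive prescription draws a background herb rather than
#'   another complete planted group. At 0 every positive is exactly a
#'   union of complete planted groups.
#' @param background_skew Zipf exponent (>= 0) for background herb
#'   frequencies; 0 gives uniform usage.
#' @param synonym_rate fraction of herbs given a second surface form,
#'   emitted in place of the canonical name with probability 1/2.
#' @param seed integer seed; the whole corpus is deterministic given the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_herbs = 100L,
                       n_efficacies = 2L,
                       groups_per_efficacy = 3L,
                       group_size_range = c(2L, 3L),
                       n_pos_per_efficacy = 50L,
                       n_neg_per_efficacy = 50L,
                       rx_len_range = c(6L, 12L),
                       noise_rate = 0.5,
                       background_skew = 1.5,
                       synonym_rate = 0,
                       seed = 1L) {
  cfg <- list(n_herbs = as.integer(n_herbs),
              n_efficacies = as.integer(n_efficacies),
              groups_per_efficacy = as.integer(groups_per_efficacy),
              group_size_range = as.integer(group_size_range),
              n_pos_per_efficacy = as.integer(n_pos_per_efficacy),
              n_neg_per_efficacy = as.integer(n_neg_per_efficacy),
              rx_len_range = as.integer(rx_len_range),
              noise_rate = as.numeric(noise_rate),
              background_skew = as.numeric(background_skew),
              synonym_rate = as.numeric(synonym_rate),
              seed = as.integer(seed))
  stopifnot(length(cfg$group_size_range) == 2L,
            length(cfg$rx_len_range) == 2L)
  if (cfg$group_size_range[1] < 2L) stop("minimum group size must be >= 2")
  if (cfg$group_size_range[1] > cfg$group_size_range[2]) {
    stop("group_size_range must be non-decreasing")
  }
  if (cfg$rx_len_range[1] < cfg$group_size_range[1]) {
    stop("minimum prescription length must be >= minimum group size")
  }
  if (cfg$rx_len_range[1] > cfg$rx_len_range[2]) {
    stop("rx_len_range must be non-decreasing")
  }
  if (cfg$noise_rate < 0 || cfg$noise_rate > 1) stop("noise_rate must be in [0, 1]")
  if (cfg$background_skew < 0) stop("background_skew must be >= 0")
  if (cfg$synonym_rate < 0 || cfg$synonym_rate > 1) stop("synonym_rate must be in [0, 1]")
  max_reserved <- cfg$n_efficacies * cfg$groups_per_efficacy * cfg$group_size_range[2]
  if (cfg$n_herbs < max_reserved + cfg$rx_len_range[2]) {
    stop("n_herbs too small: need at least ", max_reserved + cfg$rx_len_range[2],
         " herbs for ", cfg$n_efficacies, " efficacies x ",
         cfg$groups_per_efficacy, " groups plus background")
  }
  structure(cfg, class = "sim_config")
}

sim_herb_names <- function(n) sprintf("herb_%03d", seq_len(n))

sim_efficacy_names <- function(n) sprintf("efficacy_%d", seq_len(n))

#' Plant gold-standard herbal groups
#'
#' Draws `groups_per_efficacy` herb sets per efficacy from disjoint
#' efficacy-reserved pools, so no planted group of one efficacy can occur
#' by construction inside another efficacy's prescriptions. Groups within
#' an efficacy are also disjoint, hence pairwise distinct.
#'
#' @param cfg a [sim_config()].
#' @return Named list (efficacy -> list of sorted herb-name vectors), the
#'   gold standard against which mined groups are scored.
#' @export
plant_gold_groups <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- local_seed(cfg$seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  herbs <- sim_herb_names(cfg$n_herbs)
  pool <- sample(herbs)  # random reservation order
  gold <- list()
  taken <- 0L
  for (eff in sim_efficacy_names(cfg$n_efficacies)) {
    groups <- vector("list", cfg$groups_per_efficacy)
    for (g in seq_len(cfg$groups_per_efficacy)) {
      size <- sample(seq(cfg$group_size_range[1], cfg$group_size_range[2]), 1L)
      groups[[g]] <- sort(pool[taken + seq_len(size)])
      taken <- taken + size
    }
    gold[[eff]] <- groups
  }
  gold
}

# Zipf-skewed sampling weights over the background pool.
zipf_weights <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

#' Simulate a prescription corpus around planted gold groups
#'
#' For each efficacy, generates positive prescriptions that contain at
#' least one complete planted group, padded to a sampled length with
#' background herbs (probability `noise_rate` per padded slot) or further
#' complete groups of the same efficacy; and background-only negative
#' prescriptions. No prescription that lacks an efficacy label contains a
#' complete planted group of any efficacy (guaranteed by the disjoint
#' reserved pools and asserted). When `synonym_rate > 0` some herbs carry
#' a second surface form chosen uniformly per occurrence; gold groups
#' always reference the canonical name.
#'
#' @param cfg a [sim_config()].
#' @param gold gold standard from [plant_gold_groups()] under `cfg`.
#' @return A [prescription_corpus()]. Positive prescriptions carry their
#'   efficacy label; background prescriptions carry none.
#' @export
simulate_corpus <- function(cfg, gold) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- local_seed(cfg$seed + 1L)
  on.exit(restore_seed(old_seed), add = TRUE)
  herbs <- sim_herb_names(cfg$n_herbs)
  gold_herbs <- unique(unlist(gold, use.names = FALSE))
  background <- setdiff(herbs, gold_herbs)
  bg_w <- zipf_weights(length(background), cfg$background_skew)

  n_syn <- floor(cfg$synonym_rate * cfg$n_herbs)
  syn_herbs <- if (n_syn > 0) sample(herbs, n_syn) else character()
  emit <- function(h) {
    # map canonical names to surface forms
    vapply(h, function(x) {
      if (x %in% syn_herbs && stats::runif(1) < 0.5) paste0(x, "~b") else x
    }, character(1), USE.NAMES = FALSE)
  }

  draw_background <- function(k, exclude) {
    avail <- setdiff(background, exclude)
    w <- bg_w[match(avail, background)]
    avail[sample.int(length(avail), k, prob = w)]
  }

  rx <- list()
  for (eff in names(gold)) {
    groups <- gold[[eff]]
    for (i in seq_len(cfg$n_pos_per_efficacy)) {
      len <- sample(seq(cfg$rx_len_range[1], cfg$rx_len_range[2]), 1L)
      gi <- sample.int(length(groups), 1L)
      members <- groups[[gi]]
      used_groups <- gi
      # further complete groups join with probability 1 - noise_rate per
      # attempt while they fit; the rest of the prescription is
      # background, so noise_rate is the expected background share of
      # the padded portion (and 0 yields pure unions of planted groups)
      while (length(members) < len) {
        if (stats::runif(1) < cfg$noise_rate) break
        remaining <- setdiff(seq_along(groups), used_groups)
        fits <- remaining[vapply(remaining, function(j) {
          length(union(members, groups[[j]])) <= len
        }, logical(1))]
        if (length(fits) == 0L) break
        j <- fits[sample.int(length(fits), 1L)]
        members <- union(members, groups[[j]])
        used_groups <- c(used_groups, j)
      }
      if (cfg$noise_rate > 0 && length(members) < len) {
        members <- c(members,
                     draw_background(len - length(members), members))
      }
      rx[[length(rx) + 1L]] <- prescription(
        id = sprintf("%s_pos_%03d", eff, i),
        herbs = emit(sample(members)),
        efficacies = eff)
    }
  }

  n_neg <- cfg$n_efficacies * cfg$n_neg_per_efficacy
  all_gold_groups <- unlist(gold, recursive = FALSE, use.names = FALSE)
  for (i in seq_len(n_neg)) {
    repeat {
      len <- sample(seq(cfg$rx_len_range[1], cfg$rx_len_range[2]), 1L)
      members <- draw_background(len, character())
      # background pools are disjoint from gold herbs, so this can only
      # trip if the configuration is changed to share pools
      clean <- !any(vapply(all_gold_groups,
                           function(g) all(g %in% members), logical(1)))
      if (clean) break
    }
    rx[[length(rx) + 1L]] <- prescription(
      id = sprintf("neg_%03d", i),
      herbs = emit(sample(members)),
      efficacies = character())
  }

  appearing <- unique(unlist(lapply(rx, function(p) p$herbs), use.names = FALSE))
  vocab_names <- unique(c(appearing, gold_herbs))
  prescription_corpus(rx, herb_vocabulary(vocab_names))
}

#' Generate a full synthetic study (gold standard plus corpus)
#'
#' Convenience wrapper calling [plant_gold_groups()] then
#' [simulate_corpus()].
#'
#' @param cfg a [sim_config()].
#' @return list with `gold`, `corpus`, and the `config` used.
#' @export
simulate_study <- function(cfg = sim_config()) {
  gold <- plant_gold_groups(cfg)
  corpus <- simulate_corpus(cfg, gold)
  list(gold = gold, corpus = corpus, config = cfg)
}
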