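test_that("planted gold groups are deterministic, distinct, and sized as configured", {
  cfg <- sim_config(n_herbs = 100L, n_efficacies = 2L,
                    groups_per_efficacy = 3L, group_size_range = c(2L, 3L),
                    seed = 1L)
  gold <- plant_gold_groups(cfg)
  expect_named(gold, c("efficacy_1", "efficacy_2"))
  all_groups <- unlist(gold, recursive = FALSE)
  expect_length(all_groups, 6L)
  keys <- vapply(all_groups, paste, character(1), collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(lengths(all_groups) %in% 2:3))

  expect_identical(gold, plant_gold_groups(cfg))
  gold2 <- plant_gold_groups(sim_config(seed = 2L))
  expect_false(identical(gold, gold2))
})

test_that("infeasible configurations are rejected with sizing errors", {
  expect_error(sim_config(n_herbs = 10L), "n_herbs too small")
  expect_error(sim_config(group_size_range = c(1L, 2L)), "group size")
  expect_error(sim_config(rx_len_range = c(1L, 5L)), "prescription length")
  expect_error(sim_config(noise_rate = 1.2), "noise_rate")
})

test_that("every positive contains a complete planted group; negatives never do", {
  for (s in c(3L, 14L)) {
    st <- simulate_study(sim_config(seed = s, noise_rate = 0.5,
                                    n_pos_per_efficacy = 25L,
                                    n_neg_per_efficacy = 25L))
    for (eff in names(st$gold)) {
      groups <- st$gold[[eff]]
      for (p in st$corpus$prescriptions) {
        has_complete <- any(vapply(groups, function(g) all(g %in% p$herbs),
                                   logical(1)))
        if (eff %in% p$efficacies) {
          expect_true(has_complete,
                      label = paste("positive", p$id, "contains a group of", eff))
        } else {
          expect_false(has_complete,
                       label = paste("negative", p$id, "avoids groups of", eff))
        }
      }
    }
  }
})

test_that("noise-free positives are exact unions of planted groups", {
  st <- simulate_study(sim_config(seed = 5L, noise_rate = 0))
  gold_herbs <- unique(unlist(st$gold))
  pos <- Filter(function(p) length(p$efficacies) > 0, st$corpus$prescriptions)
  for (p in pos) {
    expect_true(all(p$herbs %in% gold_herbs))
    groups <- st$gold[[p$efficacies]]
    contained <- groups[vapply(groups, function(g) all(g %in% p$herbs),
                               logical(1))]
    expect_setequal(p$herbs, unlist(contained))
  }
})

test_that("planted groups dominate equally-sized background itemsets in support", {
  # Monte-Carlo over seeds: each gold group's support among its efficacy's
  # positives must stay near or above the 1/groups_per_efficacy floor from
  # uniform primary-group choice, and above any background pair support.
  for (s in 1:5) {
    st <- simulate_study(sim_config(seed = 100L + s, noise_rate = 0.5))
    cfg <- st$config
    for (eff in names(st$gold)) {
      pos <- Filter(function(p) eff %in% p$efficacies, st$corpus$prescriptions)
      floor_sup <- length(pos) / cfg$groups_per_efficacy
      sup_g <- vapply(st$gold[[eff]], function(g) {
        sum(vapply(pos, function(p) all(g %in% p$herbs), logical(1)))
      }, numeric(1))
      expect_true(all(sup_g >= 0.6 * floor_sup),
                  label = paste("group supports", paste(sup_g, collapse = ",")))
      # a planted group must dwarf the support of a typical background
      # itemset of equal size; only the handful of ubiquitous top-Zipf
      # herbs may form pairs rivaling it (the junk distillation removes)
      gold_herbs <- unique(unlist(st$gold))
      bg_tx <- lapply(pos, function(p) setdiff(p$herbs, gold_herbs))
      bg_tx <- bg_tx[lengths(bg_tx) >= 2]
      if (length(bg_tx) > 0) {
        bg_sup <- itemset_supports(bg_tx, 2L)
        expect_gt(min(sup_g), mean(bg_sup))
        expect_gt(mean(sup_g), stats::quantile(bg_sup, 0.9))
      }
    }
  }
})

test_that("synonym surface forms enter the vocabulary while gold stays canonical", {
  st <- simulate_study(sim_config(seed = 8L, synonym_rate = 0.5))
  vocab <- st$corpus$vocabulary$names
  expect_true(any(grepl("~b$", vocab)))
  expect_false(any(grepl("~b$", unlist(st$gold))))
  # corpus counts are unchanged by synonym emission
  expect_length(st$corpus$prescriptions,
                2L * (st$config$n_pos_per_efficacy + st$config$n_neg_per_efficacy))
})

test_that("simulation is reproducible and seed-sensitive", {
  cfg <- sim_config(seed = 21L, n_pos_per_efficacy = 10L,
                    n_neg_per_efficacy = 10L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(lapply(s1$corpus$prescriptions, unclass),
                   lapply(s2$corpus$prescriptions, unclass))
  s3 <- simulate_study(sim_config(seed = 22L, n_pos_per_efficacy = 10L,
                                  n_neg_per_efficacy = 10L))
  expect_false(identical(lapply(s1$corpus$prescriptions, unclass),
                         lapply(s3$corpus$prescriptions, unclass)))
})
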