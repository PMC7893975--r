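#' End-to-end pipeline configuration
#'
#' Defaults follow the reported experimental protocol: top-N distillation
#' with N = 8 over R = 10 aggregated training runs, itemset sizes
#' K in {2, 3, 4}, support ranks M in {5, 6, 7, 8}, soft accuracy over 10
#' pipeline repetitions. `smoke = TRUE` switches to reduced-scale
#' settings (R = 3 runs, 10 epochs, one K and M, 3 repeats) for quick
#' end-to-end checks.
#'
#' @param corpus_path path to a corpus JSONL/TSV, or `NULL` to simulate.
#' @param gold_path path to a gold-standard TSV, or `NULL` to simulate.
#' @param out_dir output directory (created if missing).
#' @param efficacies efficacy labels to process; default: all in the
#'   gold standard.
#' @param sim a [sim_config()] used when no corpus is given.
#' @param hyper a [hann_hyper()].
#' @param n top-N herbs kept per distilled prescription.
#' @param runs aggregated training runs R.
#' @param K integer vector of itemset sizes to sweep.
#' @param M integer vector of support ranks to sweep (`NULL` to use
#'   `min_sup`).
#' @param min_sup explicit support threshold (used when `M` is `NULL`).
#' @param mode accuracy mode, `"soft"` or `"strict"`.
#' @param repeats pipeline repetitions per setting.
#' @param seed global integer seed.
#' @param smoke use reduced-scale settings.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus_path = NULL, gold_path = NULL,
                            out_dir = "eshg_out", efficacies = NULL,
                            sim = sim_config(), hyper = hann_hyper(),
                            n = 8L, runs = 10L, K = c(2L, 3L, 4L),
                            M = c(5L, 6L, 7L, 8L), min_sup = NULL,
                            mode = "soft", repeats = 10L, seed = 1L,
                            smoke = FALSE) {
  if (isTRUE(smoke)) {
    hyper$epochs <- 10L
    runs <- 3L
    K <- K[1]
    M <- if (!is.null(M)) M[length(M)]
    repeats <- 3L
  }
  structure(list(corpus_path = corpus_path, gold_path = gold_path,
                 out_dir = out_dir, efficacies = efficacies, sim = sim,
                 hyper = hyper, n = as.integer(n), runs = as.integer(runs),
                 K = as.integer(K), M = if (is.null(M)) NULL else as.integer(M),
                 min_sup = min_sup, mode = mode,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full two-stage experimental protocol
#'
#' Loads (or simulates) the corpus and gold standard, then for every
#' (K, M) setting runs the distilled-versus-raw comparison harness over
#' the target efficacies, writing per-setting report TSVs, the corpus,
#' gold standard and configuration used, so every output can be
#' regenerated from the persisted config and seed alone.
#'
#' @param config a [pipeline_config()].
#' @return the output directory, invisibly; summary tables are also
#'   returned in the attribute `reports`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$efficacies) && length(config$efficacies) == 0L) {
    stop("empty efficacy list")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(config$corpus_path)) {
    message("simulating corpus (seed ", config$sim$seed, ")")
    study <- simulate_study(config$sim)
    corpus <- study$corpus
    gold <- study$gold
    write_corpus(corpus, file.path(config$out_dir, "corpus.jsonl"))
    write_gold_standard(gold, file.path(config$out_dir, "gold.tsv"))
  } else {
    if (is.null(config$gold_path)) stop("gold_path required with corpus_path")
    corpus <- read_corpus(config$corpus_path)
    gold <- read_gold_standard(config$gold_path)
  }
  efficacies <- if (is.null(config$efficacies)) names(gold)
                else config$efficacies
  missing_eff <- setdiff(efficacies, names(gold))
  if (length(missing_eff)) {
    stop("efficacies absent from gold standard: ",
         paste(missing_eff, collapse = ", "))
  }

  cfg_lines <- utils::capture.output(utils::str(config, give.attr = FALSE))
  writeLines(cfg_lines, file.path(config$out_dir, "config.txt"))

  m_values <- if (is.null(config$M)) list(NULL) else as.list(config$M)
  reports <- list()
  for (K in config$K) {
    for (M in m_values) {
      tag <- paste0("K", K, if (!is.null(M)) paste0("_M", M)
                    else paste0("_minsup", config$min_sup))
      message("setting ", tag)
      t0 <- Sys.time()
      rep <- tryCatch(
        compare_harness(corpus, gold, efficacies = efficacies, K = K,
                        M = M, min_sup = config$min_sup, n = config$n,
                        runs = config$runs, repeats = config$repeats,
                        base_seed = config$seed, hyper = config$hyper,
                        mode = config$mode),
        error = function(e) {
          message("setting ", tag, " failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(rep)) next
      message(sprintf("  done in %.1fs", as.numeric(Sys.time() - t0,
                                                    units = "secs")))
      utils::write.table(rep, file.path(config$out_dir,
                                        paste0("report_", tag, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      reports[[tag]] <- rep
    }
  }
  out <- config$out_dir
  attr(out, "reports") <- reports
  invisible(out)
}
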