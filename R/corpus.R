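#' Herb vocabulary
#'
#' A bijection between herb surface names and contiguous integer ids
#' `1..N` (row indices into the embedding table). Names are kept in order
#' of first appearance so that corpora read from disk index
#' deterministically.
#'
#' @param names character vector of distinct herb names.
#' @return An object of class `herb_vocabulary` with elements `names`
#'   (character) and `index` (named integer, name -> id).
#' @export
herb_vocabulary <- function(names) {
  names <- as.character(names)
  if (anyDuplicated(names)) {
    stop("herb names must be distinct")
  }
  if (any(!nzchar(names))) {
    stop("herb names must be non-empty strings")
  }
  index <- seq_along(names)
  names(index) <- names
  structure(list(names = names, index = index), class = "herb_vocabulary")
}

#' @export
length.herb_vocabulary <- function(x) length(x$names)

#' @export
print.herb_vocabulary <- function(x, ...) {
  cat("<herb_vocabulary> ", length(x$names), " herbs\n", sep = "")
  invisible(x)
}

#' Map herb names to integer ids
#'
#' @param vocab a [herb_vocabulary()].
#' @param herbs character vector of herb names.
#' @return integer vector of ids.
#' @export
herb_id <- function(vocab, herbs) {
  ids <- unname(vocab$index[herbs])
  if (anyNA(ids)) {
    missing <- herbs[is.na(ids)]
    stop("herb(s) not in vocabulary: ", paste(missing, collapse = ", "))
  }
  ids
}

#' Map integer ids back to herb names
#'
#' @param vocab a [herb_vocabulary()].
#' @param ids integer vector of ids in `1..N`.
#' @return character vector of names.
#' @export
herb_name <- function(vocab, ids) {
  if (any(ids < 1L | ids > length(vocab$names))) {
    stop("herb id out of range")
  }
  vocab$names[ids]
}

#' Construct a prescription
#'
#' A prescription is the transaction unit of the whole pipeline: an
#' identifier, an ordered list of distinct herbs, and the set of efficacy
#' labels under which it was recorded. Duplicate herbs within one record
#' are collapsed to the first occurrence with a warning.
#'
#' @param id prescription identifier (string).
#' @param herbs character vector of herb names (order preserved).
#' @param efficacies character vector of efficacy labels (may be empty).
#' @return An object of class `prescription`.
#' @export
prescription <- function(id, herbs, efficacies = character()) {
  id <- as.character(id)
  herbs <- trimws(as.character(herbs))
  herbs <- herbs[nzchar(herbs)]
  if (length(herbs) == 0L) {
    stop("prescription '", id, "' has no herbs")
  }
  if (anyDuplicated(herbs)) {
    warning("prescription '", id, "' lists duplicate herbs; collapsing")
    herbs <- herbs[!duplicated(herbs)]
  }
  efficacies <- unique(trimws(as.character(efficacies)))
  efficacies <- efficacies[nzchar(efficacies)]
  structure(list(id = id, herbs = herbs, efficacies = efficacies),
            class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
  cat("<prescription> ", x$id, ": ", paste(x$herbs, collapse = ", "),
      if (length(x$efficacies)) paste0(" [", paste(x$efficacies, collapse = "; "), "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Construct a prescription corpus
#'
#' @param prescriptions list of [prescription()] objects.
#' @param vocabulary optional [herb_vocabulary()]; built from the union of
#'   herb names in order of first appearance when omitted.
#' @return An object of class `prescription_corpus` with elements
#'   `vocabulary` and `prescriptions`.
#' @export
prescription_corpus <- function(prescriptions, vocabulary = NULL) {
  stopifnot(is.list(prescriptions))
  if (is.null(vocabulary)) {
    all_names <- unlist(lapply(prescriptions, function(p) p$herbs),
                        use.names = FALSE)
    vocabulary <- herb_vocabulary(unique(all_names))
  }
  structure(list(vocabulary = vocabulary, prescriptions = prescriptions),
            class = "prescription_corpus")
}

#' @export
print.prescription_corpus <- function(x, ...) {
  cat("<prescription_corpus> ", length(x$prescriptions), " prescriptions, ",
      length(x$vocabulary$names), " herbs\n", sep = "")
  invisible(x)
}

#' Read a prescription corpus from disk
#'
#' Two line-oriented formats are supported. `jsonl`: one JSON object per
#' line with fields `id`, `herbs` (array of names) and `efficacies` (array
#' of labels, possibly empty). `tsv`: three tab-separated columns, herbs
#' and efficacies each joined by semicolons.
#'
#' @param path file path.
#' @param format `"jsonl"` (default) or `"tsv"`.
#' @return A [prescription_corpus()]; the vocabulary covers the union of
#'   herb names in order of first appearance.
#' @export
read_corpus <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("corpus file is empty: ", path)
  prescriptions <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      parse_corpus_line(lines[[i]], format),
      error = function(e) {
        stop("malformed corpus line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    prescriptions[[i]] <- rec
  }
  prescription_corpus(prescriptions)
}

parse_corpus_line <- function(line, format) {
  if (format == "jsonl") {
    obj <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    if (is.null(obj$id)) stop("missing 'id'")
    herbs <- as.character(obj$herbs)
    eff <- if (is.null(obj$efficacies)) character() else as.character(obj$efficacies)
  } else {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) stop("expected at least 2 tab-separated fields")
    herbs <- strsplit(fields[[2]], ";", fixed = TRUE)[[1]]
    eff <- if (length(fields) >= 3L && nzchar(fields[[3]])) {
      strsplit(fields[[3]], ";", fixed = TRUE)[[1]]
    } else {
      character()
    }
    obj <- list(id = fields[[1]])
  }
  prescription(obj$id, herbs, eff)
}

#' Write a prescription corpus to disk
#'
#' Inverse of [read_corpus()]; a write/read round-trip reproduces the
#' corpus exactly (ids, herb order, efficacy sets, vocabulary order).
#'
#' @param corpus a [prescription_corpus()] or list of prescriptions.
#' @param path output file path.
#' @param format `"jsonl"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  prescriptions <- if (inherits(corpus, "prescription_corpus")) {
    corpus$prescriptions
  } else {
    corpus
  }
  lines <- vapply(prescriptions, function(p) {
    if (format == "jsonl") {
      jsonlite::toJSON(list(id = p$id, herbs = p$herbs,
                            efficacies = p$efficacies),
                       auto_unbox = TRUE)
    } else {
      paste(p$id, paste(p$herbs, collapse = ";"),
            paste(p$efficacies, collapse = ";"), sep = "\t")
    }
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build a 1:1 class-balanced dataset for one efficacy
#'
#' Prescriptions carrying the target efficacy are the positive class
#' (label 1); all others are negatives (label 0). Negatives are
#' under-sampled uniformly without replacement until the two classes have
#' equal size, reproducing the 1:1 under-sampling protocol; positives are
#' never dropped. The combined set is shuffled.
#'
#' @param corpus a [prescription_corpus()] or list of prescriptions.
#' @param efficacy target efficacy label.
#' @param seed integer seed controlling the sub-sample and the shuffle.
#' @return list with `prescriptions` (list) and `labels` (integer 0/1),
#'   aligned, plus `efficacy`.
#' @export
build_balanced_dataset <- function(corpus, efficacy, seed) {
  prescriptions <- if (inherits(corpus, "prescription_corpus")) {
    corpus$prescriptions
  } else {
    corpus
  }
  is_pos <- vapply(prescriptions, function(p) efficacy %in% p$efficacies,
                   logical(1))
  pos <- prescriptions[is_pos]
  neg <- prescriptions[!is_pos]
  if (length(pos) == 0L) stop("no positive prescriptions for efficacy '", efficacy, "'")
  if (length(neg) == 0L) stop("no negative prescriptions for efficacy '", efficacy, "'")
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  if (length(neg) > length(pos)) {
    neg <- neg[sample.int(length(neg), length(pos))]
  } else if (length(neg) < length(pos)) {
    warning("fewer negatives (", length(neg), ") than positives (",
            length(pos), ") for efficacy '", efficacy, "'; keeping all")
  }
  all_rx <- c(pos, neg)
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  ord <- sample.int(length(all_rx))
  list(prescriptions = all_rx[ord], labels = labels[ord], efficacy = efficacy)
}

#' Write herbal groups to a TSV file
#'
#' One group per line, member herbs in lexicographic order separated by
#' tabs; byte output is deterministic for a given input.
#'
#' @param groups list of character vectors (herb name sets).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  lines <- vapply(groups, function(g) {
    paste(sort(unique(as.character(g))), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read herbal groups from a TSV file
#'
#' @param path file written by [write_groups()].
#' @return list of character vectors (sorted herb names); empty list for
#'   an empty file.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("group file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) sort(strsplit(l, "\t", fixed = TRUE)[[1]]))
}

#' Write a gold standard (efficacy -> herbal groups) to TSV
#'
#' First column is the efficacy label, remaining tab-separated columns are
#' the group's herbs in lexicographic order; one group per line.
#'
#' @param gold named list: efficacy label -> list of character vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  lines <- character()
  for (eff in names(gold)) {
    for (g in gold[[eff]]) {
      lines <- c(lines, paste(c(eff, sort(unique(as.character(g)))),
                              collapse = "\t"))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gold standard from TSV
#'
#' @param path file written by [write_gold_standard()].
#' @return named list: efficacy label -> list of sorted character vectors.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop("gold standard file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  gold <- list()
  for (l in lines) {
    fields <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) stop("malformed gold standard line: ", l)
    eff <- fields[[1]]
    gold[[eff]] <- c(gold[[eff]], list(sort(fields[-1])))
  }
  gold
}

# Seed handling: set the RNG locally and restore the caller's state, so
# library functions do not perturb user-level reproducibility.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
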