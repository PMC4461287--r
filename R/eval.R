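#' Split phenotype genes into training and validation sets
#'
#' Uniform random subset without replacement of size `train_size`; the
#' complement is the validation set. Draws from the current RNG stream.
#'
#' @param genes character vector of phenotype genes
#' @param train_size integer in \[1, length(genes)\]
#' @return list with `training` and `validation` character vectors
#' @export
split_genes <- function(genes, train_size) {
  genes <- as.character(genes)
  if (train_size < 1L || train_size > length(genes))
    stop("train_size must be in [1, ", length(genes), "]")
  training <- sort(sample(genes, train_size))
  list(training = training, validation = sort(setdiff(genes, training)))
}

#' Repeated random sub-sampling cross-validation of contextualization
#'
#' For each training-set size and each of `n_splits` random splits, the PKN
#' is contextualized using only the training genes (both as the scored signal
#' and as the known part of the initial states; held-out genes are filled per
#' the configured init policy), and every subnetwork of the resulting final
#' population is then re-scored on the FULL phenotype gene profile with the
#' held-out states still withheld from the initial conditions. That full-
#' profile score measures how well the contextualized networks predict the
#' missing expression values; pooling across splits gives
#' `population_size * n_splits` scores per training size.
#'
#' With `train_size` equal to the full profile this reduces exactly to the
#' plain optimization pathway (same seed, same results).
#'
#' @param pkn the prior-knowledge network
#' @param phenotypes a [phenotype_set()]
#' @param train_sizes integer vector of training-set sizes
#' @param n_splits random splits per size (default 10)
#' @param config an [optimization_config()]; per-split seeds are derived from
#'   `config$seed`
#' @param method `"eda"` or `"random"` (baseline)
#' @return list of `crossval_run` objects: each holds `train_size`, `split`,
#'   `training_genes`, `validation_genes`, `scores` (full-profile, length
#'   `population_size`), `training_scores`, and `seed`
#' @export
cross_validate <- function(pkn, phenotypes, train_sizes, n_splits = 10L,
                           config = optimization_config(),
                           method = c("eda", "random")) {
  method <- match.arg(method)
  genes <- intersect(ph_genes(phenotypes), pkn$nodes)
  if (!length(genes)) stop("no phenotype genes present in the network")
  runs <- list()
  for (size in as.integer(train_sizes)) {
    for (split in seq_len(n_splits)) {
      split_seed <- derive_seed(config$seed, size, split)
      set.seed(split_seed)
      sp <- split_genes(genes, size)
      cfg <- config
      cfg$seed <- split_seed
      res <- contextualize(pkn, phenotypes, scored_genes = sp$training,
                           known_genes = sp$training, config = cfg,
                           method = method)
      full <- vapply(res$final_population, function(net)
        score_subnetwork(pkn, net, phenotypes, scored_genes = genes,
                         known_genes = sp$training,
                         init_policy = cfg$init_policy,
                         max_steps = cfg$max_steps,
                         inputs_hold_state = cfg$inputs_hold_state)$f,
        numeric(1))
      runs[[length(runs) + 1L]] <- structure(
        list(train_size = size, split = split, training_genes = sp$training,
             validation_genes = sp$validation, scores = full,
             training_scores = res$final_scores, seed = split_seed,
             result = res),
        class = "crossval_run")
    }
  }
  runs
}

## distinct deterministic stream per (seed, size, split), kept under 2^31
derive_seed <- function(seed, a, b) {
  as.integer((as.numeric(seed) * 7919 + a * 104729 + b * 1299709) %% 2147483647)
}

#' Pool cross-validation scores for one training size
#' @param runs list of `crossval_run` from [cross_validate()]
#' @param train_size optional filter on training-set size
#' @return numeric vector of pooled full-profile scores
#' @export
pooled_scores <- function(runs, train_size = NULL) {
  if (!is.null(train_size))
    runs <- Filter(function(r) r$train_size == train_size, runs)
  unlist(lapply(runs, `[[`, "scores"), use.names = FALSE)
}

#' Cumulative frequency curve of a score sample
#'
#' The empirical CDF evaluated at the sorted unique scores; non-decreasing
#' from its first value to 1.
#' @param scores numeric vector
#' @return data.frame with columns `score` and `cumfreq`
#' @export
score_cdf <- function(scores) {
  s <- sort(unique(scores))
  data.frame(score = s, cumfreq = stats::ecdf(scores)(s))
}

#' Welch's two-sample t-test between optimized and baseline scores
#'
#' Two-sided unequal-variance t-test (Welch-Satterthwaite degrees of
#' freedom) comparing the pooled scores of optimized subnetworks against the
#' random-search baseline. Degenerate inputs are mapped to the limits of the
#' statistic: both samples constant with equal means gives p = 1; constant
#' with different means gives p = 0.
#'
#' @param optimized_scores,baseline_scores numeric vectors, length >= 2
#' @return list (`welch_result`) with `t`, `df`, `p`
#' @export
compare_to_baseline <- function(optimized_scores, baseline_scores) {
  x <- as.numeric(optimized_scores); y <- as.numeric(baseline_scores)
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 scores per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(structure(list(t = if (eq) 0 else Inf, df = NA_real_,
                          p = if (eq) 1 else 0), class = "welch_result"))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value), class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.1f, p = %.3g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Sensitivity of contextualization to missing training information
#'
#' Re-runs the optimization with the listed genes removed from the training
#' signal — excluded from scoring and their phenotype values withheld from
#' the initial states (filled per the init policy) — then evaluates the final
#' population on ALL phenotype genes. The drop in the returned score
#' distribution relative to a standard run measures how much the
#' contextualization depends on those genes.
#'
#' @param pkn,phenotypes,config as in [contextualize()]
#' @param removed character vector of withheld phenotype genes (may be empty)
#' @return numeric vector of full-profile scores (length `population_size`)
#' @export
sensitivity_missing <- function(pkn, phenotypes, removed,
                                config = optimization_config()) {
  genes <- intersect(ph_genes(phenotypes), pkn$nodes)
  removed <- as.character(removed)
  keep <- setdiff(genes, removed)
  if (!length(keep)) stop("cannot remove all phenotype genes")
  res <- contextualize(pkn, phenotypes, scored_genes = keep,
                       known_genes = keep, config = config)
  vapply(res$final_population, function(net)
    score_subnetwork(pkn, net, phenotypes, scored_genes = genes,
                     known_genes = keep, init_policy = config$init_policy,
                     max_steps = config$max_steps,
                     inputs_hold_state = config$inputs_hold_state)$f,
    numeric(1))
}

#' Sensitivity of contextualization to wrong training information
#'
#' Bit-flips the listed genes' states in every phenotype — corrupting both
#' the training signal and the initial states — runs the optimization on the
#' corrupted phenotypes, and evaluates the final population against the
#' ORIGINAL (unflipped) phenotypes on all genes.
#'
#' @param pkn,phenotypes,config as in [contextualize()]
#' @param flipped character vector of corrupted phenotype genes (may be empty)
#' @return numeric vector of full-profile scores vs the original phenotypes
#' @export
sensitivity_wrong <- function(pkn, phenotypes, flipped,
                              config = optimization_config()) {
  genes <- intersect(ph_genes(phenotypes), pkn$nodes)
  flipped <- as.character(flipped)
  bad <- setdiff(flipped, ph_genes(phenotypes))
  if (length(bad)) stop("flipped gene(s) not in phenotypes: ", paste(bad, collapse = ", "))
  corrupted <- phenotypes
  corrupted$states[flipped, ] <- 1L - corrupted$states[flipped, , drop = FALSE]
  res <- contextualize(pkn, corrupted, scored_genes = genes,
                       known_genes = genes, config = config)
  vapply(res$final_population, function(net)
    score_subnetwork(pkn, net, phenotypes, scored_genes = genes,
                     known_genes = genes, init_policy = config$init_policy,
                     max_steps = config$max_steps,
                     inputs_hold_state = config$inputs_hold_state)$f,
    numeric(1))
}
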