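#' Normalized Hamming distance between a phenotype and an attractor
#'
#' Fraction of the scored genes whose Boolean states differ:
#' `h = (1/N_g) * sum_j |x_j(phenotype) - x_j(attractor)|`.
#'
#' @param phi named 0/1 phenotype vector
#' @param alpha named 0/1 attractor state
#' @param genes the genes to compare over (`N_g >= 1`)
#' @return a number in \[0, 1\]
#' @export
hamming_distance <- function(phi, alpha, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop("hamming_distance: empty gene set")
  miss <- setdiff(genes, names(phi))
  if (length(miss)) stop("gene(s) missing from phenotype: ", paste(miss, collapse = ", "))
  miss <- setdiff(genes, names(alpha))
  if (length(miss)) stop("gene(s) missing from attractor: ", paste(miss, collapse = ", "))
  mean(abs(as.integer(phi[genes]) - as.integer(alpha[genes])))
}

#' Score a candidate subnetwork against Booleanized phenotypes
#'
#' The fitness of a subnetwork measures how well the fixed points of its
#' synchronous Boolean model match the observed stable phenotypes. Each
#' phenotype is introduced as an initial state (unknown nodes filled per
#' `init_policy`), the model is iterated to an attractor, and the reached
#' state is compared with the phenotype:
#'
#' `f = 1 - (sum_i h_i) / N_p`
#'
#' with `h_i` the normalized Hamming distance over `scored_genes`. If any
#' phenotype's trajectory ends in a cycle, or exceeds `max_steps` and is
#' discarded, the subnetwork scores 0. `f` is the fraction of scored gene
#' states correctly explained by the model across all phenotypes: 1 means
#' every phenotype is an exactly matching fixed point.
#'
#' `scored_genes` defaults to the phenotype genes present in the network;
#' phenotype genes absent from the network are excluded (with a warning) —
#' pruning never removes nodes, but user data may be broader than the PKN.
#' For cross-validation, pass the training subset as both `scored_genes`
#' (during optimization) and `known_genes`, then re-score with
#' `scored_genes` = all genes and `known_genes` = training genes to measure
#' prediction of the held-out states.
#'
#' @param pkn the reference PKN (`signed_digraph`)
#' @param subnetwork the candidate (`signed_digraph`, edges a subset of the PKN's)
#' @param phenotypes a [phenotype_set()]
#' @param scored_genes genes entering the Hamming comparison (default: all
#'   phenotype genes present in the network)
#' @param known_genes genes whose phenotype values seed the initial state
#'   (default: same as `scored_genes`)
#' @param init_policy fill rule for remaining nodes, `"zero"` or `"random"`
#' @param max_steps trajectory cutoff (default 1000)
#' @param inputs_hold_state passed to [build_rules()]
#' @param rules optional pre-built `rule_set` for `subnetwork` (skips
#'   [build_rules()]; used by the optimizer's inner loop)
#' @return object of class `fitness_report`: `f` in \[0, 1\] and a
#'   `per_phenotype` data.frame (phenotype, outcome, h, steps)
#' @export
score_subnetwork <- function(pkn, subnetwork, phenotypes,
                             scored_genes = NULL, known_genes = NULL,
                             init_policy = c("zero", "random"),
                             max_steps = 1000L, inputs_hold_state = TRUE,
                             rules = NULL) {
  init_policy <- match.arg(init_policy)
  if (is.null(rules)) rules <- build_rules(pkn, subnetwork, inputs_hold_state)
  if (is.null(scored_genes)) {
    scored_genes <- intersect(ph_genes(phenotypes), rules$nodes)
    dropped <- setdiff(ph_genes(phenotypes), rules$nodes)
    if (length(dropped))
      warning("phenotype gene(s) absent from network excluded from scoring: ",
              paste(dropped, collapse = ", "))
  }
  scored_genes <- intersect(as.character(scored_genes), rules$nodes)
  if (!length(scored_genes)) stop("no scored genes present in the network")
  if (is.null(known_genes)) known_genes <- scored_genes
  np <- n_phenotypes(phenotypes)
  rec <- vector("list", np)
  hsum <- 0
  failed <- FALSE
  for (i in seq_len(np)) {
    phi <- get_phenotype(phenotypes, i)
    x0 <- initial_state(rules, phi, known_genes = known_genes,
                        init_policy = init_policy)
    tr <- run_to_attractor(rules, x0, max_steps = max_steps)
    h <- NA_real_
    if (tr$outcome == "fixed_point") {
      h <- hamming_distance(phi, tr$attractor_state, scored_genes)
      hsum <- hsum + h
    } else {
      failed <- TRUE
    }
    rec[[i]] <- data.frame(phenotype = colnames(phenotypes$states)[i],
                           outcome = tr$outcome, h = h,
                           steps = tr$steps_taken, stringsAsFactors = FALSE)
  }
  f <- if (failed) 0 else 1 - hsum / np
  structure(list(f = f, per_phenotype = do.call(rbind, rec),
                 scored_genes = scored_genes), class = "fitness_report")
}

#' @export
print.fitness_report <- function(x, ...) {
  cat(sprintf("fitness f = %.4f over %d scored gene(s)\n", x$f,
              length(x$scored_genes)))
  print(x$per_phenotype, row.names = FALSE)
  invisible(x)
}
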