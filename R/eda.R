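#' Optimization configuration
#'
#' Parameters of the estimation-of-distribution (EDA) pruning loop. Defaults
#' follow the configuration used throughout the validation protocols: a
#' population of 30 subnetworks, selection of the 10 top-scored ones, 100
#' iterations, and an elitism number of 5 — the maximum of the recommended
#' range (not higher than half the selection number).
#'
#' @param max_iterations number of generations sampled, scored and selected
#' @param population_size subnetworks per generation
#' @param selection_number top-scored subnetworks kept for frequency estimation
#' @param elitism_number best-ever subnetworks carried unchanged into each new
#'   generation (guarantees a non-decreasing best-score trace)
#' @param initial_edge_probability per-edge inclusion probability of the
#'   initial random population (0.5 maximizes initial entropy)
#' @param max_steps trajectory cutoff passed to the Boolean engine
#' @param seed integer seed driving every random draw of a run
#' @param init_policy fill rule for nodes without a known phenotype state
#' @param inputs_hold_state whether PKN in-degree-0 nodes hold their state
#' @param smoothing symmetric shrinkage of the estimated edge frequencies,
#'   `f -> (1-2e)f + e`. Raw frequencies (`smoothing = 0`) freeze an edge
#'   permanently once it appears in all or none of the selected subnetworks,
#'   which can trap the search at a local optimum within a few generations.
#'   The default `NULL` applies the rule-of-succession pseudocount,
#'   `e = 1/(selection_number + 2)` (i.e. frequency `(count + 1) /
#'   (selection_number + 2)`), keeping every edge explorable while elitism
#'   preserves the best-ever networks
#' @return object of class `optimization_config`
#' @export
optimization_config <- function(max_iterations = 100L, population_size = 30L,
                                selection_number = 10L, elitism_number = 5L,
                                initial_edge_probability = 0.5,
                                max_steps = 1000L, seed = 1L,
                                init_policy = c("zero", "random"),
                                inputs_hold_state = TRUE, smoothing = NULL) {
  init_policy <- match.arg(init_policy)
  cfg <- list(max_iterations = as.integer(max_iterations),
              population_size = as.integer(population_size),
              selection_number = as.integer(selection_number),
              elitism_number = as.integer(elitism_number),
              initial_edge_probability = initial_edge_probability,
              max_steps = as.integer(max_steps), seed = as.integer(seed),
              init_policy = init_policy,
              inputs_hold_state = isTRUE(inputs_hold_state),
              smoothing = if (is.null(smoothing)) 1 / (as.integer(selection_number) + 2)
                          else smoothing)
  if (cfg$max_iterations < 0L) stop("max_iterations must be >= 0")
  if (cfg$population_size < 1L) stop("population_size must be >= 1")
  if (cfg$selection_number < 1L || cfg$selection_number > cfg$population_size)
    stop("selection_number must be in [1, population_size]")
  if (cfg$elitism_number < 0L || cfg$elitism_number > cfg$selection_number)
    stop("elitism_number must be in [0, selection_number]")
  if (cfg$initial_edge_probability <= 0 || cfg$initial_edge_probability > 1)
    stop("initial_edge_probability must be in (0, 1]")
  if (cfg$smoothing < 0 || cfg$smoothing >= 0.5)
    stop("smoothing must be in [0, 0.5)")
  structure(cfg, class = "optimization_config")
}

## --- internal mask machinery -----------------------------------------------
## A candidate subnetwork is a logical mask over the PKN's canonical edge
## order; networks are only materialized as signed_digraph at the interface.

pkn_precompute <- function(pkn, inputs_hold_state) {
  nodes <- sort(pkn$nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)
  e <- pkn$edges
  list(pkn = pkn, nodes = nodes, n = length(nodes),
       to_i = idx[e$to], from_i = idx[e$from], sign = e$sign,
       keys = edge_keys(pkn),
       is_input = stats::setNames(!(nodes %in% e$to), nodes),
       inputs_hold_state = inputs_hold_state)
}

rules_from_mask <- function(pre, mask) {
  act_mat <- matrix(0L, pre$n, pre$n, dimnames = list(pre$nodes, pre$nodes))
  inh_mat <- act_mat
  a <- mask & pre$sign > 0
  i <- mask & pre$sign < 0
  act_mat[cbind(pre$to_i[a], pre$from_i[a])] <- 1L
  inh_mat[cbind(pre$to_i[i], pre$from_i[i])] <- 1L
  structure(list(nodes = pre$nodes, activators = NULL, inhibitors = NULL,
                 is_input = pre$is_input, act_mat = act_mat, inh_mat = inh_mat,
                 inputs_hold_state = pre$inputs_hold_state),
            class = "rule_set")
}

subnet_from_mask <- function(pre, mask) {
  signed_digraph(pre$pkn$edges[mask, , drop = FALSE], nodes = pre$pkn$nodes)
}

mask_key <- function(mask) rawToChar(as.raw(48L + as.integer(mask)))

## --- public stochastic primitives ------------------------------------------

#' Draw a random subnetwork of a PKN
#'
#' Each PKN edge is included independently with probability `p`; the node set
#' is preserved in full. Draws come from the current RNG stream (seed with
#' `set.seed()` for reproducibility).
#'
#' @param pkn a `signed_digraph`
#' @param p inclusion probability in (0, 1]
#' @return a `signed_digraph` whose edges are a subset of the PKN's
#' @export
random_subnetwork <- function(pkn, p = 0.5) {
  stopifnot(p > 0, p <= 1)
  keep <- stats::runif(n_edges(pkn)) <= p
  signed_digraph(pkn$edges[keep, , drop = FALSE], nodes = pkn$nodes)
}

#' Per-edge inclusion frequencies in a selected group of subnetworks
#'
#' The univariate distribution the EDA samples from: for every PKN edge, the
#' fraction of the selected subnetworks that contain it (0 for edges absent
#' from all).
#'
#' @param selected nonempty list of `signed_digraph` subnetworks of `pkn`
#' @param pkn the reference PKN
#' @return named numeric vector over the PKN's [edge_keys()]
#' @export
edge_frequencies <- function(selected, pkn) {
  if (!length(selected)) stop("edge_frequencies: empty selection")
  keys <- edge_keys(pkn)
  counts <- rowSums(vapply(selected, function(net) keys %in% edge_keys(net),
                           logical(length(keys))))
  stats::setNames(counts / length(selected), keys)
}

#' Sample a new subnetwork from edge frequencies
#'
#' For each PKN edge a fresh uniform(0,1) number is drawn; the edge is kept
#' iff the draw is lower than or equal to its frequency (so the measure-zero
#' tie at u = f is kept). The node set is preserved.
#'
#' @param freqs named frequency vector over the PKN's [edge_keys()]
#' @param pkn the reference PKN
#' @return a `signed_digraph`
#' @export
sample_from_frequencies <- function(freqs, pkn) {
  keys <- edge_keys(pkn)
  miss <- setdiff(keys, names(freqs))
  if (length(miss)) stop("frequencies missing for edge(s): ", paste(miss, collapse = ", "))
  keep <- stats::runif(length(keys)) <= freqs[keys]
  signed_digraph(pkn$edges[keep, , drop = FALSE], nodes = pkn$nodes)
}

## --- the optimization loop --------------------------------------------------

#' Contextualize a PKN by iterative evolutionary pruning
#'
#' The main entry point: searches the space of edge-subsets of `pkn` for
#' subnetworks whose Boolean model reproduces the phenotypes as fixed points,
#' using a univariate estimation-of-distribution algorithm:
#'
#' 1. Create `population_size` random subnetworks (each PKN edge kept with
#'    probability `initial_edge_probability`).
#' 2. Score every subnetwork with [score_subnetwork()] and select the
#'    `selection_number` with the highest fitness (ties broken by fewer
#'    edges, then by a stable hash of the edge set).
#' 3. Estimate each edge's inclusion frequency within the selected group
#'    (shrunk by the configured smoothing so no edge is frozen at 0 or 1) and
#'    sample a new population from those frequencies; the `elitism_number`
#'    best-ever subnetworks (deduplicated; padded with fresh samples if
#'    fewer are distinct) are appended unchanged.
#' 4. Repeat from step 2 for `max_iterations` generations.
#'
#' With `method = "random"` step 3 draws every new subnetwork from the
#' initial-density distribution instead of the estimated frequencies, while
#' keeping scoring and elitism: the random-search baseline used for
#' validation, evaluating exactly as many subnetworks as the EDA does.
#'
#' @param pkn the prior-knowledge network (`signed_digraph`)
#' @param phenotypes a [phenotype_set()]
#' @param scored_genes genes scored during optimization (default: phenotype
#'   genes present in the network)
#' @param known_genes genes whose phenotype values seed initial states
#'   (default: `scored_genes`)
#' @param config an [optimization_config()]
#' @param method `"eda"` or `"random"`
#' @param on_iteration optional callback `function(iteration, best_f, mean_f)`
#'   invoked after each completed generation; partial results can be
#'   harvested there at any time
#' @return object of class `optimization_result`: `final_population` (list of
#'   `signed_digraph`), `final_scores`, `best_networks` (elitism archive,
#'   fitness-descending), `trace` (per-generation best-so-far and mean
#'   fitness), `edge_frequency_final`, `n_evaluations`, `seed`, `config`
#' @export
contextualize <- function(pkn, phenotypes, scored_genes = NULL,
                          known_genes = NULL,
                          config = optimization_config(),
                          method = c("eda", "random"), on_iteration = NULL) {
  method <- match.arg(method)
  if (!inherits(config, "optimization_config")) stop("config must be an optimization_config")
  if (n_edges(pkn) == 0L) stop("PKN has no edges to prune")
  set.seed(config$seed)
  pre <- pkn_precompute(pkn, config$inputs_hold_state)
  E <- n_edges(pkn)
  if (is.null(scored_genes)) scored_genes <- intersect(ph_genes(phenotypes), pre$nodes)
  scored_genes <- intersect(as.character(scored_genes), pre$nodes)
  if (!length(scored_genes)) stop("no scored genes present in the network")
  if (is.null(known_genes)) known_genes <- scored_genes

  cache <- new.env(hash = TRUE, parent = emptyenv())
  n_eval <- 0L
  score_mask <- function(mask) {
    key <- mask_key(mask)
    f <- get0(key, envir = cache, ifnotfound = NULL)
    if (is.null(f)) {
      rep <- score_subnetwork(pkn, NULL, phenotypes, scored_genes = scored_genes,
                              known_genes = known_genes,
                              init_policy = config$init_policy,
                              max_steps = config$max_steps,
                              rules = rules_from_mask(pre, mask))
      f <- rep$f
      if (config$init_policy == "zero") assign(key, f, envir = cache)
    }
    n_eval <<- n_eval + 1L
    f
  }

  draw_initial <- function() stats::runif(E) <= config$initial_edge_probability
  pop <- replicate(config$population_size, draw_initial(), simplify = FALSE)
  fs <- vapply(pop, score_mask, numeric(1))

  ## elitism archive of distinct best-ever masks
  archive <- list()   # each: list(mask, f, key, n_edges)
  update_archive <- function(pop, fs) {
    if (config$elitism_number == 0L) return(invisible())
    for (j in seq_along(pop)) {
      key <- mask_key(pop[[j]])
      if (!any(vapply(archive, function(a) a$key == key, logical(1)))) {
        archive[[length(archive) + 1L]] <<- list(mask = pop[[j]], f = fs[j],
                                                 key = key,
                                                 n_edges = sum(pop[[j]]))
      }
    }
    ord <- order(-vapply(archive, `[[`, numeric(1), "f"),
                 vapply(archive, `[[`, numeric(1), "n_edges"),
                 vapply(archive, `[[`, character(1), "key"))
    archive <<- archive[ord[seq_len(min(length(archive), config$elitism_number))]]
  }
  update_archive(pop, fs)
  best_so_far <- function() if (length(archive)) archive[[1]]$f else max(fs)

  trace <- data.frame(iteration = 0L, best_f = best_so_far(), mean_f = mean(fs))

  select_top <- function(pop, fs) {
    ord <- order(-fs, vapply(pop, sum, numeric(1)),
                 vapply(pop, mask_key, character(1)))
    ord[seq_len(config$selection_number)]
  }

  freqs <- NULL
  for (it in seq_len(config$max_iterations)) {
    sel <- select_top(pop, fs)
    freqs <- Reduce(`+`, pop[sel]) / length(sel)
    if (config$smoothing > 0)
      freqs <- (1 - 2 * config$smoothing) * freqs + config$smoothing
    n_new <- config$population_size - length(archive)
    draw <- if (method == "eda") function() stats::runif(E) <= freqs
            else draw_initial
    newpop <- replicate(n_new, draw(), simplify = FALSE)
    newpop <- c(newpop, lapply(archive, `[[`, "mask"))
    fs <- vapply(newpop, score_mask, numeric(1))
    pop <- newpop
    update_archive(pop, fs)
    trace <- rbind(trace, data.frame(iteration = it, best_f = best_so_far(),
                                     mean_f = mean(fs)))
    if (!is.null(on_iteration)) on_iteration(it, best_so_far(), mean(fs))
  }

  final_sel <- select_top(pop, fs)
  final_freq <- Reduce(`+`, pop[final_sel]) / length(final_sel)
  structure(list(
    final_population = lapply(pop, function(m) subnet_from_mask(pre, m)),
    final_scores = fs,
    best_networks = lapply(archive, function(a)
      list(network = subnet_from_mask(pre, a$mask), f = a$f)),
    trace = trace,
    edge_frequency_final = stats::setNames(final_freq, pre$keys),
    n_evaluations = n_eval,
    seed = config$seed, config = config, method = method
  ), class = "optimization_result")
}

#' Random-search baseline with elitism
#'
#' Identical loop to [contextualize()] except that every new generation is
#' drawn from the initial edge-inclusion density instead of the estimated
#' edge frequencies; scoring and elitism are retained, so the total number of
#' evaluated subnetworks equals the EDA's under the same configuration. Used
#' to quantify the contribution of distribution estimation over random search.
#'
#' @inheritParams contextualize
#' @return an `optimization_result`
#' @export
random_search_baseline <- function(pkn, phenotypes, scored_genes = NULL,
                                   known_genes = NULL,
                                   config = optimization_config(),
                                   on_iteration = NULL) {
  contextualize(pkn, phenotypes, scored_genes, known_genes, config,
                method = "random", on_iteration = on_iteration)
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("optimization_result (%s): best f = %.4f after %d generation(s), %d evaluations\n",
              x$method, max(x$trace$best_f), max(x$trace$iteration), x$n_evaluations))
  invisible(x)
}

#' Exhaustively score every subnetwork of a small PKN
#'
#' Brute-force oracle for small instances: enumerates all `2^E` edge subsets
#' and scores each. Refuses PKNs with more than `max_edges` edges.
#'
#' @inheritParams contextualize
#' @param max_edges safety cap on the enumeration size (default 16)
#' @param init_policy,max_steps,inputs_hold_state as in [score_subnetwork()]
#' @return list with `best_f`, `best_network` (first maximizer in enumeration
#'   order), and `scores` (numeric vector of length `2^E`)
#' @export
enumerate_subnetworks <- function(pkn, phenotypes, scored_genes = NULL,
                                  known_genes = NULL, init_policy = "zero",
                                  max_steps = 1000L, inputs_hold_state = TRUE,
                                  max_edges = 16L) {
  E <- n_edges(pkn)
  if (E > max_edges) stop("PKN has ", E, " edges; enumeration capped at ", max_edges)
  pre <- pkn_precompute(pkn, inputs_hold_state)
  if (is.null(scored_genes)) scored_genes <- intersect(ph_genes(phenotypes), pre$nodes)
  scores <- numeric(2^E)
  best_f <- -Inf; best_mask <- NULL
  for (k in seq_len(2^E) - 1L) {
    mask <- as.logical(bitwAnd(bitwShiftR(k, seq_len(E) - 1L), 1L))
    f <- score_subnetwork(pkn, NULL, phenotypes, scored_genes = scored_genes,
                          known_genes = known_genes, init_policy = init_policy,
                          max_steps = max_steps,
                          rules = rules_from_mask(pre, mask))$f
    scores[k + 1L] <- f
    if (f > best_f) { best_f <- f; best_mask <- mask }
  }
  list(best_f = best_f, best_network = subnet_from_mask(pre, best_mask),
       scores = scores)
}
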