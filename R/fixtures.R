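#' Generate a planted-truth benchmark instance
#'
#' Emulates the benchmark design used to validate contextualization: a
#' consistent "gold standard" regulatory network whose Boolean model has the
#' two training phenotypes as exact fixed points, blindly expanded with
#' additional edges, at least some of which are inconsistent with the
#' phenotypes, so that the full PKN no longer explains them perfectly. The
#' optimizer's task is to recover a perfectly scoring subnetwork.
#'
#' Construction: a phenotype vector is drawn over `n_nodes` genes
#' (`n_inputs` of them in-degree-0 external inputs); the true network is then
#' built so that this vector AND its bitwise complement are fixed points by
#' construction — every non-input node receives at least one activator from a
#' gene sharing its phenotype state, preferentially one already wired so that
#' regulation cascades outward from the inputs, and optional extra consistent edges
#' (same-state activations, cross-state inhibitions) up to `n_true_edges`.
#' The two complementary fixed points become the phenotype pair (they differ
#' on every node, satisfying the far-apart requirement). Spurious edges are
#' then added one at a time — drawn with the same activation:inhibition ratio
#' as the true network, never targeting input nodes — and an addition is
#' rejected whenever the expanded PKN would still have both phenotypes as
#' exact fixed points; the planted subnetwork therefore scores exactly 1
#' while the full PKN scores below 1.
#'
#' `n_spurious = 0` is a degenerate mode (PKN = true network, PKN itself
#' scores 1) intended only for engine tests; the instance is flagged.
#'
#' @param n_nodes number of genes (>= 3)
#' @param n_true_edges edges of the planted network (>= `n_nodes - n_inputs`,
#'   one incoming activator per regulated node)
#' @param n_spurious context-inconsistent expansion edges
#' @param n_inputs in-degree-0 input nodes (>= 1, < `n_nodes`)
#' @param seed integer seed; the construction is fully deterministic given it
#' @param activation_ratio fraction of activating edges among the optional
#'   consistent extras (default 0.7, a typical literature-network sign
#'   balance)
#' @return object of class `planted_instance`: `pkn`, `true_subnetwork`,
#'   `phenotypes` (two complementary fixed points, named `initial`/`final`),
#'   `spurious_edges` (data.frame), `seed`, `degenerate`
#' @export
generate_planted <- function(n_nodes = 8L, n_true_edges = 8L, n_spurious = 4L,
                             n_inputs = 2L, seed = 1L, activation_ratio = 0.7) {
  stopifnot(n_nodes >= 3L, n_inputs >= 1L, n_inputs < n_nodes,
            n_true_edges >= n_nodes - n_inputs, n_spurious >= 0L)
  set.seed(as.integer(seed))
  nodes <- sprintf("g%02d", seq_len(n_nodes))
  inputs <- sort(sample(nodes, n_inputs))
  regulated <- setdiff(nodes, inputs)

  ## phenotype vector with both states represented; when there are >= 2
  ## inputs, both states must appear among them, so that every regulated node
  ## can ultimately be driven from the external inputs
  repeat {
    phi <- stats::setNames(as.integer(stats::runif(n_nodes) < 0.5), nodes)
    if (length(unique(phi)) != 2L) next
    if (n_inputs >= 2L && length(unique(phi[inputs])) != 2L) next
    break
  }

  same_state  <- function(v) nodes[phi == phi[[v]] & nodes != v]
  cross_state <- function(v) nodes[phi != phi[[v]]]

  ## backbone: one consistent activator per regulated node, preferring
  ## already-wired nodes (inputs first) so regulation cascades from the
  ## external inputs; self-loop only if no other gene shares the state
  wired <- inputs
  edges <- do.call(rbind, lapply(sample(regulated), function(v) {
    cand <- intersect(same_state(v), wired)
    if (!length(cand)) cand <- same_state(v)
    src <- if (length(cand)) sample(cand, 1L) else v
    wired <<- c(wired, v)
    data.frame(from = src, sign = 1L, to = v, stringsAsFactors = FALSE)
  }))

  ## optional extra consistent edges: same-state activation or cross-state
  ## inhibition into a regulated node
  consistent_pool <- do.call(rbind, lapply(regulated, function(v) {
    rbind(
      if (length(same_state(v)))
        data.frame(from = same_state(v), sign = 1L, to = v, stringsAsFactors = FALSE),
      data.frame(from = cross_state(v), sign = -1L, to = v, stringsAsFactors = FALSE)
    )
  }))
  consistent_pool <- consistent_pool[!(edge_keys_df(consistent_pool) %in%
                                         edge_keys_df(edges)), , drop = FALSE]
  n_extra <- n_true_edges - nrow(edges)
  if (n_extra > nrow(consistent_pool))
    stop("n_true_edges too large for this instance size; at most ",
         nrow(edges) + nrow(consistent_pool), " consistent edges exist")
  if (n_extra > 0) {
    w <- ifelse(consistent_pool$sign > 0, activation_ratio, 1 - activation_ratio)
    pick <- sample(nrow(consistent_pool), n_extra, prob = w)
    edges <- rbind(edges, consistent_pool[pick, , drop = FALSE])
  }
  true_net <- signed_digraph(edges, nodes = nodes)

  phen <- phenotype_set(cbind(initial = phi, final = 1L - phi))

  ## expansion: random signed edges into regulated nodes, same sign balance
  ## as the true network; reject any addition under which the cumulative PKN
  ## still has both phenotypes as exact fixed points
  p_act <- mean(true_net$edges$sign > 0)
  pkn_edges <- true_net$edges
  spurious <- pkn_edges[0, ]
  budget <- 200L * max(1L, n_spurious)
  both_fixed <- function(edf) {
    rules <- build_rules(signed_digraph(edf, nodes = nodes))
    all(vapply(seq_len(2), function(i) {
      st <- get_phenotype(phen, i)
      identical(unname(update_state(rules, st)), unname(as.integer(st[rules$nodes])))
    }, logical(1)))
  }
  while (nrow(spurious) < n_spurious && budget > 0L) {
    budget <- budget - 1L
    cand <- data.frame(from = sample(nodes, 1L),
                       sign = if (stats::runif(1) < p_act) 1L else -1L,
                       to = sample(regulated, 1L), stringsAsFactors = FALSE)
    if (edge_keys_df(cand) %in% edge_keys_df(pkn_edges)) next
    trial <- rbind(pkn_edges, cand)
    if (both_fixed(trial)) next
    pkn_edges <- trial
    spurious <- rbind(spurious, cand)
  }
  if (nrow(spurious) < n_spurious)
    stop("spurious-edge budget exhausted; try different instance sizes")
  pkn <- signed_digraph(pkn_edges, nodes = nodes)

  structure(list(pkn = pkn, true_subnetwork = true_net, phenotypes = phen,
                 spurious_edges = spurious, seed = as.integer(seed),
                 inputs = inputs, degenerate = n_spurious == 0L),
            class = "planted_instance")
}

#' @export
print.planted_instance <- function(x, ...) {
  cat(sprintf("planted_instance (seed %d): %d nodes, true %d + spurious %d = %d PKN edges%s\n",
              x$seed, length(x$pkn$nodes), n_edges(x$true_subnetwork),
              nrow(x$spurious_edges), n_edges(x$pkn),
              if (x$degenerate) " [degenerate: no spurious edges]" else ""))
  invisible(x)
}

#' Write a planted instance to a directory
#'
#' Emits `pkn.sif`, `true.sif`, `phenotypes.tsv` and `meta.json` (the seed,
#' sizes and input-node list needed to regenerate the instance).
#'
#' @param instance a `planted_instance`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_planted <- function(instance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(instance$pkn, file.path(dir, "pkn.sif"))
  write_network(instance$true_subnetwork, file.path(dir, "true.sif"))
  write_phenotypes(instance$phenotypes, file.path(dir, "phenotypes.tsv"))
  meta <- sprintf(
    '{"seed": %d, "n_nodes": %d, "n_true_edges": %d, "n_spurious": %d, "inputs": [%s], "degenerate": %s}',
    instance$seed, length(instance$pkn$nodes), n_edges(instance$true_subnetwork),
    nrow(instance$spurious_edges),
    paste(sprintf('"%s"', instance$inputs), collapse = ", "),
    if (instance$degenerate) "true" else "false")
  writeLines(meta, file.path(dir, "meta.json"))
  invisible(dir)
}

#' The didactic three-node Boolean system
#'
#' A tiny system with bespoke logic functions — `a = b AND c`, `b = NOT b`,
#' `c = a OR b` — encoded as the polynomial updates `a' = b*c`, `b' = 1-b`,
#' `c' = a + b - a*b`. Because of the negation self-loop on `b` it has no
#' fixed point: every one of its 8 states leads to a cyclic attractor. Used
#' to exercise the polynomial encoding and cycle detection. Note the AND
#' gate: PKN-derived rules always use OR over activators, so this system is
#' expressed as explicit update functions rather than a [build_rules()]
#' product.
#'
#' @return object of class `polynomial_rules` usable with [update_state()]
#'   and [run_to_attractor()]; its `polynomials` field holds the printable
#'   system
#' @export
toy_boolean_system <- function() {
  structure(list(
    nodes = c("a", "b", "c"),
    update = function(x) {
      c(a = x[["b"]] * x[["c"]],
        b = 1L - x[["b"]],
        c = x[["a"]] + x[["b"]] - x[["a"]] * x[["b"]])
    },
    polynomials = c(a = "b*c", b = "1-b", c = "a+b-(a*b)")
  ), class = "polynomial_rules")
}

#' Edge list of the didactic three-node system's wiring
#'
#' The signed digraph underlying [toy_boolean_system()]: b and c activate a,
#' b inhibits itself, and a and b activate c. Deriving PKN rules from this
#' topology yields OR-of-activators logic for node a, illustrating how the
#' inhibitor-dominant rule differs from the system's bespoke AND gate.
#'
#' @return a `signed_digraph` with 3 nodes and 5 edges
#' @export
toy_boolean_network <- function() {
  signed_digraph(data.frame(
    from = c("b", "c", "b", "a", "b"),
    sign = c(1L, 1L, -1L, 1L, 1L),
    to   = c("a", "a", "b", "c", "c"),
    stringsAsFactors = FALSE))
}
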